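# Shared fixtures, built in code at test time.

# Small planted-signal table plus its holdout split and full-feature baseline.
make_fixture <- function(n = c(20L, 20L, 20L), d = 30L, k = 6L, sep = 2,
                         seed = 1L) {
  syn <- make_synthetic_features(synthetic_spec(
    n_per_class = n, d_total = d, k_informative = k, separation = sep,
    seed = seed))
  split <- stratified_holdout(syn$table$labels, 0.2, seed = seed)
  list(table = syn$table, truth = syn$truth_mask, split = split)
}

# Exhaustive enumeration of all non-empty masks over d <= 16 features:
# the independent optimum oracle (no optimizer code involved).
brute_force_optimum <- function(table, split, config = cost_config()) {
  d <- ncol(table$matrix)
  stopifnot(d <= 16L)
  fitness <- make_fitness(table, split, config)
  best <- Inf
  best_mask <- NULL
  for (m in seq_len(2^d - 1L)) {
    mask <- as.integer(intToBits(m)[seq_len(d)])
    cost <- fitness(mask)$cost
    if (cost < best) {
      best <- cost
      best_mask <- mask
    }
  }
  list(cost = best, mask = best_mask)
}

# Reported mean holdout accuracies (%) of the equilibrium-optimizer-selected
# deep features, per backbone (benchmark reference values).
eo_reported_accuracy <- function() {
  read.csv(system.file("extdata", "eo_reported_accuracy.csv", package = "budl"),
           stringsAsFactors = FALSE)
}
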