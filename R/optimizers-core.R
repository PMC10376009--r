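#' Supported optimization algorithms
#'
#' Ten population-based metaheuristics operating on continuous positions in
#' `[0,1]^d`: marine predators algorithm (`mpa`), generalized normal
#' distribution optimization (`gndo`), slime mould algorithm (`sma`),
#' equilibrium optimizer (`eo`), manta-ray foraging optimization (`mrfo`),
#' atom search optimization (`aso`), Harris hawks optimization (`hho`),
#' Henry gas solubility optimization (`hgso`), pathfinder algorithm (`pfa`)
#' and poor-and-rich optimization (`pro`).
#'
#' @return Character vector of the ten algorithm identifiers.
#' @export
optimizer_algorithms <- function() {
  c("mpa", "gndo", "sma", "eo", "mrfo", "aso", "hho", "hgso", "pfa", "pro")
}

#' Optimizer run configuration
#'
#' @param algorithm one of [optimizer_algorithms()].
#' @param population_size number of search agents (default 10).
#' @param max_iterations iteration budget (default 100).
#' @param seed integer RNG seed for the whole run.
#' @param threshold binarization cut on continuous positions (default 0.5).
#' @param algo_params named list overriding algorithm-specific constants
#'   (e.g. `list(fads = 0.2)` for MPA, `list(a1 = 2, a2 = 1)` for EO).
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(algorithm, population_size = 10L,
                             max_iterations = 100L, seed = 1L,
                             threshold = 0.5, algo_params = list()) {
  algorithm <- match_algorithm(algorithm)
  stopifnot(population_size >= 2, max_iterations >= 1,
            threshold > 0, threshold < 1)
  structure(list(algorithm = algorithm,
                 population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 lower_bound = 0, upper_bound = 1,
                 seed = as.integer(seed), threshold = threshold,
                 algo_params = algo_params),
            class = "optimizer_config")
}

match_algorithm <- function(algorithm) {
  algorithm <- tolower(algorithm)
  if (!algorithm %in% optimizer_algorithms()) {
    stop(sprintf("unknown algorithm '%s'; valid algorithms: %s",
                 algorithm, paste(optimizer_algorithms(), collapse = ", ")),
         call. = FALSE)
  }
  algorithm
}

#' Binarize a continuous position into a feature mask
#'
#' A coordinate maps to 1 iff it is strictly greater than `threshold`.
#'
#' @param position numeric vector or matrix with values in `[0,1]`.
#' @param threshold cut point in (0,1); default 0.5.
#' @return Integer 0/1 vector (or matrix) of the same shape.
#' @export
binarize <- function(position, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  m <- (position > threshold) + 0L
  m
}

#' Repair an empty feature mask
#'
#' An all-zero mask cannot be scored (no features to train on); repair
#' activates exactly one uniformly chosen bit. Non-empty masks pass through
#' unchanged.
#'
#' @param mask integer 0/1 vector.
#' @return A 0/1 vector with at least one active bit.
#' @export
repair_mask <- function(mask) {
  if (sum(mask) == 0L) mask[sample.int(length(mask), 1L)] <- 1L
  mask
}

# Evaluator environments ------------------------------------------------

# Binary mode: positions -> clip -> binarize -> repair -> SVM fitness.
# Tracks the best-ever payload so elitism holds for every update scheme.
make_mask_evaluator <- function(fitness, d, threshold = 0.5) {
  ev <- new.env(parent = emptyenv())
  ev$best_cost <- Inf
  ev$best_fit <- NULL
  ev$best_mask <- NULL
  ev$best_position <- NULL
  ev$n_evals <- 0L
  ev$eval <- function(P) {
    P <- clip01(as.matrix(P))
    n <- nrow(P)
    costs <- numeric(n)
    for (i in seq_len(n)) {
      mask <- repair_mask(binarize(P[i, ], threshold))
      fit <- fitness(mask)
      costs[i] <- fit$cost
      ev$n_evals <- ev$n_evals + 1L
      if (fit$cost < ev$best_cost) {
        ev$best_cost <- fit$cost
        ev$best_fit <- fit
        ev$best_mask <- mask
        ev$best_position <- P[i, ]
      }
    }
    list(P = P, costs = costs)
  }
  ev
}

# Continuous mode: raw objective on [0,1]^d (optimizer test harness).
make_continuous_evaluator <- function(fn, d) {
  ev <- new.env(parent = emptyenv())
  ev$best_cost <- Inf
  ev$best_fit <- NULL
  ev$best_mask <- NULL
  ev$best_position <- NULL
  ev$n_evals <- 0L
  ev$eval <- function(P) {
    P <- clip01(as.matrix(P))
    costs <- apply(P, 1L, fn)
    ev$n_evals <- ev$n_evals + nrow(P)
    i <- which.min(costs)
    if (costs[i] < ev$best_cost) {
      ev$best_cost <- costs[i]
      ev$best_position <- P[i, ]
    }
    list(P = P, costs = costs)
  }
  ev
}

#' Initialize a population of search agents
#'
#' Agents start at i.i.d. uniform positions in `[0,1]^d`; each position is
#' binarized, repaired and evaluated (binary mode) or scored directly
#' (continuous mode).
#'
#' @param d search dimensionality.
#' @param config an [optimizer_config()].
#' @param evaluator evaluator environment as built internally by
#'   [run_optimizer()] / [optimize_continuous()].
#' @return Population state: positions, costs, per-algorithm scratch space.
#' @keywords internal
initialize_population <- function(d, config, evaluator) {
  P <- matrix(stats::runif(config$population_size * d),
              config$population_size, d)
  res <- evaluator$eval(P)
  list(P = res$P, costs = res$costs, aux = new.env(parent = emptyenv()))
}

#' Apply one iteration of a named update scheme
#'
#' Dispatches to the canonical position-update equations of the requested
#' algorithm (see [optimizer_algorithms()]). Positions are clipped to the box,
#' binarized, repaired and evaluated inside the scheme via the evaluator;
#' the global best is never lost (elitism).
#'
#' @param algorithm algorithm identifier.
#' @param state population state from [initialize_population()].
#' @param evaluator evaluator environment.
#' @param t current iteration (1-based).
#' @param T_max iteration budget.
#' @param config an [optimizer_config()].
#' @return Updated population state.
#' @keywords internal
update_population <- function(algorithm, state, evaluator, t, T_max, config) {
  algorithm <- match_algorithm(algorithm)
  fn <- .UPDATE_FNS[[algorithm]]
  st <- fn(state$P, state$costs, evaluator, t, T_max, state$aux,
           config$algo_params)
  state$P <- st$P
  state$costs <- st$costs
  state
}

# Shared driver for both modes.
run_search <- function(evaluator, d, config, binary = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  trace <- with_seed(config$seed, {
    state <- initialize_population(d, config, evaluator)
    T_max <- config$max_iterations
    tr <- vector("list", T_max)
    for (t in seq_len(T_max)) {
      state <- update_population(config$algorithm, state, evaluator, t,
                                 T_max, config)
      tr[[t]] <- if (binary) {
        data.frame(iteration = t, best_cost = evaluator$best_cost,
                   best_accuracy = evaluator$best_fit$accuracy,
                   best_n_selected = evaluator$best_fit$n_selected)
      } else {
        data.frame(iteration = t, best_cost = evaluator$best_cost)
      }
    }
    do.call(rbind, tr)
  })
  list(trace = trace, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Run a binary metaheuristic over the features of a table
#'
#' Searches the space of feature masks for the subset minimizing the weighted
#' accuracy/feature-ratio cost (see [wrapper_cost()]): continuous agents in
#' `[0,1]^d` are binarized at 0.5, repaired, and scored by a linear SVM on
#' the holdout split.
#'
#' @param table a [feature_table()].
#' @param split a [stratified_holdout()] over `table`'s labels.
#' @param cost_config a [cost_config()].
#' @param opt_config an [optimizer_config()].
#' @param settings SVM settings, see [svm_settings()].
#' @return A `selection_result` with fields `best_mask`, `best_cost`,
#'   `best_accuracy`, `n_selected`, `n_total`, `trace` (per-iteration best
#'   cost/accuracy/size), `elapsed_seconds`, `algorithm`, `seed`,
#'   `selected_feature_ids`, and `n_unique_evals`.
#' @examples
#' tab <- make_synthetic_features(synthetic_spec(n_per_class = c(20, 20, 20),
#'   d_total = 30, k_informative = 5, seed = 7))$table
#' sp <- stratified_holdout(tab$labels, 0.2, seed = 7)
#' res <- run_optimizer(tab, sp, cost_config(),
#'   optimizer_config("eo", max_iterations = 10, seed = 7))
#' res$best_accuracy
#' @export
run_optimizer <- function(table, split, cost_config = budl::cost_config(),
                          opt_config, settings = svm_settings()) {
  stopifnot(inherits(table, "feature_table"))
  d <- ncol(table$matrix)
  if (d == 0L) stop("feature table has zero features", call. = FALSE)
  if (nlevels(droplevels(table$labels)) < 2L) {
    stop("feature table must have at least two classes", call. = FALSE)
  }
  fitness <- make_fitness(table, split, cost_config, settings)
  ev <- make_mask_evaluator(fitness, d, opt_config$threshold)
  run <- run_search(ev, d, opt_config, binary = TRUE)
  fit <- ev$best_fit
  structure(list(
    best_mask = ev$best_mask,
    best_cost = ev$best_cost,
    best_accuracy = fit$accuracy,
    n_selected = fit$n_selected,
    n_total = fit$n_total,
    selected_feature_ids = table$feature_ids[ev$best_mask == 1L],
    trace = run$trace,
    elapsed_seconds = run$elapsed,
    algorithm = opt_config$algorithm,
    seed = opt_config$seed,
    n_unique_evals = fitness_stats(fitness)$fits
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %s (seed %d): cost %.6f, accuracy %.4f, %d/%d features, %.1fs\n",
    x$algorithm, x$seed, x$best_cost, x$best_accuracy, x$n_selected,
    x$n_total, x$elapsed_seconds))
  invisible(x)
}

#' Run an algorithm on a raw continuous objective
#'
#' Test harness mode: the objective is evaluated directly on the continuous
#' positions (no binarization), e.g. on the analytic benchmarks of
#' [benchmark_function()].
#'
#' @param fn objective `function(x) -> scalar` on `[0,1]^d`, minimized.
#' @param d dimensionality.
#' @param opt_config an [optimizer_config()].
#' @return List with `best_value`, `best_position`, `trace`,
#'   `elapsed_seconds`, `algorithm`, `seed`.
#' @export
optimize_continuous <- function(fn, d, opt_config) {
  ev <- make_continuous_evaluator(fn, d)
  run <- run_search(ev, d, opt_config, binary = FALSE)
  list(best_value = ev$best_cost, best_position = ev$best_position,
       trace = run$trace, elapsed_seconds = run$elapsed,
       algorithm = opt_config$algorithm, seed = opt_config$seed)
}
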