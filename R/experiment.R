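#' Configuration for a benchmark campaign
#'
#' Orchestrates the comparison protocol: `repeats` stratified splits, and for
#' every repeat each backbone table is optimized by each algorithm (plus an
#' all-ones full-feature baseline). One split is drawn per repeat and shared
#' across backbones and algorithms so columns are comparable.
#'
#' @param tables named list of [feature_table()] objects (one per backbone);
#'   all must share sample order and labels.
#' @param algorithms subset of [optimizer_algorithms()].
#' @param repeats number of repeated splits (default 10).
#' @param test_fraction holdout proportion (default 0.2).
#' @param cost a [cost_config()].
#' @param population_size,max_iterations optimizer budget per run.
#' @param base_seed seeds are derived as `base_seed + repeat index`.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param settings an [svm_settings()].
#' @return A `run_config` list.
#' @export
run_config <- function(tables, algorithms = optimizer_algorithms(),
                       repeats = 10L, test_fraction = 0.2,
                       cost = cost_config(), population_size = 10L,
                       max_iterations = 100L, base_seed = 1L,
                       out_dir = NULL, settings = svm_settings()) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)), repeats >= 1L)
  algorithms <- vapply(algorithms, match_algorithm, character(1))
  structure(list(tables = tables, algorithms = unname(algorithms),
                 repeats = as.integer(repeats), test_fraction = test_fraction,
                 cost = cost, population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 base_seed = as.integer(base_seed), out_dir = out_dir,
                 settings = settings),
            class = "run_config")
}

#' Run the full repeats x backbones x algorithms benchmark
#'
#' For each repeat a fresh stratified split is drawn; every backbone table is
#' then optimized by every algorithm, and the all-ones mask is scored as the
#' full-feature baseline. A failed cell is recorded as missing and the
#' campaign continues.
#'
#' @param config a [run_config()].
#' @return List with `runs` (per-run data.frame: repeat, backbone, algorithm,
#'   accuracy percent, n_selected, cost, elapsed seconds, seed),
#'   `accuracy_summary`, `nfeatures_summary` (mean +/- SD tables), and
#'   `timing_summary` (per-algorithm mean +/- SD elapsed seconds). When
#'   `config$out_dir` is set, writes `runs.csv`, the three summary CSVs and
#'   per-run JSON under `runs/`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  labels <- config$tables[[1]]$labels
  for (tab in config$tables) {
    if (!identical(as.character(tab$labels), as.character(labels))) {
      stop("all backbone tables must share labels and sample order", call. = FALSE)
    }
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- list()
  for (r in seq_len(config$repeats)) {
    seed_r <- config$base_seed + r
    split <- stratified_holdout(labels, config$test_fraction, seed = seed_r)
    for (bk in names(config$tables)) {
      tab <- config$tables[[bk]]
      base <- evaluate_mask(tab, split, rep(1L, ncol(tab$matrix)),
                            config$cost, config$settings)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_idx = r, backbone = bk, algorithm = "full_features",
        accuracy_pct = 100 * base$accuracy, n_selected = base$n_total,
        cost = base$cost, elapsed_seconds = 0, seed = seed_r)
      for (alg in config$algorithms) {
        res <- tryCatch(
          run_optimizer(tab, split, config$cost,
                        optimizer_config(alg, config$population_size,
                                         config$max_iterations, seed = seed_r),
                        config$settings),
          error = function(e) {
            warning(sprintf("cell failed (repeat %d, %s, %s): %s", r, bk, alg,
                            conditionMessage(e)), call. = FALSE)
            NULL
          })
        row <- if (is.null(res)) {
          data.frame(repeat_idx = r, backbone = bk, algorithm = alg,
                     accuracy_pct = NA_real_, n_selected = NA_integer_,
                     cost = NA_real_, elapsed_seconds = NA_real_, seed = seed_r)
        } else {
          if (!is.null(out_dir)) {
            jsonlite::write_json(
              res[c("algorithm", "seed", "best_cost", "best_accuracy",
                    "n_selected", "n_total", "selected_feature_ids",
                    "elapsed_seconds")],
              file.path(out_dir, "runs",
                        sprintf("run_r%02d_%s_%s.json", r, bk, alg)),
              auto_unbox = TRUE, digits = NA)
          }
          data.frame(repeat_idx = r, backbone = bk, algorithm = alg,
                     accuracy_pct = 100 * res$best_accuracy,
                     n_selected = res$n_selected, cost = res$best_cost,
                     elapsed_seconds = res$elapsed_seconds, seed = seed_r)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  runs <- do.call(rbind, rows)
  out <- c(list(runs = runs), summarize_runs(runs))
  if (!is.null(out_dir)) {
    utils::write.csv(runs, file.path(out_dir, "runs.csv"), row.names = FALSE)
    utils::write.csv(out$accuracy_summary,
                     file.path(out_dir, "accuracy_summary.csv"))
    utils::write.csv(out$nfeatures_summary,
                     file.path(out_dir, "nfeatures_summary.csv"))
    utils::write.csv(out$timing_summary,
                     file.path(out_dir, "timing_summary.csv"), row.names = FALSE)
  }
  out
}

# mean +/- sample SD (n-1 denominator) cell string; SD prints 0 for n = 1.
fmt_pm <- function(x, digits) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  s <- if (length(x) > 1L) stats::sd(x) else 0
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), mean(x), s)
}

#' Summarize per-run benchmark results into mean +/- SD tables
#'
#' @param runs per-run data.frame as produced by [run_benchmark()] (or read
#'   back from its `runs.csv`).
#' @return List of `accuracy_summary` (percent, 1 decimal),
#'   `nfeatures_summary` (integer counts) — backbones in rows, algorithms in
#'   columns with the full-feature baseline last — and `timing_summary`
#'   (per-algorithm mean +/- SD of elapsed seconds).
#' @export
summarize_runs <- function(runs) {
  stopifnot(nrow(runs) >= 1L)
  backbones <- unique(runs$backbone)
  algs <- setdiff(unique(runs$algorithm), "full_features")
  cols <- c(algs, "full_features")
  cell <- function(bk, alg, var, digits) {
    fmt_pm(runs[[var]][runs$backbone == bk & runs$algorithm == alg], digits)
  }
  acc <- sapply(cols, function(a) sapply(backbones, cell, a, "accuracy_pct", 1))
  nf <- sapply(cols, function(a) sapply(backbones, cell, a, "n_selected", 0))
  acc <- matrix(acc, length(backbones), length(cols),
                dimnames = list(backbones, cols))
  nf <- matrix(nf, length(backbones), length(cols),
               dimnames = list(backbones, cols))
  timing <- do.call(rbind, lapply(algs, function(a) {
    el <- runs$elapsed_seconds[runs$algorithm == a & !is.na(runs$elapsed_seconds)]
    data.frame(algorithm = a, mean_seconds = mean(el),
               sd_seconds = if (length(el) > 1L) stats::sd(el) else 0)
  }))
  list(accuracy_summary = as.data.frame(acc),
       nfeatures_summary = as.data.frame(nf),
       timing_summary = timing)
}

#' Summarize a stored benchmark results directory
#'
#' @param results_dir directory containing a `runs.csv` written by
#'   [run_benchmark()].
#' @return Same value as [summarize_runs()].
#' @export
summarize_results_dir <- function(results_dir) {
  path <- file.path(results_dir, "runs.csv")
  if (!file.exists(path)) stop("no runs.csv under ", results_dir, call. = FALSE)
  summarize_runs(utils::read.csv(path, stringsAsFactors = FALSE))
}
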