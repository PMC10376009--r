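#' Cost configuration for wrapper-based selection
#'
#' The wrapper minimizes
#' \deqn{M = \phi\,(1 - \mathrm{Accuracy}) + \gamma\,\frac{n_{selected}}{n_{total}}}
#' blending holdout classification error with the selected-feature ratio.
#' Defaults weight accuracy heavily: `phi = 0.99`, `gamma = 0.01`.
#'
#' @param phi non-negative weight on the error term.
#' @param gamma non-negative weight on the feature-ratio term.
#' @return A `cost_config` list.
#' @export
cost_config <- function(phi = 0.99, gamma = 0.01) {
  stopifnot(phi >= 0, gamma >= 0)
  structure(list(phi = phi, gamma = gamma), class = "cost_config")
}

#' Weighted accuracy/feature-ratio cost
#'
#' @param accuracy holdout accuracy in `[0,1]`.
#' @param n_selected number of active features (>= 1).
#' @param n_total total number of features.
#' @param config a [cost_config()].
#' @return `phi * (1 - accuracy) + gamma * n_selected / n_total`; lies in
#'   `[0,1]` whenever `phi + gamma = 1`.
#' @examples
#' wrapper_cost(1.0, 1, 100)            # only the ratio term remains
#' wrapper_cost(0.9679, 562, 2048)      # a published operating point
#' @export
wrapper_cost <- function(accuracy, n_selected, n_total, config = cost_config()) {
  stopifnot(all(accuracy >= 0), all(accuracy <= 1),
            all(n_selected <= n_total))
  if (any(n_selected < 1)) stop("n_selected must be at least 1", call. = FALSE)
  config$phi * (1 - accuracy) + config$gamma * n_selected / n_total
}

#' Stratified holdout split
#'
#' Each class contributes `round(count * test_fraction)` samples to the test
#' set (half counts round up, i.e. toward the larger test set), capped so at
#' least one training sample per class remains. Deterministic given `seed`.
#'
#' @param labels factor/character vector of class labels.
#' @param test_fraction proportion held out, in (0,1); default 0.2.
#' @param seed integer seed.
#' @return A `holdout_split` with `train_indices`, `test_indices`,
#'   `test_fraction`, `seed`.
#' @examples
#' lab <- rep(c("benign", "malignant", "normal"), c(437, 210, 133))
#' sp <- stratified_holdout(lab, 0.2, seed = 1)
#' length(sp$test_indices)  # 87 + 42 + 27 = 156
#' @export
stratified_holdout <- function(labels, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop(sprintf("class '%s' has fewer than 2 samples",
                 names(counts)[which(counts < 2L)[1]]), call. = FALSE)
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      n_test <- floor(length(idx) * test_fraction + 0.5)  # half rounds up
      n_test <- min(n_test, length(idx) - 1L)
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  structure(list(train_indices = setdiff(seq_along(labels), test_idx),
                 test_indices = test_idx,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "holdout_split")
}

#' SVM settings for fitness evaluation
#'
#' Defaults follow common practice for a small multiclass problem: linear
#' kernel, regularization constant `C = 1`, one-vs-one multiclass (the libsvm
#' default), with feature standardization fit on the training split.
#'
#' @param kernel SVM kernel, passed to [e1071::svm()].
#' @param C regularization constant.
#' @param standardize standardize masked columns using train-split mean/SD
#'   (constant columns map to zero).
#' @param cache cache fitness results keyed by mask bits.
#' @return An `svm_settings` list.
#' @export
svm_settings <- function(kernel = "linear", C = 1, standardize = TRUE,
                         cache = TRUE) {
  structure(list(kernel = kernel, C = C, standardize = standardize,
                 cache = cache), class = "svm_settings")
}

#' Score one feature mask with an SVM on the holdout split
#'
#' Masked columns are standardized with training-split statistics, a
#' multiclass SVM is fit on the masked training rows, and holdout accuracy is
#' blended with the feature-ratio penalty via [wrapper_cost()]. Deterministic for
#' fixed inputs.
#'
#' @param table a [feature_table()].
#' @param split a [stratified_holdout()].
#' @param mask 0/1 vector of length `ncol(table$matrix)` with >= 1 active bit.
#' @param config a [cost_config()].
#' @param settings an [svm_settings()].
#' @return A `fitness_result`: `cost`, `accuracy`, `n_selected`, `n_total`.
#' @export
evaluate_mask <- function(table, split, mask, config = cost_config(),
                          settings = svm_settings()) {
  stopifnot(inherits(table, "feature_table"))
  n_total <- ncol(table$matrix)
  if (length(mask) != n_total) {
    stop("mask length must equal the number of features", call. = FALSE)
  }
  sel <- which(mask != 0)
  if (length(sel) == 0L) stop("empty subset: mask has no active features", call. = FALSE)

  Xtr <- table$matrix[split$train_indices, sel, drop = FALSE]
  Xte <- table$matrix[split$test_indices, sel, drop = FALSE]
  ytr <- droplevels(table$labels[split$train_indices])
  yte <- table$labels[split$test_indices]

  if (settings$standardize) {
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2L, stats::sd)
    keep_scale <- sdv > 0
    Xtr <- sweep(Xtr, 2L, mu, "-")
    Xte <- sweep(Xte, 2L, mu, "-")
    Xtr[, keep_scale] <- sweep(Xtr[, keep_scale, drop = FALSE], 2L,
                               sdv[keep_scale], "/")
    Xte[, keep_scale] <- sweep(Xte[, keep_scale, drop = FALSE], 2L,
                               sdv[keep_scale], "/")
    Xtr[, !keep_scale] <- 0  # constant train columns standardize to zero
    Xte[, !keep_scale] <- 0
  }
  model <- e1071::svm(x = Xtr, y = ytr, kernel = settings$kernel,
                      cost = settings$C, scale = FALSE)
  pred <- stats::predict(model, Xte)
  accuracy <- mean(as.character(pred) == as.character(yte))
  structure(list(cost = wrapper_cost(accuracy, length(sel), n_total, config),
                 accuracy = accuracy, n_selected = length(sel),
                 n_total = n_total),
            class = "fitness_result")
}

#' Build a cached fitness evaluator
#'
#' Binds a table, split and configuration into a `function(mask) ->
#' fitness_result` for the optimizer loop. Results are cached keyed by the
#' mask bits, so re-evaluating an unchanged agent costs nothing.
#'
#' @inheritParams evaluate_mask
#' @return A callable; inspect evaluation counters with [fitness_stats()].
#' @export
make_fitness <- function(table, split, config = cost_config(),
                         settings = svm_settings()) {
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$calls <- 0L
  env$fits <- 0L
  f <- function(mask) {
    env$calls <- env$calls + 1L
    key <- paste(as.integer(mask != 0), collapse = "")
    if (settings$cache && !is.null(env$cache[[key]])) return(env$cache[[key]])
    fit <- evaluate_mask(table, split, mask, config, settings)
    env$fits <- env$fits + 1L
    if (settings$cache) env$cache[[key]] <- fit
    fit
  }
  attr(f, "env") <- env
  f
}

#' Evaluation counters of a fitness evaluator
#'
#' @param fitness a callable from [make_fitness()].
#' @return List with `calls` (total invocations) and `fits` (actual SVM fits).
#' @export
fitness_stats <- function(fitness) {
  env <- attr(fitness, "env")
  list(calls = env$calls, fits = env$fits)
}
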