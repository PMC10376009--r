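#' Summary of one optimized backbone run
#'
#' @param backbone backbone name.
#' @param algorithm optimizer identifier.
#' @param best_accuracy accuracy in percent (0-100).
#' @param feature_ids identifiers of the selected columns.
#' @return A `network_run_summary`.
#' @export
network_run_summary <- function(backbone, algorithm, best_accuracy,
                                feature_ids = character(0)) {
  stopifnot(best_accuracy >= 0, best_accuracy <= 100)
  structure(list(backbone = backbone, algorithm = algorithm,
                 best_accuracy = best_accuracy,
                 feature_ids = as.character(feature_ids)),
            class = "network_run_summary")
}

#' Select backbones clearing an accuracy threshold
#'
#' Keeps backbones whose optimized accuracy is strictly above
#' `threshold_pct` (the published rule is "above 94%", so exactly 94.0 is
#' excluded), sorted by accuracy descending. An empty result is allowed; the
#' caller decides how to proceed.
#'
#' @param summaries list of [network_run_summary()] objects.
#' @param threshold_pct accuracy threshold in percent, in (0, 100).
#' @return Character vector of backbone names.
#' @export
select_networks <- function(summaries, threshold_pct = 94) {
  stopifnot(length(summaries) > 0, threshold_pct > 0, threshold_pct < 100)
  acc <- vapply(summaries, `[[`, numeric(1), "best_accuracy")
  nm <- vapply(summaries, `[[`, character(1), "backbone")
  keep <- acc > threshold_pct
  nm[keep][order(acc[keep], decreasing = TRUE)]
}

#' Concatenate the selected features of several backbones
#'
#' Horizontally joins each summarized backbone's selected columns, keeping
#' provenance-tagged feature identifiers. All tables must share sample order
#' and labels.
#'
#' @param tables named list of per-backbone [feature_table()] objects.
#' @param summaries list of [network_run_summary()] objects naming the
#'   contributing backbones and their selected `feature_ids`.
#' @return A `feature_table` with an extra `contributing_networks` field
#'   (class `concat_features`).
#' @export
concatenate_selected <- function(tables, summaries) {
  if (length(summaries) == 0L) {
    stop("no network passed threshold: nothing to concatenate", call. = FALSE)
  }
  ref <- tables[[summaries[[1]]$backbone]]
  if (is.null(ref)) stop("missing table for backbone ", summaries[[1]]$backbone,
                         call. = FALSE)
  parts <- lapply(summaries, function(s) {
    tab <- tables[[s$backbone]]
    if (is.null(tab)) stop("missing table for backbone ", s$backbone, call. = FALSE)
    if (nrow(tab$matrix) != nrow(ref$matrix) ||
        !identical(as.character(tab$labels), as.character(ref$labels))) {
      stop("sample/label mismatch across backbone tables", call. = FALSE)
    }
    bad <- setdiff(s$feature_ids, tab$feature_ids)
    if (length(bad)) stop("unknown feature ids for ", s$backbone, ": ",
                          paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
    tab$matrix[, match(s$feature_ids, tab$feature_ids), drop = FALSE]
  })
  out <- feature_table(do.call(cbind, parts), ref$labels,
                       feature_ids = unlist(lapply(summaries, `[[`, "feature_ids")),
                       source = "concatenated selected features")
  out$contributing_networks <- vapply(summaries, `[[`, character(1), "backbone")
  class(out) <- c("concat_features", class(out))
  out
}

#' Train and score the final classifier on concatenated features
#'
#' Evaluates the full concatenated set with the SVM on the holdout split.
#' Optionally runs a second wrapper-optimization pass over the concatenated
#' columns first (`rerun`), reporting both.
#'
#' @param concat a [concatenate_selected()] result (or any [feature_table()]).
#' @param split a [stratified_holdout()].
#' @param config a [cost_config()].
#' @param settings an [svm_settings()].
#' @param rerun optional [optimizer_config()] for a second selection pass.
#' @return List with `fitness` (a `fitness_result` for the full concatenated
#'   set) and, when `rerun` is given, `selection` (a `selection_result`).
#' @export
final_classifier <- function(concat, split, config = cost_config(),
                             settings = svm_settings(), rerun = NULL) {
  stopifnot(inherits(concat, "feature_table"))
  fit <- evaluate_mask(concat, split, rep(1L, ncol(concat$matrix)),
                       config, settings)
  out <- list(fitness = fit)
  if (!is.null(rerun)) {
    out$selection <- run_optimizer(concat, split, config, rerun, settings)
  }
  out
}
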