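#' Construct a feature table
#'
#' The central data container: a numeric samples-by-features matrix with a
#' class label per row and a provenance identifier per column (conventionally
#' `"<backbone>:<index>"` for deep features).
#'
#' @param matrix numeric matrix, samples in rows.
#' @param labels factor or character vector of per-sample class labels.
#' @param feature_ids character vector of per-column identifiers; defaults to
#'   `"f0001"`-style names.
#' @param source free-text lineage of the table.
#' @return A `feature_table` object with fields `matrix`, `labels`,
#'   `feature_ids`, `source`.
#' @export
feature_table <- function(matrix, labels, feature_ids = NULL, source = "") {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  labels <- as.factor(labels)
  if (nrow(matrix) != length(labels)) {
    stop("number of rows must equal number of labels", call. = FALSE)
  }
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("f%04d", seq_len(ncol(matrix)))
  }
  if (ncol(matrix) != length(feature_ids)) {
    stop("number of columns must equal number of feature_ids", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique", call. = FALSE)
  if (!all(is.finite(matrix))) stop("feature matrix contains non-finite values", call. = FALSE)
  colnames(matrix) <- feature_ids
  structure(
    list(matrix = matrix, labels = labels,
         feature_ids = as.character(feature_ids), source = source),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features; classes: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s (%d)", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$matrix)

#' Write a feature table to CSV
#'
#' Column layout is `label,<feature_id_1>,...`; values are written with 15
#' significant digits so a round trip preserves them to better than 1e-12.
#'
#' @param t a `feature_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_feature_table()]
#' @export
save_feature_table <- function(t, path) {
  stopifnot(inherits(t, "feature_table"))
  df <- data.frame(label = as.character(t$labels), t$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Expects the layout written by [save_feature_table()]: a header line
#' `label,<feature_id_1>,...` followed by one row per sample. Malformed input
#' (missing header, ragged rows, non-numeric cells) raises an error locating
#' the offending line or cell.
#'
#' @param path CSV file path.
#' @param source lineage string recorded on the result; defaults to `path`.
#' @return A `feature_table`.
#' @export
load_feature_table <- function(path, source = path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no header: file is empty", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "label") {
    stop("malformed header: expected 'label,<feature_id>,...', got: ",
         lines[1], call. = FALSE)
  }
  if (length(lines) < 2L) stop("no data rows", call. = FALSE)
  ncol_exp <- length(header)
  cells <- strsplit(lines[-1], ",", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != ncol_exp)) {
    bad <- which(widths != ncol_exp)[1]
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad + 1L, ncol_exp, widths[bad]), call. = FALSE)
  }
  labels <- vapply(cells, `[[`, character(1), 1L)
  raw <- t(vapply(cells, function(r) r[-1], character(ncol_exp - 1L)))
  if (ncol_exp == 2L) raw <- matrix(raw, ncol = 1L)
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at line %d, column '%s'",
                 raw[idx[1], idx[2]], idx[1] + 1L, header[idx[2] + 1L]),
         call. = FALSE)
  }
  feature_table(num, labels, feature_ids = header[-1], source = source)
}
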