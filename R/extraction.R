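#' Load a folder-per-class image dataset
#'
#' Expects `root_dir` to contain one subdirectory per class holding PNG/JPEG
#' files (the layout of the public breast-ultrasound collections:
#' `benign/`, `malignant/`, `normal/`). Items are enumerated in sorted order;
#' every file is checked to decode.
#'
#' @param root_dir dataset root directory.
#' @return An `image_dataset`: `items` (data.frame of `path`, `label`,
#'   `grayscale`) and `classes` (sorted label set).
#' @export
load_image_dataset <- function(root_dir) {
  if (!dir.exists(root_dir)) stop("directory not found: ", root_dir, call. = FALSE)
  classes <- sort(basename(Filter(dir.exists, list.dirs(root_dir, recursive = FALSE))))
  if (length(classes) == 0L) stop("no class subdirectories in ", root_dir, call. = FALSE)
  items <- lapply(classes, function(cl) {
    files <- sort(list.files(file.path(root_dir, cl),
                             pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) {
      stop(sprintf("empty class directory: '%s'", cl), call. = FALSE)
    }
    gray <- vapply(files, function(f) {
      img <- tryCatch(decode_image(f), error = function(e) {
        stop(sprintf("cannot decode image '%s': %s", f, conditionMessage(e)),
             call. = FALSE)
      })
      length(dim(img)) == 2L || dim(img)[3] == 1L
    }, logical(1))
    data.frame(path = files, label = cl, grayscale = gray,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  structure(list(items = do.call(rbind, items), classes = classes),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset> %d images, classes: %s\n", nrow(x$items),
              paste(sprintf("%s (%d)", x$classes, table(x$items$label)[x$classes]),
                    collapse = ", ")))
  invisible(x)
}

# Decode PNG natively; JPEG requires EBImage (if installed).
decode_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(png::readPNG(path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG decoding requires the EBImage package", call. = FALSE)
    }
    return(as.array(EBImage::readImage(path)))
  }
  stop("unsupported image format: ", ext, call. = FALSE)
}

#' Construct an extraction backend
#'
#' A backend maps (image file, backbone spec) to the penultimate-layer
#' activation vector. The built-in `"mock"` backend produces deterministic
#' pseudo-features — a seeded hash of the image bytes and the backbone name
#' drives a uniform draw of length `feature_dim` — and satisfies the same
#' contract as a real backend, for tests and desk-scale runs. A `"real"`
#' backend requires a deep-learning runtime providing the registered
#' architectures with pretrained weights; supply one via `extract_one`.
#'
#' @param name `"mock"`, `"real"`, or a label for a custom backend.
#' @param seed integer seed mixed into the mock hash.
#' @param extract_one custom `function(path, spec) -> numeric(feature_dim)`;
#'   required for any backend other than `"mock"`.
#' @return An `extraction_backend`.
#' @export
extraction_backend <- function(name = "mock", seed = 0L, extract_one = NULL) {
  if (name == "mock" && is.null(extract_one)) {
    # Deterministic pseudo-activation: a byte-hash-seeded uniform draw offset
    # by the image's mean intensity, so feature rows reflect image content
    # (brighter lesions shift the whole row) while staying reproducible.
    extract_one <- function(path, spec) {
      bytes <- readBin(path, "raw", n = file.size(path))
      h <- (byte_hash(bytes) + byte_hash(charToRaw(spec$name)) +
              (as.integer(seed) %% 2147483647) * 2654435) %% 2147483647
      intensity <- mean(decode_image(path))
      intensity + 0.1 * with_seed(h, stats::runif(spec$feature_dim))
    }
  }
  if (is.null(extract_one)) {
    stop(sprintf(paste0(
      "backend '%s' is not available: no deep-learning runtime with ",
      "pretrained weights is bundled. Supply extract_one = function(path, ",
      "spec) returning the penultimate-layer activation, or use the 'mock' ",
      "backend for deterministic pseudo-features."), name), call. = FALSE)
  }
  structure(list(name = name, seed = as.integer(seed),
                 extract_one = extract_one),
            class = "extraction_backend")
}

#' Extract deep features for every image in a dataset
#'
#' Runs the backend over the dataset in order and assembles a
#' [feature_table()] whose column identifiers carry backbone provenance
#' (`"<backbone>:<index>"`). The registry's `feature_dim` is authoritative:
#' a backend returning a different length is a hard error.
#'
#' @param dataset an [load_image_dataset()] result.
#' @param spec a [backbone_spec()].
#' @param backend an [extraction_backend()].
#' @return A [feature_table()] with one row per image, in dataset order.
#' @export
extract_features <- function(dataset, spec, backend = extraction_backend("mock")) {
  stopifnot(inherits(dataset, "image_dataset"), inherits(spec, "backbone_spec"),
            inherits(backend, "extraction_backend"))
  rows <- lapply(dataset$items$path, function(p) {
    v <- backend$extract_one(p, spec)
    if (length(v) != spec$feature_dim) {
      stop(sprintf(
        "backend '%s' returned %d features for backbone '%s' but the registry pins %d",
        backend$name, length(v), spec$name, spec$feature_dim), call. = FALSE)
    }
    if (!all(is.finite(v))) {
      stop("backend returned non-finite activations for ", p, call. = FALSE)
    }
    v
  })
  feature_table(do.call(rbind, rows), dataset$items$label,
                feature_ids = sprintf("%s:%04d", spec$name,
                                      seq_len(spec$feature_dim)),
                source = sprintf("%s via %s backend", spec$name, backend$name))
}
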