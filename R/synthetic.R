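#' Specification for a synthetic feature table
#'
#' Desk-scale stand-in for deep-feature tables with known ground truth:
#' three classes by default (mirroring benign/malignant/normal), `k`
#' informative Gaussian columns whose class means are staggered by
#' `separation` standard deviations, and `d - k` class-independent noise
#' columns.
#'
#' @param n_per_class integer vector of per-class sample counts (>= 2 each).
#' @param d_total total number of feature columns.
#' @param k_informative number of informative columns (<= `d_total`).
#' @param separation between-class mean shift on informative columns, in SD
#'   units (class c mean = `(c-1) * separation`, unit SD).
#' @param noise_sd SD of the uninformative columns.
#' @param seed integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = c(50L, 50L, 50L), d_total = 200L,
                           k_informative = 10L, separation = 2.0,
                           noise_sd = 1.0, seed = 1L) {
  stopifnot(all(n_per_class >= 2L), k_informative <= d_total, separation >= 0,
            length(n_per_class) >= 2L)
  structure(list(n_per_class = as.integer(n_per_class),
                 d_total = as.integer(d_total),
                 k_informative = as.integer(k_informative),
                 separation = separation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic feature table with planted informative columns
#'
#' @param spec a [synthetic_spec()].
#' @return List with `table` (a [feature_table()]) and `truth_mask` (0/1
#'   vector marking the `k_informative` planted columns). Fully determined by
#'   the spec (including its seed).
#' @examples
#' out <- make_synthetic_features(synthetic_spec(seed = 42))
#' sum(out$truth_mask)  # 10
#' @export
make_synthetic_features <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n_classes <- length(spec$n_per_class)
    labels <- rep(sprintf("class%d", seq_len(n_classes)), spec$n_per_class)
    n <- length(labels)
    X <- matrix(stats::rnorm(n * spec$d_total, sd = spec$noise_sd),
                n, spec$d_total)
    info <- if (spec$k_informative > 0L) {
      sample.int(spec$d_total, spec$k_informative)
    } else integer(0)
    cls <- rep(seq_len(n_classes), spec$n_per_class)
    for (j in info) {
      X[, j] <- stats::rnorm(n, mean = (cls - 1L) * spec$separation, sd = 1)
    }
    truth <- integer(spec$d_total)
    truth[info] <- 1L
    list(table = feature_table(X, labels,
                               source = sprintf("synthetic (seed %d)", spec$seed)),
         truth_mask = truth)
  })
}

#' Generate a toy lesion image directory
#'
#' Writes grayscale PNGs in a folder-per-class layout consumable by
#' [load_image_dataset()]: `benign` images carry a smooth bright ellipse on a
#' speckled background, `malignant` an irregular star-shaped blob, and
#' `normal` speckle only. Byte-identical across runs for a fixed seed.
#'
#' @param counts named or unnamed integer vector `c(benign, malignant,
#'   normal)`.
#' @param out_dir output directory (created if needed).
#' @param size image side length in pixels (>= 64).
#' @param seed integer seed.
#' @return `out_dir`, invisibly.
#' @export
make_synthetic_images <- function(counts = c(benign = 4L, malignant = 2L,
                                             normal = 1L),
                                  out_dir = tempfile("busyn"), size = 64L,
                                  seed = 1L) {
  stopifnot(size >= 64L)
  if (is.null(names(counts))) names(counts) <- c("benign", "malignant", "normal")
  with_seed(seed, {
    for (cl in names(counts)) {
      dir.create(file.path(out_dir, cl), recursive = TRUE, showWarnings = FALSE)
      for (k in seq_len(counts[[cl]])) {
        img <- draw_lesion(cl, size)
        png::writePNG(img, file.path(out_dir, cl, sprintf("%s_%03d.png", cl, k)))
      }
    }
  })
  invisible(out_dir)
}

# Speckle background plus a class-specific lesion shape.
draw_lesion <- function(class, size) {
  img <- matrix(stats::runif(size * size, 0.2, 0.5), size, size)  # speckle
  if (class == "normal") return(img)
  cx <- stats::runif(1, 0.35, 0.65) * size
  cy <- stats::runif(1, 0.35, 0.65) * size
  # benign lesions are drawn larger and smoother than malignant ones, so the
  # three classes occupy distinct brightness/texture regimes by construction
  r0 <- if (class == "benign") stats::runif(1, 0.18, 0.25) * size
        else stats::runif(1, 0.10, 0.14) * size
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- t(xs)
  theta <- atan2(ys - cy, xs - cx)
  radius <- sqrt((xs - cx)^2 + (ys - cy)^2)
  edge <- if (class == "benign") {
    r0 * (1 + 0.1 * sin(2 * theta + stats::runif(1, 0, 2 * pi)))
  } else {
    # irregular star: strong angular modulation with random harmonics
    a <- stats::runif(3, 0.2, 0.45)
    ph <- stats::runif(3, 0, 2 * pi)
    r0 * (1 + a[1] * sin(5 * theta + ph[1]) + a[2] * sin(7 * theta + ph[2]) +
            a[3] * sin(3 * theta + ph[3]))
  }
  img[radius <= edge] <- stats::runif(sum(radius <= edge), 0.75, 0.95)
  img
}

#' Analytic benchmark objectives on the unit box
#'
#' Test harness for the continuous optimizers: `"sphere"` is
#' \eqn{f(x)=\sum x_i^2} with minimum 0 at the origin corner;
#' `"rastrigin-shifted"` is the standard Rastrigin function translated so its
#' global optimum sits at the interior point `x* = 0.25` in every coordinate.
#'
#' @param name `"sphere"` or `"rastrigin-shifted"`.
#' @return A `function(x) -> scalar` to minimize over `[0,1]^d`.
#' @examples
#' benchmark_function("sphere")(rep(1, 10))  # 10
#' @export
benchmark_function <- function(name) {
  switch(name,
    sphere = function(x) sum(x^2),
    `rastrigin-shifted` = function(x) {
      z <- (x - 0.25) * 5.12 / 0.75  # map the box so the optimum is interior
      sum(z^2 - 10 * cos(2 * pi * z) + 10)
    },
    stop("unknown benchmark '", name,
         "'; available: sphere, rastrigin-shifted", call. = FALSE)
  )
}
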