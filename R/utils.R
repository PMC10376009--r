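#' budl: wrapper-based deep-feature selection for breast ultrasound
#'
#' Deep features from pre-trained convolutional backbones (or synthetic
#' tables with planted ground truth) are pruned by ten binary population
#' metaheuristics minimizing a weighted holdout-SVM-error/feature-ratio
#' cost; backbones whose optimized accuracy clears a threshold are selected
#' and their features concatenated for a final classifier. See
#' `vignette("wrapper-feature-selection")` for the methodology.
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG state
#'
#' Seeds the R RNG, runs `expr`, and restores the caller's RNG state on exit,
#' so seeded package functions do not perturb user-level randomness.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Levy-flight step matrix (Mantegna's algorithm)
#'
#' Heavy-tailed random steps used by the long-jump phases of the marine
#' predators and Harris hawks schemes.
#'
#' @param n,d matrix dimensions.
#' @param beta stability index, default 1.5.
#' @keywords internal
levy_steps <- function(n, d, beta = 1.5) {
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- matrix(stats::rnorm(n * d, 0, sigma_u), n, d)
  v <- matrix(stats::rnorm(n * d), n, d)
  u / abs(v)^(1 / beta)
}

# Deterministic polynomial hash of raw bytes, in [0, 2^31 - 2].
# Base-31 rolling hash mod the Mersenne prime 2^31 - 1; all intermediates
# stay below 2^53 so double arithmetic is exact. Used to derive per-image
# seeds for the mock extraction backend.
byte_hash <- function(bytes) {
  p <- 2147483647
  b <- as.integer(bytes)
  h <- length(b) %% p
  for (x in b) h <- (h * 31 + x) %% p
  h
}
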