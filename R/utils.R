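#' @keywords internal
"_PACKAGE"

## Small internal helpers shared across modules.

clip01 <- function(x) pmin(pmax(x, 0), 1)

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a zero-variance vector")
  (x - mean(x)) / s
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_square <- function(m, what = "matrix") {
  if (!is_square(m)) {
    stop(sprintf("%s must be a square matrix, got %d x %d",
                 what, NROW(m), NCOL(m)))
  }
  invisible(m)
}

is_symmetric_num <- function(m, tol = 1e-10) {
  max(abs(m - t(m))) <= tol
}

## Deterministic sub-seeds below 2^31 derived from a master seed, so pipeline
## stages can be re-run independently yet reproducibly.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(template = 11L, calibrate = 101L, cohort = 211L,
               bootstrap = 307L, pilot = 401L, report = 503L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 2654435.0 + off * 97.0) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
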