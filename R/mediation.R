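## Mediation of the sex difference in memory by weighted transitivity:
## residualize mediator and outcome on age, recall room and ICV, standardize
## everything, estimate the path coefficients a, b, c, c' on the correlation
## scale, and get bias-corrected-and-accelerated (BCa) bootstrap intervals
## for the indirect effect a*b and the mediation ratio (a*b)/c'.

#' Prepare residualized, standardized mediation variables
#'
#' The mediator and outcome are replaced by their least-squares residuals on
#' the covariates (plus intercept) and standardized to unit variance; the
#' binary exposure is standardized (so with sex as exposure the a path is a
#' point-biserial-type correlation). All downstream path coefficients then
#' live on the r scale and the indirect effect a*b is comparable to them.
#'
#' @param x exposure (numeric; sex coded female = 0 / male = 1).
#' @param m mediator.
#' @param y outcome.
#' @param covariates data frame or matrix of covariates to remove from m and
#'   y (e.g. age, recall room, ICV), or \code{NULL}.
#' @return data.frame with standardized columns \code{x}, \code{m}, \code{y}.
#' @export
mediation_data <- function(x, m, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  if (anyNA(x) || anyNA(m) || anyNA(y)) stop("missing values in mediation variables; apply listwise deletion first")
  if (!is.null(covariates)) {
    cm <- as.matrix(as.data.frame(covariates))
    z <- cbind(1, cm)
    if (qr(z)$rank < ncol(z)) stop("rank-deficient covariate design")
    sd_m0 <- stats::sd(m); sd_y0 <- stats::sd(y)
    m <- stats::lm.fit(z, m)$residuals
    y <- stats::lm.fit(z, y)$residuals
    if (stats::sd(m) <= 1e-10 * max(sd_m0, 1) || stats::sd(y) <= 1e-10 * max(sd_y0, 1)) {
      stop("zero-variance residuals after covariate adjustment")
    }
  }
  data.frame(x = zscore(x), m = zscore(m), y = zscore(y))
}

## Path coefficients from the three correlations of standardized data:
## a = r_xm; y ~ x + m gives b and c'; c = r_xy; indirect = a*b.
paths_from_cor <- function(r_xm, r_xy, r_my) {
  den <- 1 - r_xm^2
  b <- (r_my - r_xy * r_xm) / den
  c_prime <- (r_xy - r_my * r_xm) / den
  c(a = r_xm, b = b, c = r_xy, c_prime = c_prime,
    indirect = r_xm * b,
    ratio = if (abs(c_prime) > 1e-10) r_xm * b / c_prime else NA_real_)
}

#' Point estimates of the mediation paths
#'
#' @param data residualized standardized data from
#'   \code{\link{mediation_data}}.
#' @return named vector: a (exposure to mediator), b (mediator to outcome
#'   given exposure), c (total), c_prime (direct), indirect (= a b), ratio
#'   (= a b / c'). The ratio is \code{NA} with a warning when the direct
#'   effect is numerically zero.
#' @export
estimate_paths <- function(data) {
  cc <- stats::cor(data[, c("x", "m", "y")])
  p <- paths_from_cor(cc["x", "m"], cc["x", "y"], cc["m", "y"])
  if (is.na(p["ratio"])) {
    warning("direct effect c' is numerically zero; mediation ratio unstable")
  }
  p
}

#' BCa bootstrap intervals for the indirect effect and mediation ratio
#'
#' Subjects are resampled with replacement; the indirect effect and ratio
#' are recomputed per draw; intervals use the bias correction
#' \code{z0 = qnorm(P(boot < estimate))} and the jackknife acceleration
#' (skewness of leave-one-out estimates). By default residualization is done
#' once on the full sample and the residualized rows are resampled;
#' \code{reresidualize} redoes the covariate adjustment inside every draw.
#'
#' @param x,m,y,covariates as in \code{\link{mediation_data}}.
#' @param B bootstrap draws (>= 1000; the study convention is 10000).
#' @param levels confidence levels in percent.
#' @param seed RNG seed for the bootstrap.
#' @param reresidualize logical; see above.
#' @return object of class \code{mediation_result}: paths, per-level BCa
#'   intervals for \code{indirect} and \code{ratio}, z0 and acceleration,
#'   and significance flags (interval excludes zero).
#' @export
bca_bootstrap <- function(x, m, y, covariates = NULL, B = 10000,
                          levels = c(95, 99, 99.5), seed = NULL,
                          reresidualize = FALSE) {
  if (B < 1000) stop("B must be at least 1000 for stable BCa intervals")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(derive_seed(seed, "bootstrap"))
  n <- length(x)
  cov_mat <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))

  stat_fun <- function(idx) {
    if (reresidualize) {
      d <- mediation_data(x[idx], m[idx], y[idx],
                          if (is.null(cov_mat)) NULL else cov_mat[idx, , drop = FALSE])
      cc <- stats::cor(d)
      paths_from_cor(cc["x", "m"], cc["x", "y"], cc["m", "y"])
    } else {
      d <- full_data[idx, ]
      cc <- stats::cor(d)
      paths_from_cor(cc["x", "m"], cc["x", "y"], cc["m", "y"])
    }
  }
  full_data <- mediation_data(x, m, y, cov_mat)
  point <- estimate_pathsq(full_data)

  boot_stats <- matrix(NA_real_, B, 2, dimnames = list(NULL, c("indirect", "ratio")))
  for (bb in seq_len(B)) {
    s <- stat_fun(sample.int(n, n, replace = TRUE))
    boot_stats[bb, ] <- s[c("indirect", "ratio")]
  }
  jack <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("indirect", "ratio")))
  for (i in seq_len(n)) {
    s <- stat_fun(setdiff(seq_len(n), i))
    jack[i, ] <- s[c("indirect", "ratio")]
  }

  ci <- list()
  diag_tab <- list()
  for (stat in c("indirect", "ratio")) {
    t0 <- point[[stat]]
    tb <- boot_stats[, stat]
    tb <- tb[is.finite(tb)]
    if (length(unique(tb)) < 2) stop("degenerate bootstrap distribution for ", stat)
    zj <- jack[is.finite(jack[, stat]), stat]
    res <- bca_interval(tb, t0, zj, levels)
    ci[[stat]] <- res$intervals
    diag_tab[[stat]] <- c(z0 = res$z0, accel = res$accel)
  }
  structure(list(paths = point, ci = ci, diagnostics = diag_tab,
                 boot = boot_stats,
                 B = B, n = n, levels = levels,
                 reresidualize = reresidualize,
                 significant = lapply(ci, function(tab) tab$lower > 0 | tab$upper < 0)),
            class = "mediation_result")
}

## internal alias so bca_bootstrap does not re-trigger the ratio warning
estimate_pathsq <- function(data) {
  cc <- stats::cor(data[, c("x", "m", "y")])
  paths_from_cor(cc["x", "m"], cc["x", "y"], cc["m", "y"])
}

## BCa endpoints for one statistic. Percentiles are interpolated between
## order statistics on the normal-quantile scale (the interpolation used by
## standard bootstrap software), so cross-checks against boot::boot.ci agree
## tightly.
bca_interval <- function(tb, t0, jack, levels) {
  bprop <- mean(tb < t0)
  clamped <- FALSE
  if (bprop == 0 || bprop == 1) {
    warning("bias correction undefined (all bootstrap draws on one side); clamping")
    bprop <- min(max(bprop, 1 / (length(tb) + 1)), length(tb) / (length(tb) + 1))
    clamped <- TRUE
  }
  z0 <- stats::qnorm(bprop)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  accel <- if (den == 0) 0 else num / den
  rows <- lapply(levels, function(L) {
    al <- (1 - L / 100) / 2
    adj <- function(a) {
      zl <- z0 + stats::qnorm(a)
      stats::pnorm(z0 + zl / (1 - accel * zl))
    }
    data.frame(level = L,
               lower = quantile_norm_interp(tb, adj(al)),
               upper = quantile_norm_interp(tb, adj(1 - al)))
  })
  list(intervals = do.call(rbind, rows), z0 = z0, accel = accel,
       clamped = clamped)
}

## Order-statistic quantile with interpolation on the qnorm scale.
quantile_norm_interp <- function(t, prob) {
  b <- length(t)
  st <- sort(t)
  rk <- (b + 1) * prob
  if (rk <= 1) return(st[1])
  if (rk >= b) return(st[b])
  k <- floor(rk)
  g <- (stats::qnorm(prob) - stats::qnorm(k / (b + 1))) /
    (stats::qnorm((k + 1) / (b + 1)) - stats::qnorm(k / (b + 1)))
  st[k] + g * (st[k + 1] - st[k])
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  p <- x$paths
  cat(sprintf("mediation_result (n = %d, B = %d%s)\n", x$n, x$B,
              if (x$reresidualize) ", re-residualized per draw" else ""))
  cat(sprintf("  a = %.3f, b = %.3f, c = %.3f, c' = %.3f\n",
              p[["a"]], p[["b"]], p[["c"]], p[["c_prime"]]))
  cat(sprintf("  indirect (a*b) = %.3f, ratio indirect/direct = %.3f\n",
              p[["indirect"]], p[["ratio"]]))
  for (stat in names(x$ci)) {
    tab <- x$ci[[stat]]
    for (i in seq_len(nrow(tab))) {
      star <- if (x$significant[[stat]][i]) " *" else ""
      cat(sprintf("  %s %.1f%% BCa CI: [%.4f, %.4f]%s\n", stat, tab$level[i],
                  tab$lower[i], tab$upper[i], star))
    }
  }
  invisible(x)
}

#' Run the full mediation analysis on a cohort
#'
#' Wires residualization, path estimation and the BCa bootstrap: sex
#' (female = 0 / male = 1) as exposure, weighted transitivity as mediator,
#' and either total recall or positive-picture recall as outcome, with age,
#' recall room and ICV removed from mediator and outcome.
#'
#' @param subjects cohort table.
#' @param transitivity per-subject weighted transitivity, aligned with
#'   \code{subjects}.
#' @param outcome \code{"all"} (total recall) or \code{"positive"}.
#' @param B,levels,seed,reresidualize passed to \code{\link{bca_bootstrap}}.
#' @return a \code{mediation_result}.
#' @export
run_mediation <- function(subjects, transitivity, outcome = c("all", "positive"),
                          B = 10000, levels = c(95, 99, 99.5), seed = NULL,
                          reresidualize = FALSE) {
  outcome <- match.arg(outcome)
  if (is.null(transitivity)) stop("no transitivity values supplied; run the metric stage first")
  if (length(transitivity) != nrow(subjects)) {
    stop("transitivity length does not match the cohort table")
  }
  y <- switch(outcome,
              all = subjects$recall_neg + subjects$recall_neu + subjects$recall_pos,
              positive = subjects$recall_pos)
  x <- as.numeric(subjects$sex == "male")
  covs <- data.frame(age = subjects$age,
                     room2 = as.numeric(subjects$batch == "room2"),
                     icv = subjects$icv)
  res <- bca_bootstrap(x, transitivity, y, covs, B = B, levels = levels,
                       seed = seed, reresidualize = reresidualize)
  res$outcome <- outcome
  res
}
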