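## Calibration of the generator's latent coefficients to the configured
## effect targets. Two stages:
##   1. a full-path pilot (edge noise + binomial tallies + population mask +
##      transitivity) estimates the dial-to-observed-transitivity mapping
##      h(lambda) and its measurement noise sd;
##   2. cheap metric-level pilots with common random numbers solve
##      (beta_sex, beta_age, sigma_eps) by a multiplicative fixed point, and
##      the memory weight gamma_t by a secant search on the target partial
##      correlation.

#' Calibrate the synthetic generator to its effect targets
#'
#' @param config a \code{\link{cohort_config}}.
#' @param n_pilot subjects per metric-level pilot (drives the accuracy with
#'   which calibrated effects hit their targets).
#' @param n_path subjects in the full tally-level pilot used to estimate the
#'   dial-to-transitivity mapping and its noise.
#' @param tolerance convergence tolerance on the achieved d and r values.
#' @param max_iter maximum fixed-point iterations.
#' @param seed RNG seed of the calibration pilots.
#' @return object of class \code{cohort_calibration}: the template, the
#'   quadratic coefficients of \code{h(lambda)}, the measurement noise sd,
#'   the calibrated coefficients, achieved pilot values, and the iteration
#'   trace.
#' @export
calibrate_effects <- function(config, n_pilot = 400000, n_path = NULL,
                              tolerance = 0.0015, max_iter = 40, seed = 2026L) {
  stopifnot(inherits(config, "cohort_config"))
  # by default the mapping pilot runs at the cohort's own size, so the
  # population mask in stage 1 is built under the same conditions as in a
  # generated cohort
  if (is.null(n_path)) n_path <- max(config$n_subjects, 200)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  template <- make_template(n_nodes = config$n_nodes, n_blocks = config$n_blocks,
                            w_within = config$w_within, w_between = config$w_between,
                            p_weak = config$p_weak, p_zero = config$p_zero,
                            jitter_sd = config$jitter_sd, seed = config$template_seed)

  ## --- stage 1: h(lambda) and measurement noise from the full path -------
  ## The pilot dial values follow (a slightly widened version of) the dial
  ## distribution a real cohort will have, so the population mask and the
  ## local slope are estimated under cohort-like conditions. A rough slope
  ## from the noise-free thresholded template sets the scale.
  set.seed(derive_seed(seed, "pilot"))
  slope_rough <- template_slope(template, config$lambda0, theta = 0.01)
  sd_guess <- 1.5 * config$sd_transitivity / slope_rough
  lam <- stats::qnorm(seq(0.002, 0.998, length.out = n_path),
                      config$lambda0, sd_guess)
  cs <- vector("list", n_path)
  for (j in seq_len(n_path)) {
    tally <- simulate_tally(template, lam[j], config$sigma_edge, config$waytotal)
    cs[[j]] <- symmetrize(tally_to_probability(tally))
  }
  mask <- build_population_mask(cs)
  t_obs <- vapply(seq_len(n_path), function(j) {
    weighted_clustering(apply_mask(cs[[j]], mask))$transitivity
  }, numeric(1))
  hfit <- stats::lm(t_obs ~ lam + I(lam^2))
  h_coef <- unname(stats::coef(hfit))
  sigma_meas <- stats::sd(stats::resid(hfit))
  slope <- h_coef[2] + 2 * h_coef[3] * config$lambda0
  if (slope <= 0) {
    stop(sprintf("calibration failed: transitivity is not increasing in the dial at lambda0 (slope %.3g)", slope))
  }
  if (sigma_meas >= 0.9 * config$sd_transitivity) {
    stop(sprintf(paste0("infeasible targets: measurement noise of observed transitivity (%.2g) ",
                        "nearly exhausts the target between-subject sd (%.2g); ",
                        "reduce sigma_edge or raise sd_transitivity"),
                 sigma_meas, config$sd_transitivity))
  }

  ## --- stage 2: coefficient fixed point on metric-level pilots -----------
  set.seed(derive_seed(seed, "calibrate"))
  covars <- generate_covariates(config, n_pilot)
  eps_std <- stats::rnorm(n_pilot)
  meas_std <- stats::rnorm(n_pilot)
  male <- as.numeric(covars$sex == "male")
  z_age <- zscore(covars$age)
  pq <- mean(male) * (1 - mean(male))

  sigma_lat <- sqrt(config$sd_transitivity^2 - sigma_meas^2) / slope
  beta_sex <- if (config$d_transitivity == 0) 0 else config$d_transitivity * sigma_lat
  beta_age <- if (config$r_age_transitivity == 0) 0 else
    config$r_age_transitivity * config$sd_transitivity / slope
  sigma_eps2 <- max(sigma_lat^2 - beta_sex^2 * pq - beta_age^2, (0.05 * sigma_lat)^2)

  trace <- NULL
  achieved <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lambda <- config$lambda0 + beta_sex * male + beta_age * z_age +
      sqrt(sigma_eps2) * eps_std
    t_lat <- h_eval(h_coef, lambda)
    t_i <- t_lat + sigma_meas * meas_std
    d_hat <- adjusted_sex_d(t_i, male, covars$age, covars$icv)
    r_hat <- stats::cor(covars$age, t_i)
    sd_hat <- stats::sd(t_i)
    trace <- rbind(trace, data.frame(iter = it, beta_sex = beta_sex,
                                     beta_age = beta_age,
                                     sigma_eps = sqrt(sigma_eps2),
                                     d = d_hat, r_age = r_hat, sd_t = sd_hat))
    ok_d <- config$d_transitivity == 0 || abs(d_hat - config$d_transitivity) <= tolerance
    ok_r <- config$r_age_transitivity == 0 || abs(r_hat - config$r_age_transitivity) <= tolerance
    ok_sd <- abs(sd_hat - config$sd_transitivity) <= 0.02 * config$sd_transitivity
    if (ok_d && ok_r && ok_sd) { converged <- TRUE; break }
    if (config$d_transitivity != 0 && abs(d_hat) > 1e-8) {
      beta_sex <- beta_sex * clamp_ratio(config$d_transitivity / d_hat)
    }
    if (config$r_age_transitivity != 0 && abs(r_hat) > 1e-8) {
      beta_age <- beta_age * clamp_ratio(config$r_age_transitivity / r_hat)
    }
    sigma_eps2 <- max(sigma_eps2 + (config$sd_transitivity^2 - sd_hat^2) / slope^2,
                      (0.02 * sigma_lat)^2)
  }
  if (!converged) {
    stop(paste0("calibration did not converge within ", max_iter,
                " iterations; trace:\n",
                paste(utils::capture.output(print(trace)), collapse = "\n")))
  }
  achieved$d_transitivity <- trace$d[nrow(trace)]
  achieved$r_age_transitivity <- trace$r_age[nrow(trace)]
  achieved$sd_transitivity <- trace$sd_t[nrow(trace)]

  ## recompute final latent state for the memory stage
  lambda <- config$lambda0 + beta_sex * male + beta_age * z_age +
    sqrt(sigma_eps2) * eps_std
  t_lat <- h_eval(h_coef, lambda)
  t_i <- t_lat + sigma_meas * meas_std
  lat_center <- mean(t_lat); lat_scale <- stats::sd(t_lat)

  ## --- stage 3: memory weight gamma_t by secant ---------------------------
  u <- stats::rnorm(n_pilot, 0, config$sigma_subject)
  unif <- matrix(stats::runif(n_pilot * 3), n_pilot, 3)
  z_lat <- (t_lat - lat_center) / lat_scale
  covmat <- cbind(age = covars$age, room2 = as.numeric(covars$batch == "room2"))
  eval_r <- function(gamma) {
    rc <- generate_recall(config, covars, z_lat, gamma, u = u, unif = unif)
    partial_correlation(t_i, rowSums(rc), covmat)$estimate
  }
  g0 <- 0; r0 <- eval_r(g0)
  if (config$r_transitivity_memory == 0) {
    gamma_t <- 0
    achieved$r_transitivity_memory <- r0
  } else {
    g1 <- 0.5 * sign(config$r_transitivity_memory - r0); r1 <- eval_r(g1)
    for (it in seq_len(12)) {
      if (abs(r1 - config$r_transitivity_memory) <= 0.003) break
      if (abs(r1 - r0) < 1e-9) break
      g2 <- g1 + (config$r_transitivity_memory - r1) * (g1 - g0) / (r1 - r0)
      g0 <- g1; r0 <- r1
      g1 <- g2; r1 <- eval_r(g1)
    }
    if (abs(r1 - config$r_transitivity_memory) > 0.02) {
      stop(sprintf("memory calibration did not converge: achieved r = %.3f for target %.3f",
                   r1, config$r_transitivity_memory))
    }
    gamma_t <- g1
    achieved$r_transitivity_memory <- r1
  }
  achieved$icv_sex_r <- stats::cor(as.numeric(covars$sex == "female"), covars$icv)

  structure(list(template = template, mask_pilot = mask,
                 h_coef = h_coef, sigma_meas = sigma_meas, slope = slope,
                 lambda0 = config$lambda0,
                 beta_sex = beta_sex, beta_age = beta_age,
                 sigma_eps = sqrt(sigma_eps2), gamma_t = gamma_t,
                 lat_center = lat_center, lat_scale = lat_scale,
                 achieved = achieved, trace = trace,
                 config = config, seed = seed,
                 n_pilot = n_pilot, n_path = n_path),
            class = "cohort_calibration")
}

h_eval <- function(h_coef, lambda) h_coef[1] + h_coef[2] * lambda + h_coef[3] * lambda^2

## Local transitivity slope of the noise-free template with sub-threshold
## edges removed (the graph a masked cohort effectively sees).
template_slope <- function(template, lambda0, theta = 0.01, eps = 0.05) {
  tv <- vapply(c(lambda0 - eps, lambda0 + eps), function(l) {
    w <- mix_template(template, l)
    w[w < theta] <- 0
    weighted_clustering(w)$transitivity
  }, numeric(1))
  slope <- (tv[2] - tv[1]) / (2 * eps)
  if (slope <= 0) stop("template transitivity is not increasing at lambda0; adjust the template")
  slope
}

clamp_ratio <- function(x) max(min(x, 4), 0.25)

## ICV-adjusted standardized sex difference, reconstructed from the t value
## of the linear model transitivity ~ sex + age + ICV.
adjusted_sex_d <- function(t_i, male, age, icv) {
  x <- cbind(1, male, age, icv)
  fit <- stats::lm.fit(x, t_i)
  df <- length(t_i) - fit$rank
  res_var <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(chol(crossprod(x)))
  t_stat <- fit$coefficients[2] / sqrt(res_var * xtx_inv[2, 2])
  n1 <- sum(male == 1); n2 <- sum(male == 0)
  cohens_d_from_t(t_stat, n1, n2, df)
}

#' @export
print.cohort_calibration <- function(x, ...) {
  cat("cohort_calibration\n")
  cat(sprintf("  dial model: lambda0 = %g, beta_sex = %.4g, beta_age = %.4g, sigma_eps = %.4g\n",
              x$lambda0, x$beta_sex, x$beta_age, x$sigma_eps))
  cat(sprintf("  h(lambda0) = %.4f, slope = %.4f, sigma_meas = %.2g, gamma_t = %.3f\n",
              h_eval(x$h_coef, x$lambda0), x$slope, x$sigma_meas, x$gamma_t))
  cat("  achieved pilot values:\n")
  for (nm in names(x$achieved)) {
    cat(sprintf("    %s = %.4f\n", nm, x$achieved[[nm]]))
  }
  invisible(x)
}

## One subject's directed streamline tally: mix the template at the
## subject's dial value, apply symmetric multiplicative log-normal edge
## noise, then draw Binomial(waytotal, w_ij) counts per ordered node pair.
simulate_tally <- function(template, lambda, sigma_edge, waytotal, id = NULL) {
  w <- subject_weights(template, lambda, sigma_edge)
  r <- nrow(w)
  counts <- matrix(stats::rbinom(r * r, waytotal, w), r, r)
  diag(counts) <- 0L
  streamline_tally(counts, waytotal, id = id)
}

subject_weights <- function(template, lambda, sigma_edge) {
  m <- mix_template(template, lambda)
  r <- nrow(m)
  if (sigma_edge > 0) {
    noise <- matrix(1, r, r)
    ut <- upper.tri(noise)
    noise[ut] <- exp(stats::rnorm(sum(ut), -sigma_edge^2 / 2, sigma_edge))
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    m <- clip01(m * noise)
  }
  m
}
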