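## Configuration of the synthetic cohort. Defaults reproduce the statistical
## structure of the study cohort: n = 655 (60% female), ages 18-35, a strong
## sex-ICV correlation (-0.69 with female coded high), a male-higher
## ICV-adjusted transitivity difference d = 0.42, an age-transitivity
## correlation of -0.23, a transitivity-memory partial correlation of -0.12,
## and free recall of 24 pictures per valence with a female advantage that is
## largest for positive pictures.

#' Synthetic cohort configuration
#'
#' @param n_subjects cohort size (default 655).
#' @param prop_female proportion of females (default 0.60).
#' @param n_nodes number of parcellation nodes, 82 for the
#'   Desikan-Killiany + subcortical scheme or 162 for Destrieux +
#'   subcortical (any value >= 3 is accepted).
#' @param age_range admissible age range in years.
#' @param age_mean,age_sd length-2 vectors (female, male) for the truncated
#'   normal age draw.
#' @param icv_mean_female,icv_sd_female,icv_sd_male intracranial volume
#'   moments on the study's printed scale (units unstated there; the
#'   simulation simply mirrors the scale). The male mean is derived from
#'   \code{icv_sex_r}.
#' @param icv_sex_r target point-biserial correlation between the female
#'   indicator and ICV (default -0.69; negative = males larger).
#' @param d_transitivity target ICV-adjusted standardized sex difference in
#'   weighted transitivity, positive = male-higher (default 0.42).
#' @param r_age_transitivity target age-transitivity Pearson correlation
#'   (default -0.23).
#' @param r_transitivity_memory target partial correlation (age and recall
#'   room adjusted) between transitivity and total recall (default -0.12).
#' @param sd_transitivity target between-subject SD of observed weighted
#'   transitivity (default 0.0025, the scale of the study's printed group
#'   SDs).
#' @param memory_logit per-valence baseline log-odds of recalling one of the
#'   24 pictures (male, room 1). Defaults put negative and positive recall
#'   above neutral.
#' @param sex_memory_logit per-valence female recall advantage on the logit
#'   scale; largest for positive pictures. This is the direct
#'   (non-connectome) sex-to-memory pathway.
#' @param batch_effect additive log-odds recall improvement in the quieter
#'   second recall room.
#' @param prop_room2 proportion of subjects tested in room 2.
#' @param sigma_subject SD of the subject-level random recall ability on the
#'   logit scale (drives the random intercept of the mixed model).
#' @param hc_probs female hormonal-contraceptive status probabilities
#'   (no, yes, missing), study proportions 155/199/37 of 391.
#' @param mc_probs female menstrual-cycle phase probabilities (first-half,
#'   second-half, no-cycle, missing), study proportions 176/169/7/39.
#' @param waytotal streamlines drawn per seed node (default 5000).
#' @param lambda0 centre of the latent clustering dial.
#' @param n_blocks,w_within,w_between,p_weak,p_zero,jitter_sd template
#'   parameters, see \code{\link{make_template}}.
#' @param sigma_edge log-normal SD of per-subject multiplicative edge noise.
#' @param template_seed seed of the (population-fixed) template draw.
#' @param seed default RNG seed for cohort generation.
#' @return validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 655,
                          prop_female = 0.60,
                          n_nodes = 82,
                          age_range = c(18, 35),
                          age_mean = c(female = 22.62, male = 23.26),
                          age_sd = c(female = 3.32, male = 3.46),
                          icv_mean_female = 15.14,
                          icv_sd_female = 1.36,
                          icv_sd_male = 1.20,
                          icv_sex_r = -0.69,
                          d_transitivity = 0.42,
                          r_age_transitivity = -0.23,
                          r_transitivity_memory = -0.12,
                          sd_transitivity = 0.0025,
                          memory_logit = c(negative = -0.62, neutral = -1.35, positive = -0.75),
                          sex_memory_logit = c(negative = 0.06, neutral = 0.04, positive = 0.15),
                          batch_effect = 0.15,
                          prop_room2 = 0.5,
                          sigma_subject = 0.45,
                          hc_probs = c(no = 155, yes = 199, missing = 37) / 391,
                          mc_probs = c(`first-half` = 176, `second-half` = 169,
                                       `no-cycle` = 7, missing = 39) / 391,
                          waytotal = 5000,
                          lambda0 = 0.5,
                          n_blocks = 7,
                          w_within = 0.78,
                          w_between = 0.55,
                          p_weak = 0.35,
                          p_zero = 0.10,
                          jitter_sd = 0.10,
                          sigma_edge = 0.05,
                          template_seed = 11L,
                          seed = NULL) {
  cfg <- list(n_subjects = n_subjects, prop_female = prop_female,
              n_nodes = n_nodes, age_range = age_range,
              age_mean = age_mean, age_sd = age_sd,
              icv_mean_female = icv_mean_female,
              icv_sd_female = icv_sd_female, icv_sd_male = icv_sd_male,
              icv_sex_r = icv_sex_r,
              d_transitivity = d_transitivity,
              r_age_transitivity = r_age_transitivity,
              r_transitivity_memory = r_transitivity_memory,
              sd_transitivity = sd_transitivity,
              memory_logit = memory_logit,
              sex_memory_logit = sex_memory_logit,
              batch_effect = batch_effect, prop_room2 = prop_room2,
              sigma_subject = sigma_subject,
              hc_probs = hc_probs, mc_probs = mc_probs,
              waytotal = waytotal, lambda0 = lambda0,
              n_blocks = n_blocks, w_within = w_within,
              w_between = w_between, p_weak = p_weak, p_zero = p_zero,
              jitter_sd = jitter_sd, sigma_edge = sigma_edge,
              template_seed = template_seed, seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$n_nodes >= 3, cfg$waytotal >= 1)
  if (!(cfg$prop_female > 0 && cfg$prop_female < 1)) {
    stop("prop_female must be strictly between 0 and 1")
  }
  if (!(cfg$prop_room2 >= 0 && cfg$prop_room2 <= 1)) stop("prop_room2 must be in [0, 1]")
  for (nm in c("icv_sex_r", "r_age_transitivity", "r_transitivity_memory")) {
    if (abs(cfg[[nm]]) >= 1) stop(sprintf("|%s| must be < 1", nm))
  }
  if (cfg$sd_transitivity <= 0) stop("sd_transitivity must be positive")
  if (diff(cfg$age_range) <= 0) stop("age_range must be increasing")
  if (length(cfg$memory_logit) != 3 || length(cfg$sex_memory_logit) != 3) {
    stop("memory_logit and sex_memory_logit need one value per valence")
  }
  if (abs(sum(cfg$hc_probs) - 1) > 1e-6 || abs(sum(cfg$mc_probs) - 1) > 1e-6) {
    stop("hc_probs and mc_probs must each sum to 1")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort_config: n = %d (%.0f%% female), %d nodes, waytotal = %d\n",
              x$n_subjects, 100 * x$prop_female, x$n_nodes, as.integer(x$waytotal)))
  cat(sprintf("  targets: d(transitivity) = %g, r(age) = %g, r(memory) = %g, r(sex, ICV) = %g\n",
              x$d_transitivity, x$r_age_transitivity,
              x$r_transitivity_memory, x$icv_sex_r))
  invisible(x)
}

## Sex-difference in ICV implied by the point-biserial target, holding the
## within-sex SDs fixed: |delta| = |r| sd_w / sqrt(p q (1 - r^2)).
icv_delta <- function(cfg) {
  p <- cfg$prop_female
  sd_w <- sqrt(p * cfg$icv_sd_female^2 + (1 - p) * cfg$icv_sd_male^2)
  if (cfg$icv_sex_r == 0) return(0)
  d <- abs(cfg$icv_sex_r) * sd_w / sqrt(p * (1 - p) * (1 - cfg$icv_sex_r^2))
  -sign(cfg$icv_sex_r) * d  # negative r (female-coded) means males higher
}

## Truncated-normal draw via inverse CDF.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## Draw the covariate block of a cohort: sex, age, ICV, recall room,
## HC-use and MC-phase. Assumes the RNG has been seeded by the caller.
generate_covariates <- function(cfg, n = cfg$n_subjects) {
  female <- stats::rbinom(n, 1, cfg$prop_female)
  male <- 1 - female
  age <- ifelse(female == 1,
                rtruncnorm(n, cfg$age_mean[["female"]], cfg$age_sd[["female"]],
                           cfg$age_range[1], cfg$age_range[2]),
                rtruncnorm(n, cfg$age_mean[["male"]], cfg$age_sd[["male"]],
                           cfg$age_range[1], cfg$age_range[2]))
  delta <- icv_delta(cfg)
  icv <- ifelse(female == 1,
                stats::rnorm(n, cfg$icv_mean_female, cfg$icv_sd_female),
                stats::rnorm(n, cfg$icv_mean_female + delta, cfg$icv_sd_male))
  batch <- ifelse(stats::runif(n) < cfg$prop_room2, "room2", "room1")
  hc <- rep("not-applicable", n)
  mc <- rep("not-applicable", n)
  nf <- sum(female == 1)
  if (nf > 0) {
    hc[female == 1] <- sample(names(cfg$hc_probs), nf, replace = TRUE,
                              prob = cfg$hc_probs)
    mc[female == 1] <- sample(names(cfg$mc_probs), nf, replace = TRUE,
                              prob = cfg$mc_probs)
  }
  data.frame(id = sprintf("S%04d", seq_len(n)),
             sex = factor(ifelse(female == 1, "female", "male"),
                          levels = c("female", "male")),
             age = age, icv = icv,
             batch = factor(batch, levels = c("room1", "room2")),
             hc_use = hc, mc_phase = mc,
             stringsAsFactors = FALSE)
}

## Per-valence free-recall counts: Binomial(24, p) with a logit-linear
## predictor carrying valence, sex, sex-by-valence, recall-room, the
## standardized latent transitivity (gamma_t) and a subject random ability u.
## Uniform draws can be supplied so calibration can reuse common random
## numbers across candidate gamma_t values.
generate_recall <- function(cfg, covars, z_trans, gamma_t, u = NULL, unif = NULL) {
  n <- nrow(covars)
  female <- as.numeric(covars$sex == "female")
  room2 <- as.numeric(covars$batch == "room2")
  if (is.null(u)) u <- stats::rnorm(n, 0, cfg$sigma_subject)
  if (is.null(unif)) unif <- matrix(stats::runif(n * 3), n, 3)
  valences <- c("negative", "neutral", "positive")
  out <- matrix(NA_integer_, n, 3, dimnames = list(NULL, valences))
  for (v in seq_along(valences)) {
    eta <- cfg$memory_logit[[v]] + cfg$sex_memory_logit[[v]] * female +
      cfg$batch_effect * room2 + gamma_t * z_trans + u
    out[, v] <- stats::qbinom(unif[, v], 24, stats::plogis(eta))
  }
  data.frame(recall_neg = out[, 1], recall_neu = out[, 2], recall_pos = out[, 3])
}
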