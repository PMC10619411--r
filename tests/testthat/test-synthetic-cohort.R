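test_that("template construction honours symmetry, block structure and degeneracy rules", {
  # complete uniform 3-node template: symmetry forces T0 proportional to W0
  m3 <- make_template(n_nodes = 3, n_blocks = 3, w_within = 0.6, w_between = 0.5,
                      p_weak = 0, p_zero = 0, jitter_sd = 0, seed = 1)
  off <- upper.tri(m3$W0)
  expect_true(all(abs(m3$T0[off] / m3$W0[off] - mean(m3$T0[off] / m3$W0[off])) < 1e-12))

  # equal within/between weight levels: block structure vanishes
  mu <- make_template(n_nodes = 12, n_blocks = 3, w_within = 0.6, w_between = 0.6 - 1e-9,
                      p_weak = 0, p_zero = 0, jitter_sd = 0, seed = 1)
  expect_lt(diff(range(mu$W0[upper.tri(mu$W0)])), 1e-6)

  tpl <- make_template(seed = 2)
  expect_true(isSymmetric(tpl$W0))
  expect_true(isSymmetric(tpl$T0))
  expect_equal(diag(tpl$W0), rep(0, 82))
  expect_equal(diag(tpl$T0), rep(0, 82))
  expect_true(all(tpl$W0 >= 0 & tpl$W0 <= 1))
  expect_true(all(tpl$T0 >= 0 & tpl$T0 <= 1))

  expect_error(make_template(n_blocks = 1), "n_blocks")
  expect_error(make_template(w_within = 0.4, w_between = 0.5), "w_between")
})

test_that("transitivity of the mixed template increases along the clustering dial", {
  tpl <- make_template(seed = 3)
  grid <- template_transitivity_grid(tpl, seq(0, 1, length.out = 11))
  expect_true(all(diff(grid$transitivity) > 0))
  expect_gt(grid$transitivity[11], grid$transitivity[1])

  # also monotone on the smaller test parcellation
  tpl2 <- make_template(n_nodes = 28, n_blocks = 4, seed = 4)
  grid2 <- template_transitivity_grid(tpl2, seq(0.2, 0.8, length.out = 7))
  expect_true(all(diff(grid2$transitivity) > 0))
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- test_config()
  cal <- small_calibration()
  c1 <- generate_cohort(cfg, cal, seed = 12L, level = "tally")
  c2 <- generate_cohort(cfg, cal, seed = 12L, level = "tally")
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$tallies[[5]]$counts, c2$tallies[[5]]$counts)
  c3 <- generate_cohort(cfg, cal, seed = 13L, level = "tally")
  expect_false(identical(c1$subjects$icv, c3$subjects$icv))

  cm1 <- generate_cohort(cfg, cal, seed = 12L, level = "metric")
  cm2 <- generate_cohort(cfg, cal, seed = 12L, level = "metric")
  expect_identical(cm1$transitivity, cm2$transitivity)
  # metric and tally levels share covariates and recall under the same seed
  expect_identical(cm1$subjects, c1$subjects)
})

test_that("cohort structure matches the study design", {
  cfg <- test_config()
  cal <- small_calibration()
  coh <- generate_cohort(cfg, cal, seed = 2L, level = "metric")
  s <- coh$subjects
  expect_equal(nrow(s), 150)
  expect_true(all(s$age >= 18 & s$age <= 35))
  expect_true(all(s$recall_neg %in% 0:24))
  expect_true(all(s$recall_neu %in% 0:24))
  expect_true(all(s$recall_pos %in% 0:24))
  expect_true(all(s$hc_use[s$sex == "male"] == "not-applicable"))
  expect_true(all(s$mc_phase[s$sex == "male"] == "not-applicable"))
  expect_true(all(s$hc_use[s$sex == "female"] %in% c("no", "yes", "missing")))
  # males get larger intracranial volumes under the negative female-coded r
  expect_gt(mean(s$icv[s$sex == "male"]), mean(s$icv[s$sex == "female"]))
})

test_that("null targets calibrate to null coefficients and null recovered effects", {
  cal0 <- null_calibration()
  expect_identical(cal0$beta_sex, 0)
  expect_identical(cal0$beta_age, 0)
  expect_identical(cal0$gamma_t, 0)

  # recovered sex/age effects on transitivity are within Monte-Carlo error of 0
  cfg0 <- null_config(n = 400)
  est <- sapply(1:30, function(s) {
    coh <- generate_cohort(cfg0, cal0, seed = s, level = "metric")
    dat <- cbind(coh$subjects, tv = coh$transitivity)
    fit <- fit_ols(tv ~ sex + age + icv, dat)
    c(d = fit$table$d_or_r[fit$table$term == "sex"],
      r = cor(dat$age, dat$tv))
  })
  expect_lt(abs(mean(est["d", ])), 2 * sd(est["d", ]) / sqrt(30))
  expect_lt(abs(mean(est["r", ])), 2 * sd(est["r", ]) / sqrt(30))
})

test_that("calibration converges on targets and responds monotonically to them", {
  cal <- small_calibration()
  cfg <- test_config()
  expect_lt(abs(cal$achieved$d_transitivity - cfg$d_transitivity), 0.002)
  expect_lt(abs(cal$achieved$r_age_transitivity - cfg$r_age_transitivity), 0.002)
  expect_lt(abs(cal$achieved$r_transitivity_memory - cfg$r_transitivity_memory), 0.02)
  expect_gt(cal$beta_sex, 0)
  expect_lt(cal$beta_age, 0)

  # a larger target sex difference needs a larger calibrated dial shift
  cal_big <- calibrate_effects(test_config(d_transitivity = 0.8),
                               n_pilot = 20000, n_path = 250, seed = 5L)
  expect_gt(cal_big$beta_sex, cal$beta_sex)
})

test_that("binomial tallies are unbiased for the subject's latent weights", {
  cal <- small_calibration()
  w <- memconn:::subject_weights(cal$template, 0.5, 0)
  set.seed(31)
  acc <- matrix(0, nrow(w), ncol(w))
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    r <- nrow(w)
    counts <- matrix(rbinom(r * r, 500, w), r, r); diag(counts) <- 0
    acc <- acc + counts / 500
  }
  phat <- acc / n_rep
  sel <- upper.tri(w) & w > 0.05
  se <- sqrt(w[sel] * (1 - w[sel]) / (500 * n_rep))
  expect_lt(max(abs(phat[sel] - w[sel]) / se), 4.5)
  expect_lt(abs(mean((phat[sel] - w[sel]) / se)), 0.2)
})

test_that("cohorts round-trip through the plain-text directory format", {
  cfg <- test_config(n_subjects = 6)
  cal <- small_calibration()
  coh <- generate_cohort(cfg, cal, seed = 8L, level = "tally")
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects$id, coh$subjects$id)
  expect_equal(back$subjects$age, coh$subjects$age, tolerance = 1e-12)
  expect_equal(back$subjects$recall_pos, coh$subjects$recall_pos)
  expect_identical(back$tallies[["S0003"]]$counts, unname(coh$tallies[["S0003"]]$counts))
  expect_equal(back$tallies[["S0003"]]$waytotal, coh$tallies[["S0003"]]$waytotal)

  expect_error(read_cohort(file.path(dir, "nope")), "no such cohort directory")
  # truncated matrix file is reported by name
  cf <- file.path(dir, "S0002_counts.tsv")
  lines <- readLines(cf)
  writeLines(lines[-1], cf)
  expect_error(read_cohort(dir), "S0002_counts.tsv")
})
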