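test_that("fit_ols matches a normal-equations oracle and classic identities", {
  set.seed(101)
  n <- 60
  df <- data.frame(y = rnorm(n), g = factor(sample(c("a", "b"), n, TRUE)),
                   x1 = rnorm(n), x2 = rnorm(n))
  res <- fit_ols(y ~ g + x1 + x2, df)
  mm <- model.matrix(y ~ g + x1 + x2, df)
  beta_oracle <- solve(t(mm) %*% mm, t(mm) %*% df$y)
  expect_equal(unname(coef(res$fit)), as.numeric(beta_oracle), tolerance = 1e-10)

  # single binary predictor: F equals the squared pooled-variance t
  res2 <- fit_ols(y ~ g, df)
  tt <- t.test(y ~ g, df, var.equal = TRUE)
  expect_equal(res2$table$F, unname(tt$statistic)^2, tolerance = 1e-10)

  # constant response: no term explains anything
  df$yc <- 5
  res3 <- fit_ols(yc ~ g + x1, df)
  expect_true(all(res3$table$F < 1e-10))

  # collinear columns are named in the error
  df$x3 <- df$x1
  expect_error(fit_ols(y ~ x1 + x3, df), "x3")
})

test_that("Cohen's d from t reproduces published and algebraic values", {
  expect_equal(cohens_d_from_t(0, 100, 120, 218), 0)
  # equal groups, df = 2n - 2: reduces to 2t / sqrt(df) (up to n/(n-1) bookkeeping)
  t <- 2.3; n <- 50
  expect_equal(cohens_d_from_t(t, n, n, 2 * n - 2), t * 2 * n / (n * sqrt(2 * n - 2)))

  # agrees with the direct standardized mean difference without covariates
  set.seed(55)
  reldiff <- replicate(20, {
    g <- rep(0:1, times = c(120, 80))
    y <- 0.5 * g + rnorm(200)
    fit <- lm(y ~ g)
    tval <- summary(fit)$coefficients["g", "t value"]
    d_t <- cohens_d_from_t(tval, 80, 120, fit$df.residual)
    sp <- sqrt(((120 - 1) * var(y[g == 0]) + (80 - 1) * var(y[g == 1])) / 198)
    d_direct <- (mean(y[g == 1]) - mean(y[g == 0])) / sp
    abs(d_t - d_direct) / abs(d_direct)
  })
  expect_lt(max(reldiff), 0.03)
})

test_that("partial correlation matches the inverse-correlation-matrix oracle", {
  set.seed(77)
  n <- 150
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- 0.4 * z1 + rnorm(n)
  y <- -0.3 * z1 + 0.2 * x + rnorm(n)
  pc <- partial_correlation(x, y, cbind(z1, z2))
  cm <- cor(cbind(x, y, z1, z2))
  pinv <- solve(cm)
  oracle <- -pinv[1, 2] / sqrt(pinv[1, 1] * pinv[2, 2])
  expect_equal(pc$estimate, oracle, tolerance = 1e-10)
  expect_equal(pc$df, n - 4)

  # covariates orthogonal in expectation leave r near the plain correlation
  w <- rnorm(n)
  expect_equal(partial_correlation(x, y, NULL)$estimate, cor(x, y))
  expect_lt(abs(partial_correlation(x, y, cbind(w))$estimate - cor(x, y)), 0.05)

  expect_equal(partial_correlation(x, x, cbind(z1))$estimate, 1)
  expect_error(partial_correlation(z1, 2 * z1 + 0 * x, cbind(`2z` = 2 * z1)),
               "zero-variance")
})

test_that("REML random-intercept fit matches a profile-likelihood grid oracle", {
  set.seed(42)
  n_subj <- 12
  long <- data.frame(id = rep(sprintf("s%02d", 1:n_subj), each = 3),
                     valence = factor(rep(c("neg", "neu", "pos"), n_subj)))
  u <- rnorm(n_subj, 0, 1.2)
  long$y <- 2 + 0.8 * (long$valence == "pos") + u[as.integer(factor(long$id))] +
    rnorm(nrow(long), 0, 0.9)
  fit <- fit_random_intercept_lmm(y ~ valence, long, group = "id")

  # independent REML profile over the variance ratio gamma = s2_b / s2_e
  x <- model.matrix(~ valence, long)
  z <- model.matrix(~ 0 + factor(long$id))
  nn <- nrow(x); p <- ncol(x)
  reml_ll <- function(gamma) {
    v <- diag(nn) + gamma * z %*% t(z)
    vi <- solve(v)
    xtvx <- t(x) %*% vi %*% x
    beta <- solve(xtvx, t(x) %*% vi %*% long$y)
    r <- long$y - x %*% beta
    s2 <- as.numeric(t(r) %*% vi %*% r) / (nn - p)
    -0.5 * ((nn - p) * log(s2) + determinant(v)$modulus +
              determinant(xtvx)$modulus)
  }
  gammas <- seq(0.01, 6, length.out = 400)
  g_star <- gammas[which.max(vapply(gammas, reml_ll, numeric(1)))]
  expect_equal(fit$sigma2_subject / fit$sigma2_resid, g_star, tolerance = 0.05)
})

test_that("the mixed model degenerates to OLS when the random variance vanishes", {
  set.seed(7)
  n_subj <- 40
  long <- data.frame(id = rep(sprintf("s%02d", 1:n_subj), each = 3),
                     valence = factor(rep(c("neg", "neu", "pos"), n_subj)),
                     x = rep(rnorm(n_subj), each = 3))
  long$y <- 1 + 0.5 * (long$valence == "pos") + 0.3 * long$x + rnorm(nrow(long))
  fit <- fit_random_intercept_lmm(y ~ valence + x, long)
  ols <- lm(y ~ valence + x, long)
  expect_lt(fit$sigma2_subject / fit$sigma2_resid, 0.15)
  expect_equal(unname(nlme::fixef(fit$fit)), unname(coef(ols)), tolerance = 0.02)
})

test_that("memory mixed model has the inner/outer df layout and recovers effects", {
  cfg <- test_config(n_subjects = 200)
  cal <- small_calibration()
  coh <- generate_cohort(cfg, cal, seed = 21L, level = "metric")
  fit <- memory_lmm(coh$subjects)
  tab <- fit$table
  n <- 200
  # between-subject terms: n - (intercept + sex + age + batch); within:
  # 2(n - 1) - sex:valence df
  expect_equal(tab$df2[tab$term == "sex"], n - 4)
  expect_equal(tab$df2[tab$term == "valence"], 2 * n - 4)
  expect_setequal(tab$term, c("sex", "valence", "age", "batch", "sex:valence"))
  # valence structure is strong by construction (neutral recalled worst)
  expect_lt(tab$p[tab$term == "valence"], 1e-6)
  expect_gt(fit$sigma2_subject, 0)

  fit2 <- memory_lmm(coh$subjects, transitivity = coh$transitivity)
  expect_true("sex:valence:metric" %in% fit2$table$term)
})

test_that("p-values of the sex test are uniform under the null generator", {
  cfg0 <- null_config(n = 200)
  cal0 <- null_calibration()
  ps <- sapply(1:300, function(s) {
    coh <- generate_cohort(cfg0, cal0, seed = s, level = "metric")
    dat <- cbind(coh$subjects, tv = coh$transitivity)
    fit <- fit_ols(tv ~ sex + age + icv, dat)
    fit$table$p[fit$table$term == "sex"]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("node-level scan controls false flags and finds injected effects", {
  set.seed(90)
  n <- 300; r_nodes <- 20
  covs <- data.frame(sex = factor(sample(c("female", "male"), n, TRUE)),
                     age = runif(n, 18, 35), icv = rnorm(n, 16, 1.5))
  # all-null clustering: expected false flags = reps * R * alpha/R
  flags <- replicate(25, {
    cl <- matrix(rnorm(n * r_nodes, 0.5, 0.05), n, r_nodes)
    sum(node_level_scan(cl, covs)$significant)
  })
  expect_lte(sum(flags), qbinom(0.999, 25 * r_nodes, 0.05 / r_nodes) + 2)

  # one node with d = 0.8: flagged despite Bonferroni correction
  hits <- replicate(15, {
    cl <- matrix(rnorm(n * r_nodes, 0.5, 0.05), n, r_nodes)
    cl[, 7] <- cl[, 7] + 0.8 * 0.05 * (covs$sex == "male")
    scan <- node_level_scan(cl, covs)
    scan$significant[7]
  })
  expect_gte(mean(hits), 0.9)

  # single-node scan reduces to one covariate-adjusted linear model
  cl1 <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "only_node"))
  scan1 <- node_level_scan(cl1, covs)
  single <- fit_ols(cl ~ sex + age + icv,
                    data.frame(cl = cl1[, 1], covs))
  expect_equal(scan1$F, single$table$F[single$table$term == "sex"])
  expect_equal(attr(scan1, "alpha_node"), 0.05)
})

test_that("covariate variants keep the sex effect and reject degenerate designs", {
  cfg <- test_config(n_subjects = 250)
  cal <- small_calibration()
  coh <- generate_cohort(cfg, cal, seed = 33L, level = "metric")
  dat <- coh$subjects
  dat$noise_cov <- rnorm(nrow(dat))
  out <- covariate_variants(coh$transitivity, dat, extra_covariates = "noise_cov")
  f_base <- out$base$table$F[out$base$table$term == "sex"]
  f_extra <- out$extra$table$F[out$extra$table$term == "sex"]
  expect_lt(abs(f_extra - f_base) / f_base, 0.15)

  # no hormonal effect was simulated: within-female HC contrast is null-ish,
  # while the male-vs-female gap keeps the factor significant
  hc_tab <- out$hc$table
  expect_true("group" %in% hc_tab$term)
  post <- fit_ols(.metric ~ group + age + icv,
                  local({
                    grp <- memconn:::hormonal_factor(dat$sex, dat$hc_use,
                                                     c(no = "HC-no", yes = "HC-yes"))
                    d2 <- cbind(dat, .metric = coh$transitivity)[!is.na(grp) & dat$sex == "female", ]
                    d2$group <- droplevels(grp[!is.na(grp) & dat$sex == "female"])
                    d2
                  }))
  expect_gt(post$table$p[post$table$term == "group"], 0.01)

  # a covariate perfectly collinear with ICV triggers the rank error
  dat$gmv <- 2 * dat$icv
  expect_error(covariate_variants(coh$transitivity, dat, extra_covariates = "gmv",
                                  variants = c("extra")), "collinear|rank")
})
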