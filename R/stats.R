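## Covariate-adjusted group models: Type-II F tests for linear models,
## t-based Cohen's d, random-intercept REML mixed models (nlme), partial
## Pearson correlations, the node-level Bonferroni scan, and the covariate
## robustness variants.

#' Fit a linear model with Type-II F tests
#'
#' Ordinary least squares with per-term F tests using Type-II sums of
#' squares (the convention of the car package, which also provides the
#' computation here). For two-level factor terms a t-based Cohen's d is
#' reported (see \code{\link{cohens_d_from_t}}); for continuous terms the
#' effect is expressed as r, the correlation reconstruction
#' \code{t / sqrt(t^2 + df)}.
#'
#' @param formula model formula.
#' @param data data frame.
#' @param type sums-of-squares type passed to \code{car::Anova}
#'   (\code{2} default; \code{3} available as the documented switch).
#' @return object of class \code{ols_result}: the \code{lm} fit, a tidy
#'   \code{table} (term, F, df1, df2, p, d_or_r), \code{n}, and group sizes
#'   for factor terms.
#' @export
fit_ols <- function(formula, data, type = 2) {
  mm <- stats::model.matrix(formula, data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  n <- nrow(mm)
  if (n <= ncol(mm)) stop("need more observations than parameters")
  fit <- stats::lm(formula, data)
  df2 <- fit$df.residual
  if (stats::var(stats::model.response(stats::model.frame(fit))) <= 1e-300) {
    # degenerate constant response: nothing to explain
    trm <- attr(stats::terms(fit), "term.labels")
    tab <- data.frame(term = trm, F = 0, df1 = NA_integer_, df2 = df2,
                      p = 1, d_or_r = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(fit = fit, table = tab, n = n, type = type),
                     class = "ols_result"))
  }
  an <- car::Anova(fit, type = type)
  terms_tab <- an[rownames(an) != "Residuals", , drop = FALSE]
  tab <- data.frame(term = rownames(terms_tab),
                    F = terms_tab[["F value"]],
                    df1 = terms_tab[["Df"]],
                    df2 = df2,
                    p = terms_tab[["Pr(>F)"]],
                    d_or_r = NA_real_,
                    stringsAsFactors = FALSE)
  mf <- stats::model.frame(fit)
  coefs <- summary(fit)$coefficients
  for (i in seq_len(nrow(tab))) {
    term <- tab$term[i]
    if (!(term %in% names(mf))) next
    v <- mf[[term]]
    if (is.factor(v) && nlevels(droplevels(v)) == 2) {
      lv <- levels(droplevels(v))
      cn <- paste0(term, lv[2])
      if (cn %in% rownames(coefs)) {
        tval <- coefs[cn, "t value"]
        n2 <- sum(v == lv[1]); n1 <- sum(v == lv[2])  # positive d = second level higher
        tab$d_or_r[i] <- cohens_d_from_t(tval, n1, n2, df2)
      }
    } else if (is.numeric(v) && term %in% rownames(coefs)) {
      tval <- coefs[term, "t value"]
      tab$d_or_r[i] <- tval / sqrt(tval^2 + df2)
    }
  }
  structure(list(fit = fit, table = tab, n = n, type = type),
            class = "ols_result")
}

#' @export
print.ols_result <- function(x, digits = 4, ...) {
  cat(sprintf("ols_result (n = %d, Type-%s F tests)\n", x$n, x$type))
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Cohen's d reconstructed from a model t value
#'
#' \code{d = t (n1 + n2) / (sqrt(n1 n2) sqrt(df))}. Because t comes from the
#' fitted linear model, d inherits the adjustment for every covariate in the
#' model. With female = 0 / male = 1 coding a positive d means males had
#' higher values.
#'
#' @param t t value of the group contrast.
#' @param n1,n2 group sizes.
#' @param df residual degrees of freedom of the model.
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n1, n2, df) {
  stopifnot(n1 > 0, n2 > 0, df > 0)
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))
}

#' Partial Pearson correlation
#'
#' Residualizes both variables on the covariates (plus intercept) by least
#' squares and correlates the residuals; the p value uses
#' \code{t = r sqrt((n - 2 - k) / (1 - r^2))} with k covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix or data frame of covariates (or
#'   \code{NULL} for a plain Pearson correlation).
#' @return list with \code{estimate}, \code{statistic}, \code{p.value},
#'   \code{n}, and \code{df}.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    k <- 0
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    cm <- as.matrix(as.data.frame(covariates))
    stopifnot(nrow(cm) == n)
    k <- ncol(cm)
    z <- cbind(1, cm)
    if (qr(z)$rank < ncol(z)) stop("rank-deficient covariate design")
    rx <- stats::lm.fit(z, x)$residuals
    ry <- stats::lm.fit(z, y)$residuals
  }
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1)) {
    stop("zero-variance residuals; partial correlation undefined")
  }
  if (n <= k + 2) stop("too few observations for the requested covariates")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  list(estimate = r, statistic = tval,
       p.value = 2 * stats::pt(-abs(tval), df), n = n, df = df)
}

#' Random-intercept mixed model fitted by REML
#'
#' Fits \code{fixed} with a subject random intercept via
#' \code{nlme::lme(..., method = "REML")} and returns per-term F tests. The
#' denominator degrees of freedom follow nlme's inner/outer (between- vs
#' within-subject) convention. \code{anova_type} \code{"sequential"}
#' (default, nlme's own) or \code{"marginal"} is the documented switch.
#'
#' @param fixed fixed-effects formula.
#' @param data long-format data with one row per subject x valence.
#' @param group name of the grouping (subject id) column.
#' @param anova_type \code{"sequential"} or \code{"marginal"}.
#' @return object of class \code{lmm_result} with the \code{nlme} fit, a
#'   tidy \code{table}, and the variance components.
#' @export
fit_random_intercept_lmm <- function(fixed, data, group = "id",
                                     anova_type = c("sequential", "marginal")) {
  anova_type <- match.arg(anova_type)
  if (!group %in% names(data)) stop("grouping column not found: ", group)
  random <- stats::as.formula(paste("~ 1 |", group))
  fit <- nlme::lme(fixed = fixed, random = random, data = data,
                   method = "REML",
                   control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                              msMaxIter = 200))
  an <- stats::anova(fit, type = anova_type)
  keep <- rownames(an) != "(Intercept)"
  tab <- data.frame(term = rownames(an)[keep],
                    F = an[["F-value"]][keep],
                    df1 = an[["numDF"]][keep],
                    df2 = an[["denDF"]][keep],
                    p = an[["p-value"]][keep],
                    stringsAsFactors = FALSE)
  vc <- as.numeric(nlme::VarCorr(fit)[, "Variance"])
  structure(list(fit = fit, table = tab,
                 sigma2_subject = vc[1], sigma2_resid = vc[2],
                 anova_type = anova_type, n_groups = nlevels(factor(data[[group]]))),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, digits = 4, ...) {
  cat(sprintf("lmm_result (REML, %d subjects; sigma2_subject = %.3g, sigma2_resid = %.3g)\n",
              x$n_groups, x$sigma2_subject, x$sigma2_resid))
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Long-format valence memory table
#'
#' Reshapes the per-subject recall counts into one row per subject and
#' valence, the layout of the mixed models (valence as within-subject
#' factor).
#'
#' @param subjects cohort table with \code{recall_neg}, \code{recall_neu},
#'   \code{recall_pos}.
#' @param transitivity optional per-subject metric merged in as a
#'   standardized \code{metric} column.
#' @return long data frame: id, sex, age, batch, valence, recall (, metric).
#' @export
memory_long <- function(subjects, transitivity = NULL) {
  valences <- c(negative = "recall_neg", neutral = "recall_neu",
                positive = "recall_pos")
  out <- do.call(rbind, lapply(names(valences), function(v) {
    data.frame(id = subjects$id, sex = subjects$sex, age = subjects$age,
               batch = subjects$batch,
               valence = factor(v, levels = names(valences)),
               recall = subjects[[valences[[v]]]],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(transitivity)) {
    out$metric <- rep(zscore(transitivity), times = 3)
  }
  out[order(out$id, out$valence), ]
}

#' Valence-resolved memory models
#'
#' Model of the sex-by-valence structure of free recall
#' (\code{recall ~ sex * valence + age + batch}, subject random intercept),
#' optionally extended with a standardized connectome measure and its
#' interactions (\code{recall ~ sex * valence * metric + age + batch}).
#'
#' @param subjects cohort table.
#' @param transitivity per-subject metric; when supplied the metric model is
#'   fitted.
#' @param anova_type passed to \code{\link{fit_random_intercept_lmm}}.
#' @return an \code{lmm_result}.
#' @export
memory_lmm <- function(subjects, transitivity = NULL,
                       anova_type = "sequential") {
  long <- memory_long(subjects, transitivity)
  fixed <- if (is.null(transitivity)) {
    recall ~ sex * valence + age + batch
  } else {
    recall ~ sex * valence * metric + age + batch
  }
  fit_random_intercept_lmm(fixed, long, group = "id", anova_type = anova_type)
}

#' Node-level sex-difference scan with Bonferroni control
#'
#' Fits \code{clustering ~ sex + age + icv} per node and flags nodes whose
#' sex effect survives the Bonferroni threshold \code{alpha / R} for R
#' nodes.
#'
#' @param clustering subject x node matrix of clustering coefficients.
#' @param data cohort table aligned with the rows of \code{clustering};
#'   must contain \code{sex}, \code{age}, \code{icv}.
#' @param alpha family-wise error level before division by the node count
#'   (default 0.05).
#' @return data.frame: node_label, F, df1, df2, p, d, significant; the
#'   per-node threshold is in attribute \code{"alpha_node"}.
#' @export
node_level_scan <- function(clustering, data, alpha = 0.05) {
  stopifnot(is.matrix(clustering), nrow(clustering) == nrow(data))
  r <- ncol(clustering)
  alpha_node <- alpha / r
  labels <- colnames(clustering) %||% default_node_labels(r)
  rows <- lapply(seq_len(r), function(j) {
    df <- data.frame(cl = clustering[, j], sex = data$sex,
                     age = data$age, icv = data$icv)
    res <- tryCatch(fit_ols(cl ~ sex + age + icv, df),
                    error = function(e) stop(sprintf("node %s: %s", labels[j],
                                                     conditionMessage(e))))
    srow <- res$table[res$table$term == "sex", ]
    data.frame(node_label = labels[j], F = srow$F, df1 = srow$df1,
               df2 = srow$df2, p = srow$p, d = srow$d_or_r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha_node
  attr(out, "alpha_node") <- alpha_node
  attr(out, "alpha") <- alpha
  out
}

#' Robustness variants of the sex-difference model
#'
#' Refits the covariate-adjusted sex model for a connectome measure with
#' additional wiring-cost or volume covariates, and with the sex factor
#' replaced by hormonal-contraceptive use (HC-no, HC-yes, male) or
#' menstrual-cycle phase (no-cycle, first-half, second-half, male) to test
#' for differences within the female group.
#'
#' @param metric per-subject metric values.
#' @param data cohort table with \code{sex}, \code{age}, \code{icv},
#'   \code{hc_use}, \code{mc_phase}, plus any extra covariate columns.
#' @param extra_covariates character vector of additional covariate columns
#'   (e.g. a per-subject mean degree).
#' @param variants which variants to run.
#' @return named list of \code{ols_result}s.
#' @export
covariate_variants <- function(metric, data,
                               extra_covariates = NULL,
                               variants = c("base", "extra", "hc", "mc")) {
  data <- cbind(data, .metric = metric)
  out <- list()
  if ("base" %in% variants) {
    out$base <- fit_ols(.metric ~ sex + age + icv, data)
  }
  if ("extra" %in% variants && length(extra_covariates)) {
    missing_cols <- setdiff(extra_covariates, names(data))
    if (length(missing_cols)) stop("missing covariate columns: ",
                                   paste(missing_cols, collapse = ", "))
    f <- stats::reformulate(c("sex", "age", "icv", extra_covariates),
                            response = ".metric")
    out$extra <- fit_ols(f, data)
  }
  if ("hc" %in% variants) {
    grp <- hormonal_factor(data$sex, data$hc_use,
                           female_levels = c(no = "HC-no", yes = "HC-yes"))
    d2 <- data[!is.na(grp), ]; d2$group <- droplevels(grp[!is.na(grp)])
    check_factor_levels(d2$group, "hc_use")
    out$hc <- fit_ols(.metric ~ group + age + icv, d2)
  }
  if ("mc" %in% variants) {
    grp <- hormonal_factor(data$sex, data$mc_phase,
                           female_levels = c(`no-cycle` = "no-cycle",
                                             `first-half` = "first-half",
                                             `second-half` = "second-half"))
    d2 <- data[!is.na(grp), ]; d2$group <- droplevels(grp[!is.na(grp)])
    check_factor_levels(d2$group, "mc_phase")
    out$mc <- fit_ols(.metric ~ group + age + icv, d2)
  }
  out
}

hormonal_factor <- function(sex, status, female_levels) {
  lv <- c(unname(female_levels), "male")
  out <- rep(NA_character_, length(sex))
  out[sex == "male"] <- "male"
  fem <- sex == "female"
  mapped <- female_levels[status[fem]]
  out[fem] <- unname(mapped)  # unmapped (missing etc.) stay NA -> listwise drop
  factor(out, levels = lv)
}

check_factor_levels <- function(f, what) {
  if (nlevels(f) < 2) {
    stop(sprintf("%s factor collapsed to a single level after dropping missing categories", what))
  }
  invisible(f)
}
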