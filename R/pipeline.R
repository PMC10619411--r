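## End-to-end orchestration: simulate -> build connectomes -> mask ->
## metrics -> group statistics -> node scan -> mediation, with plain-text
## outputs and deterministic seeding.

#' Run the whole analysis pipeline
#'
#' Synthetic mode calibrates the generator, simulates a tally-level cohort,
#' builds and masks the connectivity matrices, computes the four global
#' metrics and node-level clustering, fits the memory mixed model, the
#' ICV-association and sex-difference models for every metric, scans nodes
#' with Bonferroni control, and runs the mediation analysis for total and
#' positive-picture recall.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param seed master seed; every stage derives its own substream from it.
#' @param B bootstrap draws for the mediation stage.
#' @param alpha significance level for the four whole-brain models (0.0125,
#'   i.e. 0.05 Bonferroni-corrected for the four connectome measures).
#' @param include_paths compute the shortest-path based global metrics.
#' @param calibration optional pre-computed calibration (reused across
#'   replicate runs).
#' @param output_dir if non-NULL, write tables, the mask summary, and a log
#'   there.
#' @param mask_theta,mask_k_sd population mask parameters.
#' @return object of class \code{pipeline_result}.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L, B = 2000,
                         alpha = 0.0125, include_paths = TRUE,
                         calibration = NULL, output_dir = NULL,
                         mask_theta = 0.01, mask_k_sd = 2) {
  t_start <- Sys.time()
  if (is.null(calibration)) {
    calibration <- calibrate_effects(config, seed = derive_seed(seed, "calibrate"))
  }
  cohort <- generate_cohort(config, calibration, seed = seed, level = "tally")
  conns <- build_connectomes(cohort$tallies)
  mask <- build_population_mask(conns, theta = mask_theta, k_sd = mask_k_sd)
  masked <- lapply(conns, apply_mask, mask = mask)
  met <- cohort_metrics(masked, include_paths = include_paths)
  subjects <- cohort$subjects
  dat <- cbind(subjects, met$global[match(subjects$id, met$global$id),
                                    c("strength", "cpl", "efficiency",
                                      "transitivity", "connected")])
  dat$mean_degree <- rowMeans(met$degree)

  metrics_avail <- c("strength",
                     if (include_paths) c("cpl", "efficiency"),
                     "transitivity")

  ## model (1): valence x sex memory mixed model
  model_memory <- memory_lmm(subjects)

  ## models (2) and (3) per connectome measure
  model_icv <- lapply(metrics_avail, function(mname) {
    f <- stats::as.formula(paste(mname, "~ sex * icv + age"))
    fit_ols(f, dat)
  })
  names(model_icv) <- metrics_avail
  model_sex <- lapply(metrics_avail, function(mname) {
    f <- stats::as.formula(paste(mname, "~ sex + age + icv"))
    fit_ols(f, dat)
  })
  names(model_sex) <- metrics_avail

  ## node-level clustering scan
  node_scan <- node_level_scan(met$clustering, subjects)

  ## robustness variants for transitivity, adding a wiring-cost covariate:
  ## per-subject mean degree, or global strength when the masked edge set
  ## leaves degree without variance (typical for generated cohorts)
  wiring <- if (stats::sd(dat$mean_degree) > 0) "mean_degree" else "strength"
  variants <- covariate_variants(dat$transitivity,
                                 cbind(subjects, mean_degree = dat$mean_degree,
                                       strength = dat$strength),
                                 extra_covariates = wiring)

  ## model (4): memory ~ connectome x sex x valence
  model_memory_metric <- memory_lmm(subjects, transitivity = dat$transitivity)

  ## partial correlations on the r scale
  covs_mem <- data.frame(age = subjects$age,
                         room2 = as.numeric(subjects$batch == "room2"))
  total_recall <- subjects$recall_neg + subjects$recall_neu + subjects$recall_pos
  r_mem <- partial_correlation(dat$transitivity, total_recall, covs_mem)
  r_age <- partial_correlation(subjects$age, dat$transitivity, NULL)

  ## model (5): mediation, both outcomes
  mediation_all <- run_mediation(subjects, dat$transitivity, outcome = "all",
                                 B = B, seed = derive_seed(seed, "report"))
  mediation_pos <- run_mediation(subjects, dat$transitivity, outcome = "positive",
                                 B = B, seed = derive_seed(seed, "report") + 1L)

  res <- structure(list(config = config, seed = seed, alpha = alpha,
                        calibration = calibration,
                        subjects = dat, mask = mask,
                        metrics = met$global, clustering = met$clustering,
                        model_memory = model_memory,
                        model_icv = model_icv,
                        model_sex = model_sex,
                        node_scan = node_scan,
                        variants = variants,
                        model_memory_metric = model_memory_metric,
                        r_transitivity_memory = r_mem,
                        r_age_transitivity = r_age,
                        mediation_all = mediation_all,
                        mediation_positive = mediation_pos,
                        elapsed = as.numeric(difftime(Sys.time(), t_start,
                                                      units = "secs"))),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_report(res, output_dir)
  res
}

#' Tidy table of the group-comparison models
#'
#' @param result a \code{pipeline_result}.
#' @return data.frame: model, term, F, df1, df2, p, d_or_r, significant
#'   (at the result's alpha).
#' @export
pipeline_model_table <- function(result) {
  rows <- list()
  for (mname in names(result$model_sex)) {
    tab <- result$model_sex[[mname]]$table
    tab$model <- paste0("sex_", mname)
    rows[[length(rows) + 1]] <- tab
  }
  for (mname in names(result$model_icv)) {
    tab <- result$model_icv[[mname]]$table
    tab$model <- paste0("icv_", mname)
    rows[[length(rows) + 1]] <- tab
  }
  mem <- result$model_memory$table
  mem$d_or_r <- NA_real_
  mem$model <- "memory"
  rows[[length(rows) + 1]] <- mem
  memm <- result$model_memory_metric$table
  memm$d_or_r <- NA_real_
  memm$model <- "memory_transitivity"
  rows[[length(rows) + 1]] <- memm
  out <- do.call(rbind, rows)
  out$significant <- out$p <= result$alpha
  out[, c("model", "term", "F", "df1", "df2", "p", "d_or_r", "significant")]
}

#' Write the pipeline report to a directory
#'
#' Emits plain-text/CSV artifacts: the subject-level metric table, the model
#' table, the node scan, the mediation summaries, the mask summary and a run
#' log (seed, sizes, timing). When ggplot2 is installed, boxplot and
#' age-association figures are written as PDFs; otherwise the report
#' degrades to tables only.
#'
#' @param result a \code{pipeline_result}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_pipeline_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$subjects, file.path(dir, "subjects_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(pipeline_model_table(result),
                   file.path(dir, "model_table.csv"), row.names = FALSE)
  utils::write.csv(result$node_scan, file.path(dir, "node_scan.csv"),
                   row.names = FALSE)
  med_rows <- do.call(rbind, lapply(list(result$mediation_all,
                                         result$mediation_positive),
                                    mediation_row))
  utils::write.csv(med_rows, file.path(dir, "mediation.csv"), row.names = FALSE)

  log_lines <- c(
    sprintf("memconn pipeline run, seed %s", result$seed),
    sprintf("n_subjects = %d, n_nodes = %d", nrow(result$subjects),
            ncol(result$clustering)),
    sprintf("mask: %d / %d edges kept (theta = %g, k_sd = %g)",
            result$mask$edges_kept, result$mask$edges_total,
            result$mask$theta, result$mask$k_sd),
    sprintf("node scan: %d / %d nodes significant at alpha/R = %.3g",
            sum(result$node_scan$significant), nrow(result$node_scan),
            attr(result$node_scan, "alpha_node")),
    sprintf("elapsed: %.1f s", result$elapsed))
  writeLines(log_lines, file.path(dir, "run_log.txt"))

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    try(save_report_figures(result, dir), silent = TRUE)
  }
  invisible(dir)
}

mediation_row <- function(m) {
  ci95 <- lapply(m$ci, function(tab) tab[tab$level == 95, ])
  data.frame(outcome = m$outcome %||% NA_character_,
             a = m$paths[["a"]], b = m$paths[["b"]],
             c = m$paths[["c"]], c_prime = m$paths[["c_prime"]],
             indirect = m$paths[["indirect"]], ratio = m$paths[["ratio"]],
             indirect_lo95 = ci95$indirect$lower,
             indirect_hi95 = ci95$indirect$upper,
             significant95 = m$significant$indirect[1],
             B = m$B, stringsAsFactors = FALSE)
}

save_report_figures <- function(result, dir) {
  df <- result$subjects
  p1 <- ggplot2::ggplot(df, ggplot2::aes(x = sex, y = transitivity)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6,
                         ggplot2::aes(colour = sex)) +
    ggplot2::labs(y = "weighted transitivity", x = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(dir, "transitivity_by_sex.pdf"), p1,
                  width = 4, height = 4)
  p2 <- ggplot2::ggplot(df, ggplot2::aes(x = age, y = transitivity, colour = sex)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm", se = FALSE,
                         formula = y ~ x, colour = "black") +
    ggplot2::labs(y = "weighted transitivity", x = "age (years)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(dir, "age_vs_transitivity.pdf"), p2,
                  width = 5, height = 4)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: n = %d, seed = %s, %.1f s\n",
              nrow(x$subjects), x$seed, x$elapsed))
  st <- x$model_sex$transitivity$table
  srow <- st[st$term == "sex", ]
  cat(sprintf("  transitivity sex effect: F(%d, %d) = %.2f, p = %.3g, d = %.3f\n",
              srow$df1, srow$df2, srow$F, srow$p, srow$d_or_r))
  cat(sprintf("  node scan: %d / %d significant\n",
              sum(x$node_scan$significant), nrow(x$node_scan)))
  cat(sprintf("  mediation (all pictures): indirect = %.4f [%s]\n",
              x$mediation_all$paths[["indirect"]],
              paste(sprintf("%.4f", unlist(x$mediation_all$ci$indirect[1, c("lower", "upper")])),
                    collapse = ", ")))
  invisible(x)
}
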