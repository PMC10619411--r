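## Cohort generation: covariates, latent clustering dial, streamline tallies
## (or directly the transitivity metric) and free-recall counts.

#' Generate a synthetic cohort
#'
#' Draws subjects whose population statistics follow the calibrated effect
#' structure: sex and age act on a latent clustering dial; per-subject
#' connectivity matrices arise by mixing the population template at the
#' subject's dial value, applying multiplicative edge noise, and drawing
#' Binomial streamline tallies; recall counts embed valence, sex,
#' sex-by-valence, recall-room and transitivity effects plus a subject
#' random ability.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param calibration a \code{\link{calibrate_effects}} result for this
#'   config; calibrated on the fly (with default settings) when missing.
#' @param seed RNG seed; defaults to \code{config$seed}.
#' @param level \code{"tally"} returns full streamline tallies (the input of
#'   the connectome-construction stage); \code{"metric"} skips tractography
#'   emulation and draws observed weighted transitivity directly from the
#'   calibrated dial-to-metric model, which makes large replicate studies
#'   cheap.
#' @return object of class \code{synthetic_cohort}: \code{subjects} (the
#'   covariate and recall table), \code{tallies} (list of
#'   \code{\link{streamline_tally}}, tally level only), \code{transitivity}
#'   (metric level only), \code{lambda}, and the calibration used.
#' @export
generate_cohort <- function(config, calibration = NULL, seed = config$seed,
                            level = c("tally", "metric")) {
  stopifnot(inherits(config, "cohort_config"))
  level <- match.arg(level)
  if (is.null(calibration)) calibration <- calibrate_effects(config)
  stopifnot(inherits(calibration, "cohort_calibration"))
  check_calibration_match(config, calibration)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, "cohort"))
  }

  covars <- generate_covariates(config)
  male <- as.numeric(covars$sex == "male")
  lambda <- config$lambda0 + calibration$beta_sex * male +
    calibration$beta_age * zscore(covars$age) +
    stats::rnorm(config$n_subjects, 0, calibration$sigma_eps)
  t_lat <- h_eval(calibration$h_coef, lambda)
  z_lat <- (t_lat - calibration$lat_center) / calibration$lat_scale
  recall <- generate_recall(config, covars, z_lat, calibration$gamma_t)
  subjects <- cbind(covars, recall)

  tallies <- NULL
  transitivity <- NULL
  if (level == "tally") {
    tallies <- vector("list", config$n_subjects)
    for (i in seq_len(config$n_subjects)) {
      tallies[[i]] <- simulate_tally(calibration$template, lambda[i],
                                     config$sigma_edge, config$waytotal,
                                     id = subjects$id[i])
    }
    names(tallies) <- subjects$id
  } else {
    transitivity <- t_lat + stats::rnorm(config$n_subjects, 0, calibration$sigma_meas)
  }
  structure(list(subjects = subjects, tallies = tallies,
                 transitivity = transitivity, lambda = lambda,
                 calibration = calibration, config = config,
                 seed = seed, level = level),
            class = "synthetic_cohort")
}

check_calibration_match <- function(config, calibration) {
  cfg0 <- calibration$config
  for (nm in c("n_nodes", "d_transitivity", "r_age_transitivity",
               "r_transitivity_memory", "sd_transitivity", "waytotal",
               "sigma_edge", "lambda0", "template_seed")) {
    if (!isTRUE(all.equal(config[[nm]], cfg0[[nm]]))) {
      warning(sprintf("calibration was run for a config with different '%s'; effects may be off target", nm))
    }
  }
  invisible(TRUE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects (%d female), level = %s\n",
              nrow(x$subjects), sum(x$subjects$sex == "female"), x$level))
  invisible(x)
}

#' Build connectivity matrices from a cohort's tallies
#'
#' Runs each subject's directed tally through the probability conversion and
#' symmetrization steps.
#'
#' @param tallies list of \code{\link{streamline_tally}} objects.
#' @param node_labels optional region names; the packaged Desikan-Killiany +
#'   subcortical labels are used automatically for 82-node matrices.
#' @return list of \code{connectivity_matrix} objects.
#' @export
build_connectomes <- function(tallies, node_labels = NULL) {
  stopifnot(is.list(tallies), length(tallies) >= 1)
  r <- nrow(tallies[[1]]$counts)
  if (is.null(node_labels)) node_labels <- load_node_labels(r)
  lapply(tallies, function(tl) {
    symmetrize(tally_to_probability(tl), node_labels = node_labels, id = tl$id)
  })
}

#' Node labels for a parcellation
#'
#' Returns the packaged Desikan-Killiany (68 cortical) + subcortical (14)
#' label list for 82-node matrices and generic \code{node_###} labels for
#' any other parcellation size.
#'
#' @param r number of nodes.
#' @return character vector of length \code{r}.
#' @export
load_node_labels <- function(r) {
  if (r == 82) {
    f <- system.file("extdata", "node_labels_dk82.txt", package = "memconn")
    if (nzchar(f)) {
      lab <- readLines(f)
      lab <- lab[nzchar(lab) & !startsWith(lab, "#")]
      if (length(lab) == r) return(lab)
    }
  }
  default_node_labels(r)
}

#' Global and node-level metrics for a list of connectivity matrices
#'
#' @param c_list list of (masked) \code{connectivity_matrix} objects.
#' @param include_paths compute shortest-path metrics (see
#'   \code{\link{connectome_metrics}}).
#' @return list with \code{global} (one row per subject) and
#'   \code{clustering} (subject x node matrix of clustering coefficients,
#'   with \code{strength} and \code{degree} matrices alongside).
#' @export
cohort_metrics <- function(c_list, include_paths = TRUE) {
  n <- length(c_list)
  r <- nrow(c_list[[1]])
  labels <- attr(c_list[[1]], "node_labels") %||% default_node_labels(r)
  glob <- vector("list", n)
  clus <- matrix(NA_real_, n, r, dimnames = list(names(c_list), labels))
  stre <- clus; degr <- clus
  for (i in seq_len(n)) {
    glob[[i]] <- connectome_metrics(c_list[[i]], include_paths = include_paths)
    cl <- weighted_clustering(c_list[[i]])
    clus[i, ] <- cl$clustering
    degr[i, ] <- cl$degree
    stre[i, ] <- node_strength(c_list[[i]])
  }
  list(global = do.call(rbind, glob), clustering = clus,
       strength = stre, degree = degr)
}
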