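## Plain-text round-trip of a cohort: one covariate/recall CSV, one
## whitespace-delimited R x R integer count matrix plus a waytotal file per
## subject, and a manifest listing the subjects.

#' Write a cohort to a directory
#'
#' Creates \code{cohort.csv} (header \code{id,sex,age,icv,batch,hc_use,
#' mc_phase,recall_neg,recall_neu,recall_pos}, missing values as empty
#' fields), \code{manifest.txt}, and per subject \code{<id>_counts.tsv} and
#' \code{<id>_waytotal.tsv}. Metric-level cohorts additionally write
#' \code{transitivity.csv} instead of tally files.
#'
#' @param cohort a \code{synthetic_cohort}, or a list with \code{subjects}
#'   and \code{tallies}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subj <- cohort$subjects
  cols <- c("id", "sex", "age", "icv", "batch", "hc_use", "mc_phase",
            "recall_neg", "recall_neu", "recall_pos")
  missing_cols <- setdiff(cols, names(subj))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- subj[, cols]
  out$hc_use[is.na(out$hc_use)] <- ""
  out$mc_phase[is.na(out$mc_phase)] <- ""
  utils::write.csv(out, file.path(dir, "cohort.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  writeLines(subj$id, file.path(dir, "manifest.txt"))
  if (!is.null(cohort$tallies)) {
    for (tl in cohort$tallies) {
      utils::write.table(tl$counts,
                         file.path(dir, paste0(tl$id, "_counts.tsv")),
                         row.names = FALSE, col.names = FALSE, sep = "\t")
      writeLines(format(tl$waytotal, scientific = FALSE, trim = TRUE),
                 file.path(dir, paste0(tl$id, "_waytotal.tsv")))
    }
  }
  if (!is.null(cohort$transitivity)) {
    utils::write.csv(data.frame(id = subj$id, transitivity = cohort$transitivity),
                     file.path(dir, "transitivity.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' Inverse of \code{\link{write_cohort}}. Malformed or missing files raise
#' errors naming the offending file.
#'
#' @param dir directory written by \code{\link{write_cohort}} (or an
#'   equivalent layout holding real connectivity data).
#' @return list with \code{subjects}, \code{tallies} (possibly \code{NULL})
#'   and \code{transitivity} (possibly \code{NULL}).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("no such cohort directory: ", dir)
  cohort_file <- file.path(dir, "cohort.csv")
  manifest_file <- file.path(dir, "manifest.txt")
  if (!file.exists(cohort_file)) stop("missing file: ", cohort_file)
  if (!file.exists(manifest_file)) stop("missing file: ", manifest_file)
  subjects <- utils::read.csv(cohort_file, stringsAsFactors = FALSE, na.strings = "")
  subjects$sex <- factor(subjects$sex, levels = c("female", "male"))
  subjects$batch <- factor(subjects$batch, levels = c("room1", "room2"))
  ids <- readLines(manifest_file)
  if (!identical(sort(ids), sort(subjects$id))) {
    stop("manifest.txt and cohort.csv disagree on subject ids in ", dir)
  }
  tallies <- NULL
  first_counts <- file.path(dir, paste0(ids[1], "_counts.tsv"))
  if (file.exists(first_counts)) {
    tallies <- lapply(ids, function(id) read_tally(dir, id))
    names(tallies) <- ids
  }
  transitivity <- NULL
  tf <- file.path(dir, "transitivity.csv")
  if (file.exists(tf)) {
    tt <- utils::read.csv(tf, stringsAsFactors = FALSE)
    transitivity <- tt$transitivity[match(subjects$id, tt$id)]
  }
  list(subjects = subjects, tallies = tallies, transitivity = transitivity)
}

read_tally <- function(dir, id) {
  cf <- file.path(dir, paste0(id, "_counts.tsv"))
  wf <- file.path(dir, paste0(id, "_waytotal.tsv"))
  if (!file.exists(cf)) stop("missing file: ", cf)
  if (!file.exists(wf)) stop("missing file: ", wf)
  rows <- utils::read.table(cf, header = FALSE)
  counts <- as.matrix(rows)
  if (nrow(counts) != ncol(counts)) {
    stop(sprintf("malformed matrix in %s: %d rows x %d columns",
                 cf, nrow(counts), ncol(counts)))
  }
  waytotal <- as.numeric(readLines(wf))
  if (any(is.na(waytotal))) stop("malformed waytotal file: ", wf)
  tryCatch(streamline_tally(unname(counts), waytotal, id = id),
           error = function(e) stop(sprintf("invalid tally in %s: %s", cf, conditionMessage(e))))
}
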