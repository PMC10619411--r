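## Connectome construction: directed streamline tallies -> symmetric weighted
## connectivity matrix -> population-level spurious-connection mask.

#' Streamline tally for one subject
#'
#' Bundles the directed streamline count matrix produced by probabilistic
#' tractography with the per-seed totals (the number of valid streamlines
#' drawn from each seed region, the "waytotal"). Entry \code{counts[i, j]} is
#' the number of streamlines seeded in region \code{i} that reached region
#' \code{j}; the diagonal is ignored.
#'
#' @param counts integer-valued R x R matrix of non-negative streamline
#'   counts; the diagonal is zeroed.
#' @param waytotal positive numeric vector of length R (streamlines drawn per
#'   seed region) or a single value recycled to all seeds.
#' @param id optional subject identifier.
#' @return An object of class \code{streamline_tally}.
#' @export
streamline_tally <- function(counts, waytotal, id = NULL) {
  check_square(counts, "counts")
  r <- nrow(counts)
  if (r < 3) stop("a tally needs at least 3 nodes")
  if (length(waytotal) == 1) waytotal <- rep(waytotal, r)
  if (length(waytotal) != r) {
    stop(sprintf("waytotal has length %d but the tally has %d nodes",
                 length(waytotal), r))
  }
  if (any(waytotal <= 0)) {
    stop(sprintf("waytotal must be positive for every seed; first offending node: %d",
                 which(waytotal <= 0)[1]))
  }
  if (any(counts < 0)) stop("streamline counts must be non-negative")
  diag(counts) <- 0
  over <- counts > matrix(waytotal, r, r)
  if (any(over)) {
    ij <- which(over, arr.ind = TRUE)[1, ]
    stop(sprintf("counts[%d, %d] exceeds waytotal[%d]; a seed cannot emit more streamlines than were drawn",
                 ij[1], ij[2], ij[1]))
  }
  structure(list(counts = counts, waytotal = as.numeric(waytotal), id = id),
            class = "streamline_tally")
}

#' Convert a streamline tally to a directed connection-probability matrix
#'
#' Each row of counts is divided by the number of valid streamlines drawn
#' from that seed, giving the directed node-to-node connection probability
#' \code{P[i, j] = counts[i, j] / waytotal[i]}. The diagonal is zero.
#'
#' @param tally a \code{\link{streamline_tally}}.
#' @return R x R numeric matrix of directed probabilities in \[0, 1\].
#' @export
tally_to_probability <- function(tally) {
  stopifnot(inherits(tally, "streamline_tally"))
  p <- tally$counts / tally$waytotal  # column-recycling: divides row i by waytotal[i]
  diag(p) <- 0
  p
}

#' Symmetrize a directed probability matrix
#'
#' The undirected connection weight between regions i and j is the average of
#' the i-to-j and j-to-i tracking probabilities.
#'
#' @param p square numeric matrix (directed probabilities, zero diagonal).
#' @param node_labels optional character vector of region names.
#' @param id optional subject identifier.
#' @return A \code{connectivity_matrix}: symmetric, zero-diagonal, entries
#'   clamped to \[0, 1\].
#' @export
symmetrize <- function(p, node_labels = NULL, id = NULL) {
  check_square(p, "probability matrix")
  if (any(!is.finite(p))) stop("probability matrix contains non-finite entries")
  w <- (p + t(p)) / 2
  diag(w) <- 0
  connectivity_matrix(w, node_labels = node_labels, id = id)
}

#' Symmetric weighted connectivity matrix
#'
#' @param w symmetric numeric matrix with zero diagonal; entries are clamped
#'   to \[0, 1\] (tracking weights are probabilities).
#' @param node_labels optional region names (defaults to \code{node_001} ...).
#' @param id optional subject identifier.
#' @return matrix of class \code{connectivity_matrix} with a
#'   \code{node_labels} attribute.
#' @export
connectivity_matrix <- function(w, node_labels = NULL, id = NULL) {
  check_square(w, "connectivity matrix")
  if (!is_symmetric_num(w, tol = 1e-8)) stop("connectivity matrix must be symmetric")
  w <- (w + t(w)) / 2  # remove numerically trivial asymmetry
  diag(w) <- 0
  w <- clip01(w)
  r <- nrow(w)
  if (is.null(node_labels)) node_labels <- default_node_labels(r)
  if (length(node_labels) != r) stop("node_labels length does not match matrix dimension")
  dimnames(w) <- list(node_labels, node_labels)
  structure(w, class = c("connectivity_matrix", "matrix", "array"),
            node_labels = node_labels, id = id)
}

default_node_labels <- function(r) sprintf("node_%03d", seq_len(r))

#' Population-level mask of reliable connections
#'
#' An edge is kept when \code{mean(C_ij) + k_sd * sd(C_ij) >= theta} across
#' subjects, where sd is the sample (n - 1) standard deviation; edges whose
#' criterion falls strictly below the threshold are treated as spurious and
#' removed in every subject. Default threshold 0.01 with k_sd = 2.
#'
#' @param matrices list of \code{connectivity_matrix} objects with identical
#'   dimensions (at least two subjects).
#' @param theta connectivity threshold (default 0.01).
#' @param k_sd number of standard deviations added to the mean (default 2).
#' @return An object of class \code{population_mask}: logical keep matrix plus
#'   the parameters and a kept-edge count.
#' @export
build_population_mask <- function(matrices, theta = 0.01, k_sd = 2) {
  if (!is.list(matrices) || length(matrices) < 2) {
    stop("need at least two subjects to build a population mask")
  }
  r <- nrow(matrices[[1]])
  dims <- vapply(matrices, nrow, integer(1))
  if (any(dims != r)) {
    stop(sprintf("matrix dimensions differ across subjects: %s",
                 paste(unique(dims), collapse = ", ")))
  }
  n <- length(matrices)
  s1 <- matrix(0, r, r)
  s2 <- matrix(0, r, r)
  for (m in matrices) {
    s1 <- s1 + m
    s2 <- s2 + m * m
  }
  mu <- s1 / n
  v <- (s2 - n * mu * mu) / (n - 1)
  v[v < 0] <- 0  # guard tiny negative round-off
  keep <- (mu + k_sd * sqrt(v)) >= theta
  diag(keep) <- FALSE
  keep <- keep & t(keep)
  if (!any(keep)) stop("population mask retains no edges; lower theta")
  structure(list(keep = keep, theta = theta, k_sd = k_sd,
                 n_subjects = n,
                 edges_kept = sum(keep[upper.tri(keep)]),
                 edges_total = r * (r - 1) / 2),
            class = "population_mask")
}

#' @export
print.population_mask <- function(x, ...) {
  cat(sprintf("population_mask: %d / %d edges kept (theta = %g, k_sd = %g, n = %d)\n",
              x$edges_kept, x$edges_total, x$theta, x$k_sd, x$n_subjects))
  invisible(x)
}

#' Apply a population mask to a connectivity matrix
#'
#' Masked edges are set to zero in the subject's matrix; retained edges are
#' unchanged. Applying a mask twice is the same as applying it once.
#'
#' @param c_mat a \code{connectivity_matrix}.
#' @param mask a \code{population_mask} of matching dimension.
#' @return The masked \code{connectivity_matrix}.
#' @export
apply_mask <- function(c_mat, mask) {
  stopifnot(inherits(mask, "population_mask"))
  if (!any(mask$keep)) stop("mask retains no edges")
  if (!all(dim(c_mat) == dim(mask$keep))) {
    stop(sprintf("mask dimension %d does not match matrix dimension %d",
                 nrow(mask$keep), nrow(c_mat)))
  }
  w <- unclass(c_mat)
  w[!mask$keep] <- 0
  connectivity_matrix(w, node_labels = attr(c_mat, "node_labels"),
                      id = attr(c_mat, "id"))
}
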