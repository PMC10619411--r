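## Weighted graph metrics, computed from first principles on the symmetric
## connectivity matrix: node strength, weighted shortest paths (edge length =
## reciprocal weight, Dijkstra per source), characteristic path length,
## global efficiency, and Onnela-style weighted transitivity / clustering.

#' Node strength
#'
#' Strength of a node is the sum of the weights of its adjacent edges, an
#' estimator of physical wiring cost. The global summary is the mean over
#' nodes, which keeps the scale comparable across parcellations.
#'
#' @param c_mat symmetric weighted matrix (a \code{connectivity_matrix} or a
#'   plain matrix).
#' @return numeric vector of per-node strengths with a \code{"global"}
#'   attribute holding the mean.
#' @export
node_strength <- function(c_mat) {
  check_square(c_mat)
  s <- rowSums(unclass(c_mat))
  names(s) <- rownames(c_mat)
  attr(s, "global") <- mean(s)
  s
}

#' Weighted all-pairs shortest path distances
#'
#' Edges are mapped to lengths by the reciprocal of their weight
#' (\code{l_ij = 1 / w_ij}; stronger connections are shorter), and shortest
#' path distances are found by running Dijkstra's algorithm from every
#' source. Unreachable pairs get \code{Inf}; the diagonal is zero.
#'
#' @param c_mat symmetric weighted matrix, weights in \[0, 1\].
#' @return R x R numeric distance matrix.
#' @export
shortest_paths <- function(c_mat) {
  check_square(c_mat)
  w <- unclass(c_mat)
  if (any(w < 0)) stop("weights must be non-negative")
  r <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- Inf  # no self-loops; D[i, i] fixed to 0 below
  d_all <- matrix(Inf, r, r, dimnames = dimnames(w))
  for (s in seq_len(r)) {
    dist <- rep(Inf, r)
    dist[s] <- 0
    done <- rep(FALSE, r)
    for (it in seq_len(r)) {
      u <- which.min(dist + ifelse(done, Inf, 0))
      if (!is.finite(dist[u]) || done[u]) break
      done[u] <- TRUE
      dist <- pmin(dist, dist[u] + len[u, ])
    }
    d_all[s, ] <- dist
  }
  diag(d_all) <- 0
  d_all
}

#' Characteristic path length
#'
#' Mean shortest path distance over ordered pairs of distinct nodes. Pairs
#' that are unreachable are excluded from the mean and the graph is flagged
#' as disconnected rather than raising an error, since population-level
#' masking can in principle disconnect a matrix.
#'
#' @param d distance matrix from \code{\link{shortest_paths}}.
#' @return list with \code{cpl} and logical \code{connected}.
#' @export
characteristic_path_length <- function(d) {
  check_square(d)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  if (!any(finite)) stop("all node pairs are unreachable; path length undefined")
  list(cpl = mean(off[finite]), connected = all(finite))
}

#' Global efficiency
#'
#' Average inverse shortest path length over ordered pairs of distinct
#' nodes, with unreachable pairs contributing zero.
#'
#' @param d distance matrix from \code{\link{shortest_paths}}.
#' @return scalar efficiency (>= 0).
#' @export
global_efficiency <- function(d) {
  check_square(d)
  off <- d[row(d) != col(d)]
  inv <- ifelse(is.finite(off) & off > 0, 1 / off, 0)
  mean(inv)
}

#' Weighted clustering and transitivity
#'
#' Triangle intensity uses the geometric mean of the three edge weights after
#' normalizing the matrix by its maximum weight (Onnela variant):
#' \code{t_i = 1/2 * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)}. The node-level
#' clustering coefficient is \code{C_i = 2 t_i / (k_i (k_i - 1))} (0 when a
#' node has fewer than two neighbours), and the global weighted transitivity
#' is the ratio \code{T = sum_i 2 t_i / sum_i k_i (k_i - 1)} - the prevalence
#' of clustered connectivity around individual nodes.
#'
#' @param c_mat symmetric weighted matrix with zero diagonal.
#' @return list with per-node \code{triangle_intensity}, \code{degree},
#'   \code{clustering}, and the global \code{transitivity} (\code{NA} when
#'   no node has two neighbours, i.e. the graph has no connected triples).
#' @export
weighted_clustering <- function(c_mat) {
  check_square(c_mat)
  w <- unclass(c_mat)
  diag(w) <- 0
  mx <- max(w)
  if (mx <= 0) stop("all-zero matrix: weighted transitivity undefined")
  wh <- (w / mx)^(1 / 3)
  t_i <- diag(wh %*% wh %*% wh) / 2
  k_i <- rowSums(w > 0)
  denom_i <- k_i * (k_i - 1)
  c_i <- ifelse(denom_i > 0, 2 * t_i / denom_i, 0)
  # no node with two neighbours: no connected triples, transitivity undefined
  trans <- if (sum(denom_i) > 0) sum(2 * t_i) / sum(denom_i) else NA_real_
  list(triangle_intensity = t_i,
       degree = k_i,
       clustering = c_i,
       transitivity = trans)
}

#' All global metrics for one connectivity matrix
#'
#' Convenience wrapper computing the four whole-brain characteristics:
#' graph strength (mean node strength), characteristic path length, global
#' efficiency, and weighted transitivity.
#'
#' @param c_mat symmetric weighted matrix.
#' @param include_paths compute the shortest-path based metrics
#'   (characteristic path length and efficiency)? Skipping them makes large
#'   simulation studies that only need strength/transitivity much faster.
#' @return one-row \code{data.frame}: id, strength, cpl, efficiency,
#'   transitivity, connected.
#' @export
connectome_metrics <- function(c_mat, include_paths = TRUE) {
  s <- node_strength(c_mat)
  cl <- weighted_clustering(c_mat)
  if (include_paths) {
    d <- shortest_paths(c_mat)
    pl <- characteristic_path_length(d)
    cpl <- pl$cpl; eff <- global_efficiency(d); conn <- pl$connected
  } else {
    cpl <- NA_real_; eff <- NA_real_; conn <- NA
  }
  data.frame(id = attr(c_mat, "id") %||% NA_character_,
             strength = attr(s, "global"),
             cpl = cpl,
             efficiency = eff,
             transitivity = cl$transitivity,
             connected = conn,
             stringsAsFactors = FALSE)
}

#' Per-node metric table for one subject
#'
#' @param c_mat symmetric weighted matrix.
#' @return \code{data.frame}: id, node_label, strength, degree, clustering.
#' @export
node_metrics <- function(c_mat) {
  s <- node_strength(c_mat)
  cl <- weighted_clustering(c_mat)
  data.frame(id = attr(c_mat, "id") %||% NA_character_,
             node_label = attr(c_mat, "node_labels") %||% default_node_labels(nrow(c_mat)),
             strength = as.numeric(s),
             degree = as.integer(cl$degree),
             clustering = as.numeric(cl$clustering),
             stringsAsFactors = FALSE)
}
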