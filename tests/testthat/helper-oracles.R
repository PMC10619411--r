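# Independent oracles and shared fixtures. The oracles deliberately use
# different algorithms than the package (Floyd-Warshall instead of Dijkstra,
# exhaustive triple loops instead of matrix powers) so agreement is evidence,
# not tautology.

# All-pairs shortest paths by Floyd-Warshall on reciprocal-weight lengths.
fw_distances <- function(w) {
  r <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(r)) {
    for (i in seq_len(r)) {
      for (j in seq_len(r)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Triangle intensities, degrees, clustering and transitivity by explicit
# triple loops over the max-normalized weights.
clustering_bruteforce <- function(w) {
  r <- nrow(w)
  wh <- w / max(w)
  t_i <- numeric(r)
  for (i in seq_len(r)) {
    acc <- 0
    for (j in seq_len(r)) {
      for (h in seq_len(r)) {
        if (j != i && h != i && j != h) {
          acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
        }
      }
    }
    t_i[i] <- acc / 2
  }
  k_i <- rowSums(w > 0)
  den <- k_i * (k_i - 1)
  list(t_i = t_i,
       c_i = ifelse(den > 0, 2 * t_i / den, 0),
       transitivity = sum(2 * t_i) / sum(den))
}

# Random symmetric weighted graph with zero diagonal.
random_graph <- function(r, density = 0.6) {
  w <- matrix(0, r, r)
  ut <- upper.tri(w)
  vals <- ifelse(runif(sum(ut)) < density, runif(sum(ut), 0.05, 1), 0)
  w[ut] <- vals
  w + t(w)
}

# Small study configuration + calibration shared across test files.
# Computed once per test run; small sizes keep the suite fast while leaving
# the calibration machinery fully exercised.
# The 28-node test parcellation has far fewer triangles than the 82-node
# study graph, so its transitivity measurement noise is larger; the target
# between-subject sd is scaled up accordingly.
test_config <- function(...) {
  defaults <- list(n_subjects = 150, n_nodes = 28, n_blocks = 4,
                   waytotal = 2000, sd_transitivity = 0.012, seed = 42L)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

cached_calibration <- new.env(parent = emptyenv())

small_calibration <- function() {
  if (is.null(cached_calibration$cal)) {
    cached_calibration$cal <- calibrate_effects(test_config(), n_pilot = 30000,
                                                n_path = 400, seed = 5L)
  }
  cached_calibration$cal
}

null_config <- function(n = 300) {
  test_config(n_subjects = n, d_transitivity = 0, r_age_transitivity = 0,
              r_transitivity_memory = 0)
}

null_calibration <- function() {
  if (is.null(cached_calibration$cal_null)) {
    cached_calibration$cal_null <- calibrate_effects(null_config(), n_pilot = 30000,
                                                     n_path = 400, seed = 6L)
  }
  cached_calibration$cal_null
}

# Linear-Gaussian mediation data with known population paths on the
# standardized scale: cor(x*, m) = a; y ~ x + m has coefficients c_prime and
# b; true indirect = a * b.
linear_mediation_data <- function(n, a = 0.3, b = -0.25, c_prime = -0.15) {
  x <- rbinom(n, 1, 0.5)
  xs <- (x - mean(x)) / sd(x)
  m <- a * xs + sqrt(1 - a^2) * rnorm(n)
  s2 <- 1 - (c_prime^2 + b^2 + 2 * a * b * c_prime)
  y <- c_prime * xs + b * m + sqrt(s2) * rnorm(n)
  list(x = x, m = m, y = y, indirect = a * b)
}
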