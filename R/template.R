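## Latent network model behind the synthetic cohort: a block-modular weight
## template W0, a triangle-enriched companion T0, and a per-subject scalar
## "clustering dial" lambda that mixes the two. The dial is the single latent
## axis on which sex and age act, so the generator realizes a global
## transitivity difference without hand-placing node-level effects.

#' Build the latent network template
#'
#' \code{W0} is a symmetric block-modular weight matrix: strong within-block
#' edges, moderate between-block edges, plus a weak/absent tail of
#' between-block connections (so the population-level spurious-connection
#' mask has something to do). The companion \code{T0} re-weights the strong
#' "core" edges by their triangle support: the elementwise product of
#' \code{W0} with its normalized two-step weighted walk matrix, compressed by
#' a cube root (the scale on which geometric-mean triangle intensity lives)
#' and rescaled to maximum 1. Mixing towards \code{T0} evens out the
#' triangle-bearing core and raises weighted transitivity; the monotonicity
#' of transitivity in the mixing dial is asserted numerically in the tests.
#'
#' @param n_nodes number of parcellation nodes (>= 3).
#' @param n_blocks number of modules (>= 2).
#' @param w_within within-block edge weight level.
#' @param w_between between-block edge weight level; must satisfy
#'   \code{0 <= w_between < w_within <= 1}.
#' @param p_weak probability a between-block edge is drawn from the weak
#'   (sub-threshold) tail.
#' @param p_zero probability a between-block edge is absent.
#' @param jitter_sd log-normal sd of deterministic edge-level jitter.
#' @param core_min minimum weight for an edge to belong to the enriched core.
#' @param seed RNG seed for the template draw.
#' @return object of class \code{latent_network_model} with elements
#'   \code{W0}, \code{T0}, \code{blocks}, and the parameters.
#' @export
make_template <- function(n_nodes = 82, n_blocks = 7,
                          w_within = 0.78, w_between = 0.55,
                          p_weak = 0.35, p_zero = 0.10,
                          jitter_sd = 0.10, core_min = 0.05,
                          seed = 1L) {
  if (n_nodes < 3) stop("n_nodes must be at least 3")
  if (n_blocks < 2) stop("n_blocks must be at least 2")
  if (!(w_between >= 0 && w_between < w_within && w_within <= 1)) {
    stop("need 0 <= w_between < w_within <= 1")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  blocks <- sort(rep_len(seq_len(n_blocks), n_nodes))
  same <- outer(blocks, blocks, "==")
  w0 <- matrix(0, n_nodes, n_nodes)
  ut <- upper.tri(w0)
  base <- ifelse(same[ut], w_within, w_between)
  kind <- rep("core", sum(ut))
  between <- !same[ut]
  u <- stats::runif(sum(ut))
  kind[between & u < p_zero] <- "zero"
  kind[between & u >= p_zero & u < p_zero + p_weak] <- "weak"
  wvals <- base * exp(stats::rnorm(sum(ut), 0, jitter_sd))
  wvals[kind == "weak"] <- stats::runif(sum(kind == "weak"), 0, 0.006)
  wvals[kind == "zero"] <- 0
  w0[ut] <- clip01(wvals)
  w0 <- w0 + t(w0)
  if (all(w0 == 0)) stop("degenerate template: all weights zero")

  t0 <- triangle_enrich(w0, core_min = core_min)
  structure(list(W0 = w0, T0 = t0, blocks = blocks,
                 n_nodes = n_nodes, n_blocks = n_blocks,
                 w_within = w_within, w_between = w_between,
                 core_min = core_min, seed = seed),
            class = "latent_network_model")
}

## Triangle-enriched companion of a weight matrix. Core edges (weight >=
## core_min) get (w * s)^(1/3) where s is the max-normalized two-step walk
## support, rescaled to max 1; weak and absent edges are carried over
## unchanged so the sparsity structure is dial-invariant.
triangle_enrich <- function(w0, core_min = 0.05) {
  s <- w0 %*% w0
  diag(s) <- 0
  core <- w0 >= core_min
  if (!any(core)) stop("degenerate template: no core edges to enrich")
  s_norm <- s / max(s[core])
  raw <- (pmax(w0 * s_norm, 0))^(1 / 3)
  t0 <- w0
  t0[core] <- raw[core] / max(raw[core])
  diag(t0) <- 0
  t0
}

#' Mix the template along the clustering dial
#'
#' \code{mix(lambda) = clip((1 - lambda) W0 + lambda T0)}. The dial is a real
#' scalar; values outside \[0, 1\] extrapolate and are clipped edgewise.
#'
#' @param model a \code{latent_network_model}.
#' @param lambda scalar dial value.
#' @return symmetric weight matrix in \[0, 1\], zero diagonal.
#' @export
mix_template <- function(model, lambda) {
  stopifnot(inherits(model, "latent_network_model"), length(lambda) == 1)
  clip01((1 - lambda) * model$W0 + lambda * model$T0)
}

#' Exact transitivity of the mixed template over a dial grid
#'
#' @param model a \code{latent_network_model}.
#' @param lambdas numeric vector of dial values.
#' @return data.frame with \code{lambda} and \code{transitivity}.
#' @export
template_transitivity_grid <- function(model, lambdas = seq(0, 1, length.out = 21)) {
  tv <- vapply(lambdas, function(l) {
    weighted_clustering(mix_template(model, l))$transitivity
  }, numeric(1))
  data.frame(lambda = lambdas, transitivity = tv)
}

#' @export
print.latent_network_model <- function(x, ...) {
  cat(sprintf("latent_network_model: %d nodes, %d blocks, w_within = %g, w_between = %g\n",
              x$n_nodes, x$n_blocks, x$w_within, x$w_between))
  g <- template_transitivity_grid(x, c(0, 0.5, 1))
  cat(sprintf("  transitivity of mix(0, 0.5, 1): %.4f, %.4f, %.4f\n",
              g$transitivity[1], g$transitivity[2], g$transitivity[3]))
  invisible(x)
}

## Save/restore the global RNG state so seeded constructors do not disturb
## the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
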