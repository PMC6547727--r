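# Vectorized full-model (sampled causal configurations) likelihood over a
# whole panel. The per-replicate causal draws are made once per fit and kept
# fixed, so the objective is a deterministic function of the parameters
# during optimization (a stochastic objective would defeat Nelder-Mead).

#' Precompute full-model replicate draws for a panel
#'
#' Lays out all stored LD neighbor pairs (self included) as flat arrays and
#' attaches `K` uniform draws per (neighbor, replicate); thresholding these
#' uniforms against the mixture weights reproduces component-label draws
#' for every replicate at any parameter value without re-simulation.
#'
#' @param ld An [ld_matrix()].
#' @param panel A [reference_panel()].
#' @param K Number of replicates (causal configurations).
#' @param seed Integer seed.
#' @return An opaque list consumed by [full_loglik_panel()].
#' @export
full_model_draws <- function(ld, panel, K = 20L, seed = 1L) {
  m <- nrow(panel)
  e <- ld_edges(ld)
  nbr_snp <- c(seq_len(m), e$j)          # focal SNP of each entry
  hr2 <- c(panel$het, panel$het[e$i] * e$r^2)
  o <- order(nbr_snp)
  nbr_snp <- nbr_snp[o]; hr2 <- hr2[o]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_substream(seed, "full_draws"))
  U <- matrix(runif(length(hr2) * K), length(hr2), K)
  list(m = m, K = as.integer(K), nbr_snp = nbr_snp, hr2 = hr2, U = U)
}

# per-SNP, per-replicate tagged sums  sum_{i in component} H_i r_ij^2
replicate_sums <- function(draws, lo, hi) {
  if (hi <= lo) return(matrix(0, draws$m, draws$K))
  tagged <- (draws$U >= lo & draws$U < hi) * draws$hr2
  rowsum(tagged, draws$nbr_snp, reorder = TRUE)
}

#' Full-model weighted log-likelihood over a panel
#'
#' Evaluates the sampled-causal-configuration likelihood of every SNP at
#' once: each replicate k assigns component labels to all neighbor pairs
#' (by thresholding the precomputed uniforms), accumulates the tagged
#' covariance per SNP, and the per-SNP density is the average of the K
#' Gaussian densities. Used for the final tuning stage of the fits, where
#' the analytic fast model's moment approximation leaves a residual bias in
#' the polygenicity parameters.
#'
#' @param params [univariate_params()] or [bivariate_params()].
#' @param z1,z2 z-score vectors (z2 = NULL for univariate).
#' @param n1,n2 Sample sizes (scalar or per SNP).
#' @param weights Per-SNP pruning weights.
#' @param draws From [full_model_draws()].
#' @return The weighted log-likelihood.
#' @export
full_loglik_panel <- function(params, z1, z2 = NULL, n1, n2 = NULL, weights,
                              draws) {
  w <- if (is.data.frame(weights)) weights$w else weights
  use <- w > 0
  if (inherits(params, "univariate_params")) {
    S <- replicate_sums(draws, 0, params$pi1)
    v <- n1 * params$sigma_beta2 * S + params$sigma0_2
    ldm <- dnorm(z1, 0, sqrt(v), log = TRUE)      # recycles z1 down columns
    mx <- as.vector(do.call(pmax, asplit(ldm, 2)))
    ll <- mx + log(rowMeans(exp(ldm - mx)))
    sum(w[use] * ll[use])
  } else {
    p1 <- params$pi1; p2 <- params$pi2; p12 <- params$pi12
    S1 <- replicate_sums(draws, 0, p1)
    S2 <- replicate_sums(draws, p1, p1 + p2)
    S12 <- replicate_sums(draws, p1 + p2, p1 + p2 + p12)
    s12 <- params$rho12 * sqrt(params$sigma1_2 * params$sigma2_2)
    r0 <- params$rho0 * sqrt(params$sigma01_2 * params$sigma02_2)
    v11 <- n1 * params$sigma1_2 * (S1 + S12) + params$sigma01_2
    v22 <- n2 * params$sigma2_2 * (S2 + S12) + params$sigma02_2
    v12 <- sqrt(n1 * n2) * s12 * S12 + r0
    det <- pmax(v11 * v22 - v12^2, 1e-300)
    q <- (v22 * z1^2 - 2 * v12 * z1 * z2 + v11 * z2^2) / det
    ldm <- -log(2 * pi) - 0.5 * log(det) - 0.5 * q
    mx <- as.vector(do.call(pmax, asplit(ldm, 2)))
    ll <- mx + log(rowMeans(exp(ldm - mx)))
    sum(w[use] * ll[use])
  }
}
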