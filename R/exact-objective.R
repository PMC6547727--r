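# Exact-enumeration evaluation of the full (causal-configuration) model.
#
# The full model defines pdf_j(z) as the expectation over random causal
# configurations of the neighbors of SNP j. At cluster scale this
# expectation is approximated by sampling K configurations; at desk scale,
# where stored neighbor sets are small and polygenicity is low, it can be
# evaluated in closed form by enumerating the configurations with zero or
# one causal neighbor exactly and lumping the (rare) configurations with
# two or more causal neighbors into a single Gaussian at their mean tagged
# variance. The result is the K -> infinity limit of the sampled mixture up
# to the lumping of a small remainder mass, and is deterministic.

#' Precompute the neighbor layout for the exact full-model likelihood
#'
#' @param ld An [ld_matrix()].
#' @param panel A [reference_panel()].
#' @return An opaque list consumed by [exact_loglik_panel()].
#' @export
exact_model_structure <- function(ld, panel) {
  m <- nrow(panel)
  e <- ld_edges(ld)
  nbr_snp <- c(seq_len(m), e$j)
  a <- c(panel$het, panel$het[e$i] * e$r^2)   # H_i r_ij^2 per entry
  o <- order(nbr_snp)
  nbr_snp <- nbr_snp[o]; a <- a[o]
  deg <- tabulate(nbr_snp, nbins = m)
  suma <- as.vector(rowsum(a, nbr_snp, reorder = TRUE))
  list(m = m, nbr_snp = nbr_snp, a = a, deg = deg, suma = suma)
}

# group-sum of an entry-level vector back to SNPs
entry_rowsum <- function(x, st) as.vector(rowsum(x, st$nbr_snp, reorder = TRUE))

#' Exact full-model weighted log-likelihood over a panel
#'
#' Evaluates, for every SNP, the causal-configuration expectation of the
#' z-score density: configurations with no causal neighbor and with exactly
#' one causal neighbor are enumerated exactly; configurations with two or
#' more causal neighbors contribute a Gaussian at their conditional mean
#' tagged covariance. Exact up to that lumping (a
#' few percent of probability mass at the polygenicities where the model
#' operates), and the deterministic objective used for final tuning of the
#' fits.
#'
#' @param params [univariate_params()] or [bivariate_params()].
#' @param z1,z2 z-score vectors (`z2 = NULL` for univariate).
#' @param n1,n2 GWAS sample sizes (scalars or per-SNP vectors).
#' @param weights Per-SNP pruning weights.
#' @param st Structure from [exact_model_structure()].
#' @return The weighted log-likelihood.
#' @export
exact_loglik_panel <- function(params, z1, z2 = NULL, n1, n2 = NULL, weights,
                               st) {
  w <- if (is.data.frame(weights)) weights$w else weights
  if (inherits(params, "univariate_params")) {
    pi1 <- min(params$pi1, 1 - 1e-12)
    s2 <- params$sigma_beta2; s02 <- params$sigma0_2
    pi0 <- 1 - pi1
    P0 <- pi0^st$deg                       # no causal neighbor
    P0m1 <- pi0^(st$deg - 1)
    dens <- P0 * dnorm(z1, 0, sqrt(s02))
    n1e <- if (length(n1) > 1) n1[st$nbr_snp] else n1
    ve <- pmax(n1e * s2 * st$a + s02, 1e-12)
    de <- dnorm(z1[st$nbr_snp], 0, sqrt(ve))
    dens <- dens + pi1 * P0m1 * entry_rowsum(de, st)
    R <- pmax(1 - P0 - pi1 * P0m1 * st$deg, 0)
    mS <- pi1 * st$suma * pmax(1 - P0m1, 0) / pmax(R, 1e-300)
    n1s <- if (length(n1) > 1) n1 else rep(n1, st$m)
    dens <- dens + R * dnorm(z1, 0, sqrt(pmax(n1s * s2 * mS + s02, 1e-12)))
    ll <- log(pmax(dens, 1e-300))
    sum(w[w > 0] * ll[w > 0])
  } else {
    pis <- c(params$pi1, params$pi2, params$pi12)
    pi0 <- max(1 - sum(pis), 1e-12)
    s12 <- params$rho12 * sqrt(params$sigma1_2 * params$sigma2_2)
    r0 <- params$rho0 * sqrt(params$sigma01_2 * params$sigma02_2)
    # per-component z-scale covariance of one tagged unit a = H r^2:
    # c(v11, v22, v12) multipliers
    n1s <- if (length(n1) > 1) n1 else rep(n1, st$m)
    n2s <- if (length(n2) > 1) n2 else rep(n2, st$m)
    cmult <- list(c1 = c(params$sigma1_2, 0, 0),
                  c2 = c(0, params$sigma2_2, 0),
                  c12 = c(params$sigma1_2, params$sigma2_2, s12))
    P0 <- pi0^st$deg
    P0m1 <- pi0^(st$deg - 1)
    dbvn <- function(v11, v22, v12, zz1, zz2) {
      exp(dbvn_log(zz1, zz2, v11, v22, v12))
    }
    dens <- P0 * dbvn(params$sigma01_2, params$sigma02_2, r0, z1, z2)
    n1e <- n1s[st$nbr_snp]; n2e <- n2s[st$nbr_snp]
    z1e <- z1[st$nbr_snp]; z2e <- z2[st$nbr_snp]
    for (ci in 1:3) {
      if (pis[ci] <= 0) next
      mult <- cmult[[ci]]
      de <- dbvn(n1e * mult[1] * st$a + params$sigma01_2,
                 n2e * mult[2] * st$a + params$sigma02_2,
                 sqrt(n1e * n2e) * mult[3] * st$a + r0, z1e, z2e)
      dens <- dens + pis[ci] * P0m1 * entry_rowsum(de, st)
    }
    R <- pmax(1 - P0 - sum(pis) * P0m1 * st$deg, 0)
    mean_tag <- st$suma * pmax(1 - P0m1, 0) / pmax(R, 1e-300)
    mv11 <- mv22 <- mv12 <- rep(0, st$m)
    for (ci in 1:3) {
      mult <- cmult[[ci]]
      mv11 <- mv11 + pis[ci] * mult[1]
      mv22 <- mv22 + pis[ci] * mult[2]
      mv12 <- mv12 + pis[ci] * mult[3]
    }
    dens <- dens + R * dbvn(n1s * mv11 * mean_tag + params$sigma01_2,
                            n2s * mv22 * mean_tag + params$sigma02_2,
                            sqrt(n1s * n2s) * mv12 * mean_tag + r0, z1, z2)
    ll <- log(pmax(dens, 1e-300))
    sum(w[w > 0] * ll[w > 0])
  }
}
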