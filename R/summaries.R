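#' SNP heritability on the observed scale
#'
#' \eqn{h^2 = \pi_1 H_{total} \sigma_\beta^2}: the expected sum of
#' per-variant contributions \eqn{\beta_j^2 H_j} over causal variants,
#' approximated through the total reference heterozygosity.
#'
#' @param params A [univariate_params()].
#' @param H_total Total heterozygosity \eqn{\sum_j 2 p_j (1 - p_j)} of the
#'   reference (see [total_heterozygosity()]).
#' @return The SNP heritability estimate.
#' @export
heritability <- function(params, H_total) {
  params$pi1 * H_total * params$sigma_beta2
}

#' Genome-wide genetic correlation from mixture parameters
#'
#' \eqn{r_g = \rho_{12}\, \pi_{12} / \sqrt{\pi_1^u \pi_2^u}} with
#' \eqn{\pi_1^u = \pi_1 + \pi_{12}} and \eqn{\pi_2^u = \pi_2 + \pi_{12}}:
#' the within-shared-component correlation diluted by the fraction of each
#' trait's causal variants that are shared. Complete overlap
#' (\eqn{\pi_1 = \pi_2 = 0}) gives \eqn{r_g = \rho_{12}} exactly, and in
#' general \eqn{|r_g| \le |\rho_{12}|}.
#'
#' @param params A [bivariate_params()].
#' @return The genome-wide genetic correlation.
#' @examples
#' # reconstructing a published-style estimate from component counts
#' p <- params_from_counts(n1 = 2.10, n2 = 0.21, n12 = 6.19, rho12 = 0.853)
#' genetic_correlation(p)  # ~0.725
#' @export
genetic_correlation <- function(params) {
  pi1u <- params$pi1 + params$pi12
  pi2u <- params$pi2 + params$pi12
  if (pi1u <= 0 || pi2u <= 0)
    abort("genetic correlation undefined: zero total polygenicity.")
  params$rho12 * params$pi12 / sqrt(pi1u * pi2u)
}

#' Bivariate parameters from causal-variant counts
#'
#' Convenience constructor when only component sizes (any common unit, e.g.
#' thousands of variants) and the shared-component correlation are known;
#' genetic correlation depends on the counts only through their ratios.
#'
#' @param n1,n2,n12 Component sizes (trait-1-specific, trait-2-specific,
#'   shared), same units.
#' @param rho12 Correlation of effect sizes in the shared component.
#' @param M Reference size in the same units (default: large enough that
#'   weights are valid fractions).
#' @return A [bivariate_params()] with placeholder variances.
#' @export
params_from_counts <- function(n1, n2, n12, rho12, M = NULL) {
  M <- M %||% (1000 * (n1 + n2 + n12) + 1)
  bivariate_params(n1 / M, n2 / M, max(n12 / M, 1e-300), 1e-5, 1e-5, rho12)
}

#' Fraction of causal variants explaining a target heritability share
#'
#' Monte-Carlo estimate of the smallest fraction of causal variants whose
#' per-variant contributions \eqn{\beta_j^2 H_j} (sorted, largest first)
#' cumulatively reach `target` of the total. Used to report causal-variant
#' counts without extrapolating into infinitesimally small effects. The
#' result is invariant to rescaling `sigma_beta2`.
#'
#' @param params A [univariate_params()] (only the Gaussian effect shape
#'   matters).
#' @param het_sample Numeric vector of heterozygosities to sample from
#'   (e.g. `panel$het`).
#' @param target Heritability share, in (0, 1] (default 0.9).
#' @param n_draws Number of sampled causal effects (default 10000).
#' @param seed Integer seed.
#' @return The causal-variant fraction, in (0, 1].
#' @export
causal_fraction_for_h2 <- function(params, het_sample, target = 0.9,
                                   n_draws = 10000L, seed = 1L) {
  if (target <= 0 || target > 1) abort("`target` must lie in (0, 1].")
  if (!length(het_sample)) abort("`het_sample` must be nonempty.")
  if (target == 1) return(1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_substream(seed, "causal_fraction"))
  H <- sample(het_sample, n_draws, replace = TRUE)
  beta <- rnorm(n_draws, 0, sqrt(max(params$sigma_beta2, 1e-300)))
  v <- sort(beta^2 * H, decreasing = TRUE)
  k <- which(cumsum(v) >= target * sum(v))[1]
  k / n_draws
}

#' Venn-diagram causal-variant counts
#'
#' Converts fitted mixture weights into counts of causal variants per
#' component (trait-1-specific, trait-2-specific, shared), both raw
#' (\eqn{\pi_c M}) and adjusted to the subset of variants that jointly
#' explains a given share of heritability (default 90%) in each component.
#' Unique components use each trait's own [causal_fraction_for_h2()];
#' the shared component uses the geometric mean of the two traits'
#' fractions. Standard errors come from [propagate()] when a parameter
#' covariance is attached to the fit.
#'
#' @param fit2 A bivariate `mix_fit` (with `covariance` set for SEs).
#' @param M_ref Number of SNPs in the reference.
#' @param het_sample Heterozygosity sample for the adjustment.
#' @param level Heritability share for the adjustment (default 0.9).
#' @param n_draws,seed Monte-Carlo settings for the adjustment fractions.
#' @return A tibble with columns `component`, `raw_count`,
#'   `adjusted_count`, `se` and the per-trait fractions as attributes.
#' @export
venn_counts <- function(fit2, M_ref, het_sample, level = 0.9,
                        n_draws = 10000L, seed = 1L) {
  p <- fit2$params
  f1 <- causal_fraction_for_h2(univariate_params(max(p$pi1 + p$pi12, 1e-12),
                                                 p$sigma1_2),
                               het_sample, target = level,
                               n_draws = n_draws, seed = seed)
  f2 <- causal_fraction_for_h2(univariate_params(max(p$pi2 + p$pi12, 1e-12),
                                                 p$sigma2_2),
                               het_sample, target = level,
                               n_draws = n_draws, seed = seed + 1L)
  f12 <- sqrt(f1 * f2)
  raw <- c(n1 = p$pi1 * M_ref, n2 = p$pi2 * M_ref, n12 = p$pi12 * M_ref)
  adj <- c(raw["n1"] * f1, raw["n2"] * f2, raw["n12"] * f12)
  se <- rep(NA_real_, 3)
  if (!is.null(fit2$covariance)) {
    fac <- c(f1, f2, f12)
    for (i in 1:3) {
      nm <- c("pi1", "pi2", "pi12")[i]
      pr <- propagate(fit2$covariance,
                      function(q) q[[nm]] * M_ref * fac[i],
                      n_draws = 1000L, seed = seed + i)
      se[i] <- pr$se
    }
  }
  out <- tibble(component = c("trait1_only", "trait2_only", "shared"),
                raw_count = unname(raw), adjusted_count = unname(adj), se = se)
  attr(out, "fraction_rule") <- level
  attr(out, "fractions") <- c(trait1 = f1, trait2 = f2, shared = f12)
  out
}

#' Genome-wide significance threshold as a z-score
#'
#' Two-sided Gaussian quantile: the z with \eqn{2(1 - \Phi(z)) = \alpha}.
#'
#' @param alpha Two-sided significance level, in (0, 1).
#' @return The threshold z-score (5.45 for the conventional 5e-8).
#' @examples
#' significance_z(5e-8)  # 5.45
#' @export
significance_z <- function(alpha) {
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  qnorm(alpha / 2, lower.tail = FALSE)
}

# C(z, N, j) on a z-grid for one context: prior-weighted posterior second
# moment of the noncentrality, via Gauss-Hermite quadrature over delta
power_C <- function(zgrid, s2, pi_adj, sigma0_2, gh) {
  if (s2 <= 0 || pi_adj <= 0) return(numeric(length(zgrid)))
  delta <- sqrt(2 * s2) * gh$nodes
  # sum_i w_i/sqrt(pi) * delta_i^2 * phi(z - delta_i; sigma0)
  W <- gh$weights / sqrt(pi)
  dens <- outer(zgrid, delta, function(z, d) dnorm(z, d, sqrt(sigma0_2)))
  pi_adj * as.vector(dens %*% (W * delta^2))
}

#' GWAS power curve
#'
#' Projects the proportion S(N) of SNP heritability captured by genome-wide
#' significant SNPs at sample size N:
#' \eqn{S(N) = \sum_j \int_{|z| \ge z_t} C(z,N,j) dz \; / \; \sum_j \int_z
#' C(z,N,j) dz} where \eqn{C(z,N,j)} is the density of z times the
#' posterior mean noncentrality \eqn{E(\delta^2 | z)}, evaluated by
#' Gauss-Hermite quadrature (64 nodes) under the fast-model prior of each
#' sampled SNP context and integrated on a z-grid from 0 to 38 in steps of
#' 0.05.
#'
#' @param params A fitted [univariate_params()].
#' @param contexts A subsample of [snp_contexts()] rows (e.g. 1% of the
#'   reference).
#' @param N_grid Vector of GWAS sample sizes.
#' @param z_t Significance threshold (default 5.45).
#' @return A tibble of class `power_curve` with columns `N` and `S`;
#'   S is nondecreasing in N.
#' @export
power_curve <- function(params, contexts, N_grid, z_t = 5.45) {
  if (!nrow(contexts)) abort("empty context sample.")
  gh <- statmod::gauss.quad(64, kind = "hermite")
  dz <- 0.05
  # interior grid [0, z_t] (capped at the conventional 38); the total mass
  # integral has the closed form  int C dz = pi' E[delta^2] = pi' s2, so the
  # significant-tail numerator is total minus interior — stable for any N
  zgrid <- seq(0, min(z_t, 38), by = dz)
  S <- vapply(N_grid, function(N) {
    num <- 0; den <- 0
    for (j in seq_len(nrow(contexts))) {
      eta <- eta_shape(params$pi1, contexts$ell[j], contexts$m4_ratio[j])
      pi_adj <- min(contexts$ell[j] * params$pi1 / eta, 1)
      s2 <- N * eta * params$sigma_beta2
      total <- pi_adj * s2
      interior <- if (z_t <= 0) 0 else {
        Cz <- power_C(zgrid, s2, pi_adj, params$sigma0_2, gh)
        2 * (sum(Cz) - 0.5 * (Cz[1] + Cz[length(Cz)])) * dz  # trapezoid
      }
      num <- num + max(total - interior, 0)
      den <- den + total
    }
    if (den <= 0) 0 else min(num / den, 1)
  }, numeric(1))
  out <- tibble(N = N_grid, S = S)
  attr(out, "z_t") <- z_t
  class(out) <- c("power_curve", class(out))
  out
}

#' @rdname power_curve
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.power_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$N, y = .data$S)) +
    geom_line() + geom_point() +
    scale_x_log10() +
    labs(x = "GWAS sample size N", y = "share of h2 from significant SNPs") +
    ylim(0, 1) + theme_minimal()
}
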