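#' Default desk-scale study conditions
#'
#' The simulation conditions used throughout the package's validation
#' harness: a 20,000-SNP block-LD panel (400 blocks of 50 SNPs, AR
#' correlation 0.9), a 1/p common-variant MAF spectrum truncated to
#' \[0.05, 0.5\], total polygenicity 3e-3 per trait, N = 100,000, unit
#' residual variance and no sample overlap.
#'
#' The per-variant effect variance is back-solved on the realized panel so
#' that the genome-wide signal — the mean chi-square inflation
#' \eqn{E[z^2] - 1 = N \pi \sigma_\beta^2 \bar\ell} — matches a full-scale
#' GWAS with h2 = 0.4, polygenicity 3e-3 and the LD profile of a
#' whole-genome reference (median adjusted LD score ~63, mean
#' heterozygosity ~0.2 over 11.0M variants). Matching the aggregate signal,
#' rather than the raw per-variant variance, is what makes a 20K-SNP panel
#' informationally comparable to the powered full-scale regime.
#'
#' @param n_snps Panel size (block_size fixed at 50).
#' @param pi_u Total polygenicity per trait.
#' @param N GWAS sample size.
#' @param h2_equiv Full-scale heritability whose aggregate signal is
#'   matched.
#' @param M_full,ell_full,het_full Full-scale reference size, typical
#'   adjusted LD score and mean heterozygosity used in the matching.
#' @return A named list of study conditions; `target_inflation` is the mean
#'   chi-square inflation the effect variance is solved for.
#' @export
study_conditions <- function(n_snps = 20000L, pi_u = 3e-3, N = 1e5,
                             h2_equiv = 0.4, M_full = 11015833,
                             ell_full = 63.5, het_full = 0.2) {
  block_size <- 50L
  list(n_blocks = as.integer(n_snps / block_size), block_size = block_size,
       phi = c(0.3, 0.97), maf_spectrum = "oneoverp", maf_range = c(0.05, 0.5),
       pi_u = pi_u, N = N,
       target_inflation = N * h2_equiv * ell_full / (M_full * het_full),
       sigma0_2 = 1, rho0 = 0)
}

# build panel + LD + contexts + pruning weights once per set of conditions;
# solves sigma_beta2 on the realized panel so E[z^2] - 1 hits the target
harness_reference <- function(cond, seed) {
  pan <- make_panel(cond$n_blocks, cond$block_size, phi = cond$phi,
                    maf_spectrum = cond$maf_spectrum,
                    maf_range = cond$maf_range, seed = seed)
  ctx <- snp_contexts(pan$ld, pan$panel, n1 = cond$N, n2 = cond$N)
  w <- random_pruning_weights(pan$ld, r2_thresh = 0.1, T = 64L,
                              seed = rng_substream(seed, "weights"))
  sigma_beta2 <- cond$target_inflation / (cond$N * cond$pi_u * mean(ctx$ell))
  list(panel = pan$panel, ld = pan$ld, contexts = ctx, weights = w,
       sigma_beta2 = sigma_beta2,
       exact_structure = exact_model_structure(pan$ld, pan$panel))
}

# simulate one bivariate GWAS pair and run the staged fit
harness_fit_once <- function(ref, cond, spec, fit_options = list()) {
  eff <- draw_effects(spec, ref$panel)
  ss <- simulate_z(eff, ref$panel, ref$ld, N1 = cond$N, N2 = cond$N,
                   sigma01_2 = cond$sigma0_2, sigma02_2 = cond$sigma0_2,
                   rho0 = cond$rho0, seed = rng_substream(spec$seed, "zsim"))
  fit_options <- modifyList(list(exact_structure = ref$exact_structure),
                            fit_options)
  f1 <- fit_univariate(ss$trait1, ref$contexts, ref$weights, fit_options)
  f2 <- fit_univariate(ss$trait2, ref$contexts, ref$weights, fit_options)
  f12 <- fit_bivariate(f1, f2, ss$trait1, ss$trait2, ref$contexts,
                       ref$weights, fit_options)
  list(effects = eff, sumstats = ss, fit1 = f1, fit2 = f2, fit12 = f12)
}

#' MAF-dependence sensitivity harness
#'
#' Simulates bivariate GWAS pairs whose causal effects follow a
#' MAF-dependent architecture (effect variance proportional to
#' \eqn{H_j^S}), fits the MAF-independent mixture model, and measures the
#' relative bias of the shared-component polygenicity estimate. The
#' simulated scenario is complete polygenic overlap (`pi12 = pi_u`,
#' `rho12 = 0.5`) under [study_conditions()], which concentrates all causal
#' variants in the component being measured.
#'
#' @param S MAF-dependence exponent (default -0.75, the most extreme value
#'   a MAF-independent fit is expected to tolerate).
#' @param n_seeds Number of simulation replicates (default 10).
#' @param seed Master seed.
#' @param cond Study conditions, see [study_conditions()].
#' @return A tibble with one row per replicate (`pi12_hat`, `rel_bias`);
#'   `attr(, "mean_rel_bias_pct")` is the mean relative bias of
#'   \eqn{\hat\pi_{12}} in percent (negative = underestimation).
#' @export
maf_dependence_bias <- function(S = -0.75, n_seeds = 10L, seed = 1L,
                                cond = study_conditions()) {
  ref <- harness_reference(cond, seed = rng_substream(seed, "refpanel"))
  pi12_true <- cond$pi_u
  rows <- purrr::map_dfr(seq_len(n_seeds), function(s) {
    spec <- architecture_spec(pi1 = 0, pi2 = 0, pi12 = pi12_true,
                              sigma1_2 = ref$sigma_beta2,
                              sigma2_2 = ref$sigma_beta2,
                              rho12 = 0.5, S = S,
                              seed = rng_substream(seed, paste0("rep", s)))
    # hold total signal at the MAF-independent level: rescale so that the
    # realized sum of beta^2 H matches the S = 0 expectation
    spec$h2 <- rep(pi12_true * nrow(ref$panel) * ref$sigma_beta2 *
                     mean(ref$panel$het), 2)
    r <- harness_fit_once(ref, cond, spec)
    tibble(replicate = s, pi12_hat = r$fit12$params$pi12,
           rel_bias = (r$fit12$params$pi12 - pi12_true) / pi12_true)
  })
  attr(rows, "mean_rel_bias_pct") <- 100 * mean(rows$rel_bias)
  rows
}

#' Shared-enrichment sensitivity harness
#'
#' Simulates pairs of genetically independent traits (`pi12 = 0`) that
#' nevertheless share a pattern of differential enrichment: 10% of LD
#' blocks carry an 8-fold causal-probability multiplier in both traits
#' (renormalized to preserve the expected causal count). The bivariate fit
#' should attribute little polygenic overlap to this shared annotation
#' structure; the harness reports the mean fitted \eqn{\hat\pi_{12}} as a
#' percentage of the simulated univariate polygenicity.
#'
#' @inheritParams maf_dependence_bias
#' @param mult Enrichment multiplier (default 8).
#' @param frac_enriched Fraction of blocks enriched (default 0.1).
#' @return A tibble with one row per replicate;
#'   `attr(, "mean_overlap_pct")` is the headline percentage.
#' @export
enrichment_overlap_bias <- function(n_seeds = 10L, seed = 1L, mult = 8,
                                    frac_enriched = 0.1,
                                    cond = study_conditions()) {
  ref <- harness_reference(cond, seed = rng_substream(seed, "refpanel"))
  m <- nrow(ref$panel)
  n_blocks <- cond$n_blocks
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_substream(seed, "enrichmask"))
  enriched_blocks <- sample.int(n_blocks, round(frac_enriched * n_blocks))
  block_of <- rep(seq_len(n_blocks), each = cond$block_size)
  multipliers <- ifelse(block_of %in% enriched_blocks, mult, 1)
  rows <- purrr::map_dfr(seq_len(n_seeds), function(s) {
    spec <- architecture_spec(pi1 = cond$pi_u, pi2 = cond$pi_u, pi12 = 0,
                              sigma1_2 = ref$sigma_beta2,
                              sigma2_2 = ref$sigma_beta2,
                              rho12 = 0, S = 0, enrichment = multipliers,
                              seed = rng_substream(seed, paste0("rep", s)))
    r <- harness_fit_once(ref, cond, spec)
    tibble(replicate = s, pi12_hat = r$fit12$params$pi12,
           overlap_pct = 100 * r$fit12$params$pi12 / cond$pi_u)
  })
  attr(rows, "mean_overlap_pct") <- mean(rows$overlap_pct)
  rows
}

#' Parameter-recovery harness over a grid of overlap scenarios
#'
#' Simulates and refits bivariate GWAS pairs under the model's own
#' assumptions for each combination of overlap fraction and effect
#' correlation, returning truth and estimates for the overlap, effect
#' correlation and genetic correlation.
#'
#' @param overlap_fracs Fractions f with `pi12 = f * pi_u`.
#' @param rho12s Effect correlations in the shared component.
#' @param n_seeds Replicates per scenario.
#' @param seed Master seed.
#' @param cond Study conditions.
#' @return A tibble with one row per scenario x replicate.
#' @export
recovery_grid <- function(overlap_fracs = c(0, 0.5, 1), rho12s = c(0, 0.5),
                          n_seeds = 3L, seed = 1L, cond = study_conditions()) {
  ref <- harness_reference(cond, seed = rng_substream(seed, "refpanel"))
  grid <- tidyr::expand_grid(f = overlap_fracs, rho12 = rho12s,
                             replicate = seq_len(n_seeds))
  purrr::pmap_dfr(grid, function(f, rho12, replicate) {
    pi12 <- f * cond$pi_u
    spec <- architecture_spec(pi1 = cond$pi_u - pi12, pi2 = cond$pi_u - pi12,
                              pi12 = pi12, sigma1_2 = ref$sigma_beta2,
                              sigma2_2 = ref$sigma_beta2, rho12 = rho12,
                              seed = rng_substream(seed,
                                                   sprintf("g%.2f_%.2f_%d", f, rho12, replicate)))
    r <- harness_fit_once(ref, cond, spec)
    rg_true <- if (f > 0) rho12 * pi12 / cond$pi_u else 0
    tibble(f = f, rho12_true = rho12, replicate = replicate,
           pi12_true = pi12, pi12_hat = r$fit12$params$pi12,
           pi1u_hat = r$fit1$params$pi1, pi2u_hat = r$fit2$params$pi1,
           rho12_hat = r$fit12$params$rho12,
           rg_true = rg_true, rg_hat = r$fit12$rg,
           h2_hat1 = heritability(r$fit1$params, total_heterozygosity(ref$panel)),
           h2_true1 = attr(r$effects, "h2_realized")[1])
  })
}
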