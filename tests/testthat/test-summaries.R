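test_that("heritability is the polygenicity-discoverability product", {
  expect_equal(heritability(univariate_params(1e-7, 0, 1), 1e6), 0)
  # round-trip: solve sigma for a target h2, recover it
  H_total <- 4e6 * 0.25
  sb2 <- 0.4 / (1e-3 * H_total)
  expect_equal(heritability(univariate_params(1e-3, sb2, 1), H_total), 0.4)
})

test_that("genetic correlation reproduces published component estimates", {
  # counts in thousands and shared-component correlations, one row per pair
  rows <- list(SCZ_BIP = list(n12 = 6.19, n1 = 2.10, n2 = 0.21,
                              rho12 = 0.853, rg = 0.725),
               SCZ_EDU = list(n12 = 8.29, n1 = 0.00, n2 = 2.54,
                              rho12 = 0.071, rg = 0.062),
               BIP_EDU = list(n12 = 5.72, n1 = 0.68, n2 = 5.11,
                              rho12 = 0.278, rg = 0.191),
               EDU_Height = list(n12 = 1.76, n1 = 9.07, n2 = 1.37,
                                 rho12 = 0.519, rg = 0.157),
               SCZ_Height = list(n12 = 0.83, n1 = 7.46, n2 = 2.29,
                                 rho12 = -0.045, rg = -0.007),
               BIP_Height = list(n12 = 0.83, n1 = 5.57, n2 = 2.29,
                                 rho12 = 0.001, rg = 0.000))
  for (r in rows) {
    p <- params_from_counts(r$n1, r$n2, r$n12, r$rho12)
    expect_equal(round(genetic_correlation(p), 3), r$rg)
  }
  # complete overlap collapses rg to rho12
  p <- bivariate_params(0, 0, 1e-3, 1e-4, 1e-4, 0.61)
  expect_equal(genetic_correlation(p), 0.61)
  expect_error(genetic_correlation(bivariate_params(0, 0, 0, 1, 1, 0)),
               "polygenicity")
})

test_that("the polygenicity-ratio upper bound on rg holds with equality at nesting", {
  set.seed(12)
  for (i in 1:50) {
    pi2u <- runif(1, 1e-4, 1e-2)
    K <- runif(1, 1, 20)
    pi1u <- K * pi2u
    pi12 <- runif(1, 0, pi2u)          # overlap at most the smaller trait
    rho12 <- runif(1, -1, 1)
    p <- bivariate_params(pi1u - pi12, pi2u - pi12, max(pi12, 1e-12),
                          1e-4, 1e-4, rho12)
    rg <- genetic_correlation(p)
    expect_lte(abs(rg), abs(rho12) / sqrt(K) + 1e-12)
  }
  # equality when the smaller trait's causal set is nested in the larger
  p_eq <- bivariate_params(9e-3, 0, 1e-3, 1e-4, 1e-4, 0.8)
  expect_equal(genetic_correlation(p_eq), 0.8 / sqrt(10), tolerance = 1e-12)
})

test_that("causal fraction matches the chi-square tail oracle for constant heterozygosity", {
  p <- univariate_params(0.01, 1e-4, 1)
  expect_equal(causal_fraction_for_h2(p, c(0.3, 0.4), target = 1), 1)

  # constant H: contributions are chi-square(1); the fraction solves
  # E[X 1{X > t}] = 0.9 E[X], i.e. P(chi2_3 > t) = 0.9, fraction = P(chi2_1 > t)
  t_star <- uniroot(function(t) pchisq(t, df = 3, lower.tail = FALSE) - 0.9,
                    c(1e-6, 10))$root
  frac_oracle <- pchisq(t_star, df = 1, lower.tail = FALSE)
  expect_equal(frac_oracle, 0.44, tolerance = 0.02)
  frac_mc <- causal_fraction_for_h2(p, rep(0.4, 5), target = 0.9,
                                    n_draws = 200000, seed = 3)
  expect_lt(abs(frac_mc - frac_oracle), 0.01)

  # invariant to rescaling sigma_beta2; nonincreasing in the target
  f1 <- causal_fraction_for_h2(p, c(0.1, 0.3, 0.5), target = 0.9, seed = 5)
  p2 <- univariate_params(0.01, 1e-2, 1)
  expect_equal(causal_fraction_for_h2(p2, c(0.1, 0.3, 0.5), target = 0.9,
                                      seed = 5), f1)
  f_lo <- causal_fraction_for_h2(p, c(0.1, 0.3, 0.5), target = 0.5, seed = 5)
  expect_lte(f_lo, f1)
})

test_that("a wide MAF spectrum concentrates heritability in few causal variants", {
  # 1/p spectrum down to rare variants, the shape behind reporting counts
  # at 90% of heritability explained
  set.seed(8)
  maf <- 0.002 * (0.5 / 0.002)^runif(50000)
  het <- 2 * maf * (1 - maf)
  p <- univariate_params(0.01, 1e-4, 1)
  f90 <- causal_fraction_for_h2(p, het, target = 0.9, n_draws = 50000, seed = 2)
  f50 <- causal_fraction_for_h2(p, het, target = 0.5, n_draws = 50000, seed = 2)
  # of the order of the published 22.6% / 5% figures (spectrum-dependent)
  expect_lt(f90, 0.35); expect_gt(f90, 0.12)
  expect_lt(f50, 0.10); expect_gt(f50, 0.02)
})

test_that("venn counts scale components and vanish with the shared weight", {
  fit <- causalmix:::new_mix_fit(
    bivariate_params(2e-3, 1e-3, 0, 1e-4, 1e-4, 0.5), -10, 100, 9,
    list(), TRUE)
  vc <- venn_counts(fit, M_ref = 1e6, het_sample = rep(0.3, 100), level = 0.9)
  expect_equal(vc$raw_count[vc$component == "shared"], 0, tolerance = 1e-6)
  expect_equal(vc$adjusted_count[vc$component == "shared"], 0, tolerance = 1e-6)
  # symmetric weights give symmetric counts
  fit2 <- causalmix:::new_mix_fit(
    bivariate_params(2e-3, 2e-3, 1e-3, 1e-4, 1e-4, 0.5), -10, 100, 9,
    list(), TRUE)
  vc2 <- venn_counts(fit2, 1e6, rep(0.3, 100), level = 0.9)
  expect_equal(vc2$adjusted_count[1], vc2$adjusted_count[2], tolerance = 0.02)
  expect_equal(vc2$raw_count, c(2e-3, 2e-3, 1e-3) * 1e6)
})

test_that("the sharing fraction of published component counts is reproduced", {
  # shared / (shared + trait-1-specific) from the bipolar-educational
  # attainment component estimates
  n12 <- 5.72; n1 <- 0.68
  expect_equal(round(100 * n12 / (n12 + n1)), 89)
})

test_that("significance thresholds come from the two-sided Gaussian quantile", {
  expect_equal(round(significance_z(5e-8), 2), 5.45)
  expect_equal(significance_z(1), 0)
  expect_equal(round(significance_z(0.0455), 2), 2)
  expect_error(significance_z(0), "alpha")
})

test_that("power curves are monotone, bounded and match the degenerate-prior closed form", {
  ref <- small_ref()
  p <- univariate_params(3e-3, ref$sigma_beta2, 1)
  set.seed(91)
  ctx <- ref$contexts[sample(nrow(ref$contexts), 40), ]
  pc <- power_curve(p, ctx, N_grid = c(1e4, 1e5, 1e6, 1e8), z_t = 5.45)
  expect_true(all(diff(pc$S) >= -1e-10))
  expect_true(all(pc$S >= 0 & pc$S <= 1))
  # z_t = 0: everything is significant
  pc0 <- power_curve(p, ctx[1:5, ], N_grid = c(1e4, 1e6), z_t = 0)
  expect_equal(pc0$S, c(1, 1), tolerance = 1e-9)
  # very large N: S -> 1
  pc_inf <- power_curve(p, ctx[1:5, ], N_grid = 1e12, z_t = 5.45)
  expect_gt(pc_inf$S, 0.99)
  # stricter thresholds capture less heritability
  pc_strict <- power_curve(p, ctx, N_grid = 1e5, z_t = 7)
  pc_loose <- power_curve(p, ctx, N_grid = 1e5, z_t = 4)
  expect_lt(pc_strict$S, pc_loose$S)
  expect_error(power_curve(p, ctx[0, ], N_grid = 1e5), "empty")

  # degenerate prior: a single context with pi = 1 has delta ~ N(0, s2);
  # closed form via the noncentrality-weighted tail of the joint Gaussian
  ctx1 <- tibble::tibble(snp_id = "s", ell = 2, m4_ratio = 0.3, n1 = 1)
  p1 <- univariate_params(1, 5e-5, 1)
  N <- 2e5
  s2 <- N * 2 * 5e-5
  # S(N) = E[delta^2 1{|z| >= zt}] / E[delta^2] with z = delta + e:
  # numerically integrate the bivariate in (delta, z) as an oracle
  dg <- seq(-40, 40, by = 0.02)
  f_den <- sum(dg^2 * dnorm(dg, 0, sqrt(s2))) * 0.02
  f_num <- sum(dg^2 * dnorm(dg, 0, sqrt(s2)) *
                 (pnorm(-5.45 - dg) + 1 - pnorm(5.45 - dg))) * 0.02
  oracle <- f_num / f_den
  pc1 <- power_curve(p1, ctx1, N_grid = N, z_t = 5.45)
  expect_equal(pc1$S, oracle, tolerance = 1e-3)
})
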