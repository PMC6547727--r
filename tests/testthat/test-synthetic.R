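test_that("make_panel produces the advertised LD structure", {
  # block_size 1: no off-diagonal pairs, ell reduces to heterozygosity
  p1 <- make_panel(5, 1, phi = 0.9, seed = 1)
  expect_equal(nrow(p1$ld$pairs), 0)
  sc1 <- ld_scores(p1$ld, p1$panel)
  expect_equal(sc1$ell, p1$panel$het)

  # phi = 1: all stored within-block correlations are 1
  p2 <- make_panel(2, 4, phi = 1, seed = 2)
  expect_true(all(p2$ld$pairs$r == 1))
  expect_equal(nrow(p2$ld$pairs), 2 * choose(4, 2))

  # phi = 0.9, block 50: ell matches truncated geometric sums of H phi^2k
  p3 <- make_panel(1, 50, phi = 0.9, r2_min = 0.05, seed = 3)
  sc3 <- ld_scores(p3$ld, p3$panel)
  H <- p3$panel$het
  kmax <- floor(log(sqrt(0.05)) / log(0.9))   # lags surviving the threshold
  for (j in c(1, 25, 50)) {
    ks <- setdiff(max(1, j - kmax):min(50, j + kmax), j)
    oracle <- H[j] + sum(H[ks] * 0.9^(2 * abs(ks - j)))
    expect_equal(sc3$ell[j], oracle, tolerance = 1e-12)
  }
  expect_error(make_panel(1, 0), "block")
  expect_error(make_panel(1, 5, phi = 1.2), "phi")
  # determinism
  p4 <- make_panel(3, 10, phi = 0.8, seed = 7)
  p5 <- make_panel(3, 10, phi = 0.8, seed = 7)
  expect_identical(p4$panel$maf, p5$panel$maf)
  expect_identical(p4$ld$pairs, p5$ld$pairs)
})

test_that("draw_effects honors the mixture, MAF dependence and h2 back-solving", {
  pan <- make_panel(40, 50, phi = 0.6, seed = 9)$panel

  # degenerate shared component: identical effects
  spec <- architecture_spec(0, 0, 1, sigma1_2 = 1e-4, sigma2_2 = 1e-4,
                            rho12 = 1, seed = 3)
  eff <- draw_effects(spec, pan)
  expect_equal(eff$beta1, eff$beta2, tolerance = 1e-12)
  expect_true(all(eff$component == 12))

  # S = 0: no regression of beta^2 on log H among causal variants
  spec0 <- architecture_spec(0.5, 0, 0, sigma1_2 = 1e-4, S = 0, seed = 4)
  e0 <- draw_effects(spec0, pan)
  c0 <- e0$component == 1
  f0 <- summary(lm(e0$beta1[c0]^2 ~ log(pan$het[c0])))
  expect_gt(f0$coefficients[2, 4], 0.01)   # slope not significant

  # S = -1: beta^2 * H constant across MAF bins (per-allele equivalence)
  spec1 <- architecture_spec(0.5, 0, 0, sigma1_2 = 1e-4, S = -1, seed = 5)
  e1 <- draw_effects(spec1, pan)
  c1 <- e1$component == 1
  v <- e1$beta1[c1]^2 * pan$het[c1]
  bins <- cut(pan$het[c1], quantile(pan$het[c1], c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  m <- tapply(v, bins, mean)
  # all bin means within Monte-Carlo range of the common value 1e-4 * 3
  # (variance of a chi-square mean); ratios near 1
  expect_lt(max(m) / min(m), 1.6)

  # h2 targets are hit exactly after back-solving
  spec2 <- architecture_spec(3e-3, 3e-3, 0, h2 = c(0.4, 0.1), seed = 6)
  e2 <- draw_effects(spec2, pan)
  expect_equal(sum(e2$beta1^2 * pan$het), 0.4, tolerance = 1e-10)
  expect_equal(sum(e2$beta2^2 * pan$het), 0.1, tolerance = 1e-10)
})

test_that("enrichment modulation preserves the expected causal count", {
  pan <- make_panel(40, 50, phi = 0.6, seed = 9)$panel
  mult <- rep(c(8, 1), c(200, 1800))
  counts <- sapply(1:20, function(s) {
    spec <- architecture_spec(0.02, 0, 0, sigma1_2 = 1e-4,
                              enrichment = mult, seed = 100 + s)
    eff <- draw_effects(spec, pan)
    c(n = sum(eff$component == 1),
      n_enriched = sum(eff$component[1:200] == 1))
  })
  # expectation preserved at pi * m = 40 causal variants
  expect_lt(abs(mean(counts["n", ]) - 40), 3 * sd(counts["n", ]) / sqrt(20))
  # enriched region carries ~8x/mean(mult) its share
  expect_gt(mean(counts["n_enriched", ]) / mean(counts["n", ]), 0.3)
})

test_that("simulate_z reproduces the convolution model's first two moments", {
  pan <- make_panel(30, 20, phi = 0.8, seed = 21)
  # null: independent standard normal z-scores
  spec0 <- architecture_spec(1e-7, 0, 0, sigma1_2 = 0, sigma2_2 = 0, seed = 1)
  eff0 <- draw_effects(spec0, pan$panel)
  eff0$beta1[] <- 0; eff0$beta2[] <- 0
  ss0 <- simulate_z(eff0, pan$panel, pan$ld, N1 = 1e5, seed = 31)
  expect_gt(ks.test(ss0$trait1$z, "pnorm")$p.value, 0.01)
  expect_lt(abs(cor(ss0$trait1$z, ss0$trait2$z)), 0.05)

  # single causal SNP with no LD: mean sqrt(N H) beta at that SNP
  pan1 <- make_panel(10, 1, phi = 0, seed = 22)
  eff1 <- draw_effects(architecture_spec(1e-7, 0, 0, seed = 2), pan1$panel)
  eff1$beta1[] <- 0; eff1$beta1[4] <- 0.02
  zs <- sapply(1:400, function(s)
    simulate_z(eff1, pan1$panel, pan1$ld, N1 = 1e5, seed = s)$trait1$z[4])
  mu <- sqrt(1e5 * pan1$panel$het[4]) * 0.02
  expect_lt(abs(mean(zs) - mu), 3 / sqrt(400))

  # mean chi-square matches 1 + N pi sigma2 mean(ell) across seeds
  pan2 <- make_panel(60, 25, phi = 0.8, seed = 23)
  sc <- ld_scores(pan2$ld, pan2$panel)
  pi1 <- 0.02; sb2 <- 2e-4; N <- 1e4
  chis <- sapply(1:10, function(s) {
    spec <- architecture_spec(pi1, 0, 0, sigma1_2 = sb2, seed = 40 + s)
    eff <- draw_effects(spec, pan2$panel)
    mean(simulate_z(eff, pan2$panel, pan2$ld, N1 = N, seed = 50 + s)$trait1$z^2)
  })
  expect_lt(abs(mean(chis) - (1 + N * pi1 * sb2 * mean(sc$ell))),
            4 * sd(chis) / sqrt(10))

  # linearity in beta: the causal part adds exactly the LD convolution
  set.seed(44)
  eff_a <- eff0; eff_a$beta1 <- rnorm(nrow(eff0), 0, 1e-3)
  z_a <- simulate_z(eff_a, pan$panel, pan$ld, N1 = 1e5, seed = 31)$trait1$z
  R <- causalmix:::ld_sparse_matrix(pan$ld)
  delta <- sqrt(1e5) * as.vector(R %*% (sqrt(pan$panel$het) * eff_a$beta1))
  expect_equal(z_a - ss0$trait1$z, delta, tolerance = 1e-9)
  # trait-swap equivariance of the deterministic (causal) component
  eff_sw <- eff0; eff_sw$beta2 <- eff_a$beta1
  ss_sw <- simulate_z(eff_sw, pan$panel, pan$ld, N1 = 1e5, N2 = 1e5, seed = 31)
  expect_equal(ss_sw$trait2$z - ss0$trait2$z, delta, tolerance = 1e-9)
})

test_that("genotype-level GWAS agrees with the z-score simulator", {
  pan <- make_panel(40, 10, phi = 0.7, seed = 33)
  g <- simulate_genotypes(pan$panel, n_samples = 3000, block_size = 10,
                          phi = 0.7, seed = 34)
  # marginal allele frequencies track the panel
  expect_lt(max(abs(colMeans(g) / 2 - pan$panel$maf)), 0.05)

  # h2 -> 0: standard normal z distribution
  ss_null <- simulate_genotype_gwas(g, rep(0, ncol(g)), h2_target = 0,
                                    panel = pan$panel, seed = 35)
  expect_gt(ks.test(ss_null$z, "pnorm")$p.value, 0.01)

  # single causal SNP: z centered near sqrt(N H) beta
  beta <- rep(0, ncol(g)); beta[17] <- 0.05
  h2 <- var(g %*% beta) / (var(g %*% beta) + 1)
  zs <- sapply(1:60, function(s)
    simulate_genotype_gwas(g, beta, h2_target = h2, panel = pan$panel,
                           seed = 100 + s)$z[17])
  mu <- sqrt(3000 * pan$panel$het[17]) * 0.05
  expect_lt(abs(mean(zs) - mu), 4 / sqrt(60) + 0.1 * mu)

  # same effects through both simulators: z^2 distributions agree
  spec <- architecture_spec(0.01, 0, 0, sigma1_2 = 5e-4, seed = 36)
  eff <- draw_effects(spec, pan$panel)
  ld_emp <- compute_ld(g, window_snps = 10, r2_min = 0.05)
  z_conv <- simulate_z(eff, pan$panel, ld_emp, N1 = 3000, seed = 37)$trait1$z
  z_geno <- simulate_genotype_gwas(g, eff$beta1,
                                   h2_target = min(attr(eff, "h2_realized")[1] /
                                                     (attr(eff, "h2_realized")[1] + 1), 0.5),
                                   panel = pan$panel, seed = 38)$z
  expect_gt(ks.test(z_conv^2, z_geno^2)$p.value, 0.01)
})
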