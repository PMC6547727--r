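#' Architecture specification for synthetic GWAS
#'
#' Bundles the generative parameters of a simulated pair of traits: mixture
#' weights, per-variant effect variances (or target heritabilities to
#' back-solve them), effect correlation, the MAF-dependence exponent `S`
#' (effect variance proportional to \eqn{H_j^S}; S = 0 is the
#' MAF-independent model, S = -1 the LD-score-regression model), and
#' optional per-SNP causal-probability enrichment multipliers.
#'
#' @param pi1,pi2,pi12 Mixture weights (see [bivariate_params()]).
#' @param sigma1_2,sigma2_2 Per-variant effect variances; ignored when `h2`
#'   targets are given.
#' @param rho12 Effect correlation in the shared component.
#' @param h2 Optional length-2 vector of target heritabilities; realized
#'   effects are rescaled to hit the targets exactly.
#' @param S MAF-dependence exponent in \[-1, 0\].
#' @param enrichment Optional per-SNP multipliers of causal probability
#'   (renormalized to preserve the expected causal count).
#' @param seed Integer seed.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(pi1, pi2, pi12, sigma1_2 = 1e-5, sigma2_2 = 1e-5,
                              rho12 = 0, h2 = NULL, S = 0, enrichment = NULL,
                              seed = 1L) {
  if (S < -1 || S > 0) abort("`S` must lie in [-1, 0].")
  if (any(c(pi1, pi2, pi12) < 0) || pi1 + pi2 + pi12 > 1)
    abort("invalid mixture weights.")
  structure(list(pi1 = pi1, pi2 = pi2, pi12 = pi12,
                 sigma1_2 = sigma1_2, sigma2_2 = sigma2_2, rho12 = rho12,
                 h2 = h2, S = S, enrichment = enrichment, seed = seed),
            class = "architecture_spec")
}

draw_maf <- function(m, spectrum, maf_range) {
  lo <- maf_range[1]; hi <- maf_range[2]
  switch(spectrum,
         uniform = runif(m, lo, hi),
         beta = { x <- rbeta(m, 0.5, 0.5); lo + (hi - lo) * x },
         oneoverp = { # density proportional to 1/p, truncated
           u <- runif(m)
           lo * (hi / lo)^u
         },
         abort(sprintf("unknown MAF spectrum '%s'.", spectrum)))
}

#' Generate a block-LD synthetic reference panel
#'
#' Builds a panel of `n_blocks` independent LD blocks of `block_size` SNPs
#' with a first-order autoregressive correlation profile (\eqn{r_{i,i+k} =
#' \phi^k} within a block) and MAF drawn from a named spectrum. Returns the
#' panel together with the implied sparse LD matrix (analytic, no genotype
#' sampling noise). The median heterozygosity-adjusted LD score is reported
#' as an attribute so users can tune the profile toward realistic values.
#'
#' @param n_blocks Number of LD blocks.
#' @param block_size SNPs per block (>= 1).
#' @param phi AR correlation parameter in \[0, 1\]; a length-2 vector draws
#'   an independent per-block value uniformly from the range, producing the
#'   wide LD-score spread characteristic of real genomes.
#' @param maf_spectrum `"oneoverp"` (default; density proportional to 1/p,
#'   a crude common-variant spectrum), `"uniform"` or `"beta"`.
#' @param maf_range Truncation range of the MAF spectrum.
#' @param r2_min Storage threshold of the returned LD matrix (default
#'   0.05).
#' @param seed Integer seed.
#' @return A list with `panel` (a [reference_panel()]) and `ld` (an
#'   [ld_matrix()]); `attr(, "median_ell")` records the median LD score.
#' @export
make_panel <- function(n_blocks, block_size, phi = 0.9,
                       maf_spectrum = "oneoverp", maf_range = c(0.05, 0.5),
                       r2_min = 0.05, seed = 1L) {
  if (block_size < 1 || n_blocks < 1) abort("block sizes must be >= 1.")
  if (any(phi < 0) || any(phi > 1)) abort("`phi` must lie in [0, 1].")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_substream(seed, "panel"))
  m <- n_blocks * block_size
  phi_block <- if (length(phi) == 2) runif(n_blocks, phi[1], phi[2])
               else rep_len(phi, n_blocks)
  maf <- draw_maf(m, maf_spectrum, maf_range)
  panel <- reference_panel(sprintf("snp%06d", seq_len(m)),
                           chrom = "1", pos = seq_len(m) * 1000L,
                           allele_eff = sample(c("A", "C"), m, replace = TRUE),
                           allele_oth = sample(c("G", "T"), m, replace = TRUE),
                           maf = maf)
  pairs <- NULL
  if (block_size > 1 && any(phi_block > 0)) {
    plist <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      ph <- phi_block[b]
      if (ph <= 0) next
      max_lag <- if (ph < 1) min(block_size - 1,
                                 ceiling(log(sqrt(r2_min)) / log(ph)))
                 else block_size - 1L
      if (max_lag < 1) next
      off <- (b - 1L) * block_size
      lag <- rep(seq_len(max_lag), times = block_size - seq_len(max_lag))
      ii <- off + unlist(lapply(seq_len(max_lag),
                                function(k) seq_len(block_size - k)))
      rr <- ph^lag
      keep <- rr^2 >= r2_min
      if (any(keep))
        plist[[b]] <- tibble(i = ii[keep], j = ii[keep] + lag[keep], r = rr[keep])
    }
    pairs <- dplyr::bind_rows(plist)
  }
  if (is.null(pairs) || !nrow(pairs))
    pairs <- tibble(i = integer(0), j = integer(0), r = numeric(0))
  ld <- ld_matrix(pairs, n_snps = m, window_snps = block_size,
                  r2_min = r2_min, snp_id = panel$snp_id)
  out <- list(panel = panel, ld = ld)
  sc <- ld_scores(ld, panel)
  attr(out, "median_ell") <- median(sc$ell)
  attr(out, "phi_block") <- phi_block
  out
}

#' Draw causal effects from the four-component mixture
#'
#' Assigns each SNP a component label (null / trait 1 / trait 2 / shared) by
#' multinomial sampling — optionally modulated by per-SNP enrichment
#' multipliers, renormalized so the expected causal count is preserved —
#' and draws effects from the labelled Gaussian with variance scaled by
#' \eqn{H_j^S}. When the spec carries `h2` targets, effects are rescaled so
#' the realized heritability \eqn{\sum_j \beta_j^2 H_j} matches each target
#' exactly.
#'
#' @param spec An [architecture_spec()].
#' @param panel A [reference_panel()].
#' @return A tibble with columns `snp_id`, `component` (0, 1, 2, 12),
#'   `beta1`, `beta2`; realized heritabilities and effective effect
#'   variances are attached as attributes `h2_realized` and
#'   `sigma_effective`.
#' @export
draw_effects <- function(spec, panel) {
  m <- nrow(panel)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_substream(spec$seed, "labels"))
  probs <- matrix(rep(c(spec$pi1, spec$pi2, spec$pi12), each = m), m, 3)
  if (!is.null(spec$enrichment)) {
    mult <- rep_len(spec$enrichment, m)
    mult <- mult / mean(mult)   # preserve expected causal counts
    probs <- probs * mult
    if (any(rowSums(probs) > 1)) {
      warn("enrichment multipliers imply probabilities > 1; renormalizing rows.")
      over <- rowSums(probs) > 1
      probs[over, ] <- probs[over, ] / rowSums(probs[over, , drop = FALSE])
    }
  }
  u <- runif(m)
  c1 <- probs[, 1]; c2 <- c1 + probs[, 2]; c3 <- c2 + probs[, 3]
  comp <- integer(m)
  comp[u < c1] <- 1L
  comp[u >= c1 & u < c2] <- 2L
  comp[u >= c2 & u < c3] <- 12L
  set.seed(rng_substream(spec$seed, "effects"))
  hs <- panel$het^spec$S
  beta1 <- beta2 <- numeric(m)
  i1 <- comp == 1L; i2 <- comp == 2L; i12 <- comp == 12L
  beta1[i1] <- rnorm(sum(i1), 0, sqrt(spec$sigma1_2 * hs[i1]))
  beta2[i2] <- rnorm(sum(i2), 0, sqrt(spec$sigma2_2 * hs[i2]))
  if (any(i12)) {
    n12 <- sum(i12)
    e1 <- rnorm(n12); e2 <- rnorm(n12)
    z2 <- spec$rho12 * e1 + sqrt(1 - spec$rho12^2) * e2
    beta1[i12] <- sqrt(spec$sigma1_2 * hs[i12]) * e1
    beta2[i12] <- sqrt(spec$sigma2_2 * hs[i12]) * z2
  }
  h2r <- c(sum(beta1^2 * panel$het), sum(beta2^2 * panel$het))
  scl <- c(1, 1)
  if (!is.null(spec$h2)) {
    scl <- sqrt(spec$h2 / pmax(h2r, 1e-300))
    beta1 <- beta1 * scl[1]; beta2 <- beta2 * scl[2]
    h2r <- spec$h2
  }
  out <- tibble(snp_id = panel$snp_id, component = comp,
                beta1 = beta1, beta2 = beta2)
  attr(out, "h2_realized") <- h2r
  attr(out, "sigma_effective") <- c(spec$sigma1_2 * scl[1]^2,
                                    spec$sigma2_2 * scl[2]^2)
  out
}

#' Simulate GWAS z-scores through the LD convolution model
#'
#' \eqn{\delta_{\cdot j} = \sqrt{N_\cdot} \sum_i \sqrt{H_i} r_{ij}
#' \beta_{\cdot i}} (the causal signal convolved through local LD) plus a
#' correlated Gaussian residual with covariance
#' \eqn{[\sigma_{01}^2, \rho_0 \sigma_{01}\sigma_{02}; \cdot,
#' \sigma_{02}^2]}.
#'
#' @param effects Tibble from [draw_effects()].
#' @param panel A [reference_panel()].
#' @param ld An [ld_matrix()].
#' @param N1,N2 GWAS sample sizes.
#' @param sigma01_2,sigma02_2,rho0 Residual covariance parameters.
#' @param seed Integer seed (residual stream).
#' @return A list of two `sumstats`-shaped tibbles (`snp_id`, `a1`, `a2`,
#'   `z`, `n`, `aligned_index`), one per trait.
#' @export
simulate_z <- function(effects, panel, ld, N1, N2 = N1,
                       sigma01_2 = 1, sigma02_2 = 1, rho0 = 0, seed = 1L) {
  m <- nrow(panel)
  R <- ld_sparse_matrix(ld)
  sh <- sqrt(panel$het)
  d1 <- sqrt(N1) * as.vector(R %*% (sh * effects$beta1))
  d2 <- sqrt(N2) * as.vector(R %*% (sh * effects$beta2))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_substream(seed, "residuals"))
  e1 <- rnorm(m); e2 <- rnorm(m)
  r1 <- sqrt(sigma01_2) * e1
  r2 <- sqrt(sigma02_2) * (rho0 * e1 + sqrt(1 - rho0^2) * e2)
  mk <- function(z, n) {
    out <- tibble(snp_id = panel$snp_id, a1 = panel$allele_eff,
                  a2 = panel$allele_oth, aligned_index = seq_len(m),
                  z = z, n = rep(n, m))
    class(out) <- c("sumstats", class(out))
    out
  }
  list(trait1 = mk(d1 + r1, N1), trait2 = mk(d2 + r2, N2))
}

# dense-free sparse symmetric correlation matrix with unit diagonal
ld_sparse_matrix <- function(ld) {
  m <- ld$n_snps
  p <- ld$pairs
  Matrix::sparseMatrix(i = c(seq_len(m), p$i, p$j),
                       j = c(seq_len(m), p$j, p$i),
                       x = c(rep(1, m), p$r, p$r), dims = c(m, m))
}

#' Synthesize genotypes with block-AR LD
#'
#' Latent multivariate normal with the panel's AR block correlation,
#' thresholded to 0/1/2 by each SNP's Hardy-Weinberg genotype frequencies.
#' A desk-scale stand-in for coalescent genotype simulators: the marginal
#' MAF and the broad LD profile are matched, fine-scale haplotype structure
#' is not.
#'
#' @param panel A [reference_panel()] from [make_panel()].
#' @param n_samples Number of individuals.
#' @param block_size,phi The AR block structure used to build the panel.
#' @param seed Integer seed.
#' @return An n x m integer dosage matrix (minor-allele counts).
#' @export
simulate_genotypes <- function(panel, n_samples, block_size, phi, seed = 1L) {
  m <- nrow(panel)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_substream(seed, "genotypes"))
  n_blocks <- ceiling(m / block_size)
  lat <- function() { # one latent AR sheet, n x m
    x <- matrix(rnorm(n_samples * m), n_samples, m)
    if (phi > 0 && block_size > 1) {
      for (b in seq_len(n_blocks)) {
        cols <- ((b - 1) * block_size + 1):min(b * block_size, m)
        for (k in cols[-1]) {
          x[, k] <- phi * x[, k - 1] + sqrt(1 - phi^2) * x[, k]
        }
      }
    }
    x
  }
  # two independent haplotype sheets -> additive 0/1/2 dosage
  g <- matrix(0L, n_samples, m)
  for (h in 1:2) {
    x <- lat()
    thr <- qnorm(panel$maf)         # carrier iff latent below the MAF quantile
    g <- g + (sweep(x, 2, thr, `<`)) * 1L
  }
  colnames(g) <- panel$snp_id
  g
}

#' Simulate a GWAS from genotypes
#'
#' Synthesizes a quantitative phenotype under the additive model \eqn{y_k =
#' \sum_j g_{kj}\beta_j + \epsilon_k}, with residual variance chosen so the
#' realized heritability \eqn{var(G\beta)/var(y)} equals `h2_target`, and
#' computes per-SNP simple-regression Wald z-scores.
#'
#' @param genotypes n x m dosage matrix.
#' @param beta Per-SNP causal effect sizes (length m).
#' @param h2_target Target heritability in (0, 1); values at 0 give a pure
#'   noise phenotype.
#' @param panel Optional [reference_panel()] to label the output.
#' @param seed Integer seed.
#' @return A `sumstats`-shaped tibble (`snp_id`, `z`, `n`).
#' @export
simulate_genotype_gwas <- function(genotypes, beta, h2_target, panel = NULL,
                                   seed = 1L) {
  if (h2_target < 0 || h2_target >= 1) abort("`h2_target` must lie in [0, 1).")
  n <- nrow(genotypes); m <- ncol(genotypes)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_substream(seed, "phenotype"))
  gsc <- scale(genotypes, scale = FALSE)
  gb <- as.vector(genotypes %*% beta)
  vg <- var(gb)
  ve <- if (h2_target == 0 || vg == 0) 1 else vg * (1 - h2_target) / h2_target
  y <- gb + rnorm(n, 0, sqrt(ve))
  if (h2_target == 0) y <- rnorm(n)   # pure noise phenotype
  ysc <- y - mean(y)
  # marginal regression z: sqrt(n) * cor / sqrt(1 - cor^2)
  num <- as.vector(crossprod(gsc, ysc))
  den <- sqrt(colSums(gsc^2) * sum(ysc^2))
  rr <- ifelse(den > 0, num / den, 0)
  rr <- pmin(pmax(rr, -0.999999), 0.999999)
  z <- sqrt(n - 2) * rr / sqrt(1 - rr^2)
  ids <- if (!is.null(panel)) panel$snp_id else colnames(genotypes) %||%
    sprintf("snp%06d", seq_len(m))
  out <- tibble(snp_id = ids, z = z, n = rep(n, m))
  class(out) <- c("sumstats", class(out))
  out
}
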