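#' Per-SNP model context
#'
#' Builds the per-SNP quantities the z-score likelihood needs: the
#' heterozygosity-adjusted LD score `ell`, the fourth-moment ratio
#' `m4_ratio` = (sum H^2 r^4)/(sum H r^2) (the shape term of the fast
#' model), GWAS sample sizes, and — for the full model — the list of stored
#' LD neighbors (H_i, r_ij), self included.
#'
#' @param ld An [ld_matrix()].
#' @param panel A [reference_panel()].
#' @param n1 Per-SNP (or scalar) sample size for trait 1.
#' @param n2 Optional sample size for trait 2 (bivariate analyses).
#' @param neighbors If `TRUE`, attach the neighbor list-column required by
#'   the full model.
#' @return A tibble with columns `snp_id`, `ell`, `m4_ratio`, `n1` (and
#'   `n2`, `neighbors` when requested).
#' @export
snp_contexts <- function(ld, panel, n1, n2 = NULL, neighbors = FALSE) {
  sc <- ld_scores(ld, panel)
  out <- tibble(snp_id = sc$snp_id, ell = sc$ell, m4_ratio = sc$ratio,
                n1 = rep_len(as.numeric(n1), nrow(sc)))
  if (!is.null(n2)) out$n2 <- rep_len(as.numeric(n2), nrow(sc))
  if (neighbors) {
    e <- ld_edges(ld)
    nb <- vector("list", nrow(panel))
    for (j in seq_len(nrow(panel))) nb[[j]] <- list(H = panel$het[j], r = 1)
    if (nrow(e)) {
      spH <- split(panel$het[e$i], e$j)
      spr <- split(e$r, e$j)
      for (k in seq_along(spH)) {
        j <- as.integer(names(spH)[k])
        nb[[j]] <- list(H = c(panel$het[j], spH[[k]]), r = c(1, spr[[k]]))
      }
    }
    out$neighbors <- nb
  }
  out
}

# shape parameter eta_cj = pi_c * ell + (1 - pi_c) * m4_ratio  (component-specific)
eta_shape <- function(pi_c, ell, m4_ratio) pi_c * ell + (1 - pi_c) * m4_ratio

#' Fast-model univariate density of a GWAS z-score
#'
#' Method-of-moments approximation: the z-score of SNP j is a two-component
#' Gaussian mixture \eqn{(1-\pi') N(0, \sigma_0^2) + \pi' N(0, n \eta
#' \sigma_\beta^2 + \sigma_0^2)} with adjusted weight \eqn{\pi' = \ell \pi /
#' \eta} and shape \eqn{\eta = \pi \ell + (1-\pi) m4/\ell}. The shape term
#' carries the fourth power of allelic correlation and controls kurtosis.
#'
#' @param z Numeric vector of z-scores.
#' @param params A [univariate_params()].
#' @param ctx A [snp_contexts()] tibble (recycled against `z`).
#' @param log Return log-density?
#' @return Density values, strictly positive and finite.
#' @export
fast_pdf_uni <- function(z, params, ctx, log = FALSE) {
  eta <- eta_shape(params$pi1, ctx$ell, ctx$m4_ratio)
  if (any(eta <= 0)) abort("shape parameter eta <= 0: invalid context.")
  pi_adj <- pmin(ctx$ell * params$pi1 / eta, 1)
  v0 <- params$sigma0_2
  v1 <- pmax(ctx$n1 * eta * params$sigma_beta2 + params$sigma0_2, 1e-12)
  ld0 <- dnorm(z, 0, sqrt(v0), log = TRUE) + log1p(-pmin(pi_adj, 1 - 1e-16))
  ld1 <- dnorm(z, 0, sqrt(v1), log = TRUE) + log(pmax(pi_adj, 1e-300))
  mx <- pmax(ld0, ld1)
  out <- mx + log(exp(ld0 - mx) + exp(ld1 - mx))
  if (log) out else exp(out)
}

# log density of a bivariate normal with per-observation covariance entries
dbvn_log <- function(z1, z2, v11, v22, v12) {
  det <- v11 * v22 - v12^2
  det <- pmax(det, 1e-300)
  q <- (v22 * z1^2 - 2 * v12 * z1 * z2 + v11 * z2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# the eight fast-model components: subsets of {1, 2, 12}
fast_biv_components <- function(params, ctx) {
  ell <- ctx$ell; m4r <- ctx$m4_ratio
  comp <- list(
    c1  = list(pi = params$pi1,  s11 = params$sigma1_2, s22 = 0, s12 = 0),
    c2  = list(pi = params$pi2,  s11 = 0, s22 = params$sigma2_2, s12 = 0),
    c12 = list(pi = params$pi12, s11 = params$sigma1_2, s22 = params$sigma2_2,
               s12 = params$rho12 * sqrt(params$sigma1_2 * params$sigma2_2)))
  lapply(comp, function(cc) {
    eta <- eta_shape(cc$pi, ell, m4r)
    pi_adj <- if (cc$pi == 0) rep(0, length(ell)) else pmin(ell * cc$pi / eta, 1)
    # z-scale covariance contribution: eta * D Sigma_c D, D = diag(sqrt(n1), sqrt(n2))
    list(pi_adj = pi_adj,
         a11 = eta * ctx$n1 * cc$s11,
         a22 = eta * ctx$n2 * cc$s22,
         a12 = eta * sqrt(ctx$n1 * ctx$n2) * cc$s12)
  })
}

#' Fast-model bivariate density of a pair of GWAS z-scores
#'
#' Convolution of the three adjusted two-point mixtures (trait-1-specific,
#' trait-2-specific, shared), evaluating to a mixture of eight bivariate
#' Gaussian components, plus the residual covariance
#' \eqn{[\sigma_{01}^2, \rho_0\sigma_{01}\sigma_{02}; \cdot, \sigma_{02}^2]}.
#'
#' @param z1,z2 Numeric vectors of z-scores for the two traits.
#' @param params A [bivariate_params()].
#' @param ctx A [snp_contexts()] tibble with `n1` and `n2`.
#' @param log Return log-density?
#' @return Density values; the mixture integrates to 1.
#' @export
fast_pdf_biv <- function(z1, z2, params, ctx, log = FALSE) {
  if (is.null(ctx$n2)) abort("bivariate density needs `n2` in the context.")
  comps <- fast_biv_components(params, ctx)
  r0 <- params$rho0 * sqrt(params$sigma01_2 * params$sigma02_2)
  nz <- length(z1)
  logd <- matrix(-Inf, nz, 8)
  k <- 0
  for (s1 in 0:1) for (s2 in 0:1) for (s12 in 0:1) {
    k <- k + 1
    sel <- c(s1, s2, s12)
    lw <- rep(0, nz)
    v11 <- rep(params$sigma01_2, nz); v22 <- rep(params$sigma02_2, nz)
    v12 <- rep(r0, nz)
    for (ci in 1:3) {
      pa <- comps[[ci]]$pi_adj
      if (sel[ci] == 1) {
        lw <- lw + log(pmax(pa, 1e-300))
        v11 <- v11 + comps[[ci]]$a11
        v22 <- v22 + comps[[ci]]$a22
        v12 <- v12 + comps[[ci]]$a12
      } else {
        lw <- lw + log1p(-pmin(pa, 1 - 1e-16))
      }
    }
    # guard: assembled covariance must be PSD
    if (any(v11 * v22 - v12^2 < -1e-8))
      abort(sprintf("non-PSD covariance in fast-model component %d.", k))
    logd[, k] <- lw + dbvn_log(z1, z2, v11, v22, v12)
  }
  mx <- apply(logd, 1, max)
  out <- mx + log(rowSums(exp(logd - mx)))
  if (log) out else exp(out)
}

# draw per-replicate causal tagging sums for one SNP context (full model)
full_replicate_sums <- function(neigh, pis, K) {
  # pis = c(pi1, pi2, pi12); returns K x 3 matrix of sums H_i r_ij^2 per component
  nh <- length(neigh$H)
  hr2 <- neigh$H * neigh$r^2
  u <- matrix(runif(K * nh), K, nh)
  p1 <- pis[1]; p2 <- pis[2]; p12 <- pis[3]
  lab1 <- u < p1
  lab2 <- u >= p1 & u < p1 + p2
  lab12 <- u >= p1 + p2 & u < p1 + p2 + p12
  cbind(t1 = as.vector(lab1 %*% hr2),
        t2 = as.vector(lab2 %*% hr2),
        t12 = as.vector(lab12 %*% hr2))
}

#' Full-model density of a pair of GWAS z-scores at one SNP
#'
#' Approximates the z-score distribution at SNP j as an equal-weight mixture
#' of `K` bivariate Gaussians. Each replicate draws a component label
#' (null / trait 1 / trait 2 / shared) independently for every stored LD
#' neighbor of j and accumulates the tagged covariance \eqn{\Sigma'_{kj} =
#' \sum_{i\ causal} H_i r_{ij}^2 \Sigma_{c(i)}}, scaled by
#' \eqn{diag(\sqrt{n_1}, \sqrt{n_2})} on both sides; the residual covariance
#' is added to every component. Contributions of SNPs outside the stored LD
#' window are absorbed by the residual term.
#'
#' @param z1,z2 Scalars (or equal-length vectors) of z-scores.
#' @param params A [bivariate_params()].
#' @param ctx One row of a [snp_contexts()] tibble built with
#'   `neighbors = TRUE`.
#' @param K Number of sampled causal configurations (default 200; increase
#'   for tighter approximation).
#' @param seed Integer seed making the replicate draws reproducible.
#' @return Density values.
#' @export
full_pdf <- function(z1, z2, params, ctx, K = 200L, seed = 1L) {
  if (K < 1) abort("`K` must be >= 1.")
  neigh <- if (is.list(ctx$neighbors) && !is.null(ctx$neighbors[[1]]$H))
    ctx$neighbors[[1]] else ctx$neighbors
  if (is.null(neigh$H)) abort("context lacks a neighbor list; build with neighbors = TRUE.")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_substream(seed, "full_pdf"))
  sums <- full_replicate_sums(neigh, c(params$pi1, params$pi2, params$pi12), K)
  s12 <- params$rho12 * sqrt(params$sigma1_2 * params$sigma2_2)
  r0 <- params$rho0 * sqrt(params$sigma01_2 * params$sigma02_2)
  v11 <- ctx$n1[1] * params$sigma1_2 * (sums[, "t1"] + sums[, "t12"]) + params$sigma01_2
  v22 <- ctx$n2[1] * params$sigma2_2 * (sums[, "t2"] + sums[, "t12"]) + params$sigma02_2
  v12 <- sqrt(ctx$n1[1] * ctx$n2[1]) * s12 * sums[, "t12"] + r0
  vapply(seq_along(z1), function(i) {
    ld <- dbvn_log(z1[i], z2[i], v11, v22, v12)
    mx <- max(ld)
    exp(mx) * mean(exp(ld - mx))
  }, numeric(1))
}

#' Full-model univariate density at one SNP
#'
#' Univariate restriction of [full_pdf()]: replicates draw causal neighbors
#' with probability `pi1` and accumulate \eqn{\sigma^2_{kj} = \sigma_\beta^2
#' \sum_{i\ causal} H_i r_{ij}^2}.
#'
#' @inheritParams full_pdf
#' @param z Numeric z-scores.
#' @param params A [univariate_params()].
#' @export
full_pdf_uni <- function(z, params, ctx, K = 200L, seed = 1L) {
  if (K < 1) abort("`K` must be >= 1.")
  neigh <- if (is.list(ctx$neighbors) && !is.null(ctx$neighbors[[1]]$H))
    ctx$neighbors[[1]] else ctx$neighbors
  if (is.null(neigh$H)) abort("context lacks a neighbor list; build with neighbors = TRUE.")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_substream(seed, "full_pdf"))
  hr2 <- neigh$H * neigh$r^2
  u <- matrix(runif(K * length(hr2)), K)
  s <- as.vector((u < params$pi1) %*% hr2)
  v <- pmax(ctx$n1[1] * params$sigma_beta2 * s + params$sigma0_2, 1e-12)
  vapply(z, function(zz) mean(dnorm(zz, 0, sqrt(v))), numeric(1))
}

# dispatch density over all SNPs; returns log densities
loglik_density <- function(params, z1, z2 = NULL, contexts, model = "fast",
                           K = 200L, seed = 1L) {
  if (inherits(params, "univariate_params")) {
    if (model == "fast") {
      fast_pdf_uni(z1, params, contexts, log = TRUE)
    } else {
      vapply(seq_along(z1), function(j)
        log(full_pdf_uni(z1[j], params, contexts[j, ], K = K,
                         seed = seed + j)), numeric(1))
    }
  } else {
    if (model == "fast") {
      fast_pdf_biv(z1, z2, params, contexts, log = TRUE)
    } else {
      vapply(seq_along(z1), function(j)
        log(full_pdf(z1[j], z2[j], params, contexts[j, ], K = K,
                     seed = seed + j)), numeric(1))
    }
  }
}

#' Weighted log-likelihood of summary statistics
#'
#' \eqn{F(\theta) = \sum_j w_j \log pdf(z_j | \theta)}, with random-pruning
#' weights down-weighting SNPs in large LD blocks. SNPs with zero weight are
#' skipped entirely.
#'
#' @param params [univariate_params()] or [bivariate_params()].
#' @param z1 z-scores for trait 1 (aligned to `contexts`).
#' @param z2 z-scores for trait 2 (bivariate case), or `NULL`.
#' @param contexts A [snp_contexts()] tibble.
#' @param weights Per-SNP weights (numeric vector or the tibble returned by
#'   [random_pruning_weights()]).
#' @param model `"fast"` or `"full"`.
#' @param K,seed Full-model settings, see [full_pdf()].
#' @return The weighted log-likelihood; `-Inf` (with a warning) if any
#'   weighted SNP has non-positive density.
#' @export
weighted_loglik <- function(params, z1, z2 = NULL, contexts, weights,
                            model = "fast", K = 200L, seed = 1L) {
  w <- if (is.data.frame(weights)) weights$w else weights
  use <- w > 0
  if (!any(use)) return(0)
  ld <- loglik_density(params, z1[use], z2[use], contexts[use, , drop = FALSE],
                       model = model, K = K, seed = seed)
  if (any(!is.finite(ld))) {
    warn("non-positive density encountered; returning -Inf.")
    return(-Inf)
  }
  sum(w[use] * ld)
}

# model tail mass P(|Z| > z_t) (univariate) or P(outside [-zt,zt]^2) (bivariate)
model_tail_mass <- function(params, contexts, z_t) {
  if (inherits(params, "univariate_params")) {
    eta <- eta_shape(params$pi1, contexts$ell, contexts$m4_ratio)
    pi_adj <- pmin(contexts$ell * params$pi1 / eta, 1)
    v0 <- params$sigma0_2
    v1 <- contexts$n1 * eta * params$sigma_beta2 + params$sigma0_2
    (1 - pi_adj) * 2 * pnorm(z_t / sqrt(v0), lower.tail = FALSE) +
      pi_adj * 2 * pnorm(z_t / sqrt(v1), lower.tail = FALSE)
  } else {
    comps <- fast_biv_components(params, contexts)
    r0 <- params$rho0 * sqrt(params$sigma01_2 * params$sigma02_2)
    nz <- nrow(contexts)
    total <- rep(0, nz)
    for (s1 in 0:1) for (s2 in 0:1) for (s12 in 0:1) {
      sel <- c(s1, s2, s12)
      wgt <- rep(1, nz)
      v11 <- rep(params$sigma01_2, nz); v22 <- rep(params$sigma02_2, nz)
      v12 <- rep(r0, nz)
      for (ci in 1:3) {
        pa <- comps[[ci]]$pi_adj
        if (sel[ci] == 1) {
          wgt <- wgt * pa
          v11 <- v11 + comps[[ci]]$a11; v22 <- v22 + comps[[ci]]$a22
          v12 <- v12 + comps[[ci]]$a12
        } else wgt <- wgt * (1 - pa)
      }
      pin <- vapply(seq_len(nz), function(j) {
        if (wgt[j] <= 0) return(0)
        sig <- matrix(c(v11[j], v12[j], v12[j], v22[j]), 2)
        mvtnorm::pmvnorm(lower = c(-z_t, -z_t), upper = c(z_t, z_t),
                         sigma = sig)[1]
      }, numeric(1))
      total <- total + wgt * (1 - pin)
    }
    pmin(pmax(total, 1e-300), 1)
  }
}

#' Right-censored weighted log-likelihood
#'
#' SNPs with |z| at or below the threshold contribute their log density;
#' SNPs beyond it contribute the log of the model tail mass, so that extreme
#' z-scores (where a single-Gaussian causal component fits least well)
#' inform the fit only through their exceedance. For bivariate inputs a SNP
#' is censored when either trait exceeds the threshold, contributing
#' \eqn{\log P(\max(|Z_1|, |Z_2|) > z_t)}.
#'
#' @inheritParams weighted_loglik
#' @param z_t Censoring threshold (default 5.45, the genome-wide
#'   significance z). `Inf` recovers [weighted_loglik()].
#' @return The censored weighted log-likelihood.
#' @export
censored_loglik <- function(params, z1, z2 = NULL, contexts, weights,
                            z_t = 5.45, model = "fast", K = 200L, seed = 1L) {
  if (z_t <= 0) abort("`z_t` must be > 0.")
  w <- if (is.data.frame(weights)) weights$w else weights
  cens <- if (is.null(z2)) abs(z1) > z_t else pmax(abs(z1), abs(z2)) > z_t
  f_obs <- 0
  if (any(!cens & w > 0)) {
    f_obs <- weighted_loglik(params, z1[!cens], z2[!cens],
                             contexts[!cens, , drop = FALSE], w[!cens],
                             model = model, K = K, seed = seed)
  }
  f_cens <- 0
  usec <- cens & w > 0
  if (any(usec)) {
    tail_mass <- model_tail_mass(params, contexts[usec, , drop = FALSE], z_t)
    f_cens <- sum(w[usec] * log(pmax(tail_mass, 1e-300)))
  }
  f_obs + f_cens
}
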