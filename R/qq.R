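#' Data Q-Q curve from z-scores
#'
#' Weighted empirical Q-Q curve of GWAS p-values on the -log10 scale.
#' Points are weighted by random-pruning weights so that large LD blocks do
#' not overcount; the 95% band is the binomial interval
#' \eqn{q \pm 1.96\sqrt{q(1-q)/n_{total}}} on the quantile scale with
#' \eqn{n_{total} = \sum_j w_j}, mapped back to observed -log10 p.
#'
#' @param z Vector of z-scores.
#' @param weights Pruning weights (vector or [random_pruning_weights()]
#'   tibble).
#' @param strata Optional named list of logical masks; one curve per
#'   stratum (empty strata are dropped with a warning).
#' @param grid Expected -log10 p grid (default 0 to 6 by 0.1).
#' @return A tibble of class `qq_curve` with columns `stratum`, `expected`,
#'   `observed`, `ci_lo`, `ci_hi`, `n_total`.
#' @export
data_qq <- function(z, weights, strata = NULL, grid = seq(0, 6, by = 0.1)) {
  w <- if (is.data.frame(weights)) weights$w else weights
  stopifnot(length(z) == length(w))
  strata <- strata %||% list(all = rep(TRUE, length(z)))
  curves <- list()
  for (nm in names(strata)) {
    m <- strata[[nm]] & w > 0
    if (!any(m)) { warn(sprintf("stratum '%s' is empty; omitted.", nm)); next }
    p <- 2 * pnorm(-abs(z[m]))
    ww <- w[m]
    o <- order(p)
    p <- p[o]; ww <- ww[o]
    n_total <- sum(ww)
    qv <- cumsum(ww) / n_total       # weighted quantile level of each p
    mlp <- -log10(p)
    # weighted empirical quantile: the first observed -log10 p whose
    # cumulative weight reaches the level q
    obs_at <- function(qq) {
      qq <- pmin(pmax(qq, 0), 1)
      idx <- pmin(findInterval(qq, qv, left.open = TRUE) + 1, length(qv))
      mlp[idx]
    }
    q_grid <- 10^(-grid)             # expected quantile levels
    hw <- 1.96 * sqrt(q_grid * (1 - q_grid) / n_total)
    curves[[nm]] <- tibble(stratum = nm, expected = grid,
                           observed = obs_at(q_grid),
                           ci_lo = obs_at(pmin(q_grid + hw, 1)),
                           ci_hi = obs_at(pmax(q_grid - hw, 1e-300)),
                           n_total = n_total)
  }
  out <- dplyr::bind_rows(curves)
  class(out) <- c("qq_curve", class(out))
  out
}

# model survival function P(|Z1| >= z [, |Z2| >= z2_thresh]) averaged over contexts
model_survival <- function(params, contexts, zgrid, z2_thresh = NULL) {
  if (inherits(params, "univariate_params")) {
    # average the density over contexts, integrate the tail on the grid
    dens <- rep(0, length(zgrid))
    eta <- eta_shape(params$pi1, contexts$ell, contexts$m4_ratio)
    pi_adj <- pmin(contexts$ell * params$pi1 / eta, 1)
    v1 <- contexts$n1 * eta * params$sigma_beta2 + params$sigma0_2
    sv <- vapply(zgrid, function(zz) {
      mean((1 - pi_adj) * 2 * pnorm(zz / sqrt(params$sigma0_2), lower.tail = FALSE) +
             pi_adj * 2 * pnorm(zz / sqrt(v1), lower.tail = FALSE))
    }, numeric(1))
    return(sv)
  }
  # bivariate conditional: P(|Z1| >= z, |Z2| >= t) / P(|Z2| >= t), per context
  nz <- length(zgrid)
  num <- rep(0, nz); den <- 0
  for (j in seq_len(nrow(contexts))) {
    ctx <- contexts[j, , drop = FALSE]
    comps <- fast_biv_components(params, ctx)
    r0 <- params$rho0 * sqrt(params$sigma01_2 * params$sigma02_2)
    for (s1 in 0:1) for (s2 in 0:1) for (s12 in 0:1) {
      sel <- c(s1, s2, s12)
      wgt <- 1
      v11 <- params$sigma01_2; v22 <- params$sigma02_2; v12 <- r0
      for (ci in 1:3) {
        pa <- comps[[ci]]$pi_adj[1]
        if (sel[ci] == 1) {
          wgt <- wgt * pa
          v11 <- v11 + comps[[ci]]$a11[1]; v22 <- v22 + comps[[ci]]$a22[1]
          v12 <- v12 + comps[[ci]]$a12[1]
        } else wgt <- wgt * (1 - pa)
      }
      if (wgt <= 0) next
      if (is.null(z2_thresh) || z2_thresh <= 0) {
        # unconditional: the trait-1 marginal of each component is Gaussian
        den <- den + wgt
        num <- num + wgt * 2 * pnorm(zgrid / sqrt(v11), lower.tail = FALSE)
        next
      }
      sig <- matrix(c(v11, v12, v12, v22), 2)
      p2 <- 2 * pnorm(z2_thresh / sqrt(v22), lower.tail = FALSE)
      den <- den + wgt * p2
      num <- num + wgt * vapply(zgrid, function(zz) {
        if (zz == 0) return(p2)
        # P(|Z1| >= z, |Z2| >= t) by inclusion-exclusion over quadrants
        pr <- function(l1, u1, l2, u2)
          mvtnorm::pmvnorm(lower = c(l1, l2), upper = c(u1, u2), sigma = sig)[1]
        pr(zz, Inf, z2_thresh, Inf) + pr(zz, Inf, -Inf, -z2_thresh) +
          pr(-Inf, -zz, z2_thresh, Inf) + pr(-Inf, -zz, -Inf, -z2_thresh)
      }, numeric(1))
    }
  }
  num / max(den, 1e-300)
}

#' Model-predicted Q-Q curve
#'
#' Evaluates the fitted model's z-score distribution on a fine grid
#' (0 to 38, step 0.05), averaged across a sample of SNP contexts, and
#' transforms it to Q-Q coordinates: for each grid z the curve point is
#' (expected, observed) = (-log10 of the model's P(|Z| >= z), -log10 of the
#' nominal two-sided p at z). Null parameters give the diagonal. With
#' `condition_z2`, the bivariate model is integrated over the secondary
#' trait's tail (|z2| beyond the stratum threshold), producing conditional
#' Q-Q curves.
#'
#' @param params [univariate_params()] or [bivariate_params()].
#' @param contexts A sample of [snp_contexts()] rows (the package convention
#'   is 1% of the reference, seeded).
#' @param condition_z2 Optional vector of secondary-trait |z| thresholds;
#'   one conditional curve per threshold (0 = all SNPs).
#' @param max_mlog10p Truncate curves at this observed -log10 p (default
#'   10).
#' @return A tibble of class `qq_curve` (`ci_lo`/`ci_hi` are `NA`: model
#'   curves carry no sampling band).
#' @export
model_qq <- function(params, contexts, condition_z2 = NULL, max_mlog10p = 10) {
  zgrid <- seq(0, 38, by = 0.05)
  mlp <- -log10(pmax(2 * pnorm(-zgrid), 1e-300))
  keep <- mlp <= max_mlog10p
  thresholds <- condition_z2 %||% NA_real_
  curves <- list()
  for (t2 in thresholds) {
    sv <- if (is.na(t2) || inherits(params, "univariate_params")) {
      model_survival(params, contexts, zgrid, z2_thresh = NULL)
    } else {
      model_survival(params, contexts, zgrid, z2_thresh = t2)
    }
    nm <- if (is.na(t2)) "model" else sprintf("model|z2>=%.3g", t2)
    curves[[nm]] <- tibble(stratum = nm,
                           expected = -log10(pmax(sv[keep], 1e-300)),
                           observed = mlp[keep],
                           ci_lo = NA_real_, ci_hi = NA_real_,
                           n_total = NA_real_)
  }
  out <- dplyr::bind_rows(curves)
  class(out) <- c("qq_curve", class(out))
  out
}

#' @rdname data_qq
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.qq_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$expected, y = .data$observed,
                     colour = .data$stratum)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    geom_line() +
    labs(x = expression(expected ~ -log[10](p)),
         y = expression(observed ~ -log[10](p))) +
    theme_minimal()
}
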