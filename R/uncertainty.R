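#' Parameter covariance from observed Fisher information
#'
#' Numerically differentiates the negative log-likelihood at the fitted
#' optimum in *transformed* coordinates — logit for mixture weights, log for
#' variances, inverse-error-function scale for correlations — where the
#' boundary constraints disappear and the quadratic approximation is most
#' faithful. The inverse Hessian is the covariance of parameter errors. If
#' the joint Hessian is not positive definite, per-parameter marginal second
#' derivatives are used instead and the `fallback` flag is set.
#'
#' @param params Fitted [univariate_params()] or [bivariate_params()].
#' @param loglik_fn Function taking a parameter object and returning the
#'   (weighted) log-likelihood; typically a closure over
#'   [weighted_loglik()] with the fast model.
#' @param which Optional character vector naming the parameters to treat as
#'   free (default: all).
#' @return A `param_covariance` object: `cov` (matrix in transformed space),
#'   `point_u` (transformed point estimate), `template`, `which`,
#'   `fallback`.
#' @export
fisher_information <- function(params, loglik_fn, which = NULL) {
  tr <- param_transforms(params)
  which <- which %||% tr$names
  u0 <- params_to_u(params, which)
  nll <- function(u) {
    p <- u_to_params(u, params, which)
    val <- tryCatch(loglik_fn(p), error = function(e) NA_real_)
    if (!is.finite(val)) return(1e12)
    -val
  }
  H <- tryCatch(numDeriv::hessian(nll, u0), error = function(e) NULL)
  fallback <- FALSE
  cov <- NULL
  if (!is.null(H) && all(is.finite(H))) {
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > 0)) cov <- solve(H)
  }
  if (is.null(cov)) {
    fallback <- TRUE
    d2 <- vapply(seq_along(u0), function(i) {
      f <- function(x) { u <- u0; u[i] <- x; nll(u) }
      h <- 1e-3
      val <- (f(u0[i] + h) - 2 * f(u0[i]) + f(u0[i] - h)) / h^2
      if (!is.finite(val) || val <= 0) { # reduced-step retry
        h <- 1e-4
        val <- (f(u0[i] + h) - 2 * f(u0[i]) + f(u0[i] - h)) / h^2
      }
      val
    }, numeric(1))
    d2[!is.finite(d2) | d2 <= 0] <- Inf  # flat direction: zero information
    cov <- diag(1 / d2, nrow = length(u0))
  }
  dimnames(cov) <- list(which, which)
  structure(list(cov = cov, point_u = u0, template = params, which = which,
                 fallback = fallback),
            class = "param_covariance")
}

#' @export
print.param_covariance <- function(x, ...) {
  cat(sprintf("<parameter covariance (%s space)%s>\n",
              "transformed", if (x$fallback) ", marginal fallback" else ""))
  print(round(x$cov, 6))
  invisible(x)
}

#' Sampling-based error propagation for derived quantities
#'
#' Draws parameter vectors from the multivariate normal approximation in
#' transformed space, back-transforms each draw (so every draw lands in the
#' valid domain by construction), evaluates the supplied function, and
#' reports the sample standard deviation as the standard error.
#'
#' @param cov A `param_covariance` from [fisher_information()].
#' @param fn Function of a parameter object returning a numeric scalar
#'   (e.g. heritability or genetic correlation).
#' @param n_draws Number of parameter realizations (default 1000).
#' @param seed Integer seed.
#' @return A list with `point` (fn at the point estimate), `se`,
#'   `n_failed` (draws where fn errored; > 10% raises an error) and the
#'   draws themselves.
#' @export
propagate <- function(cov, fn, n_draws = 1000L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_substream(seed, "propagate"))
  U <- MASS::mvrnorm(n_draws, mu = cov$point_u, Sigma = cov$cov)
  if (is.null(dim(U))) U <- matrix(U, ncol = length(cov$point_u))
  vals <- apply(U, 1, function(u) {
    tryCatch(fn(u_to_params(u, cov$template, cov$which)),
             error = function(e) NA_real_)
  })
  n_failed <- sum(is.na(vals))
  if (n_failed > 0.1 * n_draws)
    abort(sprintf("propagation failed on %d of %d draws.", n_failed, n_draws))
  list(point = fn(cov$template), se = sd(vals, na.rm = TRUE),
       n_failed = n_failed, draws = vals[!is.na(vals)])
}

#' Block jack-knife standard errors
#'
#' Leave-one-block-out refits over contiguous SNP blocks; the classical
#' cross-check for Fisher-information standard errors.
#'
#' @param estimator Function of an integer index vector (SNPs kept)
#'   returning a named numeric vector of estimates.
#' @param n_snps Total number of SNPs.
#' @param n_blocks Number of contiguous blocks (default 50).
#' @return A named numeric vector of jack-knife standard errors.
#' @export
block_jackknife <- function(estimator, n_snps, n_blocks = 50L) {
  blocks <- split(seq_len(n_snps),
                  cut(seq_len(n_snps), breaks = n_blocks, labels = FALSE))
  full_est <- estimator(seq_len(n_snps))
  ests <- vapply(blocks, function(b) estimator(setdiff(seq_len(n_snps), b)),
                 full_est)
  if (is.null(dim(ests)))
    ests <- matrix(ests, nrow = 1, dimnames = list(names(full_est), NULL))
  g <- ncol(ests)
  means <- rowMeans(ests)
  se <- sqrt((g - 1) / g * rowSums((ests - means)^2))
  setNames(se, rownames(ests))
}
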