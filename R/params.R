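#' Univariate causal mixture parameters
#'
#' Container for the three parameters of the univariate causal mixture model
#' of per-variant effects, \eqn{\beta_j \sim \pi_0 N(0,0) + \pi_1
#' N(0,\sigma_\beta^2)}, together with the residual variance distortion
#' \eqn{\sigma_0^2} that inflates observed z-scores (cryptic relatedness,
#' attenuation — the analogue of the LD score regression intercept).
#'
#' @param pi1 Causal fraction, in (0, 1]. Fraction of reference SNPs with a
#'   nonzero effect on the trait.
#' @param sigma_beta2 Per-variant effect variance (discoverability), >= 0,
#'   on the per-allele scale.
#' @param sigma0_2 Residual variance distortion of z-scores, > 0; 1 means a
#'   perfectly calibrated GWAS.
#' @return An object of class `univariate_params`.
#' @examples
#' univariate_params(pi1 = 3e-3, sigma_beta2 = 1e-5, sigma0_2 = 1)
#' @export
univariate_params <- function(pi1, sigma_beta2, sigma0_2 = 1) {
  stopifnot(is.numeric(pi1), length(pi1) == 1L,
            is.numeric(sigma_beta2), length(sigma_beta2) == 1L,
            is.numeric(sigma0_2), length(sigma0_2) == 1L)
  if (pi1 <= 0 || pi1 > 1) abort("`pi1` must lie in (0, 1].")
  if (sigma_beta2 < 0) abort("`sigma_beta2` must be >= 0.")
  if (sigma0_2 <= 0) abort("`sigma0_2` must be > 0.")
  structure(list(pi1 = pi1, sigma_beta2 = sigma_beta2, sigma0_2 = sigma0_2),
            class = "univariate_params")
}

#' Bivariate causal mixture parameters
#'
#' The nine parameters of the bivariate mixture model: weights of the two
#' trait-specific components and the shared component (`pi1`, `pi2`, `pi12`;
#' the null weight is the remainder), per-variant effect variances, the
#' correlation of effect sizes within the shared component (`rho12`), and the
#' residual distortion parameters of the two GWAS (`sigma01_2`, `sigma02_2`,
#' `rho0`; `rho0` absorbs sample overlap).
#'
#' @param pi1,pi2,pi12 Mixture weights, each >= 0 with sum <= 1.
#' @param sigma1_2,sigma2_2 Per-variant effect variances for the two traits.
#' @param rho12 Correlation of effect sizes in the shared component, in
#'   \[-1, 1\].
#' @param sigma01_2,sigma02_2 Residual z-score variances, > 0.
#' @param rho0 Residual correlation from sample overlap, in \[-1, 1\].
#' @return An object of class `bivariate_params`.
#' @examples
#' bivariate_params(pi1 = 1e-3, pi2 = 1e-3, pi12 = 2e-3,
#'                  sigma1_2 = 1e-5, sigma2_2 = 2e-5, rho12 = 0.5)
#' @export
bivariate_params <- function(pi1, pi2, pi12, sigma1_2, sigma2_2, rho12 = 0,
                             sigma01_2 = 1, sigma02_2 = 1, rho0 = 0) {
  p <- list(pi1 = pi1, pi2 = pi2, pi12 = pi12,
            sigma1_2 = sigma1_2, sigma2_2 = sigma2_2, rho12 = rho12,
            sigma01_2 = sigma01_2, sigma02_2 = sigma02_2, rho0 = rho0)
  stopifnot(all(vapply(p, is.numeric, logical(1))),
            all(lengths(p) == 1L))
  if (any(c(pi1, pi2, pi12) < 0) || pi1 + pi2 + pi12 > 1 + 1e-12)
    abort("mixture weights must be >= 0 with pi1 + pi2 + pi12 <= 1.")
  if (abs(rho12) > 1 || abs(rho0) > 1) abort("correlations must lie in [-1, 1].")
  if (sigma1_2 < 0 || sigma2_2 < 0) abort("effect variances must be >= 0.")
  if (sigma01_2 <= 0 || sigma02_2 <= 0) abort("residual variances must be > 0.")
  structure(p, class = "bivariate_params")
}

#' @export
print.univariate_params <- function(x, ...) {
  cat("<univariate causal mixture parameters>\n")
  cat(sprintf("  pi1 = %.4g  sigma_beta2 = %.4g  sigma0_2 = %.4g\n",
              x$pi1, x$sigma_beta2, x$sigma0_2))
  invisible(x)
}

#' @export
print.bivariate_params <- function(x, ...) {
  cat("<bivariate causal mixture parameters>\n")
  cat(sprintf("  pi1 = %.4g  pi2 = %.4g  pi12 = %.4g\n", x$pi1, x$pi2, x$pi12))
  cat(sprintf("  sigma1_2 = %.4g  sigma2_2 = %.4g  rho12 = %.4g\n",
              x$sigma1_2, x$sigma2_2, x$rho12))
  cat(sprintf("  sigma01_2 = %.4g  sigma02_2 = %.4g  rho0 = %.4g\n",
              x$sigma01_2, x$sigma02_2, x$rho0))
  invisible(x)
}

#' @export
tidy.univariate_params <- function(x, ...) {
  tibble(term = c("pi1", "sigma_beta2", "sigma0_2"),
         estimate = c(x$pi1, x$sigma_beta2, x$sigma0_2))
}

#' @export
tidy.bivariate_params <- function(x, ...) {
  tibble(term = names(unclass(x)), estimate = unlist(unclass(x), use.names = FALSE))
}

# ---- transformed coordinates for optimization / standard errors -------------
# pi's: logit; sigma^2's: log; rho's: inverse-error-function scale
# (rho = erf(u), a strictly monotone map of the real line onto (-1, 1)).

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
erfinv <- function(r) qnorm((r + 1) / 2) / sqrt(2)

PI_FLOOR <- 1e-7

.logit <- function(p) qlogis(pmin(pmax(p, PI_FLOOR), 1 - 1e-12))
.inv_logit <- function(u) plogis(u)

param_transforms <- function(params) {
  if (inherits(params, "univariate_params")) {
    list(names = c("pi1", "sigma_beta2", "sigma0_2"),
         to = list(.logit, log, log),
         from = list(.inv_logit, exp, exp))
  } else if (inherits(params, "bivariate_params")) {
    list(names = c("pi1", "pi2", "pi12", "sigma1_2", "sigma2_2", "rho12",
                   "sigma01_2", "sigma02_2", "rho0"),
         to = list(.logit, .logit, .logit, log, log, erfinv, log, log, erfinv),
         from = list(.inv_logit, .inv_logit, .inv_logit, exp, exp, erf,
                     exp, exp, erf))
  } else {
    abort("unknown parameter class")
  }
}

params_to_u <- function(params, which = NULL) {
  tr <- param_transforms(params)
  idx <- if (is.null(which)) seq_along(tr$names) else match(which, tr$names)
  vapply(idx, function(i) tr$to[[i]](params[[tr$names[i]]]), numeric(1)) |>
    setNames(tr$names[idx])
}

u_to_params <- function(u, template, which = NULL) {
  tr <- param_transforms(template)
  nm <- if (is.null(which)) tr$names else which
  out <- unclass(template)
  for (k in seq_along(nm)) {
    i <- match(nm[k], tr$names)
    out[[nm[k]]] <- tr$from[[i]](u[[k]])
  }
  # rebuild through the constructor for validation-free speed: assign class
  structure(out, class = class(template))
}
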