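#' Akaike and Bayesian information criteria
#'
#' AIC = 2k - 2F and BIC = k ln(n) - 2F with n the effective number of SNPs
#' (the sum of pruning weights). For model comparison, k = 2 for the
#' infinitesimal model (effect variance + residual variance) and k = 3 for
#' the univariate causal mixture.
#'
#' @param loglik Weighted log-likelihood F.
#' @param k Number of free parameters.
#' @param n_effective Effective number of SNPs, > 0.
#' @return A named list with `aic` and `bic`.
#' @examples
#' information_criteria(0, 3, exp(1))   # bic = 3
#' information_criteria(10, 2, 100)     # aic = -16
#' @export
information_criteria <- function(loglik, k, n_effective) {
  if (n_effective <= 0) abort("`n_effective` must be > 0.")
  list(aic = 2 * k - 2 * loglik, bic = k * log(n_effective) - 2 * loglik)
}

default_fit_options <- function() {
  list(model_final = "auto",  # "exact"/"full" switch the final stage to the
                              # causal-configuration model; "auto" picks
                              # "exact" when an LD structure is supplied
       ld = NULL,             # ld_matrix + reference_panel enable the exact
       panel = NULL,          # final-stage objective
       exact_structure = NULL,
       K = 50L,               # replicates per SNP for the sampled full model
       censor_z = Inf,        # finite value enables right-censoring
       maxit = 400L,
       reltol = 1e-6,
       seed = 1L,
       polish = TRUE)         # bivariate: release (pi12, rho12) jointly at the end
}

# resolve the final-stage model and (when needed) the exact neighbor layout
resolve_final_model <- function(opt) {
  st <- opt$exact_structure
  if (is.null(st) && !is.null(opt$ld) && !is.null(opt$panel))
    st <- exact_model_structure(opt$ld, opt$panel)
  model <- opt$model_final
  if (model == "auto") model <- if (is.null(st)) "fast" else "exact"
  if (model == "exact" && is.null(st))
    abort("final model 'exact' needs `ld` + `panel` (or `exact_structure`) in options.")
  list(model = model, st = st)
}

new_mix_fit <- function(params, loglik, n_effective, k, trace, converged) {
  ic <- information_criteria(loglik, k, n_effective)
  structure(list(params = params, loglik = loglik, n_effective = n_effective,
                 k = k, aic = ic$aic, bic = ic$bic, trace = trace,
                 converged = converged, se = NULL, covariance = NULL),
            class = "mix_fit")
}

#' @export
print.mix_fit <- function(x, ...) {
  kind <- if (inherits(x$params, "univariate_params")) "univariate" else "bivariate"
  cat(sprintf("<%s causal mixture fit>  loglik = %.3f  n_eff = %.1f  AIC = %.1f  BIC = %.1f%s\n",
              kind, x$loglik, x$n_effective, x$aic, x$bic,
              if (isTRUE(x$converged)) "" else "  [not converged]"))
  print(x$params)
  invisible(x)
}

#' @export
tidy.mix_fit <- function(x, ...) {
  out <- tidy(x$params)
  if (!is.null(x$se)) out$std.error <- x$se[out$term]
  out
}

#' @export
glance.mix_fit <- function(x, ...) {
  tibble(logLik = x$loglik, AIC = x$aic, BIC = x$bic,
         n_effective = x$n_effective, nparam = x$k,
         converged = isTRUE(x$converged))
}

nm_optim <- function(par, fn, maxit, reltol) {
  if (length(par) == 1L) {
    # Nelder-Mead degenerates in 1-D; optim still runs it, silence the note
    res <- suppressWarnings(stats::optim(par, fn, method = "Nelder-Mead",
                                         control = list(maxit = maxit, reltol = reltol)))
  } else {
    res <- stats::optim(par, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
  }
  res
}

# objective factory: negative weighted (possibly censored) log-likelihood
make_objective <- function(z1, z2, contexts, weights, model, K, seed, censor_z,
                           st = NULL) {
  force(model)
  w <- if (is.data.frame(weights)) weights$w else weights
  if (model == "exact") {
    n1 <- contexts$n1; n2 <- contexts$n2
    return(function(params) {
      if (is.finite(censor_z)) {
        cens <- if (is.null(z2)) abs(z1) > censor_z
                else pmax(abs(z1), abs(z2)) > censor_z
        f <- exact_loglik_panel(params, z1, z2, n1, n2, ifelse(cens, 0, w), st)
        usec <- cens & w > 0
        if (any(usec)) {
          tm <- model_tail_mass(params, contexts[usec, , drop = FALSE], censor_z)
          f <- f + sum(w[usec] * log(pmax(tm, 1e-300)))
        }
      } else {
        f <- exact_loglik_panel(params, z1, z2, n1, n2, w, st)
      }
      if (!is.finite(f)) 1e12 else -f
    })
  }
  function(params) {
    f <- if (is.finite(censor_z)) {
      censored_loglik(params, z1, z2, contexts, weights, z_t = censor_z,
                      model = model, K = K, seed = seed)
    } else {
      weighted_loglik(params, z1, z2, contexts, weights,
                      model = model, K = K, seed = seed)
    }
    if (!is.finite(f)) 1e12 else -f
  }
}

#' Staged univariate maximum-likelihood fit
#'
#' Three Nelder-Mead stages, each warm-starting the next: (1) the fast model
#' under the infinitesimal constraint `pi1 = 1` fits the total signal
#' variance \eqn{\sigma^2_{inf}} and initializes \eqn{\sigma_0^2}; (2) the
#' fast model under the constraint \eqn{\pi \sigma_\beta^2 =
#' \sigma^2_{inf}} separates polygenicity from discoverability; (3) an
#' unconstrained joint fit of all three parameters. Stages 2-3 optimize in
#' the coordinates \eqn{(\log \pi\sigma^2, \log \pi/\sigma^2)}, which are
#' nearly independent directions of the likelihood surface.
#'
#' @param sumstats Harmonized sumstats tibble (columns `z`, aligned to
#'   `contexts`), or a numeric vector of z-scores.
#' @param contexts A [snp_contexts()] tibble.
#' @param weights Per-SNP pruning weights (vector or
#'   [random_pruning_weights()] tibble).
#' @param options Named list overriding [default_fit_options()]: notably
#'   `model_final` ("fast" or "full"), `K`, `censor_z`, `maxit`, `seed`.
#' @return A `mix_fit` object; `trace` records the per-stage solutions, and
#'   `converged = FALSE` flags stage non-convergence (best-so-far parameters
#'   are still returned).
#' @export
fit_univariate <- function(sumstats, contexts, weights, options = list()) {
  opt <- modifyList(default_fit_options(), options)
  z <- if (is.data.frame(sumstats)) sumstats$z else sumstats
  w <- if (is.data.frame(weights)) weights$w else weights
  stopifnot(length(z) == nrow(contexts), length(w) == nrow(contexts))
  neg_fast <- make_objective(z, NULL, contexts, w, "fast", opt$K, opt$seed, opt$censor_z)
  mk <- function(pi1, s2, s02) univariate_params(pi1, s2, s02)
  trace <- list()

  # stage 1: infinitesimal (pi1 = 1); parameters (log sigma2_inf, log sigma0_2)
  mean_z2 <- sum(w * z^2) / sum(w)
  mean_nl <- sum(w * contexts$n1 * contexts$ell) / sum(w)
  s2_init <- max((mean_z2 - 1) / mean_nl, 1e-10)
  o1 <- nm_optim(log(c(s2_init, 1)), function(u) {
    neg_fast(mk(1, exp(u[1]), exp(u[2])))
  }, opt$maxit, opt$reltol)
  sigma2_inf <- exp(o1$par[1]); sigma0_init <- exp(o1$par[2])
  trace$stage1 <- list(params = mk(1, sigma2_inf, sigma0_init),
                       loglik = -o1$value, convergence = o1$convergence)

  # stage 2: fast model with pi * sigma2 = sigma2_inf; optimize b = log(pi/sigma2)
  a <- log(sigma2_inf)  # a = log(pi * sigma2), frozen
  obj2 <- function(b) {
    pi1 <- exp((a + b) / 2)
    if (pi1 > 1 || pi1 < PI_FLOOR) return(1e12)
    neg_fast(mk(pi1, exp((a - b) / 2), sigma0_init))
  }
  b_grid <- seq(log(1e-6 / sigma2_inf), log(1 / sigma2_inf) - 1e-9, length.out = 25)
  b0 <- b_grid[which.min(vapply(b_grid, obj2, numeric(1)))]
  o2 <- nm_optim(b0, obj2, opt$maxit, opt$reltol)
  pi2_hat <- exp((a + o2$par[1]) / 2)
  s2_hat <- exp((a - o2$par[1]) / 2)
  trace$stage2 <- list(params = mk(min(pi2_hat, 1), s2_hat, sigma0_init),
                       loglik = -o2$value, convergence = o2$convergence)

  # stage 3: joint unconstrained fit in (log pi*s2, log pi/s2, log sigma0_2)
  fm <- resolve_final_model(opt)
  neg_final <- if (fm$model == "fast") neg_fast else
    make_objective(z, NULL, contexts, w, fm$model, opt$K, opt$seed,
                   opt$censor_z, st = fm$st)
  obj3 <- function(u) {
    pi1 <- exp((u[1] + u[2]) / 2)
    if (pi1 > 1 || pi1 < PI_FLOOR) return(1e12)
    neg_final(mk(pi1, exp((u[1] - u[2]) / 2), exp(u[3])))
  }
  u0 <- c(a, o2$par[1], log(sigma0_init))
  o3 <- nm_optim(u0, obj3, opt$maxit, opt$reltol)
  pi_f <- min(exp((o3$par[1] + o3$par[2]) / 2), 1)
  params <- mk(pi_f, exp((o3$par[1] - o3$par[2]) / 2), exp(o3$par[3]))
  trace$stage3 <- list(params = params, loglik = -o3$value,
                       convergence = o3$convergence)
  converged <- o1$convergence == 0 && o2$convergence == 0 && o3$convergence == 0
  fit <- new_mix_fit(params, -o3$value, sum(w), k = 3, trace = trace,
                     converged = converged)
  fit$sigma2_inf <- sigma2_inf
  fit
}

#' Staged bivariate maximum-likelihood fit
#'
#' Stage A fits the infinitesimal bivariate fast model (`pi12 = 1`, effect
#' variances anchored at the univariate infinitesimal fits) to estimate the
#' genetic correlation `rg` and the residual correlation `rho0`. Stage B
#' frees the shared-component weight `pi12` (bounded above by the smaller
#' univariate polygenicity) with all univariate parameters frozen at their
#' univariate estimates and `rho12` derived from the stage-A `rg` via
#' \eqn{\rho_{12} = r_g \sqrt{\pi_1^u \pi_2^u} / \pi_{12}} (clipped to
#' \[-1, 1\]; clipping is reported in the trace). Setting `options$polish =
#' TRUE` releases (`pi12`, `rho12`) jointly for a final refinement.
#'
#' @param fit1,fit2 Univariate `mix_fit` objects for the two traits.
#' @param z1,z2 Aligned z-score vectors (or sumstats tibbles).
#' @param contexts A [snp_contexts()] tibble with `n1` and `n2`.
#' @param weights Pruning weights.
#' @param options See [default_fit_options()].
#' @return A `mix_fit` with [bivariate_params()]; `trace` carries the
#'   stage-A estimates (`rg`, `rho0`) and a `rho12_clipped` flag.
#' @export
fit_bivariate <- function(fit1, fit2, z1, z2, contexts, weights,
                          options = list()) {
  opt <- modifyList(default_fit_options(), options)
  if (is.data.frame(z1)) z1 <- z1$z
  if (is.data.frame(z2)) z2 <- z2$z
  w <- if (is.data.frame(weights)) weights$w else weights
  p1 <- fit1$params; p2 <- fit2$params
  neg_fast <- make_objective(z1, z2, contexts, w, "fast", opt$K, opt$seed, opt$censor_z)

  # stage A: infinitesimal model; free (rho12 -> rg, rho0)
  s1_inf <- fit1$sigma2_inf %||% (p1$pi1 * p1$sigma_beta2)
  s2_inf <- fit2$sigma2_inf %||% (p2$pi1 * p2$sigma_beta2)
  s01 <- fit1$trace$stage1$params$sigma0_2 %||% p1$sigma0_2
  s02 <- fit2$trace$stage1$params$sigma0_2 %||% p2$sigma0_2
  mkA <- function(r12, r0) bivariate_params(0, 0, 1, s1_inf, s2_inf, r12,
                                            s01, s02, r0)
  # correlations bounded at +-0.999: the MLE can sit on the boundary (e.g.
  # duplicated traits) where the covariance goes singular
  rho_cap <- function(u) 0.999 * tanh(u)
  r_emp <- suppressWarnings(cor(z1, z2))
  if (!is.finite(r_emp)) r_emp <- 0
  oA <- nm_optim(c(atanh(0.9 * r_emp), atanh(0.5 * r_emp)), function(u) {
    neg_fast(mkA(rho_cap(u[1]), rho_cap(u[2])))
  }, opt$maxit, opt$reltol)
  rg_hat <- rho_cap(oA$par[1]); rho0_hat <- rho_cap(oA$par[2])

  # stage B: free pi12 in (floor, pi12_max); rho12 derived from rg
  pi1u <- p1$pi1; pi2u <- p2$pi1
  pi12_max <- min(pi1u, pi2u)
  clipped <- FALSE
  assemble <- function(pi12, rho12) {
    bivariate_params(max(pi1u - pi12, 0), max(pi2u - pi12, 0), pi12,
                     p1$sigma_beta2, p2$sigma_beta2, rho12,
                     p1$sigma0_2, p2$sigma0_2, rho0_hat)
  }
  rho12_of <- function(pi12) {
    r <- rg_hat * sqrt(pi1u * pi2u) / pi12
    if (abs(r) > 1) clipped <<- TRUE
    pmin(pmax(r, -0.999), 0.999)
  }
  fm <- resolve_final_model(opt)
  neg_B <- if (fm$model == "fast") neg_fast else
    make_objective(z1, z2, contexts, w, fm$model, opt$K, opt$seed,
                   opt$censor_z, st = fm$st)
  objB <- function(u) {
    pi12 <- pi12_max * plogis(u)
    if (pi12 < PI_FLOOR) pi12 <- PI_FLOOR
    neg_B(assemble(pi12, rho12_of(pi12)))
  }
  # coarse grid start: pi12 as a fraction of the admissible range
  fr_grid <- qlogis(c(0.02, 0.1, 0.3, 0.5, 0.7, 0.9, 0.98))
  u0 <- fr_grid[which.min(vapply(fr_grid, objB, numeric(1)))]
  oB <- nm_optim(u0, objB, opt$maxit, opt$reltol)
  pi12_hat <- max(pi12_max * plogis(oB$par[1]), PI_FLOOR)
  rho12_hat <- rho12_of(pi12_hat)
  loglik <- -oB$value
  convB <- oB$convergence

  if (isTRUE(opt$polish)) {
    objP <- function(u) {
      pi12 <- pi12_max * plogis(u[1])
      if (pi12 < PI_FLOOR) pi12 <- PI_FLOOR
      neg_B(assemble(pi12, rho_cap(u[2])))
    }
    oP <- nm_optim(c(qlogis(min(max(pi12_hat / pi12_max, 1e-6), 1 - 1e-6)),
                     atanh(pmin(pmax(rho12_hat, -0.99), 0.99))),
                   objP, opt$maxit, opt$reltol)
    pi12_hat <- max(pi12_max * plogis(oP$par[1]), PI_FLOOR)
    rho12_hat <- rho_cap(oP$par[2])
    loglik <- -oP$value
    convB <- oP$convergence
  }
  params <- assemble(pi12_hat, rho12_hat)
  trace <- list(stageA = list(rg = rg_hat, rho0 = rho0_hat, loglik = -oA$value,
                              convergence = oA$convergence),
                stageB = list(loglik = loglik, convergence = convB),
                rho12_clipped = clipped)
  fit <- new_mix_fit(params, loglik, sum(w), k = 9, trace = trace,
                     converged = oA$convergence == 0 && convB == 0)
  fit$rg <- genetic_correlation(params)
  fit
}
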