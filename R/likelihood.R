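#' Log-likelihood of a kinetic model
#'
#' Measured abundances are log-normal around the ODE mean trajectories with
#' per-isotopomer variances: \eqn{\log y_{tj} = \log \mu_t + \delta_{tj}},
#' \eqn{\delta_{tj} \sim N(0, \mathrm{diag}(\sigma^2))}. The returned value is
#' \deqn{-\frac{mT}{2} \sum_i \log \sigma_i^2
#'       - \frac12 \sum_{t,j,i} (\log y_{tji} - \log \mu_{ti})^2 / \sigma_i^2,}
#' i.e. the exact Gaussian log-likelihood of the log data with the constant
#' \eqn{-(nmT/2)\log 2\pi} omitted throughout the package (it cancels in all
#' acceptance ratios and credible computations).
#'
#' @param data Long-format abundance data (see [validate_dataset()]).
#' @param model A [kinetic_model()]; its observed states must match the
#'   data's isotopomers.
#' @param beta Numeric vector of log rate constants.
#' @param sigma2 Strictly positive error variances, one per observed state
#'   (ordered as `model$observed`, or named).
#' @param solver Passed to [solve_trajectories()].
#' @return A single number.
#' @export
log_likelihood <- function(data, model, beta, sigma2, solver = "auto") {
  ds <- dataset_internal(data, model)
  sigma2 <- order_sigma2(sigma2, ds)
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop_kb("sigma2 must be strictly positive", "kb_domain_error")
  }
  logmu <- solve_obs_logmu(model, beta, ds$times, solver = solver)
  rss <- resid_ss(ds, logmu)
  ll_from_rss(rss, sigma2, ds$m, ds$T)
}

order_sigma2 <- function(sigma2, ds) {
  if (length(sigma2) == 1L) sigma2 <- rep(sigma2, ds$n)
  if (length(sigma2) != ds$n) {
    stop_kb("sigma2 must have one entry per observed isotopomer", "kb_shape_error")
  }
  if (!is.null(names(sigma2))) {
    if (!setequal(names(sigma2), ds$isotopomers)) {
      stop_kb("names of sigma2 do not match the isotopomers", "kb_shape_error")
    }
    sigma2 <- sigma2[ds$isotopomers]
  }
  as.numeric(sigma2)
}

# per-isotopomer residual sums of squares sum_{t,j} (log y - log mu)^2
resid_ss <- function(ds, logmu) {
  r <- ds$logy - logmu[ds$row_idx, , drop = FALSE]
  colSums(r * r)
}

ll_from_rss <- function(rss, sigma2, m, Tn) {
  -(m * Tn / 2) * sum(log(sigma2)) - 0.5 * sum(rss / sigma2)
}

#' Joint log-posterior of (beta, sigma2)
#'
#' [log_likelihood()] plus the truncated-normal log prior of `beta` (see
#' [log_prior_beta()]) and the inverse-gamma log prior of each
#' \eqn{\sigma_i^2}, all up to fixed additive constants. Returns `-Inf`
#' whenever `beta` violates its truncation box.
#'
#' @inheritParams log_likelihood
#' @param prior A [beta_prior()].
#' @param hyper Shrinkage hyperparameters from [estimate_shrinkage()].
#' @return A single number (possibly `-Inf`).
#' @export
log_posterior <- function(data, model, beta, sigma2, prior, hyper,
                          solver = "auto") {
  lpb <- log_prior_beta(beta, prior)
  if (lpb == -Inf) return(-Inf)
  ll <- log_likelihood(data, model, beta, sigma2, solver = solver)
  lps <- sum(dinvgamma_log_kernel(sigma2, hyper$alpha_star, hyper$kappa_star))
  ll + lpb + lps
}
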