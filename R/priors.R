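#' Truncated multivariate normal prior on log rate constants
#'
#' The prior for \eqn{\beta} is multivariate normal with mean \eqn{\xi} and
#' covariance \eqn{\Lambda}, truncated to the box
#' \eqn{[\zeta_l, \zeta_u]} supplied by the experimentalist. Mean, spread and
#' bounds encode literature knowledge (e.g. BRENDA-type enzyme databases)
#' about plausible rate constants on the log scale.
#'
#' @param mean Numeric vector \eqn{\xi} (log-rate units), optionally named.
#' @param sd Numeric vector of prior standard deviations (diagonal
#'   \eqn{\Lambda}); ignored when `cov` is given.
#' @param cov Full covariance matrix \eqn{\Lambda} (symmetric positive
#'   definite).
#' @param lower,upper Truncation bounds \eqn{\zeta_l < \zeta_u}; `mean` must
#'   lie strictly inside.
#'
#' @return An object of class `kb_prior`.
#' @export
beta_prior <- function(mean, sd = NULL, cov = NULL, lower, upper) {
  xi <- as.numeric(mean)
  d <- length(xi)
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (is.null(cov)) {
    if (is.null(sd)) stop_kb("supply `sd` or `cov`", "kb_prior_error")
    cov <- diag(rep_len(as.numeric(sd), d)^2, d)
  }
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-8))) {
    stop_kb("Lambda must be symmetric", "kb_prior_error")
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_kb("Lambda must be positive definite", "kb_prior_error")
  }
  if (any(lower >= upper)) stop_kb("need lower < upper elementwise", "kb_prior_error")
  if (any(xi <= lower | xi >= upper)) {
    stop_kb("prior mean must lie strictly inside the truncation box",
            "kb_prior_error")
  }
  structure(list(xi = xi, Lambda = cov, Lambda_inv = solve(cov),
                 zeta_l = lower, zeta_u = upper,
                 names = names(mean)),
            class = "kb_prior")
}

#' Build a diagonal prior from plausible parameter ranges
#'
#' A convenience for the common case where only a plausible range per log
#' rate constant is known: the prior mean is the midpoint and the standard
#' deviation a quarter of the range (so the range is roughly a 95% prior
#' interval), with the range itself as the truncation box.
#'
#' @param lower,upper Numeric vectors of log-rate bounds.
#' @return A `kb_prior`.
#' @export
prior_from_ranges <- function(lower, upper) {
  beta_prior(mean = (lower + upper) / 2, sd = (upper - lower) / 4,
             lower = lower, upper = upper)
}

#' Log density of the truncated normal prior (unnormalized)
#'
#' Returns \eqn{-\tfrac12 (\beta-\xi)' \Lambda^{-1} (\beta-\xi)} inside the
#' truncation box and `-Inf` outside. The normalizing constant is omitted:
#' it cancels in every Metropolis ratio.
#'
#' @param beta Numeric vector of log rate constants.
#' @param prior A [beta_prior()].
#' @return A single number (possibly `-Inf`).
#' @export
log_prior_beta <- function(beta, prior) {
  if (length(beta) != length(prior$xi)) {
    stop_kb("beta and prior dimension mismatch", "kb_shape_error")
  }
  if (any(beta < prior$zeta_l | beta > prior$zeta_u)) return(-Inf)
  z <- beta - prior$xi
  -0.5 * sum(z * (prior$Lambda_inv %*% z))
}

#' Empirical-Bayes shrinkage hyperparameters for the error variances
#'
#' All per-isotopomer error variances \eqn{\sigma_i^2} share one
#' inverse-gamma prior whose shape \eqn{\alpha_*} and scale \eqn{\kappa_*}
#' are determined from the data: with \eqn{s_{it}^2} the sample variance of
#' log abundance over the m replicates for isotopomer i at time t, and
#' \eqn{\bar{s^2}} their grand mean over all nT cells,
#' \deqn{\alpha_* = (\bar{s^2})^2 / \{ \sum (s_{it}^2-\bar{s^2})^2/(nT-1) \} + 2,
#'       \qquad \kappa_* = \bar{s^2} (\alpha_*-1).}
#' This moment-matching pulls unstable per-isotopomer variance estimates
#' toward the ensemble, exactly as variance moderation does in
#' small-replicate omics studies.
#'
#' @param data Long-format abundance data (see [validate_dataset()]).
#' @return An object of class `kb_shrinkage` with fields `alpha_star`,
#'   `kappa_star`.
#' @export
estimate_shrinkage <- function(data) {
  ds <- dataset_internal(data)
  shrinkage_from_variances(as.numeric(ds$cellvar))
}

#' @rdname estimate_shrinkage
#' @param s2 Numeric vector of per-cell sample variances (length nT).
#' @export
shrinkage_from_variances <- function(s2) {
  s2 <- as.numeric(s2)
  if (length(s2) < 2L || any(!is.finite(s2)) || any(s2 < 0)) {
    stop_kb("need at least two finite nonnegative sample variances",
            "kb_insufficient_replicates_error")
  }
  sbar <- mean(s2)
  disp <- sum((s2 - sbar)^2) / (length(s2) - 1)
  if (disp <= 0) {
    stop_kb("sample variances are all identical: shrinkage dispersion degenerate",
            "kb_degenerate_dispersion_error")
  }
  alpha_star <- sbar^2 / disp + 2
  kappa_star <- sbar * (alpha_star - 1)
  structure(list(alpha_star = alpha_star, kappa_star = kappa_star),
            class = "kb_shrinkage")
}

#' @export
print.kb_shrinkage <- function(x, ...) {
  cat(sprintf("<kb_shrinkage> alpha* = %.4g, kappa* = %.4g (prior mean %.4g)\n",
              x$alpha_star, x$kappa_star, x$kappa_star / (x$alpha_star - 1)))
  invisible(x)
}

#' Conjugate draw of one error variance
#'
#' Given the current mean trajectories, the conditional posterior of
#' \eqn{\sigma_i^2} is inverse-gamma with shape \eqn{\alpha_* + mT/2} and
#' scale \eqn{\kappa_* + RSS_i/2}, where \eqn{RSS_i} is the residual sum of
#' squares of log abundance around log \eqn{\mu} for isotopomer i.
#'
#' @param residual_ss Nonnegative residual sum of squares
#'   \eqn{\sum_t \sum_j (\log y_{tji} - \log \mu_{ti})^2}.
#' @param hyper A `kb_shrinkage` (or list with `alpha_star`, `kappa_star`).
#' @param m,T Replicate and time-point counts.
#' @return One strictly positive draw.
#' @export
sample_sigma2_conditional <- function(residual_ss, hyper, m, T) {
  if (!is.finite(residual_ss) || residual_ss < 0) {
    stop_kb("residual_ss must be finite and >= 0", "kb_domain_error")
  }
  rinvgamma1(shape = hyper$alpha_star + m * T / 2,
             scale = hyper$kappa_star + residual_ss / 2)
}
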