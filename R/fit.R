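#' Fit a Bayesian kinetic model by MCMC
#'
#' Draws from the joint posterior of the log rate constants \eqn{\beta} and
#' the per-isotopomer error variances \eqn{\sigma^2} by Gibbs sampling: each
#' sweep performs a cyclic pass of component-wise adaptive-Metropolis
#' updates of \eqn{\beta_1..\beta_d} (with delayed rejection once active)
#' against the conditional log posterior, followed by exact conjugate
#' inverse-gamma draws of every \eqn{\sigma_i^2}. The chain starts at the
#' prior mean with \eqn{\sigma^2} initialized at the pooled per-isotopomer
#' sample variances of the log data. Proposals whose ODE solve fails or that
#' leave the truncation box are rejected (failures are counted, not fatal).
#'
#' @param data Long-format abundance data (see [validate_dataset()]).
#' @param model A [kinetic_model()].
#' @param prior A [beta_prior()] of dimension `model$d`.
#' @param config A [sampler_config()].
#' @param hyper Optional precomputed [estimate_shrinkage()] result; computed
#'   from `data` when `NULL`.
#' @param solver ODE solver choice, see [solve_trajectories()].
#'
#' @return An object of class `kb_fit` with components `beta` (n_iter x d),
#'   `sigma2` (n_iter x n), `lp` (joint log-posterior trace), `acceptance`,
#'   and the configuration used. `tidy()`, `glance()`, [posterior_summary()]
#'   and [plot_trace()] summarize it.
#' @export
#' @examples
#' mod <- exemplar_network("decay2")
#' dat <- simulate_dataset(mod, attr(mod, "beta_true"),
#'                         times = attr(mod, "default_times"), m = 3,
#'                         noise = noise_spec(sigma2 = 0.04), seed = 7)
#' fit <- fit_kinetics(dat, mod, attr(mod, "prior"),
#'                     sampler_config(n_iter = 600, burn_in = 200, l0 = 150,
#'                                    dr_onset = 200, seed = 7))
#' posterior_summary(fit)
fit_kinetics <- function(data, model, prior, config = sampler_config(),
                         hyper = NULL, solver = "auto") {
  ds <- dataset_internal(data, model)
  d <- model$d
  if (length(prior$xi) != d) {
    stop_kb("prior dimension does not match the model", "kb_shape_error")
  }
  hyper <- hyper %||% estimate_shrinkage(data)
  config$s_d <- config$s_d %||% (2.4^2 / d)
  config$C0 <- config$C0 %||% diag(diag(prior$Lambda) * 0.1, d)

  m <- ds$m; Tn <- ds$T
  xi <- prior$xi; Li <- prior$Lambda_inv
  zl <- prior$zeta_l; zu <- prior$zeta_u
  sigma2 <- pmax(colMeans(ds$cellvar), 1e-10)
  ode_failures <- 0L

  eval_fun <- function(beta, i) {
    if (any(beta < zl | beta > zu)) return(list(lp = -Inf))
    logmu <- tryCatch(solve_obs_logmu(model, beta, ds$times, solver = solver),
                      error = function(e) {
                        ode_failures <<- ode_failures + 1L
                        NULL
                      })
    if (is.null(logmu)) return(list(lp = -Inf))
    rss <- resid_ss(ds, logmu)
    z <- beta - xi
    lpb <- -0.5 * sum(z * (Li %*% z))
    list(lp = ll_from_rss(rss, sigma2, m, Tn) + lpb, rss = rss, lpb = lpb)
  }

  after_sweep <- function(cur) {
    s2 <- vapply(cur$rss, function(r) {
      sample_sigma2_conditional(r, hyper, m, Tn)
    }, numeric(1))
    sigma2 <<- s2
    ll <- ll_from_rss(cur$rss, s2, m, Tn)
    cur$lp <- ll + cur$lpb
    cur$lp_full <- cur$lp +
      sum(dinvgamma_log_kernel(s2, hyper$alpha_star, hyper$kappa_star))
    cur
  }

  record_extra <- function(cur) stats::setNames(sigma2, ds$isotopomers)

  set.seed(config$seed)
  out <- dram_engine(eval_fun, xi, config,
                     after_sweep = after_sweep, record_extra = record_extra)
  colnames(out$draws) <- model$parameters
  out$acceptance$component <- model$parameters

  structure(list(
    beta = out$draws, sigma2 = out$extra, lp = out$lp_trace,
    acceptance = out$acceptance, config = config, burn_in = config$burn_in,
    model = model, prior = prior, hyper = hyper,
    data_info = list(m = m, T = Tn, n = ds$n, times = ds$times,
                     isotopomers = ds$isotopomers),
    ode_failures = ode_failures
  ), class = "kb_fit")
}

#' Post-burn-in draws of a fitted chain
#'
#' @param fit A `kb_fit`.
#' @param what `"beta"` or `"sigma2"`.
#' @return A matrix of retained draws.
#' @export
posterior_draws <- function(fit, what = c("beta", "sigma2")) {
  what <- match.arg(what)
  keep <- seq.int(fit$burn_in + 1L, nrow(fit$beta))
  fit[[what]][keep, , drop = FALSE]
}

#' Posterior summary table
#'
#' One row per parameter (log rate constants, then error variances):
#' posterior mean, sd, HDI bounds at `level`, and the Geweke convergence
#' z-score of the post-burn-in chain.
#'
#' @param fit A `kb_fit`.
#' @param level HDI probability mass.
#' @return A tibble.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  summarize_block <- function(draws, type) {
    purrr::map_dfr(colnames(draws) %||% paste0(type, seq_len(ncol(draws))),
                   function(nm) {
      x <- draws[, nm]
      h <- hdi(x, level)
      gz <- tryCatch(geweke_z(x), error = function(e) NA_real_)
      tibble::tibble(term = nm, type = type,
                     estimate = mean(x), std.error = stats::sd(x),
                     hdi_lower = h$lower, hdi_upper = h$upper,
                     geweke_z = gz)
    })
  }
  dplyr::bind_rows(
    summarize_block(posterior_draws(fit, "beta"), "beta"),
    summarize_block(posterior_draws(fit, "sigma2"), "sigma2"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.kb_fit <- function(x, level = 0.95, ...) posterior_summary(x, level)

#' @export
glance.kb_fit <- function(x, ...) {
  acc <- x$acceptance
  tot <- sum(acc$proposals)
  tibble::tibble(
    n_iter = x$config$n_iter, burn_in = x$burn_in,
    n_parameters = ncol(x$beta), n_isotopomers = ncol(x$sigma2),
    accept_rate = sum(acc$stage1_accepts + acc$stage2_accepts) / tot,
    stage2_share = sum(acc$stage2_accepts) / tot,
    mean_log_posterior = mean(x$lp[seq.int(x$burn_in + 1L, length(x$lp))]),
    ode_failures = x$ode_failures)
}

#' @export
print.kb_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<kb_fit> %d iterations (%d burn-in), %d parameters, %d isotopomers\n",
              g$n_iter, g$burn_in, g$n_parameters, g$n_isotopomers))
  cat(sprintf("  acceptance %.1f%% (stage 2: %.1f%%), mean log-posterior %.2f\n",
              100 * g$accept_rate, 100 * g$stage2_share, g$mean_log_posterior))
  print(posterior_summary(x), n = Inf)
  invisible(x)
}
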