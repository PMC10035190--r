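#' Compare one kinetic parameter between two experimental groups
#'
#' Jointly models the two groups with the difference reparameterization
#' \eqn{\eta_k = \beta_k^{(1)} - \beta_k^{(2)}}: the sampled vector is
#' \eqn{(\beta^{(1)}, \beta^{(2)}_{-k}, \eta_k)} and group 2's k-th log
#' rate constant is reconstructed as \eqn{\beta_k^{(1)} - \eta_k} (never
#' stored). Group 1's likelihood uses \eqn{\beta^{(1)}}, group 2's the
#' reconstructed \eqn{\beta^{(2)}}; each group keeps its own error
#' variances with shrinkage hyperparameters estimated per group. The prior
#' of \eqn{\eta_k} is \eqn{N(0, \Lambda_{kk})}, the prior variance of
#' \eqn{\beta_k^{(1)}}; both full parameter vectors must respect the
#' truncation box. The null \eqn{\eta_k = 0} is assessed by the 95% HDI and
#' the credible value (two-sided; < 0.05 declared significant).
#'
#' @param data1,data2 Long-format abundance tables for the two groups,
#'   sharing the model's observed states.
#' @param model A [kinetic_model()].
#' @param param Name (or index) of the tested log rate constant.
#' @param prior A [beta_prior()] shared by both groups.
#' @param config A [sampler_config()].
#' @param eta_prior_var Override for the prior variance of \eqn{\eta_k};
#'   defaults to \eqn{\Lambda_{kk}}.
#' @param group_labels Labels used in reports; the difference is
#'   `group1 - group2`.
#' @param level HDI level for the reported interval.
#'
#' @return An object of class `kb_comparison`: `eta_draws` (post-burn-in),
#'   `hdi`, `credible_value`, `significant`, per-group chains (`chain1`,
#'   `chain2`, each with `beta` and `sigma2` draws), and bookkeeping.
#'   `tidy()` / [test_summary()] give the one-row report.
#' @export
compare_groups <- function(data1, data2, model, param, prior,
                           config = sampler_config(), eta_prior_var = NULL,
                           group_labels = c("group1", "group2"),
                           level = 0.95) {
  d <- model$d
  k <- if (is.character(param)) match(param, model$parameters) else as.integer(param)
  if (is.na(k) || k < 1L || k > d) {
    stop_kb("`param` does not name a model parameter", "kb_lookup_error")
  }
  ds1 <- dataset_internal(data1, model)
  ds2 <- dataset_internal(data2, model)
  if (length(prior$xi) != d) {
    stop_kb("prior dimension does not match the model", "kb_shape_error")
  }
  hyper1 <- estimate_shrinkage(data1)
  hyper2 <- estimate_shrinkage(data2)
  eta_var <- eta_prior_var %||% prior$Lambda[k, k]

  xi <- prior$xi; Li <- prior$Lambda_inv
  zl <- prior$zeta_l; zu <- prior$zeta_u
  Lmk_inv <- if (d > 1L) solve(prior$Lambda[-k, -k, drop = FALSE]) else NULL
  ximk <- xi[-k]

  sigma2_1 <- pmax(colMeans(ds1$cellvar), 1e-10)
  sigma2_2 <- pmax(colMeans(ds2$cellvar), 1e-10)

  # theta = (beta1 [d], beta2_{-k} [d-1], eta)
  idx_b1 <- seq_len(d)
  idx_b2 <- if (d > 1L) d + seq_len(d - 1L) else integer(0)
  idx_eta <- 2L * d

  # tiny memo for group trajectories: consecutive evaluations mostly reuse
  # the current group's solution (component updates touch one group, except
  # beta1_k and eta which touch group 2 through the reconstruction)
  memo <- new.env(parent = emptyenv())
  solve_grp <- function(tag, beta, ds) {
    key <- paste0(tag, paste(beta, collapse = ","))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- tryCatch({
      logmu <- solve_obs_logmu(model, beta, ds$times)
      resid_ss(ds, logmu)
    }, error = function(e) NA)
    memo[[key]] <- val
    keys <- ls(memo)
    if (length(keys) > 8L) rm(list = keys[1L], envir = memo)
    val
  }

  eval_fun <- function(theta, i) {
    beta1 <- theta[idx_b1]
    eta <- theta[idx_eta]
    beta2 <- numeric(d)
    if (d > 1L) beta2[-k] <- theta[idx_b2]
    beta2[k] <- beta1[k] - eta
    if (any(beta1 < zl | beta1 > zu) || any(beta2 < zl | beta2 > zu)) {
      return(list(lp = -Inf))
    }
    rss1 <- solve_grp("g1:", beta1, ds1)
    if (anyNA(rss1)) return(list(lp = -Inf))
    rss2 <- solve_grp("g2:", beta2, ds2)
    if (anyNA(rss2)) return(list(lp = -Inf))
    z1 <- beta1 - xi
    lpb <- -0.5 * sum(z1 * (Li %*% z1)) - 0.5 * eta^2 / eta_var
    if (d > 1L) {
      z2 <- beta2[-k] - ximk
      lpb <- lpb - 0.5 * sum(z2 * (Lmk_inv %*% z2))
    }
    ll <- ll_from_rss(rss1, sigma2_1, ds1$m, ds1$T) +
      ll_from_rss(rss2, sigma2_2, ds2$m, ds2$T)
    list(lp = ll + lpb, rss1 = rss1, rss2 = rss2, lpb = lpb, beta2k = beta2[k])
  }

  after_sweep <- function(cur) {
    sigma2_1 <<- vapply(cur$rss1, function(r) {
      sample_sigma2_conditional(r, hyper1, ds1$m, ds1$T)
    }, numeric(1))
    sigma2_2 <<- vapply(cur$rss2, function(r) {
      sample_sigma2_conditional(r, hyper2, ds2$m, ds2$T)
    }, numeric(1))
    ll <- ll_from_rss(cur$rss1, sigma2_1, ds1$m, ds1$T) +
      ll_from_rss(cur$rss2, sigma2_2, ds2$m, ds2$T)
    cur$lp <- ll + cur$lpb
    cur$lp_full <- cur$lp +
      sum(dinvgamma_log_kernel(sigma2_1, hyper1$alpha_star, hyper1$kappa_star)) +
      sum(dinvgamma_log_kernel(sigma2_2, hyper2$alpha_star, hyper2$kappa_star))
    cur
  }

  record_extra <- function(cur) {
    c(stats::setNames(sigma2_1, paste0("s2_1_", ds1$isotopomers)),
      stats::setNames(sigma2_2, paste0("s2_2_", ds2$isotopomers)),
      beta2k = cur$beta2k)
  }

  dim_theta <- 2L * d
  config$s_d <- config$s_d %||% (2.4^2 / dim_theta)
  config$C0 <- config$C0 %||%
    diag(c(diag(prior$Lambda), diag(prior$Lambda)[-k], eta_var) * 0.1,
         dim_theta)
  init <- c(xi, if (d > 1L) xi[-k], 0)

  set.seed(config$seed)
  out <- dram_engine(eval_fun, init, config,
                     after_sweep = after_sweep, record_extra = record_extra)

  keep <- seq.int(config$burn_in + 1L, config$n_iter)
  eta_draws <- out$draws[keep, idx_eta]
  h <- hdi(eta_draws, level)
  p <- credible_value(eta_draws, 0)
  param_name <- model$parameters[k]

  beta1_draws <- out$draws[, idx_b1, drop = FALSE]
  colnames(beta1_draws) <- model$parameters
  beta2_draws <- matrix(NA_real_, config$n_iter, d,
                        dimnames = list(NULL, model$parameters))
  if (d > 1L) beta2_draws[, -k] <- out$draws[, idx_b2]
  beta2_draws[, k] <- out$extra[, "beta2k"]
  n1 <- ds1$n

  structure(list(
    eta_draws = eta_draws, hdi = h, credible_value = p,
    significant = p < 0.05, parameter = param_name, k = k,
    group_labels = group_labels, level = level,
    chain1 = list(beta = beta1_draws,
                  sigma2 = out$extra[, seq_len(n1), drop = FALSE]),
    chain2 = list(beta = beta2_draws,
                  sigma2 = out$extra[, n1 + seq_len(ds2$n), drop = FALSE]),
    lp = out$lp_trace, acceptance = out$acceptance,
    config = config, burn_in = config$burn_in,
    hyper = list(hyper1, hyper2), eta_prior_var = eta_var
  ), class = "kb_comparison")
}

#' One-row hypothesis-test report
#'
#' The report row for a two-group comparison: tested parameter, credible
#' value, HDI of the between-group difference (`group1 - group2`) and the
#' significance call at 0.05.
#'
#' @param result A `kb_comparison`.
#' @return A one-row tibble.
#' @export
test_summary <- function(result) {
  tibble::tibble(
    parameter = result$parameter,
    credible_value = result$credible_value,
    hdi_lower = result$hdi$lower,
    hdi_upper = result$hdi$upper,
    level = result$level,
    significant = result$significant,
    difference = paste(result$group_labels, collapse = " - "),
    estimate = mean(result$eta_draws))
}

#' @export
tidy.kb_comparison <- function(x, ...) test_summary(x)

#' @export
glance.kb_comparison <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    credible_value = x$credible_value,
    significant = x$significant,
    n_iter = x$config$n_iter,
    burn_in = x$burn_in,
    accept_rate = sum(x$acceptance$stage1_accepts + x$acceptance$stage2_accepts) /
      sum(x$acceptance$proposals))
}

#' @export
print.kb_comparison <- function(x, ...) {
  cat(sprintf("<kb_comparison> %s: %s - %s\n", x$parameter,
              x$group_labels[1], x$group_labels[2]))
  cat(sprintf("  eta posterior mean %.4f, %.0f%% HDI (%.4f, %.4f)\n",
              mean(x$eta_draws), 100 * x$level, x$hdi$lower, x$hdi$upper))
  cat(sprintf("  credible value %.4g -> %s\n", x$credible_value,
              if (x$significant) "significant at 0.05" else "not significant"))
  invisible(x)
}

#' @export
autoplot.kb_comparison <- function(object, ...) {
  df <- tibble::tibble(eta = object$eta_draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eta)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(object$hdi$lower, object$hdi$upper),
                        color = "firebrick") +
    ggplot2::labs(
      x = sprintf("difference in %s (%s - %s)", object$parameter,
                  object$group_labels[1], object$group_labels[2]),
      y = "posterior density",
      title = sprintf("credible value %.4g", object$credible_value)) +
    ggplot2::theme_minimal()
}
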