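#' Posterior flux trajectory
#'
#' For each retained posterior draw of the log rate constants, integrates
#' the ODEs and evaluates a named flux (concentration/time) over a time
#' grid, then summarizes pointwise by the posterior mean and central 95%
#' credible bounds. The bounds are clamped to bracket the mean at every
#' time, so `lower <= mean <= upper` holds by construction.
#'
#' @param fit A `kb_fit` (or `kb_comparison` group chain).
#' @param flux_name Name of a flux registered in the model.
#' @param times Time grid (strictly increasing, >= 0).
#' @param max_draws Cap on the number of posterior draws used (evenly
#'   thinned); integrating the ODEs per draw dominates the cost.
#' @param level Credible level for the bounds.
#' @return A tibble of class `kb_flux_trajectory` with columns `time`,
#'   `mean`, `lower`, `upper`.
#' @export
flux_trajectory <- function(fit, flux_name, times, max_draws = 500,
                            level = 0.95) {
  model <- fit$model
  if (!flux_name %in% names(model$fluxes)) {
    stop_kb(paste0("unknown flux: ", flux_name), "kb_flux_error")
  }
  ffun <- model$fluxes[[flux_name]]
  draws <- posterior_draws(fit, "beta")
  if (nrow(draws) < 1L) stop_kb("empty chain", "kb_spec_error")
  if (nrow(draws) > max_draws) {
    draws <- draws[round(seq(1, nrow(draws), length.out = max_draws)), ,
                   drop = FALSE]
  }
  vals <- matrix(NA_real_, nrow(draws), length(times))
  for (r in seq_len(nrow(draws))) {
    beta <- draws[r, ]
    k <- stats::setNames(exp(beta), model$parameters)
    mu <- solve_mu(model, beta, times)
    vals[r, ] <- vapply(seq_along(times), function(ti) {
      ffun(mu[ti, ], k, times[ti])
    }, numeric(1))
  }
  a <- (1 - level) / 2
  mn <- colMeans(vals)
  lo <- apply(vals, 2L, stats::quantile, probs = a, names = FALSE)
  hi <- apply(vals, 2L, stats::quantile, probs = 1 - a, names = FALSE)
  out <- tibble::tibble(time = times, mean = mn,
                        lower = pmin(lo, mn), upper = pmax(hi, mn))
  class(out) <- c("kb_flux_trajectory", class(out))
  attr(out, "flux_name") <- flux_name
  attr(out, "level") <- level
  out
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.kb_flux_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time", y = "flux (concentration / time)",
                  title = attr(object, "flux_name"),
                  subtitle = sprintf("posterior mean with %.0f%% credible bounds",
                                     100 * attr(object, "level"))) +
    ggplot2::theme_minimal()
}

#' Trace plots of a fitted chain
#'
#' @param fit A `kb_fit`.
#' @param pars Optional subset of parameter names.
#' @return A ggplot.
#' @export
plot_trace <- function(fit, pars = NULL) {
  draws <- fit$beta
  if (!is.null(pars)) draws <- draws[, pars, drop = FALSE]
  df <- tibble::as_tibble(as.data.frame(draws)) |>
    dplyr::mutate(iteration = dplyr::row_number()) |>
    tidyr::pivot_longer(-"iteration", names_to = "term", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, color = "grey30") +
    ggplot2::geom_vline(xintercept = fit$burn_in, linetype = 2,
                        color = "firebrick") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "log rate constant") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kb_fit <- function(object, ...) plot_trace(object)

#' @importFrom rlang .data
NULL
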