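#' Noise specification for simulated datasets
#'
#' Either fixed per-isotopomer log-scale variances, or inverse-gamma
#' hyperparameters from which one variance per isotopomer is drawn once per
#' dataset — the latter mirrors how replicate variation is generated in the
#' simulation designs this generator emulates.
#'
#' @param sigma2 Fixed variance(s): scalar or one per observed isotopomer.
#' @param shape,scale Inverse-gamma hyperparameters (used when `sigma2` is
#'   `NULL`).
#' @return An object of class `kb_noise`.
#' @export
noise_spec <- function(sigma2 = NULL, shape = NULL, scale = NULL) {
  if (is.null(sigma2) && (is.null(shape) || is.null(scale))) {
    stop_kb("supply `sigma2` or both `shape` and `scale`", "kb_spec_error")
  }
  if (!is.null(sigma2) && any(sigma2 <= 0)) {
    stop_kb("sigma2 must be > 0", "kb_spec_error")
  }
  structure(list(sigma2 = sigma2, shape = shape, scale = scale),
            class = "kb_noise")
}

#' Simulate a replicated isotopomer time course
#'
#' Generates data with exactly the model's error structure:
#' \eqn{y_{tji} = \exp(\log \mu_{ti} + \delta_{tji})},
#' \eqn{\delta_{tji} \sim N(0, \sigma_i^2)} independently across time,
#' replicate and isotopomer, where \eqn{\mu} solves the ODEs at the true
#' log rate constants.
#'
#' @param model A [kinetic_model()].
#' @param beta_true True log rate constants.
#' @param times Observation times (strictly increasing, > 0).
#' @param m Number of replicates (default 3, a typical tracer design).
#' @param noise A [noise_spec()].
#' @param seed RNG seed; identical seeds give identical tables.
#' @return A long-format tibble (`isotopomer`, `time`, `replicate`,
#'   `abundance`) with attributes `beta_true`, `sigma2_true` and `seed`.
#' @export
simulate_dataset <- function(model, beta_true, times, m = 3,
                             noise = noise_spec(shape = 3, scale = 0.1),
                             seed = 1L) {
  set.seed(seed)
  n <- length(model$observed)
  sigma2 <- if (!is.null(noise$sigma2)) {
    rep_len(noise$sigma2, n)
  } else {
    vapply(seq_len(n), function(i) rinvgamma1(noise$shape, noise$scale),
           numeric(1))
  }
  mu <- solve_mu(model, beta_true, times)
  muo <- mu[, model$observed_idx, drop = FALSE]
  if (any(muo <= 0)) {
    stop_kb("true mean concentration <= 0 at an observed cell", "kb_domain_error")
  }
  grid <- tidyr::expand_grid(replicate = seq_len(m),
                             isotopomer = model$observed,
                             time = times)
  ti <- match(grid$time, times)
  ii <- match(grid$isotopomer, model$observed)
  logmu <- log(muo)[cbind(ti, ii)]
  grid$abundance <- exp(logmu + stats::rnorm(nrow(grid), 0, sqrt(sigma2[ii])))
  out <- dplyr::arrange(grid[, c("isotopomer", "time", "replicate", "abundance")],
                        .data$isotopomer, .data$time, .data$replicate)
  attr(out, "beta_true") <- stats::setNames(beta_true, model$parameters)
  attr(out, "sigma2_true") <- stats::setNames(sigma2, model$observed)
  attr(out, "seed") <- seed
  out
}

#' Shipped exemplar kinetic networks
#'
#' Two fully specified reference networks with documented true parameter
#' values, used in simulations, tests and examples:
#'
#' * `"decay2"`: a two-state chain A -> B -> (out) with two rate constants
#'   and closed-form trajectories — the minimal identifiable network.
#' * `"pool3_mini"`: an 8-state, 6-parameter labeled/unlabeled two-pool
#'   conversion network emulating tracer dilution: labeled substrate in the
#'   medium is taken up into the cytoplasm and converted through a
#'   serine/glycine-like chain, while the pre-existing unlabeled pools decay
#'   through the same enzymes (shared rate constants per conversion step).
#'
#' The returned model carries attributes `beta_true` (documented true log
#' rate constants), `default_times` (an observation grid over which the
#' trajectories vary visibly) and `prior` (a [prior_from_ranges()] over
#' generous log-rate bounds).
#'
#' @param name `"decay2"` or `"pool3_mini"`.
#' @return A `kb_model` with the attributes described above.
#' @export
exemplar_network <- function(name = c("decay2", "pool3_mini")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop_kb(
                     paste0("unknown exemplar network: ", name[1]),
                     "kb_lookup_error"))
  if (name == "decay2") {
    rxn <- data.frame(from = c("A", "B"), to = c("B", NA),
                      param = c("k1", "k2"),
                      name = c("v_A_B", "v_B_out"))
    mod <- mass_action_network(rxn, initial = c(A = 1, B = 0.25))
    truth <- log(c(k1 = 0.4, k2 = 0.15))
    times <- c(0.5, 1, 2, 4, 6, 8)
    pr <- prior_from_ranges(lower = rep(log(0.01), 2), upper = rep(log(10), 2))
  } else {
    rxn <- data.frame(
      from = c("Glc_med_lab", "Glc_cyt_lab", "Glc_cyt_unlab",
               "Ser_lab", "Ser_unlab", "Gly_lab", "Gly_unlab",
               "Glc_cyt_unlab", "Ser_lab", "Ser_unlab"),
      to = c("Glc_cyt_lab", "Ser_lab", "Ser_unlab",
             "Gly_lab", "Gly_unlab", "Sink", "Sink",
             "Sink", "Sink", "Sink"),
      param = c("k_uptake", "k_glc_ser", "k_glc_ser",
                "k_ser_gly", "k_ser_gly", "k_gly_use", "k_gly_use",
                "k_glc_use", "k_ser_use", "k_ser_use"),
      name = c("v_uptake", "v_glc_ser_lab", "v_glc_ser_unlab",
               "v_ser_gly_lab", "v_ser_gly_unlab", "v_gly_use_lab",
               "v_gly_use_unlab", "v_glc_use", "v_ser_use_lab",
               "v_ser_use_unlab"))
    init <- c(Glc_med_lab = 10, Glc_cyt_lab = 0, Glc_cyt_unlab = 5,
              Ser_lab = 0, Ser_unlab = 2, Gly_lab = 0, Gly_unlab = 1.5,
              Sink = 0)
    obs <- setdiff(names(init), "Sink")
    mod <- mass_action_network(rxn, initial = init, observed = obs)
    truth <- log(c(k_uptake = 0.3, k_glc_ser = 0.25, k_ser_gly = 0.35,
                   k_gly_use = 0.2, k_glc_use = 0.15, k_ser_use = 0.1))
    times <- c(0.5, 1, 2, 4, 8, 12)
    pr <- prior_from_ranges(lower = rep(log(0.01), 6), upper = rep(log(10), 6))
  }
  truth <- truth[mod$parameters]
  attr(mod, "beta_true") <- truth
  attr(mod, "default_times") <- times
  attr(mod, "prior") <- pr
  mod
}

#' Parameter-recovery study on simulated data
#'
#' Repeatedly simulates datasets at known true log rate constants, fits the
#' sampler to each, and scores the per-parameter averaged difference between
#' posterior-mean estimate and truth across runs together with its standard
#' error. A parameter is "covered" when the averaged difference lies within
#' 2 standard errors of zero — the unbiasedness summary a replicated
#' simulation design reads off per parameter.
#'
#' @param model A [kinetic_model()].
#' @param beta_true True log rate constants.
#' @param n_runs Number of independent simulated datasets (>= 2).
#' @param m Replicates per dataset.
#' @param times Observation grid.
#' @param noise A [noise_spec()].
#' @param prior A [beta_prior()].
#' @param config A [sampler_config()]; run r uses seed `config$seed + r`.
#' @return A tibble with one row per parameter: `avg_error`, `se`,
#'   `covered` (|avg_error| <= 2 se), `n_ok` (successful fits), plus a
#'   `"runs"` attribute holding the per-run estimates.
#' @export
run_recovery_study <- function(model, beta_true, n_runs = 30, m = 3,
                               times = attr(model, "default_times"),
                               noise = noise_spec(shape = 3, scale = 0.1),
                               prior = attr(model, "prior"),
                               config = sampler_config()) {
  if (n_runs < 2) stop_kb("need n_runs >= 2", "kb_spec_error")
  est <- matrix(NA_real_, n_runs, model$d,
                dimnames = list(NULL, model$parameters))
  failures <- character(0)
  for (r in seq_len(n_runs)) {
    run_seed <- config$seed + r
    res <- tryCatch({
      dat <- simulate_dataset(model, beta_true, times, m = m, noise = noise,
                              seed = run_seed)
      cfg <- config; cfg$seed <- run_seed
      fit <- fit_kinetics(dat, model, prior, cfg)
      colMeans(posterior_draws(fit, "beta"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("run %d: %s", r, conditionMessage(res)))
    } else {
      est[r, ] <- res
    }
  }
  err <- sweep(est, 2L, beta_true)
  out <- tibble::tibble(
    parameter = model$parameters,
    truth = as.numeric(beta_true),
    avg_error = colMeans(err, na.rm = TRUE),
    se = apply(err, 2L, function(x) {
      x <- x[is.finite(x)]
      stats::sd(x) / sqrt(length(x))
    }),
    n_ok = colSums(is.finite(err)))
  out$covered <- abs(out$avg_error) <= 2 * out$se
  attr(out, "runs") <- est
  attr(out, "failures") <- failures
  out
}
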