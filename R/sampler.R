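#' Sampler configuration
#'
#' Settings for the component-wise adaptive Metropolis sampler with delayed
#' rejection inside Gibbs.
#'
#' @param n_iter Total MCMC iterations (full sweeps).
#' @param burn_in Number of initial iterations discarded from summaries.
#' @param l0 Adaptation onset: the proposal covariance stays at `C0` for the
#'   first `l0` iterations and tracks the chain's sample covariance after.
#' @param dr_onset Iteration after which delayed rejection activates.
#' @param gamma Delayed-rejection variance scale for the second-stage
#'   proposal (smaller = more conservative retry).
#' @param s_d Adaptation scale; default `2.4^2 / d` (classic adaptive
#'   Metropolis scaling), resolved at fit time.
#' @param epsilon Covariance regularization ridge.
#' @param C0 Initial proposal covariance matrix; default is
#'   `diag(diag(Lambda)) * 0.1` from the prior, resolved at fit time.
#' @param seed RNG seed; identical seeds give bit-identical chains.
#'
#' @return A list of class `kb_config`.
#' @export
sampler_config <- function(n_iter = 6000, burn_in = 2000, l0 = 1500,
                           dr_onset = 2000, gamma = 0.25, s_d = NULL,
                           epsilon = 1e-6, C0 = NULL, seed = 1L) {
  if (l0 <= 0 || l0 >= n_iter) stop_kb("need 0 < l0 < n_iter", "kb_config_error")
  if (gamma <= 0) stop_kb("gamma must be > 0", "kb_config_error")
  if (epsilon <= 0) stop_kb("epsilon must be > 0", "kb_config_error")
  if (burn_in < 0 || burn_in >= n_iter) {
    stop_kb("need 0 <= burn_in < n_iter", "kb_config_error")
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 l0 = as.integer(l0), dr_onset = as.integer(dr_onset),
                 gamma = gamma, s_d = s_d, epsilon = epsilon, C0 = C0,
                 seed = as.integer(seed)),
            class = "kb_config")
}

#' Conditional proposal variance (Schur complement)
#'
#' The scalar proposal variance for component i given the joint proposal
#' covariance C: \eqn{D_i = C_{ii} - C_{i,-i} C_{-i,-i}^{-1} C_{-i,i}},
#' the conditional variance of component i under a N(0, C) draw.
#'
#' @param C Symmetric positive-definite matrix.
#' @param i Component index.
#' @return A strictly positive scalar.
#' @export
conditional_proposal_variance <- function(C, i) {
  d <- nrow(C)
  if (d == 1L) return(C[1, 1])
  Cmm <- C[-i, -i, drop = FALSE]
  cross <- tryCatch(solve(Cmm, C[-i, i]),
                    error = function(e) stop_kb(
                      "singular conditioning block in proposal covariance",
                      "kb_decomposition_error"))
  D <- C[i, i] - sum(C[i, -i] * cross)
  if (!is.finite(D) || D <= 0) {
    stop_kb("conditional proposal variance not positive", "kb_decomposition_error")
  }
  D
}

#' Adaptive proposal covariance
#'
#' Returns the initial covariance `C0` while `l <= l0`, and afterwards the
#' regularized scaled sample covariance
#' \eqn{s_d\, \mathrm{cov}(\beta^1,\dots,\beta^l) + s_d \epsilon I_d} of the
#' chain history.
#'
#' @param history Numeric matrix of past draws, one row per iteration.
#' @param l Current iteration count (rows of `history` in use).
#' @param config A [sampler_config()] with resolved `s_d` and `C0`.
#' @return A symmetric positive-definite d x d matrix.
#' @export
update_adaptation_covariance <- function(history, l, config) {
  if (l <= config$l0) return(config$C0)
  if (l < 2L) stop_kb("need at least 2 draws to adapt", "kb_insufficient_history_error")
  h <- history[seq_len(l), , drop = FALSE]
  d <- ncol(h)
  config$s_d * stats::cov(h) + config$s_d * config$epsilon * diag(d)
}

#' One component-wise Metropolis update with delayed rejection
#'
#' Stage 1 proposes \eqn{\beta_i^* \sim N(\beta_i, D_i)} and accepts with
#' the usual Metropolis probability. On rejection (and when `dr` is TRUE), a
#' second proposal \eqn{\beta_i^{**} \sim N(\beta_i, \gamma D_i)} is drawn
#' and accepted with the two-stage delayed-rejection probability in Mira's
#' form, which preserves reversibility:
#' \deqn{\alpha_2 = \min\{1,
#'   \frac{\pi(\beta^{**})\, q_1(\beta^*|\beta^{**})\, [1-\alpha_1(\beta^{**},\beta^*)]}
#'        {\pi(\beta)\, q_1(\beta^*|\beta)\, [1-\alpha_1(\beta,\beta^*)]}\}.}
#' The stage-1 proposal densities \eqn{q_1} appear on both sides at
#' different distances and are kept explicitly (they do not cancel).
#'
#' @param beta Current full parameter vector.
#' @param i Component being updated.
#' @param log_target Function of the full vector returning the log target
#'   density (may be `-Inf`; `NaN` is an error).
#' @param D_i Stage-1 proposal variance (> 0).
#' @param gamma Second-stage variance scale.
#' @param lp_current Optional cached `log_target(beta)`.
#' @param dr Attempt the delayed-rejection stage on a stage-1 rejection?
#'
#' @return A list with `beta` (retained vector), `lp` (its log target),
#'   `stage` (0 = no move, 1 or 2 = accepting stage), and `stage2_tried`.
#' @export
dr_metropolis_update <- function(beta, i, log_target, D_i, gamma,
                                 lp_current = NULL, dr = TRUE) {
  if (!is.finite(D_i) || D_i <= 0) stop_kb("D_i must be > 0", "kb_config_error")
  lp_cur <- lp_current %||% log_target(beta)
  if (is.nan(lp_cur) || lp_cur == -Inf) {
    stop_kb("log_target(current) must be finite", "kb_target_error")
  }
  sd1 <- sqrt(D_i)
  cand <- beta
  cand[i] <- stats::rnorm(1L, beta[i], sd1)
  lp1 <- log_target(cand)
  if (is.nan(lp1)) stop_kb("log_target returned NaN", "kb_target_error")
  la1 <- min(0, lp1 - lp_cur)
  if (log(stats::runif(1L)) < la1) {
    return(list(beta = cand, lp = lp1, stage = 1L, stage2_tried = FALSE))
  }
  if (!dr) return(list(beta = beta, lp = lp_cur, stage = 0L, stage2_tried = FALSE))
  cand2 <- beta
  cand2[i] <- stats::rnorm(1L, beta[i], sqrt(gamma * D_i))
  lp2 <- log_target(cand2)
  if (is.nan(lp2)) stop_kb("log_target returned NaN", "kb_target_error")
  if (lp2 > -Inf) {
    la1_zy <- min(0, lp1 - lp2)                      # alpha_1(beta**, beta*)
    lnum <- lp2 + stats::dnorm(cand[i], cand2[i], sd1, log = TRUE) + log1mexp(la1_zy)
    lden <- lp_cur + stats::dnorm(cand[i], beta[i], sd1, log = TRUE) + log1mexp(la1)
    la2 <- min(0, lnum - lden)
    if (is.finite(la2) && log(stats::runif(1L)) < la2) {
      return(list(beta = cand2, lp = lp2, stage = 2L, stage2_tried = TRUE))
    }
  }
  list(beta = beta, lp = lp_cur, stage = 0L, stage2_tried = TRUE)
}

# Shared AM + DR Gibbs engine.
#
# eval_fun(theta, i) -> list(lp = numeric scalar, aux = anything); i is the
#   component just perturbed (0 on initialization), so implementations can
#   reuse cached work for unaffected blocks.
# after_sweep(cur) -> cur; may mutate closure state (e.g. draw sigma2) and
#   must refresh cur$lp to the new conditional target for theta.
# record_extra(cur) -> named numeric vector stored per iteration.
#
# Adaptation uses the running mean/SSQ recursion over all past sweeps
# (mathematically identical to recomputing cov(theta^1..theta^l)); the
# covariance in force is frozen at the start of each sweep.
dram_engine <- function(eval_fun, init, config, after_sweep = NULL,
                        record_extra = NULL) {
  d <- length(init)
  n_iter <- config$n_iter
  s_d <- config$s_d %||% (2.4^2 / d)
  C0 <- config$C0 %||% diag(rep(0.1, d), d)
  eps <- config$epsilon
  gamma <- config$gamma

  cur <- eval_fun(init, 0L)
  if (!is.finite(cur$lp)) {
    stop_kb("initial point has non-finite log target", "kb_target_error")
  }
  cur$theta <- init

  draws <- matrix(NA_real_, n_iter, d)
  lp_trace <- numeric(n_iter)
  extra <- NULL
  acc1 <- acc2 <- prop2 <- integer(d)
  prop1 <- integer(d)

  # running first/second moments of theta^1..theta^l for adaptation
  run_n <- 0L
  run_mean <- numeric(d)
  run_M2 <- matrix(0, d, d)
  consec_stuck <- 0L
  warned_stuck <- FALSE

  for (l in seq_len(n_iter)) {
    if (l - 1L <= config$l0 || run_n < 2L) {
      C <- C0
    } else {
      C <- s_d * run_M2 / (run_n - 1L) + s_d * eps * diag(d)
    }
    Dvec <- if (d == 1L) C[1, 1] else {
      vapply(seq_len(d), function(i) conditional_proposal_variance(C, i),
             numeric(1))
    }
    dr_active <- l > config$dr_onset
    moved <- FALSE

    for (i in seq_len(d)) {
      prop1[i] <- prop1[i] + 1L
      sd1 <- sqrt(Dvec[i])
      cand_theta <- cur$theta
      cand_theta[i] <- stats::rnorm(1L, cur$theta[i], sd1)
      cand <- eval_fun(cand_theta, i)
      la1 <- min(0, cand$lp - cur$lp)
      if (la1 > -Inf && log(stats::runif(1L)) < la1) {
        cand$theta <- cand_theta
        cur <- cand
        acc1[i] <- acc1[i] + 1L
        moved <- TRUE
        next
      }
      if (!dr_active) next
      prop2[i] <- prop2[i] + 1L
      cand2_theta <- cur$theta
      cand2_theta[i] <- stats::rnorm(1L, cur$theta[i], sqrt(gamma * Dvec[i]))
      cand2 <- eval_fun(cand2_theta, i)
      if (cand2$lp == -Inf) next
      la1_zy <- min(0, cand$lp - cand2$lp)
      lnum <- cand2$lp +
        stats::dnorm(cand_theta[i], cand2_theta[i], sd1, log = TRUE) +
        log1mexp(la1_zy)
      lden <- cur$lp +
        stats::dnorm(cand_theta[i], cur$theta[i], sd1, log = TRUE) +
        log1mexp(la1)
      la2 <- min(0, lnum - lden)
      if (is.finite(la2) && log(stats::runif(1L)) < la2) {
        cand2$theta <- cand2_theta
        cur <- cand2
        acc2[i] <- acc2[i] + 1L
        moved <- TRUE
      }
    }

    if (!is.null(after_sweep)) cur <- after_sweep(cur)

    draws[l, ] <- cur$theta
    lp_trace[l] <- cur$lp_full %||% cur$lp
    if (!is.null(record_extra)) {
      row <- record_extra(cur)
      if (is.null(extra)) {
        extra <- matrix(NA_real_, n_iter, length(row),
                        dimnames = list(NULL, names(row)))
      }
      extra[l, ] <- row
    }

    run_n <- run_n + 1L
    delta <- cur$theta - run_mean
    run_mean <- run_mean + delta / run_n
    run_M2 <- run_M2 + tcrossprod(delta, cur$theta - run_mean)

    consec_stuck <- if (moved) 0L else consec_stuck + 1L
    if (consec_stuck >= 1000L && !warned_stuck) {
      warning("sampler appears stuck: 1000 consecutive sweeps without an accepted move",
              call. = FALSE)
      warned_stuck <- TRUE
    }
  }

  list(draws = draws, lp_trace = lp_trace, extra = extra,
       acceptance = tibble::tibble(
         component = seq_len(d),
         proposals = prop1, stage1_accepts = acc1,
         stage2_proposals = prop2, stage2_accepts = acc2,
         rejections = prop1 - acc1 - acc2))
}

#' Sample an arbitrary log target with the AM + DR kernel
#'
#' Runs the same component-wise adaptive Metropolis / delayed rejection
#' machinery used for kinetic-model posteriors against a user-supplied log
#' density — useful for validating the kernel on targets with known moments.
#'
#' @param log_target Function of a numeric vector returning a log density.
#' @param init Starting point (finite log target).
#' @param config A [sampler_config()].
#' @param lower,upper Optional box; proposals outside are rejected via a
#'   `-Inf` target.
#' @return A list with `draws` (n_iter x d matrix), `lp_trace`,
#'   `acceptance`, and the `config` used.
#' @export
dram_sample <- function(log_target, init, config = sampler_config(),
                        lower = -Inf, upper = Inf) {
  d <- length(init)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  eval_fun <- function(theta, i) {
    if (any(theta < lower | theta > upper)) return(list(lp = -Inf))
    lp <- log_target(theta)
    if (is.nan(lp)) stop_kb("log_target returned NaN", "kb_target_error")
    list(lp = lp)
  }
  set.seed(config$seed)
  out <- dram_engine(eval_fun, init, config)
  out$config <- config
  out
}
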