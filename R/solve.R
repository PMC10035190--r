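#' Solve mean isotopomer trajectories
#'
#' Integrates the model's ODE system from its initial state with rate
#' constants `exp(beta)` and returns the mean concentrations \eqn{\mu_t} at
#' the requested times.
#'
#' Fully first-order mass-action networks are solved exactly through the
#' eigendecomposition of the rate matrix; all other models use the
#' stiff-capable adaptive integrator [deSolve::lsoda()]. States that come out
#' negative by no more than `atol` (numerical round-off) are clipped to zero;
#' larger negative excursions raise a model-misspecification error.
#'
#' @param model A [kinetic_model()].
#' @param beta Numeric vector of log rate constants (length `model$d`).
#' @param times Strictly increasing numeric vector of times (>= 0).
#' @param solver `"auto"` (analytic for linear networks, `lsoda` otherwise),
#'   `"analytic"`, or `"lsoda"`.
#' @param rtol,atol Relative/absolute integrator tolerances.
#'
#' @return A tibble with a `time` column and one column per state.
#' @export
#' @examples
#' mod <- exemplar_network("decay2")
#' solve_trajectories(mod, beta = log(c(0.4, 0.15)), times = c(1, 2, 4))
solve_trajectories <- function(model, beta, times,
                               solver = c("auto", "analytic", "lsoda"),
                               rtol = 1e-6, atol = 1e-9) {
  solver <- match.arg(solver)
  mu <- solve_mu(model, beta, times, solver = solver, rtol = rtol, atol = atol)
  tibble::as_tibble(as.data.frame(mu)) |>
    dplyr::mutate(time = times, .before = 1L)
}

# hot-path solver returning a plain [T x n_state] matrix with state colnames
solve_mu <- function(model, beta, times, solver = "auto",
                     rtol = 1e-6, atol = 1e-9) {
  if (length(beta) != model$d || any(!is.finite(beta))) {
    stop_kb("`beta` must be finite and of length model$d", "kb_shape_error")
  }
  if (length(times) < 1L || any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop_kb("`times` must be strictly increasing and >= 0", "kb_spec_error")
  }
  k <- exp(beta)
  mu <- NULL
  if (solver == "analytic" || (solver == "auto" && model$linear)) {
    mu <- solve_mu_linear(model, k, times)
    if (is.null(mu) && solver == "analytic") {
      stop_kb("analytic solver requires a first-order mass-action network",
              "kb_spec_error")
    }
  }
  if (is.null(mu)) {
    mu <- solve_mu_lsoda(model, k, times, rtol = rtol, atol = atol)
  }
  neg <- min(mu)
  if (neg < -1e3 * atol) {
    stop_kb(sprintf("state went negative (%.3e) beyond tolerance: model misspecification", neg),
            "kb_model_misspecification_error")
  }
  mu[mu < 0] <- 0
  dimnames(mu) <- list(NULL, model$states)
  mu
}

# exact solution of dmu/dt = A mu via eigendecomposition;
# returns NULL when the network is not linear or A is numerically defective
solve_mu_linear <- function(model, k, times) {
  if (!model$linear) return(NULL)
  A <- rate_matrix(model, k)
  eg <- eigen(A)
  w <- tryCatch(solve(eg$vectors, model$initial), error = function(e) NULL)
  if (is.null(w)) return(NULL)
  # defective (repeated-eigenvalue) matrices make V ill-conditioned
  if (max(Mod(w)) > 1e10 * max(1, max(model$initial))) return(NULL)
  E <- exp(outer(eg$values, times))         # n_state x T
  mu <- t(Re(eg$vectors %*% (w * E)))
  mu
}

solve_mu_lsoda <- function(model, k, times, rtol, atol) {
  rhs <- model$rhs
  derivs <- function(t, y, parms) list(rhs(y, parms, t))
  t_solve <- times
  prepend <- times[1] > 0
  if (prepend) t_solve <- c(0, times)
  out <- tryCatch(
    deSolve::ode(y = model$initial, times = t_solve, func = derivs,
                 parms = k, method = "lsoda", rtol = rtol, atol = atol),
    warning = function(w) {
      stop_kb(paste0("ODE integration failed: ", conditionMessage(w)),
              "kb_integration_error")
    },
    error = function(e) {
      stop_kb(paste0("ODE integration failed: ", conditionMessage(e)),
              "kb_integration_error")
    }
  )
  if (nrow(out) < length(t_solve)) {
    stop_kb(sprintf("ODE integration failed at time %.4g", out[nrow(out), 1]),
            "kb_integration_error")
  }
  mu <- unname(out[, -1, drop = FALSE])
  if (prepend) mu <- mu[-1, , drop = FALSE]
  mu
}

# log of mu at observed states; domain error when an observed mean
# concentration is too small for the log-normal likelihood
solve_obs_logmu <- function(model, beta, times, solver = "auto") {
  mu <- solve_mu(model, beta, times, solver = solver)
  muo <- mu[, model$observed_idx, drop = FALSE]
  if (any(muo < 1e-300)) {
    stop_kb("observed mean concentration is <= 0; log-likelihood undefined",
            "kb_domain_error")
  }
  log(muo)
}
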