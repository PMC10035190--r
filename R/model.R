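#' Specify a kinetic ODE model
#'
#' A kinetic model describes how mean isotopomer concentrations
#' \eqn{\mu(t)} evolve: \eqn{d\mu/dt = f(\mu; \exp(\beta), t)}, where
#' \eqn{\beta} is the vector of log rate constants. The right-hand side can
#' be given either as an arbitrary R function or, for mass-action networks,
#' declaratively through [mass_action_network()].
#'
#' @param states Character vector of state (isotopomer) names.
#' @param initial Named numeric vector of nonnegative initial concentrations;
#'   names must match `states` (missing states default to 0).
#' @param parameters Character vector of unique log-rate-constant names; the
#'   order defines the order of `beta` everywhere in the package.
#' @param rhs Function `(mu, k, t)` returning the time derivative of `mu`,
#'   where `k = exp(beta)` is the named vector of rate constants. Omit when
#'   `reactions` is supplied.
#' @param reactions Optional data frame of mass-action reactions (see
#'   [mass_action_network()]); used to build `rhs` and per-reaction fluxes.
#' @param observed Character vector of states that are measured. Defaults to
#'   all states.
#' @param fluxes Named list of flux definitions. Each element is either a
#'   function `(mu, k, t)` returning a scalar flux, or the name of a reaction
#'   (for mass-action models), whose instantaneous rate is used.
#'
#' @return An object of class `kb_model`.
#' @seealso [mass_action_network()], [exemplar_network()],
#'   [solve_trajectories()]
#' @export
kinetic_model <- function(states, initial, parameters, rhs = NULL,
                          reactions = NULL, observed = states,
                          fluxes = list()) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop_kb("state names must be unique", "kb_spec_error")
  if (anyDuplicated(parameters)) {
    stop_kb("parameter names must be unique", "kb_spec_error")
  }
  init <- stats::setNames(numeric(length(states)), states)
  if (is.null(names(initial))) {
    if (length(initial) != length(states)) {
      stop_kb("unnamed `initial` must have one value per state", "kb_spec_error")
    }
    init[] <- as.numeric(initial)
  } else {
    unknown <- setdiff(names(initial), states)
    if (length(unknown)) {
      stop_kb(paste0("initial values for unknown states: ",
                     paste(unknown, collapse = ", ")), "kb_spec_error")
    }
    init[names(initial)] <- as.numeric(initial)
  }
  if (any(init < 0)) stop_kb("initial concentrations must be >= 0", "kb_spec_error")
  if (!all(observed %in% states)) {
    stop_kb("`observed` must be a subset of `states`", "kb_spec_error")
  }
  if (anyDuplicated(observed)) stop_kb("`observed` must be unique", "kb_spec_error")

  parsed <- NULL
  linear <- FALSE
  if (!is.null(reactions)) {
    parsed <- parse_reactions(reactions, states, parameters)
    linear <- all(vapply(parsed, function(r) {
      length(r$sub_idx) == 1L && all(r$sub_coef == 1)
    }, logical(1)))
    rhs <- make_mass_action_rhs(parsed, length(states))
  }
  if (is.null(rhs)) {
    stop_kb("supply either `rhs` or `reactions`", "kb_spec_error")
  }

  flux_funs <- resolve_fluxes(fluxes, parsed, states)

  model <- structure(list(
    states = states, n_state = length(states), initial = init,
    parameters = as.character(parameters), d = length(parameters),
    observed = as.character(observed),
    observed_idx = match(observed, states),
    reactions = parsed, linear = linear,
    rhs = rhs, fluxes = flux_funs
  ), class = "kb_model")

  # sanity-check the rhs dimension at the initial state
  k0 <- stats::setNames(rep(1, model$d), model$parameters)
  dmu <- model$rhs(init, k0, 0)
  if (length(dmu) != model$n_state) {
    stop_kb("rhs must return one derivative per state", "kb_spec_error")
  }
  model
}

#' Build a mass-action kinetic model from a reaction table
#'
#' Each row is one elementary reaction with rate
#' \eqn{k \prod_s \mu_s^{c_s}} over its substrates. Substrates and products
#' are written as e.g. `"A"`, `"A + B"`, or `"2 A"`; an empty/`NA` product
#' means efflux out of the modeled system. Several reactions may share one
#' rate-constant parameter (e.g. a labeled and an unlabeled species
#' converted by the same enzyme).
#'
#' @param reactions Data frame with columns `from`, `to`, `param` and
#'   optionally `name` (defaults to `"v_<param>_<row>"`).
#' @param initial Named numeric vector of initial concentrations.
#' @param observed Character vector of measured states; defaults to all
#'   states appearing in the reactions.
#' @param fluxes Named list of flux definitions passed on to
#'   [kinetic_model()]; reaction names may be used directly. By default every
#'   reaction's rate is registered as a flux under the reaction's name.
#'
#' @return A `kb_model`.
#' @export
#' @examples
#' rxn <- data.frame(from = c("A", "B"), to = c("B", NA),
#'                   param = c("k1", "k2"))
#' mod <- mass_action_network(rxn, initial = c(A = 1, B = 0))
mass_action_network <- function(reactions, initial, observed = NULL,
                                fluxes = NULL) {
  reactions <- as.data.frame(reactions)
  species <- unique(unlist(lapply(seq_len(nrow(reactions)), function(r) {
    c(parse_species(reactions$from[r])$name,
      parse_species(reactions$to[r])$name)
  })))
  states <- union(names(initial), species)
  params <- unique(as.character(reactions$param))
  if (is.null(reactions$name)) {
    reactions$name <- paste0("v_", reactions$param, "_", seq_len(nrow(reactions)))
  }
  if (is.null(fluxes)) {
    fluxes <- stats::setNames(as.list(reactions$name), reactions$name)
  }
  kinetic_model(states = states, initial = initial, parameters = params,
                reactions = reactions,
                observed = observed %||% states, fluxes = fluxes)
}

# "2 A + B" -> list(name = c("A","B"), coef = c(2,1)); NA/"" -> empty
parse_species <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(list(name = character(), coef = numeric()))
  }
  terms <- strsplit(x, "+", fixed = TRUE)[[1]]
  nm <- character(length(terms)); cf <- numeric(length(terms))
  for (ii in seq_along(terms)) {
    tok <- strsplit(trimws(terms[ii]), "[ *]+")[[1]]
    if (length(tok) == 2L && !is.na(suppressWarnings(as.numeric(tok[1])))) {
      cf[ii] <- as.numeric(tok[1]); nm[ii] <- tok[2]
    } else {
      cf[ii] <- 1; nm[ii] <- paste(tok, collapse = "")
    }
  }
  list(name = nm, coef = cf)
}

parse_reactions <- function(reactions, states, parameters) {
  reactions <- as.data.frame(reactions)
  needed <- c("from", "to", "param")
  if (!all(needed %in% names(reactions))) {
    stop_kb("reaction table needs columns from, to, param", "kb_spec_error")
  }
  if (is.null(reactions$name)) {
    reactions$name <- paste0("v_", reactions$param, "_", seq_len(nrow(reactions)))
  }
  lapply(seq_len(nrow(reactions)), function(r) {
    sub <- parse_species(reactions$from[r])
    prod <- parse_species(reactions$to[r])
    if (!length(sub$name)) {
      stop_kb("each reaction needs at least one substrate", "kb_spec_error")
    }
    bad <- setdiff(c(sub$name, prod$name), states)
    if (length(bad)) {
      stop_kb(paste0("unknown species in reactions: ",
                     paste(bad, collapse = ", ")), "kb_spec_error")
    }
    pi <- match(as.character(reactions$param[r]), parameters)
    if (is.na(pi)) {
      stop_kb(paste0("reaction parameter not declared: ", reactions$param[r]),
              "kb_spec_error")
    }
    list(name = as.character(reactions$name[r]),
         sub_idx = match(sub$name, states), sub_coef = sub$coef,
         prod_idx = match(prod$name, states), prod_coef = prod$coef,
         param_idx = pi)
  })
}

make_mass_action_rhs <- function(parsed, n_state) {
  force(parsed); force(n_state)
  function(mu, k, t) {
    dmu <- numeric(n_state)
    for (r in parsed) {
      rate <- k[[r$param_idx]] * prod(mu[r$sub_idx]^r$sub_coef)
      dmu[r$sub_idx] <- dmu[r$sub_idx] - r$sub_coef * rate
      if (length(r$prod_idx)) {
        dmu[r$prod_idx] <- dmu[r$prod_idx] + r$prod_coef * rate
      }
    }
    dmu
  }
}

resolve_fluxes <- function(fluxes, parsed, states) {
  if (!length(fluxes)) return(list())
  if (is.null(names(fluxes)) || any(!nzchar(names(fluxes)))) {
    stop_kb("`fluxes` must be a named list", "kb_spec_error")
  }
  rxn_names <- vapply(parsed %||% list(), function(r) r$name, character(1))
  lapply(fluxes, function(fl) {
    if (is.function(fl)) return(fl)
    r <- parsed[[match(as.character(fl), rxn_names)]]
    if (is.null(r)) {
      stop_kb(paste0("flux refers to unknown reaction: ", fl), "kb_flux_error")
    }
    function(mu, k, t) k[[r$param_idx]] * prod(mu[r$sub_idx]^r$sub_coef)
  })
}

# dense rate matrix A(k) for an all-first-order network: dmu/dt = A mu
rate_matrix <- function(model, k) {
  A <- matrix(0, model$n_state, model$n_state)
  for (r in model$reactions) {
    i <- r$sub_idx
    A[i, i] <- A[i, i] - k[[r$param_idx]]
    if (length(r$prod_idx)) {
      A[r$prod_idx, i] <- A[r$prod_idx, i] + r$prod_coef * k[[r$param_idx]]
    }
  }
  A
}

#' @export
print.kb_model <- function(x, ...) {
  cat("<kb_model> ", x$n_state, " states, ", x$d, " parameters",
      if (x$linear) " (linear mass-action)" else "", "\n", sep = "")
  cat("  states:   ", paste(x$states, collapse = ", "), "\n", sep = "")
  cat("  observed: ", paste(x$observed, collapse = ", "), "\n", sep = "")
  cat("  params:   ", paste(x$parameters, collapse = ", "), "\n", sep = "")
  if (length(x$fluxes)) {
    cat("  fluxes:   ", paste(names(x$fluxes), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
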