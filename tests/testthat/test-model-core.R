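test_that("trajectories solve known systems exactly", {
  # constant system: every row equals the initial state
  still <- kinetic_model(states = c("A", "B"), initial = c(A = 2, B = 3),
                         parameters = "k",
                         rhs = function(mu, k, t) c(0, 0))
  tr <- solve_trajectories(still, beta = 0.7, times = c(1, 5, 9))
  expect_equal(tr$A, rep(2, 3))
  expect_equal(tr$B, rep(3, 3))

  # first-order decay, beta = 0 (k = 1): mu(1) = exp(-1)
  dec <- mass_action_network(
    data.frame(from = "A", to = NA, param = "k"), initial = c(A = 1))
  tr <- solve_trajectories(dec, beta = 0, times = 1)
  expect_equal(tr$A, exp(-1), tolerance = 1e-6)

  # two-pool A -> B, k = 0.5, t = 2: A = exp(-1), B = 1 - exp(-1)
  ab <- mass_action_network(
    data.frame(from = "A", to = "B", param = "k"), initial = c(A = 1, B = 0))
  tr <- solve_trajectories(ab, beta = log(0.5), times = 2)
  expect_equal(tr$A, exp(-1), tolerance = 1e-6)
  expect_equal(tr$B, 1 - exp(-1), tolerance = 1e-6)

  # numerical path agrees with both the closed form and the analytic path
  tr_num <- solve_trajectories(ab, beta = log(0.5), times = 2, solver = "lsoda")
  expect_equal(tr_num$A, exp(-1), tolerance = 1e-5)
})

test_that("tightening solver tolerances changes results by less than the looser tolerance", {
  mod <- exemplar_network("pool3_mini")
  bt <- attr(mod, "beta_true")
  tms <- attr(mod, "default_times")
  loose <- kineticbayes:::solve_mu(mod, bt, tms, solver = "lsoda",
                                   rtol = 1e-6, atol = 1e-9)
  tight <- kineticbayes:::solve_mu(mod, bt, tms, solver = "lsoda",
                                   rtol = 1e-7, atol = 1e-10)
  expect_lt(max(abs(loose - tight)), 1e-6 * max(loose))
  # and the analytic solution is inside the loose tolerance too
  exact <- kineticbayes:::solve_mu(mod, bt, tms, solver = "analytic")
  expect_lt(max(abs(loose - exact)), 1e-5)
})

test_that("closed mass-action networks conserve total mass", {
  mod <- exemplar_network("pool3_mini")
  tr <- kineticbayes:::solve_mu(mod, attr(mod, "beta_true"),
                                seq(0.5, 20, by = 0.5))
  totals <- rowSums(tr)
  expect_equal(totals, rep(sum(mod$initial), length(totals)), tolerance = 1e-8)
})

test_that("solver input validation and misspecification errors fire", {
  mod <- decay2_model()
  expect_error(solve_trajectories(mod, beta = c(0, NA), times = 1),
               class = "kb_shape_error")
  expect_error(solve_trajectories(mod, beta = c(0, 0), times = c(2, 1)),
               class = "kb_spec_error")
  # rhs pushing a state strongly negative is a model misspecification
  bad <- kinetic_model(states = "A", initial = c(A = 1), parameters = "k",
                       rhs = function(mu, k, t) -1)
  expect_error(solve_trajectories(bad, beta = 0, times = 5),
               class = "kb_model_misspecification_error")
})

test_that("log-likelihood matches hand values and a brute-force oracle", {
  # zero residuals with unit variances: exactly 0
  mod <- decay2_model()
  dat0 <- decay2_data(sigma2 = 1e-22, seed = 5)
  expect_equal(log_likelihood(dat0, mod, attr(mod, "beta_true"), c(1, 1)), 0,
               tolerance = 1e-12)

  # single-cell hand evaluation of the formula engine:
  # log-determinant term 0 when sigma2 = 1, quadratic -0.5 * 2^2 = -2
  expect_equal(kineticbayes:::ll_from_rss(rss = 4, sigma2 = 1, m = 1, Tn = 1),
               -2)

  # arbitrary instance equals an independently coded triple loop
  dat <- decay2_data(seed = 11)
  beta <- attr(mod, "beta_true") + c(0.1, -0.2)
  sigma2 <- c(0.05, 0.08)
  tms <- sort(unique(dat$time))
  logmu <- log(kineticbayes:::solve_mu(mod, beta, tms)[, mod$observed_idx])
  expect_equal(log_likelihood(dat, mod, beta, sigma2),
               loglik_bruteforce(dat, logmu, sigma2, mod$observed, tms),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("log-likelihood rejects invalid variances and shapes", {
  mod <- decay2_model()
  dat <- decay2_data()
  expect_error(log_likelihood(dat, mod, attr(mod, "beta_true"), c(1, -1)),
               class = "kb_domain_error")
  expect_error(log_likelihood(dat, mod, attr(mod, "beta_true"), c(1, 1, 1)),
               class = "kb_shape_error")
})

test_that("log-posterior decomposes into likelihood plus the two priors", {
  mod <- decay2_model()
  dat <- decay2_data(seed = 13)
  prior <- attr(mod, "prior")
  hyper <- estimate_shrinkage(dat)
  beta <- attr(mod, "beta_true")
  sigma2 <- c(0.03, 0.06)

  # outside the truncation box
  expect_identical(
    log_posterior(dat, mod, prior$zeta_u + 1, sigma2, prior, hyper), -Inf)

  # at beta = xi the beta-penalty contributes exactly 0
  lp_xi <- log_posterior(dat, mod, prior$xi, sigma2, prior, hyper)
  ll_xi <- log_likelihood(dat, mod, prior$xi, sigma2)
  ig <- sum((-hyper$alpha_star - 1) * log(sigma2) - hyper$kappa_star / sigma2)
  expect_equal(lp_xi, ll_xi + ig, tolerance = 1e-10)

  # random instance: term-by-term oracle
  lp <- log_posterior(dat, mod, beta, sigma2, prior, hyper)
  z <- beta - prior$xi
  quad <- -0.5 * as.numeric(t(z) %*% solve(prior$Lambda) %*% z)
  expect_equal(lp,
               log_likelihood(dat, mod, beta, sigma2) + quad + ig,
               tolerance = 1e-10)
})

test_that("posterior-minus-likelihood depends on the data only through the priors", {
  mod <- decay2_model()
  prior <- attr(mod, "prior")
  beta <- attr(mod, "beta_true")
  sigma2 <- c(0.04, 0.05)
  datA <- decay2_data(seed = 21)
  datB <- decay2_data(seed = 22)
  hyper <- shrinkage_from_variances(c(0.02, 0.05, 0.03, 0.08))
  dA <- log_posterior(datA, mod, beta, sigma2, prior, hyper) -
    log_likelihood(datA, mod, beta, sigma2)
  dB <- log_posterior(datB, mod, beta, sigma2, prior, hyper) -
    log_likelihood(datB, mod, beta, sigma2)
  expect_equal(dA, dB, tolerance = 1e-10)
})

test_that("flux trajectories honor closed forms and bracket their mean", {
  dec <- mass_action_network(
    data.frame(from = "A", to = NA, param = "k", name = "v_out"),
    initial = c(A = 1))

  # single draw k = 1: flux at t = 0 is k * A0 = 1
  f1 <- flux_trajectory(fake_fit(dec, 0), "v_out", times = c(0, 1))
  expect_equal(f1$mean[1], 1, tolerance = 1e-6)
  expect_equal(f1$mean[2], exp(-1), tolerance = 1e-6)

  # degenerate chain: bounds collapse onto the mean
  fd <- flux_trajectory(fake_fit(dec, rep(log(0.5), 200)), "v_out",
                        times = c(0.5, 1, 2))
  expect_equal(fd$lower, fd$mean)
  expect_equal(fd$upper, fd$mean)

  # spread-out chain: bounds bracket the mean pointwise
  fs <- flux_trajectory(fake_fit(dec, rnorm(300, log(0.5), 0.2)), "v_out",
                        times = c(0.5, 1, 2, 4))
  expect_true(all(fs$lower <= fs$mean & fs$mean <= fs$upper))

  expect_error(flux_trajectory(fake_fit(dec, 0), "nope", times = 1),
               class = "kb_flux_error")
})

test_that("model constructor enforces its invariants", {
  expect_error(kinetic_model(states = c("A", "A"), initial = c(A = 1),
                             parameters = "k", rhs = function(mu, k, t) 0),
               class = "kb_spec_error")
  expect_error(kinetic_model(states = "A", initial = c(A = -1),
                             parameters = "k", rhs = function(mu, k, t) 0),
               class = "kb_spec_error")
  expect_error(kinetic_model(states = "A", initial = c(A = 1),
                             parameters = c("k", "k"),
                             rhs = function(mu, k, t) 0),
               class = "kb_spec_error")
  expect_error(kinetic_model(states = "A", initial = c(A = 1),
                             parameters = "k", observed = "Z",
                             rhs = function(mu, k, t) 0),
               class = "kb_spec_error")
  # rhs of the wrong dimension
  expect_error(kinetic_model(states = c("A", "B"), initial = c(A = 1, B = 1),
                             parameters = "k", rhs = function(mu, k, t) 0),
               class = "kb_spec_error")
})
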