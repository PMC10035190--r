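test_that("conditional proposal variance is the Schur complement", {
  C <- diag(c(2, 3, 4))
  expect_equal(conditional_proposal_variance(C, 2), 3)
  C2 <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(conditional_proposal_variance(C2, 1), 1.5)
  expect_equal(conditional_proposal_variance(matrix(7), 1), 7)

  # equals the conditional variance of a multivariate normal, any i
  set.seed(5)
  A <- matrix(rnorm(16), 4)
  C4 <- crossprod(A) + diag(4)
  for (i in 1:4) {
    D <- conditional_proposal_variance(C4, i)
    expect_gt(D, 0)
    expect_equal(D, C4[i, i] - C4[i, -i] %*% solve(C4[-i, -i]) %*% C4[-i, i],
                 ignore_attr = TRUE)
  }
  expect_error(conditional_proposal_variance(matrix(c(1, 1, 1, 1), 2), 1),
               class = "kb_decomposition_error")
})

test_that("adaptation covariance switches from C0 to scaled sample covariance", {
  cfg <- sampler_config(n_iter = 100, burn_in = 10, l0 = 20, dr_onset = 30,
                        s_d = 2.88, epsilon = 1e-6,
                        C0 = diag(c(0.5, 0.5)))
  hist <- matrix(rnorm(200), 100, 2)
  expect_identical(update_adaptation_covariance(hist, 15, cfg), cfg$C0)
  C <- update_adaptation_covariance(hist, 60, cfg)
  expect_equal(C, 2.88 * cov(hist[1:60, ]) + 2.88 * 1e-6 * diag(2))
  # constant history: only the ridge remains
  Cc <- update_adaptation_covariance(matrix(1, 50, 2), 50, cfg)
  expect_equal(Cc, 2.88 * 1e-6 * diag(2))
  expect_error(update_adaptation_covariance(hist, 1,
                                            sampler_config(n_iter = 10, l0 = 0.5,
                                                           burn_in = 1,
                                                           dr_onset = 2)),
               class = "kb_insufficient_history_error")
})

test_that("the delayed-rejection update behaves at its edge cases", {
  # flat target: stage-1 acceptance probability is 1
  set.seed(1)
  for (r in 1:10) {
    res <- dr_metropolis_update(c(0), 1, function(b) 0, D_i = 1, gamma = 0.25)
    expect_identical(res$stage, 1L)
  }
  # stage-1 proposal falling outside the support triggers the second stage
  wall <- function(b) if (abs(b) > 0.01) -Inf else 0
  set.seed(2)
  tried2 <- vapply(1:50, function(r) {
    dr_metropolis_update(c(0), 1, wall, D_i = 100, gamma = 1e-6)$stage2_tried
  }, logical(1))
  expect_true(all(tried2))
  # NaN target is an error distinct from -Inf
  expect_error(dr_metropolis_update(c(0), 1, function(b) NaN, 1, 0.25),
               class = "kb_target_error")
})

test_that("the DR kernel preserves a 1-D standard normal", {
  cfg <- sampler_config(n_iter = 1e5, burn_in = 1e4, l0 = 500, dr_onset = 1000,
                        seed = 4, C0 = matrix(4))
  out <- dram_sample(function(x) -0.5 * x^2, 0, cfg)
  x <- out$draws[-(1:1e4), 1]
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(var(x) - 1), 0.03)
})

test_that("acceptance bookkeeping is conserved and box constraints hold", {
  mod <- decay2_model()
  dat <- decay2_data(seed = 6)
  cfg <- tiny_config(600, seed = 2)
  fit <- fit_kinetics(dat, mod, attr(mod, "prior"), cfg)
  acc <- fit$acceptance
  expect_equal(acc$stage1_accepts + acc$stage2_accepts + acc$rejections,
               acc$proposals)
  expect_true(all(acc$stage2_accepts <= acc$stage2_proposals))
  pr <- attr(mod, "prior")
  expect_true(all(t(fit$beta) >= pr$zeta_l & t(fit$beta) <= pr$zeta_u))
  expect_true(all(fit$sigma2 > 0))
  expect_true(all(is.finite(fit$lp)))
})

test_that("identical seeds give bit-identical chains", {
  mod <- decay2_model()
  dat <- decay2_data(seed = 6)
  cfg <- tiny_config(300, seed = 7)
  f1 <- fit_kinetics(dat, mod, attr(mod, "prior"), cfg)
  f2 <- fit_kinetics(dat, mod, attr(mod, "prior"), cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_identical(f1$lp, f2$lp)
})

test_that("with a likelihood free of beta the variance marginal is the analytic conjugate", {
  # rhs == 0: mu stays at the initial state regardless of beta, so the
  # residual sum of squares is fixed and each sigma2 draw is exactly
  # inverse-gamma(alpha* + mT/2, kappa* + RSS/2)
  still <- kinetic_model(states = c("A", "B"), initial = c(A = 1, B = 2),
                         parameters = "k", rhs = function(mu, k, t) c(0, 0))
  set.seed(10)
  dat <- simulate_dataset(still, beta_true = 0, times = c(1, 2, 3), m = 3,
                          noise = noise_spec(sigma2 = 0.2), seed = 10)
  pr <- beta_prior(mean = 0, sd = 1, lower = -3, upper = 3)
  cfg <- sampler_config(n_iter = 4000, burn_in = 0, l0 = 100, dr_onset = 200,
                        seed = 11)
  fit <- fit_kinetics(dat, still, pr, cfg)
  hyper <- estimate_shrinkage(dat)
  ds <- kineticbayes:::dataset_internal(dat, still)
  logmu <- log(kineticbayes:::solve_mu(still, 0, ds$times)[, still$observed_idx])
  rss <- kineticbayes:::resid_ss(ds, logmu)
  for (i in 1:2) {
    ks <- ks.test(fit$sigma2[, i], function(q) {
      pinvgamma(q, hyper$alpha_star + ds$m * ds$T / 2, hyper$kappa_star + rss[i] / 2)
    })
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("disabling adaptation reduces to plain Metropolis with matching summaries", {
  target <- function(x) -0.5 * x^2
  adapt <- dram_sample(target, 0,
                       sampler_config(n_iter = 3e4, burn_in = 3e3, l0 = 500,
                                      dr_onset = 1000, seed = 3,
                                      C0 = matrix(1)))
  plain <- dram_sample(target, 0,
                       sampler_config(n_iter = 3e4, burn_in = 3e3,
                                      l0 = 3e4 - 1, dr_onset = 1000, seed = 3,
                                      C0 = matrix(1)))
  xa <- adapt$draws[-(1:3e3), 1]
  xp <- plain$draws[-(1:3e3), 1]
  expect_lt(abs(mean(xa) - mean(xp)), 0.05)
  expect_lt(abs(var(xa) - var(xp)), 0.08)
})

test_that("the sampler recovers decay-chain parameters from simulated data", {
  mod <- decay2_model()
  dat <- decay2_data(seed = 3)
  fit <- fit_kinetics(dat, mod, attr(mod, "prior"),
                      sampler_config(n_iter = 4000, burn_in = 1500, l0 = 800,
                                     dr_onset = 1200, seed = 5))
  s <- posterior_summary(fit)
  z <- abs(s$estimate[1:2] - attr(mod, "beta_true")) / s$std.error[1:2]
  expect_true(all(z < 2.5))
  expect_equal(fit$ode_failures, 0L)
})
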