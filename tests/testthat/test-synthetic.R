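test_that("simulated data follow the stated log-normal error model", {
  mod <- decay2_model()
  tms <- attr(mod, "default_times")
  bt <- attr(mod, "beta_true")

  # noiseless limit: log y equals log mu exactly
  d0 <- simulate_dataset(mod, bt, tms, m = 3, noise = noise_spec(sigma2 = 1e-30),
                         seed = 1)
  mu <- kineticbayes:::solve_mu(mod, bt, tms)
  ds <- kineticbayes:::dataset_internal(d0, mod)
  logmu <- log(mu[, mod$observed_idx])
  expect_equal(max(abs(ds$logy - logmu[ds$row_idx, ])), 0, tolerance = 1e-12)

  # fixed variance 0.25: the sample variance of log y per cell converges to it
  db <- simulate_dataset(mod, bt, c(1, 2), m = 8000,
                         noise = noise_spec(sigma2 = 0.25), seed = 2)
  v <- tapply(log(db$abundance), list(db$isotopomer, db$time), var)
  expect_true(all(abs(v - 0.25) / 0.25 < 0.06))

  # log residuals are Gaussian
  cell <- log(db$abundance[db$isotopomer == "A" & db$time == 1])
  expect_gt(ks.test((cell - mean(cell)) / sd(cell), "pnorm")$p.value, 0.01)

  # determinism
  expect_identical(simulate_dataset(mod, bt, tms, m = 3, seed = 9),
                   simulate_dataset(mod, bt, tms, m = 3, seed = 9),
                   ignore_srcref = TRUE)
})

test_that("generated datasets satisfy all dataset invariants", {
  mod <- exemplar_network("pool3_mini")
  dat <- simulate_dataset(mod, attr(mod, "beta_true"),
                          attr(mod, "default_times"), m = 3, seed = 4)
  expect_silent(validate_dataset(dat))
  ds <- kineticbayes:::dataset_internal(dat, mod)
  expect_equal(ds$T, 6)
  expect_equal(ds$m, 3)
  expect_equal(ds$n, 7)
  expect_true(all(dat$abundance > 0))
  # per-isotopomer variances drawn from the inverse-gamma hyperprior
  expect_equal(length(attr(dat, "sigma2_true")), 7)
  expect_true(all(attr(dat, "sigma2_true") > 0))
})

test_that("exemplar networks are valid and match their closed forms", {
  expect_error(exemplar_network("nope"), class = "kb_lookup_error")

  dec <- exemplar_network("decay2")
  bt <- attr(dec, "beta_true")
  k <- exp(bt)
  t <- attr(dec, "default_times")
  tr <- kineticbayes:::solve_mu(dec, bt, t)
  A0 <- dec$initial["A"]; B0 <- dec$initial["B"]
  A_cf <- A0 * exp(-k[1] * t)
  B_cf <- A0 * k[1] / (k[2] - k[1]) * (exp(-k[1] * t) - exp(-k[2] * t)) +
    B0 * exp(-k[2] * t)
  expect_equal(tr[, "A"], unname(A_cf), tolerance = 1e-8)
  expect_equal(tr[, "B"], unname(B_cf), tolerance = 1e-8)

  p3 <- exemplar_network("pool3_mini")
  expect_true(all(p3$initial >= 0))
  expect_false(anyDuplicated(p3$parameters) > 0)
  expect_true(all(p3$observed_idx %in% seq_len(p3$n_state)))
  # labeled + unlabeled mass is conserved in the closed sub-network
  tr3 <- kineticbayes:::solve_mu(p3, attr(p3, "beta_true"), c(1, 5, 10))
  expect_equal(rowSums(tr3), rep(sum(p3$initial), 3), tolerance = 1e-8)
})

test_that("the recovery study returns calibrated, reproducible tables", {
  mod <- decay2_model()
  cfg <- tiny_config(1200, seed = 100)
  tab <- run_recovery_study(mod, attr(mod, "beta_true"), n_runs = 4, m = 3,
                            noise = noise_spec(sigma2 = 0.04), config = cfg)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("parameter", "avg_error", "se", "covered", "n_ok") %in%
                    names(tab)))
  expect_true(all(tab$n_ok == 4))
  expect_true(all(is.finite(tab$se)) && all(tab$se > 0))

  tab2 <- run_recovery_study(mod, attr(mod, "beta_true"), n_runs = 4, m = 3,
                             noise = noise_spec(sigma2 = 0.04), config = cfg)
  expect_equal(tab$avg_error, tab2$avg_error, tolerance = 1e-15)

  # near-noiseless data: averaged errors essentially vanish
  tab0 <- run_recovery_study(mod, attr(mod, "beta_true"), n_runs = 3, m = 3,
                             noise = noise_spec(sigma2 = 1e-8), config = cfg)
  expect_true(all(abs(tab0$avg_error) < 0.01))
})
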