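# shared fixtures: everything is generated in code at test time

tiny_config <- function(n_iter = 400L, seed = 1L) {
  sampler_config(n_iter = n_iter, burn_in = as.integer(n_iter / 4),
                 l0 = as.integer(n_iter / 4),
                 dr_onset = as.integer(n_iter / 3), seed = seed)
}

decay2_model <- function() exemplar_network("decay2")

decay2_data <- function(seed = 3L, m = 3L, sigma2 = 0.04,
                        model = decay2_model()) {
  simulate_dataset(model, attr(model, "beta_true"),
                   attr(model, "default_times"), m = m,
                   noise = noise_spec(sigma2 = sigma2), seed = seed)
}

# independent brute-force HDI: scan every window of k sorted draws
hdi_bruteforce <- function(x, level) {
  s <- sort(x)
  L <- length(s)
  k <- min(L, ceiling(level * L))
  best <- c(s[1], s[k]); bw <- s[k] - s[1]
  if (k < L) {
    for (j in seq_len(L - k + 1L)) {
      w <- s[j + k - 1L] - s[j]
      if (w < bw) { bw <- w; best <- c(s[j], s[j + k - 1L]) }
    }
  }
  best
}

# inverse-gamma CDF in the shape/scale parameterization used throughout
pinvgamma <- function(q, shape, scale) {
  stats::pgamma(1 / q, shape = shape, rate = scale, lower.tail = FALSE)
}

# plain triple-loop log-likelihood evaluation, independent of the package's
# vectorized path
loglik_bruteforce <- function(data, logmu, sigma2, isotopomers, times) {
  m <- length(unique(data$replicate))
  Tn <- length(times)
  acc <- -(m * Tn / 2) * sum(log(sigma2))
  for (r in seq_len(nrow(data))) {
    i <- match(data$isotopomer[r], isotopomers)
    t <- match(data$time[r], times)
    acc <- acc - 0.5 * (log(data$abundance[r]) - unname(logmu[t, i]))^2 / sigma2[i]
  }
  acc
}

# a fake minimal fit object carrying an explicit set of beta draws
fake_fit <- function(model, beta_draws) {
  structure(list(model = model,
                 beta = matrix(beta_draws, ncol = model$d,
                               dimnames = list(NULL, model$parameters)),
                 burn_in = 0L),
            class = "kb_fit")
}
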