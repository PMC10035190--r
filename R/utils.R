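#' @importFrom rlang abort %||%
#' @importFrom stats rnorm runif rgamma dnorm var sd cov quantile acf setNames
#' @importFrom utils modifyList packageVersion
NULL

# log(1 - exp(x)) for x <= 0, numerically stable on both branches
log1mexp <- function(x) {
  if (x >= 0) return(if (x == 0) -Inf else NaN)
  if (x < -0.693147180559945) log1p(-exp(x)) else log(-expm1(x))
}

# one inverse-gamma draw, shape/scale parameterization:
# density propto x^{-shape-1} exp(-scale/x)
rinvgamma1 <- function(shape, scale) {
  1 / stats::rgamma(1L, shape = shape, rate = scale)
}

dinvgamma_log_kernel <- function(x, shape, scale) {
  (-shape - 1) * log(x) - scale / x
}

stop_kb <- function(msg, class) {
  rlang::abort(msg, class = c(class, "kineticbayes_error"))
}
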