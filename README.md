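# kineticbayes

Bayesian estimation and hypothesis testing for **non-steady-state kinetic
models** of stable-isotope-resolved metabolomics (SIRM) time courses.

Tracer experiments measure isotopomer abundances at a few time points with
very few replicates (typically 3), while the system is still evolving.
Frequentist least-squares fits of the underlying ODE models are plagued by
non-identifiability, ill-conditioned Hessians, and the absence of any
principled way to compare rate constants between experimental groups.
`kineticbayes` addresses all three with a Bayesian treatment aimed at
metabolomics and systems-biology researchers fitting ODE kinetic models to
replicated tracer data.

## The model

Mean concentrations follow user-specified ODEs and observations are
log-normal around them:

$$\log y_{tj} = \log \mu_t + \delta_{tj}, \qquad
  \frac{d\mu_t}{dt} = f(\mu_t;\, e^{\beta},\, t), \qquad
  \delta_{tj} \sim N(0, \mathrm{diag}(\sigma^2)),$$

with $\beta$ the log rate constants. Priors: a truncated multivariate
normal $N(\xi, \Lambda)$ on $[\zeta_l, \zeta_u]$ for $\beta$ (expert
knowledge of plausible rate ranges), and one shared empirical-Bayes
inverse-gamma prior for all error variances, with shape and scale
moment-matched to the per-cell sample variances — shrinkage that makes
$m = 3$ replicates workable. Sampling is Gibbs: exact conjugate
inverse-gamma draws of each $\sigma_i^2$ alternate with component-wise
**adaptive Metropolis** updates of $\beta$ (proposal variances are Schur
complements of an adaptively estimated joint covariance) plus **delayed
rejection** (a smaller second proposal after each rejection, accepted with
the reversibility-preserving two-stage probability).

Two groups are compared via the reparameterization
$\eta_k = \beta_k^{(1)} - \beta_k^{(2)}$, fitted jointly, and summarized by
the 95% highest-density interval of $\eta_k$ and the **credible value**
$p = 1 - \max\{\alpha : 0 \notin \mathrm{HDI}_\alpha\}$ — a two-sided
Bayesian analogue of a p-value, significant below 0.05.

## Worked example

Simulate a replicated time course from the shipped two-state decay
exemplar (A → B → out, true log rates log 0.4 = −0.916 and
log 0.15 = −1.897), fit it, and compare two groups that differ by 0.35 in
the first log rate constant:

```r
library(kineticbayes)

mod <- exemplar_network("decay2")
dat <- simulate_dataset(mod, attr(mod, "beta_true"), attr(mod, "default_times"),
                        m = 3, noise = noise_spec(sigma2 = 0.04), seed = 7)
fit <- fit_kinetics(dat, mod, attr(mod, "prior"),
                    sampler_config(n_iter = 4000, burn_in = 1500, l0 = 800,
                                   dr_onset = 1200, seed = 7))
posterior_summary(fit)
#> # A tibble: 4 × 7
#>   term  type   estimate std.error hdi_lower hdi_upper geweke_z
#>   <chr> <chr>     <dbl>     <dbl>     <dbl>     <dbl>    <dbl>
#> 1 k1    beta    -0.885     0.0279   -0.936    -0.828    -1.32
#> 2 k2    beta    -2.06      0.121    -2.31     -1.84     -0.436
#> 3 A     sigma2   0.0488    0.0166    0.0225    0.0798   -0.149
#> 4 B     sigma2   0.0417    0.0137    0.0205    0.0679    0.197
```

Both true log rates sit well inside their 95% HDIs, the error-variance
posteriors bracket the generating value 0.04, and |Geweke z| < 1.96
throughout. The two-group test:

```r
d2 <- simulate_dataset(mod, attr(mod, "beta_true") - c(0.35, 0),
                       attr(mod, "default_times"), m = 3,
                       noise = noise_spec(sigma2 = 0.04), seed = 8)
cmp <- compare_groups(dat, d2, mod, "k1", attr(mod, "prior"),
                      sampler_config(n_iter = 3000, burn_in = 1200, l0 = 600,
                                     dr_onset = 900, seed = 7),
                      group_labels = c("treated", "control"))
test_summary(cmp)
#> # A tibble: 1 × 8
#>   parameter credible_value hdi_lower hdi_upper level significant difference
#> 1 k1                     0     0.296     0.484  0.95 TRUE        treated - control
```

The 95% HDI of the difference (0.30, 0.48) covers the true shift 0.35 and
excludes 0; the credible value is below the bisection tolerance, so the
difference is significant. `flux_trajectory(fit, "v_A_B", times)` gives
posterior flux curves with credible ribbons, and `autoplot()` /
`plot_trace()` visualize any result.

A command-line interface covers the same workflow
(`exec/kineticbayes simulate|fit|compare|diagnose`), reading models and
priors from YAML and writing chains, summary tables and run manifests.

See the vignette `vignettes/kinetic-bayes-methods.Rmd` for the full model,
sampler, and design rationale.

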