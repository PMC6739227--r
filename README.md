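# spmsens

Shared parameter models for longitudinal data with informative dropout,
with a transparent, closed-form-anchored sensitivity analysis.

## The problem

In long follow-up studies (the motivating case: CD4 counts over 12
six-monthly visits in an HIV cohort), subjects who are deteriorating
fastest tend to leave the study first.  A standard linear mixed model on
the observed data then understates the decline.  A shared parameter
model (SPM) addresses this by modelling the outcome and the dropout
process jointly:

- longitudinal outcome: `Y_ij = x_ij'β + b_i1 + b_i2 t_j + ε_ij` with a
  random intercept and slope `b_i ~ N(0, Σ_b)` (modified Cholesky
  parameterization) and `ε_ij ~ N(0, σ_ε²)`;
- discrete-time dropout hazard (probit):
  `λ_il = 1 − Φ(x_Sil'α + γ₁ b_i1 + γ₂ b_i2)`, with `S_i` the last
  attended of `M` scheduled visits (completers administratively censored
  at `M`).

The two parts share the random effects; conditional on them, outcome and
dropout are assumed independent.  That assumption is unverifiable, and it
alone determines how post-dropout outcomes are extrapolated.  `spmsens`
makes the extrapolation explicit: under this SPM the conditional law of
`b_i` given a subject's observed data is a **closed skew-normal**
distribution — a Gaussian (the mixed-model conjugate update) tilted by
one probit factor per survival/event term — available in closed form, with
exact moments and an exact rejection sampler.  The *default* extrapolation
draws missing outcomes from it.  The *sensitivity* extrapolation perturbs
the post-dropout slope by

    Δ_i = a · (M − S_i)/(M − 1) · σ_{b_i2},

where `σ_{b_i2}` is the subject's conditional slope SD and `a` is a single
global sensitivity parameter with an informative triangular prior
(default support [−2, 0], mode −1).  Because `Δ_i` only ever touches the
extrapolated part, the observed-data fit is untouched — the sensitivity
analysis is transparent, and `a = 0` reproduces the default analysis
bit-for-bit.  Marginal covariate effects under both extrapolations come
from Bayesian G-computation (Monte-Carlo standardization over covariate
profiles), and model fit is assessed by a χ² posterior predictive check.

Estimation is by MCMC (JAGS), with broom-style `tidy()`/`glance()`
summaries, Gelman–Rubin/ESS convergence reports, and ggplot2 `autoplot()`
for G-computation summaries.  A synthetic-data generator emulates the
motivating cohort's structure (no public deposit of those data exists),
so the entire pipeline is runnable and testable out of the box.

## Worked example

```r
library(spmsens)

# simulate a 200-subject cohort with the built-in HIV-cohort emulation
sim <- simulate_spm(spm_generator(200, seed = 1))
sim
#> <spm_sim> N = 200 subjects (seed 1 )
#> <spm_data> 200 subjects, M = 12; completers: 90 (45%)

# fit the shared parameter model (short chains for the example)
fit <- fit_spm(sim, mcmc = mcmc_config(chains = 2, burn_in = 300,
                                       draws = 600, thin = 1, seed = 2))
dplyr::filter(tidy(fit), term %in% c("beta_time", "gamma1", "gamma2"))
#> # A tibble: 3 × 5
#>   term      estimate std.error conf.low conf.high
#>   <chr>        <dbl>     <dbl>    <dbl>     <dbl>
#> 1 beta_time   -1.19     0.271    -1.67     -0.580
#> 2 gamma1       0.225    0.0890    0.0523    0.405
#> 3 gamma2       0.320    0.0901    0.146     0.505

ppc_pvalue(fit, n_draws = 150, seed = 3)
#> <spm_ppc> posterior P(T_rep > T_obs) = 0.453 over 150 draws
```

`beta_time` is the marginal change in (transformed) outcome per unit
standardized time (baseline to final visit) for the reference profile;
positive `gamma1`/`gamma2` say that subjects with higher intercepts and
flatter slopes stay in the study longer, i.e. dropout is informative.  A
posterior predictive p-value near 0.5 indicates no evidence of lack of
fit; values near 0 or 1 would flag misfit.

G-computation contrasts two viral-load profiles under both
extrapolations:

```r
lv <- c(">30k", "0-500", "500-5k", "5k-30k")
profs <- gcomp_profiles(vl = factor(c(">30k", "0-500"), levels = lv),
                        art = 1L, sympt = 0L)
# the group-average slope-SD subsample (sigma_group_cap) is the main
# speed knob of the sensitivity column; this run takes a few minutes
gc <- spm_gcompute(fit, profs,
                   sens = sensitivity_config(sigma_group_cap = 24L),
                   n_draws = 6, n_mc = 4000, seed = 4)
subset(summarize_posterior(gc), stat == "change" & visit == 12)
#>                  profile   stat visit extrapolation estimate conf.low conf.high excludes_zero
#> 1 vl=0-500,art=1,sympt=0 change    12       default   -0.252   -0.512   0.00399         FALSE
#> 2 vl=0-500,art=1,sympt=0 change    12   sensitivity   -0.305   -0.570  -0.05017          TRUE
#> 3  vl=>30k,art=1,sympt=0 change    12       default   -0.832   -1.177  -0.25702          TRUE
#> 4  vl=>30k,art=1,sympt=0 change    12   sensitivity   -0.997   -1.427  -0.42697          TRUE
autoplot(summarize_posterior(gc))
```

The `default` column is the SPM's own answer; the `sensitivity` column
shows the same summary when post-dropout slopes are allowed to steepen
according to the prior on `a`.  The high-viral-load profile drops out
more, so its mean change moves further — exactly the asymmetry the
sensitivity analysis is designed to expose.  (Numbers above are from the
seeds shown; they are Monte-Carlo estimates and move within their
intervals under other seeds.)

A YAML-configured pipeline (`run_pipeline()`, subcommands
simulate/fit/ppc/gcomp) and a thin CLI wrapper in `inst/cli/spmsens.R`
cover scripted use; every stage writes CSV/YAML artifacts plus a manifest.

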