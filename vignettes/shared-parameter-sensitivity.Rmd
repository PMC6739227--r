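---
title: "Shared parameter models and transparent sensitivity analysis for informative dropout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared parameter models and transparent sensitivity analysis for informative dropout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Long-term longitudinal studies lose subjects.  When the decision to leave
is related to the unobserved trajectory — subjects whose outcome is
deteriorating fastest leave first — analyses that assume ignorable
missingness (a standard linear mixed model on the observed data)
underestimate the true rate of change.  The motivating setting is an HIV
cohort with CD4 counts scheduled at `M = 12` six-monthly visits, where
more than half of the women did not complete follow-up and dropout was
believed to track disease progression.

`spmsens` implements a *shared parameter model* (SPM) for this situation,
together with a sensitivity analysis that cleanly separates what the
observed data can identify from what they cannot.

## The joint model

For subject $i$ at visit $j$ ($t_j \in [0,1]$, standardized visit time),
the complete outcome follows a linear mixed model

$$Y_{ij} = x_{ij}^\top\beta + b_{i1} + b_{i2}\,t_j + \varepsilon_{ij},
  \qquad \varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2),$$

with a random intercept and slope
$b_i = (b_{i1}, b_{i2})^\top \sim N(0, \Sigma_b)$.  The dropout visit
$S_i$ (the last attended visit; $S_i = M$ for completers, treated as
administratively censored) follows a discrete-time probit hazard

$$\lambda_{i\ell} = P(S_i = \ell \mid S_i \ge \ell, b_i)
  = 1 - \Phi\!\big(x_{S,i\ell}^\top\alpha + \gamma_1 b_{i1} +
    \gamma_2 b_{i2}\big), \qquad \ell = 1, \dots, M-1.$$

The two submodels share $b_i$: positive $\gamma_2$ means subjects with
flatter (less negative) slopes are less likely to drop out.  Given $b_i$
and covariates, outcomes and dropout are assumed independent — the latent
ignorability assumption that the sensitivity analysis later perturbs.
$\Sigma_b$ is parameterized by the modified Cholesky decomposition
($b_{i1} = e_{i1}$, $b_{i2} = \delta b_{i1} + e_{i2}$, innovation SDs
$\sigma_1, \sigma_2$), so any unconstrained $(\delta, \sigma_1, \sigma_2)$
gives a valid covariance.

Intermittent (non-monotone) gaps before dropout are treated as latent
ignorable and handled by row deletion in the longitudinal likelihood; the
hazard model is unaffected.

## Estimation

`fit_spm()` samples the posterior with JAGS, treating each $b_i$ as a
latent variable.  Priors (all config-exposed through `prior_spec()`):
$N(0, 100)$ on $\beta$ and $\delta$; weakly informative $N(0, 4)$ on
$\alpha$, $\gamma_1$, $\gamma_2$ (probit-scale coefficients beyond $\pm 2$
are implausible); $\sigma_\varepsilon^2 \sim$ Inverse-Gamma(0.001, 0.001)
(shape/rate); $\sigma_k \sim U(0, 5)$.  The default run mirrors the
classic WinBUGS-style workflow — three chains, 5000 burn-in, thinning by
5, 3000 kept draws per chain — but every knob is in `mcmc_config()`, and
the examples in this vignette and the test suite use far shorter chains.

One implementation detail matters for practical chain mixing.  When the
fixed-effects design has the `baseline + time:baseline` structure (as all
the built-in specifications do), the sampler automatically switches to a
*hierarchically centered* parameterization: the subject-level means are
absorbed into the random-intercept/slope distributions.  Without
centering, the fixed effects and the latent effects are strongly
negatively correlated and single-site Gibbs/slice updates crawl; with it,
effective sample sizes per iteration improve by an order of magnitude.
Results are mapped back to the usual uncentered scale, so the
parameterization is invisible in the output.  General designs fall back
to the uncentered sampler.

`check_convergence()` reports per-parameter Gelman–Rubin statistics and
effective sample sizes (pass flag at $\hat R < 1.1$), and
`tidy()`/`glance()` provide broom-style summaries.

```{r}
library(spmsens)
sim <- simulate_spm(spm_generator(200, seed = 1))
fit <- fit_spm(sim, mcmc = mcmc_config(chains = 2, burn_in = 500,
                                       draws = 1000, thin = 2, seed = 1))
tidy(fit)
check_convergence(fit)
```

## The default extrapolation distribution

Everything about the missing post-dropout outcomes rests on the
conditional law of $b_i$ given a subject's observed data.  Under the SPM
this law is available in closed form: it has density proportional to

$$\varphi(b;\, \mu_i, \Omega_i)\; \prod_{\ell=1}^{m_i}
  \Phi(c_{i\ell} + d_{i\ell}^\top b),$$

where $(\mu_i, \Omega_i)$ is the ordinary conjugate Gaussian update of
$N(0, \Sigma_b)$ by the observed outcome rows, and each survival/event
factor of the dropout likelihood contributes one probit factor: a dropout
at $S_i < M$ contributes $m_i = S_i$ factors ($S_i - 1$ survival terms
plus the event term, whose argument enters with flipped sign because
$\lambda = \Phi(-\eta)$); a completer contributes $m_i = M - 1$ survival
terms.  This is a *closed skew-normal* (CSN) distribution; surviving
under a positive $\gamma$ tilts the law toward larger random effects, and
the event factor tilts it back down.

`conditional_random_effects()` builds this object.  Its normalizing
constant is an $m$-dimensional Gaussian orthant probability, computed by
the Genz–Bretz quasi-Monte-Carlo algorithm (`mvtnorm::pmvnorm`) with
absolute tolerance `1e-8` (config-exposed; $m \le 11$ at the motivating
scale).  `csn_moments()` returns the exact mean and covariance through
first and second derivatives of the log normalizing constant — closed
forms needing $m$-, $(m-1)$- and $(m-2)$-dimensional orthant evaluations —
and `sample_csn()` draws exactly by rejection: propose from
$N(\mu, \Omega)$, accept with probability $\prod_\ell \Phi(\cdot) \le 1$.
The acceptance rate equals the normalizing constant; a floor (default
`1e-4`) guards against pathological subjects, with an error directing
users to a sequential scheme.  The moment formulas are validated in the
test suite against two independent oracles: two-dimensional quadrature of
the density and large rejection-sampling estimates.

The *default extrapolation distribution* of a missing outcome $Y_{ik}$
($k > S_i$) is then induced by
$Y_{ik} = x_{ik}^\top\beta + z_{ik}^\top b_i + \varepsilon_{ik}$ with
$b_i$ CSN-distributed (`default_extrapolation_sample()`), drawing a
common $b_i$ across visits.  With $\gamma \equiv 0$ every probit factor
is constant and this collapses exactly to the Gaussian mixed-model
predictive — the ignorable limit.

## The sensitivity model

The conditional-independence assumption cannot be checked: it determines
the extrapolation distribution, which the observed data never see.  The
sensitivity analysis therefore *anchors* at the default extrapolation and
perturbs only the unidentified part.  Post-dropout outcomes follow the
piecewise-linear model

$$Y_{ik} = x_{ik}^\top\beta + b_{i1} + b_{i2} t_k +
  \Delta_i\,(t_k - t_{S_i})_+ + \varepsilon_{ik},
  \qquad
  \Delta_i = a\,\frac{M - S_i}{M - 1}\,\sigma_{b_{i2}},$$

where $\sigma_{b_{i2}}$ is the conditional SD of the random slope given
the subject's own observed data (from `csn_moments()`), and $a$ is a
single global sensitivity parameter.  Completers get $\Delta_i = 0$; the
earliest dropouts get the full $a\,\sigma_{b_{i2}}$; a subject missing
only the last visit gets $a/(M-1)\,\sigma_{b_{i2}}$.  Scaling by the
subject's own conditional slope SD calibrates the perturbation to their
observed-data uncertainty (and lets it implicitly interact with
covariates).  The default prior on $a$ is triangular on $[-2, 0]$ with
mode $-1$: dropouts are believed to decline *faster* than the model
predicts, by at most two conditional SDs, centred at one
(`sensitivity_config()`, `sample_a()`).

Two structural properties are guaranteed by construction and verified
bit-for-bit in the tests: the sensitivity machinery never touches the
observed-data fit (the draws are produced before any sensitivity
quantity is computed), and $a = 0$ reproduces the default analysis
exactly when random streams are shared, because the sensitivity draws are
the default draws plus the deterministic hinge shift.

## G-computation

Marginal covariate effects are obtained by Monte-Carlo standardization
(`spm_gcompute()`).  For each retained posterior draw (evenly spaced
thinning; the number of draws is a knob): draw $a$ from its prior (once
per draw — it sits outside the per-profile loop); for each covariate
profile simulate `n_mc` complete replicates from the SPM, truncate each
at its simulated dropout visit, fill the missing part from both the
default and the sensitivity extrapolation, and average.  Summaries
default to per-visit predicted means plus mean change from baseline to
visits 6 and `M`; `gcomp_contrasts()` differences profiles, and
`summarize_posterior()` reduces everything to posterior means and central
95% intervals (flagging intervals that exclude zero);
`autoplot()` draws the interval plot.

The methodology wants `n_mc` large relative to the study size (100 times
`N` is the recommendation and the default); the examples and tests use
smaller values, which only widens Monte-Carlo error.  The headline
correctness property — imputing from the exact conditional law
reconstructs the joint, so default-extrapolation predicted means equal
the marginal fixed-effect mean $x_k^\top\beta$ at every visit for *any*
$\gamma$ — is checked to within three Monte-Carlo standard errors at
`n_mc = 50,000` in the acceptance suite.

Computing $\sigma_{b_{i2}}$ exactly for every simulated replicate is the
expensive step (each value needs many orthant probabilities).  Following
the motivating analysis, `sigma_mode = "group"` (the default) averages
exact values within covariate groups — for simulated replicates the
grouping key is the profile itself — over a capped subsample
(`sigma_group_cap`, default 64; the cap controls only the Monte-Carlo
error of an average, and the replicate-level `(M - S_i)/(M-1)` scaling is
always exact).  `sigma_mode = "exact"` computes every replicate's own
value.  Because the group average pools over dropout times, the two modes
differ slightly per subject; both are exposed and compared in the tests.

## Model assessment

`ppc_pvalue()` implements a posterior predictive check with the
chi-square discrepancy
$\sum_{ij} (y_{ij} - x_{ij}^\top\beta - z_{ij}^\top b_i)^2 /
\sigma_\varepsilon^2$ conditional on the augmented random effects.  Per
posterior draw, a full replicate dataset (new random effects, outcomes
and dropout times; same covariates and sample size) is truncated at the
replicated dropout visits, and the reported p-value is the posterior
probability that the replicated discrepancy exceeds the observed one.
Two variants of this check exist — conditioning the discrepancy on the
sampled $b_i$ or marginalizing over them; the implementation conditions
on $b_i$ and replicates both outcomes and dropout.  Intermittent gaps
are not replicated: the
replicated observed data are truncation-only, which slightly enlarges the
replicated sample relative to data with intermittent missingness.

## The synthetic-data generator

No public deposit of the motivating cohort exists, so
`spm_generator()`/`simulate_spm()` emulate its structure: `M = 12` visits
at $t = (j-1)/11$; a 4-level baseline viral-load factor (reference the
highest level), a binary ART indicator, and an integer symptom score
0–5, sampled independently; fixed effects `time * (vl + art + sympt)`;
hazard terms `vl + art + sympt + time + time^2 + art:time`; true
parameter values (`hers_params()`) mirroring published posterior means so
that simulated data are realistic — a convenience calibration, not a
reproduction claim.  Covariate sampling probabilities
(viral-load 0.25/0.30/0.25/0.20, ART 0.4, symptoms Binomial(5, 0.2)) are
chosen once as plausible for a 1990s HIV cohort; they are not estimates.
Optional intermittent masking (default 0; 0.076 mimics the cohort) never
hits the baseline visit.  The generator returns the observed records and
a separate truth bundle (random effects, complete outcomes), so
observed-data code cannot leak complete-data information.

What the generator does *not* emulate: dependence among baseline
covariates, continuous dropout times within intervals, non-Gaussian
outcome tails, and measurement-occasion jitter.  Passing tests therefore
demonstrate internal correctness of the machinery under the model, not
robustness of the SPM to real-data violations of it.

Seeding: one master seed fans out deterministically to per-subject
streams (so growing `N` never reshuffles earlier subjects) and to
per-(draw, profile) G-computation streams.

## Numerical choices and degenerate inputs

* Orthant probabilities: Genz–Bretz QMC, absolute tolerance `1e-8`
  (moment lookups inside G-computation use `1e-7`); dimensions never
  exceed `M - 1`.
* Survival/event probabilities accumulate on the log scale
  (`pnorm(..., log.p = TRUE)`); the JAGS Bernoulli probabilities are
  clamped to `[1e-12, 1 - 1e-12]` against overflow at extreme linear
  predictors.
* `sigma1, sigma2 > 0` and `sigma_eps > 0` are enforced at construction;
  the modified Cholesky form guarantees a positive-definite $\Sigma_b$
  for any finite `delta`.
* Rejection sampling retries in vectorized rounds; a subject whose
  acceptance rate falls below `1e-4` raises an error rather than looping
  forever.
* Subjects must have an observed baseline outcome (visit 1); a subject
  with no observed outcomes is rejected at data assembly.

## Scale of the shipped checks

The test and acceptance suites run on one CPU and therefore use reduced
problem sizes, chosen as the package's own study design: a compact
two-arm design (`M = 8`, one binary covariate) for the replicate
calibration study (20 refits at `N = 300` with two short chains each),
`N = 200` for the end-to-end script, `n_mc` between 1,500 and 50,000
depending on the property being measured.  Statistical assertions are
made at three Monte-Carlo standard errors, or at stated exact tolerances
where the quantity is deterministic.

## Known limitations

* The sensitivity model presumes intercept+slope random effects
  (`q = 2`); the likelihood layer accepts general designs but the
  Δ-rule is slope-specific.
* The probit link is essential to the closed-form extrapolation; a
  logistic hazard would need MCMC over the random effects and is out of
  scope.
* `fit_spm()` fits the shared-association form ($\gamma$ common to all
  visits, identity weight matrices); visit-specific $\gamma_\ell$ is
  supported in the likelihood and extrapolation layers but not in the
  sampler front-end, since its identifiability is unclear.
* Location-shift (intercept) sensitivity models and informative
  intermittent missingness are natural extensions, not implemented.
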