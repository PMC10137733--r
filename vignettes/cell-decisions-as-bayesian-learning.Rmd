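---
title: "Cell decisions as Bayesian learning: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell decisions as Bayesian learning: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayescell)
```

## The model

A cell's decision variable — say, the expression level of a receptor — is
modelled as a slow internal state $X$ whose *distribution* $P(X)$ evolves,
while the microenvironment $Y$ (ligand concentration, mechanical cues) is
fast and, at the decision timescale, quasi-stationary. The package's working
hypothesis is that the cell updates its internal predisposition by Bayesian
learning: after each decision interval the posterior becomes the new prior,

$$P(X') = \frac{P(Y\mid X)\,P(X)}{P(Y)} .$$

`bayescell` implements this iteration on 1-D grids, the information-theoretic
identities it obeys, the Gibbs-form steady states it converges to when the
sensing channel is made explicit, and a Langevin/Fokker–Planck description
of the same stationary states.

### Information identities

Averaging the log update ratio over the joint law of $(X, X', Y)$ equates
the expected Kullback–Leibler divergence between consecutive priors with the
cell–environment mutual information,

$$E_Y\!\left[D\!\left(P(X\mid Y)\,\|\,P(X)\right)\right] = I(Y, X),$$

a fluctuation–dissipation relation: the dissipation of prior uncertainty per
step equals the information the environment makes available.
`expected_update_divergence()` computes the left side by quadrature over an
observation grid; `mutual_information_grid()` computes the right side by the
Fubini-swapped route, and `expected_kl_discrete()` /
`mutual_information()` give the exact discrete analogues. For small updates
the divergence is the Fisher quadratic form
$\tfrac12\,\Delta^2 F(X)$ (`fisher_quadratic_form()`), which for a Gaussian
mean shift is exact.

Two conventions are fixed here and used everywhere:

* **All information quantities are in nats** — the Gibbs/exponential forms
  below use base $e$.
* **Fisher information is the nonnegative curvature** $F = E[-\partial_x^2
  \ln p]$, so a Gaussian with standard deviation $\sigma$ gives
  $+1/\sigma^2$. (The quadratic form is treated as a nonnegative energy;
  writing the Hessian without the minus sign would make it negative
  definite.)

The update identity's normalization object — a ratio of conditional
integrals that deviates from one only when posteriors and likelihoods are
normalized on different truncated supports — is exposed as the diagnostic
`beta_tilde()`. Its printed integral definition is not a probability ratio
for fully normalized conditionals, so the package implements it literally as
a windowed-quadrature diagnostic (captured posterior mass over captured
likelihood mass) and uses the value 1 in all identity tests, which is exact
when the declared windows hold the full mass.

### The sensing channel

Sensing is a Gaussian conditional law
$Y \mid X = x \sim \mathcal N\!\left(F(x),\, \sigma_{Y|X}(x)^2\right)$ with

$$\sigma_{Y|X}(x) = b + g\,(x - \bar X),$$

where the bias $b = F(\bar X) - \bar Y > 0$ and the linear response
$g = |F'(\bar X)| \ge 0$ depend only on environment moments
(`linearize_sensing()`, `sensing_model()`). Two readings of the linear law
are possible — standard deviation linear in $x$, or variance itself equal to
$b + g(x-\bar X)^2$. Only the linear-sd reading is simultaneously consistent
with the entropy profile $\ln\!\big(b + g(x - \bar X)\big)$ that drives the
steady state *and* with the averaged variance law
$E[\sigma^2_{Y|X}] = b^2 + g^2\sigma_x^2$, so it is the default; the
variance-literal reading remains available as
`variance_mode = "literal_variance"` for exploration. The admissible
$x$-domain is truncated (with a warning, not an error) to where the sd stays
positive, because the bimodal regime below genuinely lives on a finite
interval.

The Gaussian conditional entropy is
$S(Y\mid X=x) = \tfrac12\ln\!\big(2\pi e\,\sigma_{Y|X}(x)^2\big)$
(`conditional_entropy_at()`). The steady-state exponent is insensitive to
the additive constant $\tfrac12\ln 2\pi e$ up to a shift of the linear-tilt
parameter; the default convention (`log_sd`) drops it, and
`full_gaussian` keeps it, so the two produce the same family of densities
with $\beta'$ relabelled.

### Steady states

Near perfect sensing the learning dynamics admit a Gibbs ansatz whose
potential integrates the conditional entropy profile:

$$P(x) \propto \exp\!\Big(-\beta \int^x S(Y\mid X=s)\,ds \;-\; \beta' x\Big),$$

with the sensitivity $\beta$ playing the role of an inverse temperature for
microenvironmental uncertainty and $\beta'$ a linear tilt
(`steady_state_generic()`, `steady_state_linear_sensing()`). The primary
computation is always cumulative trapezoidal quadrature of the exponent; the
closed forms (`closed_form_case()`) serve as cross-check oracles. This
ordering is deliberate: where printed closed forms admit sign ambiguities,
the package resolves them by requiring pointwise agreement with the directly
quadratured exponent.

A consequence worth stating explicitly: a *constant* entropy profile
$S \equiv s_0$ gives a cumulative integral $s_0 x$ — a linear tilt — so the
steady state is an **exponential** density with rate $\beta s_0 + \beta'$,
not a uniform one. The sensor-off case below is exactly this, with
$s_0 = \ln b$.

For the linear channel:

* **Sensor off** ($g = 0$): $S$ is constant and
  $P(x) = C\,e^{-\bar\beta x}$ with $\bar\beta = \beta\ln b + \beta'$, a
  truncated exponential (sensible as a half-line law only for
  $\bar\beta > 0$).
* **Sensor on** ($g > 0$): the exponent integrates to
  $-\beta\big[(x - \bar X + b/g)\ln(b + g(x - \bar X)) - x\big] - \beta' x$,
  and the log-density derivative $-\beta\ln(b + g(x-\bar X)) - \beta'$ has
  an interior root at $\sigma_{Y|X}(x^*) = e^{-\beta'/\beta}$ (at
  $x^* = \bar X + (1 - b)/g$ when $\beta' = 0$). Differentiating once more
  shows this root is a **maximum for $\beta > 0$** (interior-unimodal, one
  committed phenotype) and a **minimum for $\beta < 0$**
  (boundary-bimodal, probability mass pushed to the extreme states). The
  narrative convention that assigns the unimodal regime to negative
  sensitivity is the opposite of what the integrated exponent yields; the
  package reports the sign convention fixed by oracle agreement between the
  closed form and the quadratured density, and `classify_modality()` /
  `modality_sweep()` label the regimes from the computed density itself, so
  the monostable–bistable *switch at the sign change* — the substantive
  claim — is reproduced regardless of labelling.

As $g \to 0^+$ the sensor-on solution converges in $L_1$ to the sensor-off
exponential, so the two regimes join continuously.

### Learning trajectories and entropy decay

`iterate_learning()` runs the update chain. Two modes exist because the
identities need a $Y$-expectation while the chain itself is per-observation:

* `observed` draws one environment sample per step from the environment
  truth (by default the model-implied evidence under the initial prior;
  fixing it externally simulates model mismatch, under which the chain need
  not settle).
* `averaged` applies the deterministic update at the expected observation
  $E[Y]$. The exact $Y$-average of the posterior *density* is the prior
  itself (law of total probability), so that literal averaging cannot be
  iterated; the expected-observation update reproduces the exact
  $Y$-averaged posterior mean and variance for conjugate chains and gives
  the deterministic, monotone trajectories the decay statements need.

Along a chain, the averaged conditional variance
$\sigma^2_{Y|X,t} = b^2 + g^2 \sigma^2_{x,t}$ contracts toward $b^2$ as the
prior tightens, and the corresponding conditional entropy
$S_t = \tfrac12\ln(2\pi e\,\sigma^2_{Y|X,t})$ decays toward
$\ln b + \tfrac12\ln 2\pi e$ — the least-microenvironmental-uncertainty
behaviour (`entropy_decay_report()`). For a conjugate chain with unit
observation noise the prior variance follows $v_{t+1} = v_t/(1 + v_t)$, so
ten updates from $v_0 = 1$ give exactly $1/11$; this is the package's
learning sanity benchmark.

### The Langevin / Fokker–Planck bridge

The same stationary states arise from a slow–fast Ito system for $(X, Y)$
(`sde_spec()`, `euler_maruyama()`). The Fokker–Planck diffusion coefficients
are related to the noise amplitudes by $\sigma_{pq} = (\Sigma\Sigma^{\sf
T})_{pq}/2$ — a dictionary the source formalism leaves implicit, so it is
*declared* here and locked by a test: an Ornstein–Uhlenbeck slow variable
with drift $-kx$ and diffusion coefficient $\sigma_{22}$ must have
stationary variance $\sigma_{22}/k$.

Under timescale separation the joint equation splits hierarchically into a
fast conditional relaxation (realized by `fast_conditional_density()`,
which with an OU fast drift toward $F(x)$ reproduces the Gaussian sensing
channel), a 1-D stationary equation for the slow marginal
($-K_2 P + \sigma_{22} P' = 0$, solved by `stationary_solution_1d()` and
checked by `slow_equation_residual()`), and a coupling constraint
$2\partial_Y(\sigma_{12} P) + \sigma_{22}\partial_Y P = 0$
(`coupling_residual()`), which the constant choice
$\sigma_{12} = -\sigma_{22}/2$ satisfies identically for any smooth
conditional density — both that reading and the per-model residual check are
provided.

Matching the 1-D stationary solution to the Gibbs steady state forces the
drift–entropy relation

$$K_2(x) = -\beta\,\sigma_{22}\,S(Y\mid X = x) - \beta'\sigma_{22}$$

(`drift_from_entropy()`). The printed form of this relation carries a
trailing term quadratic in $x$ that is inconsistent with differentiating the
Gibbs exponent; the package resolves it by the consistency requirement that
the stationary solution of the drift reproduce the Gibbs density, which the
constant $-\beta'\sigma_{22}$ term does.
`simulate_slow_stationary()` closes the loop empirically: reflected
Euler–Maruyama under the entropy-derived drift, burn-in discarded, and a
Kolmogorov–Smirnov comparison against the analytic density.

### LEUP and its coincidence with the Bayesian steady state

The least-microenvironmental-uncertainty principle derives the internal
distribution from entropy maximization constrained by the cell–environment
mutual information and the mean state, giving the Gibbs-like form

$$P_{\rm LEUP}(x) \propto \exp\!\big(-\beta\,S(Y\mid X = x) - \beta' x\big)$$

— the entropy *itself* in the exponent (`leup_distribution()`), not its
cumulative integral. The two families coincide through localization: on a
domain shrinking around a point $\hat x$, the mean value theorem collapses
the cumulative integral to the entropy value at $\hat x$, and both densities
converge to the tilted form $\propto e^{-\beta S(\hat x) - \beta' x}$. For a
constant profile the LEUP density and that localized Bayesian form are
algebraically identical. `compare_leup_bayes()` reports both comparisons —
against the localized form (which vanishes with domain width) and against
the full cumulative-integral steady state (which is genuinely different for
nonconstant profiles and is reported, not asserted equal). Because the
densities scale like the inverse domain width, the localization statement is
asserted on *relative* sup-norm and $L_1$ distances; the absolute sup-norm
between two densities on a shrinking domain diverges by normalization alone
and would be the wrong metric.

## Numerical choices

* **Quadrature.** Uniform grids and trapezoid weights everywhere
  (`grid1d()`, 2001 points by default); cumulative exponents use the
  cumulative trapezoid. Default Gaussian windows span $\pm 8$ standard
  deviations, leaving omitted tail mass below $10^{-10}$. Tolerances in the
  tests are set from the quadrature error actually achievable at the stated
  grid sizes (e.g. the closed-form exponential comparisons use
  $6\times10^4$ nodes to push the normalizer error below $10^{-8}$).
* **Logs of small densities.** $0\ln 0 := 0$; densities are clipped at
  $10^{-300}$ before taking logs.
* **Degenerate inputs.** All-zero or non-finite densities, support
  violations in KL, zeros inside the Fisher window, evidence below
  $10^{-300}$, non-finite SDE states, and non-integrable exponents raise
  informative errors; steady-state exponents are overflow-guarded by a
  max-shift before exponentiation.
* **Modality detection.** Discrete strict local extrema with plateaus merged
  at relative tolerance $10^{-12}$; a boundary counts as a mode only if the
  boundary density exceeds its interior neighbour. For linear sensing the
  analytic stationary point of the exponent is recorded alongside the
  discrete classification.
* **Randomness.** One root seed per run; learning steps derive per-step
  substreams as `(seed mod 1e6) * 2017 + step`, so trajectories are
  reproducible and extendable; simulation helpers take explicit seeds.
* **SDE integration.** Euler–Maruyama with independent Wiener increments;
  correlated noise via the pointwise Cholesky factor of $2\sigma$; the
  timescale ratio $\varepsilon$ scales the fast drift and diffusion by
  $1/\varepsilon$. Slow-variable simulations confined to a finite domain
  use reflecting boundaries, since entropy-derived drifts diverge
  logarithmically at the sd-positivity edge. Burn-in defaults to the first
  20% of steps. Stationary-variance checks use per-path second moments
  about the known stationary mean, which avoids the correlated-sample bias
  of per-path variance estimates.
* **Problem sizes.** The shipped tests and the acceptance script use grids
  of 501–8001 nodes (up to $6\times10^4$ for closed-form normalizer
  checks), $10^5$ draws for Monte-Carlo moment checks, and
  $2\times10^5$ retained SDE samples (100 paths) for distributional
  comparisons, sizes at which the sampling error sits well inside the
  asserted bounds.

## What the synthetic scenarios do and do not show

All data in this package are generated by its own models: Gaussian sensing
channels with sd linear in the internal state, conjugate-Gaussian learning
chains, and OU-type SDE benchmarks. The default scenario family fixes
$b = 2$, $\bar X = 2$, $\beta' = 0$ and switches $g \in \{0, 1\}$ — the
reference parameter set for the sensor-off/sensor-on contrast. Passing tests
therefore demonstrate internal consistency of the theory and its numerics —
the update identities, the regime switch, the Langevin–Gibbs bridge — not
agreement with any measured single-cell data. Real sensing is nonlinear and
non-Gaussian beyond the linearization radius, real decision timescales may
not separate cleanly from environmental ones, and environment feedback with
memory (non-Markov coupling) is out of scope, as are multivariate internal
states beyond the independent-component product form
(`product_form_pmi()`).

## Known limitations

* Internal and external variables are one-dimensional; multi-component
  states enter only through the independence product form.
* The bimodal regime depends on the declared finite domain: its modes sit at
  the domain boundaries by construction.
* `beta_tilde()` is a truncation diagnostic, not a quantity entering the
  update; its printed integral definition is not well-posed for normalized
  conditionals on full supports.
* Euler–Maruyama is first order; the tests budget an $O(dt)$ bias allowance
  rather than using higher-order schemes.
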