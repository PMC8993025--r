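---
title: "Calibrating and scoring the graded response model, and comparing the choices predictively"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating and scoring the graded response model, and comparing the choices predictively}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`grmcv` implements the unidimensional graded response model (GRM) for
ordinal test responses, as used by functional-assessment instruments built
from Likert items. Person $p$ answers item $i$ in one of $J_i$ ordered
categories. With discrimination $\lambda_i > 0$, strictly increasing
thresholds $\tau_{i,2} < \dots < \tau_{i,J_i}$, and ability $\theta_p$,

$$\Pr(X_{pi} = j \mid \theta_p) =
  \frac{1}{1+e^{\lambda_i(\tau_{i,j}-\theta_p)}} -
  \frac{1}{1+e^{\lambda_i(\tau_{i,j+1}-\theta_p)}},$$

with the boundary conventions $\tau_{i,1} = -\infty$ and
$\tau_{i,J_i+1} = +\infty$, so the cumulative curves telescope and no
category needs special-casing. Each item carries its own $J_i$; nothing in
the package assumes a common category count.

The likelihood is invariant to a joint affine change of
$(\theta, \tau, \lambda)$, so a location and scale must come from
elsewhere. The two calibration routes resolve this differently, which drives
several design decisions discussed below.

## Calibration

**Marginal maximum likelihood (EM).** `calibrate_mml()` fixes the latent
density at $N(0,1)$ — imposing the scale — and maximizes the marginal
likelihood by Bock–Aitkin EM. The E-step evaluates each person's posterior
over a fixed quadrature grid (61 equally spaced nodes on $[-6, 6]$ with
renormalized normal weights); the M-step refits each item against its
expected category counts in the unconstrained parameterization
$(\log\lambda,\ \tau_2,\ \log\Delta_3,\dots)$, which enforces positivity and
threshold ordering without constrained optimization. Convergence is declared
when the marginal log-likelihood changes by less than `tol` ($10^{-5}$ by
default, 500-iteration cap); the trace is returned and is non-decreasing (EM
ascent), which the tests assert. Missing responses contribute nothing to
either step (missing-at-random). Calibration-time person scores are EAP
posterior means under the $N(0,1)$ latent.

**Bayesian hierarchical calibration.** `sample_posterior()` targets the full
posterior of the hierarchical model

$$\lambda_i \sim \mathrm{Cauchy}^+(0,5),\quad
  \tau_{i,j} \sim N(\mu_\tau, \sigma_\tau)\ \text{(ordered)},\quad
  \mu_\tau \sim N(0,5),\quad \sigma_\tau \sim \mathrm{Cauchy}^+(0,1),$$
$$\theta_p \sim N(0,\sigma),\qquad \sigma \sim \mathrm{Cauchy}^+(0,1).$$

The "ordered normal" reading of the threshold prior (rather than truncation
at zero) is deliberate: thresholds of function scales routinely span
negative values. Ordering is enforced by the same first-element +
log-increment transform, with its Jacobian included in the sampled density.

No probabilistic-programming backend is assumed: the log posterior and its
analytic gradient are implemented in C++ and sampled with Hamiltonian Monte
Carlo (dual-averaging step size targeting 0.8 acceptance, diagonal metric
estimated during warmup, jittered trajectory lengths up to `leapfrog`
steps). The gradient is verified against central finite differences, and the
density against an independently coded term-by-term oracle, in the test
suite. A mean-field Gaussian approximation fit by stochastic gradient ascent
is available behind `method = "advi"` for quick passes.

### The latent scale is only encouraged — and what we do about it

Because $\sigma$ is sampled rather than fixed, the model only *encourages* a
latent scale. The likelihood is exactly invariant under
$\lambda \to \lambda/c$, $(\tau, \mu_\tau, \sigma_\tau, \theta, \sigma) \to
c\,(\cdot)$, and along this flow the hierarchical normal densities cancel
against the volume element, leaving a weak net preference determined by the
$\lambda$ priors alone. Two consequences:

1. Plain HMC traverses this near-flat ridge very slowly. The sampler
   therefore interleaves an exact Metropolis move along the flow (with the
   Jacobian of the map in unconstrained coordinates), which mixes the scale
   direction cheaply, and initializes abilities at normal scores of mean
   item fractions so chains start on a sensible scale.
2. Raw-scale summaries (e.g. $\lambda_i$ alone) are weakly identified. The
   identified quantities are the scale-free combinations $\lambda_i\sigma$,
   $\tau_{i,j}/\sigma$, $\theta_p/\sigma$. `point_estimates()` therefore
   standardizes every draw to a unit-variance latent population by default,
   which puts the Bayesian bank on exactly the convention the MML route
   imposes — the two banks are interchangeable downstream — and convergence
   diagnostics (split $\widehat{R}$, effective sample size) are computed on
   these identified parameters. `standardize = FALSE` recovers raw
   summaries, which is what the prior-recovery test uses.

A fit is flagged non-converged when any item parameter has
$\widehat{R} > 1.05$; point extraction from such a fit warns rather than
fails.

## Scoring

Four estimators score a new respondent against a fixed bank, all returning
$(\hat\theta, \hat s)$ so downstream consumers can treat any score as the
Gaussian $N(\hat\theta, \hat s^2)$:

* `score_mle()` — maximum likelihood on a bounded interval
  ($[-6,6]$ by default); $\hat s = I(\hat\theta)^{-1/2}$ from the Fisher
  information (the Cramér–Rao bound). All-extreme patterns drive the ML
  estimate to a bound; it is pinned there and flagged.
* `score_wle()` — maximizer of $\ell(\theta) + \tfrac12\log I(\theta)$, the
  Jeffreys-mode weighted likelihood. For dichotomous two-parameter items
  this is exactly Warm's bias-corrected estimator; for polytomous items the
  original correction involves terms beyond what we adopt as a contract, so
  the Jeffreys form is named explicitly here and in the docs. It stays
  finite on all-extreme patterns.
* `score_eap_truncated()` — posterior mean under $N(0, 1)$ truncated to
  $[-B, B]$ with $B = 5$ by default. The bound is motivated by normal-tail
  rarity: under a unit-normal population, scores beyond $\pm 4$ SD occur
  about once in sixteen thousand respondents (`tail_odds(4)` ≈ 15,787) and
  beyond $\pm 5$ SD about once in 1.7 million, so the truncation loses
  essentially no mass while making extreme-pattern scores finite and
  shrunk. Both the SD and $B$ are configurable.
* `score_mml()` — maximizes the marginal likelihood of the responses over
  $\theta$ with the score variance imposed as $I(\theta)^{-1/2}$, iterated
  to a fixed point (tolerance $10^{-4}$, 50 iterations, initialized at the
  EAP estimate; non-convergence returns the last iterate, flagged).
  Integrating over the score distribution induces shrinkage comparable to
  EAP's.

Optimizers restart from $\{-2, 0, 2\}$ and break ties toward zero; item
parameters enter as point estimates only (their posterior uncertainty is
deliberately not propagated, matching how such instruments are deployed).

## The predictive deviance

To compare calibration-by-scoring pairings the package evaluates, on
held-out persons,

$$D = -2 \sum_{p} \sum_{i\ \mathrm{observed}}
  \log\left[ J_{\hat\theta_p, \hat s_p}(\lambda_i, \tau_{i,x_{pi}}) -
             J_{\hat\theta_p, \hat s_p}(\lambda_i, \tau_{i,x_{pi}+1}) \right],$$

where $J_{\theta,\sigma}(\lambda,\tau)$ is the logistic boundary curve
integrated over the Gaussian score approximation. That integral has no
closed form; it is approximated by
$\Phi\!\left(c\lambda(\theta-\tau)\big/\sqrt{1 + c^2\lambda^2\sigma^2}\right)$.

**Choice of the constant $c$.** The derivative-matched value
$\sqrt{\pi/8} \approx 0.6267$ and the minimax value $1/1.702 \approx 0.5876$
are both standard. We use $1/1.702$: category probabilities are differences
of two boundary curves, so approximation errors compound, and only the
minimax constant keeps the category-level error within the 0.02 absolute
tolerance the tests demand (measured maxima over
$\lambda \in [0.25,3], |\theta-\tau| \le 4, \sigma \in [0,2]$:
0.0095 boundary / 0.0180 category, versus 0.0176 / 0.0212 for
$\sqrt{\pi/8}$). Probabilities are floored at $10^{-12}$ before logs so the
deviance stays finite for arbitrarily extreme respondents.

`cross_validated_deviance()` partitions persons into $K$ seeded balanced
folds ($K$ is configurable per run; some instruments need $K=3$ for small
domains), calibrates on each complement with either route, scores the
held-out fold, and reports per-fold and total deviance.
`predictive_deviance(variance_mode = "point")` sets every $\hat s$ to zero —
by default still through the probit kernel, for exact continuity with the
full mode ($\sigma \to 0$ identity is tested); `exact_logistic = TRUE`
switches to the exact GRM probabilities. `holdout_deviance()` applies a bank
calibrated on one population to a disjoint (e.g. mean-shifted) population.
Held-out persons with no observed responses are dropped with a logged count.

## Synthetic data: what it emulates and what it does not

No real instrument responses ship with the package; `simulate_study()`
generates the study the methods expect: a Likert bank (slopes uniform on
$[0.8, 2.5]$, thresholds sorted within $[-2.5, 2.5]$ with a minimum gap of
0.1), a calibration ("claimant"-like) population $N(0,1)$ — the
identifiability convention — and a disjoint "control" population whose mean
is shifted by $+0.5$ (direction chosen so controls are healthier on a
function scale; the magnitude is a stand-in, as no effect size is published
for such shifts). Missingness is missing-completely-at-random; if masking
would silence a person entirely, one response is restored so every person
stays scorable.

The generator deliberately does **not** emulate: adaptive (CAT-style)
missingness, which is informative; differential item functioning;
multidimensional traits; or real item content. A green test therefore
establishes that the estimators and the deviance machinery behave as
specified on well-specified unidimensional data at desk scale (hundreds to a
thousand persons, 6–30 items) — not that any real instrument satisfies the
model.

## Numerical choices and degenerate inputs

* Probability floor $10^{-12}$ before every logarithm (configurable where it
  matters); quadrature grids: 61 nodes on $[-6,6]$ for calibration, 141 on
  $[-B,B]$ for EAP scoring (both configurable).
* EM M-step and HMC share the same unconstrained parameterization; both are
  exercised against oracles (finite differences; fine grids; adaptive
  quadrature) built before the implementations they check.
* Persons with all responses missing are unscorable: scoring a single such
  person errors; batch scoring returns an `NA` row, flags it, and logs the
  count.
* Items with an unobserved interior category abort MML calibration with the
  item and category named (collapse categories upstream if needed).
* A single-person calibration errors or returns a non-convergence flag —
  never a silent result.
* All randomness flows through explicit integer seeds (`make_folds`,
  generators, per-chain seeds `seed + chain - 1`); identical seeds give
  bit-identical EM results and draw-identical chains.

## Known limitations

* The HMC sampler is a purpose-built implementation, not a general PPL; very
  short chains can leave $\widehat{R}$ above threshold on hard problems, and
  the flag should be respected.
* The Jeffreys-mode WLE is one member of the weighted-likelihood family;
  polytomous Warm corrections differing at higher order would shift scores
  slightly.
* Score standard errors are asymptotic (Cramér–Rao) except for EAP, which
  reports the exact posterior SD under its truncated prior.
* Deviance comparisons across *different item sets* are out of scope, as are
  WAIC/AIC computation and CAT item selection.
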