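---
title: "Joint modelling of blood-pressure trajectories and time to chronic kidney disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of blood-pressure trajectories and time to chronic kidney disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpjoint)
```

## The scientific problem

Hypertensive patients under chronic care have their blood pressure (BP)
measured repeatedly — here, nominally every three months from the date of
diagnosis — while being at risk of developing chronic kidney disease
(CKD).  Treating the observed BP values as ordinary time-varying Cox
covariates ignores both measurement error and the informative link between
a patient's latent BP *trajectory* and their hazard.  The joint-modelling
framework resolves this by coupling linear mixed submodels for the
longitudinal outcomes with a proportional-hazards submodel through shared
random effects.

`bpjoint` implements this analysis chain end to end: cohort I/O and
eligibility screening, a synthetic-cohort generator with known truth,
descriptive survival statistics, mixed-model trajectory fitting, the
Bayesian multivariate joint model with five association structures, MCMC
convergence diagnostics, DIC/WAIC model comparison, and the closed-form
sample-size calculators used to design such a study.

## Model

For outcome $k$ (systolic, diastolic) of subject $i$, observed at times
$t$:

$$y_{ki}(t) = \eta_{ki}(t) + \varepsilon_{ki}(t), \qquad
\eta_{ki}(t) = x_{ki}^\top(t)\beta_k + z_{ki}^\top(t) b_{ki},$$

with $b_{ki} \sim N(0, D_k)$, $\varepsilon_{ki}(t) \sim N(0,
\sigma_{\varepsilon k}^2)$.  The time design is a natural cubic spline
with 3 columns (boundary knots at 0 and 120 months, interior knots at 40
and 80 by default; data-driven quantile knots otherwise), implemented from
truncated cubic powers so that its first derivative and running integral
are available in closed form.  Both the fixed and random designs carry the
intercept plus all three spline columns, matching the four random-effect
standard deviations reported for each outcome.

The hazard couples to the latent trajectories through association
functionals $f_{kl}$:

$$h_i(t) = h_0(t)\,
\exp\!\Big[\gamma^\top w_i + \sum_k \sum_l \alpha_{kl}
f_{kl}\big(\eta_{ki}(t)\big)\Big],$$

where $h_0$ is piecewise constant (12 intervals by default, knots at
event-time quantiles) and the five supported structures are the current
value, the slope, value-and-slope, the area, and area-and-value.

### Units and centering of the association terms

BP is modelled internally on a mmHg/10 scale (a systolic intercept near
12), so that reference trajectory coefficients on that scale are directly
usable as generator defaults.
The association functionals are defined as:

* **value**: $\eta_k(t) - c_k$, per 10 mmHg;
* **slope**: $10 \times 3 \times \eta_k'(t)$, i.e. the *quarterly* rate of
  change in mmHg — the scale on which slope hazard ratios are quoted
  ("per one mmHg change in the quarterly rate").  On the internal scale
  the quarterly slope varies by only a few hundredths of a unit across
  subjects and the coefficient would be numerically degenerate;
* **area**: $\int_0^t (\eta_k(s) - c_k)\,ds$, in (10 mmHg)·months.

The constants $c_k$ (defaults 11.2 and 8.7; the observed outcome means
when fitting) center the value and area terms.  Centering is a pure
reparameterization — the shift is absorbed exactly (value) or nearly
exactly (area) by the baseline heights — but it is numerically essential:
without it the hazard would contain $\exp(\alpha \cdot 12)$-scale factors
that overflow and stall the sampler.

### Priors

Fixed effects, survival coefficients and association coefficients get
normal priors with mean 0 and **precision** 0.001 (variance 1000).  The
analysis protocol this package encodes states the value 0.001 alongside an
explicitly noninformative intent, so it is read as a precision; the
literal variance reading (a prior SD of 0.03) would pin every coefficient
to zero and contradict that intent.  Both readings are selectable via `prior_spec(normal_0.001_is =
)`.  Residual variances get inverse-gamma(1, 0.005); baseline heights
independent gamma(0.01, 0.01); each outcome's random-effects covariance an
inverse-Wishart with identity scale and $q+1$ degrees of freedom.

## Computation

### Likelihood

The survival log-likelihood needs $\Lambda_i(T_i) = \int_0^{T_i} h_i(s)\,
ds$, evaluated by Gauss–Legendre quadrature (15 nodes per baseline
interval by default) on each baseline interval intersected with $[0,
T_i]$; segments longer than 30 months are subdivided so a long final
interval cannot degrade accuracy.  Doubling the node count changes no
subject's cumulative hazard by more than $10^{-6}$ on generator-scale
cohorts — this is verified in the test suite.  The synthetic generator
inverts exactly this evaluator (bracketing plus root refinement at
tolerance $10^{-10}$) to draw event times, so simulation and fitting share
one cumulative-hazard code path.

### Sampler

Metropolis-within-Gibbs.  Conjugate full conditionals are used wherever
they exist: inverse-gamma for the residual variances, inverse-Wishart for
the random-effect covariance blocks, and — deliberately going beyond a
random-walk update — the exact gamma full conditional for each baseline
height $\lambda_j$ given the event counts and hazard-weighted exposures.
The conjugate $\lambda$ update matters: the baseline heights are strongly
coupled to the association coefficients, and Gibbs steps remove that axis
of random-walk mixing entirely.

Everything else is adaptive random-walk Metropolis: per-outcome fixed
effects, the survival coefficients, the association coefficients (three
refreshes per sweep — the block is cheap because the hazard is linear in
$\alpha$), and the per-subject random effects, proposed for all subjects
simultaneously and accepted subject-by-subject.  Proposal shapes start
from the curvature of the separate mixed-model and Cox fits; during
burn-in a Haario-style running covariance refreshes the multivariate
proposal shapes and Robbins–Monro scaling targets acceptance rates of
0.234.  All adaptation freezes at the end of burn-in, so the retained
draws come from a fixed-kernel chain.  Initialization: trajectory
parameters and BLUPs from the maximum-likelihood mixed fits, survival
coefficients from the Cox screen, associations at zero, baseline heights
at crude interval event rates.

The protocol-scale settings (3 chains of 100,000 iterations, 25,000
burn-in, thinning 12) are the package defaults; the test suite and the
examples use far smaller runs, sized so the full suite completes in tens
of minutes on one core: recovery checks use 150-subject cohorts with 2
chains of 4,000 iterations, and model-comparison checks one chain of
2,000.

## The synthetic generator

`generator_config()` defaults encode the emulated study conditions:
408 subjects, quarterly visits, administrative censoring at 120 months,
independent exponential loss to follow-up at 0.0075/month, baseline
covariate prevalences matching the clinic population (e.g. diabetes
0.2991, positive proteinuria 0.3137, low HDL 0.3280; the fraction aged 65
or over is not reported and is set to 0.25), trajectory coefficients and
random-effect SDs from the reference longitudinal submodels it emulates,
hazard ratios from the reference survival submodel, and association
coefficients
$\log(6.25), \log(3.75), \log(4.32), \log(5.64)$ under value-and-slope.
The single baseline height (8e-6/month) was calibrated once so that the
defaults yield a ~14% cumulative event fraction and a median follow-up of
70 months — the cohort profile the generator emulates; the hypertension-duration effect
is interpreted per decade so that its reference coefficient implies a
clinically plausible 1.3 mmHg shift per 10 years.  A per-value missingness
probability of 0.002 makes roughly 9% of subjects incomplete, the complete-case
exclusion fraction the generator emulates.  All randomness flows from one seed
through named substreams (covariates, effects, event, censoring, noise,
missingness), so each stage is independently reproducible.

What the generator does *not* emulate: informative censoring, competing
risks (death before CKD), calendar-time effects, visit-time jitter, and
digit preference in recorded pressures.  Passing recovery tests therefore
demonstrates internal consistency of the machinery under the assumed
joint law, not robustness to these real-data features.

## What the simulations can and cannot show

With the full cohort size scaled down to 150 subjects the generator
yields roughly 20 events.  Two findings from the calibration experiments
are worth stating plainly:

* **Value associations** are recoverable: at ~430 subjects the posterior
  concentrates near truth, and at ~1,300 subjects both survival
  coefficients and value associations reproduce their generating values
  closely.
* **At 20 events the association posterior under the variance-1000 prior
  is nearly flat**, with a quasi-separation ridge: because the random
  effects are latent, large $|\alpha|$ can re-rank subjects' functionals
  to fit the few events at modest longitudinal cost, so chains legitimately
  wander tens of units.  Posterior means are then essentially arbitrary,
  and a 25%-relative-error recovery target cannot be met at that scale —
  the corresponding calibration check is expected to fail, and is retained
  unweakened as an honest record of this small-sample behaviour.  The
  slope associations are affected most, since the quarterly slope varies
  by well under one mmHg between subjects under the reference
  random-effect SDs.

Model selection is better behaved: WAIC (computed from per-draw subject
log-likelihood contributions; DIC from the plug-in deviance at the
posterior mean of all parameters including random effects) prefers the
generating value-and-slope structure over slope-only and area-only in the
large majority of seeds at the 150-subject scale.

## Design decisions

* **Sample-size quantiles.** The design's longitudinal sizes (393, 249)
  reproduce only under the conventional two-decimal quantiles 1.96 and
  0.84 with ceiling rounding; the exact quantile 0.8416 gives 393.35 →
  394.  `z_method = "rounded"` is therefore the default and the exact
  evaluation stays available.  The survival formula evaluates to 374.25
  (375 after rounding up), not the 373 the same design quotes; the
  calculator reports its own value.
* **Tie handling** in the Cox screen is Efron by default, Breslow by
  flag.  Incidence intervals are exact Poisson via chi-square quantiles;
  the cumulative-incidence proportion uses Clopper–Pearson.
* **Eligibility** drops subjects with missing/inconsistent outcome
  records, fewer than two BP measurements, or a baseline-CKD flag; the
  complete-case filter matches visits to the 3-month grid with a ±0.5
  month tolerance.
* **Imputation** is a single-model conditional-normal predictive draw
  from the fitted mixed model (the missing block given the observed block
  of $ZDZ^\top + \sigma^2 I$), not chained-equations multiple imputation;
  the $\sigma^2 \to 0$ limit is handled by a pseudo-inverse, and imputed
  pairs are nudged to respect the systolic > diastolic ordering.
* **Rhat** is the split rank-normalized variant; ESS uses Geyer's
  initial-monotone truncation.  WAIC is the primary ranking criterion,
  with DIC reported alongside.
* **Degenerate inputs**: zero-iteration MCMC runs return empty draw sets;
  constant chains report Rhat 1 by convention and a degenerate-ESS flag;
  monotone Cox likelihoods error with the offending covariate named.

## Limitations

Beyond the generator simplifications above: only Gaussian longitudinal
outcomes; at most the two BP outcomes are exercised (the architecture is
k-outcome but tests cover k = 1, 2); no dynamic individual prediction; no
competing risks; the cross-outcome random-effect covariance defaults to
block-diagonal with an optional intercept correlation, because only
per-outcome SDs are published.

## Appendix: why small-cohort association recovery fails

The failing calibration checks were diagnosed, not loosened.  The
sampler's cached likelihood matches an independent re-evaluation of its
visited states to within 4e-13, and on null-truth cohorts the chain
attains *higher* conditional joint log-likelihood than the generating
parameters themselves: with roughly 20 events, four association terms and
latent random effects, configurations with |alpha| of 10-35 and slightly
re-arranged random effects genuinely fit the data better than the truth.
Under the variance-1000 prior nothing penalizes that ridge.  The same
mechanism inflates null-truth credible intervals away from zero, so the
9-of-10 null-coverage target also fails at the 150-subject scale, while
the Schoenfeld calibration, the WAIC structure selection, and all exact
and oracle checks pass.  At roughly three times the cohort size the value
associations recover, and at ~1,300 subjects all coefficients do.
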