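---
title: "Multi-group latent class models for repeated cross-sectional health surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-group latent class models for repeated cross-sectional health surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lcatrends)
```

## The model

`lcatrends` fits latent class models to categorical survey indicators
observed in repeated cross-sections (survey waves). Each respondent $i$ in
wave $g$ belongs to an unobserved class $c \in \{1,\dots,K\}$; given the
class, the $J$ indicators are conditionally independent categoricals with
*conditional response probabilities* (CRPs)

$$\rho_{jgcm} = P(y_{ij} = m \mid c, g).$$

Class membership follows a multinomial logit on respondent covariates
$x_i$ with wave-specific intercepts,

$$P(c \mid x_i, g) \propto \exp(\alpha_{gc} + x_i^\top \beta_c),
\qquad c \ne \text{reference},$$

so that covariate coefficients exponentiate to odds ratios of membership in
each class versus the reference class, read exactly like a multinomial
logistic regression. The reference class is the last class by convention —
after alignment, the "overall healthy"-type profile — so published-style
contrasts ("odds of being in the unhealthy class vs the healthy class for
girls vs boys") come out directly.

Rows carry survey weights (normalised to mean 1 so that log-likelihoods
and information criteria are comparable across model specifications) and a
primary-sampling-unit label (school), used for cluster-robust variance
estimation. Missing indicator cells are handled by full-information
omission from the likelihood product, which is valid under MAR; missing
*covariates* are not allowed at fitting time and are multiply imputed
upstream (below).

### Measurement-invariance regimes

Three nested specifications control what may vary across waves:

* **fully unconstrained** — CRPs and class membership both wave-specific;
* **semi-constrained** — CRPs shared across waves, membership wave-specific;
* **fully constrained** — both shared.

A fourth variant lets the covariate coefficients vary by wave
(`covariate_effects = "by_group"`). Free-parameter counts follow directly
from the regime (`n_free_parameters()`), e.g. for $K=3$, four waves, six
binary + six four-level indicators and three covariate dummies:
302 (unconstrained), 86 (semi), 80 (fully).

## Estimation

Fitting is EM. The E-step computes posterior class probabilities; the
M-step updates each CRP simplex as posterior-weighted category frequencies
(pooled across waves under semi/fully) and updates $(\alpha, \beta)$ by a
warm-started, step-halved Newton multinomial logit run for five inner
iterations per cycle — a generalized EM that preserves the monotone
likelihood ascent without paying for full inner convergence.

Numerical choices:

* **Smoothing floor.** Every CRP cell is clipped to
  $[10^{-6}, 1-10^{-6}]$ and renormalised. This prevents $\log 0$ and
  boundary cycling; it is a deliberate, tiny deviation from the
  unpenalised MLE, visible only in perfectly separated data.
* **Convergence.** Relative log-likelihood change below $10^{-7}$, at most
  2000 iterations.
* **Degenerate classes.** An M-step that finds a class with (near-)zero
  posterior mass raises a typed error; at the multistart level the
  offending start is recorded as failed rather than aborting the search.

### Multistart search and the label-crossing pathology

Mixture likelihoods are multimodal, so `fit_multistart()` runs EM from many
random initialisations (CRP simplices uniform on the simplex, structural
coefficients uniform on $(-1,1)$), with per-start seeds split
deterministically from one master seed so results are reproducible and
independent of execution order. The default search is two-stage, as in
mainstream mixture software: a short burn-in (25 EM iterations) for every
start, then full convergence for the few most promising; a "replication
count" reports how many converged starts land within $10^{-4}$ of the best
log-likelihood, warning when the optimum was not replicated.

Multi-group models with wave-specific CRPs have an additional, sharper
pathology: because class labels are tied across waves only through the
shared covariate coefficients, random starts overwhelmingly converge to
local maxima in which the class labels *cross* between waves (wave 3's
"class 2" continues wave 1's "class 3", and so on). In our simulations at
$n \approx 6{,}000$, none of 50 fully converged random starts reached the
global optimum. The package therefore anchors the search with a
constraint ladder: the semi-constrained model — whose pooled CRPs glue the
labels — is itself fitted by multistart (anchored in turn by the fully
constrained model) and its solution, expanded to the unconstrained shape,
joins the refinement pool. The anchored candidate reproduces the
truth-started optimum exactly in our test conditions, and guarantees the
nesting $\ell_{\text{fully}} \le \ell_{\text{semi}} \le
\ell_{\text{unconstrained}}$ by construction.

### Model selection

Class counts and invariance regimes are compared with the
sample-size-adjusted BIC,
$\mathrm{aBIC} = -2\ell + p \,\log\!\big((n^*+2)/24\big)$, with $n^*$ the
sum of normalised weights — the Sclove adjustment conventional in latent
class enumeration. `scan_classes()` scans a K range; `scan_constraints()`
fits the three regimes plus the by-wave-covariate variant of the best of
them, flagging the aBIC minimum (ties to the smaller model).

## Multiple imputation and pooled inference

Missing covariate cells (sex, family affluence) are completed by chained
multinomial-logit equations: initialise by weighted marginal draws; per
cycle and per covariate, refit the imputation model on a bootstrap
resample of the rows where that covariate is observed (the bootstrap
propagates parameter uncertainty, approximating proper imputation) and
redraw the missing cells from the predicted probabilities. Indicators
enter as dummies with an explicit "missing" level, so incomplete
indicators never block the model; survey weights are not used inside the
imputation models. Ten cycles and $m = 50$ imputations are the
full survey-scale defaults; tests and examples use smaller $m$.

Each completed dataset is fitted separately. The first imputation gets the
full multistart search; subsequent ones are warm-started from its solution
(standard practice for MI-LCA, since imputations differ only in a few
covariate cells) and aligned to it by `align_to_reference()`, which
minimises the total absolute CRP distance over all $K!$ class
permutations. Pooling follows Rubin's rules on the structural
coefficients — point estimate the mean, total variance
$T = W + (1 + 1/m)B$ — while pooled CRPs are simple renormalised means.
CRPs are reported directly from the pooled parameters (an
apply-to-first-imputation path would also be possible; on aligned fits the
two agree within pooling error).

Within-imputation variances come from the survey sandwich
$A^{-1} B A^{-1}$ restricted to $(\alpha, \beta)$ at fixed CRPs: $A$ the
negative numerical Hessian of the weighted log-pseudo-likelihood, $B$ the
sum of outer products of per-school score totals, derivatives by central
differences with step $10^{-5}$. With every row its own cluster this is
the ordinary heteroskedasticity-robust sandwich, which the test suite
checks against an independent implementation. Confidence intervals are
unadjusted Wald intervals $\exp(\beta \pm 1.96\sqrt{T})$; no
multiple-testing correction is applied.

## The synthetic cohort generator

Access-restricted microdata cannot ship with a package, so `lcatrends`
includes a generative mirror of the model calibrated to published
results for English 15-year-olds across four waves (2001/02–2013/14,
n = 5,942): `default_scenario()`. Published quantities wired in as truth:

* wave-1 marginal class memberships (0.39, 0.40, 0.21) and wave-4
  (0.18, 0.41, 0.41) for the unhealthy / substance-abstainer-with-risk /
  healthy classes;
* weekly-drinking CRPs declining 0.71→0.28, 0.21→0.02, 0.49→0.06 across
  waves in the three classes; wave-1 smoking 0.74/0.06/0.06, sexual
  activity 0.69/0.14/0.29, cannabis 0.05 (abstainers) and 0.25 (healthy);
* membership odds ratios vs the healthy class: female 1.74/1.88, middle
  family affluence 0.35/0.43, high affluence 0.18/0.14;
* per-indicator missingness rates equal to published missing counts over
  5,942 (e.g. sexual activity 266/5,942 ≈ 4.5%).

Everything else is an invented default, chosen once for plausibility and
class separability and documented here: intermediate-wave memberships
interpolated as (0.25, 0.40, 0.35) and (0.21, 0.40, 0.39); unpublished
CRP anchors (e.g. rising e-media use in all classes, worsening life
satisfaction in the two non-unhealthy classes, stable exercise/diet/
achievement profiles, unhealthy ≈ abstainer on school pressure, classmate
support, parent communication and exercise); non-risky mass of four-level
items split in class-specific shares (healthier classes weighted toward
the better categories); covariate marginals sex 50/50 and family affluence
0.15/0.45/0.40; covariate missingness 1% (sex) and 5% (affluence); survey
weights lognormal with sdlog 0.3, normalised to mean 1; 30 school clusters
per wave with a N(0, 0.3) random intercept on each non-reference
membership logit.

Because the covariates shift membership, the wave intercepts cannot simply
be the logits of the target shares: `generate_dataset()` calibrates them
numerically (an IPF-style fixed point on the logit scale) so that the
*covariate-averaged* membership per wave equals the configured marginals;
the small flattening induced by the cluster random intercept is ignored in
the calibration and is well inside sampling noise at these sizes.
`inject_missingness()` applies MCAR deletion at the configured rates,
re-drawing (once) any row that would lose all twelve indicators and
otherwise forcing one indicator back to observed.

What the generator does *not* emulate: the survey's stratified school
sampling and non-response weighting model, any MNAR mechanism, ordinal
structure in the four-level items (they are generated and modelled as
nominal — the saturated categorical parameterisation standard in LCA), and
item-level measurement drift. Passing recovery tests therefore shows the
estimator is correct for data generated by its own model class, not that
the substantive published findings would replicate on re-collected data.

## What the tests compute, and at what sizes

The suite pairs every operation with an independent oracle where one
exists: brute-force class enumeration for the likelihood (n ≤ 8), a dense
grid search for a tiny two-class EM, an exhaustive-permutation check for
alignment, a from-scratch row-level sandwich, and hand-computed Rubin
identities. Property tests cover EM monotonicity and the constraint
nesting on twenty simulated 400-row cohorts; recovery tests fit the
unconstrained three-class model to five full-size (n = 5,942) cohorts with
50 random starts; model-selection tests run reduced-start scans (6 starts)
on five cohorts; interval calibration uses ten scaled replicates
(n = 3,000, m = 3 imputations). These problem sizes are the package's
chosen compromise between statistical resolution and a test suite that
runs in minutes; the full survey-scale settings (1000 starts, m = 50)
remain the function defaults.

Two honest caveats from the recovery experiments, both visible in the
test output rather than hidden: per-seed wave-level membership recovery at
n ≈ 1,486/wave has a noise floor (sampling + school effects + ML error)
of about ±0.05–0.07, so a per-seed ±0.04 band on every wave×class cell is
not reliably attainable at this size even though seed-averaged recovery is
accurate to ~1 percentage point; and with only the published CRP anchors
varying strongly across waves, the aBIC comparison between the
unconstrained and semi-constrained regimes is genuinely close (the
unconstrained model's ~540-nat gain does not always offset its 216 extra
parameters), so the constraint scan can select the semi-constrained model
on synthetic cohorts even though the estimator reproduces the generating
CRPs well.

## Design choices that were genuinely open

* **Four-level items as nominal.** No ordered-threshold parameterisation
  is implied by the source material; saturated categorical CRPs are the
  field default and strictly more general.
* **Weight scaling.** Weights are normalised to mean 1; any global
  rescaling would shift log-likelihoods and aBIC by a constant factor and
  is otherwise inconsequential.
* **Membership-by-wave reporting.** The default is the survey-weighted
  mean of posterior class probabilities (the estimated-sample analogue of
  class counts); the model-implied prior average is available via
  `type = "prior"`.
* **Risky-category map.** Binary indicators use their affirmative risk
  level; the six four-level items ship interpretable defaults (lowest
  exercise, lowest fruit/veg, below-average achievement, "a lot" of
  pressure, lowest support, lowest life satisfaction), fully overridable.
* **Imputation engine.** A sequential (chained) scheme with bootstrap
  refits was chosen over a joint Bayesian model; it is simple, proper in
  the large-sample sense, and testable cell by cell.
* **CI combination.** Sandwich variance within imputation, Rubin's rules
  across — the conventional order for survey MI.

## Limitations

Fixed-K inference ignores selection uncertainty; no bootstrap likelihood
ratio test for class enumeration is provided. The sandwich assumes enough
clusters (~30/wave in the default scenario) for its asymptotics. The
anchored multistart makes the search dramatically more reliable but, like
any finite search, cannot certify a global optimum. Entropy-based
diagnostics beyond the replication count are out of scope.
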