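---
title: "Calibration by double sampling: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration by double sampling: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegcalib)
```

## The problem

Long-term vegetation monitoring frequently has to compare a coarse,
subjective historical survey with a quantitative contemporary one. In the
setting this package targets, sites along a creek system were scored in the
mid-1990s on categorical scales — tree densities as "None / Some / Much",
understorey composition as four parts ("mostly native", "mostly weedy",
"50/50", "bare ground") estimated to the nearest 5% and summing to 100% —
while the contemporary survey measured the same attributes with
point-intercept transects (hits out of points) and belt-quadrat tree counts
over known areas. Estimating change between the two periods requires a
quantitative reinterpretation of the categorical scores, with honest
uncertainty.

`vegcalib` implements two reinterpretation strategies:

* **Calibration by double sampling.** A subset of contemporary sites is
  surveyed with *both* methods at (nearly) the same time. The relationship
  between the categorical scores and the quantitative responses, learned at
  those sites, converts the whole historical dataset onto the contemporary
  scale.
* **Bayesian reinterpretation without calibration.** No double-sampled data;
  the categorical score only constrains the latent historical value through
  an informative prior.

## The joint model

The calibration model is a single hierarchical graph with three layers,
fitted jointly by MCMC (JAGS via `rjags`).

**Calibration.** At double-sampled site $k$, the quantitative response is
$R_k \sim \mathrm{Binomial}(m_k, q_k)$ for cover attributes (hits always
enter as counts from points, never pre-reduced to proportions, so sites with
more points carry more information) or
$R_k \sim \mathrm{Poisson}(A_k\, q_k)$ for densities with sampled area
$A_k$. On the link scale (cloglog for proportions, log for densities),

$$\mathrm{link}(q_k) = a + b\, x_k + c^\top z_k + \eta_k, \qquad
  \eta_k \sim N(0, \sigma_\eta),$$

where $x_k$ is the link-transformed *latent* value behind the simultaneous
categorical score, $z_k$ are centred site covariates, and $\eta_k$ absorbs
between-site discrepancy between the two methods.

**Prediction.** The same intercept and coefficients, applied to the latent
values behind the *historical* scores, give the calibrated historical value
$r_i$ for every site, with its own site deviation $\epsilon_i$.

**Change.** The contemporary value $p_i$ equals the calibrated historical
value plus change, additively on the link scale:
$\mathrm{link}(p_i) = \mathrm{link}(r_i) + \alpha_i + \gamma T_i$, with
$\alpha_i \sim N(\mu, \sigma)$ and $T_i$ the day-of-year offset between the
site's two surveys (cover attributes vary seasonally; the season coefficient
defaults to on for proportions and off for tree densities). The contemporary
observations $Y_i$ are binomial or Poisson around $p_i$. Change is reported
as $100\, p_i / r_i$, so 100% means no change; the per-site point estimate
is the posterior mean of the percentage (not the percentage of posterior
means), and the grand mean summarises the across-site average per draw.

The cloglog link is the default for cover because it is asymmetric (suited
to skewed cover data) and, in this model family, mixes much better than the
logit, which is nevertheless retained behind `link = "logit"`; switching
links changes only the link operation in the generated code.

### Informative priors over latent historical values

A score constrains its latent value through one of four prior forms:

| form | construction | spread |
|---|---|---|
| `midpoint` | point mass at the category midpoint | none |
| `uniform` | flat over the category's range | category width |
| `normal` | moments of a link-transformed reference dataset | reference SD |
| `truncated_normal` | reference normal restricted to the category range | both |

Prior parameters live on the link scale, matching the linear predictor the
latent value enters. Category ranges come from the scoring systems: density
categories split at 40 stems/ha (medium trees) and 50 stems/ha (recruits);
composition scores carry a half-resolution (±2.5%) window. Two boundary
conventions needed decisions the scoring sheets do not make:

* the open-ended "Much" category needs a cap before a midpoint or uniform
  range exists; the default is ten times the finite boundary (400 and
  500 stems/ha), configurable per attribute;
* "None" is literally a count of zero, a point — usable by the midpoint
  form but not by a distribution. Spread-carrying forms read "None" as
  *below detection*: support $(0, z]$ with `zero_cap` $z = 1$ stem/ha by
  default. The midpoint form keeps the literal zero, which is exactly what
  produces its documented pathology (below).

Overlapping (widened) ranges as a misclassification allowance are
implemented (`overlap`) but default to 0; they made little practical
difference in the study this design follows. The `normal` form is most
useful when the reference is an *external* dataset; built from the
contemporary data themselves it pins the historical values to the
contemporary distribution and, by construction, estimates almost no change —
the package reproduces this degeneracy in its test suite, and normal priors
are rejected in the calibration model when no reference is available.

### Zeros and small constants

Observed zero proportions and densities have no finite link transform.
Before transforming, observations are nudged by half the smallest observable
nonzero value: $1/(2\,\mathrm{points})$ for proportions and $0.5/A$ for
counts. The generator and model builders additionally close the open
link-scale ends of edge scoring bins with floors `p_floor` (5e-4 on the
proportion scale) and `d_floor` (0.05 stems/ha). Percentage-of-historical is
undefined at a historical value of exactly zero; `percentage_of_historical()`
insists on an explicit epsilon in that case, and the sensitivity of
midpoint-prior results to that epsilon is treated as a property worth
testing, not a nuisance.

## Sampling design choices

Two parameterisation choices matter for MCMC efficiency and are invisible in
the results:

* **Marginalised site deviations.** At sites that were never double
  sampled, the prediction deviation $\epsilon_i$ and the change term
  $\alpha_i$ enter only through their sum, so the sampler works with
  $w_i = \epsilon_i + \alpha_i \sim N(\mu, \sigma^2 + \sigma_\eta^2)$.
  When per-site historical values are needed, `summarize_change()`
  reconstructs $\epsilon_i \mid w_i$ by exact Gaussian conditioning. We set
  $\mathrm{sd}(\epsilon) = \sigma_\eta$: both deviations express the same
  observer-method discrepancy process, once per survey period; the data
  cannot separate them at uncalibrated sites, and the calibration block
  identifies $\sigma_\eta$.
* **Centred intercept.** The sampled intercept is offset by
  $b \cdot \overline{x}$ (the mean latent-bin midpoint), decorrelating it
  from the slope; the natural-scale intercept $a$ is monitored as a
  deterministic node.

Default fitting settings are 4 chains, 2,000 warmup and 2,000 retained
iterations with an R-hat threshold of 1.01; a fit that misses the thresholds
is returned with a prominent warning, never silently. The simulation
harnesses in this package (recovery, cross-validation, the acceptance
script) explicitly pass reduced settings — typically 2 chains with a few
hundred adaptation and burn-in iterations at 40–180 sites — which are
adequate for the aggregate quantities they check while keeping a full
recovery study in minutes on one core. The intercept–mean-change pair mixes
slowest (they are separated only by the 60-pair calibration block); treat
flagged single fits accordingly.

Deviance summaries report both DIC conventions: `dic_paper = Dhat + pD`
(equal to the posterior mean deviance, matching the arithmetic of the
model-selection table layout this package mirrors) and the standard
`dic_standard = Dhat + 2 pD`; ranking uses the former by default. The
intercept-only null in such tables carries no site effect $\eta$ — with
$\eta$ retained the calibration block is per-site saturated and the null is
not a null.

## What the synthetic generator emulates — and what it does not

There is no packaged field dataset; `simulate_survey()` provides study-shaped
data: ~180 sites strung over ~200 km of creek, areas 0.5–19.9 ha, one third
double-sampled within 14 days of the contemporary survey, point counts per
site lognormal around a median of 382 (clipped to 105–846), belt-quadrat
areas from a 4 m-belt transect layout, binary site descriptors, day-of-year
offsets, and management states covering the five named grazing transitions
(licence × fence at two periods). True attribute values are Beta- (cover)
or zero-inflated-Gamma- (densities) distributed stand-ins: the real study
system's distributions are unknown, and these defaults are chosen once for
testability, not as estimates of the study area.

Two generation modes differ in where the latent predictor values come from:

* `"observer"` (default): a perceived subjective state underlies each
  score; at double-sampled sites it inverts the true calibration regression
  at the site's contemporary value, so both methods measure the same
  vegetation. This is the realistic mode used for cross-validation
  comparisons and pathology checks.
* `"from_model"`: ancestral simulation of the model graph itself — given
  the scores, latents are drawn uniformly within the scored bin on the link
  scale. Recovery and coverage experiments use this mode, because they test
  the estimator against the model's own assumptions.

The distinction matters: under the observer mode the uniform-in-bin prior is
mildly misspecified in the wide edge bins (scores near 0% or 100% cover),
which attenuates the calibration slope by a few percent — an
errors-in-variables property of the method itself, visible only because the
generator knows the truth. Real-data analyses inherit this caveat, and
passing recovery tests in `"from_model"` mode does not certify against it.

The generator also deliberately omits: spatial autocorrelation along the
creek, flood and drought dynamics, multi-observer variation (the study
design assumed a single returning observer), and any relationship between
management class and the change term (management contrasts in synthetic
summaries are null by construction). One targeted exception exists:
`pulse_prob` injects episodic recruitment at historically bare density
sites — the kind of event (mass germination after rain or flooding) that a
multiplicative change model cannot produce from a zero baseline. It is off
by default and exists to probe how prior forms behave at score-zero sites:
with pulses on, midpoint-prior percentage changes at those sites are extreme
and scale inversely with the zero-replacement epsilon, while
truncated-normal ones stay bounded and insensitive — the strongest practical
argument against midpoint reinterpretation.

## Evaluation tooling

* `crossvalidate()` holds out ten percent of units per fold (the
  double-sampled pairs' quantitative responses for the calibration model;
  contemporary site responses for the non-calibration model), refits, and
  pools held-out posterior-mean predictions across folds before computing
  one Pearson correlation with a Fisher-z interval (per-fold correlations
  are also kept). Fold exclusion is judged on the R-hat of the held-out
  prediction nodes: in the non-calibration cover model the change SD and
  residual SD are additively confounded and mix slowly without affecting
  the predictions, and excluding folds on that basis would discard sound
  predictions.
* `recovery_experiment()` wraps the simulate-refit loop and reports bias,
  RMSE and credible-interval coverage per parameter.
* `summarize_change()` produces per-site, grand-mean and per-management-
  class percentage-of-historical summaries with nested 50%/95% intervals.
* `dic_table()` reproduces the familiar model-selection table layout
  (response, covariate set, Dhat, DIC, pD).

## Known limitations

* The calibration and non-calibration models assume the observer's biases
  are stable between periods (one returning surveyor); multi-observer error
  is out of scope.
* Attributes are fitted independently; no strength is shared across
  attributes, and nativeness composition parts are treated as independent
  latents when both enter one model.
* DIC for hierarchical latent-variable models depends on the focus of the
  deviance; this package focuses on the observation-level parameters, and
  `pD` can be negative for pathological fits (reported as computed, with a
  flag).
* The intercept–mean-change ridge limits how short chains can be for single
  production fits; rely on the convergence flags.
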