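# vegcalib

Hierarchical Bayesian calibration by double sampling, for estimating
vegetation change when a coarse categorical historical survey must be
compared with a quantitative contemporary survey.

## The problem

Ecological monitoring often spans decades, and the survey methods rarely
survive that long unchanged. A 1990s survey may have scored tree density as
"None / Some (< 40 per ha) / Much (> 40 per ha)" and understorey composition
as four visually estimated parts summing to 100%, while the follow-up survey
measured the same attributes with point-intercept transects (hits out of
points) and belt-quadrat counts over known areas. Estimating change between
the two requires converting categorical scores to the quantitative scale —
and the common shortcut, replacing each score by its category midpoint,
invents precision that was never observed.

`vegcalib` implements and compares two principled alternatives:

* **Calibration by double sampling** — a subset of contemporary sites is
  surveyed with *both* methods at the same time; the joint three-part model
  (calibration → prediction → change) learns the relationship between
  methods and converts the historical data with uncertainty. For cover,

  cloglog(q_k) = a + b·x_k + c·z_k + η_k,  R_k ~ Binomial(m_k, q_k)

  at double-sampled sites (x_k the link-scale latent value behind the
  categorical score, η_k between-site method discrepancy), the same
  coefficients predict each site's calibrated historical value r_i, and
  change is additive on the link scale:
  cloglog(p_i) = cloglog(r_i) + α_i + γ·T_i with α_i ~ N(μ, σ) and T_i the
  day-of-year offset between surveys. Densities use a Poisson likelihood
  with a log link and sampled-area offset.
* **Bayesian reinterpretation (non-calibration)** — no double sampling; the
  latent historical value is constrained only by an informative prior
  implied by its score: `midpoint`, `uniform` over the category range,
  `normal` from a reference dataset, or `truncated_normal` (the reference
  normal restricted to the category range).

Change is reported as a percentage of the historical value (100% = no
change), per site, overall, and by grazing-management transition
(licence × fence at the two periods). Models are fitted by MCMC with JAGS
(`rjags`), with R-hat/ESS diagnostics, DIC model comparison (both the
`Dhat + pD` and `Dhat + 2·pD` conventions), k-fold cross-validation with
Fisher-z correlation intervals, and a seeded synthetic-data generator in
place of the (unreleased) field data.

## Worked example

Simulate a 60-site study (one third double-sampled), fit the calibration
model with a truncated-normal prior on the latent historical scores, and
summarise change by management class:

```r
library(vegcalib)

dat <- simulate_survey(generator_config(n_sites = 60, seed = 42,
                                        attributes = "nativeness"))
mod <- build_calibration_change_model(dat, "nativeness",
                                      prior_form = "truncated_normal",
                                      site_covariates = "distance_upstream")
fit <- fit_model(mod, fit_config(chains = 2, adapt = 800, burnin = 800,
                                 iterations = 1500, seed = 43))
posterior_summary(fit)[, c("parameter", "mean", "sd", "q2.5", "q97.5")]
#>   parameter          mean          sd         q2.5        q97.5
#> 1         a  0.2510931425 0.087898924  0.079056859  0.426601781
#> 2         b  0.7813011231 0.047667853  0.681427080  0.873772596
#> 3         c -0.2786257401 0.095592207 -0.443359654 -0.069064690
#> 4     gamma -0.0008022999 0.001757369 -0.004363564  0.002121385
#> 5        mu -0.0124705347 0.094567486 -0.200882910  0.166785079
#> 6    sd_eta  0.3001378357 0.064810619  0.198430102  0.452130563
#> 7     sigma  0.3808877786 0.099602403  0.117404875  0.547364202

summarize_change(fit, data = dat, group_by = "management")
#> <vc_change_summary> nativeness | prior: truncated_normal
#>   grand mean % of historical: 101.5 (95% CrI 90.3, 112.2)
#>   management classes:
#>                          class n_sites  mean  q2.5    q25    q75 q97.5
#>         Licence, install fence      10 107.9 90.18 101.43 113.99 127.1
#>                          other       9  99.9 88.35  95.29 104.07 113.8
#>              Licence, no fence       9 102.9 87.06  96.78 108.64 121.5
#>  Revoke licence, install fence      10 102.3 88.16  97.01 107.12 118.7
#>          Revoke licence, fence      12 101.5 87.82  96.42 106.37 116.4
#>              No licence, fence      10  94.5 81.17  89.28  99.41 110.5
```

Reading the output: `b` is the slope linking the link-scale latent score to
the quantitative response (near the generator's true 0.8); `sd_eta` is the
between-site method discrepancy; `mu`/`sigma` govern site-level change on
the cloglog scale, and the grand mean of 101.5% with a credible interval
spanning 100% correctly reports "no detectable overall change" for data
generated with a small true mean change. At these deliberately short chain
lengths the fit warns that two parameters miss the strict R-hat ≤ 1.01
threshold — fits never fail silently; the packaged defaults
(`fit_config()`) are 4 chains × 2,000/2,000.

Cross-validated comparison of the two approaches:

```r
cv_cal <- crossvalidate(dat, "nativeness", "calibration",
                        prior_form = "truncated_normal", k = 10,
                        config = fit_config(chains = 2, adapt = 600,
                                            burnin = 600, iterations = 1000,
                                            seed = 44))
cv_cal$r   # pooled held-out Pearson r of predicted vs observed cover
```

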