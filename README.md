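# bopmeta

Dose–response meta-regression and burden-of-proof evidence scoring for
risk–outcome pairs, in R.

Epidemiological evidence for diet–disease associations arrives as
study-level tables: each prospective cohort compares disease risk in higher
consumption categories against its lowest-consumption reference and reports
a relative risk (RR, OR, or HR) with a 95% CI. Classical meta-analysis pools
these into a mean effect but says little about how much of that effect
could be an artifact of between-study inconsistency, study-design bias, or
publication bias. `bopmeta` implements the burden-of-proof approach to both
problems at once: it estimates a non-linear mean risk curve *and* scores
the strength of the evidence behind it.

## The model

For observation *i* in study *s*, with reference interval *R*ᵢ and
alternative interval *A*ᵢ (g/day), the log effect size is modelled as

  yᵢ = (β + uₛ) · sᵢ + Σⱼ δⱼ xᵢⱼ · sᵢ + εᵢ,  uₛ ~ N(0, γ),  εᵢ ~ N(0, σᵢ²)

where the *signal* sᵢ = avg_{A_i} f − avg_{R_i} f is the difference of the
interval-averaged spline curve f(x), a quadratic spline with two interior
knots, anchored at f(0) = 0, constrained monotone non-increasing with a
linear right tail (the protective-risk configuration). The curve is fit by
trimmed weighted least squares (10% of observations trimmed by default);
study-design covariates xᵢⱼ that significantly bias the effect are retained
as multiplicative adjustments; β and the heterogeneity γ are estimated by
profile maximum likelihood, with a Fisher-information standard error on γ
guarding against underestimated heterogeneity when studies are few
(γ\* = γ̂ + z₀.₉₅·se(γ̂)).

Evidence strength is summarised by the **burden-of-proof risk function**
(BPRF) — the 95th-quantile log-RR curve closest to the null once γ\* is
included, i.e. the weakest association consistent with the data — and the
**risk–outcome score** (ROS): the signed mean of the log-BPRF over the 15th
to 85th percentiles of observed exposure. The ROS maps to a 1–5 star
rating via published percent-change cut points (protective: 0–13%,
>13–34%, >34–46%, >46% for 2–5 stars; non-positive ROS is one star). The
theoretical minimum risk exposure level (TMREL) is the 85th percentile of
the highest-consumption categories across studies. A modified Egger's
regression (residuals against heterogeneity-inflated standard deviations)
screens for small-study and publication bias.

## Worked example

The package ships a synthetic cohort generator that emulates the structure
of extracted dose–response literature (quantile-based exposure categories,
CI-derived standard errors, study-level random slopes), so the full
pipeline runs without external data:

```r
library(bopmeta)

sim    <- simulate_study_table(sim_config(n_studies = 20, seed = 42))
report <- run_pipeline(pipeline_config(seed = 42), data = sim$table)
report
#> Burden-of-proof pipeline report
#>   71 observations, 20 studies, outcome `synthetic_outcome`
#>   beta = 1.0000 (SE 0.0839), gamma_hat = 0.00000, gamma* = 0.06327
#>   ROS = 0.13 (2 stars, protective), averaged over [125.5, 419.6] g/day
#>   TMREL 367-558 g/day; risk at TMREL midpoint 21.5% (11.0-30.7) lower than at 0 g/day
#>   Egger slope 1.186, p = 0.069 (not flagged)
```

Reading the output: the fitted scaling β ≈ 1 says the spline signal already
matches the data; γ̂ = 0 but the Fisher-corrected γ\* = 0.063 keeps honest
uncertainty about between-study heterogeneity given only 20 cohorts. The
ROS of 0.13 means that, under the most conservative (95th-quantile)
reading of the evidence, average exposure is associated with a
1 − e^(−0.13) ≈ 12% lower risk than zero exposure — a two-star
association. Fitted objects follow broom conventions:

```r
glance(report$mixed_fit)
#> # A tibble: 1 × 7
#>    beta se_beta gamma_hat se_gamma logLik n_obs n_studies
#>   <dbl>   <dbl>     <dbl>    <dbl>  <dbl> <int>     <int>
#> 1     1  0.0839         0   0.0385   62.9    64        20

percent_change(report$risk_curve, 0, 100)   # % lower risk at 100 vs 0 g/day
#> # A tibble: 1 × 5
#>    mean conventional_lo conventional_hi conservative_lo conservative_hi
#>   <dbl>           <dbl>           <dbl>           <dbl>           <dbl>
#> 1  15.0            12.7            17.2            7.50            21.9
```

`autoplot(report$signal_fit)`, `autoplot(report$risk_curve)` and
`autoplot(report$egger)` draw the risk-curve and modified funnel figures;
`sensitivity_suite()` reruns the analysis without trimming and with a
forced bias covariate.

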