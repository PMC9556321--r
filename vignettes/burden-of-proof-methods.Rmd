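---
title: "Dose-response meta-regression and burden-of-proof scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response meta-regression and burden-of-proof scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bopmeta)
```

This vignette documents the statistical model behind `bopmeta`, the
numerical choices made where several implementations were defensible, and
what the synthetic-data tests do and do not establish about behaviour on
real extracted literature data.

## Data model

The unit of analysis is one exposure comparison extracted from a cohort
study: a reference interval and an alternative interval of consumption
(g/day), a relative measure (RR, OR, or HR) with a 95% CI, counts, and
binary study-design covariates (`cv_*` columns). Relative measures are
modelled on the natural-log scale; the standard error comes from the CI
under log-scale symmetry, `se = (log(hi) - log(lo)) / (2 * qnorm(0.975))`.
HR and OR are treated as RR on the log scale without transformation — the
measure type is instead available as a candidate bias covariate, which
lets the data decide whether the measure systematically shifts the effect.

Exposure standardization follows fixed rules applied in order: serving
counts convert at the study's serving size, defaulting to 77 g per serving
when none is defined; an undefined lower bound becomes 0 g/day; an
undefined upper bound is closed by adding the width of the study's
adjacent closed category; ladders reported only as per-category means are
cut at midpoints between adjacent means. Two conventions the sources leave
open: when the adjacent category is itself open we would fall back to the
widest closed category of the same cohort, and the midpoint rule is applied
only to fully means-based ladders (mixed mean/range ladders use the ranges
they report and the open-bound rules for the rest).

## The signal curve

The non-linear exposure-response shape ("signal") is a quadratic spline
$f(x)$ on $[0, x_{\max}]$ with two interior knots, under the
protective-risk configuration: $f(0) = 0$ (so the curve reads as log RR
versus zero exposure), $f' \le 0$ everywhere, and zero curvature right of
the last interior knot. Because extracted observations compare interval
*averages* rather than points, the per-observation signal is
$s_i = \frac{1}{|A_i|}\int_{A_i} f - \frac{1}{|R_i|}\int_{R_i} f$,
computed by exact piecewise-polynomial integration.

**Parameterisation.** The spline is parameterised by the values of its
derivative at the knots. For a quadratic spline the derivative is
continuous piecewise linear, so this makes all three constraints exact
rather than grid-approximate: the anchor holds by integration from zero,
the linear tail by holding the derivative constant past the last knot, and
monotonicity is the box constraint $v \le 0$ (a piecewise-linear function
interpolating non-positive values is non-positive). The weighted
least-squares problem in the sign-flipped coefficients is a non-negative
least-squares problem, solved exactly by the Lawson–Hanson active-set
method (`pracma::lsqnonneg`). Tests verify the fit against an independent
active-set-enumeration oracle.

**Knots.** Interior knots sit at the 33⅓rd and 66⅔rd percentiles of the
alternative-interval midpoints (the linear-interpolation percentile
convention, rank $p(n-1)+1$, i.e. R's type-7 quantile). Fixed quantile
knots replace ensemble/automatic knot selection: they are deterministic,
testable, and two interior knots is the published configuration for this
risk shape. At least four distinct midpoints are required.

**Trimming.** Robustness to incoherent observations uses hard trimming:
fit, rank all observations by $|y_i - s_i| / \sigma_i$, exclude the
$\lfloor 0.1 n \rfloor$ largest, refit, and iterate until the excluded set
is stable (at most 20 iterations, with a warning and the last stable mask
on non-convergence). Ties are broken by input order, making the fit
deterministic given table order. Each concentration step cannot increase
the kept-set objective. The iteration scheme and tie-breaking are this
package's choices; sources describing 10% trimming do not specify them.

## Mixed-effects meta-regression

The fitted signal is scaled through
$y_i = (\beta + u_s)\,\hat s_i + \sum_j \delta_j x_{ij}\,\hat s_i +
\varepsilon_i$, with $u_s \sim N(0,\gamma)$ and known observation
variances $\sigma_i^2$. Three deliberate modelling choices:

* **Random slope, not intercept.** The study effect multiplies the signal,
  so heterogeneity scales with effect size and a comparison of identical
  exposures stays exactly null for every study. An additive-intercept
  generator option exists for sensitivity analysis but the model is the
  slope form.
* **Multiplicative bias covariates.** Covariate effects also act on the
  signal scale; a design feature cannot create an effect where the
  exposure contrast is null. The reference prediction sets all covariates
  to 0, the least-biased coding in the schema.
* **Trimmed observations are excluded** from the meta-regression and from
  Egger's regression (a configurable choice; the alternative of keeping
  them is available via `include_trimmed = TRUE`).

$\gamma$ is estimated by profile maximum likelihood over
$\gamma \ge 0$; per-study Woodbury identities make each profile evaluation
closed-form, and the scalar profile is maximised by golden-section search
(`optimize`, tolerance $10^{-9}$) with the boundary $\gamma = 0$ checked
explicitly. Covariate selection screens each candidate singly at
$|z| \ge z_{1-\alpha/2}$ ($\alpha = 0.05$), refits survivors jointly, and
drops those losing significance in one backward pass — the published
criterion ("significantly biased") with an explicit algorithm attached.

**The Fisher correction.** The standard error of $\hat\gamma$ uses the
expected Fisher information of the heterogeneity parameter,
$I(\gamma) = \tfrac12 \sum_s \left(z_s^\top V_s^{-1} z_s\right)^2$ with
$z_s$ the within-study signal loadings. We use the expected rather than
the numerically observed information because it is available in closed
form and is strictly positive even when $\hat\gamma = 0$ sits on the
boundary (where observed curvature of the profile is not well defined).
That positivity is the point of the correction:
$\gamma^* = \hat\gamma + z_{0.95}\,\mathrm{se}(\hat\gamma)$ stays positive
in data-sparse situations where $\hat\gamma = 0$ purely from lack of
studies. The quantile level 0.95 is configurable (`het_level`); the
sources state that an upper quantile is used but not which.

Uncertainty for the risk curve comes in two widths: the conventional 95%
UI scales the curve by $\beta \pm z_{0.975}\,\mathrm{se}(\beta)$; the
conservative UI replaces $\mathrm{se}(\beta)$ with
$\sqrt{\mathrm{se}(\beta)^2 + \gamma^*}$ and therefore contains the
conventional interval pointwise.

## Evidence scoring

The BPRF is the one-sided 95th-quantile curve closest to the null:
$\beta_{\mathrm{cons}} = \hat\beta - z_{0.95}
\sqrt{\mathrm{se}(\beta)^2 + \gamma^*}$ and
$\log\mathrm{BPRF}(x) = \beta_{\mathrm{cons}} f(x)$. For a protective fit
($f \le 0$, $\hat\beta > 0$) the downward coefficient shift always moves
the curve toward the null; when $\beta_{\mathrm{cons}} < 0$ the BPRF lies
on the opposite side of the null and the score goes negative.

The ROS is the signed mean of the log-BPRF over $[p_{15}, p_{85}]$ of the
pooled alternative-interval midpoints (sign $-1$ for protective risks so
that stronger evidence is always a larger positive score). Two open
choices, resolved as follows:

* "Averaged over the 15th and 85th percentiles" is implemented as the
  *integral mean* over the interval, the natural exposure-averaged summary
  of a function of exposure; a two-point average is available for
  sensitivity.
* The exposure distribution is observation-level (one midpoint per
  observation), not cohort-level, because the extracted tables carry no
  within-cohort consumption distribution.

Star ratings use the published percent-change cuts — protective
$d = 1 - e^{-\mathrm{ROS}}$ with 0–13% / >13–34% / >34–46% / >46% for two
to five stars, harmful $h = e^{\mathrm{ROS}} - 1$ with 0–15% / >15–50% /
>50–85% / >85% — with right-closed boundaries (a reduction of exactly 13%
is two stars) and one star for any non-positive score. The mapping is by
the printed percent cuts, not by their (slightly asymmetric) ROS-scale
approximations.

The TMREL takes each study's highest-consumption category and returns the
85th percentile of the lower limits (TMREL lower bound) and of the
midpoints (upper bound), pooling across all supplied study tables when the
TMREL is shared across outcomes.

## Publication-bias screening

The modified funnel plots residuals $y_i - \hat y_i$ (fixed-effect
prediction) against $\tilde\sigma_i = \sqrt{\sigma_i^2 + \gamma^*}$.
Heterogeneity enters additively under the root, matching the funnel
axes; a signal-scaled variant is available via configuration. Egger's
regression is weighted least squares of residual on $\tilde\sigma$ with
weights $1/\tilde\sigma^2$ and a two-sided t-test on the slope at
$\alpha = 0.05$ (two-sided is the weaker claim and flags the published
borderline cases). A numerically perfect fit (zero residual variance)
resolves to $p = 1$ for a zero slope and $p = 0$ otherwise.

## The synthetic cohort generator

`simulate_study_table()` emulates the structure the analysis assumes:
per-study right-skewed consumption distributions (gamma, shape 2, scale
100 g/day with study-level jitter — consumption spanning roughly 0–1000
g/day); 3–5 quantile-based categories against the lowest-consumption
reference; a saturating protective true curve
$\theta_{\max}(1 - e^{-x/\tau})$ with $\theta_{\max} = -0.30$ and
$\tau = 75$ g/day, so that most of the risk reduction sits between zero
and low consumption as observed for this class of outcomes; multiplicative
study-level random slopes ($\gamma_{\mathrm{true}} = 0.01$ by default,
matching the small heterogeneity typical of the better-studied outcomes);
observation SEs drawn uniformly from 0.05–0.20, or derived from simulated
event counts ($\sigma \approx \sqrt{1/E_{alt} + 1/E_{ref}}$) in
events mode; and optional publication censoring that suppresses
small-study, null-consistent observations with a given probability.

Bias-covariate effects scale the signal
($y = (1 + u_s + \sum_c \delta_c x_c)\,s + \varepsilon$), matching the
analysis model. An additive formulation was rejected after it proved
structurally incoherent with the pipeline: additive shifts of the size
worth testing push half the observations positive, collapse the
monotone-decreasing signal fit to the zero curve, and leave the covariate
unidentifiable downstream.

What the generator does *not* emulate: food-frequency-questionnaire
measurement error, within-cohort correlation of category estimates sharing
a reference group, non-proportional-hazards follow-up effects, or
extraction error. Passing recovery tests therefore demonstrate internal
consistency of the estimator under its own assumptions — not robustness to
those real-data features.

## Test problem sizes

The simulation-based checks use sizes chosen to balance Monte-Carlo
resolution against runtime: signal-scaling recovery with 100 replicates of
50 studies ($\gamma_{\mathrm{true}} = 0.01$); conservative-UI coverage at
the exposure-distribution median with 200 replicates of 20 studies; Egger
null calibration with 500 replicates of 15 studies and power with 200
replicates of 50 studies under events-based SEs, an 0.8 censoring
probability, and a small-study threshold classifying most cohorts as
small (small-study bias is only defined when precision tracks study size,
so the power scenario links $\sigma$ to sample size); the sparse-data
heterogeneity correction with 50 replicates of 3 studies; and trimming
robustness with 100 replicates of 20 studies containing 10% planted
10-sigma outliers.

## Known limitations

* The signal curve and the scaling $\beta$ are estimated in two stages;
  the UIs do not propagate spline-shape uncertainty, only scaling and
  heterogeneity uncertainty. This mirrors the conventional reporting of a
  single fitted shape but slightly understates curve uncertainty away
  from the anchor.
* Profile-ML $\hat\gamma$ (rather than REML) is mildly biased downward
  with few studies; the Fisher-information quantile $\gamma^*$ is the
  mechanism that compensates in exactly that regime.
* Only the 95% CI level is supported for input effect sizes, and CIs are
  assumed symmetric on the log scale.
* Harmful and J-shaped risk configurations are out of scope for the
  spline priors (the protective-monotone configuration is hard-coded);
  the scoring functions do support the harmful direction.
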