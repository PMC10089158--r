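---
title: "Modeling postfire conifer recruitment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling postfire conifer recruitment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenfire)
```

`regenfire` models whether conifer seedlings establish after wildfire, as a
function of seed availability, burn severity, topographic heat load and
climatic water stress, and projects that probability under paired
fire-severity and climate-period scenarios. This vignette is the package's
account of its science: the statistical model, the water-balance model that
produces the climate covariates, the model-selection and thresholding
machinery, the synthetic data the test suite runs on, and the numerical
decisions underneath each.

## The recruitment model

The observational unit is a field plot surveyed at least two years after a
wildfire. The response is presence/absence of at least one seedling in the
plot. We model it with a binomial generalized linear mixed model with a
logit link:

$$
\mathrm{logit}\,p_{ij} = \mathbf{x}_{ij}^\top \boldsymbol\beta
  + u_j + \log a_{ij}, \qquad u_j \sim \mathcal N(0, \sigma^2),
$$

where $j$ indexes the wildfire, $a_{ij}$ is plot area in square metres
(entered as a fixed offset, so probabilities refer to a plot of stated
size and sampling effort is accounted for), and $u_j$ is a random intercept
that absorbs the shared history of plots within one fire - the same burn
weather, the same seed-year sequence. With the offset, the probability for
a standard 100 m^2 (0.01 ha) plot corresponds to a detectable density of
100 seedlings per hectare.

Fixed effects fall into two tiers. The *biophysical core* is always present:
time since fire, distance to the nearest live seed source (m), surrounding
live tree cover within 300 m (%), the relativized burn ratio RBR (severity),
the continuous heat-insolation load index CHILI, prefire disturbance
category (reference level "none"), and a variety term where a species has
recognized varieties. The *climate tier* - 30-y mean deficit and the
postfire anomaly extremes described below, plus their interactions - is
subject to cross-validated selection.

Continuous covariates are standardized (mean 0, sd 1, denominator $n-1$)
before fitting. The model is scale-equivariant, so this changes nothing
statistically; it conditions the optimizer, makes quadratic and interaction
columns well-scaled, and gives the partial-dependence machinery a
scale-free footing. Centers and scales are stored in the fitted object and
applied to any new data at prediction time, so users only ever see the raw
scale.

## Climatic water deficit

Plant-relevant drought is summarized by climatic water deficit (CWD):
potential minus actual evapotranspiration, the evaporative demand the site
could not meet. It is computed from monthly temperature and precipitation by
a Thornthwaite-Mather water balance:

* **PET** by the classical Thornthwaite formulation: a yearly heat index
  accumulated from the twelve monthly mean temperatures, a power law in
  monthly temperature, and a day-length correction from solar declination at
  the mid-month day of year. Months at or below 0 degrees C evaporate
  nothing.
* **Snow**: precipitation is partitioned linearly between snow (all snow at
  or below 0 degrees C) and rain (all rain at or above 6 degrees C); the pack
  melts at 2 mm per degree-day (configurable).
* **Soil**: supply is rain plus melt. When supply meets PET, AET = PET and
  the surplus recharges the soil store (capacity `whc_mm`, default 150 mm -
  a typical forest-soil value, configurable per site) before running off.
  When supply falls short, the soil releases
  $s\,(1 - e^{-(\mathrm{PET}-W)/\mathrm{whc}})$ (exponential drying), and
  whatever demand remains unmet is that month's deficit.
* **Spin-up**: the first calendar year is run once and discarded, which
  removes all sensitivity to the initial store values.

Every month satisfies exact mass balance - precipitation equals AET plus
runoff plus the change in soil and snow stores - and the test suite checks
this to 1e-6 mm on a thousand randomized series, alongside a step-by-step
hand ledger of a 24-month series coded independently of the implementation.
The PET provider is deliberately pluggable: a Penman-Monteith backend could
be swapped in without touching the bookkeeping, and because downstream
covariates are z-scores and within-site contrasts, deficit *rankings* matter
more than absolute magnitudes.

From the monthly series we derive the model's climate covariates, per site:

* 30-y (1981-2010) mean annual CWD and mean growing-season (April-September)
  CWD - the site's average stress regime;
* for the first five years after a fire, the maximum and minimum of three
  annually resolved anomalies, each standardized against the site's own
  1981-2010 mean and sd: growing-season CWD z, June-August vapor pressure
  deficit z, and growing-season precipitation z (summed over the season; the
  convention is a documented choice). A single severe postfire drought year
  is biologically decisive for germinants, which is why extremes rather than
  means enter the model.

A constant baseline (sd = 0) would make a z-score undefined; we define it as
zero everywhere and warn, which keeps degenerate synthetic sites usable.
"Annual" means calendar year, the simplest convention, stated here because
water-year aggregation is a defensible alternative.

## Fitting: Laplace-approximate maximum likelihood

The marginal likelihood integrates the random intercepts out of the
joint likelihood; with one scalar intercept per fire the integral factors by
fire. We maximize the Laplace approximation over
$(\boldsymbol\beta, \log\sigma)$:

* **Inner problem.** For given parameters, each fire's conditional mode
  $\hat u_j$ solves a one-dimensional concave problem; damped Newton steps,
  vectorized across fires and warm-started between evaluations, converge in
  a handful of iterations (tolerance 1e-10 on the mode gradient).
* **Outer problem.** L-BFGS-B with *analytic* gradients of the Laplace
  objective (including the curvature terms from the log-determinant), with
  $\log\sigma$ bounded in $[-12, 5]$. Because quasi-Newton stops on relative
  progress, a few full Newton polish steps with the observed-information
  Hessian then drive the gradient norm below 1e-6; exceeding the iteration
  cap or tolerance is a hard error, never a silent result.
* **Uncertainty.** Wald covariance from the inverse observed information
  (central differences of the analytic gradient). When $\hat\sigma$ sits on
  the lower boundary the $\log\sigma$ row is dropped and the fixed-effect
  block is inverted alone. Wald rather than profile intervals: the
  projection bands consume a multivariate-normal coefficient approximation,
  and at the sample sizes involved the difference is immaterial.

The engine carries its own oracle: adaptive Gauss-Hermite quadrature
(`marginal_loglik_gh`), centered and scaled at the conditional modes, with
nodes from the Golub-Welsch eigen decomposition. One node reproduces the
Laplace value *identically* - a definitional check - and 50 nodes give a
reference value the Laplace fit must approach. The Laplace error per fire
shrinks roughly like the inverse of the plots-per-fire count, so the
equivalence tests run on instances of 3-10 well-sampled fires (200 plots
each, sigma 0.5), the regime the approximation targets; at 25 or 50 nodes
the quadrature itself agrees to 1e-6, and in the zero-variance limit both
collapse onto plain logistic regression. Parameter recovery is verified by
simulation: 200 replicates at 100 fires x 20 plots, with 95% Wald intervals
required to cover each true coefficient in at least 90% of replicates and
the median $\hat\sigma$ within 15% of the true 1.

One caveat worth stating: duplicating every row of a dataset leaves a GLM
exactly unchanged and shrinks its standard errors by $\sqrt2$, but in a
mixed model duplicated binary rows are perfectly correlated within fires and
legitimately surface as a little extra intercept variance. The test suite
checks the scaling property where it is exact - the plot-level slope - and
documents the intercept's group-variance floor.

Model fit is assessed with randomized-quantile simulation residuals:
unconditional simulations (random intercepts redrawn each time) place each
observed outcome within its simulated distribution, giving residuals that
are uniform when the model is right and visibly non-uniform when a strong
covariate is withheld.

## Model selection: cross-validated AUC with a significance bar

Predictive skill is the area under the ROC curve, computed by the
Mann-Whitney rank statistic with ties counted one half. Cross-validation
folds partition *fires*, not plots: plots within a fire share an intercept,
and plot-level folds would leak that shared signal into the test fold and
inflate AUC. All plots of a fire stay together; fold assignment is a
seeded, deterministic deal of shuffled fires.

Backward elimination runs in two phases over a protected structure - the
biophysical core is never a removal candidate, and an interaction always
leaves before its parent main effect:

1. **Removal.** Among climate terms and interactions, the candidate whose
   removal yields the highest cross-validated AUC is accepted unless the
   removal *significantly* lowers skill - the mean of the paired per-fold
   AUC differences must stay above $-2$ standard errors of those differences
   (a paired-t-test-style rule, `se_mult = 2`). This bar, rather than "any
   decrease blocks removal", is the load-bearing design choice: with ten
   fold AUCs, the skill contribution of a truly null fire-level covariate is
   indistinguishable from noise, and a strict rule retains such terms in a
   large fraction of datasets (in our simulations, half). Requiring
   *significant* harm before keeping a term removes null climate terms in
   95% of simulated null datasets while leaving genuinely predictive terms
   untouched, and mirrors standard practice in stepwise procedures.
2. **Interaction checks.** Each interaction between the full model's
   postfire anomaly terms and the severity / seed-availability covariates
   (RBR, distance to seed source, surrounding tree cover) is then tested as
   an addition, accepted when its mean paired fold-AUC gain clears the same
   two-standard-error bar. Candidates cover the full model's anomaly terms
   even when phase 1 removed one as a main effect - an interaction can carry
   signal a marginal main effect lacks - and hierarchy is preserved by
   restoring the parent alongside its interaction. In simulations with a
   true deficit-by-severity interaction this recovers the interaction in
   every replicate at 100 fires x 20 plots.

Ties in candidate AUCs break deterministically: higher-order terms first,
then lexicographically. The trace records every candidate, its AUC and the
accept/reject decision.

## Thresholds

Probabilities become likely/unlikely calls via a cutoff chosen to maximize
either Cohen's kappa or sensitivity plus specificity. For step-function
metrics the complete candidate set is finite: midpoints between adjacent
sorted unique probabilities, plus 0 and 1; the selector scans it
exhaustively and returns the smallest cutoff among tied maximizers.
"Likely" means the probability strictly exceeds the cutoff. Cutoffs are
chosen by default on *out-of-fold* cross-validated probabilities rather than
in-sample fits, which avoids optimistic thresholds; both methods' results
are reported together, and the interval between them is the gray band of
threshold uncertainty drawn in category figures. Degenerate marginals (all
predictions one class) would make kappa 0/0; it is defined as 0 with a
warning.

## Scenario projection

Projections contrast two severity bundles at fixed effort: **low severity**
(10 m to seed source, 30% surrounding cover, RBR 100) and **high severity**
(150 m, 10% cover, RBR 400), each evaluated 10 years postfire on a 100 m^2
plot, at the population level (random intercept zero - the target is new,
unobserved fires). Climate enters through one of three 20-year periods
(1981-2000, 2001-2020, 2031-2050, the last tagged with an emissions
pathway).

A period is longer than the five-year postfire window, and a "mean
recruitment probability for the period" needs a windowing rule: we compute
the five-year anomaly extremes for *every feasible fire year in the period*
and average them, an unbiased reading that lives in one function
(`period_climate_metrics`) so an alternative rule is a one-function change.

Each site then gets a three-way category: unlikely under both bundles,
likely only under the low-severity bundle (the severity-sensitive fraction
where management leverage is largest), or likely under both. A site likely
under high severity only is geometrically possible when fitted severity
effects reverse sign (as with strongly serotinous species); it is retained
under an explicit fourth label and flagged rather than silently folded in.
Area summaries are cell-area-weighted and sum to one within each region by
construction; the tests verify invariance to site order and to splitting a
cell into two half-area cells.

Partial dependence sweeps one covariate across its observed range (100
points), holds the other continuous covariates at their medians and
categorical ones at their reference, and draws 95% bands from 1000
multivariate-normal coefficient draws (percentile 2.5/97.5). Where an
interaction is active, three curves show the interacting covariate at its
10th, 50th and 90th percentiles; a categorical focal term yields per-level
point estimates instead of a curve. The band is a quantile interval, so its
*width* converges to the coefficient-uncertainty spread rather than to
zero; what shrinks like $1/\sqrt{\text{draws}}$ is the Monte-Carlo error of
the band endpoints, and that is what the tests measure (endpoint scatter at
250 vs 1000 draws).

## The synthetic study

Real surveys of this kind are assembled from thousands of plots across
hundreds of fires, joined to gridded climate. The package ships a generator
that emulates that structure with known truth, so every stage is testable
end to end:

* fires with uniform years 1984-2018 and Normal(0, sigma^2) logit
  intercepts; one climate site per fire (gridded climate is coarse relative
  to fire extent);
* monthly climate 1979-2050 with a July-peaked sinusoidal temperature
  cycle, site offsets, interannual noise, winter-peaked gamma precipitation
  (nonnegative by construction), summer-peaked vapor pressure deficit, and
  an optional linear warming trend (degrees C per decade) that propagates
  into deficit through the water balance;
* plot covariates uniform over field-plausible ranges - distance to seed
  source 0-500 m, tree cover 0-70%, RBR 0-800, CHILI 0-255, area
  10-1000 m^2 - with prefire disturbance drawn over its five levels with
  "none" the majority, and survey delays of 2-10 years;
* outcomes from the logit-linear truth with the log-area offset.

The defaults are one choice, made once: effect signs and sizes that produce
presence frequencies and AUCs in the range real studies report, and a
random-intercept sd of order 1 on the logit scale. What the generator does
*not* emulate - spatial autocorrelation, species ranges, serotiny,
covariate correlation structure, non-uniform covariate distributions - marks
the boundary of what passing tests can show: they certify the machinery
(filters, water balance, likelihood, selection, thresholds, projection
algebra), not that any particular ecological conclusion transfers to real
data.

Problem sizes in the test suite are the package's own: selection and
recovery experiments use 100 fires of 20 plots (the scale at which the
method's operating characteristics stabilize), oracle-equivalence instances
use 3-10 fires of 200 plots, and the end-to-end determinism run uses 14
fires of 10 plots.

## Reproducibility and orchestration

`run_pipeline()` executes simulate, metrics, assemble, fit, select,
threshold and project in order, writing plain-text artifacts (CSV, JSON,
YAML) to one directory. One global seed fans out to per-stage seeds by a
stable string hash of the stage name, so a stage's output is a function of
the configuration alone, independent of execution order. Each stage records
an MD5 hash of its configuration and input files; a stage re-runs when that
hash changes, when its outputs are missing or altered, or when any upstream
stage re-ran. Two runs of the same configuration produce byte-identical
artifacts.

## Known limitations

* The water balance is monthly and temperature-driven; radiation, wind and
  humidity enter only through the VPD covariate, not PET. Absolute deficits
  will differ from radiation-based formulations, though site contrasts -
  what the model consumes - are far more stable.
* The Laplace approximation biases sigma slightly at few plots per fire;
  the quadrature oracle bounds this but the fitter does not correct it.
* Selection controls false inclusion via the two-standard-error bar, not
  via any formal error-rate guarantee across the whole greedy path.
* Projection treats scenario covariates as exactly known and propagates
  only coefficient uncertainty; random-intercept variance is deliberately
  excluded from population-level predictions.
* The generator draws covariates independently; real severity, cover and
  distance are correlated, and collinearity screening is therefore
  exercised mostly in its reporting role on synthetic data.
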