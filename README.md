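# regenfire

Tools for modeling postfire conifer regeneration. After a wildfire, whether
a conifer forest returns depends on whether seedlings establish in the first
years — which in turn depends on how far surviving seed trees are, how
severely the site burned, and how hot and dry the postfire years were. This
package implements that analysis as a tested, reusable pipeline for
ecologists and forest managers: from plot surveys and monthly climate to a
fitted recruitment model, a defensible presence threshold, and maps of where
regeneration is likely under paired fire-severity and climate scenarios.

## The model

The core is a binomial generalized linear mixed model with a logit link.
For plot *i* in wildfire *j*,

    logit p_ij = x_ij' β + u_j + log a_ij,    u_j ~ N(0, σ²)

with a fixed offset `log a_ij` (plot area, m²) so probabilities refer to a
plot of stated size, and a random intercept per wildfire absorbing the
shared conditions of plots that burned together. Fixed effects combine a
protected biophysical core (time since fire, distance to seed source,
surrounding tree cover, burn severity RBR, heat load CHILI, prefire
disturbance, variety) with climate terms derived from a Thornthwaite–Mather
monthly water balance: 30-y (1981–2010) mean climatic water deficit
(PET − AET) and the extremes, over the first five postfire years, of
growing-season deficit, June–August vapor pressure deficit and
growing-season precipitation anomalies (z-scores against each site's own
1981–2010 baseline).

Around the model sit the pieces a full analysis needs, each its own module:

* a synthetic-data generator with known ground truth (fires, plots, monthly
  climate, outcomes), so the whole pipeline is testable without field data;
* the water balance (`compute_pet`, `run_water_balance`, `climate_metrics`);
* plot-inclusion filters, design construction and collinearity screening
  (pairwise r and VIF);
* an in-package Laplace likelihood engine with an adaptive Gauss–Hermite
  oracle (`fit_glmm`, `marginal_loglik_gh`), Wald inference, and
  simulation-based residuals;
* fire-grouped 10-fold cross-validated AUC and two-phase backward selection
  over climate terms and severity×climate interactions (`cv_auc`,
  `backward_select`);
* kappa- and sensitivity+specificity-maximizing thresholds
  (`select_threshold`);
* scenario projection, three-way likelihood categories, area summaries and
  partial-dependence curves (`project_scenario`, `classify_sites`,
  `area_summary`, `partial_dependence`);
* a deterministic orchestrator (`run_pipeline`) with YAML configs, hashed
  stage caching and a seed that fans out per stage.

See the methods vignette (`vignettes/regenfire-methods.Rmd`) for the model
assumptions, parameter defaults and the reasoning behind the numerical and
design choices.

## Worked example

```r
library(regenfire)

truth <- truth_params(n_fires = 40, plots_per_fire = 20, seed = 42)
ds <- simulate_dataset(truth)
ds
#> Synthetic postfire regeneration dataset
#>   800 plots in 40 fires; overall presence frequency 0.583
#>   climate: 40 sites x 864 months

asm <- assemble_model_table(ds$plots, ds$metrics)
spec <- model_spec(
  fixed = c("time_since_fire", "distance_m", "rbr", "tree_cover_pct",
            "deficit_z_max"),
  climate = "deficit_z_max")
fit <- fit_glmm(build_design(asm$table, spec))
fit
#> Binomial logit mixed model (Laplace), random intercept by fire
#>   n = 800 plots in 40 fires; logLik = -377.813
#>   random-intercept sd (logit scale): 0.9567
#>                 estimate std_error        z
#> (Intercept)      -5.4293    0.1787 -30.3748
#> time_since_fire   0.2373    0.0942   2.5200
#> distance_m       -1.2878    0.1123 -11.4694
#> rbr              -0.3296    0.0961  -3.4299
#> tree_cover_pct    0.7349    0.0988   7.4374
#> deficit_z_max     0.2236    0.1777   1.2585
```

Coefficients are on the standardized scale: recruitment odds fall steeply
with distance to seed source and severity, rise with surrounding tree
cover, and the fitted random-intercept sd (0.96) recovers the generating
value of 1. Skill and threshold come from fire-grouped cross-validation:

```r
cv <- cv_auc(spec, asm$table, k = 10, seed = 42)
sprintf("cross-validated AUC: %.3f", cv$mean)
#> "cross-validated AUC: 0.821"

ok <- !is.na(cv$oof)
thr <- select_threshold(cv$oof[ok], asm$table$presence[ok], "max_kappa")
thr
#> Threshold (max_kappa): 0.6449
#>   kappa 0.4595  sensitivity 0.6867  specificity 0.7874
```

Projection contrasts the low-severity bundle (10 m to seed, 30 % cover,
RBR 100) with the high-severity bundle (150 m, 10 %, RBR 400), ten years
postfire on a 100 m² plot:

```r
sites <- data.frame(site = ds$sites$site)
p_lo <- project_scenario(fit, sites, ds$metrics, scenario("low", c(1981, 2000)))
p_hi <- project_scenario(fit, sites, ds$metrics, scenario("high", c(1981, 2000)))
cm <- classify_sites(p_lo$prob, p_hi$prob, thr$threshold)
area_summary(cm)
#>   region         category area proportion
#> 1    all    unlikely_both    0          0
#> 2    all  likely_low_only   40          1
#> 3    all      likely_both    0          0
#> 4    all likely_high_only    0          0
```

Under this generator's strong severity effects, every synthetic site is
severity-sensitive: recruitment is likely after a low-severity burn and
unlikely after a high-severity one — the fraction of the landscape where
reducing burn severity changes the outcome.

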