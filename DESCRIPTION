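Package: regenfire
Title: Postfire Conifer Regeneration Modeling Under Climate and Fire-Severity Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to model the probability of postfire conifer seedling
    recruitment from plot surveys and monthly climate. Includes a synthetic
    data generator with known ground truth, a Thornthwaite-Mather monthly
    water balance producing climatic water deficit metrics (30-year means and
    5-year postfire anomaly extremes), a binomial logit mixed-model engine
    with a random intercept per wildfire and a log(plot area) offset fitted by
    Laplace approximation, cross-validated AUC backward model selection,
    kappa- and sensitivity+specificity-maximizing presence thresholds, and
    scenario projection with partial dependence curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmmTMB,
    lme4,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
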