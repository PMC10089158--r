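# fit a small model with strong, sign-consistent severity effects (recruitment
# falls with distance and severity, rises with cover) used across tests
fit_signed_model <- function(seed = 401) {
  set.seed(seed)
  n_fires <- 40; npf <- 25; n <- n_fires * npf
  fi <- rep(seq_len(n_fires), each = npf)
  tab <- data.frame(
    plot_id = sprintf("p%05d", 1:n), fire_id = sprintf("f%03d", fi),
    area_m2 = 100,
    distance_m = runif(n, 0, 500), tree_cover_pct = runif(n, 0, 70),
    rbr = runif(n, 0, 800), time_since_fire = sample(2:10, n, TRUE),
    deficit_z_max = rnorm(n_fires)[fi],
    mean_annual_deficit_mm = runif(n_fires, 100, 500)[fi]
  )
  u <- rnorm(n_fires, 0, 0.4)
  eta <- 3 - 0.012 * tab$distance_m + 0.04 * tab$tree_cover_pct -
    0.004 * tab$rbr + 0.1 * tab$time_since_fire - 0.5 * tab$deficit_z_max + u[fi]
  tab$presence <- rbinom(n, 1, plogis(eta))
  spec <- model_spec(fixed = c("time_since_fire", "distance_m", "tree_cover_pct",
                               "rbr", "deficit_z_max", "mean_annual_deficit_mm"),
                     climate = c("deficit_z_max", "mean_annual_deficit_mm"))
  list(fit = fit_glmm(build_design(tab, spec)), tab = tab, spec = spec)
}

test_that("scenario bundles carry the stated covariate values", {
  lo <- scenario("low", c(1981, 2000))
  hi <- scenario("high", c(2031, 2050), rcp = "RCP4.5")
  expect_equal(unlist(lo$bundle), c(distance_m = 10, tree_cover_pct = 30, rbr = 100))
  expect_equal(unlist(hi$bundle), c(distance_m = 150, tree_cover_pct = 10, rbr = 400))
  expect_equal(lo$time_since_fire, 10)
  expect_equal(lo$area_m2, 100)
})

test_that("low-severity probabilities dominate under sign-consistent effects", {
  m <- fit_signed_model()
  b <- coef(m$fit)
  expect_lt(b[["distance_m"]], 0)
  expect_gt(b[["tree_cover_pct"]], 0)
  expect_lt(b[["rbr"]], 0)
  sites <- data.frame(site = sprintf("s%02d", 1:30),
                      time_since_fire = 10,
                      deficit_z_max = rnorm(30),
                      mean_annual_deficit_mm = runif(30, 100, 500))
  metrics <- sites[, c("site", "deficit_z_max", "mean_annual_deficit_mm")]
  p_lo <- project_scenario(m$fit, sites["site"], metrics,
                           scenario("low", c(1981, 2000)))
  p_hi <- project_scenario(m$fit, sites["site"], metrics,
                           scenario("high", c(1981, 2000)))
  expect_true(all(p_lo$prob > p_hi$prob))
  # projected probabilities equal direct evaluation of the fitted formula
  nd <- sites
  nd$distance_m <- 10; nd$tree_cover_pct <- 30; nd$rbr <- 100
  nd$time_since_fire <- 10
  direct <- predict_probability(m$fit, nd, area_m2 = 100)
  expect_equal(p_lo$prob, direct, tolerance = 1e-12)
})

test_that("classification follows the three-way rule with anomalies flagged", {
  cm <- classify_sites(c(0.70, 0.80, 0.40), c(0.30, 0.60, 0.20), threshold = 0.54)
  expect_equal(as.character(cm$category),
               c("likely_low_only", "likely_both", "unlikely_both"))
  expect_false(any(cm$anomalous))
  # degenerate threshold 0: everything with positive probability is likely
  cm0 <- classify_sites(c(0.7, 0.4), c(0.3, 0.2), threshold = 0)
  expect_true(all(cm0$category == "likely_both"))
  # reversed ordering is retained but flagged
  expect_warning(cma <- classify_sites(0.3, 0.8, 0.54), "flagged")
  expect_equal(as.character(cma$category), "likely_high_only")
  expect_true(cma$anomalous)
})

test_that("area summaries weight by cell area and sum to one", {
  cm <- classify_sites(c(0.9, 0.9, 0.7, 0.2), c(0.8, 0.6, 0.2, 0.1),
                       threshold = 0.54,
                       cell_area = c(1, 1, 1, 1))
  s <- area_summary(cm)
  expect_equal(sum(s$proportion), 1, tolerance = 1e-10)
  expect_equal(s$proportion[s$category == "likely_both"], 0.5)
  expect_equal(s$proportion[s$category == "likely_low_only"], 0.25)
  expect_equal(s$proportion[s$category == "unlikely_both"], 0.25)

  # unequal areas {1, 3}
  cm2 <- classify_sites(c(0.9, 0.2), c(0.8, 0.1), 0.54, cell_area = c(1, 3))
  s2 <- area_summary(cm2)
  expect_equal(s2$proportion[s2$category == "likely_both"], 0.25)
  expect_equal(s2$proportion[s2$category == "unlikely_both"], 0.75)

  # invariance to order and to splitting a cell into two half-cells
  cm3 <- classify_sites(c(0.2, 0.9), c(0.1, 0.8), 0.54, cell_area = c(3, 1))
  expect_equal(area_summary(cm3)$proportion, s2$proportion)
  cm4 <- classify_sites(c(0.9, 0.2, 0.2), c(0.8, 0.1, 0.1), 0.54,
                        cell_area = c(1, 1.5, 1.5))
  expect_equal(area_summary(cm4)$proportion, s2$proportion)

  # regions summarize independently
  cm5 <- classify_sites(c(0.9, 0.2), c(0.8, 0.1), 0.54,
                        region = c("north", "south"))
  s5 <- area_summary(cm5)
  expect_equal(sum(s5$proportion[s5$region == "north"]), 1)
  expect_equal(sum(s5$proportion[s5$region == "south"]), 1)
})

test_that("partial dependence matches the plug-in formula exactly", {
  m <- fit_signed_model(402)
  pd <- partial_dependence(m$fit, m$tab, focal = "distance_m", draws = 300,
                           seed = 5, n_points = 25)
  # direct evaluation at each sweep point
  base <- m$tab
  meds <- vapply(c("time_since_fire", "tree_cover_pct", "rbr", "deficit_z_max",
                   "mean_annual_deficit_mm"), function(v) median(base[[v]]),
                 numeric(1))
  nd <- data.frame(distance_m = pd$focal_value)
  for (v in names(meds)) nd[[v]] <- meds[[v]]
  direct <- predict_probability(m$fit, nd, area_m2 = 100)
  expect_equal(pd$prob, direct, tolerance = 1e-10)
  expect_true(all(pd$lwr <= pd$prob & pd$prob <= pd$upr))
})

test_that("percentile curves coincide when the model has no interaction", {
  m <- fit_signed_model(403)
  # a covariate with no effect at all: flat curve at baseline, and coincident
  # percentile curves when it is named as the interacting variable
  set.seed(404)
  m$tab$noise_cov <- runif(nrow(m$tab))
  spec2 <- model_spec(fixed = c("distance_m", "noise_cov"))
  fit2 <- fit_glmm(build_design(m$tab, spec2))
  fit2$coefficients[["noise_cov"]] <- 0     # exact null effect
  pdn <- partial_dependence(fit2, m$tab, focal = "noise_cov", draws = 250,
                            seed = 7, n_points = 10)
  expect_equal(diff(range(pdn$prob)), 0, tolerance = 1e-12)
  pdi <- partial_dependence(fit2, m$tab, focal = "distance_m",
                            interacting = "noise_cov", draws = 250, seed = 8,
                            n_points = 10)
  p10 <- pdi$prob[pdi$interacting_percentile == 10]
  p90 <- pdi$prob[pdi$interacting_percentile == 90]
  expect_equal(p10, p90, tolerance = 1e-12)
})

test_that("categorical focal terms yield per-level estimates", {
  tab <- make_model_table(15, 12, seed = 405)
  tab$prefire_disturbance <- sample(c("none", "wildfire", "blowdown"),
                                    nrow(tab), TRUE)
  spec <- model_spec(fixed = c("distance_m", "prefire_disturbance"))
  fit <- fit_glmm(build_design(tab, spec))
  pd <- partial_dependence(fit, tab, focal = "prefire_disturbance", draws = 250,
                           seed = 9)
  expect_equal(nrow(pd), 3L)
  expect_equal(pd$level, c("none", "blowdown", "wildfire"))
  expect_true(all(pd$lwr <= pd$prob & pd$prob <= pd$upr))
})
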