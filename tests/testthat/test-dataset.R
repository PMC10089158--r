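toy_raw <- function() {
  data.frame(
    plot_id = sprintf("p%d", 1:6),
    fire_id = "f1",
    burned = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    planted = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    fire_year = c(2000, 2000, 1980, 2000, 2005, 2010),
    survey_year = c(2005, 2005, 1985, 2001, 2010, 2015),
    stringsAsFactors = FALSE
  )
}

test_that("inclusion filters itemize each stated rule", {
  res <- apply_inclusion_filters(toy_raw())
  expect_equal(nrow(res$plots), 2L)
  expect_equal(res$plots$plot_id, c("p5", "p6"))
  expect_equal(unname(res$log),
               c(1L, 1L, 1L, 1L))  # unburned, planted, out-of-range, too early
  expect_equal(sum(res$log), nrow(toy_raw()) - nrow(res$plots))

  # idempotence / no-op on an all-valid table
  res2 <- apply_inclusion_filters(res$plots)
  expect_equal(res2$plots, res$plots)
  expect_true(all(res2$log == 0))

  # vacuous case
  res3 <- apply_inclusion_filters(toy_raw()[0, ])
  expect_equal(nrow(res3$plots), 0L)
  expect_true(all(res3$log == 0))

  expect_error(apply_inclusion_filters(toy_raw()[, -3]), "burned")
})

test_that("design building standardizes, dummy-codes and expands terms", {
  tab <- data.frame(
    presence = c(0, 1, 1), fire_id = c("a", "a", "b"), area_m2 = c(50, 100, 200),
    x = c(1, 2, 3), w = c(4, 0, 2),
    prefire_disturbance = c("wildfire", "none", "none"),
    stringsAsFactors = FALSE
  )
  spec <- model_spec(fixed = c("x", "w", "prefire_disturbance"),
                     quadratic = "x", interactions = list(c("x", "w")))
  des <- build_design(tab, spec)
  expect_equal(unname(des$X[, "x"]), c(-1, 0, 1))   # sd with denominator n-1
  expect_equal(des$offset, log(tab$area_m2))
  expect_equal(unname(des$X[, "I(x^2)"]), c(1, 0, 1))
  expect_equal(unname(des$X[, "x:w"]),
               unname(des$X[, "x"] * des$X[, "w"]))
  # reference level "none": dummy columns for the other levels only
  expect_true("prefire_disturbancewildfire" %in% colnames(des$X))
  expect_false(any(grepl("none", colnames(des$X))))

  # intercept-only spec
  des0 <- build_design(tab, model_spec(fixed = "x"), standardize = FALSE)
  expect_equal(unname(des0$X[, "(Intercept)"]), rep(1, 3))

  expect_error(build_design(transform(tab, x = 1), spec), "zero variance")
  expect_error(build_design(tab, model_spec(fixed = "nope")), "nope")
})

test_that("standardization round-trips through raw-scale prediction", {
  tab <- make_model_table(15, 10, seed = 40)
  spec <- model_spec(fixed = c("distance_m", "rbr"))
  fit <- fit_glmm(build_design(tab, spec))
  p_std <- predict_probability(fit, tab, area_m2 = tab$area_m2)
  # raw-scale coefficients recovered from the stored centers and scales
  b <- coef(fit)
  sc <- fit$design_info$scaling
  b_raw <- c(b[["distance_m"]], b[["rbr"]]) / sc$scale[c("distance_m", "rbr")]
  a_raw <- b[["(Intercept)"]] -
    sum(b[c("distance_m", "rbr")] * sc$center / sc$scale)
  eta_raw <- a_raw + b_raw[1] * tab$distance_m + b_raw[2] * tab$rbr +
    log(tab$area_m2)
  expect_equal(p_std, plogis(eta_raw), tolerance = 1e-10)
})

test_that("collinearity screening applies the r and VIF rules", {
  set.seed(5)
  x <- rnorm(200)
  # two identical columns -> r = 1 flagged
  sc <- collinearity_screen(cbind(a = x, b = x, c = rnorm(200)))
  expect_true(any(sc$pairs$a == "a" & sc$pairs$b == "b"))
  expect_equal(sc$pairs$r[sc$pairs$a == "a" & sc$pairs$b == "b"], 1)

  # orthogonal columns: VIF 1, nothing flagged
  n <- 400
  u <- scale(rnorm(n))[, 1]
  v <- scale(residuals(lm(rnorm(n) ~ u)))[, 1]
  sc2 <- collinearity_screen(cbind(u = u, v = v))
  expect_equal(unname(sc2$vif), c(1, 1), tolerance = 1e-10)
  expect_equal(nrow(sc2$pairs), 0L)

  # closed-form two-predictor VIF at r = 0.8
  a <- scale(rnorm(n))[, 1]
  b_res <- scale(residuals(lm(rnorm(n) ~ a)))[, 1]
  b2 <- 0.8 * a + sqrt(1 - 0.64) * b_res
  sc3 <- collinearity_screen(cbind(a = a, b = b2))
  expect_equal(unname(sc3$vif), rep(1 / (1 - 0.64), 2), tolerance = 1e-6)
  expect_equal(nrow(sc3$pairs), 1L)        # flagged by the r-rule
  expect_equal(length(sc3$flagged_vif), 0L)

  # auto-drop keeps the higher-priority (earlier) column
  sc4 <- collinearity_screen(cbind(a = x, b = x + rnorm(200, 0, 1e-6)),
                             auto_drop = TRUE)
  expect_equal(sc4$dropped, "b")
  expect_error(collinearity_screen(cbind(a = x, b = rep(1, 200))), "constant")
})

test_that("model spec enforces hierarchy and uniqueness", {
  expect_error(model_spec(fixed = c("a", "b"), interactions = list(c("a", "c"))),
               "hierarchy")
  expect_error(model_spec(fixed = c("a", "a")), "duplicated")
  expect_error(model_spec(fixed = c("a", "b"),
                          interactions = list(c("a", "b"), c("b", "a"))),
               "duplicated")
  s <- model_spec(fixed = c("a", "b"), interactions = list(c("a", "b")),
                  climate = "b")
  expect_s3_class(s, "model_spec")
})
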