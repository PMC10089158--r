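test_that("analytic gradients of the Laplace objective match finite differences", {
  inst <- make_glmm_instance(8, 25, beta = c(-0.4, 0.7, -0.3), sigma = 0.8,
                             seed = 101)
  env <- new.env(parent = emptyenv())
  env$u <- rep(0, 8)
  obj <- function(par) regenfire:::laplace_obj(par, inst$X, inst$y, inst$offset,
                                               inst$gi, 8, env)
  for (par in list(c(-0.4, 0.7, -0.3, log(0.8)), c(0.1, 0, 0.5, log(0.2)),
                   c(-1, 1, 0.2, log(2)))) {
    g_an <- unname(obj(par)$gradient)
    g_fd <- fd_gradient(function(p) obj(p)$value, par)
    expect_equal(g_an, g_fd, tolerance = 1e-5)
  }
})

test_that("the degenerate-variance limit matches plain logistic regression", {
  inst <- make_glmm_instance(80, 50, beta = c(-0.5, 0.8), sigma = 0, seed = 7)
  fit <- fit_glmm(inst$X, inst$y, groups = inst$groups)
  expect_lt(fit$sigma, 0.05)
  glm_fit <- glm.fit(inst$X, inst$y, family = binomial())
  expect_equal(unname(fit$coefficients), unname(glm_fit$coefficients),
               tolerance = 1e-3)
})

test_that("parameters are recovered within Wald uncertainty", {
  inst <- make_glmm_instance(100, 20, beta = c(-1, 0.8), sigma = 1, seed = 55)
  fit <- fit_glmm(inst$X, inst$y, groups = inst$groups)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coefficients[1] - (-1)), 3 * se[1])
  expect_lt(abs(fit$coefficients[2] - 0.8), 3 * se[2])
  expect_true(fit$convergence$gradient_norm < 1e-6)
  # covariance is symmetric positive definite
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE)$values > 0))
})

test_that("row duplication leaves estimates unchanged and shrinks SEs by sqrt(2)", {
  # duplicated binary rows are perfectly correlated within groups, which a
  # mixed model absorbs as a little extra intercept variance; the scaling
  # property is therefore exact for the plot-level slope but the intercept SE
  # keeps its group-variance floor
  inst <- make_glmm_instance(60, 40, beta = c(-0.3, 0.6), sigma = 0, seed = 26)
  fit1 <- fit_glmm(inst$X, inst$y, groups = inst$groups)
  idx <- rep(seq_along(inst$y), 2)
  fit2 <- fit_glmm(inst$X[idx, ], inst$y[idx], groups = inst$groups[idx])
  expect_equal(fit2$coefficients, fit1$coefficients, tolerance = 0.02)
  r <- sqrt(diag(fit1$vcov)) / sqrt(diag(fit2$vcov))
  expect_equal(unname(r[2]), sqrt(2), tolerance = 0.05)
})

test_that("the engine agrees with an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  inst <- make_glmm_instance(30, 20, beta = c(-0.2, 0.5), sigma = 0.9, seed = 13)
  fit <- fit_glmm(inst$X, inst$y, groups = inst$groups)
  d <- data.frame(y = inst$y, x = inst$X[, 2], g = inst$groups)
  ref <- glmmTMB::glmmTMB(y ~ x + (1 | g), family = stats::binomial(), data = d)
  expect_equal(unname(fit$coefficients), unname(glmmTMB::fixef(ref)$cond),
               tolerance = 1e-3)
  expect_equal(fit$sigma, sqrt(glmmTMB::VarCorr(ref)$cond$g[1, 1]),
               tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
})

test_that("adaptive Gauss-Hermite quadrature behaves as the oracle", {
  inst <- make_glmm_instance(3, 5, beta = c(0.2, -0.5), sigma = 0.6, seed = 31)
  beta <- c(0.1, -0.4)
  # nodes = 1 reproduces the Laplace value exactly
  env <- new.env(parent = emptyenv()); env$u <- rep(0, 3)
  lap <- regenfire:::laplace_obj(c(beta, log(0.6)), inst$X, inst$y, inst$offset,
                                 inst$gi, 3, env)$value
  gh1 <- marginal_loglik_gh(inst$X, inst$y, inst$offset, inst$groups, beta, 0.6,
                            nodes = 1)
  expect_equal(gh1, lap, tolerance = 1e-8)
  # quadrature convergence
  gh25 <- marginal_loglik_gh(inst$X, inst$y, inst$offset, inst$groups, beta,
                             0.6, nodes = 25)
  gh50 <- marginal_loglik_gh(inst$X, inst$y, inst$offset, inst$groups, beta,
                             0.6, nodes = 50)
  expect_equal(gh25, gh50, tolerance = 1e-6)
  # sigma -> 0 limit equals the independent-Bernoulli log-likelihood
  gh0 <- marginal_loglik_gh(inst$X, inst$y, inst$offset, inst$groups, beta, 0)
  eta <- drop(inst$X %*% beta)
  expect_equal(gh0, sum(dbinom(inst$y, 1, plogis(eta), log = TRUE)),
               tolerance = 1e-10)
})

test_that("log-likelihood never decreases along the fitted solution path", {
  # the returned optimum must beat the starting GLM solution
  inst <- make_glmm_instance(25, 20, beta = c(-0.5, 0.9), sigma = 1, seed = 61)
  fit <- fit_glmm(inst$X, inst$y, groups = inst$groups)
  env <- new.env(parent = emptyenv()); env$u <- rep(0, 25)
  glm_fit <- suppressWarnings(glm.fit(inst$X, inst$y, family = binomial()))
  ll_start <- regenfire:::laplace_obj(c(glm_fit$coefficients, log(0.5)),
                                      inst$X, inst$y, inst$offset, inst$gi, 25,
                                      env)$value
  expect_gte(fit$loglik, ll_start)
})

test_that("rank deficiency and degenerate groupings are explicit errors", {
  inst <- make_glmm_instance(5, 10, beta = c(0, 0.5), sigma = 0.5, seed = 71)
  Xbad <- cbind(inst$X, inst$X[, 2])
  expect_error(fit_glmm(Xbad, inst$y, groups = inst$groups), "rank deficient")
  expect_error(fit_glmm(inst$X, inst$y, groups = rep(1, length(inst$y))),
               "2 groups")
  expect_error(fit_glmm(inst$X, inst$y + 1, groups = inst$groups), "binary")
})

test_that("population predictions honour the offset contract", {
  tab <- make_model_table(10, 10, seed = 81)
  spec <- model_spec(fixed = c("distance_m", "rbr"))
  fit <- fit_glmm(build_design(tab, spec))
  nd <- tab[1:5, ]
  p100 <- predict_probability(fit, nd, area_m2 = 100)
  p200 <- predict_probability(fit, nd, area_m2 = 200)
  eta100 <- qlogis(p100); eta200 <- qlogis(p200)
  expect_equal(eta200 - eta100, rep(log(2), 5), tolerance = 1e-10)
  expect_true(all(p100 > 0 & p100 < 1))
})

test_that("unseen factor levels are rejected at prediction time", {
  tab <- make_model_table(10, 10, seed = 82)
  tab$prefire_disturbance <- sample(c("none", "wildfire"), nrow(tab), TRUE)
  spec <- model_spec(fixed = c("distance_m", "prefire_disturbance"))
  fit <- fit_glmm(build_design(tab, spec))
  nd <- tab[1:2, ]
  nd$prefire_disturbance <- "blowdown"
  expect_error(predict_probability(fit, nd), "unseen")
})

test_that("simulation residuals are uniform under the fitted model", {
  inst <- make_glmm_instance(40, 50, beta = c(-0.5, 0.8), sigma = 1, seed = 91)
  fit <- fit_glmm(inst$X, inst$y, groups = inst$groups)
  r <- simulation_residuals(fit, inst$X, inst$y, inst$offset, inst$groups,
                            n_sims = 250, seed = 17)
  expect_true(all(r >= 0 & r <= 1))
  expect_lt(abs(mean(r) - 0.5), 0.02)

  # omitting a strong covariate worsens the fit visibly
  fit_bad <- fit_glmm(inst$X[, 1, drop = FALSE], inst$y, groups = inst$groups)
  r_bad <- simulation_residuals(fit_bad, inst$X[, 1, drop = FALSE], inst$y,
                                inst$offset, inst$groups, n_sims = 250, seed = 17)
  ks_ok <- ks.test(r, "punif")$statistic
  ks_bad <- ks.test(r_bad, "punif")$statistic
  expect_gt(ks_bad, ks_ok)
})

test_that("fitted models round-trip through JSON", {
  tab <- make_model_table(12, 10, seed = 83)
  spec <- model_spec(fixed = c("distance_m", "rbr", "deficit_z_max"),
                     interactions = list(c("distance_m", "rbr")),
                     climate = "deficit_z_max")
  fit <- fit_glmm(build_design(tab, spec))
  tf <- withr::local_tempfile(fileext = ".json")
  write_glmm_json(fit, tf)
  fit2 <- read_glmm_json(tf)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(fit2$sigma, fit$sigma, tolerance = 1e-12)
  p1 <- predict_probability(fit, tab[1:8, ], area_m2 = 100)
  p2 <- predict_probability(fit2, tab[1:8, ], area_m2 = 100)
  expect_equal(p1, p2, tolerance = 1e-10)
})
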