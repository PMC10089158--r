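# shared builders for small synthetic instances used across test files

# grouped binary data from a logit-linear model with per-group intercepts
make_glmm_instance <- function(n_groups, n_per_group, beta, sigma, seed,
                               p_extra = 0) {
  set.seed(seed)
  n <- n_groups * n_per_group
  gi <- rep(seq_len(n_groups), each = n_per_group)
  X <- cbind(1, matrix(rnorm(n * (length(beta) - 1 + p_extra)), n))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  u <- rnorm(n_groups, 0, sigma)
  eta <- drop(X[, seq_along(beta), drop = FALSE] %*% beta) + u[gi]
  y <- rbinom(n, 1, plogis(eta))
  list(X = X, y = y, groups = factor(gi), gi = gi, u = u, eta = eta,
       offset = rep(0, n))
}

# minimal model table for selection/threshold tests: biophysical covariates
# plus climate metric columns, with outcomes from a chosen truth
make_model_table <- function(n_fires, plots_per_fire, seed,
                             beta = c(intercept = -0.2, distance_m = -0.006,
                                      rbr = -0.0015),
                             sigma = 0.8, interaction_deficit_rbr = 0) {
  set.seed(seed)
  n <- n_fires * plots_per_fire
  fi <- rep(seq_len(n_fires), each = plots_per_fire)
  tab <- data.frame(
    plot_id = sprintf("p%05d", seq_len(n)),
    fire_id = sprintf("f%03d", fi),
    area_m2 = 100,
    distance_m = runif(n, 0, 500),
    rbr = runif(n, 0, 800),
    mean_annual_deficit_mm = runif(n_fires, 100, 500)[fi],
    stringsAsFactors = FALSE
  )
  # climate metrics are fire-level quantities
  tab$deficit_z_max <- rnorm(n_fires)[fi]
  u <- rnorm(n_fires, 0, sigma)
  eta <- beta[["intercept"]] +
    beta[["distance_m"]] * tab$distance_m +
    beta[["rbr"]] * tab$rbr +
    (if ("deficit_z_max" %in% names(beta)) beta[["deficit_z_max"]] * tab$deficit_z_max else 0) +
    (if ("mean_annual_deficit_mm" %in% names(beta))
      beta[["mean_annual_deficit_mm"]] * tab$mean_annual_deficit_mm else 0) +
    interaction_deficit_rbr * tab$deficit_z_max * scale(tab$rbr)[, 1] +
    u[fi]
  tab$presence <- rbinom(n, 1, plogis(eta))
  tab
}

# central-difference gradient of a scalar function (independent check of the
# engine's analytic gradients)
fd_gradient <- function(f, par, h = 1e-6) {
  vapply(seq_along(par), function(j) {
    e <- numeric(length(par)); e[j] <- h * max(1, abs(par[j]))
    (f(par + e) - f(par - e)) / (2 * e[j])
  }, numeric(1))
}

# whole-calendar-year monthly climate frame for water-balance tests
make_climate_years <- function(years, tmean_fn, precip_fn, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(month = 1:12, year = years, KEEP.OUT.ATTRS = FALSE)
  data.frame(year = grid$year, month = grid$month,
             tmean_c = tmean_fn(grid$month, grid$year),
             precip_mm = precip_fn(grid$month, grid$year))
}
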