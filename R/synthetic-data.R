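#' Ground-truth parameters for the synthetic study
#'
#' Bundles the data-generating truth for a synthetic postfire regeneration
#' study: fixed-effect coefficients on the logit scale (applied to raw
#' covariate columns), the standard deviation of the per-wildfire random
#' intercept, study dimensions, covariate ranges, and a temperature trend that
#' propagates into climatic water deficit.
#'
#' Coefficient names refer to plot-table columns; quadratic terms are written
#' `"col^2"` and interactions `"a:b"`. An `"(Intercept)"` entry is the
#' baseline logit for a 1 m2 plot (the log-area offset is always added on
#' top).
#'
#' @param fixed_coefficients Named numeric vector of logit-scale coefficients.
#' @param random_intercept_sd Nonnegative sd of the wildfire random intercept.
#' @param n_fires,plots_per_fire Study dimensions.
#' @param area_m2_range Length-2 positive range plot areas are drawn from (m2).
#' @param covariate_ranges Named list of length-2 ranges for the uniform
#'   covariate draws. Defaults span typical western-US postfire surveys:
#'   distance to seed source 0-500 m, surrounding tree cover 0-70 %,
#'   RBR 0-800, CHILI 0-255.
#' @param climate_trend Warming trend in degrees C per decade applied to the
#'   synthetic temperature series (drives a drying deficit trend downstream).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(fixed_coefficients = c(
                           "(Intercept)" = -4.2,
                           distance_m = -0.008,
                           tree_cover_pct = 0.03,
                           rbr = -0.002,
                           time_since_fire = 0.1
                         ),
                         random_intercept_sd = 1,
                         n_fires = 50L,
                         plots_per_fire = 20L,
                         area_m2_range = c(10, 1000),
                         covariate_ranges = list(
                           distance_m = c(0, 500),
                           tree_cover_pct = c(0, 70),
                           rbr = c(0, 800),
                           chili = c(0, 255)
                         ),
                         climate_trend = 0,
                         seed = DEFAULT_SEED) {
  stop_if_not(is.numeric(fixed_coefficients) && length(fixed_coefficients) > 0 &&
                !is.null(names(fixed_coefficients)),
              "`fixed_coefficients` must be a named numeric vector")
  check_number(random_intercept_sd, "random_intercept_sd", lower = 0)
  n_fires <- check_count(n_fires, "n_fires")
  plots_per_fire <- check_count(plots_per_fire, "plots_per_fire")
  stop_if_not(length(area_m2_range) == 2L && all(area_m2_range > 0) &&
                diff(area_m2_range) >= 0, "`area_m2_range` must be a positive interval")
  stop_if_not(is.list(covariate_ranges) && length(covariate_ranges) > 0 &&
                all(vapply(covariate_ranges, function(r)
                  length(r) == 2L && is.numeric(r) && diff(r) >= 0, logical(1))),
              "`covariate_ranges` must be a nonempty list of intervals")
  check_number(climate_trend, "climate_trend")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(fixed_coefficients = fixed_coefficients,
                 random_intercept_sd = random_intercept_sd,
                 n_fires = n_fires, plots_per_fire = plots_per_fire,
                 area_m2_range = as.numeric(area_m2_range),
                 covariate_ranges = covariate_ranges,
                 climate_trend = climate_trend, seed = seed),
            class = "truth_params")
}

#' @export
print.truth_params <- function(x, ...) {
  cat("Synthetic-study truth parameters\n")
  cat("  fires:", x$n_fires, " plots/fire:", x$plots_per_fire,
      " random-intercept sd:", x$random_intercept_sd, "\n")
  cat("  coefficients:\n")
  print(x$fixed_coefficients)
  invisible(x)
}

#' Generate wildfires with random logit-scale intercepts
#'
#' Draws `n_fires` fires with independent Normal(0, sd^2) intercepts on the
#' logit scale and fire years uniform on 1984-2018.
#'
#' @param n_fires Number of fires (>= 1).
#' @param sd Nonnegative sd of the random intercepts.
#' @param seed Integer seed.
#' @return A data.frame with columns `fire_id`, `fire_year`, `intercept`.
#' @export
generate_fires <- function(n_fires, sd = 1, seed = DEFAULT_SEED) {
  n_fires <- check_count(n_fires, "n_fires")
  check_number(sd, "sd", lower = 0)
  with_seed(seed, {
    data.frame(
      fire_id = sprintf("fire_%04d", seq_len(n_fires)),
      fire_year = sample(1984:2018, n_fires, replace = TRUE),
      intercept = stats::rnorm(n_fires, 0, sd),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate synthetic monthly climate series
#'
#' Emulates gridMET-style site climate at monthly resolution over 1979-2050:
#' temperature follows a sinusoidal seasonal cycle (July peak) plus a site
#' offset, interannual noise, and an optional linear warming trend;
#' precipitation is winter-peaked gamma noise (nonnegative by construction);
#' vapor pressure deficit is summer-peaked. One series per site.
#'
#' @param site_count Number of sites (>= 1).
#' @param trend_c_per_decade Warming trend added to temperature (degrees C per
#'   decade, referenced to 1979).
#' @param seed Integer seed.
#' @param years Years covered (default 1979:2050 spanning historical and
#'   future periods).
#' @return A long data.frame (`site`, `year`, `month`, `tmean_c`, `precip_mm`,
#'   `vpd_kpa`) with a `sites` attribute holding per-site latitude.
#' @export
generate_climate_series <- function(site_count, trend_c_per_decade = 0,
                                    seed = DEFAULT_SEED, years = 1979:2050) {
  site_count <- check_count(site_count, "site_count")
  check_number(trend_c_per_decade, "trend_c_per_decade")
  with_seed(seed, {
    sites <- data.frame(
      site = sprintf("site_%04d", seq_len(site_count)),
      latitude = stats::runif(site_count, 33, 48),
      tmean_offset_c = stats::runif(site_count, 2, 10),
      tamp_c = stats::runif(site_count, 8, 14),
      precip_mu_mm = stats::runif(site_count, 25, 80),
      vpd_base_kpa = stats::runif(site_count, 0.6, 1.4),
      stringsAsFactors = FALSE
    )
    ny <- length(years)
    grid <- expand.grid(month = 1:12, year = years, site_i = seq_len(site_count),
                        KEEP.OUT.ATTRS = FALSE)
    m <- grid$month
    season <- cos(2 * pi * (m - 7) / 12)           # +1 in July, -1 in January
    trend <- trend_c_per_decade * (grid$year - years[1]) / 10
    tmean <- sites$tmean_offset_c[grid$site_i] + sites$tamp_c[grid$site_i] * season +
      trend + stats::rnorm(nrow(grid), 0, 1.5)
    pr_mu <- sites$precip_mu_mm[grid$site_i] * (1 + 0.6 * cos(2 * pi * (m - 1) / 12))
    precip <- stats::rgamma(nrow(grid), shape = 2, scale = pmax(pr_mu, 1) / 2)
    vpd <- pmax(0.05, sites$vpd_base_kpa[grid$site_i] + 0.8 * season +
                  0.1 * trend + stats::rnorm(nrow(grid), 0, 0.15))
    out <- data.frame(site = sites$site[grid$site_i], year = grid$year,
                      month = m, tmean_c = tmean, precip_mm = precip,
                      vpd_kpa = vpd, stringsAsFactors = FALSE)
    out <- out[order(out$site, out$year, out$month), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "sites") <- sites[, c("site", "latitude")]
    out
  })
}

# expand a truth-term name against the plot table: plain column, "col^2"
# quadratic, or "a:b" product; "(Intercept)" handled by the caller
truth_term_column <- function(plots, term) {
  if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    vals <- lapply(parts, truth_term_column, plots = plots)
    return(Reduce(`*`, vals))
  }
  if (grepl("^2", term, fixed = TRUE)) {
    base <- sub("\\^2$", "", term)
    stop_if_not(base %in% names(plots),
                "term `%s` has no matching column `%s` in the plot table", term, base)
    return(plots[[base]]^2)
  }
  stop_if_not(term %in% names(plots),
              "term `%s` has no matching column in the plot table", term)
  v <- plots[[term]]
  stop_if_not(is.numeric(v), "term `%s` refers to a non-numeric column", term)
  v
}

#' Simulate binomial recruitment outcomes from known truth
#'
#' Applies the logit-linear recruitment process: the linear predictor is
#' X beta + fire intercept + log(area m2), and presence is Bernoulli with
#' probability `plogis` of that predictor. Fire intercepts are taken from a
#' `fire_intercept` column when present (0 otherwise).
#'
#' @param plots Covariate table with one row per plot; must contain
#'   `area_m2 > 0` and a column for every term named in
#'   `truth$fixed_coefficients`.
#' @param truth A [truth_params()] object.
#' @param seed Integer seed (defaults to `truth$seed`).
#' @return `plots` with `prob` (true probability) and `presence` (0/1) added.
#' @export
simulate_recruitment <- function(plots, truth, seed = truth$seed) {
  stopifnot(inherits(truth, "truth_params"), is.data.frame(plots))
  check_columns(plots, "area_m2", "plot table")
  stop_if_not(all(plots$area_m2 > 0), "plot areas must be positive")
  beta <- truth$fixed_coefficients
  eta <- rep(0, nrow(plots))
  for (term in names(beta)) {
    x <- if (term %in% c("(Intercept)", "intercept")) 1 else truth_term_column(plots, term)
    eta <- eta + beta[[term]] * x
  }
  if ("fire_intercept" %in% names(plots)) eta <- eta + plots$fire_intercept
  eta <- eta + log(plots$area_m2)
  plots$prob <- logistic(eta)
  plots$presence <- with_seed(seed, stats::rbinom(nrow(plots), 1L, plots$prob))
  plots
}

# draw per-plot covariates for a fire table under the truth ranges
simulate_plot_covariates <- function(truth, fires, seed) {
  n <- nrow(fires) * truth$plots_per_fire
  fi <- rep(seq_len(nrow(fires)), each = truth$plots_per_fire)
  with_seed(seed, {
    plots <- data.frame(
      plot_id = sprintf("plot_%06d", seq_len(n)),
      fire_id = fires$fire_id[fi],
      fire_year = fires$fire_year[fi],
      stringsAsFactors = FALSE
    )
    delay <- sample(2:10, n, replace = TRUE)
    plots$survey_year <- plots$fire_year + delay
    plots$time_since_fire <- delay
    plots$area_m2 <- stats::runif(n, truth$area_m2_range[1], truth$area_m2_range[2])
    for (cv in names(truth$covariate_ranges)) {
      r <- truth$covariate_ranges[[cv]]
      plots[[cv]] <- stats::runif(n, r[1], r[2])
    }
    dist_levels <- c("none", "wildfire", "fuel_treatment", "beetle_outbreak", "blowdown")
    plots$prefire_disturbance <- sample(dist_levels, n, replace = TRUE,
                                        prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
    plots$variety <- sample(c("coastal", "interior"), n, replace = TRUE,
                            prob = c(0.55, 0.45))
    plots$burned <- TRUE
    plots$planted <- FALSE
    plots$fire_intercept <- fires$intercept[fi]
    plots
  })
}

#' Simulate a complete synthetic postfire regeneration study
#'
#' Generates fires with random intercepts, one climate site per fire, plot
#' covariates, per-site climatic water deficit metrics, and binomial
#' recruitment outcomes from the stated truth. The result feeds every
#' downstream stage (filtering, design, fitting, selection, projection).
#'
#' When climate metric columns (for example `deficit_z_max`) appear in
#' `truth$fixed_coefficients` they are joined onto the plot table before
#' outcomes are simulated, so climate effects in the truth are honoured.
#'
#' @param truth A [truth_params()] object.
#' @param whc_mm Soil water-holding capacity passed to the water balance.
#' @return An object of class `synthetic_dataset`: list with `plots`,
#'   `fires`, `climate`, `sites`, `metrics`, `truth`.
#' @export
simulate_dataset <- function(truth = truth_params(), whc_mm = 150) {
  stopifnot(inherits(truth, "truth_params"))
  fires <- generate_fires(truth$n_fires, truth$random_intercept_sd,
                          seed = stage_seed(truth$seed, "fires"))
  climate <- generate_climate_series(truth$n_fires, truth$climate_trend,
                                     seed = stage_seed(truth$seed, "climate"))
  sites <- attr(climate, "sites")
  # one climate site per fire, in order
  fires$site <- sites$site
  metrics <- climate_metrics(climate, sites, fires, whc_mm = whc_mm)
  plots <- simulate_plot_covariates(truth, fires,
                                    seed = stage_seed(truth$seed, "plots"))
  plots <- merge(plots, metrics, by = "fire_id", sort = FALSE)
  plots <- plots[order(plots$plot_id), , drop = FALSE]
  rownames(plots) <- NULL
  plots <- simulate_recruitment(plots, truth,
                                seed = stage_seed(truth$seed, "recruitment"))
  structure(list(plots = plots, fires = fires, climate = climate,
                 sites = sites, metrics = metrics, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic postfire regeneration dataset\n")
  cat(sprintf("  %d plots in %d fires; overall presence frequency %.3f\n",
              nrow(x$plots), nrow(x$fires), mean(x$plots$presence)))
  cat(sprintf("  climate: %d sites x %d months\n", nrow(x$sites),
              nrow(x$climate) / nrow(x$sites)))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `plots.csv`, `climate.csv` (long format: site, year, month,
#' tmean_c, precip_mm, vpd_kpa), `sites.csv`, `fires.csv`, `metrics.csv` and
#' a `truth.yaml` record of the generating parameters.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plots = file.path(dir, "plots.csv"),
             climate = file.path(dir, "climate.csv"),
             sites = file.path(dir, "sites.csv"),
             fires = file.path(dir, "fires.csv"),
             metrics = file.path(dir, "metrics.csv"),
             truth = file.path(dir, "truth.yaml"))
  utils::write.csv(dataset$plots, paths["plots"], row.names = FALSE)
  utils::write.csv(dataset$climate, paths["climate"], row.names = FALSE)
  utils::write.csv(dataset$sites, paths["sites"], row.names = FALSE)
  utils::write.csv(dataset$fires, paths["fires"], row.names = FALSE)
  utils::write.csv(dataset$metrics, paths["metrics"], row.names = FALSE)
  tr <- dataset$truth
  yaml::write_yaml(list(
    fixed_coefficients = as.list(tr$fixed_coefficients),
    random_intercept_sd = tr$random_intercept_sd,
    n_fires = tr$n_fires, plots_per_fire = tr$plots_per_fire,
    area_m2_range = tr$area_m2_range,
    covariate_ranges = tr$covariate_ranges,
    climate_trend = tr$climate_trend, seed = tr$seed
  ), paths["truth"])
  invisible(paths)
}
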