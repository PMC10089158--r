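#' Thornthwaite monthly potential evapotranspiration
#'
#' Classical Thornthwaite PET from monthly mean temperature and latitude:
#' the annual heat index is accumulated from the twelve monthly temperatures,
#' and each month's unadjusted PET is corrected by mean day length (from solar
#' declination at mid-month) and month length. Months at or below 0 degrees C
#' contribute no PET.
#'
#' @param tmean_c Numeric length-12 vector of monthly mean temperature
#'   (degrees C), January through December.
#' @param latitude_deg Site latitude in degrees, in \[-90, 90\].
#' @param year Calendar year (leap years lengthen February).
#' @return Numeric length-12 vector of PET in mm/month.
#' @export
compute_pet <- function(tmean_c, latitude_deg, year) {
  stop_if_not(length(tmean_c) == 12L && is.numeric(tmean_c),
              "`tmean_c` must be a numeric vector of 12 monthly means")
  check_number(latitude_deg, "latitude_deg", lower = -90, upper = 90)
  year <- check_count(year, "year", min = 0L)
  I <- sum((pmax(tmean_c, 0) / 5)^1.514)
  if (I <= 0) return(rep(0, 12))
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  nd <- days_in_month(year)
  L <- daylength_hours(latitude_deg, mid_month_doy(year))
  pet <- 16 * (10 * pmax(tmean_c, 0) / I)^a * (L / 12) * (nd / 30)
  pet[tmean_c <= 0] <- 0
  pet
}

days_in_month <- function(year) {
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  c(31L, 28L + as.integer(leap), 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
}

mid_month_doy <- function(year) {
  nd <- days_in_month(year)
  cumsum(nd) - nd / 2
}

# mean day length (hours) from solar declination; clamped for polar day/night
daylength_hours <- function(latitude_deg, doy) {
  phi <- latitude_deg * pi / 180
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  24 * acos(x) / pi
}

#' Run a Thornthwaite-Mather monthly water balance
#'
#' Tracks snowpack and soil moisture through a gap-free monthly series and
#' returns PET, AET, climatic water deficit (PET - AET), and the store states.
#' Precipitation is partitioned linearly into snow (all snow at or below
#' `t_snow_c`, all rain at or above `t_rain_c`); melt is proportional to
#' degree-days. When water supply (rain + melt) meets PET, AET = PET and any
#' surplus recharges soil then runs off; otherwise soil releases
#' `soil * (1 - exp(-(PET - supply)/whc))` (exponential drying) and the
#' unmet remainder is deficit. The first calendar year is run once as spin-up
#' and discarded, removing initial-condition sensitivity.
#'
#' @param series Data.frame with columns `year`, `month`, `tmean_c`,
#'   `precip_mm`, whole calendar years, chronologically ordered and gap-free.
#' @param whc_mm Soil water-holding capacity (mm), > 0.
#' @param latitude_deg Site latitude (degrees).
#' @param soil_init_mm Initial soil moisture (defaults to full, `whc_mm`).
#' @param t_snow_c,t_rain_c Snow/rain partition temperatures (degrees C).
#' @param melt_coef_mm_per_degday Degree-day melt coefficient (mm per C-day).
#' @param spinup Repeat the first year once to initialise stores (default TRUE).
#' @return Data.frame of class `water_balance`: `year`, `month`, `pet_mm`,
#'   `aet_mm`, `deficit_mm`, `snow_mm`, `soil_mm`, `runoff_mm` (store columns
#'   are end-of-month states).
#' @export
run_water_balance <- function(series, whc_mm = 150, latitude_deg = 45,
                              soil_init_mm = whc_mm, t_snow_c = 0, t_rain_c = 6,
                              melt_coef_mm_per_degday = 2, spinup = TRUE) {
  check_number(whc_mm, "whc_mm")
  stop_if_not(whc_mm > 0, "`whc_mm` must be > 0")
  check_number(latitude_deg, "latitude_deg", lower = -90, upper = 90)
  check_number(soil_init_mm, "soil_init_mm", lower = 0, upper = whc_mm)
  check_columns(series, c("year", "month", "tmean_c", "precip_mm"), "climate series")
  stop_if_not(nrow(series) >= 12L, "series must cover at least one calendar year")
  key <- series$year * 12 + (series$month - 1)
  gaps <- which(diff(key) != 1)
  if (length(gaps) > 0) {
    stop(sprintf("climate series has a gap or disorder after %d-%02d",
                 series$year[gaps[1]], series$month[gaps[1]]), call. = FALSE)
  }
  stop_if_not(series$month[1] == 1L && series$month[nrow(series)] == 12L,
              "series must consist of whole calendar years (Jan-Dec)")
  stop_if_not(all(series$precip_mm >= 0), "precipitation must be nonnegative")

  years <- unique(series$year)
  pet <- numeric(nrow(series))
  for (yr in years) {
    idx <- which(series$year == yr)
    pet[idx] <- compute_pet(series$tmean_c[idx], latitude_deg, yr)
  }

  n <- nrow(series)
  run_idx <- if (spinup) c(1:12, 1:n) else 1:n
  keep <- if (spinup) -(1:12) else TRUE

  snow <- 0
  soil <- soil_init_mm
  snow_start <- soil_start <- NA_real_  # states entering the first kept month
  aet <- def <- run <- snow_end <- soil_end <- numeric(length(run_idx))
  tm <- series$tmean_c[run_idx]
  pr <- series$precip_mm[run_idx]
  pe <- pet[run_idx]
  nd <- days_in_month(2001)[series$month[run_idx]]  # non-leap; melt scale only
  fs <- pmin(pmax((t_rain_c - tm) / (t_rain_c - t_snow_c), 0), 1)
  n_spin <- if (spinup) 12L else 0L
  for (i in seq_along(run_idx)) {
    if (i == n_spin + 1L) {
      snow_start <- snow
      soil_start <- soil
    }
    snow <- snow + pr[i] * fs[i]
    melt <- min(snow, melt_coef_mm_per_degday * max(tm[i], 0) * nd[i])
    snow <- snow - melt
    supply <- pr[i] * (1 - fs[i]) + melt
    if (supply >= pe[i]) {
      aet[i] <- pe[i]
      recharge <- min(whc_mm - soil, supply - pe[i])
      soil <- soil + recharge
      run[i] <- supply - pe[i] - recharge
      def[i] <- 0
    } else {
      withdrawal <- soil * (1 - exp(-(pe[i] - supply) / whc_mm))
      aet[i] <- min(supply + withdrawal, pe[i])
      soil <- soil - withdrawal
      run[i] <- 0
      def[i] <- max(pe[i] - aet[i], 0)
    }
    snow_end[i] <- snow
    soil_end[i] <- soil
  }
  out <- data.frame(year = series$year, month = series$month, pet_mm = pet,
                    aet_mm = aet[keep][seq_len(n)], deficit_mm = def[keep][seq_len(n)],
                    snow_mm = snow_end[keep][seq_len(n)],
                    soil_mm = soil_end[keep][seq_len(n)],
                    runoff_mm = run[keep][seq_len(n)])
  attr(out, "snow_init") <- snow_start
  attr(out, "soil_init") <- soil_start
  class(out) <- c("water_balance", "data.frame")
  out
}

#' Z-scores against a fixed baseline period
#'
#' Standardizes an annual (or seasonal-by-year) series against the mean and
#' sd (denominator n - 1) of a baseline period, 1981-2010 by default. A
#' zero-variance baseline yields all-zero z-scores with a warning.
#'
#' @param values Numeric series, one value per year.
#' @param years Integer years aligned with `values`.
#' @param baseline_years Years defining the baseline (>= 2 must be present).
#' @return Numeric z-scores aligned with `values`.
#' @export
baseline_zscore <- function(values, years, baseline_years = 1981:2010) {
  stop_if_not(length(values) == length(years), "`values` and `years` differ in length")
  base <- values[years %in% baseline_years]
  stop_if_not(length(base) >= 2L, "need at least 2 baseline years, found %d", length(base))
  m <- mean(base)
  s <- stats::sd(base)
  if (s == 0) {
    warning("baseline sd is 0; z-scores set to 0", call. = FALSE)
    return(rep(0, length(values)))
  }
  (values - m) / s
}

#' Postfire extremes of an annual anomaly series
#'
#' Returns the maximum and minimum of a per-year seasonal z-score series over
#' the first `window` years following a fire (fire_year + 1 through
#' fire_year + window).
#'
#' @param z Numeric z series, one value per year.
#' @param years Integer years aligned with `z`.
#' @param fire_year Year of the fire.
#' @param window Number of postfire years (default 5).
#' @return Named numeric vector `c(max = , min = )`.
#' @export
postfire_extremes <- function(z, years, fire_year, window = 5L) {
  window <- check_count(window, "window")
  want <- fire_year + seq_len(window)
  missing <- setdiff(want, years)
  stop_if_not(length(missing) == 0L,
              "postfire window incomplete; missing year(s): %s",
              paste(missing, collapse = ", "))
  zz <- z[match(want, years)]
  c(max = max(zz), min = min(zz))
}

# annual aggregates used for the climate metrics: calendar-year deficit sum,
# growing-season (Apr-Sep) deficit and precipitation sums, June-Aug VPD mean
annual_climate_series <- function(wb, climate_site) {
  yrs <- sort(unique(wb$year))
  gs <- wb$month %in% 4:9
  ann_def <- rowsum(wb$deficit_mm, wb$year)[, 1]
  gs_def <- rowsum(wb$deficit_mm[gs], wb$year[gs])[, 1]
  gs_pr <- rowsum(climate_site$precip_mm[gs], climate_site$year[gs])[, 1]
  jja <- climate_site$month %in% 6:8
  jja_vpd <- rowsum(climate_site$vpd_kpa[jja], climate_site$year[jja])[, 1] / 3
  list(years = yrs, annual_deficit = ann_def[as.character(yrs)],
       gs_deficit = gs_def[as.character(yrs)],
       gs_precip = gs_pr[as.character(yrs)],
       jja_vpd = jja_vpd[as.character(yrs)])
}

#' Per-site climate metrics for the regeneration model
#'
#' For each fire (one climate site per fire) runs the water balance and
#' derives the model's climate covariates: 30-y (1981-2010) mean annual and
#' growing-season (April-September) climatic water deficit, and the maximum
#' and minimum over the first 5 postfire years of three baseline-standardized
#' anomalies: growing-season deficit z, June-August vapor pressure deficit z,
#' and growing-season precipitation z.
#'
#' @param climate Long monthly climate table (`site`, `year`, `month`,
#'   `tmean_c`, `precip_mm`, `vpd_kpa`).
#' @param sites Data.frame with `site` and `latitude`.
#' @param fires Data.frame with `fire_id`, `fire_year`, `site`.
#' @param whc_mm Soil water-holding capacity (mm).
#' @param baseline_years Baseline period for means and z-scores.
#' @param window Postfire window length in years (default 5).
#' @return Data.frame keyed by `fire_id` and `site` with columns
#'   `mean_annual_deficit_mm`, `mean_gs_deficit_mm`, `deficit_z_max`,
#'   `deficit_z_min`, `vpd_z_max`, `vpd_z_min`, `precip_z_max`, `precip_z_min`.
#' @export
climate_metrics <- function(climate, sites, fires, whc_mm = 150,
                            baseline_years = 1981:2010, window = 5L) {
  check_columns(climate, c("site", "year", "month", "tmean_c", "precip_mm", "vpd_kpa"),
                "climate table")
  check_columns(sites, c("site", "latitude"), "sites table")
  check_columns(fires, c("fire_id", "fire_year", "site"), "fires table")
  res <- vector("list", nrow(fires))
  ann_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(fires))) {
    s <- fires$site[i]
    if (is.null(ann_cache[[s]])) {
      cs <- climate[climate$site == s, , drop = FALSE]
      lat <- sites$latitude[match(s, sites$site)]
      wb <- run_water_balance(cs, whc_mm = whc_mm, latitude_deg = lat)
      ann_cache[[s]] <- annual_climate_series(wb, cs)
    }
    a <- ann_cache[[s]]
    z_def <- baseline_zscore(a$gs_deficit, a$years, baseline_years)
    z_vpd <- baseline_zscore(a$jja_vpd, a$years, baseline_years)
    z_pr <- baseline_zscore(a$gs_precip, a$years, baseline_years)
    e_def <- postfire_extremes(z_def, a$years, fires$fire_year[i], window)
    e_vpd <- postfire_extremes(z_vpd, a$years, fires$fire_year[i], window)
    e_pr <- postfire_extremes(z_pr, a$years, fires$fire_year[i], window)
    base <- a$years %in% baseline_years
    res[[i]] <- data.frame(
      fire_id = fires$fire_id[i], site = s,
      mean_annual_deficit_mm = mean(a$annual_deficit[base]),
      mean_gs_deficit_mm = mean(a$gs_deficit[base]),
      deficit_z_max = e_def[["max"]], deficit_z_min = e_def[["min"]],
      vpd_z_max = e_vpd[["max"]], vpd_z_min = e_vpd[["min"]],
      precip_z_max = e_pr[["max"]], precip_z_min = e_pr[["min"]],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, res)
}

#' Period-average climate metrics for scenario projection
#'
#' For a 20-y projection period, computes for every feasible fire year in the
#' period (those whose full postfire window lies within the climate series)
#' the 5-y postfire anomaly extremes, and averages them across fire years.
#' The 30-y baseline means are unchanged. This is the climate input for
#' projecting mean recruitment probability over a period.
#'
#' @inheritParams climate_metrics
#' @param period Length-2 integer vector, e.g. `c(1981, 2000)`.
#' @return Data.frame keyed by `site` with the same metric columns as
#'   [climate_metrics()].
#' @export
period_climate_metrics <- function(climate, sites, period, whc_mm = 150,
                                   baseline_years = 1981:2010, window = 5L) {
  stop_if_not(length(period) == 2L && period[2] >= period[1],
              "`period` must be c(start, end)")
  check_columns(climate, c("site", "year", "month", "tmean_c", "precip_mm", "vpd_kpa"),
                "climate table")
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites$site[i]
    cs <- climate[climate$site == s, , drop = FALSE]
    wb <- run_water_balance(cs, whc_mm = whc_mm, latitude_deg = sites$latitude[i])
    a <- annual_climate_series(wb, cs)
    fire_years <- period[1]:period[2]
    fire_years <- fire_years[fire_years + window <= max(a$years)]
    stop_if_not(length(fire_years) > 0,
                "no feasible fire year in period %d-%d given the climate series",
                period[1], period[2])
    z_def <- baseline_zscore(a$gs_deficit, a$years, baseline_years)
    z_vpd <- baseline_zscore(a$jja_vpd, a$years, baseline_years)
    z_pr <- baseline_zscore(a$gs_precip, a$years, baseline_years)
    ex <- vapply(fire_years, function(fy) c(
      postfire_extremes(z_def, a$years, fy, window),
      postfire_extremes(z_vpd, a$years, fy, window),
      postfire_extremes(z_pr, a$years, fy, window)
    ), numeric(6))
    m <- rowMeans(ex)
    base <- a$years %in% baseline_years
    out[[i]] <- data.frame(
      site = s,
      mean_annual_deficit_mm = mean(a$annual_deficit[base]),
      mean_gs_deficit_mm = mean(a$gs_deficit[base]),
      deficit_z_max = m[1], deficit_z_min = m[2],
      vpd_z_max = m[3], vpd_z_min = m[4],
      precip_z_max = m[5], precip_z_min = m[6],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
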