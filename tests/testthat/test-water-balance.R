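test_that("Thornthwaite PET follows the convention and the formula", {
  tm <- c(-5, -2, 1, 6, 12, 17, 21, 20, 15, 8, 2, -3)
  pet <- compute_pet(tm, 45, 2000)
  expect_true(all(pet[tm <= 0] == 0))
  expect_true(all(pet >= 0))
  # daylength monotonicity: same temperature, June beats December at 45 N
  tm_flat <- rep(10, 12)
  pet_flat <- compute_pet(tm_flat, 45, 2001)
  expect_gt(pet_flat[6], pet_flat[12])
  # warmer months evaporate more at fixed daylength (same month, two series)
  pet_warm <- compute_pet(replace(tm, 7, 25), 45, 2000)
  expect_gt(pet_warm[7], pet[7])
  # spreadsheet oracle agreement
  expect_equal(pet, oracle_thornthwaite(tm, 45, 2000), tolerance = 1e-12)
  expect_equal(compute_pet(tm_flat, 60, 1996),
               oracle_thornthwaite(tm_flat, 60, 1996), tolerance = 1e-12)
  expect_error(compute_pet(tm, 95, 2000), "latitude")
})

test_that("water balance honours the saturated and desert limits", {
  # saturated: precipitation far above PET, soil full -> zero deficit
  wet <- make_climate_years(2000:2002, function(m, y) 5 + 10 * cos(2 * pi * (m - 7) / 12),
                            function(m, y) rep(400, length(m)))
  wb <- run_water_balance(wet, whc_mm = 150, latitude_deg = 45)
  expect_true(all(wb$deficit_mm <= 1e-9))
  expect_equal(wb$aet_mm, wb$pet_mm, tolerance = 1e-9)

  # desert: no precipitation, empty soil, warm months -> AET 0, deficit = PET
  dry <- make_climate_years(2000:2001, function(m, y) rep(20, length(m)),
                            function(m, y) rep(0, length(m)))
  wb2 <- run_water_balance(dry, whc_mm = 150, latitude_deg = 35, soil_init_mm = 0)
  expect_true(all(wb2$aet_mm == 0))
  expect_equal(wb2$deficit_mm, wb2$pet_mm)
})

test_that("water balance bookkeeping matches an independent hand ledger", {
  set.seed(8)
  series <- make_climate_years(2000:2001,
                               function(m, y) 2 + 12 * cos(2 * pi * (m - 7) / 12),
                               function(m, y) runif(length(m), 0, 120))
  whc <- 150; lat <- 44
  wb <- run_water_balance(series, whc_mm = whc, latitude_deg = lat)
  ledger <- oracle_water_ledger(series, whc, lat)
  expect_equal(wb$aet_mm, ledger$aet, tolerance = 1e-8)
  expect_equal(wb$deficit_mm, ledger$deficit, tolerance = 1e-8)
})

test_that("deficit is antitone in precipitation", {
  set.seed(15)
  base <- make_climate_years(1990:1992,
                             function(m, y) 4 + 11 * cos(2 * pi * (m - 7) / 12),
                             function(m, y) runif(length(m), 0, 60))
  wb0 <- run_water_balance(base, 150, 45)
  for (i in c(5, 18, 30)) {
    up <- base
    up$precip_mm[i] <- up$precip_mm[i] + 50
    wb1 <- run_water_balance(up, 150, 45)
    expect_true(all(wb1$deficit_mm <= wb0$deficit_mm + 1e-9))
  }
})

test_that("gap and ordering violations are rejected with the offending month", {
  s <- make_climate_years(2000:2000, function(m, y) rep(10, 12),
                          function(m, y) rep(50, 12))
  s2 <- s[-5, ]
  expect_error(run_water_balance(rbind(s2, s[5, ])), "2000-04")
})

test_that("baseline z-scores standardize exactly and handle degeneracy", {
  z <- baseline_zscore(c(1, 2, 3, 4), years = c(1981, 1982, 1983, 2020),
                       baseline_years = 1981:1983)
  expect_equal(z[4], 2)        # (4 - 2) / 1
  expect_equal(z[2], 0)        # query at the baseline mean

  vals <- rnorm(40, 5, 2)
  yrs <- 1981:2020
  zz <- baseline_zscore(vals, yrs, 1981:2010)
  inb <- yrs %in% 1981:2010
  expect_lt(abs(mean(zz[inb])), 1e-10)
  expect_lt(abs(sd(zz[inb]) - 1), 1e-10)

  expect_warning(zc <- baseline_zscore(rep(3, 5), 1981:1985, 1981:1985), "sd is 0")
  expect_true(all(zc == 0))
  expect_error(baseline_zscore(1, 1981, 1981:2010), "baseline")
})

test_that("postfire extremes pick the window max and min", {
  z <- c(0.5, -1.2, 2.0, 0.1, -0.3)
  yrs <- 2001:2005
  ex <- postfire_extremes(z, yrs, fire_year = 2000, window = 5)
  expect_equal(ex, c(max = 2.0, min = -1.2))
  expect_equal(postfire_extremes(rep(0.7, 5), yrs, 2000, 5), c(max = 0.7, min = 0.7))
  expect_equal(postfire_extremes(z, yrs, 2000, window = 1), c(max = 0.5, min = 0.5))
  expect_error(postfire_extremes(z, yrs, 2003, 5), "2006, 2007, 2008")
})

test_that("30-y mean annual deficit equals the mean of annual sums", {
  cl <- generate_climate_series(1, 0, seed = 77, years = 1979:2024)
  sites <- attr(cl, "sites")
  fires <- data.frame(fire_id = "f1", fire_year = 2015, site = sites$site)
  m <- climate_metrics(cl, sites, fires)
  wb <- run_water_balance(cl, whc_mm = 150, latitude_deg = sites$latitude[1])
  ann <- tapply(wb$deficit_mm, wb$year, sum)
  expect_equal(m$mean_annual_deficit_mm,
               mean(ann[as.character(1981:2010)]), tolerance = 1e-12)
  expect_true(m$deficit_z_max >= m$deficit_z_min)
  expect_true(m$vpd_z_max >= m$vpd_z_min)
  expect_true(m$precip_z_max >= m$precip_z_min)
})

test_that("period metrics average the per-fire-year extremes", {
  cl <- generate_climate_series(1, 0, seed = 78, years = 1979:2030)
  sites <- attr(cl, "sites")
  pm <- period_climate_metrics(cl, sites, period = c(2001, 2020))
  fy <- 2001:2020
  per_year <- sapply(fy, function(f) {
    m <- climate_metrics(cl, sites, data.frame(fire_id = "f", fire_year = f,
                                               site = sites$site))
    m$deficit_z_max
  })
  expect_equal(pm$deficit_z_max, mean(per_year), tolerance = 1e-12)
})
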