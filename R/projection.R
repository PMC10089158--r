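# Scenario projection: severity-bundle x climate-period predictions,
# three-way likelihood categories, area summaries, partial dependence.

#' Define a fire-severity projection scenario
#'
#' The two severity bundles fix the seed-availability and severity covariates:
#' low severity = 10 m to seed source, 30 % surrounding tree cover, RBR 100;
#' high severity = 150 m, 10 % cover, RBR 400. Time since fire (10 y) and
#' plot area (100 m2) are held constant, so probabilities refer to at least
#' one seedling in a 0.01-ha plot (100 trees/ha equivalent).
#'
#' @param severity `"low"` or `"high"`.
#' @param period Length-2 integer climate period, one of 1981-2000, 2001-2020,
#'   2031-2050 in the standard run (any range is accepted).
#' @param rcp Optional emissions label for future periods ("RCP4.5"/"RCP8.5").
#' @return Object of class `scenario` with the covariate bundle.
#' @export
scenario <- function(severity = c("low", "high"), period, rcp = NA_character_) {
  severity <- match.arg(severity)
  stop_if_not(length(period) == 2L && period[2] >= period[1],
              "`period` must be c(start, end)")
  bundle <- if (severity == "low") {
    list(distance_m = 10, tree_cover_pct = 30, rbr = 100)
  } else {
    list(distance_m = 150, tree_cover_pct = 10, rbr = 400)
  }
  structure(list(severity = severity, period = as.integer(period), rcp = rcp,
                 bundle = bundle, time_since_fire = 10, area_m2 = 100),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("%s-severity scenario, period %d-%d%s\n", x$severity,
              x$period[1], x$period[2],
              if (is.na(x$rcp)) "" else paste0(" (", x$rcp, ")")))
  cat(sprintf("  distance %g m, tree cover %g %%, RBR %g; 10 y postfire, 100 m2\n",
              x$bundle$distance_m, x$bundle$tree_cover_pct, x$bundle$rbr))
  invisible(x)
}

#' Project recruitment probability under a scenario
#'
#' Overrides the severity covariates with the scenario bundle, joins the
#' period's climate metrics, fixes time since fire at 10 y and plot area at
#' 100 m2, and predicts at the population level (random intercept zero,
#' targeting new fires). Non-scenario covariates come from `sites`;
#' categorical covariates default to their reference level when absent.
#'
#' @param fitted A `regen_glmm` carrying design info.
#' @param sites Data.frame of per-site covariates (must include `site` and
#'   any model covariates not set by the scenario or the metrics).
#' @param metrics Period climate metrics from [period_climate_metrics()]
#'   (keyed by `site`).
#' @param scen A [scenario()].
#' @return `sites` with a `prob` column appended.
#' @export
project_scenario <- function(fitted, sites, metrics, scen) {
  stopifnot(inherits(fitted, "regen_glmm"), inherits(scen, "scenario"))
  check_columns(sites, "site", "sites table")
  check_columns(metrics, "site", "metrics table")
  stop_if_not(all(sites$site %in% metrics$site),
              "metrics missing for %d site(s)", sum(!sites$site %in% metrics$site))
  nd <- merge(sites, metrics, by = "site", sort = FALSE,
              suffixes = c(".site", ""))
  nd <- nd[match(sites$site, nd$site), , drop = FALSE]
  for (v in names(scen$bundle)) nd[[v]] <- scen$bundle[[v]]
  nd$time_since_fire <- scen$time_since_fire
  spec <- fitted$design_info$spec
  for (v in spec$categorical) {
    if (!v %in% names(nd)) nd[[v]] <- fitted$design_info$scaling$xlevels[[v]][1]
  }
  missing <- setdiff(spec$fixed, names(nd))
  stop_if_not(length(missing) == 0L, "sites/metrics lack model covariate(s): %s",
              paste(missing, collapse = ", "))
  sites$prob <- predict_probability(fitted, nd, area_m2 = scen$area_m2,
                                    level = "population")
  sites
}

#' Classify sites by scenario-pair likelihood
#'
#' Applies the three-way rule: recruitment unlikely under both severity
#' scenarios, likely only under the low-severity scenario, or likely under
#' both ("likely" = probability strictly above the threshold). Sites likely
#' under high severity but not low (possible only when severity effects are
#' sign-reversed) get the explicit fourth category and are flagged.
#'
#' @param prob_low,prob_high Per-site probabilities under the low/high bundle.
#' @param threshold Probability cutoff in \[0, 1\].
#' @param site Optional site labels.
#' @param region Optional region labels.
#' @param cell_area Per-site area weights (default 1).
#' @return Data.frame of class `category_map`: `site`, `region`, `cell_area`,
#'   `prob_low`, `prob_high`, `category` (factor), `anomalous` (logical).
#' @export
classify_sites <- function(prob_low, prob_high, threshold,
                           site = seq_along(prob_low), region = "all",
                           cell_area = 1) {
  stop_if_not(length(prob_low) == length(prob_high),
              "probability vectors differ in length")
  stop_if_not(all(prob_low >= 0 & prob_low <= 1) &&
                all(prob_high >= 0 & prob_high <= 1),
              "probabilities must be in [0, 1]")
  check_number(threshold, "threshold", lower = 0, upper = 1)
  lo <- prob_low > threshold
  hi <- prob_high > threshold
  lev <- c("unlikely_both", "likely_low_only", "likely_both", "likely_high_only")
  cat_chr <- ifelse(lo & hi, "likely_both",
                    ifelse(lo & !hi, "likely_low_only",
                           ifelse(!lo & !hi, "unlikely_both", "likely_high_only")))
  anomalous <- !lo & hi
  if (any(anomalous)) {
    warning(sprintf("%d site(s) likely under high severity only (flagged)",
                    sum(anomalous)), call. = FALSE)
  }
  out <- data.frame(site = site, region = rep_len(region, length(prob_low)),
                    cell_area = rep_len(cell_area, length(prob_low)),
                    prob_low = prob_low, prob_high = prob_high,
                    category = factor(cat_chr, levels = lev),
                    anomalous = anomalous, stringsAsFactors = FALSE)
  class(out) <- c("category_map", "data.frame")
  out
}

#' Area-weighted category proportions by region
#'
#' @param map A [classify_sites()] result.
#' @param by Grouping column (default `"region"`).
#' @return Data.frame with one row per region x category and columns
#'   `region`, `category`, `area`, `proportion`; proportions sum to 1 within
#'   each region.
#' @export
area_summary <- function(map, by = "region") {
  stopifnot(inherits(map, "category_map"))
  stop_if_not(nrow(map) > 0, "empty category map")
  stop_if_not(all(map$cell_area > 0), "cell areas must be positive")
  regions <- unique(map$region)
  out <- list()
  for (r in regions) {
    sub <- map[map$region == r, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("region `%s` is empty; omitted", r), call. = FALSE)
      next
    }
    tot <- sum(sub$cell_area)
    stop_if_not(tot > 0, "region `%s` has zero total area", r)
    area <- rowsum(sub$cell_area, sub$category)[, 1]
    area <- area[levels(map$category)]
    area[is.na(area)] <- 0
    names(area) <- levels(map$category)
    out[[r]] <- data.frame(region = r, category = names(area),
                           area = unname(area),
                           proportion = unname(area) / tot,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Partial dependence of recruitment probability on a model term
#'
#' Sweeps a continuous focal covariate over its observed range (raw scale)
#' while holding all other continuous covariates at their medians and
#' categorical covariates at their reference level, and predicts at the
#' population level for a 100-m2 plot 10 y postfire (time since fire is held
#' at its median if it is not the focal term and `fix_time` is NA). When an
#' interacting covariate is named, three curves are drawn with it held at its
#' 10th, 50th and 90th percentiles. 95% bands come from multivariate-normal
#' draws of the coefficients (percentile 2.5/97.5). A categorical focal term
#' yields per-level point estimates with the same intervals.
#'
#' @param fitted A `regen_glmm` with design info.
#' @param data Model table the percentiles/medians are computed from.
#' @param focal Name of the focal covariate.
#' @param interacting Optional name of an interacting covariate.
#' @param draws Coefficient draws for the bands (>= 200; default 1000).
#' @param seed Integer seed for the draws.
#' @param n_points Sweep resolution (default 100).
#' @param area_m2 Plot area for predictions (default 100).
#' @return Data.frame with `focal`, `focal_value` (or `level`),
#'   `interacting`, `interacting_percentile`, `prob`, `lwr`, `upr`.
#' @export
partial_dependence <- function(fitted, data, focal, interacting = NULL,
                               draws = 1000L, seed = DEFAULT_SEED,
                               n_points = 100L, area_m2 = 100) {
  stopifnot(inherits(fitted, "regen_glmm"))
  draws <- check_count(draws, "draws", min = 200L)
  spec <- fitted$design_info$spec
  stop_if_not(focal %in% spec$fixed, "`%s` is not a model term", focal)
  check_columns(data, spec$fixed, "model table")

  base <- data.frame(row.names = 1)
  for (v in spec$fixed) {
    base[[v]] <- if (v %in% spec$categorical) {
      fitted$design_info$scaling$xlevels[[v]][1]
    } else {
      stats::median(data[[v]])
    }
  }

  if (focal %in% spec$categorical) {
    levels_f <- fitted$design_info$scaling$xlevels[[focal]]
    nd <- base[rep(1, length(levels_f)), , drop = FALSE]
    nd[[focal]] <- levels_f
    grid_info <- data.frame(focal = focal, level = levels_f,
                            interacting = NA_character_,
                            interacting_percentile = NA_real_,
                            stringsAsFactors = FALSE)
  } else {
    sweep <- seq(min(data[[focal]]), max(data[[focal]]), length.out = n_points)
    if (is.null(interacting)) {
      nd <- base[rep(1, n_points), , drop = FALSE]
      nd[[focal]] <- sweep
      grid_info <- data.frame(focal = focal, focal_value = sweep,
                              interacting = NA_character_,
                              interacting_percentile = NA_real_,
                              stringsAsFactors = FALSE)
    } else {
      stop_if_not(interacting %in% spec$fixed && !(interacting %in% spec$categorical),
                  "`interacting` must be a continuous model term")
      pct <- stats::quantile(data[[interacting]], c(0.1, 0.5, 0.9), names = FALSE)
      nd <- base[rep(1, 3 * n_points), , drop = FALSE]
      nd[[focal]] <- rep(sweep, 3)
      nd[[interacting]] <- rep(pct, each = n_points)
      grid_info <- data.frame(focal = focal, focal_value = rep(sweep, 3),
                              interacting = interacting,
                              interacting_percentile = rep(c(10, 50, 90),
                                                           each = n_points),
                              stringsAsFactors = FALSE)
    }
  }
  rownames(nd) <- NULL
  nd$area_m2 <- area_m2
  nd$fire_id <- "new_fire"
  des <- build_design(nd, spec, scaling = fitted$design_info$scaling)
  eta <- drop(des$X %*% fitted$coefficients) + des$offset
  grid_info$prob <- logistic(eta)

  V <- fitted$vcov
  cholV <- chol((V + t(V)) / 2)
  Z <- with_seed(seed, matrix(stats::rnorm(draws * ncol(V)), draws, ncol(V)))
  beta_draws <- Z %*% cholV
  beta_draws <- sweep(beta_draws, 2, fitted$coefficients, `+`)
  eta_draws <- beta_draws %*% t(des$X)                      # draws x points
  p_draws <- logistic(sweep(eta_draws, 2, des$offset, `+`))
  ci <- apply(p_draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  grid_info$lwr <- ci[1, ]
  grid_info$upr <- ci[2, ]
  grid_info
}
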