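# End-to-end orchestration: simulate -> metrics -> assemble -> fit -> select
# -> threshold -> project, with per-stage seeds, config hashing and cached
# stage outputs.

#' Build a pipeline run configuration
#'
#' One global seed fans out to per-stage seeds by stable hashing of stage
#' names, so every stage is reproducible independent of execution order. The
#' configuration round-trips through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory for stage artifacts.
#' @param n_fires,plots_per_fire Synthetic study dimensions.
#' @param random_intercept_sd Truth random-intercept sd.
#' @param fixed_coefficients Named truth coefficients (raw covariate scale).
#' @param climate_trend Warming trend, degrees C per decade.
#' @param whc_mm Soil water-holding capacity for the water balance.
#' @param k Cross-validation folds.
#' @param spec A [model_spec()] for the full model (default: biophysical core
#'   + postfire deficit anomaly + 30-y mean deficit + their interaction).
#' @param threshold_method `"max_kappa"` (default) or `"max_sens_spec"`.
#' @param periods Named list of projection periods.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = DEFAULT_SEED,
                       out_dir = tempfile("regenfire_run_"),
                       n_fires = 40L, plots_per_fire = 20L,
                       random_intercept_sd = 0.8,
                       fixed_coefficients = c(
                         "(Intercept)" = -4.4,
                         distance_m = -0.008,
                         tree_cover_pct = 0.03,
                         rbr = -0.0015,
                         time_since_fire = 0.1,
                         deficit_z_max = -0.6,
                         mean_annual_deficit_mm = -0.004
                       ),
                       climate_trend = 0.3,
                       whc_mm = 150,
                       k = 10L,
                       spec = NULL,
                       threshold_method = "max_kappa",
                       periods = list(`1981-2000` = c(1981L, 2000L),
                                      `2001-2020` = c(2001L, 2020L),
                                      `2031-2050` = c(2031L, 2050L))) {
  if (is.null(spec)) {
    spec <- model_spec(
      fixed = c("time_since_fire", "distance_m", "rbr", "tree_cover_pct",
                "chili", "prefire_disturbance", "variety",
                "deficit_z_max", "mean_annual_deficit_mm"),
      interactions = list(c("deficit_z_max", "mean_annual_deficit_mm")),
      climate = c("deficit_z_max", "mean_annual_deficit_mm")
    )
  }
  structure(list(seed = check_count(seed, "seed", min = 0L), out_dir = out_dir,
                 n_fires = check_count(n_fires, "n_fires"),
                 plots_per_fire = check_count(plots_per_fire, "plots_per_fire"),
                 random_intercept_sd = random_intercept_sd,
                 fixed_coefficients = fixed_coefficients,
                 climate_trend = climate_trend, whc_mm = whc_mm,
                 k = check_count(k, "k", min = 2L), spec = spec,
                 threshold_method = threshold_method, periods = periods),
            class = "run_config")
}

#' Write a run configuration as YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  doc <- unclass(config)
  doc$fixed_coefficients <- as.list(doc$fixed_coefficients)
  doc$spec <- list(response = config$spec$response, fixed = config$spec$fixed,
                   quadratic = config$spec$quadratic,
                   interactions = config$spec$interactions,
                   categorical = config$spec$categorical,
                   climate = config$spec$climate)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path A file written by [write_run_config()].
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  spec <- model_spec(fixed = unlist(doc$spec$fixed),
                     quadratic = as.character(unlist(doc$spec$quadratic)),
                     interactions = lapply(doc$spec$interactions, unlist),
                     categorical = as.character(unlist(doc$spec$categorical)),
                     climate = as.character(unlist(doc$spec$climate)),
                     response = doc$spec$response)
  run_config(seed = doc$seed, out_dir = doc$out_dir, n_fires = doc$n_fires,
             plots_per_fire = doc$plots_per_fire,
             random_intercept_sd = doc$random_intercept_sd,
             fixed_coefficients = unlist(doc$fixed_coefficients),
             climate_trend = doc$climate_trend, whc_mm = doc$whc_mm,
             k = doc$k, spec = spec, threshold_method = doc$threshold_method,
             periods = lapply(doc$periods, as.integer))
}

# stable hash of an R object: canonical serialization to a temp file, md5
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}

file_hashes <- function(paths) {
  unname(vapply(paths, function(p) unname(tools::md5sum(p)), character(1)))
}

#' Run the full analysis pipeline
#'
#' Executes the seven stages in dependency order, writing plain-text
#' artifacts under `config$out_dir`. Each stage records a hash of its
#' configuration plus its input files; a stage is re-used from cache only
#' when that hash and its own output files are unchanged, so corrupting or
#' reconfiguring any stage recomputes it and its descendants.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress (default FALSE).
#' @return Invisibly, the run manifest: list with per-stage artifact paths,
#'   hashes, cached flags and timings (seconds). The manifest is also written
#'   (without timings) to `manifest.json`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  old <- if (file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path, simplifyVector = FALSE),
             error = function(e) list())
  } else list()
  manifest <- list()
  timings <- c()
  say <- function(...) if (verbose) message(sprintf(...))

  stage_fresh <- function(name, hash, outputs) {
    rec <- old[[name]]
    !is.null(rec) && identical(rec$hash, hash) &&
      all(file.exists(outputs)) &&
      identical(unlist(rec$output_md5), file_hashes(outputs))
  }
  recomputed <- character()
  run_stage <- function(name, stage_cfg, inputs, outputs, fn, parents = character()) {
    hash <- config_hash(list(stage = name, cfg = stage_cfg,
                             inputs = file_hashes(inputs)))
    if (!any(parents %in% recomputed) && stage_fresh(name, hash, outputs)) {
      say("stage %-10s cached", name)
      manifest[[name]] <<- list(hash = hash, outputs = as.list(basename(outputs)),
                                output_md5 = as.list(file_hashes(outputs)),
                                cached = TRUE)
      return(invisible(NULL))
    }
    say("stage %-10s running", name)
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({fn(); TRUE}, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    recomputed <<- c(recomputed, name)
    manifest[[name]] <<- list(hash = hash, outputs = as.list(basename(outputs)),
                              output_md5 = as.list(file_hashes(outputs)),
                              cached = FALSE)
    invisible(NULL)
  }
  path <- function(f) file.path(config$out_dir, f)

  # 1. simulate ---------------------------------------------------------------
  sim_cfg <- config[c("seed", "n_fires", "plots_per_fire", "random_intercept_sd",
                      "fixed_coefficients", "climate_trend", "whc_mm")]
  sim_cfg$fixed_coefficients <- as.list(sim_cfg$fixed_coefficients)
  sim_out <- path(c("plots.csv", "climate.csv", "sites.csv", "fires.csv",
                    "metrics.csv", "truth.yaml"))
  run_stage("simulate", sim_cfg, character(), sim_out, function() {
    truth <- truth_params(fixed_coefficients = config$fixed_coefficients,
                          random_intercept_sd = config$random_intercept_sd,
                          n_fires = config$n_fires,
                          plots_per_fire = config$plots_per_fire,
                          climate_trend = config$climate_trend,
                          seed = stage_seed(config$seed, "simulate"))
    ds <- simulate_dataset(truth, whc_mm = config$whc_mm)
    write_dataset(ds, config$out_dir)
  })

  # 2. metrics (recomputed from the climate CSV; validates the written files)
  run_stage("metrics", list(whc = config$whc_mm), path(c("climate.csv",
                                                         "sites.csv", "fires.csv")),
            path("metrics_check.csv"), function() {
    climate <- utils::read.csv(path("climate.csv"))
    sites <- utils::read.csv(path("sites.csv"))
    fires <- utils::read.csv(path("fires.csv"))
    m <- climate_metrics(climate, sites, fires, whc_mm = config$whc_mm)
    utils::write.csv(m, path("metrics_check.csv"), row.names = FALSE)
  }, parents = "simulate")

  # 3. assemble ---------------------------------------------------------------
  run_stage("assemble", list(), path(c("plots.csv", "metrics_check.csv")),
            path(c("model_table.csv", "screen.json")), function() {
    plots <- utils::read.csv(path("plots.csv"))
    metrics <- utils::read.csv(path("metrics_check.csv"))
    asm <- assemble_model_table(plots, metrics)
    utils::write.csv(asm$table, path("model_table.csv"), row.names = FALSE)
    cont <- intersect(setdiff(config$spec$fixed, config$spec$categorical),
                      names(asm$table))
    screen <- collinearity_screen(as.matrix(asm$table[, cont, drop = FALSE]))
    jsonlite::write_json(list(filter_log = as.list(asm$filter_log),
                              n_dropped_missing = asm$n_dropped_missing,
                              flagged_pairs = screen$pairs,
                              vif = as.list(screen$vif)),
                         path("screen.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }, parents = c("simulate", "metrics"))

  # 4. fit the full model -----------------------------------------------------
  run_stage("fit", list(), path("model_table.csv"), path("model_full.json"),
            function() {
    tab <- utils::read.csv(path("model_table.csv"))
    fit <- fit_glmm(build_design(tab, config$spec))
    write_glmm_json(fit, path("model_full.json"))
  }, parents = "assemble")

  # 5. backward selection + final refit ---------------------------------------
  run_stage("select", list(k = config$k), path("model_table.csv"),
            path(c("selection.json", "model_final.json")), function() {
    tab <- utils::read.csv(path("model_table.csv"))
    tr <- backward_select(config$spec, tab, k = config$k,
                          seed = stage_seed(config$seed, "select"))
    write_selection_json(tr, path("selection.json"))
    fit <- fit_glmm(build_design(tab, tr$final_spec))
    write_glmm_json(fit, path("model_final.json"))
  }, parents = "assemble")

  # 6. thresholds on out-of-fold predictions ----------------------------------
  run_stage("threshold", list(k = config$k, method = config$threshold_method),
            path(c("model_table.csv", "selection.json")),
            path("thresholds.json"), function() {
    tab <- utils::read.csv(path("model_table.csv"))
    sel <- jsonlite::read_json(path("selection.json"), simplifyVector = TRUE)
    spec <- model_spec(fixed = unlist(sel$final_spec$fixed),
                       quadratic = as.character(unlist(sel$final_spec$quadratic)),
                       interactions = json_interactions(sel$final_spec$interactions),
                       categorical = as.character(unlist(sel$final_spec$categorical)),
                       climate = as.character(unlist(sel$final_spec$climate)),
                       response = sel$final_spec$response)
    cv <- cv_auc(spec, tab, k = config$k, seed = stage_seed(config$seed, "select"))
    ok <- !is.na(cv$oof)
    rep <- threshold_report(cv$oof[ok], tab[[spec$response]][ok])
    write_threshold_json(rep, path("thresholds.json"))
  }, parents = c("assemble", "select"))

  # 7. projection under severity x period scenarios ---------------------------
  run_stage("project", list(periods = config$periods,
                            method = config$threshold_method),
            path(c("model_final.json", "thresholds.json", "climate.csv",
                   "sites.csv", "model_table.csv")),
            path(c("projections.csv", "categories.csv", "summary.csv")),
            function() {
    fit <- read_glmm_json(path("model_final.json"))
    thr <- jsonlite::read_json(path("thresholds.json"), simplifyVector = TRUE)
    threshold <- thr[[config$threshold_method]]$threshold
    climate <- utils::read.csv(path("climate.csv"))
    sites <- utils::read.csv(path("sites.csv"))
    tab <- utils::read.csv(path("model_table.csv"))
    # non-scenario site covariates held at the study medians
    sites$chili <- stats::median(tab$chili)
    sites$region <- ifelse(sites$latitude >= stats::median(sites$latitude),
                           "north", "south")
    proj <- list(); cats <- list()
    for (pn in names(config$periods)) {
      pm <- period_climate_metrics(climate, sites, config$periods[[pn]],
                                   whc_mm = config$whc_mm)
      p_lo <- project_scenario(fit, sites, pm, scenario("low", config$periods[[pn]]))
      p_hi <- project_scenario(fit, sites, pm, scenario("high", config$periods[[pn]]))
      proj[[pn]] <- data.frame(period = pn, site = sites$site,
                               region = sites$region,
                               prob_low = p_lo$prob, prob_high = p_hi$prob)
      cm <- classify_sites(p_lo$prob, p_hi$prob, threshold, site = sites$site,
                           region = sites$region)
      cm$period <- pn
      cats[[pn]] <- cm
    }
    proj_df <- do.call(rbind, proj)
    utils::write.csv(proj_df, path("projections.csv"), row.names = FALSE)
    cat_df <- do.call(rbind, cats)
    utils::write.csv(cat_df, path("categories.csv"), row.names = FALSE)
    summ <- do.call(rbind, lapply(names(cats), function(pn) {
      s <- area_summary(cats[[pn]])
      s$period <- pn
      s
    }))
    utils::write.csv(summ, path("summary.csv"), row.names = FALSE)
  }, parents = c("simulate", "assemble", "fit", "select", "threshold"))

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(manifest = manifest, timings = timings,
                 out_dir = config$out_dir))
}

# interactions parsed from JSON arrive as a matrix, list, or NULL
json_interactions <- function(x) {
  if (is.null(x) || length(x) == 0L) return(list())
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
  if (is.data.frame(x)) return(lapply(seq_len(nrow(x)), function(i) unlist(x[i, ])))
  lapply(x, unlist)
}
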