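#' Apply the plot-inclusion rules
#'
#' Retains only burned, unplanted plots from wildfires in 1984-2018 surveyed
#' at least 2 years postfire, and itemizes exclusions per rule (each dropped
#' row is counted once, under the first rule it violates, in the order:
#' unburned, planted, fire year out of range, surveyed too early).
#'
#' @param raw Data.frame with at least `burned`, `planted`, `fire_year`,
#'   `survey_year`.
#' @param year_range Allowed fire years (default `c(1984, 2018)`).
#' @param min_years_postfire Minimum survey delay (default 2).
#' @return A list with `plots` (retained rows) and `log` (named integer
#'   exclusion counts).
#' @export
apply_inclusion_filters <- function(raw, year_range = c(1984, 2018),
                                    min_years_postfire = 2) {
  check_columns(raw, c("burned", "planted", "fire_year", "survey_year"), "plot table")
  rules <- list(
    unburned = function(d) !(d$burned %in% c(TRUE, 1)),
    planted = function(d) d$planted %in% c(TRUE, 1),
    fire_year_out_of_range = function(d)
      d$fire_year < year_range[1] | d$fire_year > year_range[2],
    surveyed_too_early = function(d)
      (d$survey_year - d$fire_year) < min_years_postfire
  )
  keep <- rep(TRUE, nrow(raw))
  log <- integer(length(rules))
  names(log) <- names(rules)
  for (r in names(rules)) {
    bad <- keep & rules[[r]](raw)
    bad[is.na(bad)] <- TRUE & keep[is.na(bad)]
    log[[r]] <- sum(bad)
    keep <- keep & !bad
  }
  plots <- raw[keep, , drop = FALSE]
  rownames(plots) <- NULL
  list(plots = plots, log = log)
}

#' Specify the recruitment model's term structure
#'
#' Describes a binomial recruitment model: fixed-effect covariates (with
#' optional quadratic expansion), pairwise interactions, categorical terms,
#' the log(plot area) offset and the per-fire random intercept (both always
#' present). `climate` names the terms that backward selection may remove;
#' everything else (the biophysical core: time since fire, seed-source
#' distance, severity, tree cover, heat load, disturbance, variety) is
#' protected.
#'
#' @param fixed Character vector of covariate names (columns of the model
#'   table). Categorical covariates are detected via `categorical`.
#' @param quadratic Subset of `fixed` to also enter as squared terms.
#' @param interactions List of length-2 character vectors; both parents must
#'   be in `fixed` (hierarchy).
#' @param categorical Names in `fixed` treated as factors (dummy-coded
#'   against a reference level; `"none"` for `prefire_disturbance`).
#' @param climate Subset of `fixed` that selection may remove.
#' @param response Response column (default `"presence"`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(fixed,
                       quadratic = character(),
                       interactions = list(),
                       categorical = intersect(c("prefire_disturbance", "variety"), fixed),
                       climate = character(),
                       response = "presence") {
  stopifnot(is.character(fixed), length(fixed) > 0)
  stop_if_not(!anyDuplicated(fixed), "duplicated fixed terms")
  stop_if_not(all(quadratic %in% fixed), "quadratic terms must be among `fixed`")
  stop_if_not(all(categorical %in% fixed), "categorical terms must be among `fixed`")
  stop_if_not(all(climate %in% fixed), "climate terms must be among `fixed`")
  for (ia in interactions) {
    stop_if_not(is.character(ia) && length(ia) == 2L,
                "each interaction must be a length-2 character vector")
    stop_if_not(all(ia %in% fixed),
                "interaction %s violates hierarchy: parents must be fixed terms",
                paste(ia, collapse = ":"))
  }
  keys <- vapply(interactions, function(ia) paste(sort(ia), collapse = ":"), character(1))
  stop_if_not(!anyDuplicated(keys), "duplicated interaction terms")
  structure(list(response = response, fixed = fixed, quadratic = quadratic,
                 interactions = interactions, categorical = categorical,
                 climate = climate),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Recruitment model specification\n")
  cat("  response:", x$response, "(binomial, logit link, offset log area, ",
      "random intercept by fire)\n", sep = "")
  cat("  fixed:", paste(x$fixed, collapse = ", "), "\n")
  if (length(x$quadratic)) cat("  quadratic:", paste(x$quadratic, collapse = ", "), "\n")
  if (length(x$interactions))
    cat("  interactions:", paste(vapply(x$interactions, paste, character(1),
                                        collapse = ":"), collapse = ", "), "\n")
  if (length(x$climate)) cat("  removable (climate):",
                             paste(x$climate, collapse = ", "), "\n")
  invisible(x)
}

interaction_labels <- function(spec) {
  vapply(spec$interactions, paste, character(1), collapse = ":")
}

factor_reference <- function(name, levels) {
  if (name == "prefire_disturbance" && "none" %in% levels) "none" else levels[1]
}

#' Build the design matrix for a model specification
#'
#' Continuous covariates are standardized (mean 0, sd 1 with denominator
#' n - 1) over the table, with centers and scales stored for prediction-time
#' reuse and raw-scale back-transformation; categorical covariates are
#' dummy-coded against a reference level (`"none"` for prefire disturbance);
#' quadratic and interaction columns are built from the standardized values.
#' The offset is log(area m2) and the grouping factor is fire id.
#'
#' @param table Model table (one row per plot).
#' @param spec A [model_spec()].
#' @param standardize Standardize continuous covariates (default TRUE).
#' @param scaling Optional scaling (named list with `center`, `scale`) and
#'   factor levels from a training design, as stored in a `regen_design`,
#'   to apply instead of recomputing (used for prediction on new data).
#' @return An object of class `regen_design`: list with `X` (matrix incl.
#'   intercept), `y`, `offset`, `groups` (factor), `spec`, `scaling`,
#'   `xlevels`.
#' @export
build_design <- function(table, spec, standardize = TRUE, scaling = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  need <- unique(c(spec$fixed, "area_m2", "fire_id"))
  check_columns(table, need, "model table")  # response optional (prediction)
  n <- nrow(table)
  stop_if_not(n > 0, "model table is empty")
  stop_if_not(all(table$area_m2 > 0), "plot areas must be positive")

  continuous <- setdiff(spec$fixed, spec$categorical)
  if (is.null(scaling)) {
    center <- scale_ <- stats::setNames(numeric(length(continuous)), continuous)
    for (v in continuous) {
      x <- table[[v]]
      stop_if_not(is.numeric(x) && !anyNA(x), "covariate `%s` must be numeric without NA", v)
      s <- stats::sd(x)
      if (standardize) {
        stop_if_not(s > 0, "covariate `%s` has zero variance", v)
        center[v] <- mean(x); scale_[v] <- s
      } else {
        center[v] <- 0; scale_[v] <- 1
      }
    }
    xlevels <- lapply(stats::setNames(spec$categorical, spec$categorical), function(v) {
      lv <- sort(unique(as.character(table[[v]])))
      ref <- factor_reference(v, lv)
      c(ref, setdiff(lv, ref))
    })
  } else {
    center <- scaling$center[continuous]
    scale_ <- scaling$scale[continuous]
    stop_if_not(!anyNA(center) && !anyNA(scale_),
                "stored scaling does not cover all continuous covariates")
    xlevels <- scaling$xlevels[spec$categorical]
  }

  std <- lapply(stats::setNames(continuous, continuous), function(v)
    (table[[v]] - center[v]) / scale_[v])

  cols <- list("(Intercept)" = rep(1, n))
  for (v in spec$fixed) {
    if (v %in% spec$categorical) {
      vals <- as.character(table[[v]])
      lv <- xlevels[[v]]
      unseen <- setdiff(unique(vals), lv)
      stop_if_not(length(unseen) == 0L, "covariate `%s` has unseen level(s): %s",
                  v, paste(unseen, collapse = ", "))
      for (l in lv[-1]) cols[[paste0(v, l)]] <- as.numeric(vals == l)
    } else {
      cols[[v]] <- std[[v]]
    }
  }
  for (v in spec$quadratic) {
    stop_if_not(!(v %in% spec$categorical), "quadratic term `%s` must be continuous", v)
    cols[[paste0("I(", v, "^2)")]] <- std[[v]]^2
  }
  for (ia in spec$interactions) {
    stop_if_not(all(ia %in% continuous),
                "interaction parents must be continuous covariates: %s",
                paste(ia, collapse = ":"))
    cols[[paste(ia, collapse = ":")]] <- std[[ia[1]]] * std[[ia[2]]]
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  y <- table[[spec$response]]
  if (!is.null(y)) {
    stop_if_not(all(y %in% c(0, 1)) || all(is.na(y)), "response must be 0/1")
    y <- as.numeric(y)
  }
  structure(list(X = X, y = y, offset = log(table$area_m2),
                 groups = factor(table$fire_id), spec = spec,
                 scaling = list(center = center, scale = scale_, xlevels = xlevels),
                 xlevels = xlevels),
            class = "regen_design")
}

#' Screen predictors for collinearity
#'
#' Flags every pair of continuous design columns with |Pearson r| >= `r_max`
#' and every column whose variance inflation factor (from regressing it on
#' all other columns) is >= `vif_max` - the screening rule applied before a
#' set of predictors may share a model. Removal is advisory: flagged pairs
#' are reported, and with `auto_drop = TRUE` the lower-priority member of
#' each offending pair (later in `priority`) is dropped.
#'
#' @param X Numeric matrix or data.frame of continuous predictor columns
#'   (>= 2 columns; no intercept).
#' @param r_max Pairwise correlation threshold (default 0.6).
#' @param vif_max VIF threshold (default 5).
#' @param auto_drop Drop the lower-priority member of each flagged pair.
#' @param priority Column names in decreasing priority (default: input order).
#' @return List with `pairs` (data.frame a, b, r for flagged pairs), `vif`
#'   (named vector), `flagged_vif`, `dropped`, `retained`.
#' @export
collinearity_screen <- function(X, r_max = 0.6, vif_max = 5,
                                auto_drop = FALSE, priority = colnames(X)) {
  X <- as.matrix(X)
  stop_if_not(ncol(X) >= 2L, "need at least 2 columns to screen")
  sds <- apply(X, 2, stats::sd)
  stop_if_not(all(sds > 0), "constant column(s): %s",
              paste(colnames(X)[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  p <- ncol(X)
  pairs <- which(abs(R) >= r_max & upper.tri(R), arr.ind = TRUE)
  pair_df <- data.frame(a = colnames(X)[pairs[, 1]], b = colnames(X)[pairs[, 2]],
                        r = R[pairs], stringsAsFactors = FALSE)
  # VIF_j = 1/(1 - R^2_j) = j-th diagonal of the inverse correlation matrix
  vif <- tryCatch(diag(solve(R)), error = function(e) rep(Inf, p))
  names(vif) <- colnames(X)
  dropped <- character()
  if (auto_drop && nrow(pair_df) > 0) {
    rank <- stats::setNames(seq_along(priority), priority)
    for (i in seq_len(nrow(pair_df))) {
      a <- pair_df$a[i]; b <- pair_df$b[i]
      if (a %in% dropped || b %in% dropped) next
      dropped <- c(dropped, if (rank[[a]] <= rank[[b]]) b else a)
    }
  }
  list(pairs = pair_df, vif = vif, flagged_vif = names(vif)[vif >= vif_max],
       dropped = dropped, retained = setdiff(colnames(X), dropped))
}

#' Assemble the modeling table
#'
#' Applies the inclusion filters, joins per-fire climate metrics, drops rows
#' with missing model covariates (logged), and returns the table downstream
#' modeling consumes.
#'
#' @param plots Raw plot table.
#' @param metrics Per-fire climate metrics from [climate_metrics()].
#' @param covariates Covariate columns that must be complete.
#' @return List with `table`, `filter_log`, `n_dropped_missing`.
#' @export
assemble_model_table <- function(plots, metrics,
                                 covariates = c("distance_m", "tree_cover_pct",
                                                "rbr", "chili")) {
  filt <- apply_inclusion_filters(plots)
  tab <- filt$plots
  if (!all(c("mean_annual_deficit_mm") %in% names(tab))) {
    tab <- merge(tab, metrics, by = "fire_id", sort = FALSE)
  }
  if (!"time_since_fire" %in% names(tab)) {
    tab$time_since_fire <- tab$survey_year - tab$fire_year
  }
  present <- intersect(covariates, names(tab))
  complete <- stats::complete.cases(tab[, present, drop = FALSE])
  n_missing <- sum(!complete)
  tab <- tab[complete, , drop = FALSE]
  tab <- tab[order(tab$plot_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, filter_log = filt$log, n_dropped_missing = n_missing)
}
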