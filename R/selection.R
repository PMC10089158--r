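# Cross-validated AUC machinery and backward elimination over climate terms
# and interactions, with fire-grouped folds.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive scores above a randomly chosen negative, with ties counted 1/2.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  stop_if_not(length(scores) == length(labels), "`scores` and `labels` differ in length")
  stop_if_not(all(labels %in% c(0, 1)), "labels must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  stop_if_not(n1 > 0 && n0 > 0, "both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic fire-grouped fold assignment: shuffle fires under the seed,
# deal them round-robin into k folds
make_fire_folds <- function(fire_ids, k, seed) {
  fires <- sort(unique(as.character(fire_ids)))
  stop_if_not(length(fires) >= k, "need at least k = %d fires, found %d", k, length(fires))
  shuffled <- with_seed(seed, sample(fires))
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(shuffled)), shuffled)
  unname(fold_of[as.character(fire_ids)])
}

#' Cross-validated AUC of a model specification
#'
#' Folds partition fires, not plots: all plots of a fire share a fold, so no
#' random-intercept information leaks between training and test. Each fold is
#' scored by a model fitted on the remaining folds, predicting at the
#' population level (random intercept zero). Folds whose test plots are all
#' one class are skipped with a warning.
#'
#' @param spec A [model_spec()].
#' @param data Assembled model table.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param warm Optional warm-start parameters (list with `beta`, `tau`).
#' @return List with `mean` (mean fold AUC), `per_fold`, `skipped_folds`,
#'   `oof` (out-of-fold predicted probabilities aligned with `data` rows).
#' @export
cv_auc <- function(spec, data, k = 10L, seed = DEFAULT_SEED, warm = NULL) {
  k <- check_count(k, "k", min = 2L)
  des <- build_design(data, spec)
  folds <- make_fire_folds(data$fire_id, k, seed)
  if (is.null(warm)) {
    # warm-start the fold fits from the full-data solution
    full <- tryCatch(fit_glmm(des$X, des$y, des$offset, des$groups),
                     error = function(e) NULL)
    if (!is.null(full)) warm <- list(beta = full$coefficients, tau = full$tau)
  }
  per_fold <- rep(NA_real_, k)
  oof <- rep(NA_real_, nrow(data))
  skipped <- integer()
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_glmm(des$X[!test, , drop = FALSE], des$y[!test],
                    des$offset[!test], droplevels(des$groups[!test]),
                    start = warm)
    eta <- drop(des$X[test, , drop = FALSE] %*% fit$coefficients) + des$offset[test]
    oof[test] <- logistic(eta)
    if (length(unique(des$y[test])) < 2L) {
      warning(sprintf("fold %d has a single class; skipped", f), call. = FALSE)
      skipped <- c(skipped, f)
      next
    }
    per_fold[f] <- auc(oof[test], des$y[test])
  }
  list(mean = mean(per_fold, na.rm = TRUE), per_fold = per_fold,
       skipped_folds = skipped, oof = oof)
}

# removable terms of a spec under hierarchy: all interactions, plus climate
# main effects that no remaining interaction or quadratic depends on
removable_terms <- function(spec) {
  ints <- interaction_labels(spec)
  parents <- unique(unlist(spec$interactions))
  # dropping a main effect also drops its quadratic term (drop_term), so only
  # interactions gate the hierarchy here
  mains <- setdiff(spec$climate, parents)
  list(interactions = ints, mains = mains)
}

drop_term <- function(spec, term) {
  ints <- interaction_labels(spec)
  if (term %in% ints) {
    spec$interactions <- spec$interactions[ints != term]
  } else {
    spec$fixed <- setdiff(spec$fixed, term)
    spec$quadratic <- setdiff(spec$quadratic, term)
    spec$climate <- setdiff(spec$climate, term)
    spec$categorical <- setdiff(spec$categorical, term)
  }
  spec
}

add_interaction <- function(spec, pair) {
  spec$interactions <- c(spec$interactions, list(pair))
  spec
}

# candidate ordering: higher-order (interaction) terms first, then
# lexicographic; used to break CV-AUC ties deterministically
order_candidates <- function(terms, interactions) {
  is_int <- terms %in% interactions
  terms[order(!is_int, terms)]
}

#' Backward model selection by cross-validated AUC
#'
#' Phase 1 greedily removes, among climate terms and interactions (the
#' biophysical core is protected), the single term whose removal yields the
#' highest cross-validated AUC, repeating while the best removal does not
#' significantly lower skill: a term survives only when dropping it costs
#' more than `se_mult` standard errors of the paired per-fold AUC
#' differences, a paired-t-test-style parsimony rule (ties favor the simpler
#' model and interactions leave before their parent main effects). Phase 2
#' then tests adding each interaction between the full model's postfire
#' climate anomaly terms and the severity / seed-availability covariates
#' (RBR, distance to seed source, surrounding tree cover), restoring a parent
#' main effect that phase 1 removed when its interaction is tested, and
#' keeping additions whose mean paired per-fold AUC gain clears the same
#' significance bar, applied symmetrically.
#'
#' @param full_spec Starting [model_spec()] including climate terms and
#'   climate interactions; `full_spec$climate` marks the removable terms.
#' @param data Assembled model table.
#' @param k Folds (default 10).
#' @param seed Integer seed (fold assignment is fixed across all candidate
#'   evaluations so AUCs are comparable).
#' @param postfire_climate Names of postfire anomaly terms eligible for
#'   phase-2 interactions (default: the full model's climate terms containing
#'   `"_z_"`).
#' @param severity_terms Phase-2 partners (default RBR, distance, tree cover,
#'   intersected with the spec).
#' @param se_mult Parsimony bar in standard-error units (default 2): a term
#'   is retained only when removing it costs more than `se_mult` standard
#'   errors of the paired per-fold AUC differences (roughly a one-sided
#'   paired t-test), and an interaction is added only when it gains more
#'   than the same bar.
#' @param tol Tie tolerance on CV AUC (default 1e-12).
#' @return Object of class `selection_trace`: list with `trace` (data.frame:
#'   phase, action, term, cv_auc, accepted), `final_spec`, `final_auc`,
#'   `initial_auc`.
#' @export
backward_select <- function(full_spec, data, k = 10L, seed = DEFAULT_SEED,
                            postfire_climate = NULL,
                            severity_terms = intersect(
                              c("rbr", "distance_m", "tree_cover_pct"),
                              full_spec$fixed),
                            se_mult = 2, tol = 1e-12) {
  stopifnot(inherits(full_spec, "model_spec"))
  spec <- full_spec
  cur_cv <- cv_auc(spec, data, k, seed)
  current <- cur_cv$mean
  initial_auc <- current
  best <- current
  trace <- list()
  note <- function(phase, action, term, auc_val, accepted) {
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, action = action, term = term, cv_auc = auc_val,
      accepted = accepted, stringsAsFactors = FALSE)
  }

  # phase 1: greedy removal of interactions and climate terms
  repeat {
    rem <- removable_terms(spec)
    cands <- order_candidates(c(rem$interactions, rem$mains), rem$interactions)
    if (length(cands) == 0L) break
    scores <- rep(NA_real_, length(cands))
    cvs <- vector("list", length(cands))
    for (i in seq_along(cands)) {
      cand_spec <- drop_term(spec, cands[i])
      cvs[[i]] <- tryCatch(cv_auc(cand_spec, data, k, seed),
                           error = function(e) {
                             warning(sprintf("candidate removal `%s` infeasible: %s",
                                             cands[i], conditionMessage(e)),
                                     call. = FALSE)
                             NULL
                           })
      if (!is.null(cvs[[i]])) scores[i] <- cvs[[i]]$mean
    }
    if (all(is.na(scores))) break
    ibest <- which.max(scores)          # first max; candidates pre-ordered
    # one-standard-error parsimony: accept the best removal unless it costs
    # distinguishably more skill than paired fold noise
    d <- cvs[[ibest]]$per_fold - cur_cv$per_fold
    d <- d[is.finite(d)]
    se_d <- if (length(d) >= 2) stats::sd(d) / sqrt(length(d)) else 0
    if (mean(d) >= -se_mult * se_d - tol) {
      spec <- drop_term(spec, cands[ibest])
      cur_cv <- cvs[[ibest]]
      current <- scores[ibest]
      best <- max(best, current)
      note(1L, "remove", cands[ibest], current, TRUE)
    } else {
      note(1L, "remove", cands[ibest], scores[ibest], FALSE)
      break
    }
  }

  # phase 2: test postfire-climate x severity/seed-availability interactions.
  # Candidates cover every postfire anomaly term of the full model, even ones
  # phase 1 removed as main effects: an interaction can carry skill a marginal
  # main effect lacks, and hierarchy is preserved by restoring the parent.
  if (is.null(postfire_climate)) {
    postfire_climate <- grep("_z_", full_spec$climate, value = TRUE)
  }
  add_candidate <- function(spec, cl, sv) {
    if (!(cl %in% spec$fixed)) {
      spec$fixed <- c(spec$fixed, cl)
      spec$climate <- union(spec$climate, cl)
    }
    add_interaction(spec, c(cl, sv))
  }
  repeat {
    existing <- interaction_labels(spec)
    cands <- list()
    for (cl in postfire_climate) {
      for (sv in severity_terms) {
        lab <- paste(c(cl, sv), collapse = ":")
        rlab <- paste(c(sv, cl), collapse = ":")
        if (!(lab %in% existing) && !(rlab %in% existing) &&
            sv %in% spec$fixed) {
          cands[[length(cands) + 1L]] <- c(cl, sv)
        }
      }
    }
    if (length(cands) == 0L) break
    labs <- vapply(cands, paste, character(1), collapse = ":")
    ord <- order(labs)
    cands <- cands[ord]; labs <- labs[ord]
    scores <- rep(NA_real_, length(cands))
    cvs <- vector("list", length(cands))
    for (i in seq_along(cands)) {
      cand_spec <- add_candidate(spec, cands[[i]][1], cands[[i]][2])
      cvs[[i]] <- tryCatch(cv_auc(cand_spec, data, k, seed),
                           error = function(e) NULL)
      if (!is.null(cvs[[i]])) scores[i] <- cvs[[i]]$mean
    }
    if (all(is.na(scores))) break
    ibest <- which.max(scores)
    # symmetric one-standard-error bar: complexity is added only when it
    # improves skill distinguishably beyond paired fold noise
    d <- cvs[[ibest]]$per_fold - cur_cv$per_fold
    d <- d[is.finite(d)]
    se_d <- if (length(d) >= 2) stats::sd(d) / sqrt(length(d)) else 0
    if (length(d) > 0 && mean(d) > se_mult * se_d + tol) {
      spec <- add_candidate(spec, cands[[ibest]][1], cands[[ibest]][2])
      cur_cv <- cvs[[ibest]]
      current <- scores[ibest]
      best <- max(best, current)
      note(2L, "add", labs[ibest], current, TRUE)
    } else {
      note(2L, "add", labs[ibest], scores[ibest], FALSE)
      break
    }
  }

  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(phase = integer(), action = character(), term = character(),
               cv_auc = numeric(), accepted = logical())
  structure(list(trace = trace_df, final_spec = spec, final_auc = current,
                 initial_auc = initial_auc),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Backward selection by %s-fold CV AUC\n", "fire-grouped"))
  cat(sprintf("  initial CV AUC %.4f -> final %.4f\n", x$initial_auc, x$final_auc))
  if (nrow(x$trace)) print(x$trace) else cat("  no candidate steps\n")
  invisible(x)
}

#' Serialize a selection trace to JSON
#' @param trace A `selection_trace`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_selection_json <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  spec <- trace$final_spec
  jsonlite::write_json(list(
    initial_auc = trace$initial_auc, final_auc = trace$final_auc,
    steps = trace$trace,
    final_spec = list(response = spec$response, fixed = spec$fixed,
                      quadratic = spec$quadratic,
                      interactions = spec$interactions,
                      categorical = spec$categorical, climate = spec$climate)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
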