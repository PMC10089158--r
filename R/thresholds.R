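# Presence/absence cutoffs: kappa-maximizing and sensitivity+specificity-
# maximizing thresholds over the complete candidate set.

#' Cohen's kappa from a 2x2 confusion
#'
#' Chance-corrected agreement: kappa = (po - pe) / (1 - pe), with expected
#' agreement pe from the marginal products. Degenerate marginals (pe = 1)
#' yield kappa = 0 with a warning.
#'
#' @param tp,fn,fp,tn Confusion counts (true positive, false negative, false
#'   positive, true negative); total must be positive.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  stop_if_not(n > 0, "confusion counts sum to zero")
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (pe >= 1) {
    warning("degenerate marginals (expected agreement 1); kappa set to 0",
            call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

confusion_at <- function(probs, labels, threshold) {
  pred <- probs > threshold          # "likely" when probability exceeds cutoff
  c(tp = sum(pred & labels == 1), fn = sum(!pred & labels == 1),
    fp = sum(pred & labels == 0), tn = sum(!pred & labels == 0))
}

threshold_objective <- function(probs, labels, threshold, method) {
  cf <- confusion_at(probs, labels, threshold)
  sens <- cf[["tp"]] / (cf[["tp"]] + cf[["fn"]])
  spec <- cf[["tn"]] / (cf[["tn"]] + cf[["fp"]])
  obj <- switch(method,
                max_kappa = suppressWarnings(
                  cohens_kappa(cf[["tp"]], cf[["fn"]], cf[["fp"]], cf[["tn"]])),
                max_sens_spec = sens + spec)
  list(objective = obj, sensitivity = sens, specificity = spec, confusion = cf)
}

#' Select a presence threshold
#'
#' Evaluates every candidate cutoff (midpoints between adjacent sorted unique
#' probabilities, plus 0 and 1 - a complete candidate set for step-function
#' metrics) and returns the one maximizing the chosen objective: Cohen's
#' kappa, or the sum of sensitivity and specificity. Among tied maximizers
#' the smallest cutoff is returned. A plot is classified "likely" when its
#' probability strictly exceeds the cutoff.
#'
#' @param probs Predicted probabilities in \[0, 1\].
#' @param labels Observed 0/1 outcomes; both classes required.
#' @param method `"max_kappa"` or `"max_sens_spec"`.
#' @return Object of class `threshold_result`: list with `method`,
#'   `threshold`, `kappa`, `sensitivity`, `specificity`, `objective`,
#'   `confusion` (named counts).
#' @export
select_threshold <- function(probs, labels, method = c("max_kappa", "max_sens_spec")) {
  method <- match.arg(method)
  stop_if_not(length(probs) == length(labels), "`probs` and `labels` differ in length")
  stop_if_not(all(probs >= 0 & probs <= 1), "probabilities must be in [0, 1]")
  stop_if_not(all(labels %in% c(0, 1)), "labels must be 0/1")
  stop_if_not(length(unique(labels)) == 2L, "both classes must be present")
  u <- sort(unique(probs))
  candidates <- sort(unique(c(0, (u[-1] + u[-length(u)]) / 2, 1)))
  objs <- vapply(candidates, function(t)
    threshold_objective(probs, labels, t, method)$objective, numeric(1))
  t_star <- candidates[which.max(objs)]   # first max = smallest tied cutoff
  res <- threshold_objective(probs, labels, t_star, method)
  kap <- suppressWarnings(cohens_kappa(res$confusion[["tp"]], res$confusion[["fn"]],
                                       res$confusion[["fp"]], res$confusion[["tn"]]))
  structure(list(method = method, threshold = t_star, kappa = kap,
                 sensitivity = res$sensitivity, specificity = res$specificity,
                 objective = res$objective, confusion = res$confusion),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Threshold (%s): %.4f\n", x$method, x$threshold))
  cat(sprintf("  kappa %.4f  sensitivity %.4f  specificity %.4f\n",
              x$kappa, x$sensitivity, x$specificity))
  invisible(x)
}

#' Threshold report for both methods
#'
#' Computes the kappa-maximizing and sensitivity+specificity-maximizing
#' cutoffs on the same predictions (by default out-of-fold cross-validated
#' probabilities, to avoid optimistic in-sample cutoffs). The pair brackets
#' the band of threshold probabilities shown in gray in category figures.
#'
#' @param probs Predicted probabilities.
#' @param labels Observed 0/1 outcomes.
#' @return Named list of two `threshold_result`s (`max_kappa`,
#'   `max_sens_spec`).
#' @export
threshold_report <- function(probs, labels) {
  list(max_kappa = select_threshold(probs, labels, "max_kappa"),
       max_sens_spec = select_threshold(probs, labels, "max_sens_spec"))
}

#' Serialize a threshold report to JSON
#' @param report A [threshold_report()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_threshold_json <- function(report, path) {
  doc <- lapply(report, function(r) list(
    method = r$method, threshold = r$threshold, kappa = r$kappa,
    sensitivity = r$sensitivity, specificity = r$specificity,
    confusion = as.list(r$confusion)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
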