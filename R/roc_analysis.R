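#' ROC analysis with Youden-index cut-off
#'
#' Empirical ROC curve of a continuous score against a binary outcome. The
#' AUC is the trapezoidal area (equivalently the scaled Mann-Whitney U
#' statistic), with a 95% DeLong confidence interval. The reported best
#' cut-off maximizes Youden's J = sensitivity + specificity - 1 over the
#' observed thresholds (midpoints between consecutive distinct score
#' values); ties in J are broken toward the lower cut-off.
#'
#' The decision direction is auto-detected: if the score is *lower* in the
#' positive class (AUC below 0.5 with the conventional direction), the curve
#' is flipped and `flipped = TRUE` is recorded, so a negatively associated
#' predictor still reports its discriminative AUC above 0.5.
#'
#' @param scores Numeric vector of predictor values.
#' @param labels Binary outcome vector (logical, 0/1, or a two-level
#'   factor); both classes must be present.
#' @param conf_level Confidence level for the AUC CI (default 0.95).
#' @param direction `"auto"` (default), `"higher"` (higher score predicts
#'   the positive class) or `"lower"`.
#' @return An object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `best_cutoff`, `sensitivity` and `specificity` (percent, at the best
#'   cut-off), `youden_j`, `direction`, `flipped`, `n_pos`, `n_neg`, and the
#'   underlying `pROC` fit in `$fit`. [tidy()] returns the per-threshold
#'   curve, [glance()] the one-row summary.
#' @export
roc_analysis <- function(scores, labels, conf_level = 0.95,
                         direction = c("auto", "higher", "lower")) {
  direction <- match.arg(direction)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  lab <- as_binary_labels(labels)
  if (length(unique(lab)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  flipped <- FALSE
  dir_sym <- if (direction == "lower") ">" else "<"
  fit <- pROC::roc(
    response = lab, predictor = scores, levels = c(0, 1),
    direction = dir_sym, quiet = TRUE
  )
  if (direction == "auto" && as.numeric(pROC::auc(fit)) < 0.5) {
    fit <- pROC::roc(
      response = lab, predictor = scores, levels = c(0, 1),
      direction = ">", quiet = TRUE
    )
    flipped <- TRUE
  }
  auc <- as.numeric(pROC::auc(fit))
  # pROC warns that a degenerate (AUC = 1) interval "can be misleading";
  # the interval itself is what we want to report
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(fit, conf.level = conf_level, method = "delong"))
  )
  # pick the Youden optimum from the full threshold table ourselves so exact
  # ties in J resolve to the lower cut-off
  all_pts <- pROC::coords(fit,
    x = "all",
    ret = c("threshold", "sensitivity", "specificity"), transpose = FALSE
  )
  all_pts <- all_pts[order(all_pts$threshold), , drop = FALSE]
  j <- all_pts$sensitivity + all_pts$specificity - 1
  best <- all_pts[which(j > max(j) - 1e-12)[1], ]
  structure(
    list(
      auc = auc, ci_low = ci[1], ci_high = ci[3],
      best_cutoff = best$threshold,
      sensitivity = 100 * best$sensitivity,
      specificity = 100 * best$specificity,
      youden_j = best$sensitivity + best$specificity - 1,
      direction = if (fit$direction == "<") "higher" else "lower",
      flipped = flipped,
      n_pos = sum(lab == 1), n_neg = sum(lab == 0),
      conf_level = conf_level, fit = fit
    ),
    class = "roc_result"
  )
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) {
    return(as.integer(labels))
  }
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("outcome factor must have 2 levels", call. = FALSE)
    return(as.integer(labels) - 1L)
  }
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) {
    stop("`labels` must be binary (logical, 0/1, or a two-level factor)",
      call. = FALSE
    )
  }
  as.integer(labels)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "ROC analysis (%d positive / %d negative)\n",
      "  AUC = %.3f (%d%% CI %.3f-%.3f)\n",
      "  Youden cut-off = %.4g (%s score predicts positive)%s\n",
      "  sensitivity = %.0f%%, specificity = %.0f%%\n"
    ),
    x$n_pos, x$n_neg, x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
    x$best_cutoff, x$direction, if (x$flipped) " [auto-flipped]" else "",
    x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  pts <- pROC::coords(x$fit,
    x = "all",
    ret = c("threshold", "sensitivity", "specificity"), transpose = FALSE
  )
  as_tibble(pts)
}

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
    best_cutoff = x$best_cutoff, sensitivity = x$sensitivity,
    specificity = x$specificity, direction = x$direction,
    flipped = x$flipped, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Compare two paired AUCs (DeLong test)
#'
#' Two-sided DeLong test for correlated ROC curves: both scores are measured
#' on the same subjects with the same outcome. Identical or rank-equivalent
#' scores give an AUC difference of exactly zero, reported as p = 1.
#'
#' @param scores_a,scores_b Numeric score vectors, same subjects.
#' @param labels Binary outcome vector.
#' @return One-row tibble: `auc_a`, `auc_b`, `p_value`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
    length(scores_a) != length(labels)) {
    stop("paired comparison requires equal-length vectors", call. = FALSE)
  }
  lab <- as_binary_labels(labels)
  if (length(unique(lab)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  ra <- pROC::roc(lab, scores_a, levels = c(0, 1), direction = "<", quiet = TRUE)
  rb <- pROC::roc(lab, scores_b, levels = c(0, 1), direction = "<", quiet = TRUE)
  auc_a <- as.numeric(pROC::auc(ra))
  auc_b <- as.numeric(pROC::auc(rb))
  p <- tryCatch(
    suppressWarnings(
      pROC::roc.test(ra, rb, paired = TRUE, method = "delong")$p.value
    ),
    error = function(e) NaN
  )
  # degenerate DeLong variance (e.g. identical curves): no evidence of a
  # difference when the AUCs coincide
  if (!is.finite(p) && abs(auc_a - auc_b) < 1e-12) p <- 1
  tibble(auc_a = auc_a, auc_b = auc_b, p_value = p)
}
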