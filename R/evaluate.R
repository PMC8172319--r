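#' Regression performance report
#'
#' Computes the regression metric suite used throughout the workflow for the
#' age-estimation task: mean absolute error (MAE), Pearson's correlation with
#' its two-sided p-value (t transform with n - 2 degrees of freedom), and the
#' prediction R² (also called cross-validation R² or q²),
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` with the mean taken over the
#' evaluation set itself. Prediction R² can be negative for models worse than
#' predicting the evaluation-set mean.
#'
#' Degenerate inputs are flagged rather than silently zeroed: when the targets
#' (or the predictions) have zero variance the correlation and, for constant
#' targets, the R² are reported as `NA` with `degenerate = TRUE`.
#'
#' @param targets numeric vector of true values (e.g. age in years).
#' @param preds numeric vector of predicted values, same length.
#' @return an object of class `regression_report`: list with `mae`,
#'   `pearson_r`, `p_value`, `r2_score`, `n`, `degenerate`.
#' @examples
#' regression_metrics(c(8, 10, 12, 14), c(9, 9, 13, 13))
#' @export
regression_metrics <- function(targets, preds) {
  stopifnot(length(targets) == length(preds))
  if (length(targets) < 2) stop_vbm("regression_metrics needs n >= 2", class = "vbmnet_input_error")
  if (!all(is.finite(targets)) || !all(is.finite(preds))) {
    stop_vbm("non-finite values in targets or predictions", class = "vbmnet_input_error")
  }
  n <- length(targets)
  mae <- mean(abs(targets - preds))
  ss_tot <- sum((targets - mean(targets))^2)
  ss_res <- sum((targets - preds)^2)
  degenerate <- FALSE
  if (ss_tot == 0) {
    r2 <- NA_real_
    r <- NA_real_
    p <- NA_real_
    degenerate <- TRUE
  } else {
    r2 <- 1 - ss_res / ss_tot
    if (sd(preds) == 0) {
      r <- NA_real_
      p <- NA_real_
      degenerate <- TRUE
    } else {
      ct <- cor.test(targets, preds, method = "pearson", alternative = "two.sided")
      r <- unname(ct$estimate)
      p <- ct$p.value
    }
  }
  structure(
    list(mae = mae, pearson_r = r, p_value = p, r2_score = r2, n = n,
         degenerate = degenerate),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Regression report (n = %d)\n", x$n))
  cat(sprintf("  MAE      : %.4f\n", x$mae))
  cat(sprintf("  Pearson r: %s (p = %s)\n",
              if (is.na(x$pearson_r)) "undefined" else sprintf("%.4f", x$pearson_r),
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3)))
  cat(sprintf("  R2-score : %s\n",
              if (is.na(x$r2_score)) "undefined" else sprintf("%.4f", x$r2_score)))
  if (x$degenerate) cat("  [degenerate input flagged]\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-statistic AUC: the probability that a randomly drawn positive scores
#' higher than a randomly drawn negative, with ties counting one half. Computed
#' from midranks (Mann-Whitney form), so it is exact under ties and agrees
#' with the O(n²) pairwise definition.
#'
#' @param labels binary vector (0/1 or logical); both classes must be present.
#' @param scores numeric vector of classifier scores, higher = more positive.
#' @return scalar AUC in \[0, 1\].
#' @export
auc_roc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop_vbm("auc_roc requires both classes present (pos = %d, neg = %d)",
             n_pos, n_neg, class = "vbmnet_input_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Sensitivity/specificity at a threshold; positive prediction when score >= thr.
.confusion_at <- function(labels, scores, threshold) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' ROC operating-point selection
#'
#' Chooses, on validation data, the score cutoff that maximizes the harmonic
#' mean between sensitivity and specificity,
#' `2 * sens * spec / (sens + spec)`. Candidate cutoffs are the midpoints
#' between consecutive sorted unique scores plus one candidate below the
#' minimum and one above the maximum, which exhausts all distinct confusion
#' tables. Ties are broken toward the lowest threshold. The selected cutoff is
#' then applied unchanged to test data (see [classification_metrics()]).
#'
#' @param val_labels binary labels of the validation set.
#' @param val_scores numeric scores of the validation set.
#' @return scalar threshold; a prediction is positive when `score >= threshold`.
#' @export
select_operating_point <- function(val_labels, val_scores) {
  val_labels <- as.integer(val_labels)
  stopifnot(length(val_labels) == length(val_scores))
  if (length(unique(val_labels)) < 2) {
    stop_vbm("operating-point selection requires both classes", class = "vbmnet_input_error")
  }
  u <- sort(unique(val_scores))
  if (length(u) == 1) {
    warning("all validation scores identical; degenerate operating point")
    return(u)
  }
  candidates <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  best_thr <- candidates[1]
  best_h <- -Inf
  for (thr in candidates) {
    cm <- .confusion_at(val_labels, val_scores, thr)
    sens <- if (cm["tp"] + cm["fn"] > 0) cm["tp"] / (cm["tp"] + cm["fn"]) else 0
    spec <- if (cm["tn"] + cm["fp"] > 0) cm["tn"] / (cm["tn"] + cm["fp"]) else 0
    h <- if (sens + spec > 0) 2 * sens * spec / (sens + spec) else 0
    if (h > best_h + 1e-12) {
      best_h <- h
      best_thr <- thr
    }
  }
  unname(best_thr)
}

#' Classification performance report
#'
#' Confusion-matrix metrics at a fixed threshold (chosen beforehand on
#' validation data, see [select_operating_point()]) plus the threshold-free
#' AUC-ROC. Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic
#' mean. When no positive predictions exist, precision is undefined and
#' flagged as `NA` rather than zeroed.
#'
#' @param labels binary labels of the evaluation set.
#' @param scores numeric classifier scores.
#' @param threshold scalar; positive prediction when `score >= threshold`.
#' @return an object of class `classification_report`.
#' @export
classification_metrics <- function(labels, scores, threshold) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), length(threshold) == 1)
  if (length(unique(labels)) < 2) {
    stop_vbm("classification_metrics requires both classes", class = "vbmnet_input_error")
  }
  cm <- .confusion_at(labels, scores, threshold)
  precision <- if (cm["tp"] + cm["fp"] > 0) cm["tp"] / (cm["tp"] + cm["fp"]) else NA_real_
  recall <- cm["tp"] / (cm["tp"] + cm["fn"])
  f1 <- if (!is.na(precision) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else if (is.na(precision)) NA_real_ else 0
  structure(
    list(precision = unname(precision), recall = unname(recall), f1 = unname(f1),
         auc_roc = auc_roc(labels, scores), threshold = unname(threshold),
         n_positive = sum(labels == 1L), n_negative = sum(labels == 0L),
         confusion = cm),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report (pos = %d, neg = %d, threshold = %.4g)\n",
              x$n_positive, x$n_negative, x$threshold))
  cat(sprintf("  precision: %s\n",
              if (is.na(x$precision)) "undefined (no positive predictions)" else sprintf("%.4f", x$precision)))
  cat(sprintf("  recall   : %.4f\n", x$recall))
  cat(sprintf("  F1       : %s\n", if (is.na(x$f1)) "undefined" else sprintf("%.4f", x$f1)))
  cat(sprintf("  AUC-ROC  : %.4f\n", x$auc_roc))
  invisible(x)
}

#' Total-brain-volume confound check
#'
#' Quantifies how much of the gender and age signal is explainable by total
#' brain volume alone: per subject the brain volume is summarised as the count
#' of in-brain voxels with tissue density above zero (alternatively the sum of
#' densities), then the AUC-ROC of that scalar against gender and the Pearson
#' correlation against age are reported. Values near 0.5 / 0 indicate that a
#' model's performance cannot be attributed to gross volume differences.
#'
#' @param samples a `sample_set` (see [as_sample_set()]) or list of sample
#'   tensors with phenotype attributes.
#' @param statistic `"count"` (default): voxels with density > 0 in either
#'   tissue channel; `"sum"`: summed density over both channels.
#' @return list with `auc_gender`, `r_age`, `p_age`, `volumes`.
#' @export
confound_check <- function(samples, statistic = c("count", "sum")) {
  statistic <- match.arg(statistic)
  ss <- as_sample_set(samples)
  if (nrow(ss$phenotypes) < 2) stop_vbm("need >= 2 subjects", class = "vbmnet_input_error")
  nvox <- prod(ss$shape)
  volumes <- vapply(seq_len(ncol(ss$values)), function(i) {
    v <- ss$values[, i]
    gm <- v[seq_len(nvox)]
    wm <- v[nvox + seq_len(nvox)]
    if (statistic == "count") sum(gm > 0 | wm > 0) else sum(gm[gm > 0]) + sum(wm[wm > 0])
  }, numeric(1))
  gender <- ss$phenotypes$gender
  auc_g <- auc_roc(gender, volumes)
  reg <- suppressWarnings(cor.test(ss$phenotypes$age, volumes))
  list(auc_gender = auc_g, r_age = unname(reg$estimate), p_age = reg$p.value,
       volumes = volumes)
}
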