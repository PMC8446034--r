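#' Agreement statistics between predicted and measured values
#'
#' Pearson's product-moment correlation, and the R-squared and RMSE of the
#' ordinary least-squares regression of measured on predicted.
#'
#' @param predicted,measured numeric vectors of equal length (n >= 3, both
#'   with nonzero variance).
#' @return list with `pearson_r`, `r2`, `rmse`.
#' @export
agreement_stats <- function(predicted, measured) {
  check_paired(predicted, measured, min_n = 3, need_variance = TRUE)
  fit <- stats::lm(measured ~ predicted)
  res <- stats::residuals(fit)
  list(pearson_r = stats::cor(predicted, measured),
       r2 = 1 - sum(res^2) / sum((measured - mean(measured))^2),
       rmse = sqrt(mean(res^2)))
}

#' Calibration of predicted against measured values
#'
#' Calibration slope is the OLS slope of measured on predicted (ideal 1);
#' calibration-in-the-large is `mean(measured) - mean(predicted)` (ideal 0).
#' With this sign convention calibration-in-the-large is identical to the
#' Bland-Altman bias.
#'
#' @inheritParams agreement_stats
#' @return list with `slope`, `citl`.
#' @export
calibration <- function(predicted, measured) {
  check_paired(predicted, measured, min_n = 3, need_variance = TRUE)
  list(slope = unname(stats::coef(stats::lm(measured ~ predicted))[2]),
       citl = mean(measured) - mean(predicted))
}

#' Bland-Altman agreement summary
#'
#' Differences are `measured - predicted`; bias is their mean and `sd` the
#' sample standard deviation (n - 1 denominator).
#'
#' @inheritParams agreement_stats
#' @return list with `bias`, `sd`.
#' @export
bland_altman <- function(predicted, measured) {
  check_paired(predicted, measured, min_n = 2)
  d <- measured - predicted
  list(bias = mean(d), sd = stats::sd(d))
}

check_paired <- function(predicted, measured, min_n = 2, need_variance = FALSE) {
  if (length(predicted) != length(measured))
    stop_validation("predicted and measured must have equal length")
  if (any(!is.finite(predicted)) || any(!is.finite(measured)))
    stop_validation("paired samples must be finite (filter missing first)")
  if (length(predicted) < min_n)
    stop_validation("need at least ", min_n, " pairs")
  if (need_variance &&
      (stats::var(predicted) == 0 || stats::var(measured) == 0))
    stop_validation("zero variance in a paired sample")
}

#' Classification metrics from a confusion table
#'
#' Standard definitions: accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)`. The odds
#' ratio is `(TP*TN)/(FP*FN)` with a Woolf log-method 95\% CI; when any cell
#' is zero, 0.5 is added to every cell for the OR and its CI (documented
#' continuity correction). Wilson score 95\% intervals accompany each rate.
#'
#' @param tp,fp,tn,fn nonnegative integer cell counts, total > 0.
#' @return object of class `confusion_metrics`: list of rates (proportions in
#'   `[0, 1]` with `lo`/`hi` Wilson bounds) plus `odds_ratio` with CI.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  for (v in c(tp, fp, tn, fn))
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      stop_validation("cells must be single nonnegative integers")
  total <- tp + fp + tn + fn
  if (total == 0) stop_validation("empty confusion table")
  rate <- function(num, den) {
    if (den == 0) return(list(est = NA_real_, lo = NA_real_, hi = NA_real_))
    ci <- wilson_interval(num, den)
    list(est = num / den, lo = ci[1], hi = ci[2])
  }
  cells <- c(tp, fp, tn, fn)
  corrected <- any(cells == 0)
  or_cells <- if (corrected) cells + 0.5 else cells
  or <- (or_cells[1] * or_cells[3]) / (or_cells[2] * or_cells[4])
  se_log <- sqrt(sum(1 / or_cells))
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = rate(tp + tn, total),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    odds_ratio = list(est = or, lo = exp(log(or) - 1.96 * se_log),
                      hi = exp(log(or) + 1.96 * se_log),
                      continuity_corrected = corrected)
  ), class = "confusion_metrics")
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(x, n, z = 1.96) {
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("Confusion table: TP %d, FP %d, TN %d, FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
    r <- x[[nm]]
    if (is.na(r$est)) next
    cat(sprintf("  %-11s %5.1f%% (95%% CI %.1f-%.1f)\n", nm,
                round_half_up(100 * r$est, 1),
                round_half_up(100 * r$lo, 1), round_half_up(100 * r$hi, 1)))
  }
  o <- x$odds_ratio
  cat(sprintf("  OR %.2f (95%% CI %.2f-%.2f)%s\n", o$est, o$lo, o$hi,
              if (o$continuity_corrected) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Discrimination curves: AUROC and AUPRC
#'
#' AUROC is computed as the rank (Mann-Whitney) statistic with midrank tie
#' correction, which equals the trapezoidal area over all distinct score
#' thresholds. AUPRC is the average-precision step estimator (no trapezoidal
#' interpolation in precision-recall space), evaluated over distinct score
#' cut-offs so ties are handled as a block. Orientation: higher `scores`
#' indicate the positive class; when scoring osteoporosis with predicted BMD
#' or T-score, pass the negated value.
#'
#' @param scores numeric risk scores.
#' @param labels logical (or 0/1) class labels; both classes must be present.
#' @return list with `auroc`, `auprc`.
#' @export
roc_pr_curves <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || any(is.na(scores)) || any(is.na(labels)))
    stop_validation("scores and labels must be complete and of equal length")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop_validation("both classes must be present")
  r <- rank(scores)
  auroc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # average precision over distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y); cum_pp <- seq_along(y)
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)
  tp_b <- cum_tp[last_of_block]; pp_b <- cum_pp[last_of_block]
  recall <- tp_b / n1
  precision <- tp_b / pp_b
  auprc <- sum(diff(c(0, recall)) * precision)
  list(auroc = auroc, auprc = auprc)
}

#' Search the PPV/NPV operating thresholds
#'
#' Finds the dual triage thresholds on a score where *lower* values indicate
#' osteoporosis (predicted BMD or T-score). For `type = "ppv"`: the largest
#' threshold `t1` such that calling `value < t1` positive attains PPV >=
#' `target` (maximising captured positives subject to the constraint). For
#' `type = "npv"`: the smallest `t2` such that calling `value >= t2` negative
#' attains NPV >= `target`. Candidate thresholds are the distinct observed
#' values (and the open extremes); an unattainable target returns
#' `achieved = FALSE` rather than an error.
#'
#' @param values predicted BMD or T-scores.
#' @param labels logical: TRUE = osteoporotic (positive).
#' @param target required predictive value, default 0.95.
#' @param type `"ppv"` or `"npv"`.
#' @return list with `achieved`, `threshold`, `attained` (the realised
#'   PPV/NPV at the returned threshold, NA when not achieved), and `n_called`
#'   (positives called for PPV, negatives for NPV).
#' @export
find_threshold <- function(values, labels, target = 0.95,
                           type = c("ppv", "npv")) {
  type <- match.arg(type)
  labels <- as.logical(labels)
  if (length(values) != length(labels) || any(is.na(values)) || any(is.na(labels)))
    stop_validation("values and labels must be complete and of equal length")
  if (!any(labels) || all(labels))
    stop_validation("both classes must be present")
  assert_scalar_number(target, "target", lower = 0, upper = 1)
  ord <- order(values)
  v <- values[ord]; y <- labels[ord]
  n <- length(v)
  distinct <- unique(v)
  if (type == "ppv") {
    # threshold candidates from largest down; predict positive when value < t
    best <- NULL
    for (t in c(Inf, rev(distinct))) {
      called <- v < t
      np <- sum(called)
      if (np == 0) next
      ppv <- sum(y[called]) / np
      if (ppv >= target) { best <- list(t = t, val = ppv, n = np); break }
    }
    if (is.null(best))
      return(list(achieved = FALSE, threshold = NA_real_, attained = NA_real_,
                  n_called = 0L))
    list(achieved = TRUE, threshold = best$t, attained = best$val,
         n_called = best$n)
  } else {
    best <- NULL
    for (t in c(-Inf, distinct)) {
      called <- v >= t
      nn <- sum(called)
      if (nn == 0) next
      npv <- sum(!y[called]) / nn
      if (npv >= target) { best <- list(t = t, val = npv, n = nn); break }
    }
    if (is.null(best))
      return(list(achieved = FALSE, threshold = NA_real_, attained = NA_real_,
                  n_called = 0L))
    list(achieved = TRUE, threshold = best$t, attained = best$val,
         n_called = best$n)
  }
}

#' Full metrics report for a screening evaluation
#'
#' Bundles agreement, calibration, Bland-Altman, discrimination, and
#' confusion-matrix metrics for one paired sample, optionally stratified.
#'
#' @param predicted,measured paired BMD values (g/cm^2).
#' @param positive logical ground-truth osteoporosis labels (from measured
#'   lowest T); when supplied with `pred_positive`, confusion metrics are
#'   included.
#' @param pred_positive logical predicted-positive calls.
#' @return list of class `metrics_report`.
#' @export
metrics_report <- function(predicted, measured, positive = NULL,
                           pred_positive = NULL) {
  out <- c(agreement_stats(predicted, measured),
           calibration(predicted, measured))
  ba <- bland_altman(predicted, measured)
  out$ba_bias <- ba$bias; out$ba_sd <- ba$sd
  if (!is.null(positive)) {
    curves <- roc_pr_curves(-predicted, positive)
    out$auroc <- curves$auroc; out$auprc <- curves$auprc
    if (!is.null(pred_positive)) {
      cm <- confusion_metrics(sum(pred_positive & positive),
                              sum(pred_positive & !positive),
                              sum(!pred_positive & !positive),
                              sum(!pred_positive & positive))
      out$confusion <- cm
    }
  }
  structure(out, class = "metrics_report")
}
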