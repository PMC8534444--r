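# Image-level diagnostic performance: confusion semantics at a probability
# threshold, the five diagnostic metrics with exact binomial CIs, ROC over a
# fixed threshold grid with trapezoidal AUC and Youden-optimal cutoffs, and
# the IoU >= 0.5 localization ratio.

#' Per-image decision score
#'
#' Reduces a frame's predicted boxes to one decision score: the maximum box
#' confidence, or 0 when no boxes were predicted. An image is called
#' detector-positive at threshold `t` when its score is `>= t`, matching the
#' frame-level reading that any box at or above threshold makes the image
#' positive.
#'
#' @param frame A [frame_record()].
#' @return A number in `[0, 1]`.
#' @export
image_score <- function(frame) {
  if (length(frame$pred_boxes) == 0L) return(0)
  max(vapply(frame$pred_boxes, `[[`, numeric(1), "score"))
}

#' Classify one image into the 2x2 confusion table
#'
#' An image with ground-truth boxes and any predicted box is a true positive
#' regardless of box overlap or count; an image with neither is a true
#' negative; predicted boxes without ground truth give one false positive;
#' ground truth without predicted boxes gives a false negative. One label
#' per image.
#'
#' @param gt_present Logical: does the image carry ground-truth boxes?
#' @param pred_present Logical: does the image carry predicted boxes at or
#'   above the working threshold?
#' @return One of `"TP"`, `"TN"`, `"FP"`, `"FN"`.
#' @export
classify_image <- function(gt_present, pred_present) {
  stopifnot(is.logical(gt_present), is.logical(pred_present),
            length(gt_present) == 1L, length(pred_present) == 1L)
  if (gt_present) {
    if (pred_present) "TP" else "FN"
  } else {
    if (pred_present) "FP" else "TN"
  }
}

#' Confusion counts over a frame set at a fixed threshold
#'
#' @param frames A [frame_dataset()] of retained frames.
#' @param threshold Probability threshold in `(0, 1)`; an image is
#'   detector-positive when [image_score()] `>= threshold`.
#' @return A `"confusion_counts"` object: list with integer fields `n_tp`,
#'   `n_fn`, `n_fp`, `n_tn`.
#' @export
confusion_at_threshold <- function(frames, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single probability in (0, 1)", call. = FALSE)
  }
  gt <- vapply(frames, function(f) length(f$gt_boxes) > 0L, logical(1))
  score <- vapply(frames, image_score, numeric(1))
  pred <- score >= threshold
  confusion_counts(n_tp = sum(gt & pred), n_fn = sum(gt & !pred),
                   n_fp = sum(!gt & pred), n_tn = sum(!gt & !pred))
}

#' @rdname confusion_at_threshold
#' @param n_tp,n_fn,n_fp,n_tn Non-negative integer image counts.
#' @export
confusion_counts <- function(n_tp, n_fn, n_fp, n_tn) {
  counts <- list(n_tp = as.integer(n_tp), n_fn = as.integer(n_fn),
                 n_fp = as.integer(n_fp), n_tn = as.integer(n_tn))
  if (anyNA(unlist(counts)) || any(unlist(counts) < 0L)) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(counts, class = "confusion_counts")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, computed from beta
#' quantiles: the lower bound is the `alpha/2` quantile of
#' `Beta(k, n - k + 1)` (0 when `k = 0`) and the upper bound the
#' `1 - alpha/2` quantile of `Beta(k + 1, n - k)` (1 when `k = n`). The
#' interval always contains `k / n`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `>= 1`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(626, 662) # approximately (0.926, 0.962)
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > n) {
    stop("k must satisfy 0 <= k <= n", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

metric_row <- function(k, d, level) {
  if (d == 0L) {
    return(data.frame(estimate = NA_real_, lower = NA_real_,
                      upper = NA_real_, numerator = k, denominator = d))
  }
  ci <- clopper_pearson(k, d, level)
  data.frame(estimate = k / d, lower = ci[["lower"]], upper = ci[["upper"]],
             numerator = k, denominator = d)
}

#' The five diagnostic metrics with exact confidence intervals
#'
#' Sensitivity `= n(TP)/(n(TP)+n(FN))`, specificity `= n(TN)/(n(TN)+n(FP))`,
#' PPV `= n(TP)/(n(TP)+n(FP))`, NPV `= n(TN)/(n(TN)+n(FN))`, and accuracy
#' `= (n(TP)+n(TN))/total`, each with a two-sided exact Clopper-Pearson
#' interval on its own numerator/denominator pair. A metric whose
#' denominator is zero is reported as `NA` (undefined), never coerced to 0
#' or 1.
#'
#' @param counts A [confusion_counts()] object with positive total.
#' @param level Confidence level for the intervals (default 0.95).
#' @return A `"diagnostic_report"` data frame with one row per metric
#'   (`sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`) and columns
#'   `estimate`, `lower`, `upper`, `numerator`, `denominator`.
#' @export
diagnostic_metrics <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$n_tp + counts$n_fn + counts$n_fp + counts$n_tn
  if (total == 0L) {
    stop("all confusion counts are zero: no images to evaluate",
         call. = FALSE)
  }
  rows <- rbind(
    sensitivity = metric_row(counts$n_tp, counts$n_tp + counts$n_fn, level),
    specificity = metric_row(counts$n_tn, counts$n_tn + counts$n_fp, level),
    ppv = metric_row(counts$n_tp, counts$n_tp + counts$n_fp, level),
    npv = metric_row(counts$n_tn, counts$n_tn + counts$n_fn, level),
    accuracy = metric_row(counts$n_tp + counts$n_tn, total, level))
  structure(rows, class = c("diagnostic_report", "data.frame"))
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Diagnostic performance (exact 95% CIs):\n")
  for (m in rownames(x)) {
    if (is.na(x[m, "estimate"])) {
      cat(sprintf("  %-11s undefined (denominator 0)\n", m))
    } else {
      cat(sprintf("  %-11s %5.1f%% (%.1f-%.1f)  [%d/%d]\n", m,
                  100 * x[m, "estimate"], 100 * x[m, "lower"],
                  100 * x[m, "upper"], x[m, "numerator"],
                  x[m, "denominator"]))
    }
  }
  invisible(x)
}

#' ROC curve over the fixed probability-threshold grid
#'
#' Sensitivity and specificity are computed at every threshold from 0.01 to
#' 0.99 in steps of 0.01, together with the Youden index
#' `J = sensitivity + specificity - 1`. The AUC is obtained by the
#' trapezoidal rule over the grid points in (1 - specificity, sensitivity)
#' space with the anchor points (0, 0) and (1, 1) appended (the grid itself
#' cannot reach the corners). The Youden-optimal cutoff is the set of grid
#' thresholds attaining the maximal `J`; ties at adjacent grid points are
#' reported as a contiguous range.
#'
#' @param frames A [frame_dataset()] containing at least one lesion-positive
#'   and one lesion-negative image.
#' @param grid Threshold grid (default `seq(0.01, 0.99, by = 0.01)`).
#' @return A `"roc_curve"` object: list with `points` (data frame of
#'   `threshold`, `sensitivity`, `specificity`, `youden_j`), `auc`,
#'   `optimal_thresholds`, `max_youden_j`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(frames, grid = ROC_GRID) {
  gt <- vapply(frames, function(f) length(f$gt_boxes) > 0L, logical(1))
  score <- vapply(frames, image_score, numeric(1))
  roc_from_scores(score, gt, grid)
}

# internal workhorse so oracles/tests can run on bare scores as well
roc_from_scores <- function(score, gt, grid = ROC_GRID) {
  n_pos <- sum(gt)
  n_neg <- sum(!gt)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires at least one lesion-positive and one lesion-negative ",
         "image", call. = FALSE)
  }
  sens <- vapply(grid, function(t) mean(score[gt] >= t), numeric(1))
  spec <- vapply(grid, function(t) mean(score[!gt] < t), numeric(1))
  points <- data.frame(threshold = grid, sensitivity = sens,
                       specificity = spec, youden_j = sens + spec - 1)
  fpr <- c(0, rev(1 - spec), 1)
  tpr <- c(0, rev(sens), 1)
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (utils::head(tpr[o], -1) +
                               utils::tail(tpr[o], -1)) / 2)
  curve <- structure(list(points = points, auc = auc, n_pos = n_pos,
                          n_neg = n_neg),
                     class = "roc_curve")
  opt <- youden_optimal(curve)
  curve$optimal_thresholds <- opt$thresholds
  curve$max_youden_j <- opt$max_youden_j
  curve
}

#' Youden-optimal threshold(s) of an ROC curve
#'
#' Returns every grid threshold attaining the maximal Youden index. When the
#' optimum is attained on a run of contiguous grid points the formatted
#' label is a range such as `"0.05-0.06"`; otherwise the single threshold.
#'
#' @param curve A `"roc_curve"` object.
#' @return A list with `thresholds` (numeric vector), `max_youden_j`, and
#'   `label` (formatted threshold or range).
#' @export
youden_optimal <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  p <- curve$points
  if (nrow(p) == 0L) stop("empty ROC curve", call. = FALSE)
  jmax <- max(p$youden_j)
  # guard against floating-point noise between algebraically equal J values
  thr <- p$threshold[p$youden_j >= jmax - 1e-12]
  list(thresholds = thr, max_youden_j = jmax,
       label = format_threshold_range(thr))
}

format_threshold_range <- function(thr) {
  if (length(thr) == 1L) return(format(thr))
  paste0(format(min(thr)), "-", format(max(thr)))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, %d positive / %d negative images\n",
              nrow(x$points), x$n_pos, x$n_neg))
  cat(sprintf("  AUC (trapezoidal): %.3f\n", x$auc))
  cat(sprintf("  max Youden J: %.3f at threshold %s\n", x$max_youden_j,
              format_threshold_range(x$optimal_thresholds)))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x A `"roc_curve"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  p <- x$points
  graphics::plot(c(0, rev(1 - p$specificity), 1),
                 c(0, rev(p$sensitivity), 1),
                 type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Localization-accuracy ratio among true-positive images
#'
#' Among images that are true positives at the working threshold, the
#' fraction whose best ground-truth-to-predicted-box match (predicted boxes
#' at or above the threshold only) reaches the IoU cutoff. For a frame with
#' two ground-truth boxes the best match over the ground-truth boxes is
#' used. The default cutoff is IoU `>= 0.5`; set `strict = TRUE` for a
#' strict inequality.
#'
#' @param tp_frames A [frame_dataset()] of images that are TP at
#'   `threshold` (ground-truth boxes present and at least one predicted box
#'   scoring `>= threshold`).
#' @param threshold Working probability threshold.
#' @param iou_cut IoU cutoff (default 0.5).
#' @param strict Use `>` instead of `>=` at the cutoff (default `FALSE`).
#' @return A list with `n_localized`, `n_tp`, `ratio` and `percent`.
#' @export
iou50_ratio <- function(tp_frames, threshold, iou_cut = 0.5,
                        strict = FALSE) {
  if (length(tp_frames) == 0L) {
    stop("iou50_ratio requires a non-empty set of true-positive images",
         call. = FALSE)
  }
  hit <- vapply(tp_frames, function(f) {
    if (length(f$gt_boxes) == 0L) {
      stop("iou50_ratio: frame without ground-truth boxes is not a TP image",
           call. = FALSE)
    }
    scores <- vapply(f$pred_boxes, `[[`, numeric(1), "score")
    boxes <- lapply(f$pred_boxes[scores >= threshold], `[[`, "box")
    if (length(boxes) == 0L) {
      stop("iou50_ratio: frame with no predicted box at or above the ",
           "threshold is not a TP image", call. = FALSE)
    }
    best <- max(best_match(f$gt_boxes, boxes)$iou)
    if (strict) best > iou_cut else best >= iou_cut
  }, logical(1))
  n <- length(hit)
  k <- sum(hit)
  list(n_localized = k, n_tp = n, ratio = k / n, percent = 100 * k / n)
}

#' Diagnostic report stratified by imaging mode
#'
#' Produces per-mode and overall rows of diagnostic performance. Each mode
#' is evaluated at its own Youden-optimal threshold and, additionally, at
#' the overall Youden-optimal threshold; the overall stratum is evaluated at
#' its optimal threshold only. Columns: stratum, image counts and
#' prevalence, threshold (formatted range when tied), Youden index, the
#' five metrics with exact CIs, and the IoU localization ratio among TP
#' images. Modes with no frames, or with only one class (so no ROC can be
#' drawn), are omitted with a warning.
#'
#' @param frames A [frame_dataset()] of retained frames.
#' @param grid Threshold grid for the ROC (default `ROC_GRID`).
#' @param iou_cut IoU cutoff for the localization ratio (default 0.5).
#' @param level Confidence level (default 0.95).
#' @return A data frame with one row per (stratum, threshold) pair.
#' @export
stratified_report <- function(frames, grid = ROC_GRID, iou_cut = 0.5,
                              level = 0.95) {
  if (!inherits(frames, "frame_dataset")) frames <- frame_dataset(frames)
  modes <- vapply(frames, `[[`, character(1), "mode")
  overall_curve <- roc_curve(frames, grid)
  overall_thr <- min(overall_curve$optimal_thresholds)
  rows <- list(report_row(frames, "Overall", overall_curve, overall_thr,
                          iou_cut, level))
  for (m in c("WLI", "CE", "NBI")) {
    sub <- frame_dataset(unclass(frames)[modes == m])
    if (length(sub) == 0L) {
      warning("stratum ", m, " has no frames; row omitted", call. = FALSE)
      next
    }
    gt <- vapply(sub, function(f) length(f$gt_boxes) > 0L, logical(1))
    if (all(gt) || !any(gt)) {
      warning("stratum ", m, " has a single class; row omitted",
              call. = FALSE)
      next
    }
    curve <- roc_curve(sub, grid)
    own_thr <- min(curve$optimal_thresholds)
    rows <- c(rows, list(report_row(sub, m, curve, own_thr, iou_cut, level)))
    if (!isTRUE(all.equal(own_thr, overall_thr))) {
      rows <- c(rows, list(report_row(sub, m, curve, overall_thr, iou_cut,
                                      level)))
    }
  }
  do.call(rbind, rows)
}

report_row <- function(frames, stratum, curve, threshold, iou_cut, level) {
  counts <- confusion_at_threshold(frames, threshold)
  rep <- diagnostic_metrics(counts, level)
  gt <- vapply(frames, function(f) length(f$gt_boxes) > 0L, logical(1))
  score <- vapply(frames, image_score, numeric(1))
  tp_frames <- frame_dataset(unclass(frames)[gt & score >= threshold])
  loc <- if (length(tp_frames) > 0L) {
    iou50_ratio(tp_frames, threshold, iou_cut)
  } else {
    list(n_localized = 0L, n_tp = 0L, ratio = NA_real_,
         percent = NA_real_)
  }
  at_own <- isTRUE(all.equal(threshold, min(curve$optimal_thresholds)))
  j_at_thr <- curve$points$youden_j[
    which.min(abs(curve$points$threshold - threshold))]
  cell <- function(metric) {
    data.frame(est = rep[metric, "estimate"],
               lo = rep[metric, "lower"], hi = rep[metric, "upper"])
  }
  s <- cell("sensitivity"); sp <- cell("specificity"); pp <- cell("ppv")
  np <- cell("npv"); ac <- cell("accuracy")
  data.frame(
    stratum = stratum,
    n_images = length(frames),
    n_positive = sum(gt),
    prevalence = mean(gt),
    auc = curve$auc,
    threshold = threshold,
    threshold_label = if (at_own)
      format_threshold_range(curve$optimal_thresholds)
    else format(threshold),
    at_own_optimum = at_own,
    youden_j = j_at_thr,
    sensitivity = s$est, sensitivity_lower = s$lo, sensitivity_upper = s$hi,
    specificity = sp$est, specificity_lower = sp$lo,
    specificity_upper = sp$hi,
    ppv = pp$est, ppv_lower = pp$lo, ppv_upper = pp$hi,
    npv = np$est, npv_lower = np$lo, npv_upper = np$hi,
    accuracy = ac$est, accuracy_lower = ac$lo, accuracy_upper = ac$hi,
    iou50_percent = loc$percent,
    iou50_localized = loc$n_localized,
    iou50_tp = loc$n_tp,
    stringsAsFactors = FALSE
  )
}
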