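test_that("image_score is the maximum box confidence, 0 without boxes", {
  expect_equal(image_score(mk_frame(1)), 0)
  expect_equal(image_score(mk_frame(1, score = 0.27)), 0.27)
  f <- frame_record("c", 0, 0, pred_boxes = list(
    list(box = c(0, 0, 10, 10), score = 0.2),
    list(box = c(20, 20, 30, 30), score = 0.9)))
  expect_equal(image_score(f), 0.9)
})

test_that("classify_image follows the per-image 2x2 semantics", {
  # overlap and box counts are irrelevant at image level
  expect_equal(classify_image(TRUE, TRUE), "TP")
  expect_equal(classify_image(FALSE, FALSE), "TN")
  expect_equal(classify_image(FALSE, TRUE), "FP")
  expect_equal(classify_image(TRUE, FALSE), "FN")
})

test_that("confusion_at_threshold matches an exhaustive hand count", {
  # gt present but predicted box disjoint from it is still TP at image level
  disjoint <- frame_dataset(list(
    mk_frame(1, gt = TRUE, score = 0.8, pred_box = c(500, 500, 600, 600))))
  cc <- confusion_at_threshold(disjoint, 0.27)
  expect_equal(cc$n_tp, 1L)

  # 10-frame fixture enumerated by hand at threshold 0.5:
  # positives with scores {0.9, 0.5, 0.49, NA} -> TP, TP, FN, FN
  # negatives with scores {0.6, 0.5, 0.4, NA, NA, 0.2} -> FP, FP, TN x4
  ds <- mk_dataset(gt = c(rep(TRUE, 4), rep(FALSE, 6)),
                   scores = c(0.9, 0.5, 0.49, NA, 0.6, 0.5, 0.4, NA, NA,
                              0.2))
  cc <- confusion_at_threshold(ds, 0.5)
  expect_equal(unclass(cc),
               list(n_tp = 2L, n_fn = 2L, n_fp = 2L, n_tn = 4L))

  # all-negative dataset, nothing predicted
  neg <- mk_dataset(gt = rep(FALSE, 5), scores = rep(NA, 5))
  expect_equal(confusion_at_threshold(neg, 0.27)$n_tn, 5L)

  # threshold above every score flags nothing
  cc2 <- confusion_at_threshold(ds, 0.95)
  expect_equal(cc2$n_tp + cc2$n_fp, 0L)
  # just below the top score, only the 0.9-scored positive is flagged
  cc3 <- confusion_at_threshold(ds, 0.85)
  expect_equal(cc3$n_tp + cc3$n_fp, 1L)
  expect_error(confusion_at_threshold(ds, 0), "\\(0, 1\\)")
})

test_that("counts are conserved and monotone across thresholds", {
  set.seed(5)
  ds <- mk_dataset(gt = runif(60) < 0.4,
                   scores = ifelse(runif(60) < 0.8, runif(60), NA))
  prev_tp <- Inf
  prev_fp <- Inf
  for (t in seq(0.05, 0.95, by = 0.05)) {
    cc <- confusion_at_threshold(ds, t)
    expect_equal(cc$n_tp + cc$n_fn + cc$n_fp + cc$n_tn, 60L)
    expect_lte(cc$n_tp, prev_tp)
    expect_lte(cc$n_fp, prev_fp)
    prev_tp <- cc$n_tp
    prev_fp <- cc$n_fp
  }
})

test_that("diagnostic_metrics applies the five formulas with exact CIs", {
  # published worked example: 626 TP / 36 FN
  rep1 <- diagnostic_metrics(confusion_counts(626, 36, 284, 5585))
  expect_equal(round(100 * rep1["sensitivity", "estimate"], 1), 94.6)
  expect_equal(round(100 * rep1["sensitivity", "lower"], 1), 92.6)
  expect_equal(round(100 * rep1["sensitivity", "upper"], 1), 96.2)

  rep2 <- diagnostic_metrics(confusion_counts(173, 9, 0, 0))
  expect_equal(round(100 * rep2["sensitivity", "estimate"], 1), 95.1)
  # zero-denominator metrics are undefined, never 0 or 1
  expect_true(is.na(rep2["specificity", "estimate"]))
  expect_equal(rep2["npv", "estimate"], 0) # 0/9: defined, just zero

  rep3 <- diagnostic_metrics(confusion_counts(1, 1, 1, 1))
  expect_equal(unname(rep3[, "estimate"]), rep(0.5, 5))

  expect_error(diagnostic_metrics(confusion_counts(0, 0, 0, 0)),
               "zero")
  expect_error(confusion_counts(-1, 0, 0, 1), "non-negative")
})

test_that("each point estimate lies inside its own CI", {
  set.seed(9)
  for (rep in 1:20) {
    cc <- confusion_counts(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    total <- cc$n_tp + cc$n_fn + cc$n_fp + cc$n_tn
    if (total == 0L) next
    r <- diagnostic_metrics(cc)
    ok <- !is.na(r$estimate)
    expect_true(all(r$estimate[ok] >= r$lower[ok] - 1e-12))
    expect_true(all(r$estimate[ok] <= r$upper[ok] + 1e-12))
  }
})

test_that("clopper_pearson agrees with the binomial tail-sum oracle", {
  cases <- list(c(626, 662), c(1, 10), c(7, 8), c(50, 100), c(173, 182))
  for (kn in cases) {
    got <- clopper_pearson(kn[1], kn[2])
    want <- cp_tail_oracle(kn[1], kn[2])
    expect_equal(got, want, tolerance = 1e-8)
    expect_true(got[["lower"]] <= kn[1] / kn[2])
    expect_true(got[["upper"]] >= kn[1] / kn[2])
  }
  expect_identical(clopper_pearson(0, 20)[["lower"]], 0)
  expect_identical(clopper_pearson(20, 20)[["upper"]], 1)
  expect_error(clopper_pearson(1, 0), "n must")
  expect_error(clopper_pearson(5, 3), "k must")
})

test_that("roc_curve: anchors, degenerate collapse, and oracle agreement", {
  perfect <- mk_dataset(gt = c(rep(TRUE, 5), rep(FALSE, 5)),
                        scores = c(rep(0.9, 5), rep(0.1, 5)))
  expect_equal(roc_curve(perfect)$auc, 1)

  # identical scores collapse to the anchor diagonal
  flat <- mk_dataset(gt = c(TRUE, TRUE, FALSE, FALSE),
                     scores = rep(0.5, 4))
  expect_equal(roc_curve(flat)$auc, 0.5)

  expect_error(roc_curve(mk_dataset(gt = c(TRUE, TRUE),
                                    scores = c(0.5, 0.6))),
               "positive and")

  # 200 synthetic frames: trapezoidal grid AUC vs rank-statistic oracle
  set.seed(31)
  gt <- rep(c(TRUE, FALSE), each = 100)
  scores <- c(rbeta(100, 4, 2), rbeta(100, 1.2, 4))
  ds <- mk_dataset(gt, scores)
  curve <- roc_curve(ds)
  expect_lt(abs(curve$auc - rank_auc(scores, gt)), 0.01)

  # sensitivity non-increasing, specificity non-decreasing in threshold
  expect_true(all(diff(curve$points$sensitivity) <= 1e-12))
  expect_true(all(diff(curve$points$specificity) >= -1e-12))
  expect_true(curve$auc >= 0 && curve$auc <= 1)
})

test_that("youden_optimal is the exhaustive-scan argmax, ranges formatted", {
  # positives at 0.27, negatives at 0.26: J = 1 uniquely at t = 0.27
  ds <- mk_dataset(gt = c(TRUE, TRUE, FALSE, FALSE),
                   scores = c(0.27, 0.27, 0.26, 0.26))
  curve <- roc_curve(ds)
  opt <- youden_optimal(curve)
  expect_equal(opt$thresholds, 0.27)
  expect_equal(opt$label, "0.27")

  # constructed tie: thresholds 0.05 and 0.06 give identical counts
  ds2 <- mk_dataset(gt = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                    scores = c(0.06, 0.9, 0.04, 0.5, 0.95))
  opt2 <- youden_optimal(roc_curve(ds2))
  expect_equal(opt2$thresholds, c(0.05, 0.06))
  expect_equal(opt2$label, "0.05-0.06")

  # argmax agrees with an exhaustive scan on random data
  set.seed(13)
  ds3 <- mk_dataset(gt = runif(80) < 0.5, scores = runif(80))
  curve3 <- roc_curve(ds3)
  jmax <- -Inf
  best <- numeric()
  for (i in seq_len(nrow(curve3$points))) {
    j <- curve3$points$youden_j[i]
    if (j > jmax + 1e-12) {
      jmax <- j
      best <- curve3$points$threshold[i]
    } else if (abs(j - jmax) <= 1e-12) {
      best <- c(best, curve3$points$threshold[i])
    }
  }
  expect_equal(youden_optimal(curve3)$thresholds, best)
})

test_that("monotone scores with one positive put max J at the isolating thresholds", {
  ds <- mk_dataset(gt = c(TRUE, FALSE, FALSE, FALSE),
                   scores = c(0.8, 0.6, 0.4, 0.2))
  opt <- youden_optimal(roc_curve(ds))
  # any grid threshold in (0.6, 0.8] isolates the positive: J = 1
  expect_equal(opt$max_youden_j, 1)
  expect_equal(range(opt$thresholds), c(0.61, 0.8))
})

test_that("iou50_ratio counts well-localized TP images", {
  good <- mk_frame(1, gt = TRUE, score = 0.9,
                   pred_box = c(100, 100, 200, 200)) # identical to gt
  off <- mk_frame(2, gt = TRUE, score = 0.9,
                  pred_box = c(250, 250, 450, 450)) # disjoint from gt
  # gt 200x240, prediction shifted down 80 px: 32000/64000 = 0.5 exactly
  half <- frame_record("c1", 10, 2L, gt_boxes = list(c(100, 100, 300, 340)),
                       pred_boxes = list(list(box = c(100, 180, 300, 420),
                                              score = 0.9)))
  ds <- frame_dataset(list(good, off, half))
  res <- iou50_ratio(ds, 0.27)
  expect_equal(res$n_localized, 2L) # >= 0.5 is inclusive at the boundary
  expect_equal(res$n_tp, 3L)
  strict <- iou50_ratio(ds, 0.27, strict = TRUE)
  expect_equal(strict$n_localized, 1L)

  all_good <- frame_dataset(list(good))
  expect_equal(iou50_ratio(all_good, 0.27)$percent, 100)
  all_off <- frame_dataset(list(off))
  expect_equal(iou50_ratio(all_off, 0.27)$percent, 0)
  expect_error(iou50_ratio(frame_dataset(), 0.27), "non-empty")
  # a frame that is not TP at the threshold is rejected
  expect_error(iou50_ratio(frame_dataset(list(mk_frame(1, gt = TRUE))),
                           0.27), "not a TP")
})

test_that("stratified_report mirrors the table layout", {
  set.seed(17)
  gt <- runif(300) < 0.3
  scores <- ifelse(gt, rbeta(300, 4, 1.5), NA)
  fp_mask <- !gt & runif(300) < 0.15
  scores[fp_mask] <- rbeta(sum(fp_mask), 1, 4)
  # single-mode dataset: stratum row equals the unstratified overall row
  ds <- mk_dataset(gt, scores, modes = "WLI")
  warns <- capture_warnings(rep <- stratified_report(ds))
  expect_length(warns, 2L) # empty CE and NBI strata are announced
  expect_match(warns, "no frames", all = TRUE)
  overall <- rep[rep$stratum == "Overall", ]
  wli_own <- rep[rep$stratum == "WLI" & rep$at_own_optimum, ]
  expect_equal(wli_own$sensitivity, overall$sensitivity)
  expect_equal(wli_own$threshold, overall$threshold)
  expect_equal(overall$n_images, 300L)
  expect_equal(overall$prevalence, mean(gt))

  # three-mode dataset: per-mode rows at own and overall optima
  ds3 <- mk_dataset(gt, scores, modes = c("WLI", "CE", "NBI"))
  rep3 <- stratified_report(ds3)
  expect_true(all(c("Overall", "WLI", "CE", "NBI") %in% rep3$stratum))
  for (m in c("WLI", "CE", "NBI")) {
    rows <- rep3[rep3$stratum == m, ]
    expect_true(any(rows$at_own_optimum) || nrow(rows) == 1L)
    expect_true(min(rep3$threshold[rep3$stratum == "Overall"]) %in%
                  rows$threshold || all(rows$at_own_optimum))
  }
})
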