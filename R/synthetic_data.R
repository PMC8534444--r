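# Synthetic detector output with the statistical structure of a colonoscopy
# still-image study: mode-dependent lesion prevalence, Beta-distributed box
# confidences calibrated to a stated operating point, sporadic false-positive
# boxes, box-position jitter, and frame-rate detection streams around lesion
# appearances.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards; all generator randomness flows through here.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Solve the Beta shape2 so that P(X >= q) = p_exceed with shape1 fixed.
# pbeta(q, s1, s2) increases monotonically in s2, so uniroot on log(s2).
solve_beta_shape2 <- function(shape1, q, p_exceed) {
  if (p_exceed <= 0 || p_exceed >= 1) {
    stop("exceedance probability must be in (0, 1)", call. = FALSE)
  }
  f <- function(ls2) stats::pbeta(q, shape1, exp(ls2)) - (1 - p_exceed)
  exp(stats::uniroot(f, c(-12, 12), tol = 1e-12)$root)
}

#' Detector profile for the synthetic generator
#'
#' Describes the stochastic behaviour of an emulated box detector. Box
#' confidences on lesion frames follow a `Beta(hit_shape1, .)` distribution
#' and false-positive box confidences a `Beta(miss_shape1, .)`; the second
#' shape of each is solved numerically so that at the stated `cutoff` the
#' frame-level sensitivity equals `sensitivity_at_cutoff` and specificity
#' equals `specificity_at_cutoff`. `fp_rate` is the probability that a
#' lesion-free frame carries a false-positive box at all, so the
#' specificity constraint requires `fp_rate >= 1 - specificity_at_cutoff`.
#' `jitter` is the maximal predicted-box offset as a fraction of the box
#' side (0 reproduces the ground-truth box exactly).
#'
#' The defaults place the operating point at threshold 0.27 with 94.6%
#' sensitivity and 95.2% specificity, the regime of a well-trained
#' real-time colonoscopy detector.
#'
#' @param sensitivity_at_cutoff Frame-level sensitivity at `cutoff`.
#' @param specificity_at_cutoff Frame-level specificity at `cutoff`.
#' @param cutoff Operating threshold the calibration targets.
#' @param fp_rate Probability a lesion-free frame carries any predicted box.
#' @param hit_rate Probability a lesion frame carries a predicted box at
#'   all (default 1: the score distribution alone controls sensitivity).
#' @param hit_shape1,miss_shape1 First Beta shapes of the two score
#'   distributions.
#' @param jitter Maximal box offset as a fraction of the box side, in
#'   `[0, 1)`; see [jitter_for_iou()].
#' @return A list with class `"detector_profile"` including the solved
#'   `hit_shape2` and `miss_shape2`.
#' @export
detector_profile <- function(sensitivity_at_cutoff = 0.946,
                             specificity_at_cutoff = 0.952,
                             cutoff = 0.27,
                             fp_rate = 0.12,
                             hit_rate = 1,
                             hit_shape1 = 2,
                             miss_shape1 = 0.8,
                             jitter = 0.1) {
  stopifnot(cutoff > 0, cutoff < 1,
            sensitivity_at_cutoff > 0, sensitivity_at_cutoff < 1,
            specificity_at_cutoff > 0, specificity_at_cutoff < 1,
            fp_rate >= 0, fp_rate <= 1, hit_rate > 0, hit_rate <= 1,
            jitter >= 0, jitter < 1)
  if (sensitivity_at_cutoff > hit_rate) {
    stop("sensitivity_at_cutoff cannot exceed hit_rate", call. = FALSE)
  }
  fp_target <- 1 - specificity_at_cutoff
  if (fp_rate < fp_target) {
    stop("fp_rate (", fp_rate, ") must be at least 1 - ",
         "specificity_at_cutoff (", fp_target, ") for the calibration to ",
         "be feasible", call. = FALSE)
  }
  structure(list(
    sensitivity_at_cutoff = sensitivity_at_cutoff,
    specificity_at_cutoff = specificity_at_cutoff,
    cutoff = cutoff,
    fp_rate = fp_rate,
    hit_rate = hit_rate,
    hit_shape1 = hit_shape1,
    hit_shape2 = solve_beta_shape2(hit_shape1, cutoff,
                                   sensitivity_at_cutoff / hit_rate),
    miss_shape1 = miss_shape1,
    miss_shape2 = if (fp_rate > 0)
      solve_beta_shape2(miss_shape1, cutoff, fp_target / fp_rate)
    else NA_real_,
    jitter = jitter
  ), class = "detector_profile")
}

#' Study profile for the synthetic generator
#'
#' The sampled-still-image corpus being emulated: total frame count, the
#' mix of imaging modes, the per-mode image-level lesion prevalence, and
#' the image size. The defaults reproduce a therapeutic-colonoscopy corpus
#' of 6531 frames — 5527 white-light (prevalence 6.0%), 824
#' chromoendoscopy (22.1%) and 180 narrow-band (81.1%) — for an overall
#' prevalence near 10.1%.
#'
#' @param n_images Total number of frames.
#' @param mode_mix Named fractions over `WLI`, `CE`, `NBI`; must sum to 1.
#' @param prevalence Named per-mode lesion-positive probabilities in
#'   `[0, 1]`.
#' @param image_size `c(width, height)` in pixels.
#' @param n_cases Number of cases the frames are spread over.
#' @param sample_interval Seconds between consecutive sampled frames.
#' @return A list with class `"study_profile"`.
#' @export
study_profile <- function(n_images = 6531,
                          mode_mix = c(WLI = 5527, CE = 824, NBI = 180) /
                            6531,
                          prevalence = c(WLI = 334 / 5527, CE = 182 / 824,
                                         NBI = 146 / 180),
                          image_size = c(1280, 1024),
                          n_cases = 20,
                          sample_interval = 5) {
  stopifnot(n_images >= 1, n_cases >= 1, sample_interval > 0,
            length(image_size) == 2L, all(image_size > 0))
  need <- c("WLI", "CE", "NBI")
  if (!all(need %in% names(mode_mix)) ||
      abs(sum(mode_mix) - 1) > 1e-8) {
    stop("mode_mix must be named fractions over WLI, CE, NBI summing to 1",
         call. = FALSE)
  }
  if (!all(need %in% names(prevalence)) ||
      any(prevalence < 0 | prevalence > 1)) {
    stop("prevalence must give a probability in [0, 1] for each of WLI, ",
         "CE, NBI", call. = FALSE)
  }
  structure(list(n_images = as.integer(n_images),
                 mode_mix = mode_mix[need],
                 prevalence = prevalence[need],
                 image_size = as.numeric(image_size),
                 n_cases = as.integer(n_cases),
                 sample_interval = sample_interval),
            class = "study_profile")
}

#' Box-jitter fraction attaining a target IoU
#'
#' For a predicted box shifted diagonally by a fraction `f` of its width
#' and height, the overlap with the ground-truth box is
#' `(1 - f)^2 / (2 - (1 - f)^2)`. Inverting this relation gives the shift
#' fraction whose worst-case (full-shift) IoU equals `target_iou`; during
#' generation per-axis shifts are drawn uniformly in `[-f, f]`, so the
#' target is the lower edge of the induced IoU distribution.
#'
#' @param target_iou Desired minimal IoU in `(0, 1]`.
#' @return Shift fraction `f` in `[0, 1)`.
#' @export
jitter_for_iou <- function(target_iou) {
  stopifnot(target_iou > 0, target_iou <= 1)
  1 - sqrt(2 * target_iou / (1 + target_iou))
}

random_box <- function(image_size, min_side = 60, max_side = 400) {
  w <- stats::runif(1, min_side, min(max_side, image_size[[1L]] / 2))
  h <- stats::runif(1, min_side, min(max_side, image_size[[2L]] / 2))
  x <- stats::runif(1, 0, image_size[[1L]] - w)
  y <- stats::runif(1, 0, image_size[[2L]] - h)
  bbox(x, y, x + w, y + h)
}

jitter_box <- function(b, frac, image_size) {
  if (frac == 0) return(b)
  w <- b[[3L]] - b[[1L]]
  h <- b[[4L]] - b[[2L]]
  dx <- stats::runif(1, -frac, frac) * w
  dy <- stats::runif(1, -frac, frac) * h
  # keep the jittered box inside the image so it remains a valid annotation
  dx <- min(max(dx, -b[[1L]]), image_size[[1L]] - b[[3L]])
  dy <- min(max(dy, -b[[2L]]), image_size[[2L]] - b[[4L]])
  bbox(b[[1L]] + dx, b[[2L]] + dy, b[[3L]] + dx, b[[4L]] + dy)
}

#' Generate a synthetic annotated image dataset
#'
#' Draws a full still-image corpus under a [study_profile()] and a
#' [detector_profile()]: per-mode frame counts follow the mode mix,
#' lesion positivity is Bernoulli per frame at the mode's prevalence,
#' lesion frames carry one or two ground-truth boxes (second box with
#' probability `p_two_boxes`) plus a jittered predicted copy scored from
#' the hit distribution (with probability `hit_rate`), and lesion-free
#' frames carry a false-positive box with probability `fp_rate`, scored
#' from the miss distribution. Output is reproducible given `seed`.
#'
#' @param study A [study_profile()].
#' @param detector A [detector_profile()].
#' @param seed Integer seed; the only source of randomness.
#' @param p_two_boxes Probability a lesion frame shows two lesions.
#' @return A [frame_dataset()].
#' @export
generate_image_dataset <- function(study = study_profile(),
                                   detector = detector_profile(),
                                   seed = 1L, p_two_boxes = 0.1) {
  stopifnot(inherits(study, "study_profile"),
            inherits(detector, "detector_profile"))
  with_seed(seed, {
    n <- study$n_images
    counts <- round(n * study$mode_mix)
    counts[[1L]] <- n - sum(counts[-1L]) # absorb rounding in WLI
    modes <- rep(names(counts), times = counts)
    modes <- sample(modes, n) # interleave modes across cases
    case_of <- rep(seq_len(study$n_cases), length.out = n,
                   each = ceiling(n / study$n_cases))[seq_len(n)]
    frames <- vector("list", n)
    frame_in_case <- integer(study$n_cases)
    for (i in seq_len(n)) {
      cid <- case_of[[i]]
      k <- frame_in_case[[cid]]
      frame_in_case[[cid]] <- k + 1L
      mode <- modes[[i]]
      positive <- stats::runif(1) < study$prevalence[[mode]]
      gt <- list()
      pred <- list()
      if (positive) {
        n_gt <- 1L + (stats::runif(1) < p_two_boxes)
        gt <- replicate(n_gt, random_box(study$image_size),
                        simplify = FALSE)
        if (stats::runif(1) < detector$hit_rate) {
          score <- stats::rbeta(1, detector$hit_shape1, detector$hit_shape2)
          pred <- list(list(box = jitter_box(gt[[1L]], detector$jitter,
                                             study$image_size),
                            score = score))
        }
      } else if (stats::runif(1) < detector$fp_rate) {
        score <- stats::rbeta(1, detector$miss_shape1, detector$miss_shape2)
        pred <- list(list(box = random_box(study$image_size), score = score))
      }
      frames[[i]] <- frame_record(
        case_id = sprintf("case%02d", cid),
        timestamp = k * study$sample_interval,
        frame_index = k,
        mode = mode,
        gt_boxes = gt,
        pred_boxes = pred)
    }
    frame_dataset(frames)
  })
}

#' Generate a synthetic lesion clip with its detection stream
#'
#' Emulates a short video-recorded scene around a lesion's first
#' appearance: `pre_s` seconds of pre-appearance footage where raw hits are
#' sporadic background false positives, then `post_s` seconds where the
#' detector hits each frame independently with `per_frame_hit_prob`. The
#' clip defaults (5 s before, 10 s after, 30 fps) match a scene of median
#' length 15 s.
#'
#' @param fps Frames per second.
#' @param pre_s Seconds of footage before the lesion appears.
#' @param post_s Seconds of footage from the appearance onward.
#' @param per_frame_hit_prob Per-frame raw detection probability once the
#'   lesion is visible.
#' @param background_hit_prob Per-frame false-positive probability before
#'   the appearance.
#' @param lesion_id,case_id,paris_class,size_mm Passed to [lesion_event()].
#' @param seed Integer seed.
#' @return A list with elements `event` (a [lesion_event()]) and `stream`
#'   (its [detection_stream()], identical to `event$clip`).
#' @export
generate_lesion_clip <- function(fps = 30, pre_s = 5, post_s = 10,
                                 per_frame_hit_prob = 0.9,
                                 background_hit_prob = 0.02,
                                 lesion_id = "lesion1", case_id = "case1",
                                 paris_class = "0-Is", size_mm = 5L,
                                 seed = 1L) {
  stopifnot(fps > 0, pre_s >= 0, post_s > 0,
            per_frame_hit_prob >= 0, per_frame_hit_prob <= 1,
            background_hit_prob >= 0, background_hit_prob <= 1)
  with_seed(seed, {
    n_pre <- round(pre_s * fps)
    n_post <- round(post_s * fps)
    hits <- c(stats::runif(n_pre) < background_hit_prob,
              stats::runif(n_post) < per_frame_hit_prob)
    stream <- detection_stream(case_id = case_id, fps = fps, hits = hits)
    event <- lesion_event(lesion_id = lesion_id, case_id = case_id,
                          appearance_frame = n_pre + 1L, clip = stream,
                          paris_class = paris_class, size_mm = size_mm)
    list(event = event, stream = stream)
  })
}

#' Generate a cohort of lesion clips
#'
#' Draws `n_lesions` clips with independent sub-seeds derived from `seed`.
#' `n_undetectable` of them (the last ones) are generated with
#' `per_frame_hit_prob = 0`, emulating lesions the detector never fires on.
#'
#' @param n_lesions Number of lesions.
#' @param n_undetectable How many lesions carry zero hit probability.
#' @param seed Integer seed.
#' @inheritParams generate_lesion_clip
#' @return A list of [lesion_event()]s.
#' @export
generate_lesion_cohort <- function(n_lesions = 69, n_undetectable = 1,
                                   fps = 30, pre_s = 5, post_s = 10,
                                   per_frame_hit_prob = 0.9,
                                   background_hit_prob = 0.02,
                                   seed = 1L) {
  stopifnot(n_lesions >= 1, n_undetectable >= 0,
            n_undetectable <= n_lesions)
  subseeds <- with_seed(seed,
                        sample.int(.Machine$integer.max, n_lesions))
  lapply(seq_len(n_lesions), function(i) {
    p <- if (i > n_lesions - n_undetectable) 0 else per_frame_hit_prob
    bg <- if (i > n_lesions - n_undetectable) 0 else background_hit_prob
    generate_lesion_clip(fps = fps, pre_s = pre_s, post_s = post_s,
                         per_frame_hit_prob = p, background_hit_prob = bg,
                         lesion_id = sprintf("lesion%03d", i),
                         case_id = sprintf("case%02d", 1L + (i - 1L) %% 20L),
                         seed = subseeds[[i]])$event
  })
}
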