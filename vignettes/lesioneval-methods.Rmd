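---
title: "Methods: low-bias evaluation of colonoscopy CADe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-bias evaluation of colonoscopy CADe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesioneval)
```

## Scope and model

`lesioneval` evaluates a frame-level lesion detector in two complementary
analyses.

The **image-based analysis** treats each sampled still frame as one
binary trial. Frames are drawn from the procedure video on a fixed clock
(default every 5 s, first sample at t = 0) with no quality screening, so
the operator cannot bias either prevalence or image quality. Six
exclusion criteria then remove frames that cannot meaningfully be scored:
outside the colorectum, post-resection sites, imaging modes other than
WLI/CE/NBI, artificial objects, submucosal injection blebs, and frames
with more than two lesions. Five of the six are semantic judgments an
expert makes on the image; they enter the pipeline as annotation labels
and are *not* computed. Only the lesion-count rule is derived from the
ground-truth boxes, read literally as "more than two" (a two-lesion frame
is retained).

A frame's decision score is the maximum confidence over its predicted
boxes, 0 when there are none. This is the only reduction consistent with
the per-image confusion semantics, where any displayed box makes the
image detector-positive and an image with both ground-truth and predicted
boxes is a true positive regardless of overlap or box count. Overlap is
scored separately, among TP images only, as the fraction whose best
ground-truth-to-predicted match reaches IoU ≥ 0.5 — this separates "does
the system fire on lesion frames" from "does it point at the lesion".

The **lesion-based analysis** asks how quickly the deployed system shows
a box after a lesion first becomes visible. The deployed display rule is
a persistence filter: a box appears only when raw detections occur in at
least 3 of 5 sequential frames. Latency is counted from the
expert-marked appearance frame to the first *displayed* frame, in frames,
divided by the clip frame rate; a lesion not displayed within 5 s is a
detection failure. Failures enter the detection rate but never the
latency median/range.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| sampling `interval` | 5 s | still-image extraction clock |
| ROC grid | 0.01–0.99 step 0.01 | thresholds scanned for the ROC/Youden cutoff |
| `iou_cut` | 0.5 (inclusive) | localization-accuracy cutoff |
| filter `window`, `min_hits` | 5, 3 | persistence rule (product-side, trial-and-error choice) |
| `timeout_s` | 5 s | latency failure rule |
| `fps` | 30 | clip frame rate; a required per-clip input, 30 is the common video default |
| CI `level` | 0.95 | two-sided exact Clopper–Pearson |

## Numerical and design choices

**Box convention.** Boxes are half-open pixel rectangles
`[x_min, x_max) × [y_min, y_max)` with the origin at the top-left, so
integer-coordinate boxes have exact integer areas and IoU can be checked
*exactly* against a pixel-cell enumeration oracle (the test suite does
this on 1000 random pairs). Degenerate zero-area boxes are rejected, not
given IoU 0.

**Matching.** Each ground-truth box is matched greedily to the
predicted box of maximal IoU; one prediction may serve several
ground-truth boxes, because the image-level metrics never require a
bijection. Ties break to the lowest predicted-box index for determinism.
On the rare frame with two ground-truth boxes, the localization ratio
uses the maximum best-match IoU across them.

**Threshold grid.** The default grid is `round(seq(0.01, 0.99, .01), 2)`:
un-rounded `seq()` accumulates binary floating-point drift (its "0.06" is
`0.060000000000000005`), which silently breaks exact `score >= threshold`
comparisons at grid points. Scores are compared to thresholds with `>=`,
so a box scoring exactly at the cutoff is positive.

**AUC.** Trapezoidal rule over the grid points in (1 − specificity,
sensitivity) space with anchors (0, 0) and (1, 1) appended; without the
anchors a perfectly separating detector could not reach AUC 1 because the
grid stops at 0.99. On continuous scores the grid AUC agrees with the
rank-statistic (Mann–Whitney) estimate to within the grid discretization
(±0.01, property-tested).

**Youden ties.** All grid thresholds attaining the maximal J are
returned; a contiguous run is formatted as a range (`"0.05-0.06"`).
Downstream report rows use the smallest optimal threshold.

**Exact CIs.** Clopper–Pearson bounds come from beta quantiles
(`qbeta(α/2, k, n−k+1)`, `qbeta(1−α/2, k+1, n−k)`), with the boundary
conventions lower = 0 at k = 0 and upper = 1 at k = n. The tests verify
them against an independent root-finding construction on binomial tail
sums, and empirically confirm ≥ 93% coverage at n = 662, p = 0.95 (exact
intervals are conservative, so coverage exceeds the nominal 95% minus
discreteness effects). Each derived metric's CI is computed on that
metric's own numerator/denominator pair; a metric with a zero denominator
is reported as `NA`, never coerced to 0 or 1 — small strata would
otherwise be silently biased.

**Persistence filter.** The window is causal — the current frame plus
the four preceding, padded with misses before the stream start — because
a real-time monitor cannot use future frames; with this convention an
uninterrupted run of detections first displays on its third frame,
matching the observed sub-second latencies. The rule is applied
image-wide (any detection counts), not per tracked region: the deployed
system's spatial linking, if any, is undocumented, and image-wide is the
weakest assumption. The vectorized implementation is exhaustively
checked against a brute-force window enumerator on all 4096 length-12
hit sequences.

**Latency boundary.** "Not detected for 5 s means failure" is
implemented strictly: a display exactly 5.000 s after appearance is a
failure, so every reported latency is < timeout. Latency is measured
against the *filtered* display stream by default (that is what the
endoscopist sees); `use_raw = TRUE` measures against raw hits for
ablation. Frame indices are 1-based inside R, 0-based in the serialized
CSV/JSON formats.

## The synthetic generator

`generate_image_dataset()` emulates the statistical structure of a
therapeutic-colonoscopy still-image corpus: 6531 frames over 20 cases,
mode mix 5527 WLI / 824 CE / 180 NBI with per-mode lesion prevalence
6.0% / 22.1% / 81.1% (overall ≈ 10.1%). Lesion frames carry one or two
ground-truth boxes (two with probability 0.1 — multi-lesion frames are
uncommon after the more-than-two exclusion) of uniformly random size
60–400 px in a 1280×1024 image. Box confidences are Beta-distributed:
the second shape parameter of each family is solved (monotone root-find
on the Beta CDF) so that at the stated cutoff 0.27 the frame-level
sensitivity is 94.6% and specificity 95.2%. A lesion-free frame carries a
false-positive box with probability `fp_rate = 0.12` — sporadic FPs at
roughly one frame in eight, chosen so that miss-scores above the cutoff
reproduce the 4.8% frame-level FP rate; any `fp_rate ≥ 0.048` can be
calibrated, and 0.12 leaves the miss-score distribution realistically
heavy near zero. Predicted boxes on lesion frames are jittered copies of
a ground-truth box; the jitter fraction has a closed-form relation to the
worst-case IoU, `IoU = (1−f)²/(2−(1−f)²)`, inverted by
`jitter_for_iou()` so a target IoU floor can be dialed directly. All
randomness flows from one seed through a save/restore wrapper, so
generation is bit-reproducible and never perturbs the caller's RNG.

`generate_lesion_clip()` emulates a scene around a lesion appearance:
5 s of pre-appearance footage with a 2% per-frame background
false-positive rate, then 10 s in which the lesion is hit independently
per frame (default probability 0.9, a strong detector on a visible
lesion) at 30 fps — a 15 s clip, the median scene length in this kind of
review. The mean display latency under the 3-of-5 filter is verified
against an exact absorbing-Markov-chain expectation over the 16 window
states.

**What the generator does not emulate** — and therefore what a green
test does *not* establish: no pixel content (image quality, blur, bowel
preparation), no scope motion or temporal correlation between sampled
still frames, no correlation between lesion morphology/size and
detectability, no per-case clustering of detector behaviour, and
detector scores that are exchangeable within class rather than
image-difficulty-dependent. Green acceptance tests establish that the
*measurement pipeline* is correct at known ground truth, not that any
particular detector performs well.

## Known limitations

- Image-level analysis only: no per-box average precision, no pixel
  masks, no rotated boxes.
- AUC confidence intervals are not computed (the appropriate binomial
  denominator for a trapezoidal grid AUC is ambiguous).
- Exclusion labels are trusted as given; the package cannot detect
  outside-body or instrument frames from pixels.
- The persistence filter does not track regions across frames, so on
  frames where the rule fires without a raw hit the display stream
  carries presence only, no box geometry.
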