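# Independent oracles and small fixture builders shared across the suite.
# Each oracle deliberately uses a different computational route than the
# implementation it checks.

# IoU by brute-force enumeration of integer pixel cells. Only valid for
# boxes with integer coordinates; each cell (x, y) covers [x, x+1) x [y, y+1).
pixel_iou <- function(a, b) {
  cells <- function(box) {
    xs <- seq.int(box[[1L]], box[[3L]] - 1L)
    ys <- seq.int(box[[2L]], box[[4L]] - 1L)
    as.vector(outer(xs, ys, function(x, y) paste(x, y)))
  }
  ca <- cells(a)
  cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# Rank-statistic (Mann-Whitney) AUC over raw scores: the probability a
# random positive outscores a random negative, ties counting one half.
rank_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Clopper-Pearson by root-finding on binomial tail sums, independent of the
# beta-quantile route used by the package.
cp_tail_oracle <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (k == 0) 0 else {
    stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (k == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower = lower, upper = upper)
}

# Exact expected display latency (in frames past the appearance frame) of
# the min_hits-of-window persistence rule when the lesion is hit each frame
# independently with probability p and the pre-appearance window is empty.
# Dynamic programming over the 2^(window-1) window-history states, solved
# as an absorbing-chain linear system.
expected_filter_latency_frames <- function(p, window = 5L, min_hits = 3L) {
  m <- window - 1L
  histories <- as.matrix(expand.grid(rep(list(c(0L, 1L)), m)))
  n_states <- nrow(histories)
  key <- function(h) paste(h, collapse = "")
  idx <- stats::setNames(seq_len(n_states), apply(histories, 1L, key))
  A <- diag(n_states)
  b <- rep(1, n_states)
  for (s in seq_len(n_states)) {
    h <- histories[s, ]
    for (hit in c(0L, 1L)) {
      prob <- if (hit == 1L) p else 1 - p
      if (sum(h) + hit >= min_hits) next # absorbed: displayed this frame
      nxt <- idx[[key(c(h[-1L], hit))]]
      A[s, nxt] <- A[s, nxt] - prob
    }
  }
  N <- solve(A, b) # expected frames consumed, counting the current one
  N[[idx[[key(rep(0L, m))]]]] - 1
}

# Quick single-frame builder: gt controls lesion positivity, score the
# confidence of one predicted box (NA = no predicted box).
mk_frame <- function(i, gt = FALSE, score = NA, case_id = "c1",
                     mode = "WLI", labels = character(),
                     n_gt = if (gt) 1L else 0L,
                     pred_box = c(110, 110, 210, 210)) {
  gt_boxes <- rep(list(c(100, 100, 200, 200)), n_gt)
  pred_boxes <- if (is.na(score)) list() else {
    list(list(box = pred_box, score = score))
  }
  frame_record(case_id = case_id, timestamp = 5 * (i - 1), frame_index = i - 1L,
               mode = mode, exclusion_labels = labels, gt_boxes = gt_boxes,
               pred_boxes = pred_boxes)
}

# Dataset from parallel vectors of gt flags and scores.
mk_dataset <- function(gt, scores, modes = "WLI") {
  modes <- rep_len(modes, length(gt))
  frame_dataset(lapply(seq_along(gt), function(i) {
    mk_frame(i, gt = gt[[i]], score = scores[[i]], mode = modes[[i]])
  }))
}

random_int_box <- function(lim = 30L, max_side = 12L) {
  x0 <- sample.int(lim, 1L) - 1L
  y0 <- sample.int(lim, 1L) - 1L
  c(x0, y0, x0 + sample.int(max_side, 1L), y0 + sample.int(max_side, 1L))
}
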