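# Axis-aligned bounding boxes on the pixel grid.
#
# Convention: a box is the half-open rectangle [x_min, x_max) x [y_min, y_max)
# with the origin at the image top-left, so for integer coordinates the area
# is an exact count of pixel cells.

#' Construct an axis-aligned bounding box
#'
#' A bounding box is a numeric vector `c(x_min, y_min, x_max, y_max)`
#' interpreted as the half-open rectangle \eqn{[x_{min}, x_{max}) \times
#' [y_{min}, y_{max})} in pixel coordinates, origin at the image top-left.
#' Boxes must have strictly positive area and finite, non-negative
#' coordinates.
#'
#' @param x_min,y_min,x_max,y_max Pixel coordinates; `x_max > x_min` and
#'   `y_max > y_min`.
#' @return A numeric vector of length 4 with class `"bbox"`.
#' @examples
#' bbox(0, 0, 10, 10)
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_bbox(b)
  class(b) <- "bbox"
  b
}

#' @rdname bbox
#' @param x A numeric vector of length 4 (`x_min, y_min, x_max, y_max`) or a
#'   `bbox`.
#' @export
as_bbox <- function(x) {
  if (inherits(x, "bbox")) return(x)
  if (!is.numeric(x) || length(x) != 4L) {
    stop("a bounding box must be a numeric vector of length 4 ",
         "(x_min, y_min, x_max, y_max)", call. = FALSE)
  }
  bbox(x[[1L]], x[[2L]], x[[3L]], x[[4L]])
}

validate_bbox <- function(b) {
  if (anyNA(b) || !all(is.finite(b))) {
    stop("bounding box coordinates must be finite", call. = FALSE)
  }
  if (any(b < 0)) {
    stop("bounding box coordinates must be non-negative", call. = FALSE)
  }
  if (b[[3L]] <= b[[1L]] || b[[4L]] <= b[[2L]]) {
    stop("degenerate bounding box: x_max must exceed x_min and y_max must ",
         "exceed y_min (zero-area boxes are invalid)", call. = FALSE)
  }
  invisible(b)
}

bbox_area <- function(b) {
  (b[[3L]] - b[[1L]]) * (b[[4L]] - b[[2L]])
}

#' Intersection over union of two bounding boxes
#'
#' IoU is the area of the overlap between two axis-aligned boxes divided by
#' the area of their union. It is symmetric in its arguments, equals 1 only
#' for identical boxes, and 0 for disjoint boxes.
#'
#' @param a,b Bounding boxes (see [bbox()]); plain numeric length-4 vectors
#'   are accepted.
#' @return A single number in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 5, 15, 15)) # 25 / 175 = 1/7
#' @export
iou <- function(a, b) {
  a <- as_bbox(a)
  b <- as_bbox(b)
  iw <- min(a[[3L]], b[[3L]]) - max(a[[1L]], b[[1L]])
  ih <- min(a[[4L]], b[[4L]]) - max(a[[2L]], b[[2L]])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (bbox_area(a) + bbox_area(b) - inter)
}

#' Match each ground-truth box to its best-overlapping predicted box
#'
#' For every ground-truth box the predicted box with maximal IoU is selected
#' (greedy, per ground-truth box; one predicted box may serve several
#' ground-truth boxes). Ties on IoU are broken by the lowest predicted-box
#' index, so the result is deterministic. When `pred_boxes` is empty every
#' match has `pred_index = NA` and `iou = 0`.
#'
#' @param gt_boxes Non-empty list of ground-truth bounding boxes.
#' @param pred_boxes Possibly empty list of predicted bounding boxes.
#' @return A data frame with one row per ground-truth box and columns
#'   `gt_index`, `pred_index` (`NA` when no candidate exists) and `iou`.
#' @examples
#' gt <- list(bbox(0, 0, 10, 10))
#' pred <- list(bbox(8, 8, 20, 20), bbox(1, 1, 11, 11))
#' best_match(gt, pred)
#' @export
best_match <- function(gt_boxes, pred_boxes) {
  if (length(gt_boxes) == 0L) {
    stop("gt_boxes must be non-empty", call. = FALSE)
  }
  gt_boxes <- lapply(gt_boxes, as_bbox)
  pred_boxes <- lapply(pred_boxes, as_bbox)
  n_gt <- length(gt_boxes)
  out <- data.frame(gt_index = seq_len(n_gt),
                    pred_index = rep(NA_integer_, n_gt),
                    iou = numeric(n_gt))
  if (length(pred_boxes) == 0L) return(out)
  for (i in seq_len(n_gt)) {
    ious <- vapply(pred_boxes, iou, numeric(1), b = gt_boxes[[i]])
    j <- which.max(ious) # which.max returns the first maximum: lowest index
    out$pred_index[i] <- j
    out$iou[i] <- ious[[j]]
  }
  out
}
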