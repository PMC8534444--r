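# Annotated frame streams: the annotation schema, fixed-interval frame
# sampling, and the six image exclusion criteria.

ANNOTATION_SCHEMA_VERSION <- "1.0"

#' Imaging modes and exclusion reasons
#'
#' `imaging_modes()` returns the recognized colonoscopy imaging modes:
#' white-light imaging (`WLI`), chromoendoscopy (`CE`), narrow-band imaging
#' (`NBI`), and `OTHER` for any further mode. `OTHER` frames are always
#' excluded from metric computation.
#'
#' `exclusion_reasons()` returns the six exclusion criteria in their fixed
#' tally order. Five are semantic image properties supplied as human labels
#' on the record (`OUTSIDE_COLORECTUM`, `POST_RESECTION`,
#' `OTHER_IMAGING_MODE`, `ARTIFICIAL_OBJECT`, `SUBMUCOSAL_BLEB`); the sixth,
#' `TOO_MANY_LESIONS`, is derived from the annotations (more than two
#' ground-truth lesions on the frame).
#'
#' @return A character vector.
#' @export
imaging_modes <- function() c("WLI", "CE", "NBI", "OTHER")

#' @rdname imaging_modes
#' @export
exclusion_reasons <- function() {
  c("OUTSIDE_COLORECTUM", "POST_RESECTION", "OTHER_IMAGING_MODE",
    "ARTIFICIAL_OBJECT", "SUBMUCOSAL_BLEB", "TOO_MANY_LESIONS")
}

#' Construct a single annotated frame record
#'
#' One sampled still image from a colonoscopy video: its position in the
#' stream, imaging mode, any human exclusion labels, ground-truth lesion
#' boxes, and detector-predicted boxes with confidence scores.
#'
#' @param case_id Opaque case identifier (character scalar).
#' @param timestamp Seconds from the start of the video, `>= 0`.
#' @param frame_index Integer frame number `>= 0` within the case.
#' @param mode One of [imaging_modes()].
#' @param exclusion_labels Character vector of human-provided exclusion
#'   labels; a subset of [exclusion_reasons()] excluding `TOO_MANY_LESIONS`
#'   (which is derived, never supplied).
#' @param gt_boxes List of ground-truth [bbox()]es; non-empty means the
#'   frame is lesion-positive.
#' @param pred_boxes List of predicted boxes, each a list with elements
#'   `box` (a [bbox()]) and `score` (confidence in `[0, 1]`).
#' @return A list with class `"frame_record"`.
#' @export
frame_record <- function(case_id, timestamp, frame_index, mode = "WLI",
                         exclusion_labels = character(),
                         gt_boxes = list(), pred_boxes = list()) {
  rec <- list(case_id = as.character(case_id),
              timestamp = as.numeric(timestamp),
              frame_index = as.integer(frame_index),
              mode = as.character(mode),
              exclusion_labels = as.character(exclusion_labels),
              gt_boxes = lapply(gt_boxes, as_bbox),
              pred_boxes = lapply(pred_boxes, as_pred_box))
  validate_frame_record(rec)
  class(rec) <- "frame_record"
  rec
}

as_pred_box <- function(p) {
  if (!is.list(p) || !all(c("box", "score") %in% names(p))) {
    stop("a predicted box must be a list with elements 'box' and 'score'",
         call. = FALSE)
  }
  score <- as.numeric(p$score)
  if (length(score) != 1L || is.na(score) || score < 0 || score > 1) {
    stop("predicted-box confidence score must be a single value in [0, 1], ",
         "got ", format(p$score), call. = FALSE)
  }
  list(box = as_bbox(p$box), score = score)
}

validate_frame_record <- function(rec) {
  if (length(rec$case_id) != 1L || is.na(rec$case_id)) {
    stop("case_id must be a single non-missing identifier", call. = FALSE)
  }
  if (length(rec$timestamp) != 1L || is.na(rec$timestamp) ||
      rec$timestamp < 0) {
    stop("timestamp must be a single non-negative number of seconds",
         call. = FALSE)
  }
  if (length(rec$frame_index) != 1L || is.na(rec$frame_index) ||
      rec$frame_index < 0L) {
    stop("frame_index must be a single non-negative integer", call. = FALSE)
  }
  if (!rec$mode %in% imaging_modes()) {
    stop("unknown imaging mode '", rec$mode, "'; expected one of ",
         paste(imaging_modes(), collapse = ", "), call. = FALSE)
  }
  allowed <- setdiff(exclusion_reasons(), "TOO_MANY_LESIONS")
  bad <- setdiff(rec$exclusion_labels, allowed)
  if (length(bad) > 0L) {
    stop("unknown exclusion label(s): ", paste(bad, collapse = ", "),
         " (TOO_MANY_LESIONS is derived from annotations, not supplied)",
         call. = FALSE)
  }
  invisible(rec)
}

#' Bundle frame records into a dataset
#'
#' A frame dataset is an ordered list of [frame_record()]s. Within each case
#' the timestamps must be strictly increasing with `frame_index`.
#'
#' @param frames List of [frame_record()]s.
#' @return A list with class `"frame_dataset"`.
#' @export
frame_dataset <- function(frames = list()) {
  frames <- lapply(frames, function(f) {
    if (!inherits(f, "frame_record")) {
      stop("all elements must be frame_record objects", call. = FALSE)
    }
    f
  })
  ds <- structure(frames, class = "frame_dataset")
  validate_frame_dataset(ds)
  ds
}

validate_frame_dataset <- function(ds) {
  if (length(ds) == 0L) return(invisible(ds))
  cases <- vapply(ds, `[[`, character(1), "case_id")
  ts <- vapply(ds, `[[`, numeric(1), "timestamp")
  idx <- vapply(ds, `[[`, integer(1), "frame_index")
  for (cid in unique(cases)) {
    sel <- cases == cid
    o <- order(idx[sel])
    if (any(diff(ts[sel][o]) <= 0)) {
      stop("timestamps within case '", cid, "' must be strictly increasing ",
           "with frame_index", call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.frame_dataset <- function(x, ...) {
  n <- length(x)
  npos <- sum(vapply(x, function(f) length(f$gt_boxes) > 0L, logical(1)))
  cases <- unique(vapply(x, `[[`, character(1), "case_id"))
  cat(sprintf("<frame_dataset> %d frames, %d lesion-positive, %d case(s)\n",
              n, npos, length(cases)))
  invisible(x)
}

#' Summarize a frame dataset as a data frame
#'
#' One row per frame with scalar fields plus counts of ground-truth and
#' predicted boxes and the per-image decision score.
#'
#' @param object A [frame_dataset()].
#' @param ... Ignored.
#' @return A data frame.
#' @export
summary.frame_dataset <- function(object, ...) {
  data.frame(
    case_id = vapply(object, `[[`, character(1), "case_id"),
    timestamp = vapply(object, `[[`, numeric(1), "timestamp"),
    frame_index = vapply(object, `[[`, integer(1), "frame_index"),
    mode = vapply(object, `[[`, character(1), "mode"),
    n_exclusion_labels = vapply(object, function(f)
      length(f$exclusion_labels), integer(1)),
    n_gt = vapply(object, function(f) length(f$gt_boxes), integer(1)),
    n_pred = vapply(object, function(f) length(f$pred_boxes), integer(1)),
    score = vapply(object, image_score, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Sample still frames from a stream at a fixed time interval
#'
#' Emulates automatic, blind extraction of still images from a video at
#' regular intervals (default every 5 s), without any quality-based
#' selection. For each case the frame nearest each target time
#' `t = phase, phase + interval, ...` up to the last timestamp is selected;
#' ties go to the earlier frame, no frame is selected twice, and
#' chronological order is preserved.
#'
#' @param stream A [frame_dataset()] at native frame rate.
#' @param interval Sampling interval in seconds, `> 0`.
#' @param phase Time of the first sample in seconds (default 0).
#' @return A [frame_dataset()] of the sampled frames.
#' @export
sample_frames <- function(stream, interval = 5, phase = 0) {
  if (!inherits(stream, "frame_dataset")) stream <- frame_dataset(stream)
  if (length(stream) == 0L) {
    stop("cannot sample from an empty stream", call. = FALSE)
  }
  if (!is.numeric(interval) || length(interval) != 1L || is.na(interval) ||
      interval <= 0) {
    stop("interval must be a single positive number of seconds",
         call. = FALSE)
  }
  cases <- vapply(stream, `[[`, character(1), "case_id")
  ts <- vapply(stream, `[[`, numeric(1), "timestamp")
  keep <- logical(length(stream))
  for (cid in unique(cases)) {
    sel <- which(cases == cid)
    tcase <- ts[sel]
    targets <- seq(from = phase, to = max(tcase), by = interval)
    for (tt in targets) {
      # nearest frame; ties broken toward the earlier frame (which.min
      # returns the first minimum and frames are in chronological order)
      keep[sel[which.min(abs(tcase - tt))]] <- TRUE
    }
  }
  frame_dataset(unclass(stream)[keep])
}

exclusion_reason_for <- function(frame) {
  # first applicable reason in the fixed enumeration order, or NA if retained
  applicable <- frame$exclusion_labels
  if (frame$mode == "OTHER") {
    applicable <- c(applicable, "OTHER_IMAGING_MODE")
  }
  if (length(frame$gt_boxes) > 2L) {
    applicable <- c(applicable, "TOO_MANY_LESIONS")
  }
  if (length(applicable) == 0L) return(NA_character_)
  exclusion_reasons()[min(match(applicable, exclusion_reasons()))]
}

#' Apply the six image exclusion criteria
#'
#' A frame is retained iff it carries no human exclusion label, its imaging
#' mode is not `OTHER`, and it shows at most two ground-truth lesions. Each
#' excluded frame is tallied once, under the first applicable reason in the
#' order of [exclusion_reasons()], so the retained count plus the tally sum
#' always equals the input size.
#'
#' @param frames A [frame_dataset()].
#' @return A list with elements `retained` (a [frame_dataset()]) and `tally`
#'   (a named integer vector over all six reasons).
#' @export
apply_exclusions <- function(frames) {
  if (!inherits(frames, "frame_dataset")) frames <- frame_dataset(frames)
  reasons <- vapply(frames, exclusion_reason_for, character(1))
  tally <- table(factor(reasons, levels = exclusion_reasons()))
  list(retained = frame_dataset(unclass(frames)[is.na(reasons)]),
       tally = stats::setNames(as.integer(tally), exclusion_reasons()))
}

# ---- annotation schema I/O --------------------------------------------------

frame_to_json_list <- function(f) {
  list(case_id = f$case_id,
       timestamp = f$timestamp,
       frame_index = f$frame_index,
       mode = f$mode,
       exclusion_labels = as.list(f$exclusion_labels),
       gt_boxes = lapply(f$gt_boxes, function(b) as.numeric(b)),
       pred_boxes = lapply(f$pred_boxes, function(p)
         list(box = as.numeric(p$box), score = p$score)))
}

#' Read and write annotation files
#'
#' The annotation schema is a single JSON document per dataset with a
#' mandatory `schema_version` field and a `frames` array; each frame carries
#' exactly the fields of [frame_record()], boxes serialized as
#' `[x_min, y_min, x_max, y_max]`. Reading validates every record (score
#' range, box validity, per-case timestamp ordering) and rejects unknown
#' fields; `write_annotations()` followed by `read_annotations()` is the
#' identity on valid datasets.
#'
#' @param path File path.
#' @param frames A [frame_dataset()].
#' @return `read_annotations()` returns a [frame_dataset()];
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  known_top <- c("schema_version", "frames")
  extra <- setdiff(names(doc), known_top)
  if (length(extra) > 0L) {
    stop("unknown top-level field(s) ", paste(extra, collapse = ", "),
         " in annotation file (schema version ", ANNOTATION_SCHEMA_VERSION,
         " expects only ", paste(known_top, collapse = ", "), ")",
         call. = FALSE)
  }
  if (is.null(doc$schema_version)) {
    stop("annotation file lacks the mandatory schema_version field",
         call. = FALSE)
  }
  if (!identical(as.character(doc$schema_version),
                 ANNOTATION_SCHEMA_VERSION)) {
    stop("unsupported annotation schema version '", doc$schema_version,
         "'; this reader supports version ", ANNOTATION_SCHEMA_VERSION,
         call. = FALSE)
  }
  known_fields <- c("case_id", "timestamp", "frame_index", "mode",
                    "exclusion_labels", "gt_boxes", "pred_boxes")
  frames <- lapply(seq_along(doc$frames), function(i) {
    rec <- doc$frames[[i]]
    extra <- setdiff(names(rec), known_fields)
    if (length(extra) > 0L) {
      stop("record ", i, ": unknown field(s) ", paste(extra, collapse = ", "),
           " (schema version ", ANNOTATION_SCHEMA_VERSION, ")",
           call. = FALSE)
    }
    tryCatch(
      frame_record(case_id = rec$case_id,
                   timestamp = rec$timestamp,
                   frame_index = rec$frame_index,
                   mode = rec$mode,
                   exclusion_labels = unlist(rec$exclusion_labels),
                   gt_boxes = lapply(rec$gt_boxes, function(b)
                     as.numeric(unlist(b))),
                   pred_boxes = lapply(rec$pred_boxes, function(p)
                     list(box = as.numeric(unlist(p$box)), score = p$score))),
      error = function(e) {
        stop("record ", i, " (case ",
             if (is.null(rec$case_id)) "<missing>" else rec$case_id,
             ", frame ",
             if (is.null(rec$frame_index)) "<missing>" else rec$frame_index,
             "): ", conditionMessage(e), call. = FALSE)
      })
  })
  tryCatch(frame_dataset(frames), error = function(e) {
    stop("annotation file invalid: ", conditionMessage(e), call. = FALSE)
  })
}

#' @rdname read_annotations
#' @export
write_annotations <- function(frames, path) {
  if (!inherits(frames, "frame_dataset")) frames <- frame_dataset(frames)
  doc <- list(schema_version = ANNOTATION_SCHEMA_VERSION,
              frames = lapply(frames, frame_to_json_list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
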