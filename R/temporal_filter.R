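# Display-side persistence rule: a bounding box is shown only when raw
# detections occur in at least `min_hits` of the last `window` sequential
# frames (default 3 of 5), suppressing flicker false positives.

#' Construct a per-frame detection stream
#'
#' Raw detector output for one video clip: an ordered sequence of per-frame
#' hit flags (detection at or above the working threshold), the frame rate,
#' and optionally per-frame scores.
#'
#' @param case_id Case identifier.
#' @param fps Frames per second, `> 0`.
#' @param hits Logical vector of raw per-frame detections, length `>= 1`.
#' @param scores Optional numeric vector of per-frame scores, same length as
#'   `hits`.
#' @return A list with class `"detection_stream"`.
#' @export
detection_stream <- function(case_id, fps, hits, scores = NULL) {
  hits <- as.logical(hits)
  if (length(hits) < 1L || anyNA(hits)) {
    stop("hits must be a non-empty logical vector without NAs",
         call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  if (!is.null(scores)) {
    scores <- as.numeric(scores)
    if (length(scores) != length(hits)) {
      stop("scores must have the same length as hits", call. = FALSE)
    }
  }
  structure(list(case_id = as.character(case_id), fps = fps, hits = hits,
                 scores = scores),
            class = "detection_stream")
}

#' @export
print.detection_stream <- function(x, ...) {
  cat(sprintf("<detection_stream> case %s: %d frames at %g fps, %d raw hits\n",
              x$case_id, length(x$hits), x$fps, sum(x$hits)))
  invisible(x)
}

resolve_hits <- function(stream) {
  if (inherits(stream, "detection_stream")) stream$hits
  else as.logical(stream)
}

#' Persistence filter: display only sustained detections
#'
#' A frame's detection is displayed iff the causal window consisting of the
#' current frame and the `window - 1` preceding frames (padded with
#' non-detections before the stream start) contains at least `min_hits` raw
#' hits. With the defaults (3 of 5) an uninterrupted run of hits first
#' displays on its third frame; isolated single- or double-frame hits are
#' suppressed. A real-time monitor cannot look ahead, hence the causal
#' window.
#'
#' @param stream A [detection_stream()] or a logical vector of raw hits.
#' @param window Window length in frames (default 5).
#' @param min_hits Minimum raw hits in the window to display (default 3);
#'   must satisfy `1 <= min_hits <= window`.
#' @return A logical vector of displayed flags, same length as the hits.
#' @export
persistence_filter <- function(stream, window = 5L, min_hits = 3L) {
  hits <- resolve_hits(stream)
  window <- as.integer(window)
  min_hits <- as.integer(min_hits)
  if (is.na(window) || window < 1L) {
    stop("window must be a positive integer", call. = FALSE)
  }
  if (is.na(min_hits) || min_hits < 1L || min_hits > window) {
    stop("min_hits must satisfy 1 <= min_hits <= window", call. = FALSE)
  }
  n <- length(hits)
  if (n == 0L) stop("empty hit sequence", call. = FALSE)
  cs <- cumsum(hits)
  lagged <- c(rep(0L, min(window, n)), cs)[seq_len(n)]
  (cs - lagged) >= min_hits
}

#' Brute-force reference for the persistence filter
#'
#' Evaluates every causal window explicitly with a loop; kept deliberately
#' independent of the vectorized [persistence_filter()] so the two can be
#' checked against each other.
#'
#' @inheritParams persistence_filter
#' @return A logical vector of displayed flags.
#' @export
filter_equivalence_oracle <- function(stream, window = 5L, min_hits = 3L) {
  hits <- resolve_hits(stream)
  window <- as.integer(window)
  min_hits <- as.integer(min_hits)
  if (is.na(min_hits) || min_hits < 1L || min_hits > window) {
    stop("min_hits must satisfy 1 <= min_hits <= window", call. = FALSE)
  }
  n <- length(hits)
  out <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window + 1L)
    out[i] <- sum(hits[lo:i]) >= min_hits
  }
  out
}

#' Read and write detection-stream CSV files
#'
#' Columns: `frame_index` (0-based, as recorded by the capture system),
#' `timestamp` (seconds), `hit` (0/1), and optionally `score`. The frame
#' rate is stored in a `# fps: <value>` comment on the first line so a
#' stream file is self-contained.
#'
#' @param stream A [detection_stream()].
#' @param path File path.
#' @param case_id Case identifier to attach on read.
#' @return `read_detection_stream()` returns a [detection_stream()];
#'   `write_detection_stream()` returns `path` invisibly.
#' @export
write_detection_stream <- function(stream, path) {
  stopifnot(inherits(stream, "detection_stream"))
  n <- length(stream$hits)
  df <- data.frame(frame_index = seq_len(n) - 1L,
                   timestamp = (seq_len(n) - 1L) / stream$fps,
                   hit = as.integer(stream$hits))
  if (!is.null(stream$scores)) df$score <- stream$scores
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps: %s", format(stream$fps)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detection_stream
#' @export
read_detection_stream <- function(path, case_id = basename(path)) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# fps:", first)) {
    stop("stream file ", path, " lacks the '# fps:' header line",
         call. = FALSE)
  }
  fps <- as.numeric(sub("^# fps:\\s*", "", first))
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame_index", "timestamp", "hit")
  if (!all(need %in% names(df))) {
    stop("stream file ", path, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$frame_index), , drop = FALSE]
  detection_stream(case_id = case_id, fps = fps,
                   hits = df$hit != 0,
                   scores = if ("score" %in% names(df)) df$score else NULL)
}
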