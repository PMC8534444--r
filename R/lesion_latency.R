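# Lesion-based analysis: latency from a lesion's first appearance to its
# first displayed detection, with a timeout failure rule, and per-lesion
# summary statistics.

PARIS_CLASSES <- c("0-Ip", "0-Isp", "0-Is", "0-IIa", "0-IIb", "0-IIc",
                   "0-III")

#' Construct a lesion event
#'
#' One lesion clinically requiring resection, tied to the video clip around
#' its first appearance: the expert-identified appearance frame, the
#' lesion's endoscopic morphology (Paris classification) and size, and the
#' raw detection stream covering the clip.
#'
#' @param lesion_id,case_id Identifiers.
#' @param appearance_frame 1-based index of the frame where the lesion first
#'   becomes visible; must lie within the clip.
#' @param clip A [detection_stream()] covering the appearance.
#' @param paris_class Paris morphology class, e.g. `"0-Is"` (sessile) or
#'   `"0-IIa"` (flat-elevated).
#' @param size_mm Lesion size in millimetres, a positive integer.
#' @return A list with class `"lesion_event"`.
#' @export
lesion_event <- function(lesion_id, case_id, appearance_frame, clip,
                         paris_class = "0-Is", size_mm = 5L) {
  stopifnot(inherits(clip, "detection_stream"))
  appearance_frame <- as.integer(appearance_frame)
  if (is.na(appearance_frame) || appearance_frame < 1L ||
      appearance_frame > length(clip$hits)) {
    stop("appearance_frame must lie within the clip (1..",
         length(clip$hits), ")", call. = FALSE)
  }
  if (!paris_class %in% PARIS_CLASSES) {
    stop("unknown Paris class '", paris_class, "'; expected one of ",
         paste(PARIS_CLASSES, collapse = ", "), call. = FALSE)
  }
  size_mm <- as.integer(size_mm)
  if (is.na(size_mm) || size_mm <= 0L) {
    stop("size_mm must be a positive integer", call. = FALSE)
  }
  structure(list(lesion_id = as.character(lesion_id),
                 case_id = as.character(case_id),
                 appearance_frame = appearance_frame,
                 clip = clip,
                 paris_class = paris_class,
                 size_mm = size_mm),
            class = "lesion_event")
}

#' Detection latency of one lesion
#'
#' Latency is the time from the lesion's first appearance to the first
#' frame, at or after the appearance, on which the persistence-filtered
#' display stream shows a box: `(display_frame - appearance_frame) / fps`
#' seconds. A lesion not displayed within `timeout_s` seconds of its
#' appearance counts as a detection failure (no latency reported). By
#' default the filtered display stream is used, since the persistence rule
#' is active in the deployed system; set `use_raw = TRUE` to measure
#' against the raw hits instead (ablation).
#'
#' @param event A [lesion_event()].
#' @param display Optional logical display stream aligned frame-for-frame
#'   with the clip; computed with [persistence_filter()] defaults when
#'   omitted.
#' @param timeout_s Failure timeout in seconds (default 5).
#' @param use_raw Measure against raw hits instead of the filtered display.
#' @param window,min_hits Persistence-filter parameters used when `display`
#'   is computed internally.
#' @return A `"latency_result"` list: `lesion_id`, `detected` (flag),
#'   `latency_s` (`NA` when not detected).
#' @export
detection_latency <- function(event, display = NULL, timeout_s = 5,
                              use_raw = FALSE, window = 5L, min_hits = 3L) {
  stopifnot(inherits(event, "lesion_event"))
  hits <- event$clip$hits
  if (is.null(display)) {
    display <- if (use_raw) hits
    else persistence_filter(hits, window, min_hits)
  }
  display <- as.logical(display)
  if (length(display) != length(hits)) {
    stop("display stream (", length(display), " frames) is not aligned ",
         "with the clip (", length(hits), " frames)", call. = FALSE)
  }
  fps <- event$clip$fps
  a <- event$appearance_frame
  cand <- which(display[a:length(display)])
  detected <- FALSE
  latency <- NA_real_
  if (length(cand) > 0L) {
    latency <- (cand[[1L]] - 1L) / fps
    # not displayed for timeout_s seconds from appearance => failure
    if (latency < timeout_s) detected <- TRUE else latency <- NA_real_
  }
  structure(list(lesion_id = event$lesion_id, detected = detected,
                 latency_s = latency),
            class = "latency_result")
}

#' Summarize per-lesion latency results
#'
#' Detection rate is the fraction of lesions displayed before the timeout,
#' reported as a percentage. Median and range of latency are taken over
#' detected lesions only; failures enter the detection rate, not the
#' latency statistics.
#'
#' @param results List of `"latency_result"` objects.
#' @return A list: `n`, `n_detected`, `detection_rate` (proportion),
#'   `detection_rate_pct` (percent, one decimal), `median_latency_s`,
#'   `min_latency_s`, `max_latency_s` (all `NA` when nothing was detected).
#' @export
summarize_latencies <- function(results) {
  if (length(results) == 0L) {
    stop("summarize_latencies requires a non-empty result list",
         call. = FALSE)
  }
  detected <- vapply(results, `[[`, logical(1), "detected")
  lat <- vapply(results, `[[`, numeric(1), "latency_s")
  if (any(detected & is.na(lat)) || any(!detected & !is.na(lat))) {
    stop("inconsistent latency results: detected flags must match the ",
         "presence of a latency", call. = FALSE)
  }
  lat <- lat[detected]
  list(n = length(results),
       n_detected = sum(detected),
       detection_rate = mean(detected),
       detection_rate_pct = round(100 * mean(detected), 1),
       median_latency_s = if (length(lat)) stats::median(lat) else NA_real_,
       min_latency_s = if (length(lat)) min(lat) else NA_real_,
       max_latency_s = if (length(lat)) max(lat) else NA_real_)
}

#' Per-lesion latency table
#'
#' Runs [detection_latency()] over a list of lesion events and returns one
#' row per lesion.
#'
#' @param events List of [lesion_event()]s.
#' @inheritParams detection_latency
#' @return A data frame with columns `lesion_id`, `case_id`, `paris_class`,
#'   `size_mm`, `appearance_frame`, `detected`, `latency_s`.
#' @export
latency_table <- function(events, timeout_s = 5, use_raw = FALSE,
                          window = 5L, min_hits = 3L) {
  rows <- lapply(events, function(ev) {
    res <- detection_latency(ev, timeout_s = timeout_s, use_raw = use_raw,
                             window = window, min_hits = min_hits)
    data.frame(lesion_id = ev$lesion_id, case_id = ev$case_id,
               paris_class = ev$paris_class, size_mm = ev$size_mm,
               appearance_frame = ev$appearance_frame,
               detected = res$detected, latency_s = res$latency_s,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
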