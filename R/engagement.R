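# Engagement index from behavior-interval annotations.
#
# Six target behaviors are annotated as (start, stop) intervals; at any
# instant the engagement level is the fraction of behaviors concurrently
# active, in {0, 1/6, ..., 1}. Its x6 integer is the 7-class label the
# classifiers predict.

#' The six annotated target behaviors
#' @export
TARGET_BEHAVIORS <- c("eye_gaze", "vocalization", "smiling",
                      "self_initiated", "triadic", "imitation")

#' Construct a validated annotation set
#'
#' Events are validated (`stop > start`, behavior drawn from the closed
#' six-element vocabulary) and overlapping or abutting events of the same
#' behavior are merged into their union, so a behavior contributes at most
#' 1/6 to the engagement level at any instant. Intervals are closed-open
#' `[start, stop)`, which lets abutting events tile without double counting.
#'
#' @param behavior character vector of behavior names.
#' @param start_s,stop_s event bounds in seconds.
#' @return a data frame of class `annotation_set` with merged events, sorted
#'   by behavior then start time.
#' @export
behavior_events <- function(behavior, start_s, stop_s) {
  stopifnot(length(behavior) == length(start_s), length(start_s) == length(stop_s))
  bad <- setdiff(unique(behavior), TARGET_BEHAVIORS)
  if (length(bad) > 0) {
    stop("vocabulary error: unknown behavior(s): ", paste(bad, collapse = ", "))
  }
  if (any(stop_s <= start_s)) {
    i <- which(stop_s <= start_s)[1]
    stop(sprintf("interval error: stop <= start for %s [%g, %g]",
                 behavior[i], start_s[i], stop_s[i]))
  }
  if (any(start_s < 0)) stop("interval error: negative start time")
  df <- data.frame(behavior = behavior, start_s = start_s, stop_s = stop_s,
                   stringsAsFactors = FALSE)
  merged <- do.call(rbind, lapply(split(df, df$behavior), merge_intervals))
  merged <- merged[order(merged$behavior, merged$start_s), ]
  rownames(merged) <- NULL
  class(merged) <- c("annotation_set", "data.frame")
  merged
}

merge_intervals <- function(df) {
  df <- df[order(df$start_s), ]
  out <- df[1, , drop = FALSE]
  if (nrow(df) > 1) {
    for (i in 2:nrow(df)) {
      j <- nrow(out)
      if (df$start_s[i] <= out$stop_s[j]) {
        out$stop_s[j] <- max(out$stop_s[j], df$stop_s[i])
      } else {
        out <- rbind(out, df[i, , drop = FALSE])
      }
    }
  }
  out
}

# Column-name aliases accepted from BORIS-style CSV exports.
BORIS_ALIASES <- list(
  behavior = c("behavior", "Behavior", "behaviour", "Behaviour"),
  start_s = c("start_s", "start", "Start", "Start..s.", "Start (s)"),
  stop_s = c("stop_s", "stop", "Stop", "Stop..s.", "Stop (s)")
)

#' Read behavior events from a BORIS-style CSV export
#'
#' Expects columns naming the behavior and its start/stop times in seconds
#' (several common header spellings are accepted; extra columns are ignored).
#' Events are validated and merged via [behavior_events()].
#'
#' @param file path to the CSV export.
#' @return an `annotation_set`.
#' @export
read_behavior_events <- function(file) {
  if (!file.exists(file)) stop("annotation file does not exist: ", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = TRUE)
  pick <- function(key) {
    hit <- intersect(BORIS_ALIASES[[key]], names(df))
    if (length(hit) == 0) stop("annotation CSV lacks a '", key, "' column")
    df[[hit[1]]]
  }
  behavior_events(pick("behavior"), as.numeric(pick("start_s")),
                  as.numeric(pick("stop_s")))
}

#' Per-frame engagement index series
#'
#' Frame `t` (0-based) sits at time `t / fps`; its level is the number of
#' target behaviors with a merged event covering that time (intervals
#' closed-open) divided by 6, and its class index is that count. Event
#' timestamps are mapped to frames by rounding `start * fps` and `stop * fps`
#' to the nearest frame index.
#'
#' @param events an `annotation_set` (or anything [behavior_events()] accepts
#'   as a data frame with behavior/start_s/stop_s columns).
#' @param n_frames number of frames, at least 1.
#' @param fps frames per second, positive.
#' @return object of class `engagement_series`: list with `level` (in
#'   `{0, 1/6, ..., 1}`), `klass` (integers 0-6), `fps`.
#' @export
engagement_series <- function(events, n_frames, fps) {
  stopifnot(n_frames >= 1, fps > 0)
  count <- integer(n_frames)
  if (!is.null(events) && nrow(events) > 0) {
    if (!inherits(events, "annotation_set")) {
      events <- behavior_events(events$behavior, events$start_s, events$stop_s)
    }
    for (i in seq_len(nrow(events))) {
      i0 <- round(events$start_s[i] * fps)
      i1 <- round(events$stop_s[i] * fps)
      lo <- max(0L, i0); hi <- min(n_frames - 1L, i1 - 1L)
      if (hi >= lo) count[(lo:hi) + 1L] <- count[(lo:hi) + 1L] + 1L
    }
  }
  structure(list(level = count / 6, klass = as.integer(count), fps = fps),
            class = "engagement_series")
}

#' @export
print.engagement_series <- function(x, ...) {
  cat(sprintf("<engagement_series> %d frames @ %g fps; class counts: %s\n",
              length(x$klass), x$fps,
              paste(level_histogram(x), collapse = " ")))
  invisible(x)
}

#' @export
length.engagement_series <- function(x) length(x$klass)

#' Class histogram of an engagement series
#'
#' @param series an `engagement_series` (or a bare integer vector of classes).
#' @return named integer vector of counts for classes 0-6, summing to the
#'   series length.
#' @export
level_histogram <- function(series) {
  klass <- if (inherits(series, "engagement_series")) series$klass else series
  if (length(klass) == 0) stop("empty series")
  counts <- tabulate(klass + 1L, nbins = 7L)
  names(counts) <- 0:6
  counts
}
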