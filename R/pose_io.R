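# Keypoint stream ingestion: OpenPose-style per-frame records -> single-subject
# tracks with gap handling.

# BODY_25 indices (0-based, as emitted upstream) for the joints the pipeline uses.
BODY25 <- c(
  nose = 0L, neck = 1L,
  r_shoulder = 2L, r_elbow = 3L, r_wrist = 4L,
  l_shoulder = 5L, l_elbow = 6L, l_wrist = 7L,
  mid_hip = 8L
)

N_BODY <- 25L
N_FACE <- 70L

# 70-point face model: eye contours 36-47, outer lip 48-59, inner lip 60-67,
# pupils 68-69 (0-based).
FACE_EYE_IDS   <- 36:47
FACE_LIP_IDS   <- 48:67
FACE_PUPIL_IDS <- 68:69
FACIAL_POINT_IDS <- c(FACE_EYE_IDS, FACE_LIP_IDS, FACE_PUPIL_IDS)

#' Construct a keypoint track
#'
#' A `keypoint_track` is a single subject's time series of 2D body and face
#' keypoints. Coordinates follow image convention (origin top-left, y grows
#' downward) and are kept in raw pixels. Absent detections are encoded as
#' `conf = 0, x = y = 0`; interpolated points carry real coordinates with
#' `conf = 0`.
#'
#' @param subject_id character scalar.
#' @param fps frames per second, positive.
#' @param frame_index integer vector of original (0-based) frame indices,
#'   strictly increasing.
#' @param body numeric array `n x 25 x 3` (x, y, confidence).
#' @param face numeric array `n x 70 x 3`.
#' @param detected logical vector; `FALSE` marks frames where the subject was
#'   absent (all-zero keypoints).
#' @param gap_mask logical vector flagging frames produced by interpolation.
#' @return an object of class `keypoint_track`.
#' @export
keypoint_track <- function(subject_id, fps, frame_index, body, face,
                           detected = rep(TRUE, length(frame_index)),
                           gap_mask = rep(FALSE, length(frame_index))) {
  n <- length(frame_index)
  stopifnot(is.numeric(fps), fps > 0)
  if (any(diff(frame_index) <= 0)) {
    stop("frame_index must be strictly increasing with no duplicates")
  }
  stopifnot(identical(dim(body), c(n, N_BODY, 3L)) || all(dim(body) == c(n, N_BODY, 3)))
  stopifnot(all(dim(face) == c(n, N_FACE, 3)))
  structure(
    list(subject_id = as.character(subject_id), fps = fps,
         frame_index = as.integer(frame_index),
         body = body, face = face,
         detected = detected, gap_mask = gap_mask),
    class = "keypoint_track"
  )
}

#' @export
print.keypoint_track <- function(x, ...) {
  cat(sprintf("<keypoint_track> subject %s: %d frames @ %g fps (%d interpolated, %d segments)\n",
              x$subject_id, length(x$frame_index), x$fps,
              sum(x$gap_mask), max(track_segments(x))))
  invisible(x)
}

#' @export
length.keypoint_track <- function(x) length(x$frame_index)

#' Contiguous-segment labels for a track
#'
#' Frames belong to the same segment when their original frame indices are
#' consecutive. Long dropped-frame gaps (see [fill_gaps()]) therefore split a
#' track into segments; windowed computations never span a segment boundary.
#'
#' @param track a `keypoint_track`.
#' @return integer vector of segment ids, one per frame.
#' @export
track_segments <- function(track) {
  fi <- track$frame_index
  if (length(fi) == 0) return(integer(0))
  as.integer(cumsum(c(1L, diff(fi) != 1L)))
}

parse_frame_number <- function(path) {
  m <- regmatches(basename(path), gregexpr("[0-9]+", basename(path)))[[1]]
  if (length(m) == 0) return(NA_integer_)
  as.integer(m[length(m)])
}

person_from_vectors <- function(pose, face, frame_id) {
  if (length(pose) != N_BODY * 3L) {
    stop(sprintf("schema error at frame %s: expected %d body keypoint values, got %d",
                 frame_id, N_BODY * 3L, length(pose)))
  }
  if (length(face) != N_FACE * 3L) {
    stop(sprintf("schema error at frame %s: expected %d face keypoint values, got %d",
                 frame_id, N_FACE * 3L, length(face)))
  }
  list(body = matrix(pose, ncol = 3, byrow = TRUE),
       face = matrix(face, ncol = 3, byrow = TRUE))
}

read_frame_json <- function(path, frame_id) {
  rec <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("parse error at frame %s (%s): %s",
                                 frame_id, basename(path), conditionMessage(e)))
                  })
  people <- rec$people
  if (is.null(people)) people <- list()
  persons <- lapply(people, function(p) {
    person_from_vectors(unlist(p$pose_keypoints_2d),
                        unlist(p$face_keypoints_2d), frame_id)
  })
  list(frame_index = frame_id, people = persons)
}

#' Read an OpenPose-style keypoint stream
#'
#' Accepts either a directory of per-frame JSON files (the upstream dialect:
#' `people[*]$pose_keypoints_2d` holding 75 numbers and `face_keypoints_2d`
#' holding 210), a single JSON file holding a list of frame records, or a flat
#' CSV (`frame, person, kind, point_id, x, y, conf`). Frames may contain any
#' number of person detections, preserved in input order; original frame
#' indices are preserved (parsed from file names for directories).
#'
#' @param source path to a directory or file.
#' @param fps frames per second of the source video.
#' @return list of raw frames, each `list(frame_index, people)` where each
#'   person holds `body` (25 x 3) and `face` (70 x 3) matrices, plus an `fps`
#'   attribute.
#' @export
read_keypoint_stream <- function(source, fps = 30) {
  if (!file.exists(source)) stop("source does not exist: ", source)
  if (dir.exists(source)) {
    files <- list.files(source, pattern = "\\.json$", full.names = TRUE)
    if (length(files) == 0) stop("no .json keypoint files under ", source)
    ids <- vapply(files, parse_frame_number, integer(1))
    if (anyNA(ids)) ids <- seq_along(files) - 1L
    ord <- order(ids)
    frames <- mapply(read_frame_json, files[ord], ids[ord], SIMPLIFY = FALSE)
  } else if (grepl("\\.json$", source)) {
    recs <- jsonlite::fromJSON(source, simplifyVector = FALSE)
    frames <- lapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      fid <- if (!is.null(r$frame_index)) as.integer(r$frame_index) else i - 1L
      persons <- lapply(r$people, function(p) {
        person_from_vectors(unlist(p$pose_keypoints_2d),
                            unlist(p$face_keypoints_2d), fid)
      })
      list(frame_index = fid, people = persons)
    })
  } else {
    frames <- read_keypoint_csv(source)
  }
  names(frames) <- NULL
  attr(frames, "fps") <- fps
  frames
}

# Flat CSV alternative: one row per keypoint.
# Columns: frame, person (optional, default 0), kind ("body"/"face"), point_id,
# x, y, conf.
read_keypoint_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "kind", "point_id", "x", "y", "conf")
  if (!all(need %in% names(df))) {
    stop("keypoint CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$person)) df$person <- 0L
  lapply(split(df, df$frame)[order(unique(df$frame))], function(fd) {
    persons <- lapply(split(fd, fd$person), function(pd) {
      body <- matrix(0, N_BODY, 3)
      face <- matrix(0, N_FACE, 3)
      b <- pd[pd$kind == "body", ]
      f <- pd[pd$kind == "face", ]
      if (nrow(b) > 0 && (any(b$point_id < 0) || any(b$point_id >= N_BODY))) {
        stop(sprintf("schema error at frame %d: body point_id out of range", fd$frame[1]))
      }
      body[b$point_id + 1L, ] <- cbind(b$x, b$y, b$conf)
      face[f$point_id + 1L, ] <- cbind(f$x, f$y, f$conf)
      list(body = body, face = face)
    })
    names(persons) <- NULL
    list(frame_index = as.integer(fd$frame[1]), people = persons)
  })
}

mean_position <- function(kp) {
  ok <- kp[, 3] > 0
  if (!any(ok)) return(c(NA_real_, NA_real_))
  c(mean(kp[ok, 1]), mean(kp[ok, 2]))
}

#' Select one subject from a multi-person keypoint stream
#'
#' The upstream library's person-ID assignment is unreliable in free-moving
#' recordings, so tracking is done by positional continuity instead: the first
#' frame seeds with the candidate of largest mean body confidence, and every
#' subsequent frame picks the candidate whose mean keypoint position is nearest
#' the previously selected one. Frames with no candidates become absent markers
#' (selection resumes from the last anchor).
#'
#' @param raw_frames output of [read_keypoint_stream()].
#' @param fps frames per second; defaults to the stream's `fps` attribute.
#' @param subject_id label for the resulting track.
#' @return a `keypoint_track` with `detected = FALSE` at absent frames.
#' @export
select_subject <- function(raw_frames, fps = attr(raw_frames, "fps"),
                           subject_id = "subject") {
  if (length(raw_frames) == 0) stop("empty-track error: no frames in stream")
  if (is.null(fps)) fps <- 30
  n <- length(raw_frames)
  body <- array(0, c(n, N_BODY, 3))
  face <- array(0, c(n, N_FACE, 3))
  detected <- rep(FALSE, n)
  fi <- vapply(raw_frames, function(f) as.integer(f$frame_index), integer(1))
  anchor <- NULL
  for (i in seq_len(n)) {
    people <- raw_frames[[i]]$people
    if (length(people) == 0) next
    pick <- if (is.null(anchor)) {
      which.max(vapply(people, function(p) mean(p$body[, 3]), numeric(1)))
    } else {
      d <- vapply(people, function(p) {
        pos <- mean_position(p$body)
        if (anyNA(pos)) Inf else sum((pos - anchor)^2)
      }, numeric(1))
      which.min(d)
    }
    body[i, , ] <- people[[pick]]$body
    face[i, , ] <- people[[pick]]$face
    detected[i] <- TRUE
    pos <- mean_position(people[[pick]]$body)
    if (!anyNA(pos)) anchor <- pos
  }
  if (!any(detected)) stop("empty-track error: no person detected in any frame")
  keypoint_track(subject_id, fps, fi, body, face, detected = detected)
}

# Linear interpolation of coordinate series at missing frame indices.
interp_columns <- function(known_idx, known_vals, out_idx) {
  apply(known_vals, 2, function(v) {
    stats::approx(known_idx, v, xout = out_idx, method = "linear", rule = 1)$y
  })
}

#' Fill short detection gaps in a track
#'
#' Absent runs (undetected frames or missing frame indices) of at most
#' `max_gap_frames` frames are filled by per-coordinate linear interpolation
#' between the flanking detected frames and flagged in `gap_mask`;
#' interpolated confidences are set to 0. Longer runs are left out, splitting
#' the track into contiguous segments (see [track_segments()]). Within
#' segments, individual keypoints with `conf <= 0` (failed detections) are
#' likewise interpolated over runs of at most `max_gap_frames` interior
#' frames. The default of 15 frames is half a second at 30 fps: windowed
#' features spanning longer fabricated stretches would be meaningless.
#'
#' The operation is idempotent: filled frames count as present thereafter.
#'
#' @param track a `keypoint_track`.
#' @param max_gap_frames maximum gap length to interpolate (default 15).
#' @return a gap-filled `keypoint_track`.
#' @export
fill_gaps <- function(track, max_gap_frames = 15) {
  stopifnot(max_gap_frames >= 0)
  fi <- track$frame_index[track$detected]
  if (length(fi) == 0) stop("empty-track error: no detected frames")
  full <- seq(min(fi), max(fi))
  missing <- setdiff(full, fi)
  fill_idx <- integer(0)
  if (length(missing) > 0) {
    runs <- split(missing, cumsum(c(1L, diff(missing) != 1L)))
    fill_idx <- unlist(runs[vapply(runs, length, integer(1)) <= max_gap_frames],
                       use.names = FALSE)
  }
  out_idx <- sort(c(fi, fill_idx))
  n <- length(out_idx)
  is_fill <- out_idx %in% fill_idx

  det_body <- track$body[track$detected, , , drop = FALSE]
  det_face <- track$face[track$detected, , , drop = FALSE]
  flat <- function(a) matrix(a, nrow = dim(a)[1])
  body_m <- interp_columns(fi, flat(det_body), out_idx)
  face_m <- interp_columns(fi, flat(det_face), out_idx)
  body <- array(body_m, c(n, N_BODY, 3))
  face <- array(face_m, c(n, N_FACE, 3))
  # interpolated frames: coordinates kept, confidence zeroed
  body[is_fill, , 3] <- 0
  face[is_fill, , 3] <- 0

  gap_mask <- is_fill
  prev_mask <- track$gap_mask[track$detected]
  gap_mask[match(fi, out_idx)] <- prev_mask

  seg <- cumsum(c(1L, diff(out_idx) != 1L))
  body <- fill_point_dropouts(body, seg, max_gap_frames)
  face <- fill_point_dropouts(face, seg, max_gap_frames)

  keypoint_track(track$subject_id, track$fps, out_idx, body, face,
                 detected = rep(TRUE, n), gap_mask = gap_mask)
}

# Interpolate interior runs (<= max_gap) of per-point detection failures
# (conf <= 0 with zero coordinates) within each contiguous segment.
fill_point_dropouts <- function(arr, seg, max_gap) {
  n <- dim(arr)[1]
  for (p in seq_len(dim(arr)[2])) {
    absent <- arr[, p, 3] <= 0 & arr[, p, 1] == 0 & arr[, p, 2] == 0
    if (!any(absent) || all(absent)) next
    for (s in unique(seg)) {
      rows <- which(seg == s)
      a <- absent[rows]
      if (!any(a) || all(a)) next
      runs <- rle(a)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        if (starts[r] == 1L || ends[r] == length(rows)) next  # edge run: no anchors
        if (runs$lengths[r] > max_gap) next
        lo <- rows[starts[r] - 1L]; hi <- rows[ends[r] + 1L]
        span <- rows[starts[r]:ends[r]]
        w <- (span - lo) / (hi - lo)
        arr[span, p, 1] <- (1 - w) * arr[lo, p, 1] + w * arr[hi, p, 1]
        arr[span, p, 2] <- (1 - w) * arr[lo, p, 2] + w * arr[hi, p, 2]
        # confidence stays 0: the values are synthetic
      }
    }
  }
  arr
}

#' Optional scale normalization by inter-shoulder distance
#'
#' Coordinates are kept in raw pixels by default throughout the pipeline; this
#' helper divides all coordinates by the track-median distance between the two
#' shoulder keypoints for analyses that need scale invariance. Off by default
#' everywhere.
#'
#' @param track a `keypoint_track`.
#' @return the rescaled track.
#' @export
normalize_track <- function(track) {
  ls <- track$body[, BODY25["l_shoulder"] + 1L, 1:2, drop = FALSE]
  rs <- track$body[, BODY25["r_shoulder"] + 1L, 1:2, drop = FALSE]
  d <- sqrt(rowSums((ls - rs)[, 1, ]^2))
  s <- stats::median(d[d > 0], na.rm = TRUE)
  if (!is.finite(s) || s <= 0) stop("cannot normalize: shoulder distance undefined")
  track$body[, , 1:2] <- track$body[, , 1:2] / s
  track$face[, , 1:2] <- track$face[, , 1:2] / s
  track
}

#' Serialize a track to CSV
#'
#' One row per keypoint with full double precision, so that a write/read
#' round trip reproduces every coordinate exactly.
#'
#' @param track a `keypoint_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  n <- length(track$frame_index)
  rows <- function(arr, kind) {
    np <- dim(arr)[2]
    data.frame(
      frame = rep(track$frame_index, np),
      kind = kind,
      point_id = rep(seq_len(np) - 1L, each = n),
      x = sprintf("%.17g", as.vector(arr[, , 1])),
      y = sprintf("%.17g", as.vector(arr[, , 2])),
      conf = sprintf("%.17g", as.vector(arr[, , 3])),
      gap = rep(as.integer(track$gap_mask), np),
      stringsAsFactors = FALSE
    )
  }
  df <- rbind(rows(track$body, "body"), rows(track$face, "face"))
  df <- df[order(df$frame, df$kind != "body", df$point_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track serialized by [write_track_csv()]
#'
#' @param path CSV file.
#' @param subject_id,fps track metadata (not stored in the CSV).
#' @return a `keypoint_track`.
#' @export
read_track_csv <- function(path, subject_id = "subject", fps = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fi <- sort(unique(df$frame))
  n <- length(fi)
  build <- function(kind, np) {
    d <- df[df$kind == kind, ]
    arr <- array(0, c(n, np, 3))
    r <- match(d$frame, fi)
    idx <- cbind(r, d$point_id + 1L)
    arr[cbind(idx, 1L)] <- d$x
    arr[cbind(idx, 2L)] <- d$y
    arr[cbind(idx, 3L)] <- d$conf
    arr
  }
  b0 <- df[df$kind == "body" & df$point_id == 0, ]
  gap <- as.logical(b0$gap[match(fi, b0$frame)])
  keypoint_track(subject_id, fps, fi, build("body", N_BODY), build("face", N_FACE),
                 gap_mask = gap)
}
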