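# Synthetic cohort generator: pose tracks and behavior annotations with
# known engagement structure, so every pipeline stage is testable without
# the original recordings.
#
# Behavior events are drawn first (per-behavior alternating renewal process
# started in its stationary state); the active-behavior count at each instant
# selects the kinematic regime. Higher engagement maps to strictly larger
# arm-swing amplitude and a more raised/open posture, mirroring the premise
# that low-level movement features carry engagement signal; an engaged head
# pose (facial keypoints shifted upward) and smiling-driven lip widening give
# the facial channels independent signal. Keypoints are synthesized by 2D
# forward kinematics from smooth sinusoidal joint-angle trajectories plus
# Gaussian pixel noise, with frames dropped at a configured probability.

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions: 18 subjects (13 TD / 5 ASD),
#' 12,000 frames (~400 s) at 30 fps per subject. Per engagement class `k`
#' (0-6): arm-swing amplitude `0.02 * 2^k` rad (geometric, ratio 2, so
#' regimes are separable by construction), base shoulder abduction
#' `0.25 + 0.12 k` rad, facial jitter `1.5 * (1 + 0.1 k)` px and an upward
#' head shift of `2 k` px. All six behaviors follow a renewal process with
#' exponential on/off durations (means 20 s / 30 s, stationary activity 0.4
#' per behavior). Coordinate noise 1 px; frames dropped independently with
#' probability 0.01.
#'
#' @param n_subjects cohort size.
#' @param n_td number of typically-developing subjects; the rest are ASD.
#' @param frames frames per subject.
#' @param fps frames per second.
#' @param amplitude_rad,base_shoulder_rad,face_jitter_px,head_shift_px
#'   length-7 per-class regime vectors.
#' @param freq_hz arm-swing frequency.
#' @param smile_widen lip x-spread multiplier minus one while smiling is
#'   active.
#' @param mean_on_s,mean_off_s mean on/off durations of the behavior renewal
#'   processes (scalar or length 6).
#' @param noise_px coordinate noise standard deviation.
#' @param drop_prob per-frame drop probability.
#' @param seed master seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 18, n_td = 13, frames = 12000,
                             fps = 30,
                             amplitude_rad = 0.02 * 2^(0:6),
                             base_shoulder_rad = 0.25 + 0.12 * (0:6),
                             face_jitter_px = 1.5 * (1 + 0.1 * (0:6)),
                             head_shift_px = 2 * (0:6),
                             freq_hz = 0.6, smile_widen = 0.4,
                             mean_on_s = 20, mean_off_s = 30,
                             noise_px = 1.0, drop_prob = 0.01, seed = 1) {
  stopifnot(frames >= 1, fps > 0, n_subjects >= 1, n_td >= 0,
            n_td <= n_subjects)
  stopifnot(length(amplitude_rad) == 7, all(diff(amplitude_rad) > 0))
  structure(list(n_subjects = n_subjects, n_td = n_td, frames = frames,
                 fps = fps, amplitude_rad = amplitude_rad,
                 base_shoulder_rad = base_shoulder_rad,
                 face_jitter_px = face_jitter_px,
                 head_shift_px = head_shift_px,
                 freq_hz = freq_hz, smile_widen = smile_widen,
                 mean_on_s = rep(mean_on_s, length.out = 6),
                 mean_off_s = rep(mean_off_s, length.out = 6),
                 noise_px = noise_px, drop_prob = drop_prob, seed = seed),
            class = "synthetic_config")
}

#' Collapse all engagement regimes to identical kinematics
#'
#' Removes every class dependence from the generator (equal amplitudes and
#' postures, no head shift, no lip widening, equal jitter) while keeping the
#' event process, so generated labels carry no information about the
#' keypoints. Used for null checks: classifiers trained on such data cannot
#' beat the trivial majority-class rate.
#'
#' @param config a `synthetic_config`.
#' @return the collapsed config.
#' @export
collapse_regimes <- function(config) {
  mid <- config$amplitude_rad[4]
  config$amplitude_rad <- mid + (0:6) * 1e-9  # strictly increasing, but degenerate
  config$base_shoulder_rad <- rep(config$base_shoulder_rad[4], 7)
  config$face_jitter_px <- rep(config$face_jitter_px[1], 7)
  config$head_shift_px <- rep(0, 7)
  config$smile_widen <- 0
  config
}

# Alternating renewal process over [0, T], started in stationarity.
sample_behavior_intervals <- function(mean_on, mean_off, T) {
  if (mean_on <= 0) return(data.frame(start_s = numeric(0), stop_s = numeric(0)))
  p_on <- mean_on / (mean_on + mean_off)
  state_on <- stats::runif(1) < p_on
  t <- 0
  # stationary residual life of the initial state
  starts <- numeric(0); stops <- numeric(0)
  while (t < T) {
    dur <- stats::rexp(1, 1 / (if (state_on) mean_on else mean_off))
    if (state_on) {
      starts <- c(starts, t)
      stops <- c(stops, min(t + dur, T))
    }
    t <- t + dur
    state_on <- !state_on
  }
  data.frame(start_s = starts, stop_s = stops)
}

# Deterministic 70-point face template centred at (0, 0), pixels.
face_template <- function() {
  pts <- matrix(0, N_FACE, 2)
  pts[1:17, ] <- cbind(seq(-42, 42, length.out = 17),
                       30 + 22 * cos(seq(-1.3, 1.3, length.out = 17)))
  pts[18:22, ] <- cbind(seq(-38, -12, length.out = 5), -26)  # right brow
  pts[23:27, ] <- cbind(seq(12, 38, length.out = 5), -26)    # left brow
  pts[28:31, ] <- cbind(0, seq(-18, 4, length.out = 4))      # nose bridge
  pts[32:36, ] <- cbind(seq(-8, 8, length.out = 5), 9)       # nose base
  eye <- function(cx) cbind(cx + c(-9, -4, 4, 9, 4, -4), c(0, -4, -4, 0, 4, 4) - 14)
  pts[37:42, ] <- eye(-24)   # right eye contour (ids 36-41)
  pts[43:48, ] <- eye(24)    # left eye contour (ids 42-47)
  outer_a <- seq(0, 2 * pi, length.out = 13)[1:12]
  pts[49:60, ] <- cbind(16 * cos(outer_a), 25 + 8 * sin(outer_a))   # outer lip 48-59
  inner_a <- seq(0, 2 * pi, length.out = 9)[1:8]
  pts[61:68, ] <- cbind(10 * cos(inner_a), 25 + 4 * sin(inner_a))   # inner lip 60-67
  pts[69, ] <- c(-24, -14)   # right pupil (68)
  pts[70, ] <- c(24, -14)    # left pupil (69)
  pts
}

#' Generate one synthetic subject
#'
#' @param config a `synthetic_config`.
#' @param seed integer seed for this subject.
#' @param subject_id label for the track.
#' @return list with `track` (a `keypoint_track`, possibly with dropped
#'   frame indices), `events` (an `annotation_set`), `engagement` (the
#'   ground-truth `engagement_series` over all original frames) and `config`.
#' @export
generate_subject <- function(config, seed = config$seed, subject_id = "S01") {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$frames < 1) stop("degenerate config: zero frames")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nf <- config$frames
  fps <- config$fps
  T_s <- nf / fps

  evs <- NULL
  for (b in seq_along(TARGET_BEHAVIORS)) {
    iv <- sample_behavior_intervals(config$mean_on_s[b], config$mean_off_s[b], T_s)
    if (nrow(iv) > 0) {
      evs <- rbind(evs, data.frame(behavior = TARGET_BEHAVIORS[b], iv))
    }
  }
  events <- if (is.null(evs)) {
    structure(data.frame(behavior = character(0), start_s = numeric(0),
                         stop_s = numeric(0)),
              class = c("annotation_set", "data.frame"))
  } else behavior_events(evs$behavior, evs$start_s, evs$stop_s)
  eng <- engagement_series(events, nf, fps)
  k <- eng$klass  # regime per frame

  tt <- (seq_len(nf) - 1L) / fps
  A <- config$amplitude_rad[k + 1L]
  base_s <- config$base_shoulder_rad[k + 1L]
  w <- 2 * pi * config$freq_hz
  th_s_l <- base_s + A * sin(w * tt)
  th_s_r <- base_s + A * sin(w * tt + pi / 3)
  th_e_l <- 0.7 + 0.8 * A * sin(w * tt + pi / 4)
  th_e_r <- 0.7 + 0.8 * A * sin(w * tt + pi / 2)

  neck <- c(320, 150); midhip <- c(320, 400)
  Lu <- 85; Lf <- 75
  ls <- c(380, 160); rs <- c(260, 160)
  arm <- function(sh, th_s, th_e, sgn) {
    # upper-arm direction angle measured from the downward torso axis
    ex <- sh[1] + sgn * Lu * sin(th_s)
    ey <- sh[2] + Lu * cos(th_s)
    # forearm rotated so the interior elbow angle is th_e
    beta <- th_s + (pi - th_e)
    wx <- ex + sgn * Lf * sin(beta)
    wy <- ey + Lf * cos(beta)
    list(elbow = cbind(ex, ey), wrist = cbind(wx, wy))
  }
  la <- arm(ls, th_s_l, th_e_l, +1)
  ra <- arm(rs, th_s_r, th_e_r, -1)

  body <- array(0, c(nf, N_BODY, 3))
  put <- function(arr, id, xy) {
    arr[, id + 1L, 1] <- xy[, 1]; arr[, id + 1L, 2] <- xy[, 2]
    arr[, id + 1L, 3] <- stats::runif(nf, 0.5, 0.95)
    arr
  }
  rep_xy <- function(p) cbind(rep(p[1], nf), rep(p[2], nf))
  head_dy <- config$head_shift_px[k + 1L]
  body <- put(body, BODY25["nose"], cbind(rep(320, nf), 105 - head_dy))
  body <- put(body, BODY25["neck"], rep_xy(neck))
  body <- put(body, BODY25["mid_hip"], rep_xy(midhip))
  body <- put(body, BODY25["l_shoulder"], rep_xy(ls))
  body <- put(body, BODY25["r_shoulder"], rep_xy(rs))
  body <- put(body, BODY25["l_elbow"], la$elbow)
  body <- put(body, BODY25["r_elbow"], ra$elbow)
  body <- put(body, BODY25["l_wrist"], la$wrist)
  body <- put(body, BODY25["r_wrist"], ra$wrist)
  # lower body invisible in the recording setup: left absent (0, 0, 0)

  tmpl <- face_template()
  face <- array(0, c(nf, N_FACE, 3))
  smiling <- rep(FALSE, nf)
  sm <- events[events$behavior == "smiling", , drop = FALSE]
  for (i in seq_len(nrow(sm))) {
    lo <- max(0L, round(sm$start_s[i] * fps)); hi <- min(nf - 1L, round(sm$stop_s[i] * fps) - 1L)
    if (hi >= lo) smiling[(lo:hi) + 1L] <- TRUE
  }
  widen <- 1 + config$smile_widen * smiling
  jitter <- config$face_jitter_px[k + 1L]
  for (p in seq_len(N_FACE)) {
    sx <- if ((p - 1L) %in% FACE_LIP_IDS) widen else 1
    face[, p, 1] <- 320 + tmpl[p, 1] * sx
    face[, p, 2] <- (105 - head_dy) + tmpl[p, 2]
    face[, p, 3] <- stats::runif(nf, 0.5, 0.95)
  }
  # noise on all present coordinates (per-frame sd for the face: regime jitter)
  add_noise <- function(arr, sd_per_frame) {
    pres <- arr[, , 3] > 0
    for (d in 1:2) {
      m <- arr[, , d]
      noise <- matrix(stats::rnorm(length(m)), nrow(m)) * sd_per_frame
      m[pres] <- m[pres] + noise[pres]
      arr[, , d] <- m
    }
    arr
  }
  body <- add_noise(body, config$noise_px)
  face <- add_noise(face, jitter)

  keep <- stats::runif(nf) >= config$drop_prob
  if (!any(keep)) keep[1] <- TRUE
  track <- keypoint_track(subject_id, fps, which(keep) - 1L,
                          body[keep, , , drop = FALSE],
                          face[keep, , , drop = FALSE])
  list(track = track, events = events, engagement = eng, config = config)
}

#' Generate a synthetic cohort
#'
#' Per-subject seeds derive from the master seed; the first `n_td` subjects
#' are tagged TD, the rest ASD. Two cohorts generated from the same master
#' seed are identical.
#'
#' @param config a `synthetic_config`.
#' @return list of per-subject results (as [generate_subject()]) each with a
#'   `group` tag and `subject_id`.
#' @export
generate_cohort <- function(config) {
  lapply(seq_len(config$n_subjects), function(i) {
    sid <- sprintf("S%02d", i)
    seed_i <- (config$seed %% 20000000L) * 100L + i
    out <- generate_subject(config, seed = seed_i, subject_id = sid)
    out$subject_id <- sid
    out$group <- if (i <= config$n_td) "TD" else "ASD"
    out
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits, per subject, the same formats the ingestion functions consume: a
#' flat keypoint CSV (or per-frame JSON dialect with `format = "json"`) and
#' a BORIS-style annotation CSV, plus a cohort manifest.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created).
#' @param format `"csv"` (one keypoint file per subject) or `"json"`
#'   (one file per frame under `keypoints/`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- NULL
  for (s in cohort) {
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    if (format == "csv") {
      write_keypoints_flat_csv(s$track, file.path(sdir, "keypoints.csv"))
    } else {
      write_keypoints_json(s$track, file.path(sdir, "keypoints"))
    }
    utils::write.csv(as.data.frame(s$events)[, c("behavior", "start_s", "stop_s")],
                     file.path(sdir, "annotations.csv"), row.names = FALSE)
    manifest <- rbind(manifest,
                      data.frame(subject = s$subject_id, group = s$group,
                                 fps = s$track$fps,
                                 frames = length(s$track$frame_index),
                                 total_frames = s$config$frames))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

# Flat one-person keypoint CSV in the format read_keypoint_stream() accepts.
write_keypoints_flat_csv <- function(track, path) {
  n <- length(track$frame_index)
  rows <- function(arr, kind) {
    np <- dim(arr)[2]
    data.frame(frame = rep(track$frame_index, np),
               person = 0L, kind = kind,
               point_id = rep(seq_len(np) - 1L, each = n),
               x = sprintf("%.17g", as.vector(arr[, , 1])),
               y = sprintf("%.17g", as.vector(arr[, , 2])),
               conf = sprintf("%.17g", as.vector(arr[, , 3])),
               stringsAsFactors = FALSE)
  }
  df <- rbind(rows(track$body, "body"), rows(track$face, "face"))
  df <- df[order(df$frame, df$kind != "body", df$point_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Per-frame JSON files in the upstream dialect.
write_keypoints_json <- function(track, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(track$frame_index)) {
    rec <- list(version = 1.3, people = list(list(
      pose_keypoints_2d = as.vector(t(track$body[i, , ])),
      face_keypoints_2d = as.vector(t(track$face[i, , ]))
    )))
    jsonlite::write_json(rec, file.path(dir, sprintf("frame_%012d_keypoints.json",
                                                     track$frame_index[i])),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
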