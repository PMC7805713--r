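# Laban Movement Analysis effort features (space, weight, time) from
# upper-body keypoints.
#
# Space is the summed area of the two triangles spanned by the shoulder/hand
# vectors; weight is a torque-like magnitude sum(L^2 w^2 sin(theta) * mass)
# over the shoulder and elbow joints; time is the summed magnitude of angular
# acceleration over the same joints. "Hand" keypoints are the BODY_25 wrists
# (indices 4 and 7): the recording setup has no reliable finger tracking.

LABAN_JOINTS <- c("left_shoulder", "right_shoulder", "left_elbow", "right_elbow")

kp_present <- function(row) row[3] > 0 || !(row[1] == 0 && row[2] == 0)

get_kp <- function(body, name, what) {
  row <- body[BODY25[name] + 1L, ]
  if (!kp_present(row)) stop("missing keypoint: ", what)
  row[1:2]
}

vec_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(max(-1, min(1, sum(u * v) / (nu * nv))))
}

#' Arm geometry of a single pose frame
#'
#' Computes the four position vectors between shoulders and hands and the two
#' angles used by the space effort feature: `a` left shoulder to left hand,
#' `b` right shoulder to left shoulder, `c` right hand to right shoulder,
#' `d` left hand to right hand; `theta1` is the angle between `a` and `d`,
#' `theta2` between `c` and `b` (radians in `[0, pi]`). A zero-length operand
#' makes the corresponding angle `NA` and flags the geometry degenerate.
#'
#' @param frame either a 25 x 3 body keypoint matrix or a list with a `body`
#'   element.
#' @return list with `a`, `b`, `c`, `d`, `theta1`, `theta2`, `degenerate`.
#' @export
arm_geometry <- function(frame) {
  body <- if (is.list(frame)) frame$body else frame
  ls <- get_kp(body, "l_shoulder", "left_shoulder")
  rs <- get_kp(body, "r_shoulder", "right_shoulder")
  lh <- get_kp(body, "l_wrist", "left_hand")
  rh <- get_kp(body, "r_wrist", "right_hand")
  a <- lh - ls
  b <- ls - rs
  cc <- rs - rh
  d <- rh - lh
  t1 <- vec_angle(a, d)
  t2 <- vec_angle(cc, b)
  list(a = a, b = b, c = cc, d = d, theta1 = t1, theta2 = t2,
       degenerate = is.na(t1) || is.na(t2))
}

#' Space effort of a single frame
#'
#' `0.5 |a||d| sin(theta1) + 0.5 |c||b| sin(theta2)`: the summed area (pixels
#' squared) of triangles (left shoulder, left hand, right hand) and (right
#' hand, right shoulder, left shoulder), i.e. the planar extent of the arm
#' configuration. Degenerate terms contribute 0.
#'
#' @inheritParams arm_geometry
#' @return non-negative number.
#' @export
laban_space <- function(frame) {
  g <- arm_geometry(frame)
  tri <- function(u, v, th) {
    if (is.na(th)) return(0)
    0.5 * sqrt(sum(u^2)) * sqrt(sum(v^2)) * sin(th)
  }
  tri(g$a, g$d, g$theta1) + tri(g$c, g$b, g$theta2)
}

# Vectorized space over all frames of a track; NA where keypoints are absent.
# 0.5|a||d|sin(theta) equals half the cross-product magnitude, so no acos.
space_series <- function(track) {
  xy <- function(name, k) track$body[, BODY25[name] + 1L, k]
  pres <- function(name) {
    track$body[, BODY25[name] + 1L, 3] > 0 |
      xy(name, 1) != 0 | xy(name, 2) != 0
  }
  ok <- pres("l_shoulder") & pres("r_shoulder") & pres("l_wrist") & pres("r_wrist")
  ax <- xy("l_wrist", 1) - xy("l_shoulder", 1); ay <- xy("l_wrist", 2) - xy("l_shoulder", 2)
  dx <- xy("r_wrist", 1) - xy("l_wrist", 1);    dy <- xy("r_wrist", 2) - xy("l_wrist", 2)
  cx <- xy("r_shoulder", 1) - xy("r_wrist", 1); cy <- xy("r_shoulder", 2) - xy("r_wrist", 2)
  bx <- xy("l_shoulder", 1) - xy("r_shoulder", 1); by <- xy("l_shoulder", 2) - xy("r_shoulder", 2)
  s <- 0.5 * abs(ax * dy - ay * dx) + 0.5 * abs(cx * by - cy * bx)
  s[!ok] <- NA_real_
  s
}

# Phase-unwrap an angle series (jumps > pi folded back).
unwrap_angle <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  adj <- -2 * pi * round(d / (2 * pi))
  theta + c(0, cumsum(adj + d)) - c(0, cumsum(d))
}

# Central differences scaled by fps, one-sided at segment endpoints.
fd_derivative <- function(x, fps) {
  n <- length(x)
  if (n < 2) return(rep(NA_real_, n))
  d <- numeric(n)
  if (n >= 3) {
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fps / 2
  }
  d[1] <- (x[2] - x[1]) * fps
  d[n] <- (x[n] - x[n - 1]) * fps
  d
}

joint_theta_L <- function(track, joint_id) {
  xy <- function(name) track$body[, BODY25[name] + 1L, 1:2, drop = FALSE][, 1, ]
  side <- if (grepl("^left", joint_id)) "l" else "r"
  sh <- xy(paste0(side, "_shoulder"))
  el <- xy(paste0(side, "_elbow"))
  if (grepl("shoulder$", joint_id)) {
    torso <- xy("mid_hip") - xy("neck")
    arm <- el - sh
    u <- torso; v <- arm
    L <- sqrt(rowSums(arm^2))
  } else {
    wr <- xy(paste0(side, "_wrist"))
    u <- sh - el; v <- wr - el
    L <- sqrt(rowSums((wr - el)^2))
  }
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  cth <- rowSums(u * v) / (nu * nv)
  theta <- acos(pmax(-1, pmin(1, cth)))
  theta[nu == 0 | nv == 0] <- NA_real_
  list(theta = theta, L = L)
}

#' Joint angle kinematics of a track
#'
#' Per-frame joint angle `theta`, angular velocity `omega` and angular
#' acceleration `omega_dot` for one of the four upper-body joints. The elbow
#' angle is the interior angle between upper-arm and forearm vectors; the
#' shoulder angle is between the torso vector (neck to mid-hip) and the
#' upper-arm vector (shoulder to elbow). Derivatives are central differences
#' scaled by the track fps (one-sided at segment endpoints) on the unwrapped
#' angle series, computed independently per contiguous segment. `L` is the
#' driven segment length in pixels (upper arm for shoulders, forearm for
#' elbows); `mass` defaults to 1 (no per-joint masses are defined for the
#' keypoint skeleton).
#'
#' @param track a `keypoint_track`.
#' @param joint_id one of `"left_shoulder"`, `"right_shoulder"`,
#'   `"left_elbow"`, `"right_elbow"`.
#' @param mass dimensionless weight factor.
#' @return object of class `joint_kinematics`: list with `joint_id`, `theta`,
#'   `omega`, `omega_dot`, `L`, `mass`, aligned with the track's frames.
#' @export
joint_kinematics <- function(track, joint_id, mass = 1) {
  joint_id <- match.arg(joint_id, LABAN_JOINTS)
  n <- length(track$frame_index)
  if (n < 3) stop("too-short error: need at least 3 frames, got ", n)
  tl <- joint_theta_L(track, joint_id)
  omega <- rep(NA_real_, n)
  omega_dot <- rep(NA_real_, n)
  seg <- track_segments(track)
  for (s in unique(seg)) {
    i <- which(seg == s)
    if (length(i) < 3) next  # too short to differentiate; stays NA
    th <- unwrap_angle(tl$theta[i])
    om <- fd_derivative(th, track$fps)
    omega[i] <- om
    omega_dot[i] <- fd_derivative(om, track$fps)
  }
  structure(list(joint_id = joint_id, theta = tl$theta, omega = omega,
                 omega_dot = omega_dot, L = tl$L, mass = mass),
            class = "joint_kinematics")
}

#' Weight effort at a frame
#'
#' `sum_i L_i^2 omega_i^2 sin(theta_i) * mass_i` over the supplied joints,
#' evaluated at one frame: a torque-like magnitude of movement power
#' (pixels^2 rad^2 / s^2). Each summand is a product of squares and
#' `sin(theta)` with `theta` in `[0, pi]`, so weight is non-negative.
#'
#' @param kinematics list of `joint_kinematics`.
#' @param frame 1-based frame position within the track.
#' @return non-negative number.
#' @export
laban_weight <- function(kinematics, frame) {
  sum(vapply(kinematics, function(k) {
    k$L[frame]^2 * k$omega[frame]^2 * sin(k$theta[frame]) * k$mass
  }, numeric(1)))
}

#' Time effort at a frame
#'
#' Movement urgency: by default the sum over joints of the magnitude of
#' angular acceleration `|omega_dot_i|` (rad/s^2). The classical formulation
#' is ambiguous about whether velocities or accelerations are summed;
#' accelerations are the default (a constant-speed movement carries no
#' urgency) and `mode = "velocity"` gives the alternative.
#'
#' @inheritParams laban_weight
#' @param mode `"acceleration"` (default) or `"velocity"`.
#' @return non-negative number.
#' @export
laban_time <- function(kinematics, frame, mode = c("acceleration", "velocity")) {
  mode <- match.arg(mode)
  sum(vapply(kinematics, function(k) {
    v <- if (mode == "acceleration") k$omega_dot[frame] else k$omega[frame]
    abs(v)
  }, numeric(1)))
}

# Trailing moving mean with partial windows at segment starts, NA-tolerant.
trailing_mean <- function(x, w) {
  n <- length(x)
  v <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cv <- cumsum(v); cc <- cumsum(cnt)
  lag <- function(cs) if (n <= w) rep(0, n) else c(rep(0, w), cs[seq_len(n - w)])
  sums <- cv - lag(cv)
  ns <- cc - lag(cc)
  out <- sums / ns
  out[ns == 0] <- NA_real_
  out
}

#' Laban effort series over a track
#'
#' Computes instantaneous space, weight and time per frame, then aggregates
#' each with a trailing moving mean of `window_frames` frames (1 s at 30 fps
#' by default), stride 1, within contiguous segments. The first
#' `window_frames - 1` frames of each segment carry the mean of the frames
#' available so far. Frames with missing keypoints yield `NA` instantaneous
#' values and are excluded from the window means.
#'
#' @param track a `keypoint_track` (gap-filled; see [fill_gaps()]).
#' @param window_frames moving-window length in frames, at least 1.
#' @param joints joints entering weight and time; default both shoulders and
#'   both elbows, the upper-body joints with well-defined angles.
#' @param time_mode passed to [laban_time()].
#' @return object of class `laban_series`: data frame with `frame_index`,
#'   `space`, `weight`, `time` plus a `window_frames` attribute; rows align
#'   with the track's frames.
#' @export
laban_series <- function(track, window_frames = 30, joints = LABAN_JOINTS,
                         time_mode = c("acceleration", "velocity")) {
  time_mode <- match.arg(time_mode)
  stopifnot(window_frames >= 1)
  n <- length(track$frame_index)
  if (n < 3) stop("too-short error: need at least 3 frames, got ", n)

  sp <- space_series(track)
  kins <- lapply(joints, function(j) joint_kinematics(track, j))
  wt <- rep(0, n); tm <- rep(0, n)
  for (k in kins) {
    wt <- wt + k$L^2 * k$omega^2 * sin(k$theta) * k$mass
    v <- if (time_mode == "acceleration") k$omega_dot else k$omega
    tm <- tm + abs(v)
  }

  seg <- track_segments(track)
  agg <- function(x) {
    out <- rep(NA_real_, n)
    for (s in unique(seg)) {
      i <- which(seg == s)
      out[i] <- trailing_mean(x[i], window_frames)
    }
    out
  }
  structure(
    data.frame(frame_index = track$frame_index,
               space = agg(sp), weight = agg(wt), time = agg(tm)),
    window_frames = window_frames,
    class = c("laban_series", "data.frame")
  )
}

#' Export a Laban series as CSV
#' @param x a `laban_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_laban_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("frame_index", "space", "weight", "time")],
                   path, row.names = FALSE)
  invisible(path)
}
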