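# Independent oracles and small fixture builders used across the suite.

# Shoelace area of a polygon given as an n x 2 matrix of vertices in order.
shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Build a 25 x 3 body keypoint matrix from named (x, y) positions; all other
# points absent. Confidence 0.9 for the provided points.
make_body <- function(...) {
  pts <- list(...)
  body <- matrix(0, 25, 3)
  ids <- c(nose = 0, neck = 1, r_shoulder = 2, r_elbow = 3, r_wrist = 4,
           l_shoulder = 5, l_elbow = 6, l_wrist = 7, mid_hip = 8)
  for (nm in names(pts)) {
    body[ids[[nm]] + 1, ] <- c(pts[[nm]], 0.9)
  }
  body
}

# Track whose frames are generated by a function frame_fn(i) -> 25 x 3 body
# matrix; face points all at a fixed template with conf 0.9.
make_track <- function(n, frame_fn, fps = 30, frame_index = seq_len(n) - 1L) {
  body <- array(0, c(n, 25, 3))
  face <- array(0, c(n, 70, 3))
  for (i in seq_len(n)) body[i, , ] <- frame_fn(i)
  face[, , 1] <- matrix(rep(300 + seq_len(70), each = n), n)
  face[, , 2] <- matrix(rep(100 + seq_len(70), each = n), n)
  face[, , 3] <- 0.9
  keypoint_track("test", fps, frame_index, body, face)
}

# Track that realises a prescribed left-shoulder joint angle series theta(i):
# vertical torso, elbow placed by forward kinematics, wrists present so that
# space() is defined.
make_angle_track <- function(theta, fps = 30) {
  make_track(length(theta), function(i) {
    th <- theta[i]
    sh <- c(380, 160)
    el <- sh + 85 * c(sin(th), cos(th))
    make_body(neck = c(320, 150), mid_hip = c(320, 400),
              l_shoulder = sh, r_shoulder = c(260, 160),
              l_elbow = el, l_wrist = el + c(0, 75),
              r_elbow = c(260, 245), r_wrist = c(260, 320))
  }, fps = fps)
}

# Unit-square arm configuration (space = s^2). Shifted off the origin (a
# coordinate at exactly (0, 0) encodes an absent detection) and with elbows
# on the shoulder-wrist segments so joint kinematics are defined.
square_body <- function(s = 1, offset = c(50, 50)) {
  ls <- s * c(0, 1) + offset; rs <- s * c(1, 1) + offset
  lw <- s * c(0, 0) + offset; rw <- s * c(1, 0) + offset
  make_body(l_shoulder = ls, r_shoulder = rs, l_wrist = lw, r_wrist = rw,
            l_elbow = (ls + lw) / 2, r_elbow = (rs + rw) / 2,
            neck = c(320, 150), mid_hip = c(320, 400))
}

# Minimal joint_kinematics stand-in for direct weight/time evaluation.
make_kin <- function(theta, omega, omega_dot, L, mass = 1) {
  structure(list(joint_id = "left_shoulder", theta = theta, omega = omega,
                 omega_dot = omega_dot, L = L, mass = mass),
            class = "joint_kinematics")
}

# Brute-force confusion-matrix reference for the weighted metrics.
reference_weighted_metrics <- function(y_true, y_pred) {
  acc_n <- 0
  f1_sum <- 0
  n <- length(y_true)
  for (k in 0:6) {
    support <- sum(y_true == k)
    if (support == 0) next
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    f1_sum <- f1_sum + f1 * support
    acc_n <- acc_n + tp
  }
  list(accuracy = acc_n / n, f1 = f1_sum / n)
}

# Quick separable windowed dataset with unit-scale features: class k windows
# have mean k in every channel plus small noise.
tiny_dataset <- function(n = 210, seq_len = 5, n_features = 71, classes = 0:6,
                         noise = 0.1, seed = 42, subject_id = "toy") {
  set.seed(seed)
  y <- rep(classes, length.out = n)
  x <- array(stats::rnorm(n * seq_len * n_features, sd = noise),
             c(n, seq_len, n_features))
  for (i in seq_len(n)) x[i, , ] <- x[i, , ] + y[i]
  windowed_dataset(x, y, subject_id = subject_id)
}

# Tiny end-to-end synthetic subject -> windowed dataset.
pipeline_dataset <- function(frames = 1200, seed = 11, config = NULL,
                             subject_id = "P", group = "TD") {
  if (is.null(config)) config <- synthetic_config(frames = frames, seed = seed)
  s <- generate_subject(config, seed = seed, subject_id = subject_id)
  tr <- fill_gaps(s$track, 15)
  fm <- assemble_features(facial_features(tr), laban_series(tr))
  make_windows(fm, s$engagement, subject_id = subject_id, group = group)
}
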