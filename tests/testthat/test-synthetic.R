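# Synthetic cohort generator: determinism, ground-truth structure,
# closed-form recovery, and round-tripping through the readers.

test_that("generation is seed-deterministic", {
  cfg <- synthetic_config(frames = 300, seed = 1)
  a <- generate_subject(cfg, seed = 99)
  b <- generate_subject(cfg, seed = 99)
  expect_identical(a$track$body, b$track$body)
  expect_identical(a$track$face, b$track$face)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  c <- generate_subject(cfg, seed = 100)
  expect_false(identical(a$track$body, c$track$body))
})

test_that("zero event rates give an all-zero engagement series and lowest-regime motion", {
  cfg <- synthetic_config(frames = 300, mean_on_s = 0, drop_prob = 0,
                          noise_px = 0, seed = 2)
  s <- generate_subject(cfg, seed = 2)
  expect_equal(nrow(s$events), 0)
  expect_equal(s$engagement$klass, rep(0L, 300))
  # arm swing bounded by the class-0 amplitude
  tr <- s$track
  kin <- joint_kinematics(tr, "left_shoulder")
  th <- kin$theta[!is.na(kin$theta)]
  expect_lt(max(th) - min(th), 2 * cfg$amplitude_rad[1] + 1e-6)
})

test_that("noiseless single-regime tracks recover the closed-form Laban features", {
  cfg <- synthetic_config(frames = 240, noise_px = 0, drop_prob = 0,
                          mean_on_s = 0, seed = 3,
                          amplitude_rad = 0.15 + (0:6) * 1e-6,
                          base_shoulder_rad = rep(0.6, 7),
                          head_shift_px = rep(0, 7))
  s <- generate_subject(cfg, seed = 3)
  tr <- s$track
  fps <- cfg$fps
  t <- tr$frame_index / fps
  A <- cfg$amplitude_rad[1]; w <- 2 * pi * cfg$freq_hz
  # left shoulder: theta = 0.6 + A sin(w t) by construction
  kin <- joint_kinematics(tr, "left_shoulder")
  interior <- 3:(length(t) - 2)
  expect_lt(max(abs(kin$theta - (0.6 + A * sin(w * t)))), 1e-9)
  dt <- 1 / fps
  tol_w <- A * w^3 * dt^2 / 6 * 2
  expect_lt(max(abs(kin$omega[interior] - A * w * cos(w * t[interior]))), tol_w)
  tol_a <- A * w^4 * dt^2 * 2
  expect_lt(max(abs(kin$omega_dot[interior] + A * w^2 * sin(w * t[interior]))), tol_a)
  # upper-arm length is the generator's constant
  expect_equal(unname(kin$L[1]), 85, tolerance = 1e-9)
})

test_that("label histograms match the renewal process's stationary expectation", {
  cfg <- synthetic_config(frames = 9000, mean_on_s = 20, mean_off_s = 30,
                          drop_prob = 0, seed = 4)
  s <- generate_subject(cfg, seed = 4)
  p <- 20 / 50  # stationary activity per behavior
  mean_count <- mean(s$engagement$klass)
  # effective sample size: one draw per behavior cycle
  T_s <- cfg$frames / cfg$fps
  n_eff <- 6 * T_s / (cfg$mean_on_s[1] + cfg$mean_off_s[1])
  se <- sqrt(6 * p * (1 - p) / n_eff)
  expect_lt(abs(mean_count - 6 * p), 3 * se)
})

test_that("cohorts carry the 13 TD / 5 ASD structure and derive per-subject seeds", {
  cfg <- synthetic_config(n_subjects = 18, n_td = 13, frames = 60, seed = 6)
  coh <- generate_cohort(cfg)
  expect_length(coh, 18)
  groups <- vapply(coh, `[[`, character(1), "group")
  expect_equal(sum(groups == "TD"), 13)
  expect_equal(sum(groups == "ASD"), 5)
  expect_equal(vapply(coh, `[[`, character(1), "subject_id"),
               sprintf("S%02d", 1:18))
  coh2 <- generate_cohort(cfg)
  expect_identical(coh[[7]]$track$body, coh2[[7]]$track$body)
  one <- generate_cohort(synthetic_config(n_subjects = 1, n_td = 1, frames = 60, seed = 6))
  expect_length(one, 1)
})

test_that("written cohorts round-trip through the keypoint and annotation readers", {
  cfg <- synthetic_config(n_subjects = 1, n_td = 1, frames = 50, seed = 8,
                          drop_prob = 0.05)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir, format = "csv")
  s <- coh[[1]]
  frames <- read_keypoint_stream(file.path(dir, "S01", "keypoints.csv"), fps = 30)
  tr <- select_subject(frames, fps = 30, subject_id = "S01")
  expect_equal(tr$frame_index, s$track$frame_index)
  expect_equal(tr$body, s$track$body)
  ev <- read_behavior_events(file.path(dir, "S01", "annotations.csv"))
  expect_equal(as.data.frame(ev), as.data.frame(s$events))

  # JSON dialect round-trips too (small frame count: one file per frame)
  cfg2 <- synthetic_config(n_subjects = 1, n_td = 1, frames = 8, seed = 9,
                           drop_prob = 0)
  coh2 <- generate_cohort(cfg2)
  dir2 <- withr::local_tempdir()
  write_cohort(coh2, dir2, format = "json")
  fr2 <- read_keypoint_stream(file.path(dir2, "S01", "keypoints"), fps = 30)
  tr2 <- select_subject(fr2, fps = 30)
  expect_equal(tr2$body, coh2[[1]]$track$body, tolerance = 1e-12)
})

test_that("collapsed regimes remove every class dependence from the kinematics", {
  cfg <- collapse_regimes(synthetic_config(frames = 100, seed = 10))
  expect_lt(diff(range(cfg$amplitude_rad)), 1e-6)
  expect_equal(length(unique(cfg$base_shoulder_rad)), 1)
  expect_equal(cfg$head_shift_px, rep(0, 7))
  expect_equal(cfg$smile_widen, 0)
  s <- generate_subject(cfg, seed = 10)
  expect_s3_class(s$track, "keypoint_track")
})

test_that("smiling widens the synthetic lip spread", {
  n <- 3000
  cfg <- synthetic_config(frames = n, noise_px = 0, drop_prob = 0, seed = 12,
                          head_shift_px = rep(0, 7),
                          face_jitter_px = rep(0, 7) + 1e-9)
  s <- generate_subject(cfg, seed = 12)
  smiling <- rep(FALSE, n)
  sm <- s$events[s$events$behavior == "smiling", ]
  for (i in seq_len(nrow(sm))) {
    lo <- max(0, round(sm$start_s[i] * 30)); hi <- min(n - 1, round(sm$stop_s[i] * 30) - 1)
    if (hi >= lo) smiling[(lo:hi) + 1] <- TRUE
  }
  expect_gt(sum(smiling), 10)     # the fixed seed yields both phases
  expect_gt(sum(!smiling), 10)
  lip_x <- s$track$face[, 49:60, 1]  # outer lip ids 48-59
  spread <- apply(lip_x, 1, function(r) diff(range(r)))
  expect_gt(mean(spread[smiling]), mean(spread[!smiling]) * 1.2)
})
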