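# Keypoint stream ingestion, subject tracking and gap filling.

write_json_frame <- function(dir, idx, people) {
  rec <- list(version = 1.3, people = people)
  jsonlite::write_json(rec, file.path(dir, sprintf("v_%012d_keypoints.json", idx)),
                       auto_unbox = TRUE, digits = NA)
}

json_person <- function(x0 = 100, y0 = 100, conf = 0.9, n_body = 25) {
  list(pose_keypoints_2d = as.vector(t(cbind(x0 + seq_len(n_body),
                                             y0 + seq_len(n_body),
                                             rep(conf, n_body)))),
       face_keypoints_2d = as.vector(t(cbind(x0 + seq_len(70),
                                             y0 + 50 + seq_len(70),
                                             rep(conf, 70)))))
}

test_that("JSON stream reading preserves frames, people and empty records", {
  dir <- withr::local_tempdir()
  write_json_frame(dir, 0, list(json_person(100, 100)))
  write_json_frame(dir, 1, list(json_person(100, 100), json_person(500, 500)))
  write_json_frame(dir, 2, list())
  frames <- read_keypoint_stream(dir, fps = 30)
  expect_length(frames, 3)
  expect_equal(vapply(frames, `[[`, integer(1), "frame_index"), 0:2)
  expect_equal(vapply(frames, function(f) length(f$people), integer(1)),
               c(1L, 2L, 0L))
  expect_equal(dim(frames[[1]]$people[[1]]$body), c(25, 3))
  expect_equal(dim(frames[[1]]$people[[1]]$face), c(70, 3))
})

test_that("records with wrong keypoint counts raise a schema error naming the frame", {
  dir <- withr::local_tempdir()
  write_json_frame(dir, 0, list(json_person()))
  write_json_frame(dir, 7, list(json_person(n_body = 24)))
  expect_error(read_keypoint_stream(dir), "schema error at frame 7")
})

test_that("track CSV serialization round-trips coordinates exactly", {
  set.seed(1)
  tr <- make_track(12, function(i) {
    b <- make_body(neck = c(320, 150), mid_hip = c(320, 400),
                   l_shoulder = runif(2, 0, 640), r_shoulder = runif(2, 0, 640),
                   l_wrist = runif(2, 0, 640), r_wrist = runif(2, 0, 640))
    b
  })
  tr$gap_mask[3] <- TRUE
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tr, path)
  back <- read_track_csv(path, subject_id = tr$subject_id, fps = tr$fps)
  expect_identical(back$body, tr$body)
  expect_identical(back$face, tr$face)
  expect_identical(back$frame_index, tr$frame_index)
  expect_identical(back$gap_mask, tr$gap_mask)
})

parsed_person <- function(x0 = 100, y0 = 100, conf = 0.9) {
  list(body = cbind(x0 + seq_len(25), y0 + seq_len(25), rep(conf, 25)),
       face = cbind(x0 + seq_len(70), y0 + 50 + seq_len(70), rep(conf, 70)))
}

test_that("subject selection follows positional continuity", {
  near <- parsed_person(100, 100, conf = 0.9)
  far <- parsed_person(500, 500, conf = 0.5)
  frames <- lapply(0:4, function(i) list(frame_index = i, people = list(near, far)))
  attr(frames, "fps") <- 30
  tr <- select_subject(frames)
  # seed = highest-confidence candidate; then nearest-neighbour throughout
  expect_true(all(tr$detected))
  for (i in 1:5) {
    expect_equal(tr$body[i, 1, 1], 100 + 1)  # the (100,100) person's first point
  }
  # swapping input order must not change the winner once seeded
  frames2 <- lapply(0:4, function(i) list(frame_index = i, people = list(far, near)))
  attr(frames2, "fps") <- 30
  tr2 <- select_subject(frames2)
  expect_equal(tr2$body[3, , ], tr$body[3, , ])
})

test_that("single-person streams pass through unchanged and absences are marked", {
  p <- parsed_person(200, 120)
  frames <- lapply(0:3, function(i) {
    list(frame_index = i, people = if (i == 2) list() else list(p))
  })
  attr(frames, "fps") <- 30
  tr <- select_subject(frames)
  expect_equal(tr$detected, c(TRUE, TRUE, FALSE, TRUE))
  ref <- unname(p$body)
  expect_equal(tr$body[1, , ], ref)
  expect_equal(tr$body[4, , ], ref)  # selection resumed after the absence
  expect_error(select_subject(list()), "empty-track")
})

test_that("short gaps are linearly interpolated and flagged, long gaps split", {
  mk <- function(x) make_body(neck = c(320, 150), mid_hip = c(320, 400),
                              l_shoulder = c(x, 160), r_shoulder = c(260, 160),
                              l_wrist = c(x, 320), r_wrist = c(260, 320))
  # frames 0,1,3,4 present; frame 2 missing (within max_gap)
  tr <- make_track(4, function(i) mk(c(10, 10, 20, 20)[i]),
                   frame_index = c(0L, 1L, 3L, 4L))
  filled <- fill_gaps(tr, max_gap_frames = 15)
  expect_equal(filled$frame_index, 0:4)
  expect_equal(filled$gap_mask, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(filled$body[3, 6, 1], 15)           # midpoint of 10 and 20
  expect_equal(filled$body[3, 6, 3], 0)            # interpolated conf zeroed
  expect_equal(max(track_segments(filled)), 1)

  # gap of max_gap + 1 -> split, no fabricated frames
  tr2 <- make_track(6, function(i) mk(10), frame_index = c(0:2, 6:8))
  split2 <- fill_gaps(tr2, max_gap_frames = 2)
  expect_equal(length(split2$frame_index), 6)      # detected frames preserved
  expect_equal(max(track_segments(split2)), 2)
})

test_that("fill_gaps is idempotent and identity on gap-free tracks", {
  tr <- make_track(10, function(i) {
    make_body(neck = c(320, 150), mid_hip = c(320, 400),
              l_shoulder = c(380, 160), r_shoulder = c(260, 160),
              l_wrist = c(380 + i, 320), r_wrist = c(260, 320))
  })
  once <- fill_gaps(tr, 15)
  expect_equal(once$body, tr$body)
  expect_false(any(once$gap_mask))
  twice <- fill_gaps(once, 15)
  expect_equal(twice$body, once$body)
  expect_equal(twice$gap_mask, once$gap_mask)
  # idempotence with an actual gap
  trg <- make_track(5, function(i) {
    make_body(neck = c(320, 150), mid_hip = c(320, 400),
              l_shoulder = c(380, 160), r_shoulder = c(260, 160),
              l_wrist = c(300 + 10 * i, 320), r_wrist = c(260, 320))
  }, frame_index = c(0L, 1L, 2L, 4L, 5L))
  f1 <- fill_gaps(trg, 15)
  f2 <- fill_gaps(f1, 15)
  expect_equal(f2$body, f1$body)
  expect_equal(f2$gap_mask, f1$gap_mask)
})

test_that("per-point detection dropouts are interpolated within segments", {
  tr <- make_track(7, function(i) {
    b <- make_body(neck = c(320, 150), mid_hip = c(320, 400),
                   l_shoulder = c(380, 160), r_shoulder = c(260, 160),
                   l_wrist = c(300 + 10 * i, 320), r_wrist = c(260, 320))
    if (i == 4) b[8, ] <- 0  # left wrist lost in frame 4
    b
  })
  filled <- fill_gaps(tr, 15)
  expect_equal(filled$body[4, 8, 1], mean(c(330, 350)))
  expect_equal(filled$body[4, 8, 3], 0)
})

test_that("flat CSV streams parse to the same frames as JSON", {
  cfg <- synthetic_config(frames = 40, drop_prob = 0, seed = 5)
  s <- generate_subject(cfg, seed = 5)
  dir <- withr::local_tempdir()
  lmaengage:::write_keypoints_flat_csv(s$track, file.path(dir, "kp.csv"))
  frames <- read_keypoint_stream(file.path(dir, "kp.csv"), fps = 30)
  tr <- select_subject(frames, fps = 30)
  expect_equal(tr$body, s$track$body)
  expect_equal(tr$face, s$track$face)
})
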