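# Laban effort features: geometry, kinematics, windowed series.

test_that("arm geometry reproduces dot-product angles and flags degeneracies", {
  g <- arm_geometry(square_body())
  expect_equal(g$theta1, pi / 2)
  expect_equal(g$theta2, pi / 2)
  expect_false(g$degenerate)

  all_same <- make_body(l_shoulder = c(5, 5), r_shoulder = c(5, 5),
                        l_wrist = c(5, 5), r_wrist = c(5, 5))
  gd <- arm_geometry(all_same)
  expect_true(gd$degenerate)

  # left hand at left shoulder: a = 0 so theta1 undefined, theta2 still fine
  part <- make_body(l_shoulder = c(0, 1), r_shoulder = c(1, 1),
                    l_wrist = c(0, 1), r_wrist = c(1, 0))
  gp <- arm_geometry(part)
  expect_true(is.na(gp$theta1))
  expect_false(is.na(gp$theta2))
  expect_true(gp$degenerate)

  b <- square_body(); b[6, ] <- 0
  expect_error(arm_geometry(b), "missing keypoint: left_shoulder")
})

test_that("space equals the quadrilateral shoelace area and scales quadratically", {
  expect_equal(laban_space(square_body()), 1.0)
  expect_equal(laban_space(square_body(2)), 4.0)
  # collinear points span no area
  col <- make_body(l_shoulder = c(0, 0), r_shoulder = c(3, 0),
                   l_wrist = c(1, 0), r_wrist = c(2, 0))
  expect_equal(laban_space(col), 0.0)
})

test_that("space matches the shoelace oracle on 1000 random convex arm configurations", {
  set.seed(202)
  worst <- 0
  for (i in 1:1000) {
    # random convex quadrilateral: points on a random ellipse, in cyclic order
    ang <- sort(runif(4, 0, 2 * pi))
    cx <- runif(1, -100, 100); cy <- runif(1, -100, 100)
    rx <- runif(1, 1, 50); ry <- runif(1, 1, 50)
    rot <- runif(1, 0, 2 * pi)
    pts <- cbind(rx * cos(ang), ry * sin(ang)) %*%
      matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2) +
      matrix(c(cx, cy), 4, 2, byrow = TRUE)
    # cycle LS -> LH -> RH -> RS
    body <- make_body(l_shoulder = pts[1, ], l_wrist = pts[2, ],
                      r_wrist = pts[3, ], r_shoulder = pts[4, ])
    a <- laban_space(body)
    b <- shoelace_area(pts)
    worst <- max(worst, abs(a - b) / max(b, .Machine$double.eps))
  }
  expect_lt(worst, 1e-9)
})

test_that("space is rigid-motion invariant and scales as s^2", {
  set.seed(9)
  base <- matrix(runif(8, 0, 100), 4, 2)
  mk <- function(p) make_body(l_shoulder = p[1, ], l_wrist = p[2, ],
                              r_wrist = p[3, ], r_shoulder = p[4, ])
  s0 <- laban_space(mk(base))
  shift <- base + matrix(c(13.5, -7.2), 4, 2, byrow = TRUE)
  expect_equal(laban_space(mk(shift)), s0)
  th <- 0.73
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  expect_equal(laban_space(mk(base %*% R)), s0)
  expect_equal(laban_space(mk(base * 3)), 9 * s0)
})

test_that("angular velocity and acceleration match closed forms on noiseless tracks", {
  fps <- 30
  n <- 60
  t <- (seq_len(n) - 1) / fps

  static <- make_angle_track(rep(0.5, n), fps)
  ks <- joint_kinematics(static, "left_shoulder")
  expect_equal(max(abs(ks$omega)), 0, tolerance = 1e-12)
  expect_equal(max(abs(ks$omega_dot)), 0, tolerance = 1e-12)

  lin <- make_angle_track(0.2 * t + 0.3, fps)
  kl <- joint_kinematics(lin, "left_shoulder")
  interior <- 2:(n - 1)
  expect_lt(max(abs(kl$omega[interior] - 0.2)), 1e-9)

  quad <- make_angle_track(0.5 + t^2 * 0.5, fps)   # theta = t^2/2 + 0.5
  kq <- joint_kinematics(quad, "left_shoulder")
  # omega = t (exact for central differences on quadratics at interior frames)
  expect_lt(max(abs(kq$omega[interior] - t[interior])), 1e-9)
  # omega_dot = 1 at doubly-interior frames
  expect_lt(max(abs(kq$omega_dot[3:(n - 2)] - 1)), 1e-6)

  # O(dt^2) truncation on a sinusoid
  A <- 0.5; w <- 2 * pi * 0.7  # keeps theta in (0, pi): no acos fold
  sin_tr <- make_angle_track(0.6 + A * sin(w * t), fps)
  kw <- joint_kinematics(sin_tr, "left_shoulder")
  dt <- 1 / fps
  bound_w <- A * w^3 * dt^2 / 6 * 1.5
  expect_lt(max(abs(kw$omega[interior] - A * w * cos(w * t[interior]))), bound_w)
  bound_a <- A * w^4 * dt^2 * 1.5
  expect_lt(max(abs(kw$omega_dot[3:(n - 2)] + A * w^2 * sin(w * t[3:(n - 2)]))),
            bound_a)

  expect_error(joint_kinematics(make_angle_track(c(0, 0.1)), "left_shoulder"),
               "too-short")
})

test_that("weight evaluates L^2 w^2 sin(theta) mass and is additive and non-negative", {
  k1 <- make_kin(theta = pi / 2, omega = 3, omega_dot = 0, L = 2)
  expect_equal(laban_weight(list(k1), 1), 36.0)  # 4 * 9 * 1 * 1
  k2 <- make_kin(theta = pi / 4, omega = 1.5, omega_dot = 0, L = 3)
  expect_equal(laban_weight(list(k1, k2), 1),
               laban_weight(list(k1), 1) + laban_weight(list(k2), 1))
  static <- make_kin(theta = 1, omega = 0, omega_dot = 0, L = 5)
  expect_equal(laban_weight(list(static), 1), 0)
  # non-negativity over random kinematics
  set.seed(3)
  for (i in 1:200) {
    k <- make_kin(theta = runif(1, 0, pi), omega = rnorm(1, sd = 5),
                  omega_dot = 0, L = runif(1, 0, 10), mass = runif(1, 0.1, 2))
    expect_gte(laban_weight(list(k), 1), 0)
  }
})

test_that("time sums acceleration magnitudes, with a velocity-mode switch", {
  const <- make_kin(theta = 1, omega = 2, omega_dot = 0, L = 1)
  expect_equal(laban_time(list(const, const), 1), 0)
  kp <- make_kin(theta = 1, omega = 0, omega_dot = +2, L = 1)
  km <- make_kin(theta = 1, omega = 0, omega_dot = -2, L = 1)
  expect_equal(laban_time(list(kp, km), 1), 4.0)  # |.| convention, not signed
  expect_equal(laban_time(list(kp, km), 1, mode = "velocity"), 0)

  # two joints with theta = t^2 -> |omega_dot| = 2 each at interior frames
  fps <- 30; n <- 40; t <- (seq_len(n) - 1) / fps
  tr <- make_angle_track(0.3 + t^2, fps)
  k <- joint_kinematics(tr, "left_shoulder")
  expect_equal(laban_time(list(k, k), 5), 4.0, tolerance = 1e-6)
})

test_that("laban_series windows with a trailing mean and honours window 1", {
  n <- 50
  tr <- make_track(n, function(i) square_body(10))
  ls <- laban_series(tr, window_frames = 30)
  expect_equal(nrow(ls), n)
  expect_equal(ls$space, rep(100, n))           # constant pose: static area
  expect_equal(ls$weight[3:n], rep(0, n - 2))
  expect_equal(ls$time[3:n], rep(0, n - 2))

  # window 1 equals the instantaneous series
  fps <- 30; t <- (seq_len(n) - 1) / fps
  tr2 <- make_angle_track(0.5 + 0.3 * sin(2 * pi * t), fps)
  inst <- laban_series(tr2, window_frames = 1)
  win <- laban_series(tr2, window_frames = 10)
  # moving-average oracle applied to the instantaneous series
  for (col in c("space", "weight", "time")) {
    ora <- vapply(seq_len(n), function(i) {
      mean(inst[[col]][max(1, i - 9):i])
    }, numeric(1))
    expect_equal(win[[col]], ora, tolerance = 1e-12)
  }

  # step change in instantaneous space ramps linearly over the window
  big <- square_body(10); small <- square_body(0.001)
  tr3 <- make_track(80, function(i) if (i <= 40) small else big)
  ls3 <- laban_series(tr3, window_frames = 30)
  ramp <- ls3$space[41:70]
  expect_true(all(diff(ramp) > 0))
  expect_equal(ls3$space[70], 100, tolerance = 0.01)
  steps <- diff(ramp)
  expect_lt(max(abs(steps - steps[1])), 1e-6)   # linear ramp
})
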