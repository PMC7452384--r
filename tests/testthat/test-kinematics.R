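test_that("degenerate motions give the analytically forced kinematics", {
  t <- seq(0, 5, by = 0.1)
  # stationary subject: everything zero
  still <- trajectory(t, rep(3, length(t)), rep(4, length(t)), frame_rate = 10)
  k <- compute_kinematics(still, smooth_window = 0)
  expect_true(all(k$speed == 0))
  expect_true(all(k$turn_rate == 0))
  expect_true(all(k$lin_accel == 0) && all(k$ang_accel == 0))

  # straight line at 2 units/s sampled at 10 Hz
  line <- trajectory(t, 2 * t, rep(0, length(t)), frame_rate = 10)
  k <- compute_kinematics(line, smooth_window = 0)
  expect_equal(k$speed, rep(2, nrow(k)), tolerance = 1e-12)
  expect_equal(k$turn_rate, rep(0, nrow(k)), tolerance = 1e-12)
})

test_that("circular motion matches the closed form within 1% at fine steps", {
  r <- 5; w <- 1; fr <- 200                       # dt*w = 0.005 << 0.05 rad
  k <- compute_kinematics(circle_traj(r, w, fr), smooth_window = 0)
  expect_lt(max(abs(k$speed - r * w) / (r * w)), 0.01)
  expect_lt(max(abs(k$turn_rate - w) / w), 0.01)
  expect_lt(max(abs(k$ang_accel)), 0.05 * w)      # ~0 angular acceleration
})

test_that("speed and turn rate are invariant under rigid motions", {
  traj <- rw_traj(n = 300, seed = 42)
  k0 <- compute_kinematics(traj, smooth_window = 0.3)
  for (seed in 1:3) {
    set.seed(seed)
    th <- runif(1, 0, 2 * pi); dx <- runif(1, -50, 50); dy <- runif(1, -50, 50)
    xr <- traj$x * cos(th) - traj$y * sin(th) + dx
    yr <- traj$x * sin(th) + traj$y * cos(th) + dy
    kr <- compute_kinematics(trajectory(traj$t, xr, yr, frame_rate = 10),
                             smooth_window = 0.3)
    expect_equal(kr$speed, k0$speed, tolerance = 1e-9)
    expect_equal(kr$turn_rate, k0$turn_rate, tolerance = 1e-9)
  }
})

test_that("time reversal preserves speeds and negates linear acceleration", {
  traj <- rw_traj(n = 120, seed = 7)
  n <- nrow(traj)
  rev_traj <- trajectory(max(traj$t) - rev(traj$t), rev(traj$x), rev(traj$y),
                         frame_rate = 10)
  kf <- compute_kinematics(traj, smooth_window = 0)
  kr <- compute_kinematics(rev_traj, smooth_window = 0)
  # reversed speed index j corresponds to forward index n-j (one-off shift
  # from the end-of-series truncation)
  m <- nrow(kf)
  expect_equal(kr$speed[2:(m - 1)], rev(kf$speed[3:m]), tolerance = 1e-9)
  j <- 3:(m - 1)                                   # interior, centered diffs
  expect_equal(kr$lin_accel[j], -rev(kf$lin_accel[j]), tolerance = 1e-9)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(trajectory(c(0, 1), c(0, 0), c(0, 0)), "insufficient data")
  expect_error(trajectory(c(0, 1, 1), c(0, 0, 0), c(0, 0, 0)),
               "invalid time base")
  tr <- rw_traj(n = 50)
  tr$x[3] <- NA
  expect_error(compute_kinematics(tr), "missing positions")
})

test_that("gap handling interpolates short gaps and splits on long ones", {
  t <- seq(0, 9.9, by = 0.1)
  x <- t; y <- 2 * t
  # no gaps: identical trajectory, one segment
  tr <- trajectory(t, x, y, frame_rate = 10)
  filled <- fill_gaps(tr, max_gap = 0.5)
  expect_equal(filled$x, x)
  expect_equal(unique(filled$segment), 1L)

  # one 0.1 s gap (single missing frame): midpoint interpolation
  x2 <- x; y2 <- y; x2[50] <- NA; y2[50] <- NA
  filled <- fill_gaps(trajectory(t, x2, y2, frame_rate = 10), max_gap = 0.5)
  expect_equal(nrow(filled), length(t))
  expect_equal(filled$x[50], (x[49] + x[51]) / 2)
  expect_equal(filled$y[50], (y[49] + y[51]) / 2)
  expect_equal(unique(filled$segment), 1L)

  # a 2 s gap with max_gap = 0.5: two segments, nothing interpolated
  x3 <- x; y3 <- y; gap <- 40:59
  x3[gap] <- NA; y3[gap] <- NA
  filled <- fill_gaps(trajectory(t, x3, y3, frame_rate = 10), max_gap = 0.5)
  expect_equal(nrow(filled), length(t) - length(gap))
  expect_equal(sort(unique(filled$segment)), c(1L, 2L))
  expect_equal(sum(filled$segment == 1L), 39)

  # all missing
  expect_error(fill_gaps(trajectory(t, NA * x, NA * y, frame_rate = 10)),
               "empty trajectory")
})

test_that("kinematics across segments never differentiates over a gap", {
  t <- seq(0, 9.9, by = 0.1)
  x <- sin(t); y <- cos(t)
  x[40:59] <- NA; y[40:59] <- NA
  filled <- fill_gaps(trajectory(t, x, y, frame_rate = 10), max_gap = 0.5)
  k <- compute_kinematics(filled, smooth_window = 0)
  # per-segment sample count: each segment loses its 2 trailing samples
  expect_equal(as.integer(table(k$segment)), c(37L, 39L))
  expect_true(all(is.finite(k$lin_accel)))
})

test_that("trajectory CSV + metadata sidecar round-trips", {
  dir <- withr::local_tempdir()
  tr <- rw_traj(n = 60, seed = 3)
  attr(tr, "subject_id") <- "f01"
  attr(tr, "size_class") <- "large"
  attr(tr, "condition") <- "match"
  path <- file.path(dir, "f01.csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  expect_equal(attr(back, "size_class"), "large")
  expect_equal(attr(back, "condition"), "match")
  expect_equal(attr(back, "frame_rate"), attr(tr, "frame_rate"),
               tolerance = 1e-9)

  # alternative column layout via col_map
  df <- data.frame(time_s = tr$t, posx = tr$x, posy = tr$y)
  alt <- file.path(dir, "alt.csv")
  write.csv(df, alt, row.names = FALSE)
  back2 <- read_trajectory(alt, meta = list(frame_rate = 10),
                           col_map = c(t = "time_s", x = "posx", y = "posy"))
  expect_equal(back2$y, tr$y, tolerance = 1e-12)
})
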