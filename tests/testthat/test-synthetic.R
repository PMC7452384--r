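test_that("dyad simulation is bit-reproducible and respects the arena", {
  cfg <- dyad_sim_config(duration = 60)
  d1 <- simulate_dyad(cfg, seed = 5)
  d2 <- simulate_dyad(cfg, seed = 5)
  expect_identical(d1$small$x, d2$small$x)
  expect_identical(d1$large$y, d2$large$y)
  d3 <- simulate_dyad(cfg, seed = 6)
  expect_false(identical(d1$small$x, d3$small$x))
  for (tr in d1) {
    expect_true(all(tr$x >= 0 & tr$x <= cfg$arena[1]))
    expect_true(all(tr$y >= 0 & tr$y <= cfg$arena[2]))
    expect_equal(nrow(tr), 60 * 30)
  }
  expect_equal(attr(d1$small, "size_class"), "small")
  expect_error(dyad_sim_config(arena = c(0.5, 0.5)), "infeasible config")
})

test_that("simulated speeds hover around the configured mean", {
  d <- simulate_dyad(dyad_sim_config(duration = 300, coupling_strength = 0),
                     seed = 7)
  k <- compute_kinematics(d$small, smooth_window = 0)
  expect_lt(abs(mean(k$speed) - 8) / 8, 0.25)
  expect_true(all(k$speed >= 0))
})

test_that("the coupled chain hits its closed-form transfer entropy", {
  ch <- simulate_coupled_chain(0.5, n = 60000, seed = 8)
  # empirical copy rate is c plus the 1/4 chance of an accidental match
  emp <- mean(ch$y$symbol[-1] == ch$x$symbol[-60000])
  expect_lt(abs(emp - (0.5 + 0.5 / 4)), 3 * sqrt(0.625 * 0.375 / 60000))
  expect_lt(abs(transfer_entropy(ch$x, ch$y)$te - coupled_chain_te(0.5)), 0.02)
})

test_that("transfer entropy from leader to follower increases with coupling strength", {
  te_at <- function(cc) {
    mean(vapply(1:6, function(s) {
      d <- simulate_dyad(dyad_sim_config(duration = 300,
                                         coupling_strength = cc),
                         seed = 500 + s)
      p <- prep_dyad(d)
      transfer_entropy(p$sym_small, p$sym_large)$te
    }, numeric(1)))
  }
  tes <- vapply(c(0, 0.3, 0.6), te_at, numeric(1))
  expect_true(all(diff(tes) > 0))
})

test_that("the relay channel reproduces, delays and degrades as configured", {
  d <- simulate_dyad(dyad_sim_config(duration = 120), seed = 9)
  fish <- d$small
  # identity channel: replica == fish wherever defined
  rep0 <- teleport_channel(fish, channel_config(delay = 0), seed = 1)
  expect_equal(rep0$x, fish$x, tolerance = 1e-12)
  expect_equal(attr(rep0, "subject_id"), paste0(attr(fish, "subject_id"), "_replica"))
  # pure delay of 0.2 s (6 frames at 30 Hz): shifted copy
  rep_d <- teleport_channel(fish, channel_config(delay = 0.2), seed = 1)
  n <- nrow(fish)
  expect_true(all(is.na(rep_d$x[1:6])))
  expect_equal(rep_d$x[7:n], fish$x[1:(n - 6)], tolerance = 1e-9)
  # dropout fraction ~0.15 -> coverage ~0.85
  rep_dr <- teleport_channel(fish, channel_config(dropout_fraction = 0.15),
                             seed = 2)
  cov <- mean(!is.na(rep_dr$x))
  expect_lt(abs(cov - 0.85), 3 * sqrt(0.15 * 0.85 / n))
  # channel noise stays inside the arena bounds
  rep_n <- teleport_channel(fish, channel_config(pos_noise_sd = 2), seed = 3)
  b <- attr(fish, "arena_bounds")
  expect_true(all(rep_n$x >= b[1] & rep_n$x <= b[2], na.rm = TRUE))
  # deterministic given the channel seed
  expect_identical(teleport_channel(fish, channel_config(dropout_fraction = 0.15),
                                    seed = 2)$x, rep_dr$x)
})

test_that("the coupling lag is recovered from speed cross-correlation across seeds", {
  hits <- vapply(1:20, function(s) {
    d <- simulate_dyad(dyad_sim_config(duration = 120), seed = 600 + s)
    ks <- compute_kinematics(d$small); kl <- compute_kinematics(d$large)
    xc <- normalized_xcorr(ks$speed, kl$speed, max_lag = 0.5, frame_rate = 30)
    abs(xc$lag - 0.1) <= 1 / 30 + 1e-9          # within one frame of 0.1 s
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("swapping the leader reverses the sign of the net transfer entropy", {
  net_for <- function(leader, s) {
    d <- simulate_dyad(dyad_sim_config(duration = 300, leader = leader),
                       seed = s)
    p <- prep_dyad(d)
    net_transfer_entropy(p$sym_small, p$sym_large)$net_te
  }
  net_small <- mean(vapply(1:6, function(s) net_for("small", 700 + s), numeric(1)))
  net_large <- mean(vapply(1:6, function(s) net_for("large", 700 + s), numeric(1)))
  expect_gt(net_small, 0)
  expect_lt(net_large, 0)
})

test_that("study simulation produces the configured sessions with replicas where due", {
  sessions <- simulate_study(n_pairs = 2, cfg = dyad_sim_config(duration = 30),
                             seed = 11)
  expect_length(sessions, 6)
  conds <- vapply(sessions, `[[`, character(1), "condition")
  expect_equal(sort(unique(conds)), c("control", "match", "mismatch"))
  for (s in sessions) {
    expect_s3_class(s$small, "trajectory")
    if (s$condition == "match") {
      expect_s3_class(s$replica_small, "trajectory")
      expect_s3_class(s$replica_large, "trajectory")
    } else {
      expect_null(s$replica_small)
    }
    expect_equal(attr(s$small, "condition"), s$condition)
  }
  # reproducible end to end
  sessions2 <- simulate_study(n_pairs = 2, cfg = dyad_sim_config(duration = 30),
                              seed = 11)
  expect_identical(sessions[[4]]$large$x, sessions2[[4]]$large$x)
})
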