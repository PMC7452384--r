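# Synthetic coupled-swimmer dyads, a noisy delayed relay channel producing
# replica trajectories, and a symbol-level coupled Markov chain with a known
# closed-form transfer entropy. Together these provide ground truth for every
# analysis stage.
#
# Generator design: the leader swims autonomously (mean-reverting speed,
# autocorrelated heading with soft wall avoidance); the follower keeps an
# internal autonomous state of the same kind and blends it with the leader's
# LAGGED speed and heading with weight c, plus a distance-dependent
# attraction toward the leader that is also modulated by c. Coupling thus
# acts on exactly the channels the analysis reads (speed and turn rate), the
# cross-correlation peak sits exactly at the coupling lag, and c = 0 yields
# two statistically independent swimmers.

#' Configuration of the coupled-swimmer dyad generator
#'
#' Defaults emulate a 10-minute session of two zebrafish in a shallow
#' rectangular tank: 600 s at 30 Hz in a 45 x 45 cm arena, cruising speed
#' around 8 cm/s with an autocorrelation time of ~0.5 s, and the small fish
#' leading the large one with coupling strength 0.6 at a 0.1 s lag.
#'
#' @param duration session length in seconds.
#' @param frame_rate sampling rate in Hz.
#' @param arena `c(width, height)` in length units (cm).
#' @param leader which subject drives the interaction: `"small"` or
#'   `"large"`.
#' @param coupling_strength c in `[0, 1]`: weight of the leader's lagged
#'   speed/heading in the follower's dynamics; 0 = independent swimmers.
#' @param coupling_lag lag tau (seconds) at which the follower tracks the
#'   leader.
#' @param speed_mean,speed_reversion,speed_noise_sd mean (length units/s),
#'   mean-reversion rate (1/s) and noise intensity (length units/s per
#'   sqrt(s)) of the Ornstein-Uhlenbeck speed process.
#' @param heading_noise_sd turning noise intensity (rad per sqrt(s)).
#' @param wall_gain soft wall-avoidance steering gain (rad/s at the wall).
#' @param attraction_gain steering gain (rad/s per rad of bearing error) of
#'   the follower's attraction toward the leader; modulated by
#'   `coupling_strength`.
#' @param body_length_small,body_length_large body lengths (length units)
#'   recorded as metadata (about a 33% size difference by default).
#' @return A `dyad_sim_config` list.
#' @export
dyad_sim_config <- function(duration = 600, frame_rate = 30,
                            arena = c(45, 45),
                            leader = c("small", "large"),
                            coupling_strength = 0.6, coupling_lag = 0.1,
                            speed_mean = 8, speed_reversion = 2,
                            speed_noise_sd = 6,
                            heading_noise_sd = 2, wall_gain = 6,
                            attraction_gain = 1,
                            body_length_small = 3, body_length_large = 4) {
  leader <- match.arg(leader)
  stopifnot(coupling_strength >= 0, coupling_strength <= 1,
            coupling_lag >= 0, duration > 0, frame_rate > 0,
            all(arena > 0))
  if (speed_mean / frame_rate > 0.25 * min(arena))
    stop("infeasible config: arena too small for the speed process")
  structure(list(duration = duration, frame_rate = frame_rate, arena = arena,
                 leader = leader, coupling_strength = coupling_strength,
                 coupling_lag = coupling_lag, speed_mean = speed_mean,
                 speed_reversion = speed_reversion,
                 speed_noise_sd = speed_noise_sd,
                 heading_noise_sd = heading_noise_sd, wall_gain = wall_gain,
                 attraction_gain = attraction_gain,
                 body_length_small = body_length_small,
                 body_length_large = body_length_large),
            class = "dyad_sim_config")
}

# mean-reverting (OU) speed series, vectorized via the AR(1) recursion
ou_speed <- function(n, mu, rev, sd_noise, dt, s0, noise) {
  a <- 1 - rev * dt
  s <- mu + stats::filter(sd_noise * sqrt(dt) * noise, a, method = "recursive",
                          init = s0 - mu)
  pmax(as.numeric(s), 0.05 * mu)
}

# integrate one swimmer's heading/position given its (precomputed) speed
# series; guide_heading (if not NULL) is blended in with weight c at lag
# lag_f frames; target_xy (n x 2) is the attraction target
integrate_swimmer <- function(speed, hnoise, dt, arena, gain_wall, margin,
                              h0, p0, c = 0, lag_f = 0L, guide_heading = NULL,
                              gain_att = 0, target_xy = NULL) {
  .integrate_swimmer_cpp(speed, hnoise, dt, arena, gain_wall, margin,
                         h0, p0, c, as.integer(lag_f),
                         guide_heading %||% numeric(0), gain_att,
                         if (is.null(target_xy)) numeric(0) else target_xy[, 1L],
                         if (is.null(target_xy)) numeric(0) else target_xy[, 2L])
}

#' Simulate a coupled leader-follower dyad
#'
#' Generates the two trajectories of a dyad under `cfg` (see
#' [dyad_sim_config()]). Deterministic given `seed`.
#'
#' @param cfg a [dyad_sim_config()].
#' @param seed integer RNG seed.
#' @param pair_id identifier recorded in subject metadata.
#' @param condition condition label recorded in metadata.
#' @return `list(small = trajectory, large = trajectory)`; which of the two
#'   is the leader is set by `cfg$leader`.
#' @export
simulate_dyad <- function(cfg, seed = 1L, pair_id = "pair1",
                          condition = "control") {
  stopifnot(inherits(cfg, "dyad_sim_config"))
  set.seed(seed)
  fr <- cfg$frame_rate; dt <- 1 / fr
  n <- as.integer(round(cfg$duration * fr))
  lag_f <- as.integer(round(cfg$coupling_lag * fr))
  c <- cfg$coupling_strength
  margin <- 0.12 * min(cfg$arena)
  hsd <- cfg$heading_noise_sd * sqrt(dt)

  # all randomness drawn up front for bit-reproducibility
  eL <- stats::rnorm(n); eF <- stats::rnorm(n)
  hL <- stats::rnorm(n, sd = hsd); hF <- stats::rnorm(n, sd = hsd)
  init <- stats::runif(6)

  sL <- ou_speed(n, cfg$speed_mean, cfg$speed_reversion, cfg$speed_noise_sd,
                 dt, cfg$speed_mean, eL)
  leader <- integrate_swimmer(sL, hL, dt, cfg$arena, cfg$wall_gain, margin,
                              h0 = 2 * pi * init[1],
                              p0 = c(cfg$arena[1] * (0.25 + 0.5 * init[2]),
                                     cfg$arena[2] * (0.25 + 0.5 * init[3])))

  sOwn <- ou_speed(n, cfg$speed_mean, cfg$speed_reversion, cfg$speed_noise_sd,
                   dt, cfg$speed_mean, eF)
  sF <- sOwn
  if (c > 0 && lag_f < n) {
    idx <- (lag_f + 1L):n
    sF[idx] <- (1 - c) * sOwn[idx] + c * sL[idx - lag_f]
  }
  follower <- integrate_swimmer(sF, hF, dt, cfg$arena, cfg$wall_gain, margin,
                                h0 = 2 * pi * init[4],
                                p0 = c(cfg$arena[1] * (0.25 + 0.5 * init[5]),
                                       cfg$arena[2] * (0.25 + 0.5 * init[6])),
                                c = c, lag_f = lag_f,
                                guide_heading = leader$h,
                                gain_att = cfg$attraction_gain * c,
                                target_xy = cbind(leader$x, leader$y))

  t <- (seq_len(n) - 1L) * dt
  bounds <- c(0, cfg$arena[1], 0, cfg$arena[2])
  mk <- function(sim, size_class) {
    trajectory(t, sim$x, sim$y,
               subject_id = paste(pair_id, size_class, sep = "_"),
               size_class = size_class, condition = condition,
               frame_rate = fr, arena_bounds = bounds)
  }
  if (cfg$leader == "small")
    list(small = mk(leader, "small"), large = mk(follower, "large"))
  else
    list(small = mk(follower, "small"), large = mk(leader, "large"))
}

#' Configuration of the relay ("teleporting") channel
#'
#' Emulates the transfer of a live fish's trajectory onto a remote replica:
#' a transport delay with per-frame jitter, additive positional noise, and a
#' fraction of dropped (untracked) frames.
#'
#' @param delay transport delay in seconds.
#' @param jitter_sd per-frame jitter of the delay, in seconds.
#' @param dropout_fraction fraction of replica frames marked missing, in
#'   `[0, 1)`.
#' @param pos_noise_sd positional noise, length units.
#' @return A `channel_config` list.
#' @export
channel_config <- function(delay = 0.1, jitter_sd = 0, dropout_fraction = 0,
                           pos_noise_sd = 0) {
  stopifnot(delay >= 0, jitter_sd >= 0,
            dropout_fraction >= 0, dropout_fraction < 1, pos_noise_sd >= 0)
  structure(list(delay = delay, jitter_sd = jitter_sd,
                 dropout_fraction = dropout_fraction,
                 pos_noise_sd = pos_noise_sd),
            class = "channel_config")
}

#' Pass a trajectory through the relay channel
#'
#' The replica trajectory equals the input delayed by `delay` (plus
#' per-frame jitter), with additive positional noise; `dropout_fraction` of
#' frames are marked missing (`NA`). Uses its own RNG stream (`seed`) so
#' channel effects can be toggled without changing the underlying dyad.
#' Deterministic given `seed`.
#'
#' @param traj a [trajectory()].
#' @param ch a [channel_config()].
#' @param seed integer RNG seed for the channel noise.
#' @return A replica [trajectory()] on the same session clock; frames before
#'   the delayed signal exists, and dropped frames, are `NA`.
#' @export
teleport_channel <- function(traj, ch, seed = 1L) {
  stopifnot(inherits(ch, "channel_config"))
  set.seed(seed)
  n <- nrow(traj)
  td <- traj$t - ch$delay -
    if (ch$jitter_sd > 0) stats::rnorm(n, sd = ch$jitter_sd) else 0
  xs <- stats::approx(traj$t, traj$x, xout = td, rule = 1)$y
  ys <- stats::approx(traj$t, traj$y, xout = td, rule = 1)$y
  if (ch$pos_noise_sd > 0) {
    xs <- xs + stats::rnorm(n, sd = ch$pos_noise_sd)
    ys <- ys + stats::rnorm(n, sd = ch$pos_noise_sd)
  }
  bounds <- attr(traj, "arena_bounds")
  if (!is.null(bounds)) {
    xs <- pmin(pmax(xs, bounds[1]), bounds[2])
    ys <- pmin(pmax(ys, bounds[3]), bounds[4])
  }
  if (ch$dropout_fraction > 0) {
    drop <- stats::runif(n) < ch$dropout_fraction
    xs[drop] <- NA_real_; ys[drop] <- NA_real_
  }
  trajectory(traj$t, xs, ys,
             subject_id = paste0(attr(traj, "subject_id"), "_replica"),
             size_class = attr(traj, "size_class"),
             condition = attr(traj, "condition"),
             frame_rate = attr(traj, "frame_rate"),
             arena_bounds = bounds)
}

#' Coupled 4-symbol Markov chain with known transfer entropy
#'
#' `X` is i.i.d. uniform on the 4 symbols; `Y[t+1] = X[t]` with probability
#' `c`, otherwise i.i.d. uniform. The exact transfer entropy X -> Y (any
#' k >= 1) is available in closed form via [coupled_chain_te()], making this
#' the analytic oracle for the plug-in estimator.
#'
#' @param c coupling probability in `[0, 1]`.
#' @param n chain length.
#' @param seed integer RNG seed.
#' @param frame_rate nominal sampling rate used for the time base.
#' @return `list(x = symbol_series, y = symbol_series)`.
#' @export
simulate_coupled_chain <- function(c, n, seed = 1L, frame_rate = 30) {
  stopifnot(c >= 0, c <= 1, n >= 2)
  set.seed(seed)
  x <- sample.int(4L, n, replace = TRUE)
  copy <- stats::runif(n - 1L) < c
  y <- c(sample.int(4L, 1L),
         ifelse(copy, x[seq_len(n - 1L)], sample.int(4L, n - 1L, replace = TRUE)))
  list(x = new_symbol_series(x, frame_rate = frame_rate, subject_id = "chain_x"),
       y = new_symbol_series(as.integer(y), frame_rate = frame_rate,
                             subject_id = "chain_y"))
}

#' Closed-form transfer entropy of the coupled chain
#'
#' For the chain of [simulate_coupled_chain()], `Y[t+1]` depends only on
#' `X[t]` (uniform) and fresh noise, and is independent of `Y`'s own past, so
#' TE equals the mutual information `I(Y[t+1]; X[t]) = log(4) - H(a, b, b, b)`
#' with `a = c + (1-c)/4`, `b = (1-c)/4`.
#'
#' @param c coupling probability.
#' @param base logarithm base (2 = bits).
#' @return Transfer entropy X -> Y in units of `log base`.
#' @export
coupled_chain_te <- function(c, base = 2) {
  a <- c + (1 - c) / 4
  b <- (1 - c) / 4
  plogp <- function(p) ifelse(p > 0, p * log(p), 0)
  (log(4) + plogp(a) + 3 * plogp(b)) / log(base)
}

#' Simulate a multi-pair, multi-condition study
#'
#' Builds an in-memory synthetic study mirroring a within-subject design:
#' for each pair, a `"control"` session (direct dyad at the configured
#' coupling), a `"match"` session (same coupling routed through the relay
#' channel: the effective lag is the coupling lag plus the channel delay, and
#' replica trajectories are attached for similarity scoring) and a
#' `"mismatch"` session (coupling strength 0: the asymmetric interaction is
#' abolished).
#'
#' @param n_pairs number of dyads (12 by default, as in a 12-pair design).
#' @param cfg baseline [dyad_sim_config()].
#' @param channel [channel_config()] used in the `"match"` condition.
#' @param conditions subset of `c("control", "match", "mismatch")`.
#' @param seed integer master seed; per-session seeds are derived from it.
#' @return List of sessions, each
#'   `list(pair_id, condition, small, large, replica_small, replica_large)`
#'   (replicas only for `"match"`).
#' @export
simulate_study <- function(n_pairs = 12, cfg = dyad_sim_config(),
                           channel = channel_config(delay = 0.1),
                           conditions = c("control", "match", "mismatch"),
                           seed = 1L) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  sessions <- list()
  for (i in seq_len(n_pairs)) {
    pid <- sprintf("pair%02d", i)
    for (cond in conditions) {
      # double arithmetic: exact below 2^53, no integer overflow for any
      # 32-bit master seed
      sseed <- as.integer((as.numeric(seed) * 1009 + i * 97 +
                           match(cond, c("control", "match", "mismatch"))) %%
                          .Machine$integer.max)
      ses <- switch(cond,
        control = {
          d <- simulate_dyad(cfg, seed = sseed, pair_id = pid, condition = cond)
          list(small = d$small, large = d$large)
        },
        match = {
          cfg_m <- cfg
          cfg_m$coupling_lag <- cfg$coupling_lag + channel$delay
          d <- simulate_dyad(cfg_m, seed = sseed, pair_id = pid, condition = cond)
          cseed <- function(k)
            as.integer((as.numeric(sseed) + k) %% .Machine$integer.max)
          list(small = d$small, large = d$large,
               replica_small = teleport_channel(d$small, channel, seed = cseed(1)),
               replica_large = teleport_channel(d$large, channel, seed = cseed(2)))
        },
        mismatch = {
          cfg_u <- cfg
          cfg_u$coupling_strength <- 0
          d <- simulate_dyad(cfg_u, seed = sseed, pair_id = pid, condition = cond)
          list(small = d$small, large = d$large)
        })
      ses$pair_id <- pid
      ses$condition <- cond
      sessions[[length(sessions) + 1L]] <- ses
    }
  }
  sessions
}

#' Materialize a synthetic study as CSV fixtures on disk
#'
#' Writes one `t,x,y` CSV (plus JSON metadata sidecar) per subject per
#' session under `dir`, and a `study.yaml` session manifest consumable by
#' [run_study()].
#'
#' @inheritParams simulate_study
#' @param dir output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_fixture_study <- function(dir, n_pairs = 12, cfg = dyad_sim_config(),
                                channel = channel_config(delay = 0.1),
                                conditions = c("control", "match", "mismatch"),
                                seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sessions <- simulate_study(n_pairs, cfg, channel, conditions, seed)
  manifest <- lapply(sessions, function(s) {
    base <- file.path(dir, paste(s$pair_id, s$condition, sep = "_"))
    entry <- list(pair_id = s$pair_id, condition = s$condition,
                  path_small = paste0(base, "_small.csv"),
                  path_large = paste0(base, "_large.csv"))
    write_trajectory(s$small, entry$path_small)
    write_trajectory(s$large, entry$path_large)
    if (!is.null(s$replica_small)) {
      entry$path_replica_small <- paste0(base, "_replica_small.csv")
      entry$path_replica_large <- paste0(base, "_replica_large.csv")
      write_trajectory(s$replica_small, entry$path_replica_small)
      write_trajectory(s$replica_large, entry$path_replica_large)
    }
    entry
  })
  manifest_path <- file.path(dir, "study.yaml")
  yaml::write_yaml(list(seed = seed, sessions = manifest), manifest_path)
  invisible(manifest_path)
}
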