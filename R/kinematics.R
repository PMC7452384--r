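# Kinematic derivation: trajectory -> speed / turn rate / accelerations.
#
# Conventions: speed and heading are forward differences (the velocity lives
# between frames); turn rate is by default the UNSIGNED angular speed, so
# that "increase in turn rate" is well defined irrespective of turning
# direction; accelerations are centered differences (one-sided at segment
# ends), which keeps the two derivative series phase-aligned before joint
# symbolization.

wrap_angle <- function(a) atan2(sin(a), cos(a))

# running mean over w samples with shrinking windows at the edges
moving_avg <- function(v, w) {
  if (w <= 1L) return(v)
  n <- length(v)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Derive speed, turn rate and accelerations from a trajectory
#'
#' Speed is the forward-difference step length per unit time; heading is the
#' `atan2` of the displacement; turn rate is the wrapped heading change per
#' unit time (unsigned by default). Both series are optionally smoothed with
#' a moving average before the linear and angular accelerations are taken as
#' centered finite differences (one-sided at segment ends). All four series
#' share one time base, per tracking segment.
#'
#' @param traj a [trajectory()] with no missing positions (run [fill_gaps()]
#'   first).
#' @param smooth_window moving-average window in seconds applied to speed and
#'   turn rate before differentiation; `0` disables. The default corresponds
#'   to 3 samples at 30 Hz.
#' @param signed_turn if `TRUE`, keep the sign of the heading change
#'   (counter-clockwise positive) instead of the default unsigned angular
#'   speed.
#' @return A `kinematics` object: data frame with columns `t`, `speed`
#'   (length units/s), `turn_rate` (rad/s), `lin_accel` (length units/s^2),
#'   `ang_accel` (rad/s^2) and `segment`, with the trajectory metadata
#'   carried as attributes.
#' @export
compute_kinematics <- function(traj, smooth_window = 0.1, signed_turn = FALSE) {
  if (any(is.na(traj$x) | is.na(traj$y)))
    stop("missing positions: run fill_gaps() before compute_kinematics()")
  if (smooth_window < 0) stop("smooth_window must be >= 0")
  fr <- attr(traj, "frame_rate")
  w <- if (smooth_window > 0) max(1L, as.integer(round(smooth_window * fr))) else 1L
  if (w > 1L && w %% 2L == 0L) w <- w + 1L   # symmetric window

  per_seg <- lapply(split(seq_len(nrow(traj)), traj$segment), function(idx) {
    n <- length(idx)
    if (n < 3L) return(NULL)
    t <- traj$t[idx]; x <- traj$x[idx]; y <- traj$y[idx]
    dt <- diff(t)
    dx <- diff(x); dy <- diff(y)
    speed <- sqrt(dx^2 + dy^2) / dt                    # n-1, at interval starts
    heading <- atan2(dy, dx)                           # n-1
    dturn <- wrap_angle(diff(heading)) / dt[-(n - 1L)] # n-2
    turn <- if (signed_turn) dturn else abs(dturn)
    m <- n - 2L
    tt <- t[seq_len(m)]
    sp <- speed[seq_len(m)]
    sp <- moving_avg(sp, w)
    tu <- moving_avg(turn, w)
    data.frame(t = tt,
               speed = sp,
               turn_rate = tu,
               lin_accel = central_diff(sp, tt),
               ang_accel = central_diff(tu, tt),
               segment = traj$segment[idx][seq_len(m)])
  })
  per_seg <- per_seg[!vapply(per_seg, is.null, logical(1))]
  if (length(per_seg) == 0L) stop("insufficient data: no segment has >= 3 samples")
  out <- if (length(per_seg) == 1L) per_seg[[1L]] else {
    cols <- lapply(names(per_seg[[1L]]), function(nm)
      unlist(lapply(per_seg, `[[`, nm), use.names = FALSE))
    names(cols) <- names(per_seg[[1L]])
    as.data.frame(cols)
  }
  rownames(out) <- NULL
  structure(out,
            subject_id = attr(traj, "subject_id"),
            size_class = attr(traj, "size_class"),
            condition = attr(traj, "condition"),
            frame_rate = fr,
            signed_turn = signed_turn,
            class = c("kinematics", "data.frame"))
}

# centered finite differences, one-sided at the ends
central_diff <- function(v, t) {
  n <- length(v)
  if (n == 1L) return(0)
  if (n == 2L) return(rep(diff(v) / diff(t), 2L))
  d <- numeric(n)
  d[1L] <- (v[2L] - v[1L]) / (t[2L] - t[1L])
  d[n] <- (v[n] - v[n - 1L]) / (t[n] - t[n - 1L])
  i <- 2L:(n - 1L)
  d[i] <- (v[i + 1L] - v[i - 1L]) / (t[i + 1L] - t[i - 1L])
  d
}

#' @export
print.kinematics <- function(x, ...) {
  cat(sprintf("<kinematics> subject=%s n=%d samples, mean speed %.3g, mean turn rate %.3g rad/s\n",
              attr(x, "subject_id"), nrow(x), mean(x$speed), mean(x$turn_rate)))
  invisible(x)
}
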