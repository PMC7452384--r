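# Normalized cross-correlation with signed time-lag: leader-follower
# inference on speed/turn-rate series, and the windowed trajectory
# similarity index that scores how faithfully a replica mirrors a fish.
#
# Sign convention: a positive lag means series `a` (the small fish) precedes
# series `b` (the large fish / the replica) — `b` follows `a`.

# Pearson correlation of a vs b at every integer-frame lag in
# -max_lag_frames..max_lag_frames; normalization is recomputed on the
# overlapping support at each lag (no zero padding). NA-safe: frames where
# either series is missing are dropped pairwise.
xcorr_by_lag <- function(a, b, max_lag_frames, min_overlap = 10L) {
  stopifnot(length(b) == length(a))
  list(lags = (-max_lag_frames):max_lag_frames,
       r = .xcorr_profile_cpp(as.numeric(a), as.numeric(b),
                              as.integer(max_lag_frames),
                              as.integer(min_overlap)))
}

# index of the maximum correlation, ties broken toward the smallest |lag|
# (then toward the negative lag) for determinism
pick_max_lag <- function(lags, r) {
  ok <- which(!is.na(r))
  if (length(ok) == 0L) return(NA_integer_)
  best <- ok[r[ok] >= max(r[ok]) - 1e-12]
  best[order(abs(lags[best]), lags[best])][1L]
}

#' Maximum normalized cross-correlation and its signed time-lag
#'
#' Scans integer-frame lags in `[-max_lag, max_lag]`, computing the Pearson
#' correlation of the two series on the overlapping support at each lag
#' (both series mean-centered and unit-scaled over that overlap). A positive
#' lag means `a` precedes `b`, i.e. `b` follows `a`'s maneuvers.
#'
#' @param a,b aligned numeric series sampled at `frame_rate` (e.g. the speed
#'   or turn-rate series of the small and large subject).
#' @param max_lag largest lag searched, in seconds.
#' @param frame_rate sampling rate in Hz.
#' @return An `xcorr_result`: `max_corr`, `lag` (seconds, signed),
#'   `max_lag_searched`, plus the full correlation-by-lag profile.
#' @export
normalized_xcorr <- function(a, b, max_lag = 0.2, frame_rate = 30) {
  if (stats::sd(a, na.rm = TRUE) == 0 || stats::sd(b, na.rm = TRUE) == 0)
    stop("zero variance: constant series")
  Lmax <- max(1L, as.integer(round(max_lag * frame_rate)))
  if (length(a) < 2L * Lmax)
    stop("insufficient data: series shorter than twice the lag window")
  sc <- xcorr_by_lag(a, b, Lmax)
  i <- pick_max_lag(sc$lags, sc$r)
  if (is.na(i)) stop("zero variance: no lag had a computable correlation")
  structure(list(max_corr = sc$r[i], lag = sc$lags[i] / frame_rate,
                 max_lag_searched = Lmax / frame_rate,
                 lags = sc$lags / frame_rate, corr = sc$r,
                 frame_rate = frame_rate),
            class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("<xcorr_result> max corr %.4f at lag %+.4f s (searched +/- %.3g s)\n",
              x$max_corr, x$lag, x$max_lag_searched))
  invisible(x)
}

#' Windowed trajectory similarity between a fish and its replica
#'
#' The session is tiled with non-overlapping windows (default 20 s). In each
#' window the X and Y coordinate series of fish and replica are
#' cross-correlated over lags up to `max_lag`; the per-lag channel
#' correlations are combined (`"min"` by default: both coordinates must
#' match) and the similarity index is the maximum of the combined profile,
#' with the lag achieving it. A window is successful when similarity >= 0.95
#' and |lag| <= 0.2 s. `coverage_fraction` is the fraction of frames with
#' valid replica tracking.
#'
#' @param fish,replica [trajectory()] objects on the same session clock
#'   (equal `t`); the replica may contain `NA` dropout frames.
#' @param window window length in seconds.
#' @param max_lag largest lag searched in seconds.
#' @param combine `"min"` (conservative; both coordinates must match) or
#'   `"mean"` of the X/Y channel correlations at each lag.
#' @param success_sim,success_lag thresholds of the per-window success rule.
#' @param min_coverage minimum fraction of valid replica frames for a window
#'   to be scored.
#' @return A `similarity_result`: per-window data frame (`window_start`,
#'   `similarity`, `lag`, `coverage`, `success`) and session summary
#'   (`mean_similarity`, `mean_abs_lag`, `success_fraction`,
#'   `coverage_fraction`).
#' @export
similarity_index <- function(fish, replica, window = 20, max_lag = 1,
                             combine = c("min", "mean"),
                             success_sim = 0.95, success_lag = 0.2,
                             min_coverage = 0.5) {
  combine <- match.arg(combine)
  if (nrow(replica) == 0L) stop("no replica data")
  if (nrow(fish) != nrow(replica) || any(abs(fish$t - replica$t) > 1e-9))
    stop("alignment error: fish and replica must share the session clock")
  fr <- attr(fish, "frame_rate")
  wf <- max(2L, as.integer(round(window * fr)))
  Lmax <- max(1L, as.integer(round(max_lag * fr)))
  n <- nrow(fish)
  n_win <- n %/% wf
  if (n_win < 1L) stop("insufficient data: session shorter than one window")
  rows <- vector("list", n_win)
  valid_rep <- !(is.na(replica$x) | is.na(replica$y))
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * wf + 1L):(w * wf)
    cov_w <- mean(valid_rep[idx])
    sim <- NA_real_; lag <- NA_real_
    if (cov_w >= min_coverage) {
      cx <- xcorr_by_lag(fish$x[idx], replica$x[idx], Lmax)
      cy <- xcorr_by_lag(fish$y[idx], replica$y[idx], Lmax)
      comb <- if (combine == "min") pmin(cx$r, cy$r) else (cx$r + cy$r) / 2
      i <- pick_max_lag(cx$lags, comb)
      if (!is.na(i)) { sim <- comb[i]; lag <- cx$lags[i] / fr }
    }
    rows[[w]] <- data.frame(window_start = fish$t[idx[1L]],
                            similarity = sim, lag = lag, coverage = cov_w,
                            success = !is.na(sim) && sim >= success_sim &&
                                      abs(lag) <= success_lag)
  }
  per_window <- do.call(rbind, rows)
  scored <- !is.na(per_window$similarity)
  structure(list(
    per_window = per_window,
    window_length = window, max_lag_searched = max_lag, combine = combine,
    mean_similarity = if (any(scored)) mean(per_window$similarity[scored]) else NA_real_,
    mean_abs_lag = if (any(scored)) mean(abs(per_window$lag[scored])) else NA_real_,
    success_fraction = mean(per_window$success),
    coverage_fraction = mean(valid_rep)),
    class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> %d windows of %gs: mean similarity %.4f, mean |lag| %.4f s, success %.1f%%, coverage %.1f%%\n",
              nrow(x$per_window), x$window_length, x$mean_similarity,
              x$mean_abs_lag, 100 * x$success_fraction,
              100 * x$coverage_fraction))
  invisible(x)
}

#' Write the per-window similarity table to CSV
#'
#' @param x a `similarity_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(x, path) {
  utils::write.csv(x$per_window, path, row.names = FALSE)
  invisible(path)
}

# statistic factories over kinematics pairs (a = small, b = large)
stat_mean_xcorr <- function(channel, what = c("corr", "lag"),
                            max_lag_frames, frame_rate) {
  what <- match.arg(what)
  function(pairs) {
    mean(vapply(pairs, function(p) {
      sc <- xcorr_by_lag(p$a, p$b, max_lag_frames)
      i <- pick_max_lag(sc$lags, sc$r)
      if (is.na(i)) return(NA_real_)
      if (what == "corr") sc$r[i] else sc$lags[i] / frame_rate
    }, numeric(1)), na.rm = TRUE)
  }
}

#' Across-pair leader-follower summary with surrogate tests
#'
#' For each dyad the maximum normalized cross-correlation of the chosen
#' kinematic channel and its signed lag are computed (positive lag = the
#' small subject leads); the across-pair averages are tested against
#' surrogate distributions — the correlation one-tailed (upper), the lag
#' two-tailed, mirroring the reporting structure of leader-follower tables.
#'
#' @param pairs list of dyads, each `list(small = kinematics, large =
#'   kinematics)` on a common clock.
#' @param channel `"speed"` or `"turn_rate"`.
#' @param max_lag largest lag searched, in seconds. The default 0.2 s
#'   brackets typical fish response latencies; see the methods vignette.
#' @param n_surrogates surrogate replicates per test.
#' @param method surrogate construction (see [permutation_test()]).
#' @param seed RNG seed.
#' @return A `leader_follower_result`: per-pair table and two
#'   `perm_test_result`s (`corr_test`, `lag_test`).
#' @export
leader_follower_summary <- function(pairs, channel = c("speed", "turn_rate"),
                                    max_lag = 0.2, n_surrogates = 20000L,
                                    method = "rotate", seed = NULL) {
  channel <- match.arg(channel)
  stopifnot(length(pairs) >= 1L)
  fr <- attr(pairs[[1L]]$small, "frame_rate")
  Lmax <- max(1L, as.integer(round(max_lag * fr)))
  vec_pairs <- lapply(pairs, function(p)
    list(a = p$small[[channel]], b = p$large[[channel]]))
  per_pair <- do.call(rbind, lapply(seq_along(vec_pairs), function(i) {
    sc <- xcorr_by_lag(vec_pairs[[i]]$a, vec_pairs[[i]]$b, Lmax)
    j <- pick_max_lag(sc$lags, sc$r)
    data.frame(pair = i, max_corr = sc$r[j], lag = sc$lags[j] / fr)
  }))
  if (!is.null(seed)) set.seed(seed)
  corr_test <- permutation_test(
    stat_mean_xcorr(channel, "corr", Lmax, fr), vec_pairs,
    n_surrogates = n_surrogates, tail = "one_tailed_upper", method = method)
  lag_test <- permutation_test(
    stat_mean_xcorr(channel, "lag", Lmax, fr), vec_pairs,
    n_surrogates = n_surrogates, tail = "two_tailed", method = method)
  structure(list(channel = channel, per_pair = per_pair,
                 mean_corr = mean(per_pair$max_corr),
                 mean_lag = mean(per_pair$lag),
                 corr_test = corr_test, lag_test = lag_test,
                 max_lag = max_lag, seed = seed),
            class = "leader_follower_result")
}

#' @export
print.leader_follower_result <- function(x, ...) {
  cat(sprintf("<leader_follower> %s: mean corr %.4f (p=%.4g), mean lag %+.4f s (p=%.4g) over %d pairs\n",
              x$channel, x$mean_corr, x$corr_test$p_value,
              x$mean_lag, x$lag_test$p_value, nrow(x$per_pair)))
  invisible(x)
}
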