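# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths (no te_core, no xcorr_profile): brute-force
# probability sums, exhaustive lag scans, and Monte-Carlo references.

# brute-force plug-in transfer entropy: explicit sum over all observed
# (next symbol, destination history, source history) combinations, with
# probabilities computed from logical vectors
te_bruteforce <- function(x, y, k = 1, base = 2) {
  n <- length(y)
  idx <- k:(n - 1)                      # history ends at t, predicts y[t+1]
  hist_str <- function(v, t) paste(v[(t - k + 1):t], collapse = ",")
  hx <- vapply(idx, function(t) hist_str(x, t), character(1))
  hy <- vapply(idx, function(t) hist_str(y, t), character(1))
  ynext <- y[idx + 1]
  m <- length(idx)
  te <- 0
  for (sy in unique(ynext)) {
    for (hyv in unique(hy)) {
      sel_y <- hy == hyv
      sel_sy <- ynext == sy & sel_y
      p_y <- sum(sel_sy) / sum(sel_y)
      if (p_y == 0) next
      for (hxv in unique(hx[sel_y])) {
        sel_full <- sel_y & hx == hxv
        n_joint <- sum(sel_sy & hx == hxv)
        if (n_joint == 0) next
        p_full <- n_joint / sum(sel_full)
        te <- te + (n_joint / m) * log(p_full / p_y, base)
      }
    }
  }
  te
}

# exhaustive lag scan with stats::cor on complete cases
xcorr_bruteforce <- function(a, b, max_lag_frames) {
  n <- length(a)
  lags <- (-max_lag_frames):max_lag_frames
  r <- vapply(lags, function(L) {
    if (L >= 0) { av <- a[seq_len(n - L)]; bv <- b[(1 + L):n] }
    else        { av <- a[(1 - L):n];      bv <- b[seq_len(n + L)] }
    ok <- stats::complete.cases(av, bv)
    if (sum(ok) < 10) return(NA_real_)
    suppressWarnings(stats::cor(av[ok], bv[ok]))
  }, numeric(1))
  list(lags = lags, r = r)
}

# fixture: circular motion at radius r, angular velocity w
circle_traj <- function(r = 5, w = 1, frame_rate = 200, duration = 5,
                        center = c(10, 10)) {
  t <- seq(0, duration, by = 1 / frame_rate)
  trajectory(t, center[1] + r * cos(w * t), center[2] + r * sin(w * t),
             frame_rate = frame_rate)
}

# fixture: smooth random-walk trajectory with constant time step
rw_traj <- function(n = 200, frame_rate = 10, seed = 1) {
  set.seed(seed)
  h <- cumsum(rnorm(n, sd = 0.3))
  s <- pmax(1 + cumsum(rnorm(n, sd = 0.05)), 0.1)
  x <- cumsum(c(0, s[-n] * cos(h[-n]) / frame_rate))
  y <- cumsum(c(0, s[-n] * sin(h[-n]) / frame_rate))
  trajectory((seq_len(n) - 1) / frame_rate, x, y, frame_rate = frame_rate)
}

# fixture: kinematics object with prescribed accelerations (for symbolize)
fake_kin <- function(lin, ang, frame_rate = 10) {
  n <- length(lin)
  structure(data.frame(t = (seq_len(n) - 1) / frame_rate,
                       speed = rep(1, n), turn_rate = rep(1, n),
                       lin_accel = lin, ang_accel = ang,
                       segment = rep(1L, n)),
            subject_id = "fake", frame_rate = frame_rate,
            class = c("kinematics", "data.frame"))
}

# fixture: symbol series from raw integer codes
sym_series <- function(symbol, frame_rate = 30, id = "s") {
  teledyad:::new_symbol_series(as.integer(symbol), frame_rate = frame_rate,
                               subject_id = id)
}

# quick prep of a simulated study into symbol/kinematics pairs
prep_dyad <- function(session, smooth_window = 0.1) {
  ks <- compute_kinematics(session$small, smooth_window = smooth_window)
  kl <- compute_kinematics(session$large, smooth_window = smooth_window)
  list(kin_small = ks, kin_large = kl,
       sym_small = symbolize(ks), sym_large = symbolize(kl))
}
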