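# Joint symbolization of speed and turn-rate dynamics into a 4-letter
# alphabet: each sample is labelled by the pair of signs of the linear and
# angular accelerations ("--", "-+", "+-", "++"), i.e. whether speed and
# turn rate are momentarily decreasing or increasing.

#' Symbol alphabet used by [symbolize()]
#'
#' Integer codes 1:4 map to `"--"`, `"-+"`, `"+-"`, `"++"`; the first sign is
#' the sign of the linear acceleration (speed decreasing/increasing), the
#' second the sign of the angular acceleration (turn rate
#' decreasing/increasing).
#' @return Character vector of the four symbol labels.
#' @export
symbol_alphabet <- function() c("--", "-+", "+-", "++")

#' Encode kinematics into the 4-symbol joint series
#'
#' Each acceleration sample becomes one symbol from the joint alphabet of
#' sign pairs. Exact zero accelerations (plateaus) carry no trend of their
#' own and are resolved by `tie_rule`: `"carry"` (default, deterministic)
#' continues the preceding sign in that channel, initialising at "-";
#' `"random"` draws the sign from a seeded RNG.
#'
#' @param kin a `kinematics` object from [compute_kinematics()].
#' @param tie_rule `"carry"` or `"random"`.
#' @param seed RNG seed used when `tie_rule = "random"`.
#' @return A `symbol_series` object: data frame with columns `t`, `symbol`
#'   (integer 1:4, see [symbol_alphabet()]), `label` and `segment`.
#' @export
symbolize <- function(kin, tie_rule = c("carry", "random"), seed = 1L) {
  tie_rule <- match.arg(tie_rule)
  if (nrow(kin) < 1L) stop("insufficient data: empty kinematic series")
  lin <- resolve_signs(kin$lin_accel, kin$segment, tie_rule, seed)
  ang <- resolve_signs(kin$ang_accel, kin$segment, tie_rule, seed + 1L)
  sym <- 1L + 2L * (lin > 0) + 1L * (ang > 0)
  out <- data.frame(t = kin$t, symbol = as.integer(sym),
                    label = symbol_alphabet()[sym],
                    segment = kin$segment)
  structure(out,
            subject_id = attr(kin, "subject_id"),
            size_class = attr(kin, "size_class"),
            condition = attr(kin, "condition"),
            frame_rate = attr(kin, "frame_rate"),
            alphabet_size = 4L,
            class = c("symbol_series", "data.frame"))
}

# map accelerations to signs in {-1, +1}, resolving exact zeros per segment
resolve_signs <- function(a, segment, tie_rule, seed) {
  s <- sign(a)
  zeros <- s == 0
  if (!any(zeros)) return(s)
  if (tie_rule == "random") {
    rng <- local_rng(seed)
    s[zeros] <- rng(sum(zeros))
    return(s)
  }
  # carry-last within segment, plateaus at a segment start default to "-"
  for (idx in split(seq_along(a), segment)) {
    ss <- s[idx]
    if (ss[1L] == 0) ss[1L] <- -1
    z <- which(ss == 0)
    for (i in z) ss[i] <- ss[i - 1L]
    s[idx] <- ss
  }
  s
}

local_rng <- function(seed) {
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample(c(-1, 1), n, replace = TRUE)
  }
}

#' @export
print.symbol_series <- function(x, ...) {
  tab <- table(factor(x$label, levels = symbol_alphabet()))
  cat(sprintf("<symbol_series> subject=%s n=%d | %s\n",
              attr(x, "subject_id"), nrow(x),
              paste(sprintf("%s:%.3f", names(tab), tab / nrow(x)), collapse = " ")))
  invisible(x)
}

#' Empirical symbol distribution
#'
#' @param s a `symbol_series`.
#' @return Named numeric vector of relative frequencies over the 4 symbols
#'   (sums to 1).
#' @export
symbol_distribution <- function(s) {
  p <- tabulate(s$symbol, 4L) / nrow(s)
  names(p) <- symbol_alphabet()
  p
}

# construct a symbol_series from raw integer codes (used by the synthetic
# coupled-chain generator and by tests)
new_symbol_series <- function(symbol, t = NULL, frame_rate = 30,
                              segment = NULL, subject_id = NA_character_) {
  n <- length(symbol)
  if (is.null(t)) t <- (seq_len(n) - 1L) / frame_rate
  if (is.null(segment)) segment <- rep.int(1L, n)
  structure(data.frame(t = t, symbol = as.integer(symbol),
                       label = symbol_alphabet()[symbol], segment = segment),
            subject_id = subject_id, frame_rate = frame_rate,
            alphabet_size = 4L,
            class = c("symbol_series", "data.frame"))
}
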