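# Surrogate-data generation and non-parametric permutation tests.
#
# The default surrogate circularly rotates one series of a pair by a uniform
# random offset in [0.1 n, 0.9 n] frames: this preserves the series' marginal
# distribution and autocorrelation while destroying any cross-coupling to its
# partner — a conservative null for transfer entropy and cross-correlation.
# Alternatives: within-series shuffle (destroys autocorrelation too) and
# cross-pair swap (pairs each series with another pair's partner).

rotate_values <- function(v, offset) {
  n <- length(v)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0) v else c(v[(offset + 1L):n], v[1:offset])
}

# series containers: symbol series (any list with $symbol, e.g. a
# symbol_series data frame or a light list(symbol=, segment=)) or a bare
# numeric vector
series_values <- function(s) {
  if (is.list(s)) {
    if (!is.null(s$symbol)) s$symbol else stop("unsupported series type")
  } else as.numeric(s)
}

replace_values <- function(s, v) {
  if (is.list(s)) {
    s$symbol <- as.integer(v)
    if (!is.null(s$label)) s$label <- symbol_alphabet()[s$symbol]
    s
  } else v
}

#' Generate a surrogate partner for a series pair
#'
#' Returns `a` unchanged and a surrogate `b*` whose cross-coupling to `a` is
#' destroyed. `"rotate"` (default) circularly shifts `b` by a random offset
#' drawn uniformly from `[0.1 n, 0.9 n]` frames (offset 0 is excluded by
#' construction), preserving `b`'s marginals and autocorrelation;
#' `"shuffle"` randomly permutes `b`'s values, preserving only the marginals.
#'
#' @param a,b aligned series: `symbol_series` objects or numeric vectors.
#' @param method `"rotate"` or `"shuffle"` (cross-pair swap is available at
#'   the [permutation_test()] level, where multiple pairs exist).
#' @param min_frac,max_frac admissible rotation offsets as fractions of the
#'   series length.
#' @return `list(a = a, b = b*)`.
#' @export
make_surrogate_pair <- function(a, b, method = c("rotate", "shuffle"),
                                min_frac = 0.1, max_frac = 0.9) {
  method <- match.arg(method)
  vb <- series_values(b)
  n <- length(vb)
  if (n < 10L) stop("insufficient data: need at least 10 samples for surrogates")
  vb_s <- switch(method,
    rotate = {
      lo <- max(1L, as.integer(ceiling(min_frac * n)))
      hi <- min(n - 1L, as.integer(floor(max_frac * n)))
      rotate_values(vb, if (lo >= hi) lo else sample.int(hi - lo + 1L, 1L) + lo - 1L)
    },
    shuffle = vb[sample.int(n)])
  list(a = a, b = replace_values(b, vb_s))
}

surrogate_pairs <- function(pairs, method) {
  if (method == "cross_swap") {
    P <- length(pairs)
    if (P < 2L) stop("cross_swap needs at least 2 pairs")
    repeat {                                  # derangement by rejection
      perm <- sample.int(P)
      if (all(perm != seq_len(P))) break
    }
    return(lapply(seq_len(P), function(i) {
      a <- pairs[[i]]$a
      b <- pairs[[perm[i]]]$b
      va <- series_values(a); vb <- series_values(b)
      n <- min(length(va), length(vb))
      list(a = truncate_series(a, n), b = truncate_series(b, n))
    }))
  }
  lapply(pairs, function(p) make_surrogate_pair(p$a, p$b, method = method))
}

truncate_series <- function(s, n) {
  if (is.data.frame(s)) return(s[seq_len(n), , drop = FALSE])
  if (is.list(s)) {
    for (f in intersect(names(s), c("t", "symbol", "label", "segment")))
      s[[f]] <- s[[f]][seq_len(n)]
    return(s)
  }
  s[seq_len(n)]
}

#' Non-parametric permutation test against a surrogate distribution
#'
#' The observed statistic is `stat_fn` evaluated on the real pairs; each of
#' the `n_surrogates` replicates re-evaluates `stat_fn` on a full set of
#' per-pair surrogates (one fresh surrogate per pair per replicate, averaged
#' across pairs exactly as the observed statistic is). p-values use the
#' add-one estimator `p = (1 + #\{surrogate >= observed\}) / (1 + n)` for the
#' one-tailed upper test, and analogously `#\{|surrogate| >= |observed|\}`
#' for the two-tailed test (null centered at 0, as for net transfer entropy
#' and signed lags). Reported quantiles are order statistics of the surrogate
#' sample: the 95% quantile for one-tailed tests, the (2.5%, 97.5%) pair for
#' two-tailed tests.
#'
#' @param stat_fn function mapping a list of pairs (each `list(a=, b=)`) to a
#'   scalar, e.g. a trial-averaged transfer entropy.
#' @param pairs list of aligned series pairs.
#' @param n_surrogates number of surrogate replicates (20,000 by default;
#'   reduce for exploratory runs).
#' @param tail `"one_tailed_upper"` or `"two_tailed"`.
#' @param method surrogate construction: `"rotate"`, `"shuffle"` or
#'   `"cross_swap"`.
#' @param seed RNG seed recorded in the result; `NULL` uses the current RNG
#'   state.
#' @return A `perm_test_result`: observed value, surrogate quantiles,
#'   p-value, tail, method, seed, and the surrogate sample itself.
#' @export
permutation_test <- function(stat_fn, pairs, n_surrogates = 20000L,
                             tail = c("one_tailed_upper", "two_tailed"),
                             method = c("rotate", "shuffle", "cross_swap"),
                             seed = NULL) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  if (length(pairs) < 1L) stop("need at least one pair")
  if (n_surrogates < 100L) warning("unstable quantiles: n_surrogates < 100")
  if (!is.null(seed)) set.seed(seed)
  observed <- stat_fn(pairs)
  surr <- vapply(seq_len(n_surrogates),
                 function(i) stat_fn(surrogate_pairs(pairs, method)),
                 numeric(1))
  p <- if (tail == "one_tailed_upper") {
    (1 + sum(surr >= observed)) / (1 + n_surrogates)
  } else {
    (1 + sum(abs(surr) >= abs(observed))) / (1 + n_surrogates)
  }
  q <- stats::quantile(surr, c(0.95, 0.025, 0.975), names = FALSE)
  structure(list(observed = observed, n_surrogates = as.integer(n_surrogates),
                 quantile_95 = q[1], quantile_2_5 = q[2], quantile_97_5 = q[3],
                 p_value = p, tail = tail, method = method, seed = seed,
                 surrogates = surr),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  band <- if (x$tail == "one_tailed_upper")
    sprintf("q95=%.5g", x$quantile_95)
  else
    sprintf("q2.5=%.5g q97.5=%.5g", x$quantile_2_5, x$quantile_97_5)
  cat(sprintf("<perm_test> observed=%.5g %s p=%.4g (%s, %d surrogates, %s)\n",
              x$observed, band, x$p_value, x$tail, x$n_surrogates, x$method))
  invisible(x)
}

# ---- statistic factories used by the pipeline -------------------------------

#' Trial-averaged transfer-entropy statistics for permutation tests
#'
#' Factories returning statistic functions for [permutation_test()]. Pairs
#' are `list(a = symbol_series, b = symbol_series)` with `a` the small and
#' `b` the large subject: `stat_mean_te("ab")` averages TE(a -> b) across
#' pairs, `stat_mean_te("ba")` the reverse direction, and
#' `stat_mean_net_te()` averages the per-pair net TE (a -> b minus b -> a).
#'
#' @param direction `"ab"` or `"ba"`.
#' @param k history length.
#' @param base logarithm base.
#' @return A function suitable as `stat_fn` in [permutation_test()].
#' @export
stat_mean_te <- function(direction = c("ab", "ba"), k = 1L, base = 2) {
  direction <- match.arg(direction)
  function(pairs) {
    mean(vapply(pairs, function(p) {
      if (direction == "ab")
        te_core(p$a$symbol, p$b$symbol, k = k, base = base, seg = p$b$segment)$te
      else
        te_core(p$b$symbol, p$a$symbol, k = k, base = base, seg = p$a$segment)$te
    }, numeric(1)))
  }
}

#' @rdname stat_mean_te
#' @export
stat_mean_net_te <- function(k = 1L, base = 2) {
  function(pairs) {
    mean(vapply(pairs, function(p) {
      te_core(p$a$symbol, p$b$symbol, k = k, base = base, seg = p$b$segment)$te -
        te_core(p$b$symbol, p$a$symbol, k = k, base = base, seg = p$a$segment)$te
    }, numeric(1)))
  }
}
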