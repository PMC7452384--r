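# Plug-in (maximum-likelihood) symbolic transfer entropy over the 4-symbol
# alphabet:
#
#   TE_{X->Y} = sum p(y_{t+1}, y_t^{(k)}, x_t^{(k)})
#               log[ p(y_{t+1} | y_t^{(k)}, x_t^{(k)}) / p(y_{t+1} | y_t^{(k)}) ]
#
# estimated from the joint histogram of (next symbol, k-history of the
# destination, k-history of the source), with the empty-cell convention
# 0 log 0 = 0. No bias correction is applied: significance is assessed
# against surrogates that share the same finite-sample bias.

ALPHABET_SIZE <- 4L

# core estimator on integer symbol vectors; seg masks transitions that
# would bridge a segment boundary (counts are pooled across segments).
# Returns list(te, n) with te in units of log base `base`.
te_core <- function(x, y, k = 1L, base = 2, seg = NULL) {
  if (is.null(seg) || seg[1L] == seg[length(seg)]) seg <- integer(0)
  .te_core_cpp(as.integer(x), as.integer(y), as.integer(k), base,
               as.integer(seg))
}

align_symbol_pair <- function(src, dst) {
  if (nrow(src) != nrow(dst) || any(abs(src$t - dst$t) > 1e-9))
    stop("alignment error: symbol series must share a common clock")
  if (!all(src$segment == dst$segment))
    stop("alignment error: segment structure differs between series")
  invisible(TRUE)
}

#' Symbolic transfer entropy between two symbol series
#'
#' Plug-in estimate of the directed information flow from `src` to `dst`:
#' how much the source's `k`-step symbol history reduces uncertainty about
#' the destination's next symbol beyond the destination's own history. Joint
#' counts are pooled across tracking segments without bridging gaps.
#'
#' @param src,dst aligned `symbol_series` objects (source and destination).
#' @param k history length (symbols); the default 1 keeps the 4^3-cell joint
#'   histogram well sampled at 10-minute sessions.
#' @param base logarithm base; 2 gives bits (default), `exp(1)` nats.
#' @param min_n joint-sample count below which the result is flagged `low_n`.
#' @return A `te_result`: list with `te`, `direction` (source id,
#'   destination id), `k`, `base`, `n_samples`, `low_n`.
#' @export
transfer_entropy <- function(src, dst, k = 1L, base = 2, min_n = 100L) {
  stopifnot(k >= 1L)
  align_symbol_pair(src, dst)
  res <- te_core(src$symbol, dst$symbol, k = as.integer(k), base = base,
                 seg = dst$segment)
  structure(list(te = res$te,
                 direction = c(source = attr(src, "subject_id"),
                               destination = attr(dst, "subject_id")),
                 k = as.integer(k), base = base,
                 n_samples = res$n, low_n = res$n < min_n),
            class = "te_result")
}

#' @export
print.te_result <- function(x, ...) {
  cat(sprintf("<te_result> TE(%s -> %s) = %.5g (base %g, k=%d, n=%d%s)\n",
              x$direction[["source"]], x$direction[["destination"]],
              x$te, x$base, x$k, x$n_samples,
              if (x$low_n) ", LOW N" else ""))
  invisible(x)
}

#' Net transfer entropy of a dyad
#'
#' `net_te = TE(small -> large) - TE(large -> small)`: positive values mean
#' the small subject's dynamics are more informative about the large
#' subject's future than vice versa (the small subject dominates the
#' interaction).
#'
#' @param small,large aligned `symbol_series` for the two subjects.
#' @inheritParams transfer_entropy
#' @return A `net_te_result`: list with `net_te`, and the two `te_result`
#'   components `small_to_large` and `large_to_small`.
#' @export
net_transfer_entropy <- function(small, large, k = 1L, base = 2, min_n = 100L) {
  sl <- transfer_entropy(small, large, k = k, base = base, min_n = min_n)
  ls <- transfer_entropy(large, small, k = k, base = base, min_n = min_n)
  structure(list(net_te = sl$te - ls$te,
                 small_to_large = sl, large_to_small = ls,
                 k = as.integer(k), base = base),
            class = "net_te_result")
}

#' @export
print.net_te_result <- function(x, ...) {
  cat(sprintf("<net_te_result> net TE = %.5g (S->L %.5g, L->S %.5g; base %g, k=%d)\n",
              x$net_te, x$small_to_large$te, x$large_to_small$te, x$base, x$k))
  invisible(x)
}

#' Serialize a TE result to a JSON record
#'
#' @param x a `te_result`.
#' @param pair_id,condition optional identifiers added to the record.
#' @return JSON string.
#' @export
te_to_json <- function(x, pair_id = NA, condition = NA) {
  jsonlite::toJSON(list(pair_id = pair_id, condition = condition,
                        direction = as.list(x$direction), te = x$te,
                        k = x$k, base = x$base, n = x$n_samples),
                   auto_unbox = TRUE, digits = NA, na = "null")
}
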