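#' Construct a trajectory object
#'
#' A `trajectory` is a data frame with columns `t` (seconds, strictly
#' increasing), `x`, `y` (arena-frame Cartesian coordinates, origin at the
#' lower-left corner of `arena_bounds`) and `segment` (integer label of the
#' contiguous tracking segment; see [fill_gaps()]). Session metadata travels
#' as attributes. Missing samples (tracking dropouts) are encoded as `NA`
#' in `x`/`y` and are resolved by [fill_gaps()] before analysis.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y numeric coordinates in arena length units; `NA` marks a
#'   tracking dropout.
#' @param subject_id identifier of the subject.
#' @param size_class `"small"` or `"large"`.
#' @param condition `"control"`, `"match"` or `"mismatch"`.
#' @param frame_rate sampling rate in Hz; if `NULL`, estimated as the
#'   reciprocal median time step.
#' @param arena_bounds numeric vector `c(xmin, xmax, ymin, ymax)` in the same
#'   length units as `x`/`y`, or `NULL` for unbounded.
#' @param segment optional integer vector of segment labels.
#' @return A `trajectory` object.
#' @export
trajectory <- function(t, x, y,
                       subject_id = NA_character_,
                       size_class = c("small", "large"),
                       condition = c("control", "match", "mismatch"),
                       frame_rate = NULL,
                       arena_bounds = NULL,
                       segment = NULL) {
  size_class <- match.arg(size_class)
  condition <- match.arg(condition)
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have equal length")
  if (length(t) < 3L) stop("insufficient data: need at least 3 samples")
  if (any(!is.finite(t))) stop("invalid time base: non-finite timestamps")
  if (any(diff(t) <= 0)) stop("invalid time base: timestamps must be strictly increasing")
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(diff(t))
  if (!is.finite(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  if (!is.null(arena_bounds)) {
    stopifnot(length(arena_bounds) == 4L)
    ok <- is.na(x) | (x >= arena_bounds[1] & x <= arena_bounds[2] &
                      y >= arena_bounds[3] & y <= arena_bounds[4])
    if (!all(ok))
      stop("positions outside arena_bounds")
  }
  if (is.null(segment)) segment <- rep.int(1L, length(t))
  out <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                    segment = as.integer(segment))
  structure(out,
            subject_id = subject_id, size_class = size_class,
            condition = condition, frame_rate = frame_rate,
            arena_bounds = arena_bounds,
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> subject=%s size=%s condition=%s n=%d frames @ %.3g Hz, %d segment(s)\n",
              attr(x, "subject_id"), attr(x, "size_class"), attr(x, "condition"),
              nrow(x), attr(x, "frame_rate"), length(unique(x$segment))))
  invisible(x)
}

traj_meta <- function(traj) {
  list(subject_id = attr(traj, "subject_id"),
       size_class = attr(traj, "size_class"),
       condition = attr(traj, "condition"),
       frame_rate = attr(traj, "frame_rate"),
       arena_bounds = attr(traj, "arena_bounds"))
}

#' Read a trajectory from delimited text
#'
#' Expects a header row and (by default) columns `t,x,y`; empty fields are
#' read as missing samples. Other column layouts (e.g. deposited datasets
#' with different column names) are handled through `col_map`. Metadata is
#' taken from a JSON or YAML sidecar file (same path with extension `.json`
#' or `.yaml`) or passed explicitly via `meta`.
#'
#' @param path CSV file path.
#' @param meta optional named list with `subject_id`, `size_class`,
#'   `condition`, `frame_rate`, `arena_bounds`; overrides the sidecar.
#' @param col_map named character vector mapping the canonical names
#'   `t`, `x`, `y` to the file's column names.
#' @param sep field separator.
#' @return A [trajectory()] object.
#' @export
read_trajectory <- function(path, meta = NULL,
                            col_map = c(t = "t", x = "x", y = "y"),
                            sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  for (nm in c("t", "x", "y"))
    if (!col_map[[nm]] %in% names(df))
      stop(sprintf("column '%s' (mapped to '%s') not found in %s",
                   col_map[[nm]], nm, path))
  if (is.null(meta)) {
    for (ext in c(".json", ".yaml", ".yml")) {
      side <- paste0(tools::file_path_sans_ext(path), ext)
      if (file.exists(side)) {
        meta <- if (ext == ".json") jsonlite::read_json(side, simplifyVector = TRUE)
                else yaml::read_yaml(side)
        break
      }
    }
  }
  if (is.null(meta)) meta <- list()
  trajectory(df[[col_map[["t"]]]], df[[col_map[["x"]]]], df[[col_map[["y"]]]],
             subject_id = meta$subject_id %||% NA_character_,
             size_class = meta$size_class %||% "small",
             condition = meta$condition %||% "control",
             frame_rate = meta$frame_rate,
             arena_bounds = unlist(meta$arena_bounds))
}

#' Write a trajectory and its metadata sidecar
#'
#' @param traj a [trajectory()].
#' @param path output CSV path; metadata goes to the same path with a
#'   `.json` extension. Missing samples are written as empty fields.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(traj[, c("t", "x", "y")], path, sep = ",", na = "",
                     row.names = FALSE, quote = FALSE)
  meta <- traj_meta(traj)
  meta$arena_bounds <- as.numeric(meta$arena_bounds)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Interpolate short tracking gaps and split long ones into segments
#'
#' Gaps (runs of `NA` positions) spanning at most `max_gap` seconds are
#' filled by linear interpolation of `x` and `y`; longer gaps split the
#' session into independently analysed segments. Downstream statistics pool
#' counts across segments without bridging the gap.
#'
#' @param traj a [trajectory()], possibly with `NA` positions.
#' @param max_gap longest gap (seconds) that may be interpolated.
#' @return A [trajectory()] with no missing positions and a `segment`
#'   column marking the independent pieces.
#' @export
fill_gaps <- function(traj, max_gap = 0.5) {
  miss <- is.na(traj$x) | is.na(traj$y)
  if (all(miss)) stop("empty trajectory: all samples missing")
  if (!any(miss)) return(traj)
  t <- traj$t
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !miss
  interp <- logical(length(t))
  split_after <- logical(length(t))   # segment break after this index
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    a <- starts[i]; b <- ends[i]
    # gap duration measured from last valid sample to next valid sample
    lo <- if (a > 1L) t[a - 1L] else t[a]
    hi <- if (b < length(t)) t[b + 1L] else t[b]
    interior <- a > 1L && b < length(t)
    if (interior && (hi - lo) <= max_gap) {
      interp[a:b] <- TRUE
    } else if (a > 1L) {
      split_after[a - 1L] <- TRUE
    }
  }
  ok <- keep | interp
  xs <- traj$x; ys <- traj$y
  if (any(interp)) {
    xs <- stats::approx(t[keep], traj$x[keep], xout = t, rule = 1)$y
    ys <- stats::approx(t[keep], traj$y[keep], xout = t, rule = 1)$y
    xs[keep] <- traj$x[keep]; ys[keep] <- traj$y[keep]
  }
  seg <- cumsum(c(1L, utils::head(split_after, -1L)))[ok]
  seg <- as.integer(factor(seg))      # renumber 1..n_segments
  trajectory(t[ok], xs[ok], ys[ok],
             subject_id = attr(traj, "subject_id"),
             size_class = attr(traj, "size_class"),
             condition = attr(traj, "condition"),
             frame_rate = attr(traj, "frame_rate"),
             arena_bounds = attr(traj, "arena_bounds"),
             segment = seg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
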