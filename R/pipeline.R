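# Study orchestration: run the full analysis over all sessions of a
# multi-condition study and emit machine-readable tables (per-condition
# transfer entropy and cross-correlation with surrogate quantiles and
# p-values, per-session similarity summaries).

#' Default analysis parameters of [run_study()]
#'
#' @param k transfer-entropy history length (symbols).
#' @param base logarithm base for entropies (2 = bits).
#' @param n_surrogates surrogate replicates per permutation test.
#' @param surrogate_method `"rotate"`, `"shuffle"` or `"cross_swap"`.
#' @param smooth_window kinematic smoothing window, seconds.
#' @param max_lag_lf lag search bound for leader-follower analysis, seconds.
#' @param max_lag_sim lag search bound for fish-replica similarity, seconds.
#' @param window similarity window length, seconds.
#' @param max_gap longest interpolated tracking gap, seconds.
#' @param seed master RNG seed.
#' @return Named list of parameters.
#' @export
study_params <- function(k = 1L, base = 2, n_surrogates = 20000L,
                         surrogate_method = "rotate", smooth_window = 0.1,
                         max_lag_lf = 0.2, max_lag_sim = 1, window = 20,
                         max_gap = 0.5, seed = 1L) {
  list(k = as.integer(k), base = base, n_surrogates = as.integer(n_surrogates),
       surrogate_method = surrogate_method, smooth_window = smooth_window,
       max_lag_lf = max_lag_lf, max_lag_sim = max_lag_sim, window = window,
       max_gap = max_gap, seed = as.integer(seed))
}

#' Assemble a study configuration
#'
#' Sessions may reference CSV files (`path_small`, `path_large`, optionally
#' `path_replica_small`/`path_replica_large`) or carry [trajectory()] objects
#' directly (`small`, `large`, `replica_small`, `replica_large`). A YAML
#' manifest written by [write_fixture_study()] can be loaded with
#' [read_study_config()].
#'
#' @param sessions list of session entries; each needs `pair_id` and
#'   `condition` plus trajectories or paths as above.
#' @param params analysis parameters from [study_params()].
#' @return A `study_config`.
#' @export
study_config <- function(sessions, params = study_params()) {
  if (length(sessions) == 0L) stop("no sessions")
  key <- vapply(sessions, function(s)
    paste(s$pair_id, s$condition, sep = "/"), character(1))
  if (anyDuplicated(key))
    stop("every pair_id must appear once per condition")
  structure(list(sessions = sessions, params = params),
            class = "study_config")
}

#' Load a study configuration from a YAML manifest
#'
#' @param path manifest path (see [write_fixture_study()]).
#' @param params analysis parameters from [study_params()].
#' @return A `study_config`.
#' @export
read_study_config <- function(path, params = study_params()) {
  man <- yaml::read_yaml(path)
  study_config(man$sessions, params)
}

# load trajectories for one session entry and derive kinematics + symbols
prepare_session <- function(s, params) {
  get_traj <- function(obj, path) {
    if (!is.null(obj)) obj
    else if (!is.null(path)) read_trajectory(path)
    else NULL
  }
  small <- get_traj(s$small, s$path_small)
  large <- get_traj(s$large, s$path_large)
  if (is.null(small) || is.null(large))
    stop(sprintf("session %s/%s: missing trajectories", s$pair_id, s$condition))
  small <- fill_gaps(small, params$max_gap)
  large <- fill_gaps(large, params$max_gap)
  ks <- compute_kinematics(small, smooth_window = params$smooth_window)
  kl <- compute_kinematics(large, smooth_window = params$smooth_window)
  list(pair_id = s$pair_id, condition = s$condition,
       traj_small = small, traj_large = large,
       kin_small = ks, kin_large = kl,
       sym_small = symbolize(ks), sym_large = symbolize(kl),
       replica_small = get_traj(s$replica_small, s$path_replica_small),
       replica_large = get_traj(s$replica_large, s$path_replica_large))
}

#' Transfer-entropy and cross-correlation analysis of one condition
#'
#' Computes, over the dyads of one condition, the trial-averaged transfer
#' entropy in both directions (one-tailed surrogate tests), the net transfer
#' entropy (two-tailed), and the speed / turn-rate leader-follower
#' cross-correlation summaries.
#'
#' @param prepared list of prepared sessions of one condition (internal
#'   structure produced by [run_study()]; each element carries `sym_small`,
#'   `sym_large`, `kin_small`, `kin_large`).
#' @param params analysis parameters from [study_params()].
#' @return Named list of `perm_test_result`s and `leader_follower_result`s.
#' @export
analyze_condition <- function(prepared, params = study_params()) {
  # light containers keep the surrogate loop allocation-free
  sym_pairs <- lapply(prepared, function(p)
    list(a = list(symbol = p$sym_small$symbol, segment = p$sym_small$segment),
         b = list(symbol = p$sym_large$symbol, segment = p$sym_large$segment)))
  kin_pairs <- lapply(prepared, function(p) list(small = p$kin_small, large = p$kin_large))
  set.seed(params$seed)
  te_sl <- permutation_test(stat_mean_te("ab", params$k, params$base),
                            sym_pairs, params$n_surrogates,
                            tail = "one_tailed_upper",
                            method = params$surrogate_method)
  te_ls <- permutation_test(stat_mean_te("ba", params$k, params$base),
                            sym_pairs, params$n_surrogates,
                            tail = "one_tailed_upper",
                            method = params$surrogate_method)
  net <- permutation_test(stat_mean_net_te(params$k, params$base),
                          sym_pairs, params$n_surrogates,
                          tail = "two_tailed",
                          method = params$surrogate_method)
  xc_speed <- leader_follower_summary(kin_pairs, "speed",
                                      max_lag = params$max_lag_lf,
                                      n_surrogates = params$n_surrogates,
                                      method = params$surrogate_method)
  xc_turn <- leader_follower_summary(kin_pairs, "turn_rate",
                                     max_lag = params$max_lag_lf,
                                     n_surrogates = params$n_surrogates,
                                     method = params$surrogate_method)
  list(te_small_to_large = te_sl, te_large_to_small = te_ls, net_te = net,
       xcorr_speed = xc_speed, xcorr_turn_rate = xc_turn,
       n_pairs = length(prepared))
}

#' Run the full study analysis
#'
#' Prepares every configured session (gap handling, kinematics,
#' symbolization), quarantining failures rather than dropping them silently;
#' then per condition computes the transfer-entropy and cross-correlation
#' summaries with surrogate tests, and per session with replica data the
#' trajectory similarity summary. Deterministic given the configuration and
#' `params$seed`.
#'
#' @param cfg a [study_config()].
#' @param out_dir optional output directory for the JSON report and flat CSV
#'   tables (see [write_study_report()]).
#' @param verbose emit one progress line per (session, stage).
#' @return A `study_report`: per-condition `te_table` and `xcorr_table` data
#'   frames, `similarity` per-session summaries, `quarantined` failures,
#'   `params`, and counts.
#' @export
run_study <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  params <- cfg$params
  prepared <- list(); quarantined <- list()
  for (s in cfg$sessions) {
    res <- tryCatch(prepare_session(s, params), error = function(e) e)
    if (inherits(res, "error")) {
      quarantined[[length(quarantined) + 1L]] <-
        list(pair_id = s$pair_id, condition = s$condition,
             error = conditionMessage(res))
      if (verbose) message(sprintf("[prepare] %s/%s QUARANTINED: %s",
                                   s$pair_id, s$condition, conditionMessage(res)))
    } else {
      prepared[[length(prepared) + 1L]] <- res
      if (verbose) message(sprintf("[prepare] %s/%s ok (%d frames)",
                                   s$pair_id, s$condition, nrow(res$kin_small)))
    }
  }
  if (length(prepared) == 0L) stop("no sessions could be prepared")

  conditions <- unique(vapply(prepared, `[[`, character(1), "condition"))
  by_cond <- lapply(conditions, function(cd)
    prepared[vapply(prepared, function(p) p$condition == cd, logical(1))])
  names(by_cond) <- conditions

  te_rows <- list(); xc_rows <- list(); analyses <- list()
  for (cd in conditions) {
    if (verbose) message(sprintf("[analyze] condition %s (%d pairs)",
                                 cd, length(by_cond[[cd]])))
    an <- analyze_condition(by_cond[[cd]], params)
    analyses[[cd]] <- an
    te_rows[[cd]] <- data.frame(
      condition = cd,
      te_small_to_large = an$te_small_to_large$observed,
      te_sl_q95 = an$te_small_to_large$quantile_95,
      te_sl_p = an$te_small_to_large$p_value,
      te_large_to_small = an$te_large_to_small$observed,
      te_ls_q95 = an$te_large_to_small$quantile_95,
      te_ls_p = an$te_large_to_small$p_value,
      net_te = an$net_te$observed,
      net_q2_5 = an$net_te$quantile_2_5,
      net_q97_5 = an$net_te$quantile_97_5,
      net_p = an$net_te$p_value,
      n_pairs = an$n_pairs)
    xc_rows[[cd]] <- data.frame(
      condition = cd,
      speed_corr = an$xcorr_speed$mean_corr,
      speed_corr_q95 = an$xcorr_speed$corr_test$quantile_95,
      speed_corr_p = an$xcorr_speed$corr_test$p_value,
      speed_lag = an$xcorr_speed$mean_lag,
      speed_lag_q2_5 = an$xcorr_speed$lag_test$quantile_2_5,
      speed_lag_q97_5 = an$xcorr_speed$lag_test$quantile_97_5,
      speed_lag_p = an$xcorr_speed$lag_test$p_value,
      turn_corr = an$xcorr_turn_rate$mean_corr,
      turn_corr_q95 = an$xcorr_turn_rate$corr_test$quantile_95,
      turn_corr_p = an$xcorr_turn_rate$corr_test$p_value,
      turn_lag = an$xcorr_turn_rate$mean_lag,
      turn_lag_q2_5 = an$xcorr_turn_rate$lag_test$quantile_2_5,
      turn_lag_q97_5 = an$xcorr_turn_rate$lag_test$quantile_97_5,
      turn_lag_p = an$xcorr_turn_rate$lag_test$p_value,
      n_pairs = an$n_pairs)
  }

  sim_rows <- list()
  for (p in prepared) {
    for (side in c("small", "large")) {
      rep_traj <- p[[paste0("replica_", side)]]
      if (is.null(rep_traj)) next
      fish <- p[[paste0("traj_", side)]]
      sim <- tryCatch(
        similarity_index(fish, rep_traj, window = params$window,
                         max_lag = params$max_lag_sim),
        error = function(e) e)
      if (inherits(sim, "error")) {
        quarantined[[length(quarantined) + 1L]] <-
          list(pair_id = p$pair_id, condition = p$condition,
               error = paste("similarity:", conditionMessage(sim)))
        next
      }
      sim_rows[[length(sim_rows) + 1L]] <- data.frame(
        pair_id = p$pair_id, condition = p$condition, subject = side,
        mean_similarity = sim$mean_similarity,
        mean_abs_lag = sim$mean_abs_lag,
        success_fraction = sim$success_fraction,
        coverage_fraction = sim$coverage_fraction)
    }
  }

  report <- structure(list(
    te_table = do.call(rbind, c(te_rows, list(make.row.names = FALSE))),
    xcorr_table = do.call(rbind, c(xc_rows, list(make.row.names = FALSE))),
    similarity = if (length(sim_rows)) do.call(rbind, sim_rows) else NULL,
    analyses = analyses,
    quarantined = quarantined,
    n_configured = length(cfg$sessions),
    n_analyzed = length(prepared),
    params = params),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d/%d sessions analyzed (%d quarantined)\n",
              x$n_analyzed, x$n_configured, length(x$quarantined)))
  cat("\nTransfer entropy (per condition):\n")
  print(x$te_table, row.names = FALSE, digits = 4)
  cat("\nCross-correlation (per condition):\n")
  print(x$xcorr_table, row.names = FALSE, digits = 4)
  if (!is.null(x$similarity)) {
    cat("\nSimilarity (per session, mean over subjects):\n")
    agg <- stats::aggregate(cbind(mean_similarity, mean_abs_lag,
                                  success_fraction, coverage_fraction)
                            ~ condition, data = x$similarity, FUN = mean)
    print(agg, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `te_table.csv` and `xcorr_table.csv` (rows = condition, columns =
#' statistic / surrogate quantiles / p-value), `similarity.csv` when replica
#' sessions exist, and `report.json` with everything including parameters
#' and quarantined sessions.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$te_table, file.path(dir, "te_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$xcorr_table, file.path(dir, "xcorr_table.csv"),
                   row.names = FALSE)
  if (!is.null(report$similarity))
    utils::write.csv(report$similarity, file.path(dir, "similarity.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(te_table = report$te_table, xcorr_table = report$xcorr_table,
         similarity = report$similarity, quarantined = report$quarantined,
         n_configured = report$n_configured, n_analyzed = report$n_analyzed,
         params = report$params),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", null = "null")
  invisible(dir)
}
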