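#' Default reaction-time analysis grid
#'
#' Right edges of consecutive 10-ms bins spanning 0-1700 ms, the range implied
#' by the RT inclusion filter.  Empirical CDFs, the race-model bound and all
#' difference curves are evaluated on this common grid.
#'
#' @param max_ms upper edge (ms).
#' @param bin_ms bin width (ms).
#' @return numeric vector of bin right edges.
#' @export
rt_grid <- function(max_ms = 1700, bin_ms = 10) {
  seq(bin_ms, max_ms, by = bin_ms)
}

#' Filter reaction times to the valid response window
#'
#' Removes trials with responses faster than 200 ms (anticipations) or slower
#' than 1700 ms; the boundary values themselves are retained.  Missed trials
#' (`rt_ms` is `NA`) are kept: they carry information for the hit rate and for
#' the CDF denominator.  No further outlier trimming is applied.
#'
#' @param trials trial tibble with an `rt_ms` column (ms).
#' @param min_ms,max_ms inclusive bounds of the valid window.
#' @return the filtered tibble.
#' @examples
#' filter_rts(tibble::tibble(rt_ms = c(150, 200, 900, 1700, 1701)))
#' @export
filter_rts <- function(trials, min_ms = 200, max_ms = 1700) {
  dplyr::filter(trials, is.na(.data$rt_ms) |
                  (.data$rt_ms >= min_ms & .data$rt_ms <= max_ms))
}

#' Hit rates per design cell
#'
#' The hit rate is the proportion of correct responses relative to the total
#' number of target stimuli in each (subject, intensity, stimulus type) cell.
#'
#' @param trials trial tibble with `is_target` and `correct` columns.
#' @param ... grouping columns (defaults to subject, intensity, stim_type).
#' @return tibble of grouping columns plus `n_target`, `n_correct`, `hit_rate`.
#' @export
hit_rates <- function(trials, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    groups <- rlang::quos(.data$subject, .data$group,
                          .data$intensity, .data$stim_type)
  }
  out <- trials |>
    dplyr::filter(.data$is_target) |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(
      n_target = dplyr::n(),
      n_correct = sum(.data$correct, na.rm = TRUE),
      hit_rate = .data$n_correct / .data$n_target,
      .groups = "drop"
    )
  if (nrow(out) == 0) stop("no target trials to compute hit rates from", call. = FALSE)
  out
}

#' Empirical response CDF on a fixed grid
#'
#' `p(t)` is the proportion of trials with a response at or before `t`.
#' Missed trials count in the denominator (they never respond), so a cell
#' with misses plateaus below 1.
#'
#' @param rts numeric RTs (ms) for responded trials.
#' @param n_total total target trials in the cell, misses included; defaults
#'   to `length(rts)`.
#' @param grid evaluation grid (bin right edges, ms).
#' @return tibble with columns `t_ms` and `p`.
#' @examples
#' empirical_cdf(c(300, 400), n_total = 2)[35, ]  # p = 0.5 at 350 ms
#' @export
empirical_cdf <- function(rts, n_total = length(rts), grid = rt_grid()) {
  rts <- rts[!is.na(rts)]
  if (n_total < 1) stop("no target trials in cell", call. = FALSE)
  p <- vapply(grid, function(t) sum(rts <= t) / n_total, numeric(1))
  tibble::tibble(t_ms = grid, p = p)
}

#' Per-subject empirical CDFs for every design cell
#'
#' @param trials filtered trial tibble.
#' @param grid common evaluation grid (ms).
#' @return tibble with `subject`, `group`, `intensity`, `stim_type`, `t_ms`, `p`.
#' @export
rt_cdfs <- function(trials, grid = rt_grid()) {
  trials |>
    dplyr::filter(.data$is_target) |>
    dplyr::group_by(.data$subject, .data$group, .data$intensity, .data$stim_type) |>
    dplyr::reframe(empirical_cdf(.data$rt_ms[!is.na(.data$rt_ms)],
                                 n_total = dplyr::n(), grid = grid))
}

#' Race-model (Miller) bound from two unimodal CDFs
#'
#' The independent race prediction for the redundant condition:
#' \deqn{P_{race}(t) = P_A(t) + P_V(t) - P_A(t) P_V(t).}
#' The bound dominates both unimodal CDFs pointwise and never exceeds 1.
#'
#' @param cdf_a,cdf_v tibbles with `t_ms` and `p` on the same grid.
#' @return tibble with `t_ms` and `p` (the race bound).
#' @examples
#' a <- empirical_cdf(c(300, 500), grid = c(400))
#' v <- empirical_cdf(c(350, 450), grid = c(400))
#' race_model_cdf(a, v)  # 0.5 + 0.5 - 0.25 = 0.75
#' @export
race_model_cdf <- function(cdf_a, cdf_v) {
  if (!isTRUE(all.equal(cdf_a$t_ms, cdf_v$t_ms))) {
    stop("unimodal CDFs are on different grids", call. = FALSE)
  }
  tibble::tibble(t_ms = cdf_a$t_ms, p = cdf_a$p + cdf_v$p - cdf_a$p * cdf_v$p)
}

#' Per-subject probability difference curves (AV minus race bound)
#'
#' For each subject and intensity the AV empirical CDF minus the race-model
#' bound built from that subject's unimodal CDFs, per 10-ms bin.  Positive
#' values mark behavior faster than any independent race can produce, i.e.
#' audio-visual integration.
#'
#' @param trials filtered trial tibble containing A, V and AV target trials.
#' @param grid common evaluation grid (ms).
#' @return tibble with `subject`, `group`, `intensity`, `t_ms`, `diff`.
#' @export
race_diff_curves <- function(trials, grid = rt_grid()) {
  cdfs <- rt_cdfs(trials, grid = grid)
  wide <- cdfs |>
    tidyr::pivot_wider(names_from = "stim_type", values_from = "p")
  missing <- setdiff(c("A", "V", "AV"), names(wide))
  if (length(missing) > 0) {
    stop("missing stimulus type(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  wide |>
    dplyr::mutate(race = .data$A + .data$V - .data$A * .data$V,
                  diff = .data$AV - .data$race) |>
    dplyr::select("subject", "group", "intensity", "t_ms", "diff")
}

#' Test for race-model violation per time bin
#'
#' At each bin a one-sample two-tailed t test of the subjects' difference
#' values against zero.  Bins that are significant (`p <= alpha`) *and* have a
#' positive mean form the integration window; maximal contiguous runs of such
#' bins are reported as ms intervals.  No correction across bins is applied.
#'
#' @param diff_curves tibble from [race_diff_curves()] (one intensity/group
#'   slice) with columns `subject`, `t_ms`, `diff`.
#' @param alpha per-bin significance level.
#' @return list with `bins` (tibble `t_ms`, `mean_diff`, `p`, `significant`)
#'   and `windows` (tibble `start_ms`, `end_ms`).
#' @export
violation_test <- function(diff_curves, alpha = 0.05) {
  n_sub <- dplyr::n_distinct(diff_curves$subject)
  if (n_sub < 2) stop("violation test needs at least 2 subjects", call. = FALSE)
  bins <- diff_curves |>
    dplyr::group_by(.data$t_ms) |>
    dplyr::summarise(mean_diff = mean(.data$diff),
                     p = one_sample_p(.data$diff),
                     .groups = "drop") |>
    dplyr::mutate(significant = .data$p <= alpha & .data$mean_diff > 0)
  r <- runs_of(bins$significant)
  windows <- tibble::tibble(start_ms = bins$t_ms[r$start],
                            end_ms = bins$t_ms[r$end])
  list(bins = bins, windows = windows)
}

#' Summarize race-model facilitation
#'
#' Averages the per-subject difference curves into the mean probability
#' difference curve and derives the standard integration indices: peak
#' benefit (maximum of the mean curve), group peak latency (time of that
#' maximum), per-subject peak latencies (for between-group tests), and the
#' positive AUC, i.e. the bin-sum of the positive part of the curve (of the
#' mean curve at group level; of each subject's own curve individually).
#'
#' @param diff_curves tibble with `subject`, `t_ms`, `diff` (one
#'   group/intensity slice).
#' @param alpha significance level passed to [violation_test()].
#' @return an object of class `race_model_result`.
#' @export
summarize_race <- function(diff_curves, alpha = 0.05) {
  if (nrow(diff_curves) == 0) stop("empty difference curves", call. = FALSE)
  vt <- violation_test(diff_curves, alpha = alpha)
  mean_curve <- vt$bins
  i_pk <- which.max(mean_curve$mean_diff)
  per_subject <- diff_curves |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      peak_benefit = max(.data$diff),
      peak_latency_ms = .data$t_ms[which.max(.data$diff)],
      auc = sum(pmax(.data$diff, 0)),
      .groups = "drop"
    )
  structure(
    list(
      mean_curve = mean_curve,
      windows = vt$windows,
      peak_benefit = mean_curve$mean_diff[i_pk],
      peak_latency_ms = mean_curve$t_ms[i_pk],
      auc = sum(pmax(mean_curve$mean_diff, 0)),
      per_subject = per_subject,
      alpha = alpha,
      n_subjects = dplyr::n_distinct(diff_curves$subject)
    ),
    class = "race_model_result"
  )
}

#' @export
print.race_model_result <- function(x, ...) {
  cat("<race_model_result>\n")
  cat(sprintf("  subjects: %d, alpha = %g\n", x$n_subjects, x$alpha))
  cat(sprintf("  peak benefit %.3f at %g ms; positive AUC %.3f\n",
              x$peak_benefit, x$peak_latency_ms, x$auc))
  if (nrow(x$windows) > 0) {
    cat("  integration window(s):",
        paste(sprintf("%g-%g ms", x$windows$start_ms, x$windows$end_ms),
              collapse = ", "), "\n")
  } else {
    cat("  no significant integration window\n")
  }
  invisible(x)
}

#' Full race-model analysis of a trial table
#'
#' Convenience wrapper: filters RTs, builds per-subject difference curves and
#' summarizes each (group, intensity) slice separately.
#'
#' @param trials raw trial tibble.
#' @param grid evaluation grid (ms).
#' @param alpha per-bin significance level.
#' @param min_ms,max_ms RT inclusion bounds passed to [filter_rts()].
#' @return tibble with one row per (group, intensity) and a list-column
#'   `result` of `race_model_result` objects, plus unnested summary columns.
#' @export
race_model_analysis <- function(trials, grid = rt_grid(), alpha = 0.05,
                                min_ms = 200, max_ms = 1700) {
  diffs <- trials |>
    filter_rts(min_ms = min_ms, max_ms = max_ms) |>
    race_diff_curves(grid = grid)
  diffs |>
    dplyr::group_by(.data$group, .data$intensity) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(
      result = purrr::map(.data$data, summarize_race, alpha = alpha),
      peak_benefit = purrr::map_dbl(.data$result, "peak_benefit"),
      peak_latency_ms = purrr::map_dbl(.data$result, "peak_latency_ms"),
      auc = purrr::map_dbl(.data$result, "auc")
    ) |>
    dplyr::select(-"data")
}
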