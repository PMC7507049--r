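#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a race-model result
#'
#' One row per time bin of the mean probability difference curve.
#'
#' @param x a `race_model_result`.
#' @param ... unused.
#' @return tibble with `t_ms`, `mean_diff`, `p`, `significant`.
#' @export
tidy.race_model_result <- function(x, ...) {
  x$mean_curve
}

#' @rdname tidy.race_model_result
#' @return for `glance`: a one-row tibble with the scalar integration
#'   indices and the overall window span.
#' @export
glance.race_model_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    peak_benefit = x$peak_benefit,
    peak_latency_ms = x$peak_latency_ms,
    auc = x$auc,
    n_windows = nrow(x$windows),
    window_start_ms = if (nrow(x$windows)) min(x$windows$start_ms) else NA_real_,
    window_end_ms = if (nrow(x$windows)) max(x$windows$end_ms) else NA_real_
  )
}

#' Tidy a pointwise group comparison
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return tibble with one row per time sample (`time_ms`, `t`, `p`,
#'   `significant`).
#' @export
tidy.group_comparison <- function(x, ...) {
  x$samples
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    groups = paste(x$groups, collapse = " vs "),
    tail = x$tail, alpha = x$alpha,
    n_samples = nrow(x$samples),
    n_significant = sum(x$samples$significant),
    n_windows = nrow(x$windows)
  )
}

#' Tidy a mixed-ANOVA result
#'
#' @param x a `mixed_anova_result`.
#' @param ... unused.
#' @return the per-effect tibble (F, dfs, uncorrected and GG-corrected p,
#'   partial eta squared).
#' @export
tidy.mixed_anova_result <- function(x, ...) {
  x$effects
}

#' @rdname tidy.mixed_anova_result
#' @export
glance.mixed_anova_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_effects = nrow(x$effects),
    n_significant = sum(x$effects$p_gg <= 0.05)
  )
}
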