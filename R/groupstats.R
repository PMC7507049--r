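#' Pointwise two-sample t tests on connectivity time series
#'
#' Compares two groups of per-subject time series sample by sample with
#' independent two-sample t tests (Welch by default), one-tailed in an
#' explicitly stated direction.  Samples with `p <= alpha` form the
#' significance mask; maximal contiguous runs of significant samples are
#' reported as ms windows.  No correction across time points is applied:
#' windows are descriptive localizations, not family-wise claims.
#'
#' @param data tibble with one row per (subject, time point): columns
#'   `subject`, `group`, `time_ms` and the value column.
#' @param value name of the value column (default `"mean_pli"`).
#' @param groups length-2 character: the two group labels; the alternative is
#'   stated as `groups[1]` versus `groups[2]`.
#' @param tail `"greater"` (first group larger), `"less"`, or `"two.sided"`.
#' @param alpha per-sample significance level.
#' @param var_equal passed to [stats::t.test()].
#' @return an object of class `group_comparison`: list with `samples`
#'   (tibble `time_ms`, `t`, `p`, `significant`), `windows` (tibble
#'   `start_ms`, `end_ms`), plus the test metadata.
#' @export
pointwise_ttest <- function(data, value = "mean_pli",
                            groups = c("elderly", "younger"),
                            tail = c("greater", "less", "two.sided"),
                            alpha = 0.05, var_equal = FALSE) {
  tail <- match.arg(tail)
  stopifnot(all(c("subject", "group", "time_ms", value) %in% names(data)))
  a <- dplyr::filter(data, .data$group == groups[1])
  b <- dplyr::filter(data, .data$group == groups[2])
  if (dplyr::n_distinct(a$subject) < 2 || dplyr::n_distinct(b$subject) < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  ta <- sort(unique(a$time_ms)); tb <- sort(unique(b$time_ms))
  if (!isTRUE(all.equal(ta, tb))) stop("groups have mismatched time axes", call. = FALSE)

  wa <- tidyr::pivot_wider(a[, c("subject", "time_ms", value)],
                           names_from = "subject",
                           values_from = dplyr::all_of(value))
  wb <- tidyr::pivot_wider(b[, c("subject", "time_ms", value)],
                           names_from = "subject",
                           values_from = dplyr::all_of(value))
  wa <- wa[order(wa$time_ms), ]; wb <- wb[order(wb$time_ms), ]
  ma <- as.matrix(wa[, -1]); mb <- as.matrix(wb[, -1])

  res <- purrr::map(seq_along(ta), function(k) {
    tt <- stats::t.test(ma[k, ], mb[k, ], alternative = tail,
                        var.equal = var_equal)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  samples <- tibble::tibble(
    time_ms = ta,
    t = purrr::map_dbl(res, "t"),
    p = purrr::map_dbl(res, "p")
  ) |>
    dplyr::mutate(significant = .data$p <= alpha)
  r <- runs_of(samples$significant)
  windows <- tibble::tibble(start_ms = samples$time_ms[r$start],
                            end_ms = samples$time_ms[r$end])
  structure(
    list(samples = samples, windows = windows, groups = groups,
         tail = tail, alpha = alpha, value = value),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s (%s, alpha = %g) on %s\n",
              x$groups[1], x$groups[2], x$tail, x$alpha, x$value))
  cat(sprintf("  %d / %d samples significant\n",
              sum(x$samples$significant), nrow(x$samples)))
  if (nrow(x$windows) > 0) {
    cat("  windows:", paste(sprintf("%g-%g ms", x$windows$start_ms,
                                    x$windows$end_ms), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Average a time series inside a time window
#'
#' Arithmetic mean of the value column over samples falling inside the closed
#' interval `window`, per group of identifying columns — used to reduce each
#' subject's connectivity series to one scalar per condition before the
#' factorial ANOVA.
#'
#' @param data tibble with a `time_ms` column and the value column.
#' @param window length-2 numeric, ms interval (closed).
#' @param value name of the value column.
#' @param ... grouping columns (tidy-select); defaults to every column except
#'   `time_ms` and the value column.
#' @return tibble of grouping columns plus the window mean (same value name).
#' @export
window_mean <- function(data, window, value = "mean_pli", ...) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  rng <- range(data$time_ms)
  if (window[1] < rng[1] || window[2] > rng[2]) {
    stop(sprintf("window %g-%g ms lies outside the time axis %g-%g ms",
                 window[1], window[2], rng[1], rng[2]), call. = FALSE)
  }
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    keep <- setdiff(names(data), c("time_ms", value))
    groups <- rlang::syms(keep)
  }
  data |>
    dplyr::filter(.data$time_ms >= window[1], .data$time_ms <= window[2]) |>
    dplyr::group_by(!!!groups) |>
    dplyr::summarise(!!value := mean(.data[[value]]), .groups = "drop")
}

#' Mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' Factorial ANOVA for the standard 2 group x 2 intensity x 3 stimulus-type
#' design: one between-subject factor and two crossed within-subject factors
#' on a balanced complete design.  Within-subject effects carry
#' Greenhouse-Geisser epsilon and GG-corrected degrees of freedom and
#' p-values (epsilon is 1, hence no correction, for 1-df effects).  Effect
#' sizes are partial eta squared, \eqn{SS_{eff}/(SS_{eff}+SS_{err})}.  Post
#' hoc pairwise comparisons (two-sample t for the between factor, paired t
#' across subject-level means for within factors) are Bonferroni-adjusted
#' within each family.
#'
#' @param data tibble with one row per subject x within-cell: columns
#'   `subject`, the between column, the within columns, and the value column.
#' @param value name of the dependent-variable column.
#' @param between name of the between-subjects factor column.
#' @param within character vector naming the within-subject factor columns.
#' @return an object of class `mixed_anova_result` with elements `effects`
#'   (tibble: effect, df1, df2, F, p, pes, gg_epsilon, df1_gg, df2_gg, p_gg)
#'   and `posthoc` (tibble of pairwise comparisons).
#' @export
mixed_anova <- function(data, value, between = "group",
                        within = c("intensity", "stim_type")) {
  stopifnot(all(c("subject", value, between, within) %in% names(data)))
  cells <- data |>
    dplyr::count(.data$subject, dplyr::across(dplyr::all_of(within)))
  if (any(cells$n != 1)) stop("expected exactly one value per subject x within cell",
                              call. = FALSE)
  n_cells <- prod(purrr::map_int(within, ~ dplyr::n_distinct(data[[.x]])))
  per_subj <- dplyr::count(data, .data$subject)
  if (any(per_subj$n != n_cells)) stop("design has missing cells", call. = FALSE)

  # wide subject x within-cell response matrix for the mlm route
  wide <- data |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c(between, within)), as.character)) |>
    tidyr::pivot_wider(id_cols = c("subject", dplyr::all_of(between)),
                       names_from = dplyr::all_of(within),
                       values_from = dplyr::all_of(value),
                       names_sep = ".")
  if (dplyr::n_distinct(wide[[between]]) < 2) {
    stop("need at least 2 levels of the between factor", call. = FALSE)
  }
  resp_cols <- setdiff(names(wide), c("subject", between))
  Y <- as.matrix(wide[, resp_cols])
  idata <- do.call(rbind, strsplit(resp_cols, ".", fixed = TRUE))
  idata <- as.data.frame(idata, stringsAsFactors = FALSE)
  names(idata) <- within
  idata[] <- lapply(idata, factor)
  grp <- factor(wide[[between]])

  # sum-to-zero contrasts so the type-3 decomposition matches the balanced
  # error-strata ANOVA
  mod <- stats::lm(Y ~ grp, contrasts = list(grp = "contr.sum"))
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  aov_res <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  s <- withCallingHandlers(
    summary(aov_res, multivariate = FALSE),
    # Huynh-Feldt epsilon capping is routine and not actionable here
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  uni <- s$univariate.tests
  adj <- s$pval.adjustments

  eff_names <- rownames(uni)
  keep <- eff_names != "(Intercept)"
  uni <- uni[keep, , drop = FALSE]
  eff_names <- eff_names[keep]
  # car names effects with the model's internal between label; restore ours
  pretty <- gsub("\\bgrp\\b", between, eff_names)

  gg_eps <- rep(1, length(eff_names))
  p_gg <- uni[, "Pr(>F)"]
  if (!is.null(adj) && nrow(adj) > 0) {
    m <- match(rownames(adj), eff_names)
    gg_eps[m] <- adj[, "GG eps"]
    p_gg[m] <- adj[, "Pr(>F[GG])"]
  }
  effects <- tibble::tibble(
    effect = unname(pretty),
    df1 = unname(uni[, "num Df"]), df2 = unname(uni[, "den Df"]),
    F = unname(uni[, "F value"]), p = unname(uni[, "Pr(>F)"]),
    pes = unname(uni[, "Sum Sq"] / (uni[, "Sum Sq"] + uni[, "Error SS"])),
    gg_epsilon = unname(gg_eps),
    df1_gg = unname(uni[, "num Df"] * gg_eps),
    df2_gg = unname(uni[, "den Df"] * gg_eps),
    p_gg = unname(p_gg)
  )

  posthoc <- mixed_anova_posthoc(data, value, between, within)
  structure(
    list(effects = effects, posthoc = posthoc, value = value,
         between = between, within = within,
         n_subjects = nrow(wide), car_fit = aov_res),
    class = "mixed_anova_result"
  )
}

# All pairwise level comparisons per factor, Bonferroni within each factor.
# Within factors: paired t on subject-level marginal means; between factor:
# two-sample t on subject means.
mixed_anova_posthoc <- function(data, value, between, within) {
  one_factor <- function(fac) {
    by <- unique(c("subject", between, fac))
    marg <- data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(m = mean(.data[[value]]), .groups = "drop")
    levs <- sort(unique(as.character(marg[[fac]])))
    prs <- utils::combn(levs, 2, simplify = FALSE)
    rows <- purrr::map(prs, function(pr) {
      if (fac == between) {
        x <- marg$m[marg[[fac]] == pr[1]]
        y <- marg$m[marg[[fac]] == pr[2]]
        tt <- stats::t.test(x, y)
      } else {
        w <- marg |>
          dplyr::filter(.data[[fac]] %in% pr) |>
          tidyr::pivot_wider(id_cols = "subject", names_from = dplyr::all_of(fac),
                             values_from = "m")
        tt <- stats::t.test(w[[pr[1]]], w[[pr[2]]], paired = TRUE)
      }
      tibble::tibble(factor = fac, level_1 = pr[1], level_2 = pr[2],
                     estimate = unname(tt$estimate[1]) -
                       ifelse(fac == between, unname(tt$estimate[2]), 0),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value)
    })
    out <- dplyr::bind_rows(rows)
    out$p_adj <- pmin(1, out$p * nrow(out))  # Bonferroni within the factor
    out
  }
  facs <- c(between, within)
  dplyr::bind_rows(purrr::map(facs, one_factor))
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat(sprintf("<mixed_anova_result> %s ~ %s x (%s), n = %d subjects\n",
              x$value, x$between, paste(x$within, collapse = " x "),
              x$n_subjects))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-28s F(%.2f, %.2f) = %7.3f, p = %.4f, pes = %.3f\n",
                eff$effect[i], eff$df1_gg[i], eff$df2_gg[i],
                eff$F[i], eff$p_gg[i], eff$pes[i]))
  }
  invisible(x)
}

#' Group comparison of global connectivity with window averaging
#'
#' Convenience wrapper over [pointwise_ttest()] and [window_mean()]: locates
#' the significant window(s) for one band and returns both the pointwise
#' comparison and the per-subject window-averaged PLI (over the union span of
#' the detected windows, or a caller-supplied window).
#'
#' @param data tibble with `subject`, `group`, `time_ms`, `mean_pli` (plus
#'   any condition columns, carried through to the window means).
#' @param tail,groups,alpha passed to [pointwise_ttest()].
#' @param window optional length-2 ms interval; when `NULL`, the span from
#'   the first to the last significant sample is used (error if none).
#' @return list with `comparison` (a `group_comparison`) and `window_means`
#'   (tibble) and `window` (the interval used).
#' @export
group_compare <- function(data, tail = "greater",
                          groups = c("elderly", "younger"),
                          alpha = 0.05, window = NULL) {
  cmp <- pointwise_ttest(data, groups = groups, tail = tail, alpha = alpha)
  if (is.null(window)) {
    if (nrow(cmp$windows) == 0) {
      stop("no significant window detected; supply `window` explicitly",
           call. = FALSE)
    }
    window <- c(min(cmp$windows$start_ms), max(cmp$windows$end_ms))
  }
  wm <- window_mean(data, window)
  list(comparison = cmp, window_means = wm, window = window)
}
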