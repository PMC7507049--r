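make_series <- function(n_per_group, n_time = 20, shift_fun = NULL, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(c("elderly", "younger"), function(g) {
    purrr::map_dfr(seq_len(n_per_group), function(s) {
      mu <- if (is.null(shift_fun)) 0 else shift_fun(g, seq_len(n_time))
      tibble::tibble(subject = paste0(g, s), group = g,
                     time_ms = 4 * (seq_len(n_time) - 1),
                     mean_pli = rnorm(n_time, 0.2, 0.03) + mu)
    })
  })
}

test_that("pointwise t-test validates its inputs", {
  d <- make_series(1)
  expect_error(pointwise_ttest(d), "2 subjects")
  d2 <- make_series(3)
  bad <- dplyr::mutate(d2, time_ms = ifelse(group == "elderly", time_ms, time_ms + 1))
  expect_error(pointwise_ttest(bad), "time axes")
})

test_that("an injected group offset is localized in time", {
  shift <- function(g, idx) if (g == "elderly") ifelse(idx >= 8 & idx <= 14, 0.15, 0) else 0
  d <- make_series(8, shift_fun = shift, seed = 42)
  cmp <- pointwise_ttest(d, tail = "greater")
  expect_s3_class(cmp, "group_comparison")
  w <- cmp$windows
  expect_gt(nrow(w), 0)
  # detected window overlaps the injected samples (idx 8..14 -> 28..52 ms)
  expect_true(any(w$start_ms <= 52 & w$end_ms >= 28))
  # the reverse tail finds nothing
  cmp_rev <- pointwise_ttest(d, tail = "less")
  expect_lt(sum(cmp_rev$samples$significant), 3)
})

test_that("window mean averages the closed interval and is linear", {
  d <- tibble::tibble(subject = "s1", group = "g", time_ms = seq(0, 96, 4),
                      mean_pli = seq_along(seq(0, 96, 4)))
  const <- dplyr::mutate(d, mean_pli = 0.42)
  expect_equal(window_mean(const, c(0, 96))$mean_pli, 0.42)
  expect_equal(window_mean(d, c(40, 40))$mean_pli, d$mean_pli[d$time_ms == 40])
  # brute-force enumeration oracle
  w <- c(12, 60)
  brute <- mean(d$mean_pli[d$time_ms >= 12 & d$time_ms <= 60])
  expect_equal(window_mean(d, w)$mean_pli, brute)
  # linearity
  lin <- dplyr::mutate(d, mean_pli = 3 * mean_pli + 2)
  expect_equal(window_mean(lin, w)$mean_pli, 3 * brute + 2)
  expect_error(window_mean(d, c(-10, 50)), "outside")
})

test_that("mixed ANOVA F values match an independent error-strata fit", {
  set.seed(31)
  Y <- matrix(rnorm(36, 10), 6, 6)
  Y[4:6, ] <- Y[4:6, ] + 1.5  # group shift
  Y[, 4:6] <- Y[, 4:6] + 0.8  # intensity shift
  d <- anova_table(Y, rep(c("elderly", "younger"), each = 3))

  res <- mixed_anova(d, value = "value")
  eff <- res$effects

  fit <- stats::aov(value ~ group * intensity * stim_type +
                      Error(subject / (intensity * stim_type)),
                    data = dplyr::mutate(d, dplyr::across(
                      c(group, intensity, stim_type), factor)))
  s <- summary(fit)
  f_of <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  expect_equal(eff$F[eff$effect == "group"],
               f_of("Error: subject", "group"), tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "intensity"],
               f_of("Error: subject:intensity", "intensity"), tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "stim_type"],
               f_of("Error: subject:stim_type", "stim_type"), tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "group:intensity"],
               f_of("Error: subject:intensity", "group:intensity"), tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "group:stim_type"],
               f_of("Error: subject:stim_type", "group:stim_type"), tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "intensity:stim_type"],
               f_of("Error: subject:intensity:stim_type", "intensity:stim_type"),
               tolerance = 1e-8)
  expect_equal(eff$F[eff$effect == "group:intensity:stim_type"],
               f_of("Error: subject:intensity:stim_type",
                    "group:intensity:stim_type"), tolerance = 1e-8)
})

test_that("mixed ANOVA reports sane epsilons, effect sizes and post hocs", {
  set.seed(52)
  Y <- matrix(rnorm(60, 5), 10, 6)
  d <- anova_table(Y, rep(c("elderly", "younger"), each = 5))
  res <- mixed_anova(d, value = "value")
  eff <- res$effects
  # 1-df within effects carry no sphericity correction
  expect_equal(eff$gg_epsilon[eff$effect == "intensity"], 1)
  expect_equal(eff$p_gg[eff$effect == "intensity"],
               eff$p[eff$effect == "intensity"])
  # 3-level effects: epsilon in (1/2, 1]
  eps3 <- eff$gg_epsilon[eff$effect == "stim_type"]
  expect_gt(eps3, 0.5)
  expect_lte(eps3, 1)
  expect_true(all(eff$pes >= 0 & eff$pes <= 1))
  # post hoc: 1 group pair + 1 intensity pair + 3 stimulus pairs
  expect_equal(nrow(res$posthoc), 5)
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p - 1e-12))

  # a pure group shift is detected by the group post hoc
  Y2 <- Y; Y2[1:5, ] <- Y2[1:5, ] + 3
  res2 <- mixed_anova(anova_table(Y2, rep(c("elderly", "younger"), each = 5)),
                      value = "value")
  expect_lt(res2$effects$p_gg[res2$effects$effect == "group"], 0.01)
})

test_that("mixed ANOVA rejects incomplete designs", {
  set.seed(1)
  Y <- matrix(rnorm(36), 6, 6)
  d <- anova_table(Y, rep(c("elderly", "younger"), each = 3))
  expect_error(mixed_anova(d[-1, ], value = "value"), "missing cells")
  dup <- dplyr::bind_rows(d, d[1, ])
  expect_error(mixed_anova(dup, value = "value"), "one value per")
})

test_that("group_compare averages PLI inside the detected window", {
  shift <- function(g, idx) if (g == "elderly") ifelse(idx >= 5 & idx <= 15, 0.2, 0) else 0
  d <- make_series(8, shift_fun = shift, seed = 11)
  gcp <- group_compare(d, tail = "greater")
  expect_true(all(c("comparison", "window_means", "window") %in% names(gcp)))
  expect_equal(nrow(gcp$window_means), 16)  # one scalar per subject
  m <- gcp$window_means |>
    dplyr::group_by(group) |>
    dplyr::summarise(m = mean(mean_pli))
  expect_gt(m$m[m$group == "elderly"], m$m[m$group == "younger"])
})
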