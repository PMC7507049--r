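# racepli

Race-model analysis of audio–visual reaction times and phase-lag-index EEG
connectivity, with synthetic ground-truth generators for both.

## The problem

Ageing studies of multisensory integration ask two linked questions:

1. **Behavior.** Do older adults integrate auditory and visual information
   more (or later) than younger adults? Faster responses to combined
   audio–visual (AV) targets are not evidence by themselves — two
   independent racing channels already predict facilitation. The test is
   whether the empirical AV response CDF exceeds the independent race
   (Miller) bound
   `P(A≤t) + P(V≤t) − P(A≤t)·P(V≤t)`,
   evaluated per subject in 10-ms bins. The package computes the per-bin
   probability difference curves, tests them across subjects, and reports
   the standard indices: the AVI time window (contiguous bins with a
   significant positive difference), peak benefit, peak latency, and the
   positive AUC.

2. **Brain connectivity.** Do the groups differ in global functional
   connectivity while processing the same stimuli? From channels × time ×
   trials EEG epochs the package extracts instantaneous phase with a
   200-ms-Hamming windowed Fourier transform at 1-Hz steps and computes the
   phase lag index per channel pair,
   `PLI(t,f) = | mean_n sign(Δφ_n(t,f)) |`,
   a statistic insensitive to zero-lag (volume-conducted) coupling. Band
   averages (theta/alpha/beta/gamma) give 28×28 adjacency tensors; the
   network mean over all 378 channel pairs gives a global connectivity time
   series per subject, compared between groups with pointwise one-tailed t
   tests, window-averaged, and submitted to a 2 group × 2 intensity × 3
   stimulus-type mixed ANOVA with Greenhouse–Geisser correction.

Because real data of this kind are rarely shareable, the package ships
synthetic generators with recorded ground truth: ex-Gaussian RTs with a
race architecture and a tunable coactivation gain, and coupled-oscillator
EEG with von Mises phase jitter controlling coupling strength. Every
analysis stage is validated by parameter recovery against these generators.

## Worked example

```r
library(racepli)
library(dplyr)

# --- behavior: simulate a cohort with genuine coactivation and analyze it
trials <- simulate_rt_trials(
  rt_gen_spec(coactivation_gain = 0.12, seed = 42), n_subjects_per_group = 20)

res <- race_model_analysis(trials)
res |> select(group, intensity, peak_benefit, peak_latency_ms, auc)
#> # A tibble: 4 × 5
#>   group   intensity peak_benefit peak_latency_ms   auc
#>   <chr>   <chr>            <dbl>           <dbl> <dbl>
#> 1 elderly high             0.404             470  5.86
#> 2 elderly low              0.481             510  6.90
#> 3 younger high             0.365             400  5.21
#> 4 younger low              0.397             430  5.11

print(res$result[[1]])
#> <race_model_result>
#>   subjects: 20, alpha = 0.05
#>   peak benefit 0.404 at 470 ms; positive AUC 5.863
#>   integration window(s): 340-640 ms
```

The peak benefit is the maximum of the mean AV-minus-race probability
difference curve; the window is the contiguous range of 10-ms bins where
that difference is significantly positive across subjects; the positive AUC
sums the positive part of the curve over bins (unitless). `tidy()` returns
the per-bin curve, `glance()` the scalar summary, and `autoplot()` draws the
curve with the window shaded.

```r
# --- EEG: two cohorts differing only in theta-band phase coupling
conn <- bind_rows(
  cohort_connectivity(theta_contrast_spec(40,  seed = 1), 10, "elderly"),
  cohort_connectivity(theta_contrast_spec(0.2, seed = 2), 10, "younger"))

cmp <- pointwise_ttest(filter(conn, band == "theta"), tail = "greater")
cmp$windows
#> # A tibble: 4 × 2
#>   start_ms end_ms
#>      <dbl>  <dbl>
#> 1      -88    -72
#> 2       60     68
#> 3       84    328
#> 4      416    428
```

The main detected window (84–328 ms) recovers the interval in which the
generator locked the oscillators (100–300 ms), smeared by the 200-ms
analysis window; isolated single-bin runs are reported as-is, since no
minimum-duration rule is imposed. `window_mean()` then reduces each subject to one scalar per
condition and `mixed_anova()` runs the factorial comparison.

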