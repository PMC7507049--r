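---
title: "Methods: race-model integration analysis and PLI connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: race-model integration analysis and PLI connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racepli)
library(dplyr)
```

`racepli` implements a two-track analysis of multisensory ageing experiments:
a behavioral track that quantifies audio--visual integration (AVI) from
redundant-signals reaction times, and an electrophysiological track that
quantifies global functional brain connectivity from multichannel EEG via the
phase lag index (PLI), with pointwise group statistics that localize age
differences in time. Both tracks are driven by synthetic generators with
known ground truth, so every stage of the pipeline can be validated by
parameter recovery.

## Behavioral track: the race model

In a redundant-signals design, subjects respond to auditory (A), visual (V)
or combined audio--visual (AV) targets. Faster AV responses alone do not
demonstrate integration: two independent racing channels already predict a
statistical facilitation. The race-model (Miller) bound on the AV response
CDF is

$$P_{\mathrm{race}}(t) = P_A(t) + P_V(t) - P_A(t)\,P_V(t),$$

the distribution of the winner of two independent channels. Empirical AV
CDFs exceeding this bound indicate genuine coactivation.

The pipeline is:

1. **RT filter.** Responses faster than 200 ms or slower than 1700 ms are
   excluded; the boundary values are kept (the bounds are read as a closed
   valid interval). No further outlier trimming is done. Missed trials are
   retained as response-less rows.
2. **Empirical CDFs** per subject and condition on a common grid of 10-ms
   bins spanning 0--1700 ms (right-edge evaluation; the ceiling matches the
   RT filter). Misses count in the denominator, so a cell with misses
   plateaus below 1. This miss-in-denominator convention is a documented
   choice (`n_total` in `empirical_cdf()` makes it switchable).
3. **Difference curves.** Per subject: AV CDF minus the race bound built
   from that subject's own unimodal CDFs.
4. **Violation test.** Per 10-ms bin, a one-sample two-tailed t test of the
   subject difference values against zero; bins with $p \le .05$ *and*
   positive mean form the AVI window(s), reported as maximal contiguous
   runs. The positivity requirement operationalizes "significantly greater":
   a two-tailed test alone would also flag bins where the bound
   significantly *exceeds* the AV CDF. No correction across bins is applied.
5. **Summary indices.** Peak benefit (maximum of the across-subject mean
   difference curve), peak latency (time of that maximum), per-subject peak
   latencies (for between-group tests), and the positive AUC, computed as
   the plain bin-sum of the positive part of the difference curve. The
   bin-sum convention (rather than a probability-by-ms area) keeps the index
   unitless and on the scale commonly reported for this paradigm; it equals
   the trapezoid-free Riemann sum divided by the bin width.

### What the RT generator emulates

`rt_gen_spec()` / `simulate_rt_trials()` draw unimodal RTs from ex-Gaussian
distributions, the standard unimodal RT phenomenology (Gaussian perceptual
plus exponential decision stage). Defaults ($\mu_A = 420$, $\sigma_A = 50$,
$\tau_A = 110$ ms; $\mu_V = 390$, $\sigma_V = 45$, $\tau_V = 100$ ms) give
realistic unimodal means near 500--530 ms. AV trials are built
architecturally, not distributionally:

$$RT_{AV} = (1 - g)\,\min(A', V'),$$

with fresh draws $A', V'$. At coactivation gain $g = 0$ this *is* an
independent race, so the empirical AV CDF equals the race bound in
expectation at every bin -- the generator's null is exactly the model's
null. A single parameter $g$ then produces controllable, monotone violations.
Group slowing (default 80 ms) shifts every modality additively for the
elderly group; intensity slowing (default 30 ms) does the same for
low-intensity stimuli, emulating slower processing of weaker stimuli.
Misses occur independently at `miss_rate` and are uninformative (no RT,
counted as incorrect).

What it does **not** emulate: commission errors or responses to nontargets,
sequential effects, fatigue drifts, or subject-level parameter
heterogeneity beyond the additive group shift. Passing tests therefore show
that the analysis recovers architectural facilitation and additive slowing,
not that it is robust to every real-world RT pathology.

### Calibration facts worth knowing

Under the pure-race null the pointwise t test is well calibrated only in
"central" bins where the mean AV CDF is away from 0 and 1. In sparse tail
bins a single subject with a non-zero difference yields $|t| = \sqrt{n}$ and
a spurious rejection; this is a small-sample artifact of pointwise race
tests generally, not of this implementation. The package's validation suite
therefore evaluates the type-I rate over bins with mean AV CDF in
$(0.1, 0.9)$, where measured positive and negative rejection rates are
symmetric and close to $\alpha/2$.

## EEG track: windowed-Fourier phase and the phase lag index

Epochs are channels $\times$ samples $\times$ trials tensors at 250 Hz
spanning $-800$ to $+2000$ ms around stimulus onset (700 samples).
Preprocessing (`preprocess_epochs()`): drop EOG channels, re-reference to
the averaged mastoids (TP9/TP10, then dropped; 32 raw channels become 28),
zero-phase 1--50 Hz Butterworth band-pass (forward--backward, because phase
is the analyte and a causal filter would add frequency-dependent phase
shifts), an artifact-removal hook that defaults to the identity (synthetic
epochs are artifact-free), then per-trial baseline correction by the
prestimulus mean. Baseline correction follows filtering; for
amplitude-independent phase measures the order is immaterial, and the hook
position documents where ICA would sit on real data.

**Phase extraction** (`wft_phase()`): a windowed Fourier transform with a
fixed 200-ms (50-sample) Hamming window evaluated at integer frequencies
1--50 Hz in 1-Hz steps,

$$c(t, f) = \sum_{k=0}^{W-1} x[t + k - W/2]\; h[k]\;
  e^{-i 2\pi f (k - W/2)/f_s}, \qquad \varphi(t,f) = \arg c(t,f).$$

The coefficients are computed as direct windowed inner products, not by FFT
bins: a 50-sample FFT has 5-Hz resolution, while the analysis needs 1-Hz
steps. The complex exponential is referenced to the window centre so that
the phase of a noiseless sinusoid equals its analytic instantaneous phase
$\theta + 2\pi f_0 t$ at the output sample (validated to < 0.05 rad
mid-epoch; the per-frequency constant that a window-start reference would
add cancels in cross-channel differences either way). Epoch edges are
zero-padded; all edge-affected samples fall inside the trimmed region.

**PLI** (`pli_pair()`, `compute_pli()`): for channels $i, j$,

$$\mathrm{PLI}(t,f) = \left|\frac{1}{N}\sum_{n=1}^{N}
  \operatorname{sign}\bigl(\Delta\varphi_n(t,f)\bigr)\right| \in [0,1],$$

with $\Delta\varphi_n = \varphi_i - \varphi_j$ wrapped to $(-\pi, \pi]$ and
$\operatorname{sign}(0) = 0$. The absolute value makes the index a
magnitude, as required for averaging connection weights over a network; a
signed trial average would be a different (directional) statistic. The
$\operatorname{sign}(0) = 0$ convention makes exactly zero-lag activity --
the signature of volume conduction, where one source is mixed
instantaneously into both electrodes -- contribute nothing, which is the
defining robustness property of the PLI. The index is also invariant to any
channel amplitude rescaling, being a pure phase statistic.

Per-frequency PLI values are averaged over the canonical bands (theta 4--7,
alpha 8--13, beta 14--30, gamma 31--50 Hz, inclusive integer ranges) into
channels $\times$ channels $\times$ time adjacency tensors. The first 600 ms
(150 samples) and last 1400 ms (350 samples) of the epoch are then trimmed
(`trim_pli()`), leaving 200 samples covering $-200$ to $+600$ ms, which
removes all window-edge distortion (600 ms > the 100-ms window half-width by
a wide margin). Global functional connectivity is the network mean weight:
the average over all $\binom{28}{2} = 378$ unordered off-diagonal pairs at
each time sample.

### What the EEG generator emulates

`eeg_gen_spec()` / `simulate_eeg_epochs()` build epochs as a sum of:

* **Oscillatory sources**: sinusoids at a band frequency, active in a fixed
  window, projected onto a set of channels with specified phase lags. Each
  trial draws a fresh uniform base phase; each channel adds von Mises jitter
  with concentration $\kappa$, so $\kappa$ *is* the coupling strength:
  $\kappa = 0$ gives no coupling, $\kappa \ge 10^6$ perfect locking (and
  then a noiseless constant-lag pair yields band PLI exactly 1 in the
  trimmed window).
* **Broadband noise**: i.i.d. Gaussian per sample.
* **A zero-lag common component**: one sinusoid added identically to every
  channel, a deliberately adversarial volume-conduction surrogate that the
  PLI must ignore.
* **Subject heterogeneity**: per-subject lognormal multipliers on source
  amplitude (sd 0.2) and on $\kappa$ (sd 0.3). Without inter-individual
  variability a simulated cohort is statistically degenerate -- the
  between-subject variance that group t tests divide by shrinks toward
  zero and seed-level accidents dominate; with it, the group tests are
  honestly calibrated. Degenerate concentrations (0 and $\ge 10^6$) are
  left exact so limiting cases stay exact.

Not emulated: realistic head-model mixing (beyond the common zero-lag
term), 1/f spectra, artifacts, or nonstationary coupling. Test passes show
coupling-strength recovery and volume-conduction immunity under this model,
not robustness to real-EEG confounds.

## Group statistics

`pointwise_ttest()` compares two groups of per-subject connectivity series
sample by sample with independent (Welch) t tests, one-tailed in an
**explicitly supplied** direction -- the hypothesized direction is a
required analysis parameter, not something inferred from the data. Samples
with $p \le .05$ form the significance mask; maximal contiguous runs are
reported as windows, including single-sample runs (no minimum-duration rule
is imposed). No correction across time points is applied, so windows are
descriptive localizations. `window_mean()` then reduces each subject's
series to one scalar per condition by averaging inside a closed ms interval
-- either data-derived (the span of detected windows) or supplied; the
package ships the window defaults established for this paradigm (theta
52--348, alpha 108--328, beta 108--240, gamma 0--200 ms) in
`pipeline_config()`.

`mixed_anova()` runs the 2 group $\times$ 2 intensity $\times$ 3 stimulus
type mixed-design ANOVA on such scalars: between-subject group factor,
crossed within-subject factors, type-III decomposition with sum-to-zero
contrasts (identical to the classical stratum decomposition on balanced
data -- verified against an explicit cell-means computation). Within-subject
effects carry Greenhouse--Geisser $\epsilon$ and GG-corrected degrees of
freedom and p values ($\epsilon \equiv 1$ for 1-df effects; $\epsilon$ is
exactly 1 when the within-subject error covariance is exactly spherical).
Effect sizes are partial eta squared, $SS_{\mathrm{eff}} /
(SS_{\mathrm{eff}} + SS_{\mathrm{err}})$. Post hoc pairwise comparisons are
paired t tests across subjects for within factors and a two-sample t test
for the group factor, Bonferroni-adjusted within each factor's family --
Bonferroni being the conservative default where no adjustment is otherwise
specified.

## The reference group-contrast experiment

`theta_contrast_spec()` freezes the simulated experiment used to validate
time-resolved group comparison: 6 channels, one theta source at 5.5 Hz
(band centre), amplitude 1.5 against broadband noise of sd 1.5 (amplitude
SNR 1, a realistic rhythm-to-background ratio), lags $0, \pi/3, -2\pi/3$ on
three channels, active 100--300 ms; the group contrast is carried entirely
by $\kappa$ (40, strong locking, for the "elderly" cohort versus 0.2,
effectively unlocked, for the "younger" one), with 10 subjects per group
and 24 trials each. The theta-band pointwise test reliably localizes a
window overlapping 100--300 ms, and the beta and gamma bands stay at chance
levels.

### A resolution limit worth understanding

The alpha band does **not** stay at chance in this experiment, and cannot:
a 50-sample Hamming window has 5-Hz-wide frequency bins, and its measured
amplitude response at 2.5--4 Hz offsets is still 0.60--0.82 of peak. A
phase-locked 5.5-Hz source therefore produces phase-locked energy at the
8--10 Hz alpha edge at more than half of its in-band response -- and
because the PLI is amplitude-invariant, no signal-to-noise ratio can
suppress the leaked locking without also destroying the in-band locking
(the available in-band:leaked ratio is at most about 1.7). Any theta-band
lagged source analyzed with a 200-ms window will thus also elevate
alpha-band PLI over the same time course. This is an intrinsic
time--frequency trade-off of the 200-ms window choice, shared by any
analysis built on it; interpreting band-specific group effects near band
edges requires either longer windows (at the cost of temporal resolution)
or explicit spectral-leakage controls. The package's validation suite
asserts band specificity for all non-theta bands and documents that the
alpha assertion fails for exactly this reason.

## Numerical choices and degenerate inputs

* Wrapping convention: $(-\pi, \pi]$ everywhere, with $-\pi \mapsto +\pi$;
  `sign(wrap())` is computed as `sign(sin())` with an explicit correction at
  exactly $\pi$, which is algebraically identical and avoids `atan2` in the
  hot loop.
* Zero-variance bins in the violation test ($t$ undefined): all-zero
  differences give $p = 1$ (never significant); identical non-zero
  differences give $p = 0$.
* The band-pass is a 2nd-order high-pass at 1 Hz plus an 8th-order low-pass
  at 50 Hz, each forward--backward; the split avoids the numerical
  fragility of a single high-order band-pass with a very small normalized
  lower edge, and the measured attenuation at 60 Hz exceeds 20 dB.
* All randomness flows from one user seed through a documented splitting
  scheme (`seed * 7919 + stream * 104729 mod 2^31 - 1`), so fixed seeds give
  bit-identical datasets.
* Problem sizes in the validation suite (500 null replicates and 200 power
  replicates for the race suite at 20 subjects x 30 trials; 3 replicate
  cohorts of 10 + 10 subjects for the connectivity contrast; 100-200
  replicates for the statistical calibrations) were chosen to give
  Monte-Carlo standard errors comfortably below the asserted margins.

## Known limitations

* AUC scale is a bin-sum convention; comparisons with analyses that
  integrate probability over milliseconds need a factor of the bin width.
* The pointwise race-model test is anticonservative in extreme-tail bins
  (see above); windows should be read from the well-populated part of the
  RT range.
* Band-edge specificity of PLI effects is limited by the 200-ms window's
  5-Hz resolution (see the resolution-limit section).
* The mixed ANOVA requires a complete balanced design; missing cells abort
  rather than being imputed.
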