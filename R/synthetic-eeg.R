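#' Oscillatory source description for the EEG generator
#'
#' One band-limited source: a sinusoid at `band_center_hz` active between
#' `onset_ms` and `offset_ms`, projected onto a set of channels with fixed
#' relative phase lags.  On each trial the source takes a fresh uniform base
#' phase; every involved channel then receives that phase plus its nominal
#' lag plus von Mises jitter with concentration `kappa`, so `kappa`
#' controls the trial-to-trial consistency of the cross-channel lags:
#' `kappa = 0` gives uniform jitter (no coupling) and `kappa >= 1e6` perfect
#' phase locking.
#'
#' @param band_center_hz source frequency (Hz), must lie in 1-50 Hz (the
#'   analysis band-pass range).
#' @param band_name label (e.g. "theta").
#' @param channel_lags named numeric vector: per-channel phase lag (radians),
#'   wrapped to (-pi, pi].  Channels absent from the vector do not carry the
#'   source.
#' @param kappa von Mises concentration of the per-channel phase jitter, >= 0.
#' @param onset_ms,offset_ms activation window relative to stimulus onset.
#' @param amplitude peak amplitude (signal units).
#' @return a list of class `eeg_source`.
#' @export
eeg_source <- function(band_center_hz, band_name = "band",
                       channel_lags, kappa = 5,
                       onset_ms = 0, offset_ms = 600, amplitude = 1) {
  if (band_center_hz < 1 || band_center_hz > 50) {
    stop("source frequency must lie within the 1-50 Hz analysis range", call. = FALSE)
  }
  stopifnot(kappa >= 0, offset_ms > onset_ms, amplitude >= 0,
            !is.null(names(channel_lags)))
  structure(
    list(band_center_hz = band_center_hz, band_name = band_name,
         channel_lags = wrap_phase(channel_lags), kappa = kappa,
         onset_ms = onset_ms, offset_ms = offset_ms, amplitude = amplitude),
    class = "eeg_source"
  )
}

#' Specification for the synthetic EEG generator
#'
#' Epochs are built as a sum of [eeg_source()] oscillations, i.i.d. Gaussian
#' broadband noise, and an optional zero-lag common component added
#' identically to all channels (a volume-conduction surrogate: instantaneously
#' mixed activity that a lag-based connectivity measure must ignore).
#'
#' @param n_channels number of scalp channels (default 28).
#' @param fs sampling rate (Hz, default 250).
#' @param epoch_span_ms length-2 vector, epoch start and end relative to
#'   stimulus onset (default -800...+2000 ms, i.e. 700 samples at 250 Hz).
#' @param n_trials trials per subject.
#' @param sources list of [eeg_source()] objects.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param common_zero_lag_amplitude amplitude of the shared zero-lag sinusoid
#'   (0 disables it).
#' @param common_zero_lag_hz frequency of the shared component (default 10 Hz).
#' @param subject_amp_sd,subject_kappa_sd lognormal sigma of per-subject
#'   multipliers applied to each source's amplitude and von Mises
#'   concentration, emulating inter-individual differences in oscillation
#'   strength and coupling consistency.  Degenerate concentrations (0, or
#'   >= 1e6 meaning exact locking) are left untouched.
#' @param channel_names channel labels (default the standard 28-label scalp
#'   montage, truncated/extended to `n_channels`).
#' @param seed integer master seed.
#' @return an object of class `eeg_gen_spec`.
#' @export
eeg_gen_spec <- function(n_channels = 28, fs = 250,
                         epoch_span_ms = c(-800, 2000),
                         n_trials = 30, sources = list(),
                         noise_sd = 0.5,
                         common_zero_lag_amplitude = 0,
                         common_zero_lag_hz = 10,
                         subject_amp_sd = 0.2, subject_kappa_sd = 0.3,
                         channel_names = NULL, seed = 1L) {
  stopifnot(n_channels >= 2, fs > 0, length(epoch_span_ms) == 2,
            epoch_span_ms[2] > epoch_span_ms[1], n_trials >= 1,
            noise_sd >= 0, common_zero_lag_amplitude >= 0,
            subject_amp_sd >= 0, subject_kappa_sd >= 0)
  for (s in sources) stopifnot(inherits(s, "eeg_source"))
  if (is.null(channel_names)) {
    base <- scalp_channels_28()
    channel_names <- if (n_channels <= length(base)) base[seq_len(n_channels)]
                     else c(base, sprintf("X%02d", seq_len(n_channels - length(base))))
  }
  stopifnot(length(channel_names) == n_channels)
  n_samples <- round(diff(epoch_span_ms) * fs / 1000)
  structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         epoch_span_ms = epoch_span_ms, n_samples = as.integer(n_samples),
         n_trials = as.integer(n_trials), sources = sources,
         noise_sd = noise_sd,
         common_zero_lag_amplitude = common_zero_lag_amplitude,
         common_zero_lag_hz = common_zero_lag_hz,
         subject_amp_sd = subject_amp_sd, subject_kappa_sd = subject_kappa_sd,
         channel_names = channel_names, seed = as.integer(seed)),
    class = "eeg_gen_spec"
  )
}

#' @export
print.eeg_gen_spec <- function(x, ...) {
  cat(sprintf("<eeg_gen_spec> %d ch x %d samples x %d trials @ %g Hz, span %g...%g ms\n",
              x$n_channels, x$n_samples, x$n_trials, x$fs,
              x$epoch_span_ms[1], x$epoch_span_ms[2]))
  cat(sprintf("  %d source(s); noise_sd=%g; common zero-lag amp=%g @ %g Hz; seed=%d\n",
              length(x$sources), x$noise_sd, x$common_zero_lag_amplitude,
              x$common_zero_lag_hz, x$seed))
  invisible(x)
}

# Simulate one subject's epochs from a spec. `extra_channels`: named list of
# label -> generator function(n_samples, n_trials) used for raw-montage
# channels (EOG, mastoids) appended after the scalp channels.
simulate_one_subject <- function(spec, subject_seed, condition = NULL,
                                 extra_channels = NULL) {
  set.seed(subject_seed)
  ns <- spec$n_samples
  nt <- spec$n_trials
  nc <- spec$n_channels
  t_ms <- spec$epoch_span_ms[1] + (seq_len(ns) - 1) * 1000 / spec$fs
  t_s <- (seq_len(ns) - 1) / spec$fs  # time from epoch start, for phase ramps
  dat <- array(stats::rnorm(nc * ns * nt, sd = spec$noise_sd), dim = c(nc, ns, nt))

  for (src in spec$sources) {
    # subject-level heterogeneity: oscillation strength and coupling
    # consistency vary across individuals
    amp <- src$amplitude * stats::rlnorm(1, 0, spec$subject_amp_sd)
    kap <- src$kappa
    if (kap > 0 && kap < 1e6) kap <- kap * stats::rlnorm(1, 0, spec$subject_kappa_sd)
    idx <- match(names(src$channel_lags), spec$channel_names)
    if (anyNA(idx)) {
      stop("source references unknown channel(s): ",
           paste(names(src$channel_lags)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    active <- t_ms >= src$onset_ms & t_ms <= src$offset_ms
    omega <- 2 * pi * src$band_center_hz
    for (n in seq_len(nt)) {
      theta <- stats::runif(1, -pi, pi)
      jitter <- rvonmises(length(idx), mu = 0, kappa = kap)
      ph <- theta + src$channel_lags + jitter
      wave <- outer(ph, omega * t_s, "+")      # length(idx) x ns phase matrix
      w <- amp * cos(wave)
      w[, !active] <- 0
      dat[idx, , n] <- dat[idx, , n] + w
    }
  }

  if (spec$common_zero_lag_amplitude > 0) {
    omega <- 2 * pi * spec$common_zero_lag_hz
    for (n in seq_len(nt)) {
      psi <- stats::runif(1, -pi, pi)
      common <- spec$common_zero_lag_amplitude * cos(omega * t_s + psi)
      dat[, , n] <- sweep(dat[, , n], 2, common, "+")
    }
  }

  ch_names <- spec$channel_names
  if (!is.null(extra_channels)) {
    extra <- lapply(extra_channels, function(f) f(ns, nt))
    xarr <- array(unlist(extra), dim = c(ns, nt, length(extra)))
    xarr <- aperm(xarr, c(3, 1, 2))
    dat2 <- array(0, dim = c(nc + length(extra), ns, nt))
    dat2[seq_len(nc), , ] <- dat
    dat2[nc + seq_along(extra), , ] <- xarr
    dat <- dat2
    ch_names <- c(ch_names, names(extra_channels))
  }

  epoch_array(dat, fs = spec$fs, t0_ms = spec$epoch_span_ms[1],
              channel_names = ch_names, condition = condition)
}

#' Generate synthetic EEG epochs for a cohort
#'
#' One [epoch_array()] per subject.  With `raw_montage = TRUE` the output
#' additionally carries VEOG/HEOG electro-oculogram channels and the TP9/TP10
#' mastoid reference channels (all noise-only) so that the full preprocessing
#' chain, including channel exclusion and mastoid re-referencing, can be
#' exercised; the default emits the analysis-ready scalp montage directly.
#'
#' @param spec an [eeg_gen_spec()].
#' @param n_subjects number of subjects.
#' @param condition optional named list/vector (group, intensity, stim_type)
#'   stamped on each epoch array.
#' @param raw_montage if TRUE, append EOG and mastoid channels.
#' @return list of `epoch_array`, one per subject, named `s01`, `s02`, ...
#' @export
simulate_eeg_epochs <- function(spec, n_subjects = 1, condition = NULL,
                                raw_montage = FALSE) {
  stopifnot(inherits(spec, "eeg_gen_spec"), n_subjects >= 1)
  extra <- NULL
  if (raw_montage) {
    noise_ch <- function(sd) function(ns, nt) {
      matrix(stats::rnorm(ns * nt, sd = sd), ns, nt)
    }
    extra <- list(VEOG = noise_ch(5), HEOG = noise_ch(5),
                  TP9 = noise_ch(spec$noise_sd), TP10 = noise_ch(spec$noise_sd))
  }
  out <- lapply(seq_len(n_subjects), function(s) {
    simulate_one_subject(spec, split_seed(spec$seed, 100 + s),
                         condition = condition, extra_channels = extra)
  })
  names(out) <- sprintf("s%02d", seq_len(n_subjects))
  out
}
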