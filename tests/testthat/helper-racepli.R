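# Shared builders for the test suite.  Everything is generated in code; no
# stored fixtures.

# Tiny trial table with known RTs for one subject/cell.
toy_trials <- function(rts, stim_type = "A", subject = "s01",
                       group = "younger", intensity = "high",
                       correct = !is.na(rts)) {
  tibble::tibble(subject = subject, group = group, intensity = intensity,
                 stim_type = stim_type, is_target = TRUE,
                 rt_ms = rts, correct = correct)
}

# Noiseless multi-channel sinusoid epochs: each channel i carries
# amplitude * cos(2*pi*f0*t + theta[i]) with t in seconds from epoch start.
sinusoid_epochs <- function(theta, f0 = 10, n_trials = 1, fs = 250,
                            n_samples = 700, t0_ms = -800, amplitude = 1) {
  t_s <- (seq_len(n_samples) - 1) / fs
  dat <- array(0, dim = c(length(theta), n_samples, n_trials))
  for (i in seq_along(theta)) {
    for (n in seq_len(n_trials)) {
      dat[i, , n] <- amplitude * cos(2 * pi * f0 * t_s + theta[i])
    }
  }
  epoch_array(dat, fs = fs, t0_ms = t0_ms)
}

# Spectral-phase object assembled directly from a phase array, bypassing the
# WFT - used to feed the PLI kernel exactly known phases.
phase_object <- function(ph, freqs, fs = 250, t0_ms = 0,
                         channel_names = NULL) {
  stopifnot(length(dim(ph)) == 4)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dim(ph)[1]))
  }
  structure(
    list(phase = ph, freqs = freqs, fs = fs, t0_ms = t0_ms,
         window_ms = 200, channel_names = channel_names, condition = NULL),
    class = "spectral_phase"
  )
}

# Brute-force PLI oracle: explicit loops, wrap via atan2 - independent of the
# vectorised implementation in the package.
pli_bruteforce <- function(ph, i, j) {
  d <- dim(ph)  # ch x samples x freqs x trials
  out <- matrix(0, d[2], d[3])
  for (t in seq_len(d[2])) {
    for (f in seq_len(d[3])) {
      s <- 0
      for (n in seq_len(d[4])) {
        dphi <- ph[i, t, f, n] - ph[j, t, f, n]
        w <- atan2(sin(dphi), cos(dphi))
        if (w == -pi) w <- pi
        s <- s + sign(w)
      }
      out[t, f] <- abs(s / d[4])
    }
  }
  out
}

# Balanced 2 x 2 x 3 mixed-design table from a subject x cell matrix.
anova_table <- function(Y, groups) {
  cells <- tidyr::expand_grid(intensity = c("high", "low"),
                              stim_type = c("A", "V", "AV"))
  purrr::map_dfr(seq_len(nrow(Y)), function(s) {
    tibble::tibble(subject = sprintf("s%02d", s), group = groups[s],
                   intensity = cells$intensity, stim_type = cells$stim_type,
                   value = Y[s, ])
  })
}
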