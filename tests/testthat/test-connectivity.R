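test_that("preprocessing reduces a 32-channel raw montage to 28 channels", {
  spec <- eeg_gen_spec(n_channels = 28, n_trials = 3, seed = 19)
  raw <- simulate_eeg_epochs(spec, 1, raw_montage = TRUE)[[1]]
  out <- preprocess_epochs(raw)
  expect_equal(dim(out$data)[1], 28)
  expect_false(any(c("VEOG", "HEOG", "TP9", "TP10") %in% out$channel_names))
  expect_equal(dim(out$data)[2:3], dim(raw$data)[2:3])
})

test_that("missing mastoid labels abort preprocessing", {
  ep <- sinusoid_epochs(c(0, 1), n_trials = 1)
  expect_error(preprocess_epochs(ep), "mastoid")
})

test_that("zeroed mastoids leave the data unchanged up to filtering", {
  set.seed(23)
  dat <- array(rnorm(4 * 700 * 2), dim = c(4, 700, 2))
  dat[3, , ] <- 0  # TP9
  dat[4, , ] <- 0  # TP10
  ep <- epoch_array(dat, channel_names = c("C3", "C4", "TP9", "TP10"))
  out <- preprocess_epochs(ep, eog_channels = character(0), baseline = FALSE)
  ref <- racepli:::bandpass_zero_phase(dat[1:2, , , drop = FALSE],
                                       fs = 250, band = c(1, 50))
  expect_equal(out$data, ref, tolerance = 1e-10)
})

test_that("band-pass attenuates a 60 Hz tone by at least 20 dB", {
  t_s <- (seq_len(700) - 1) / 250
  x <- cos(2 * pi * 60 * t_s)
  dat <- array(x, dim = c(1, 700, 1))
  filt <- racepli:::bandpass_zero_phase(dat, fs = 250, band = c(1, 50))
  mid <- 200:500  # away from filter edge transients
  atten_db <- 10 * log10(mean(x[mid]^2) / mean(filt[1, mid, 1]^2))
  expect_gt(atten_db, 20)
  # and a 10 Hz tone passes essentially unchanged
  y <- cos(2 * pi * 10 * t_s)
  fy <- racepli:::bandpass_zero_phase(array(y, dim = c(1, 700, 1)),
                                      fs = 250, band = c(1, 50))
  expect_equal(fy[1, mid, 1], y[mid], tolerance = 0.05)
})

test_that("WFT phase matches the analytic phase of a noiseless sinusoid", {
  theta <- 0.7
  ep <- sinusoid_epochs(theta, f0 = 10)
  ph <- wft_phase(ep, freqs = c(6, 10, 20))
  t_s <- (seq_len(700) - 1) / 250
  mid <- 250:450
  est <- ph$phase[1, mid, 2, 1]
  anal <- wrap_phase(theta + 2 * pi * 10 * t_s[mid])
  expect_lt(max(abs(wrap_phase(est - anal))), 0.05)
})

test_that("identical channels have zero phase difference everywhere", {
  ep <- sinusoid_epochs(c(0.3, 0.3), f0 = 12, n_trials = 2)
  ph <- wft_phase(ep, freqs = c(5, 12, 30))
  expect_equal(max(abs(ph$phase[1, , , ] - ph$phase[2, , , ])), 0)
  expect_true(all(abs(ph$phase) <= pi + 1e-12))
})

test_that("WFT rejects out-of-range frequencies and short epochs", {
  ep <- sinusoid_epochs(0, f0 = 10)
  expect_error(wft_phase(ep, freqs = c(10, 60)), "1-50")
  expect_error(wft_phase(ep, freqs = 0:10), "1-50")
  short <- epoch_array(array(0, c(1, 30, 1)))
  expect_error(wft_phase(short, freqs = 10), "shorter")
})

test_that("PLI kernel: constant lag 1, balanced lags 0, zero lag 0", {
  ns <- 8; nf <- 2; nt <- 10
  base <- array(rep(runif(ns * nf * nt, -pi, pi), each = 2), c(2, ns, nf, nt))
  # constant +pi/4 lag on channel 1
  ph <- base
  ph[1, , , ] <- wrap_phase(ph[1, , , ] + pi / 4)
  obj <- phase_object(ph, freqs = c(5, 6))
  expect_equal(unname(pli_pair(obj, 1, 2)), matrix(1, ns, nf))
  expect_equal(pli_pair(obj, 2, 1), pli_pair(obj, 1, 2))  # symmetry

  # half the trials +pi/4, half -pi/4: signs cancel
  ph2 <- base
  sgn <- rep(c(1, -1), each = nt / 2)
  for (n in seq_len(nt)) ph2[1, , , n] <- wrap_phase(ph2[1, , , n] + sgn[n] * pi / 4)
  expect_equal(unname(pli_pair(phase_object(ph2, c(5, 6)), 1, 2)),
               matrix(0, ns, nf))

  # exactly zero lag contributes nothing: sign(0) = 0
  expect_equal(unname(pli_pair(phase_object(base, c(5, 6)), 1, 2)),
               matrix(0, ns, nf))
  # diagonal defined as zero
  expect_equal(unname(pli_pair(obj, 1, 1)), matrix(0, ns, nf))
})

test_that("uniform random phase differences give small PLI at N = 100", {
  set.seed(77)
  hits <- vapply(1:50, function(r) {
    ph <- array(runif(2 * 1 * 1 * 100, -pi, pi), c(2, 1, 1, 100))
    pli_pair(phase_object(ph, 5), 1, 2)[1, 1]
  }, numeric(1))
  expect_true(mean(hits <= 0.3) >= 0.98)
  # sd across trials approximately 1/sqrt(N)
  expect_equal(sd(hits), 1 / sqrt(100), tolerance = 0.6)
})

test_that("PLI is invariant to channel amplitude rescaling", {
  spec <- eeg_gen_spec(n_channels = 2, n_trials = 8, noise_sd = 0.3, seed = 41,
                       sources = list(eeg_source(10, channel_lags = c(Fp1 = 0, Fp2 = 1),
                                                 kappa = 3, onset_ms = -800,
                                                 offset_ms = 2000)))
  ep <- simulate_eeg_epochs(spec, 1)[[1]]
  ep2 <- ep
  ep2$data[2, , ] <- 7.3 * ep2$data[2, , ]  # pure gain change on one channel
  p1 <- pli_pair(wft_phase(ep, freqs = 9:11), 1, 2)
  p2 <- pli_pair(wft_phase(ep2, freqs = 9:11), 1, 2)
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("PLI matches a brute-force oracle on a random 3x10x5 toy", {
  set.seed(99)
  ph <- array(runif(3 * 6 * 5 * 10, -pi, pi), c(3, 6, 5, 10))
  obj <- phase_object(ph, freqs = 1:5)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(unname(pli_pair(obj, i, j)), pli_bruteforce(ph, i, j),
                 tolerance = 1e-12)
  }
})

test_that("band averaging uses exactly the band's integer frequencies", {
  m <- matrix(runif(10 * 8), 10, 8)
  colnames(m) <- as.character(3:10)
  # theta = 4-7 Hz: columns 4,5,6,7
  expect_equal(band_average(m, "theta"), rowMeans(m[, c("4", "5", "6", "7")]))
  con <- matrix(0.42, 5, 4, dimnames = list(NULL, 4:7))
  expect_equal(band_average(con, "theta"), rep(0.42, 5))
  expect_error(band_average(m, c(20, 30)), "inside the band")
})

test_that("trimming keeps 200 samples covering -200 to +596 ms", {
  spec <- eeg_gen_spec(n_channels = 2, n_trials = 2, seed = 3,
                       sources = list(eeg_source(5, channel_lags = c(Fp1 = 0, Fp2 = 1))))
  ep <- simulate_eeg_epochs(spec, 1)[[1]]
  pt <- compute_pli(wft_phase(ep, freqs = 4:7), "theta")
  expect_equal(dim(pt$pli)[3], 700)
  tr <- trim_pli(pt)
  expect_equal(dim(tr$pli)[3], 200)
  expect_equal(tr$time_ms[1], -200)
  expect_equal(tr$time_ms[200], 596)
  expect_equal(150 + 200 + 350, 700)
  expect_error(trim_pli(tr), "already trimmed")
})

test_that("global connectivity averages the off-diagonal pairs", {
  nc <- 28
  pt <- structure(list(
    pli = array(0.5, c(nc, nc, 3)), band = "theta", band_range = c(4, 7),
    freqs = 4:7, time_ms = c(0, 4, 8), fs = 250, t0_ms = 0,
    channel_names = sprintf("c%d", 1:nc), condition = NULL, trimmed = TRUE),
    class = "pli_tensor")
  expect_equal(global_connectivity(pt)$mean_pli, rep(0.5, 3))

  # one pair set to 1, the rest 0: mean = 1/378 over the 378 pairs
  pt$pli <- array(0, c(nc, nc, 1))
  pt$pli[1, 2, 1] <- 1; pt$pli[2, 1, 1] <- 1
  pt$time_ms <- 0
  expect_equal(global_connectivity(pt)$mean_pli, 1 / 378)

  # brute-force double loop oracle on random symmetric data
  set.seed(6)
  m <- matrix(runif(nc * nc), nc, nc); m <- (m + t(m)) / 2; diag(m) <- 0
  pt$pli <- array(m, c(nc, nc, 1))
  acc <- 0; cnt <- 0
  for (i in 1:(nc - 1)) for (j in (i + 1):nc) { acc <- acc + m[i, j]; cnt <- cnt + 1 }
  expect_equal(cnt, 378)
  expect_equal(global_connectivity(pt)$mean_pli, acc / cnt)
})

test_that("volume conduction: common zero-lag input leaves pair PLI unchanged", {
  mk <- function(common) {
    eeg_gen_spec(n_channels = 2, n_trials = 12, noise_sd = 0.2, seed = 55,
                 subject_amp_sd = 0, subject_kappa_sd = 0,
                 common_zero_lag_amplitude = common, common_zero_lag_hz = 6,
                 sources = list(eeg_source(10, channel_lags = c(Fp1 = 0, Fp2 = 1.2),
                                           kappa = 1e6, onset_ms = -800,
                                           offset_ms = 2000)))
  }
  p_without <- pli_pair(wft_phase(simulate_eeg_epochs(mk(0), 1)[[1]], freqs = 10), 1, 2)
  p_with <- pli_pair(wft_phase(simulate_eeg_epochs(mk(0.5), 1)[[1]], freqs = 10), 1, 2)
  mid <- 200:500
  expect_equal(mean(p_with[mid, 1]), mean(p_without[mid, 1]), tolerance = 0.05)
  expect_gt(mean(p_without[mid, 1]), 0.95)  # locked lagged source
})

test_that("a purely zero-lag network has near-zero PLI", {
  spec <- eeg_gen_spec(n_channels = 2, n_trials = 20, noise_sd = 0, seed = 61,
                       common_zero_lag_amplitude = 3, common_zero_lag_hz = 10)
  ep <- simulate_eeg_epochs(spec, 1)[[1]]
  p <- pli_pair(wft_phase(ep, freqs = 10), 1, 2)
  mid <- 200:500
  expect_lt(max(p[mid, 1]), 0.05)
})
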