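#' Specification for the synthetic reaction-time generator
#'
#' Defines the ground-truth parameters of a redundant-signals (A / V / AV)
#' detection experiment.  Unimodal reaction times are ex-Gaussian
#' (Gaussian plus exponential tail), the standard unimodal RT phenomenology.
#' AV responses are produced by a race between fresh auditory and visual
#' draws, optionally sped up by a proportional coactivation component:
#' \deqn{RT_{AV} = (1 - g)\,\min(A', V')}
#' so `coactivation_gain = 0` yields pure statistical facilitation (the race
#' bound holds in expectation at every quantile) while `g > 0` produces
#' controllable, monotone violations of the Miller bound.
#'
#' @param mu_a,sigma_a,tau_a ex-Gaussian parameters of auditory RTs (ms).
#' @param mu_v,sigma_v,tau_v ex-Gaussian parameters of visual RTs (ms).
#' @param coactivation_gain fraction in \[0, 1): proportional AV speed-up
#'   beyond the pure race.
#' @param group_slowing additive shift (ms) applied to every modality for the
#'   "elderly" group.
#' @param intensity_slowing additive shift (ms) applied to every modality in
#'   the low-intensity condition (high-intensity stimuli are processed
#'   faster).
#' @param miss_rate probability in \[0, 1) that a target trial receives no
#'   response; missed trials keep their row but have `rt_ms = NA`.
#' @param n_trials_per_type target trials per (subject, intensity, type) cell.
#' @param seed integer master seed; all draws flow from it.
#' @return an object of class `rt_gen_spec`.
#' @examples
#' rt_gen_spec(coactivation_gain = 0.15, n_trials_per_type = 30)
#' @export
rt_gen_spec <- function(mu_a = 420, sigma_a = 50, tau_a = 110,
                        mu_v = 390, sigma_v = 45, tau_v = 100,
                        coactivation_gain = 0,
                        group_slowing = 80,
                        intensity_slowing = 30,
                        miss_rate = 0.03,
                        n_trials_per_type = 30,
                        seed = 1L) {
  stopifnot(
    sigma_a > 0, sigma_v > 0, tau_a > 0, tau_v > 0,
    coactivation_gain >= 0, coactivation_gain < 1,
    miss_rate >= 0, miss_rate < 1,
    n_trials_per_type >= 1
  )
  structure(
    list(
      mu_a = mu_a, sigma_a = sigma_a, tau_a = tau_a,
      mu_v = mu_v, sigma_v = sigma_v, tau_v = tau_v,
      coactivation_gain = coactivation_gain,
      group_slowing = group_slowing,
      intensity_slowing = intensity_slowing,
      miss_rate = miss_rate,
      n_trials_per_type = as.integer(n_trials_per_type),
      seed = as.integer(seed)
    ),
    class = "rt_gen_spec"
  )
}

#' @export
print.rt_gen_spec <- function(x, ...) {
  cat("<rt_gen_spec>\n")
  cat(sprintf("  A: exGauss(mu=%g, sigma=%g, tau=%g) ms\n", x$mu_a, x$sigma_a, x$tau_a))
  cat(sprintf("  V: exGauss(mu=%g, sigma=%g, tau=%g) ms\n", x$mu_v, x$sigma_v, x$tau_v))
  cat(sprintf("  coactivation_gain=%g, group_slowing=%g ms, intensity_slowing=%g ms\n",
              x$coactivation_gain, x$group_slowing, x$intensity_slowing))
  cat(sprintf("  miss_rate=%g, %d trials/type, seed=%d\n",
              x$miss_rate, x$n_trials_per_type, x$seed))
  invisible(x)
}

# ex-Gaussian draws, truncated at > 0 (resample the rare non-positive values)
rexgauss <- function(n, mu, sigma, tau) {
  x <- stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
  bad <- x <= 0
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mu, sigma) + stats::rexp(sum(bad), rate = 1 / tau)
    bad <- x <= 0
  }
  x
}

#' Generate a synthetic behavioral trial table
#'
#' Draws target trials for both groups (`elderly`, `younger`), both stimulus
#' intensities (`high`, `low`) and all three stimulus types (`A`, `V`, `AV`)
#' from the architecture described in [rt_gen_spec()].  AV trials use fresh
#' unimodal draws \eqn{A', V'} and take \eqn{(1-g)\min(A', V')}.  A fraction
#' `miss_rate` of trials is marked as a miss (`rt_ms = NA`, `correct =
#' FALSE`); responded trials are correct.
#'
#' @param spec an [rt_gen_spec()].
#' @param n_subjects_per_group subjects per group.
#' @param groups,intensities subsets of the group / intensity labels to
#'   generate (defaults: both groups, both intensities).
#' @return a tibble with one row per target trial and columns `subject`,
#'   `group`, `intensity`, `stim_type`, `is_target`, `rt_ms`, `correct`.  The
#'   generating spec is attached as attribute `"ground_truth"`.
#' @examples
#' trials <- simulate_rt_trials(rt_gen_spec(n_trials_per_type = 10), 2)
#' dplyr::count(trials, group, intensity, stim_type)
#' @export
simulate_rt_trials <- function(spec, n_subjects_per_group = 20,
                               groups = c("elderly", "younger"),
                               intensities = c("high", "low")) {
  stopifnot(inherits(spec, "rt_gen_spec"), n_subjects_per_group >= 1,
            all(groups %in% c("elderly", "younger")),
            all(intensities %in% c("high", "low")))
  set.seed(split_seed(spec$seed, 1))
  nt <- spec$n_trials_per_type
  grid <- tidyr::expand_grid(
    group = groups,
    subject_idx = seq_len(n_subjects_per_group),
    intensity = intensities,
    stim_type = c("A", "V", "AV")
  )
  draw_cell <- function(group, subject_idx, intensity, stim_type) {
    shift <- (group == "elderly") * spec$group_slowing +
      (intensity == "low") * spec$intensity_slowing
    rt <- switch(stim_type,
      A = shift + rexgauss(nt, spec$mu_a, spec$sigma_a, spec$tau_a),
      V = shift + rexgauss(nt, spec$mu_v, spec$sigma_v, spec$tau_v),
      AV = {
        a <- shift + rexgauss(nt, spec$mu_a, spec$sigma_a, spec$tau_a)
        v <- shift + rexgauss(nt, spec$mu_v, spec$sigma_v, spec$tau_v)
        (1 - spec$coactivation_gain) * pmin(a, v)
      }
    )
    miss <- stats::runif(nt) < spec$miss_rate
    rt[miss] <- NA_real_
    tibble::tibble(
      subject = sprintf("%s_%02d", substr(group, 1, 1), subject_idx),
      group = group, intensity = intensity, stim_type = stim_type,
      is_target = TRUE, rt_ms = rt, correct = !miss
    )
  }
  out <- purrr::pmap(grid, draw_cell)
  out <- dplyr::bind_rows(out)
  attr(out, "ground_truth") <- spec
  out
}

#' Write / read a trial table as delimited text
#'
#' Plain tab-separated text with a header line; missed trials have an empty
#' `rt_ms` field.  The ground-truth spec, when present, is written as a JSON
#' sidecar `<path>.json`.
#'
#' @param trials a trial tibble as from [simulate_rt_trials()].
#' @param path output file path.
#' @return `path`, invisibly (writer); the trial tibble (reader).
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- attr(trials, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(unclass(gt), paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(rt_ms = "numeric"))
  out <- tibble::as_tibble(df)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    gt <- jsonlite::fromJSON(sidecar)
    attr(out, "ground_truth") <- do.call(rt_gen_spec, gt)
  }
  out
}
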