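#' Wrap phase angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # %% maps -pi to -pi; the convention here is (-pi, pi], so fold it to +pi
  w[w == -pi] <- pi
  w
}

# Derive a stream-specific 31-bit seed from a master seed.  All randomness in
# the package flows from one user seed through this splitter so that the RT
# and EEG generators (and replicate loops) draw from decorrelated streams.
split_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` reduces to the uniform
#' distribution on (-pi, pi]; very large `kappa` (>= 1e6) is treated as a
#' point mass at `mu` so that perfectly phase-locked oscillators can be
#' simulated exactly.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter, >= 0.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0)
  if (kappa == 0) {
    return(wrap_phase(stats::runif(n, -pi, pi)))
  }
  if (kappa >= 1e6) {
    return(wrap_phase(rep(mu, n)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      u3 <- stats::runif(1)
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_phase(out + mu)
}

# Contiguous runs of TRUE in a logical vector -> tibble of start/end indices.
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

# One-sample t p-value that tolerates zero variance (t.test() errors there).
# sd == 0 & mean == 0 -> p = 1; sd == 0 & mean != 0 -> p = 0.
one_sample_p <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (n < 2) stop("need at least 2 observations for a t test", call. = FALSE)
  if (s == 0) {
    return(if (m == 0) 1 else 0)
  }
  tval <- m / (s / sqrt(n))
  2 * stats::pt(-abs(tval), df = n - 1)
}
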