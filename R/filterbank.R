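#' Filter-bank configuration
#'
#' The encoder splits the 100-2000 Hz band (where extracellular action
#' potentials carry their energy; spike spectra rarely exceed 3 kHz) into
#' `n_filters` narrow band-pass channels with linearly spaced center
#' frequencies. Narrow bands (~60 Hz) give the frequency resolution needed to
#' tell spike shapes apart while a low filter order (<= 3) keeps the impulse
#' response short enough to resolve spikes arriving within a few tens of
#' milliseconds.
#'
#' @param n_filters Number of band-pass channels (default 32).
#' @param f_low_hz Center frequency of the first filter (default 100).
#' @param f_high_hz Center frequency of the last filter (default 2000).
#' @param bandwidth_hz Passband width of each filter (default 60).
#' @param order Butterworth order (default 2, must be <= 3).
#' @return An object of class `filter_bank_config`.
#' @export
filter_bank_config <- function(n_filters = 32, f_low_hz = 100,
                               f_high_hz = 2000, bandwidth_hz = 60,
                               order = 2) {
  if (n_filters < 1) stop("'n_filters' must be >= 1", call. = FALSE)
  if (n_filters == 1 && f_low_hz != f_high_hz) {
    stop("with a single filter, 'f_low_hz' must equal 'f_high_hz'",
         call. = FALSE)
  }
  if (n_filters > 1 && !(f_low_hz < f_high_hz)) {
    stop("'f_low_hz' must be < 'f_high_hz'", call. = FALSE)
  }
  if (f_low_hz <= 0) stop("'f_low_hz' must be > 0", call. = FALSE)
  if (bandwidth_hz <= 0) stop("'bandwidth_hz' must be > 0", call. = FALSE)
  if (order < 1 || order > 3) {
    stop("'order' must be 1, 2 or 3 (short impulse response requirement)",
         call. = FALSE)
  }
  structure(
    list(n_filters = as.integer(n_filters), f_low_hz = f_low_hz,
         f_high_hz = f_high_hz, bandwidth_hz = bandwidth_hz,
         order = as.integer(order)),
    class = "filter_bank_config"
  )
}

#' Center frequencies of the filter bank
#'
#' Linearly spaced from `f_low_hz` to `f_high_hz` inclusive.
#'
#' @param config A [filter_bank_config()].
#' @return Numeric vector of length `n_filters`, strictly increasing.
#' @examples
#' diff(center_frequencies(filter_bank_config()))[1] # 1900/31 ~ 61.29 Hz
#' @export
center_frequencies <- function(config) {
  stopifnot(inherits(config, "filter_bank_config"))
  if (config$n_filters == 1) return(config$f_low_hz)
  seq(config$f_low_hz, config$f_high_hz, length.out = config$n_filters)
}

#' Butterworth band-pass coefficients
#'
#' Designs a digital Butterworth band-pass filter (analog prototype, lowpass
#' to bandpass transform, bilinear transform with frequency pre-warping),
#' returning transfer-function coefficients for a causal single-pass filter.
#' An order-`n` design has `2n` poles.
#'
#' @param f_low_hz,f_high_hz Passband edges in Hz (0 < low < high < Nyquist).
#' @param rate_hz Sampling rate in Hz.
#' @param order Prototype order (1-3 supported here).
#' @return List with numerator `b` and denominator `a` coefficient vectors
#'   (`a[1] == 1`).
#' @export
butter_bandpass <- function(f_low_hz, f_high_hz, rate_hz, order = 2) {
  stopifnot(order >= 1, f_low_hz > 0, f_high_hz > f_low_hz,
            f_high_hz < rate_hz / 2)
  fs2 <- 2 * rate_hz
  w1 <- fs2 * tan(pi * f_low_hz / rate_hz)
  w2 <- fs2 * tan(pi * f_high_hz / rate_hz)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  n <- as.integer(order)
  # analog lowpass prototype poles (unit cutoff, Butterworth circle)
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # lowpass -> bandpass: each pole splits into a conjugate-free pair
  ps <- p_lp * bw / 2
  disc <- sqrt(ps^2 - w0^2)
  p_bp <- c(ps + disc, ps - disc)
  gain <- bw^n                       # n zeros at s = 0
  # bilinear transform (zeros at s=0 -> z=1; 2n-n extra zeros at z=-1)
  p_z <- (fs2 + p_bp) / (fs2 - p_bp)
  z_z <- c(rep(1 + 0i, n), rep(-1 + 0i, n))
  gain_z <- gain * Re(prod(fs2 - rep(0i, n)) / prod(fs2 - p_bp))
  b <- Re(poly_from_roots(z_z)) * gain_z
  a <- Re(poly_from_roots(p_z))
  list(b = b, a = a)
}

# monic polynomial coefficients from roots (descending powers)
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs) * root
  coefs
}

#' Magnitude response of a digital filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| directly from the coefficients.
#'
#' @param coef List with `b` and `a` as returned by [butter_bandpass()].
#' @param f_hz Frequencies at which to evaluate (Hz).
#' @param rate_hz Sampling rate (Hz).
#' @return Numeric vector of magnitudes.
#' @export
filter_response <- function(coef, f_hz, rate_hz) {
  vapply(f_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / rate_hz)
    zp_b <- z^(seq_along(coef$b) - 1)
    zp_a <- z^(seq_along(coef$a) - 1)
    Mod(sum(coef$b * zp_b) / sum(coef$a * zp_a))
  }, numeric(1))
}

#' Encode a trace into rectified band-pass channels
#'
#' Passes the (normalized) trace through each band-pass filter of the bank,
#' causally (single pass, not zero-phase, as a real-time system would), and
#' full-wave rectifies the result. Channel k carries the instantaneous energy
#' of the trace near the k-th center frequency; these channel envelopes are
#' the "finger print" by which spike shapes are told apart, and they drive
#' the input layer of the network.
#'
#' Filters whose passband would cross 0 Hz or the Nyquist frequency are
#' clipped to the valid range with a warning.
#'
#' @param trace A [signal_trace()] (normalize first with [normalize_trace()]).
#' @param config A [filter_bank_config()].
#' @return A `channel_set`: list with `channels` (samples x n_filters matrix,
#'   all values >= 0), `rate_hz`, `t0_s` and `centers_hz`.
#' @export
encode <- function(trace, config = filter_bank_config()) {
  stopifnot(inherits(trace, "signal_trace"),
            inherits(config, "filter_bank_config"))
  nyq <- trace$rate_hz / 2
  centers <- center_frequencies(config)
  if (max(centers) >= nyq) {
    stop("filter passband reaches the Nyquist frequency; lower the bank range ",
         "or raise the sampling rate", call. = FALSE)
  }
  half <- config$bandwidth_hz / 2
  n <- length(trace$samples)
  out <- matrix(0, nrow = n, ncol = config$n_filters)
  clipped <- FALSE
  for (k in seq_len(config$n_filters)) {
    lo <- centers[k] - half
    hi <- centers[k] + half
    if (lo <= 0) { lo <- min(1, centers[k] / 2); clipped <- TRUE }
    if (hi >= nyq) { hi <- nyq * 0.999; clipped <- TRUE }
    coef <- butter_bandpass(lo, hi, trace$rate_hz, config$order)
    out[, k] <- abs(iir_filter_cpp(coef$b, coef$a, trace$samples))
  }
  if (clipped) {
    warning("one or more filter passbands were clipped to (0, Nyquist)",
            call. = FALSE)
  }
  structure(
    list(channels = out, rate_hz = trace$rate_hz, t0_s = trace$t0_s,
         centers_hz = centers),
    class = "channel_set"
  )
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> %d channels x %d samples @ %g Hz, centers %g-%g Hz\n",
              ncol(x$channels), nrow(x$channels), x$rate_hz,
              min(x$centers_hz), max(x$centers_hz)))
  invisible(x)
}

#' @export
as.list.channel_set <- function(x, ...) {
  lapply(seq_len(ncol(x$channels)), function(k) {
    signal_trace(x$channels[, k], x$rate_hz, x$t0_s)
  })
}

#' Band-energy profile of a waveform
#'
#' Mean rectified output of every filter-bank channel for a given trace;
#' used e.g. to check that two spike templates have distinguishable
#' frequency-domain finger prints.
#'
#' @param trace A [signal_trace()].
#' @param config A [filter_bank_config()].
#' @return Numeric vector of per-channel mean rectified amplitudes.
#' @export
band_energy_profile <- function(trace, config = filter_bank_config()) {
  enc <- encode(trace, config)
  colMeans(enc$channels)
}
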