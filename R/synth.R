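#' Spike waveform template
#'
#' A stereotyped action-potential shape as seen by an extracellular
#' electrode: 0.5-3 ms long, with spectral content below 3 kHz. Distinct
#' units produce distinct shapes, hence distinct band-energy finger prints in
#' the filter bank.
#'
#' @param waveform Numeric vector sampled at `rate_hz`.
#' @param rate_hz Sampling rate (Hz).
#' @param amplitude Peak absolute amplitude the waveform is scaled to.
#' @param label Unit name (e.g. `"A"`).
#' @return An object of class `spike_template`.
#' @export
spike_template <- function(waveform, rate_hz, amplitude = 1, label = "unit") {
  waveform <- as.numeric(waveform)
  dur_ms <- length(waveform) / rate_hz * 1000
  if (dur_ms < 0.5 || dur_ms > 3) {
    stop(sprintf("template duration %.2f ms outside [0.5, 3] ms", dur_ms),
         call. = FALSE)
  }
  if (!all(is.finite(waveform))) {
    stop("template waveform must be finite", call. = FALSE)
  }
  m <- max(abs(waveform))
  if (m == 0) stop("template waveform must be non-zero", call. = FALSE)
  structure(list(waveform = waveform / m * amplitude, rate_hz = rate_hz,
                 amplitude = amplitude, label = label),
            class = "spike_template")
}

#' Built-in spike template presets
#'
#' `"crayfish_pair"` (the default) produces two deterministic templates
#' emulating two units in a nerve recording: unit `"A"`, a narrow biphasic
#' spike (~1.1 ms) with energy concentrated around 1.3 kHz, and unit `"B"`, a
#' broader triphasic spike (~2.2 ms) centered near 450 Hz. Their band-energy
#' finger prints over the default 100-2000 Hz filter bank are well separated
#' (cosine similarity < 0.95). Both shapes are windowed cosines, so the
#' spectral content stays below 3 kHz.
#'
#' @param kind Preset name; currently `"crayfish_pair"`.
#' @param rate_hz Sampling rate the templates are rendered at.
#' @return List of [spike_template()] objects.
#' @export
make_templates <- function(kind = "crayfish_pair", rate_hz = 20000) {
  if (!identical(kind, "crayfish_pair")) {
    stop("unknown template preset: ", kind, call. = FALSE)
  }
  gabor <- function(f_hz, sigma_s, dur_s, phase = 0) {
    t <- seq(0, dur_s, by = 1 / rate_hz)
    tc <- dur_s / 2
    cos(2 * pi * f_hz * (t - tc) + phase) * exp(-(t - tc)^2 / (2 * sigma_s^2))
  }
  list(
    spike_template(gabor(1300, 0.22e-3, 1.1e-3), rate_hz, 1, "A"),
    spike_template(gabor(450, 0.45e-3, 2.2e-3, phase = pi / 2), rate_hz, 1, "B")
  )
}

#' Ground-truth event times
#'
#' @param events Named list: unit label -> sorted numeric vector of event
#'   times (s).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(events) {
  stopifnot(is.list(events), !is.null(names(events)))
  for (u in names(events)) {
    if (is.unsorted(events[[u]])) {
      stop("event times for unit '", u, "' must be sorted", call. = FALSE)
    }
  }
  structure(events, class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  for (u in names(x)) {
    cat(sprintf("  %s: %d events%s\n", u, length(x[[u]]),
                if (length(x[[u]])) sprintf(" in [%.2f, %.2f] s",
                                            min(x[[u]]), max(x[[u]])) else ""))
  }
  invisible(x)
}

#' Synthetic-recording configuration
#'
#' Describes an extracellular-like recording: spike templates placed at
#' Poisson event times (thinned by a per-unit refractory period), white
#' Gaussian background noise, and one low-frequency interference sinusoid
#' (field-potential-like, below the 100 Hz analysis band). The default is a
#' staged two-unit protocol scaled to desk size (0.1x of a 681 s recording):
#' unit B fires throughout 0-68.1 s, unit A only during 28.5-54.5 s, so the
#' network first learns B, then must pick up A as a new class, then shows
#' that A's neuron falls silent again.
#'
#' Event rates default to 3.3 Hz (tens of events per 10 s); amplitude/noise
#' defaults (template peak 1, `noise_sigma` 0.05) are calibration constants
#' for a clean nerve recording. `noise_kind = "pink"` adds 1/f background for
#' noisier, cortex-like traces.
#'
#' @param rate_hz Sampling rate (default 20 kHz).
#' @param duration_s Total duration (s).
#' @param templates List of [spike_template()].
#' @param unit_rates_hz Mean event rate per unit (recycled).
#' @param noise_sigma Gaussian background noise sd.
#' @param lf_noise_amp,lf_noise_hz Low-frequency sinusoid amplitude and
#'   frequency (must stay below 100 Hz).
#' @param refractory_s Per-unit minimum inter-event interval (recycled).
#' @param onset_s,offset_s Per-unit activity window (recycled; defaults give
#'   the staged protocol for two units, or the full duration otherwise).
#' @param noise_kind `"white"` or `"pink"`.
#' @param seed Seed for the generation substream.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(rate_hz = 20000, duration_s = 68.1,
                         templates = make_templates("crayfish_pair", rate_hz),
                         unit_rates_hz = 3.3, noise_sigma = 0.05,
                         lf_noise_amp = 0.2, lf_noise_hz = 7.5,
                         refractory_s = 0.01, onset_s = NULL, offset_s = NULL,
                         noise_kind = c("white", "pink"), seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  n_units <- length(templates)
  stopifnot(n_units >= 1, duration_s > 0, rate_hz > 0)
  if (any(unit_rates_hz <= 0)) stop("unit rates must be > 0", call. = FALSE)
  if (any(refractory_s < 0)) stop("refractory must be >= 0", call. = FALSE)
  if (lf_noise_hz >= 100) {
    stop("'lf_noise_hz' must be below the 100 Hz analysis band",
         call. = FALSE)
  }
  if (is.null(onset_s)) {
    onset_s <- if (n_units == 2) c(28.5, 0) * duration_s / 68.1 else
      rep(0, n_units)
  }
  if (is.null(offset_s)) {
    offset_s <- if (n_units == 2) c(54.5, 68.1) * duration_s / 68.1 else
      rep(duration_s, n_units)
  }
  structure(
    list(rate_hz = rate_hz, duration_s = duration_s, templates = templates,
         unit_rates_hz = rep_len(unit_rates_hz, n_units),
         noise_sigma = noise_sigma, lf_noise_amp = lf_noise_amp,
         lf_noise_hz = lf_noise_hz,
         refractory_s = rep_len(refractory_s, n_units),
         onset_s = rep_len(onset_s, n_units),
         offset_s = rep_len(pmin(offset_s, duration_s), n_units),
         noise_kind = noise_kind, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic extracellular recording with ground truth
#'
#' Event times per unit are drawn from a homogeneous Poisson process on the
#' unit's activity window and thinned by the refractory period; the unit's
#' template is added (linear superposition, so overlapping spikes from
#' different units occur naturally at high rates) and background noise plus
#' the low-frequency interference are superimposed. Generation is a pure
#' function of the configuration (including its seed).
#'
#' @param config A [synth_config()].
#' @return List with `trace` (a [signal_trace()]) and `truth`
#'   (a [ground_truth()]).
#' @export
generate_recording <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(substream_seed(config$seed, "synth"))
  n <- as.integer(round(config$duration_s * config$rate_hz))
  for (tpl in config$templates) {
    if (length(tpl$waveform) > n) {
      stop("template longer than the trace", call. = FALSE)
    }
  }
  x <- numeric(n)
  events <- list()
  for (u in seq_along(config$templates)) {
    tpl <- config$templates[[u]]
    times <- poisson_events(config$unit_rates_hz[u], config$onset_s[u],
                            config$offset_s[u], config$refractory_s[u])
    events[[tpl$label]] <- times
    wf <- tpl$waveform
    for (tt in times) {
      i0 <- as.integer(round(tt * config$rate_hz)) + 1L
      i1 <- min(i0 + length(wf) - 1L, n)
      if (i0 > n) next
      x[i0:i1] <- x[i0:i1] + wf[seq_len(i1 - i0 + 1L)]
    }
  }
  if (config$noise_sigma > 0) {
    noise <- stats::rnorm(n, sd = config$noise_sigma)
    if (config$noise_kind == "pink") noise <- pink_filter(noise)
    x <- x + noise
  }
  if (config$lf_noise_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    tvec <- (seq_len(n) - 1) / config$rate_hz
    x <- x + config$lf_noise_amp * sin(2 * pi * config$lf_noise_hz * tvec +
                                       phase)
  }
  list(trace = signal_trace(x, config$rate_hz),
       truth = ground_truth(events))
}

# homogeneous Poisson event times on [onset, offset], thinned so consecutive
# kept events are >= refractory apart
poisson_events <- function(rate_hz, onset_s, offset_s, refractory_s) {
  if (offset_s <= onset_s) return(numeric(0))
  span <- offset_s - onset_s
  n_exp <- stats::rpois(1, rate_hz * span)
  if (n_exp == 0) return(numeric(0))
  times <- sort(stats::runif(n_exp, onset_s, offset_s))
  kept <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory_s) {
      kept <- c(kept, tt)
      last <- tt
    }
  }
  kept
}

# Paul Kellet's economy 1/f filter: turns white noise into pink-ish noise
# with matched variance
pink_filter <- function(white) {
  n <- length(white)
  b0 <- 0; b1 <- 0; b2 <- 0
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- white[i]
    b0 <- 0.99765 * b0 + w * 0.0990460
    b1 <- 0.96300 * b1 + w * 0.2965164
    b2 <- 0.57000 * b2 + w * 1.0526913
    out[i] <- b0 + b1 + b2 + w * 0.1848
  }
  out * (stats::sd(white) / stats::sd(out))
}
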