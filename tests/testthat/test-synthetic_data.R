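test_that("template presets are deterministic with separable finger prints", {
  tp1 <- make_templates("crayfish_pair", 20000)
  tp2 <- make_templates("crayfish_pair", 20000)
  expect_length(tp1, 2)
  expect_identical(tp1, tp2)
  expect_equal(vapply(tp1, function(t) t$label, ""), c("A", "B"))
  durs <- vapply(tp1, function(t) length(t$waveform) / t$rate_hz, 0)
  expect_true(all(durs >= 0.5e-3 & durs <= 3e-3))
  expect_error(make_templates("nonesuch"), "unknown")

  # band-energy finger prints over the default bank are distinguishable
  pad <- function(tpl) signal_trace(c(tpl$waveform, rep(0, 4000)), 20000)
  p1 <- band_energy_profile(pad(tp1[[1]]))
  p2 <- band_energy_profile(pad(tp1[[2]]))
  cosine <- sum(p1 * p2) / sqrt(sum(p1^2) * sum(p2^2))
  expect_lt(cosine, 0.95)
})

test_that("template spectra stay below 3 kHz", {
  for (tpl in make_templates("crayfish_pair", 20000)) {
    x <- c(tpl$waveform, rep(0, 4096 - length(tpl$waveform)))
    spec <- Mod(stats::fft(x))[1:2048]
    freq <- (0:2047) * 20000 / 4096
    frac_high <- sum(spec[freq > 3000]^2) / sum(spec^2)
    expect_lt(frac_high, 0.01)
  }
  expect_error(spike_template(rep(1, 100), 20000), "duration") # 5 ms: too long
})

test_that("a noise-free recording is the exact superposition of templates", {
  cfg <- synth_config(duration_s = 5, unit_rates_hz = 2, noise_sigma = 0,
                      lf_noise_amp = 0, onset_s = c(0, 0), offset_s = c(5, 5),
                      seed = 21)
  rec <- generate_recording(cfg)
  n <- length(rec$trace$samples)
  manual <- numeric(n)
  for (u in seq_along(cfg$templates)) {
    tpl <- cfg$templates[[u]]
    for (tt in rec$truth[[tpl$label]]) {
      i0 <- as.integer(round(tt * cfg$rate_hz)) + 1L
      i1 <- min(i0 + length(tpl$waveform) - 1L, n)
      manual[i0:i1] <- manual[i0:i1] + tpl$waveform[seq_len(i1 - i0 + 1L)]
    }
  }
  expect_equal(rec$trace$samples, manual)
  expect_gt(sum(lengths(unclass(rec$truth))), 0)
})

test_that("event counts follow the Poisson expectation and honor windows", {
  r <- 5; dur <- 60
  cfg <- synth_config(duration_s = dur, unit_rates_hz = r, refractory_s = 0,
                      templates = make_templates()[1], onset_s = 0,
                      offset_s = dur, seed = 8)
  rec <- generate_recording(cfg)
  count <- length(rec$truth$A)
  expect_lt(abs(count - r * dur), 4 * sqrt(r * dur))

  # staged default protocol: unit A exists only inside its activity window
  staged <- generate_recording(synth_config(seed = 2))
  expect_true(all(staged$truth$A >= 28.5 & staged$truth$A <= 54.5))
  expect_true(all(staged$truth$B <= 68.1))
  expect_gt(length(staged$truth$B[staged$truth$B < 28.5]), 0)

  # refractory thinning: consecutive events at least refractory_s apart
  cfg2 <- synth_config(duration_s = 30, unit_rates_hz = 20,
                       refractory_s = 0.03, templates = make_templates()[1],
                       onset_s = 0, offset_s = 30, seed = 4)
  rec2 <- generate_recording(cfg2)
  expect_true(all(diff(rec2$truth$A) >= 0.03))
})

test_that("generation is a pure function of configuration and seed", {
  r1 <- generate_recording(synth_config(duration_s = 4, seed = 33))
  r2 <- generate_recording(synth_config(duration_s = 4, seed = 33))
  expect_identical(r1, r2)
  r3 <- generate_recording(synth_config(duration_s = 4, seed = 34))
  expect_false(identical(r1$trace$samples, r3$trace$samples))
})

test_that("sub-100 Hz interference barely leaks through the encoder", {
  rate <- 20000
  t <- seq(0, 1, by = 1 / rate)
  lf <- signal_trace(0.2 * sin(2 * pi * 7.5 * t), rate)
  tpl <- make_templates()[[2]]
  spike <- signal_trace(c(rep(0, 200), tpl$waveform,
                          rep(0, rate - 200 - length(tpl$waveform) + 1)), rate)
  e_lf <- sum(band_energy_profile(lf)^2)
  e_spike <- sum(band_energy_profile(spike)^2)
  expect_lt(e_lf, 0.01 * e_spike)
})

test_that("pink background noise is supported and reproducible", {
  cfg <- synth_config(duration_s = 2, noise_kind = "pink", seed = 12)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$trace$samples, r2$trace$samples)
  expect_error(synth_config(lf_noise_hz = 150), "below")
})
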