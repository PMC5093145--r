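test_that("max-abs normalization scales, preserves zeros and is idempotent", {
  tr <- signal_trace(c(0, 2, -4), 1000)
  expect_equal(normalize_trace(tr)$samples, c(0, 0.5, -1))

  z <- signal_trace(rep(0, 10), 1000)
  expect_equal(normalize_trace(z)$samples, rep(0, 10))

  set.seed(11)
  for (k in 1:10) {
    tr <- signal_trace(rnorm(200, sd = runif(1, 0.1, 50)), 5000)
    n1 <- normalize_trace(tr)
    expect_equal(max(abs(n1$samples)), 1)
    expect_equal(normalize_trace(n1)$samples, n1$samples)
    expect_equal(n1$rate_hz, tr$rate_hz)
    expect_length(n1$samples, length(tr$samples))
  }
})

test_that("traces reject non-finite samples and bad rates", {
  expect_error(signal_trace(c(1, NA), 1000), "finite")
  expect_error(signal_trace(c(1, Inf), 1000), "finite")
  expect_error(signal_trace(numeric(0), 1000), "at least one")
  expect_error(signal_trace(1:5, -1), "positive")
})

test_that("streaming normalization is causal and bounded", {
  x <- c(rep(0.5, 100), rep(2, 100))
  tr <- signal_trace(x, 1000)
  out <- normalize_trace(tr, streaming = TRUE, window_s = 0.05)
  expect_equal(out$samples[1:100], rep(1, 100))  # running max = |x| so far
  expect_true(all(abs(out$samples) <= 1))
})

test_that("center frequencies are linearly spaced over 100-2000 Hz", {
  cf <- center_frequencies(filter_bank_config())
  expect_length(cf, 32)
  expect_equal(cf[1], 100)
  expect_equal(cf[32], 2000)
  expect_true(all(diff(cf) > 0))
  expect_equal(unique(round(diff(cf), 10)), round(1900 / 31, 10))
  expect_equal(cf[16], 100 + 15 * 1900 / 31) # ~1019.35 Hz

  expect_equal(center_frequencies(filter_bank_config(n_filters = 2)),
               c(100, 2000))
  expect_error(filter_bank_config(n_filters = 1), "f_low_hz")
  expect_error(filter_bank_config(order = 4), "order")
})

test_that("band-pass magnitude response matches a sinusoid-probe oracle", {
  rate <- 20000
  cf <- center_frequencies(filter_bank_config())
  probe_gain <- function(coef, f) {
    # independent oracle: steady-state amplitude of a filtered sinusoid,
    # estimated from the RMS (robust to sampling phase at few samples/cycle)
    t <- seq(0, 0.6, by = 1 / rate)
    y <- iir_filter_cpp(coef$b, coef$a, sin(2 * pi * f * t))
    sqrt(2 * mean(y[6001:length(y)]^2))
  }
  for (k in c(1, 16, 32)) {
    coef <- butter_bandpass(cf[k] - 30, cf[k] + 30, rate, 2)
    g_centre <- probe_gain(coef, cf[k])
    expect_equal(g_centre, filter_response(coef, cf[k], rate),
                 tolerance = 0.01)
    # response at the center beats responses outside [center +/- bandwidth]
    for (f_out in c(cf[k] - 90, cf[k] + 90)) {
      if (f_out > 10) {
        expect_gt(g_centre, probe_gain(coef, f_out))
        expect_gt(filter_response(coef, cf[k], rate),
                  filter_response(coef, f_out, rate))
      }
    }
  }
})

test_that("encoding rectifies, selects the matching channel and rejects DC", {
  rate <- 20000
  cfgf <- filter_bank_config()
  cf <- center_frequencies(cfgf)
  t <- seq(0, 0.5, by = 1 / rate)

  # sinusoid at channel 16's center -> largest time-averaged output there
  tr <- signal_trace(sin(2 * pi * cf[16] * t), rate)
  enc <- encode(tr, cfgf)
  expect_true(all(enc$channels >= 0))
  expect_equal(which.max(colMeans(enc$channels)), 16)

  # zero input -> all channels zero
  enc0 <- encode(signal_trace(rep(0, 1000), rate), cfgf)
  expect_true(all(enc0$channels == 0))

  # constant (DC) input -> all channels ~0 after the transient
  encdc <- encode(signal_trace(rep(0.5, rate / 2), rate), cfgf)
  late <- encdc$channels[(nrow(encdc$channels) - 999):nrow(encdc$channels), ]
  expect_lt(max(late), 1e-6)
})

test_that("encoding is linear before rectification", {
  rate <- 20000
  set.seed(3)
  x <- rnorm(4000)
  cfgf <- filter_bank_config(n_filters = 4, f_low_hz = 200, f_high_hz = 800)
  e1 <- encode(signal_trace(x, rate), cfgf)
  e3 <- encode(signal_trace(3 * x, rate), cfgf)
  expect_equal(e3$channels, 3 * e1$channels, tolerance = 1e-9)
})

test_that("filter ringing dies out fast enough to resolve spikes tens of ms apart", {
  # The dominant pole pair of a 60 Hz-wide band-pass bounds the decay near
  # ln(100)/(pi*60) ~ 24 ms; the full 4-pole response reaches 1% of peak
  # within 50 ms for every filter in the default bank.
  rate <- 20000
  cf <- center_frequencies(filter_bank_config())
  impulse <- c(1, rep(0, rate - 1))
  for (k in c(1, 8, 16, 24, 32)) {
    coef <- butter_bandpass(cf[k] - 30, cf[k] + 30, rate, 2)
    h <- iir_filter_cpp(coef$b, coef$a, impulse)
    decay_s <- max(which(abs(h) > 0.01 * max(abs(h)))) / rate
    expect_lt(decay_s, 0.050)
  }
})

test_that("out-of-range passbands error or clip with a warning", {
  expect_error(
    encode(signal_trace(rnorm(100), 3000), filter_bank_config()),
    "Nyquist")
  expect_warning(
    encode(signal_trace(rnorm(2000), 20000),
           filter_bank_config(n_filters = 4, f_low_hz = 20, f_high_hz = 500)),
    "clipped")
})
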