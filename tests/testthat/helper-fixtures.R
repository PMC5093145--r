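# Shared fixtures, built in code at test time.

# default end-to-end pipeline (68 s staged two-unit recording, seed 1),
# memoized because several test files inspect it
default_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_config()
      rec <- generate_recording(synth_config(seed = cfg$seed))
      run <- spike_sort(rec$trace, cfg)
      ev <- evaluate_run(run, rec$truth, evaluation_config(), rec$trace)
      cache <<- list(cfg = cfg, rec = rec, run = run, ev = ev)
    }
    cache
  }
})

# a short two-unit recording for fast network-level tests
short_recording <- function(duration_s = 3, seed = 7, rates = 8) {
  synth_config(duration_s = duration_s, unit_rates_hz = rates,
               onset_s = c(0, 0), offset_s = c(duration_s, duration_s),
               seed = seed)
}

# a zero-spread distribution: conductances are exactly 1/median
exact_dist <- function() {
  resistance_distribution(median_lrs_ohm = 25e3, sigma_log_lrs = 0,
                          median_hrs_ohm = 250e3, sigma_log_hrs = 0)
}

# single-channel set holding a given drive matrix
drive_channels <- function(mat, rate_hz = 20000) {
  structure(list(channels = mat, rate_hz = rate_hz, t0_s = 0,
                 centers_hz = seq_len(ncol(mat))),
            class = "channel_set")
}
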