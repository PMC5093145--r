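test_that("assignment matches neurons to units causally and injectively", {
  cfg <- evaluation_config()
  truth <- ground_truth(list(A = c(1, 2, 3), B = c(1.5, 2.5, 3.5)))
  # neuron 1 follows A events by 5 ms, neuron 2 follows B events by 8 ms
  out <- spike_train(sort(c(c(1, 2, 3) + 0.005, c(1.5, 2.5, 3.5) + 0.008)),
                     c(1, 2, 1, 2, 1, 2))
  a <- assign_neurons(out, truth, cfg)
  expect_equal(a[["A"]], 1L)
  expect_equal(a[["B"]], 2L)
  expect_equal(anyDuplicated(a), 0L)

  # a neuron spiking only BEFORE events is not assigned to that unit
  pre <- spike_train(c(0.99, 1.99, 2.99), c(1, 1, 1))
  expect_length(assign_neurons(pre, ground_truth(list(A = c(1, 2, 3))), cfg), 0)

  expect_warning(a0 <- assign_neurons(spike_train(), truth, cfg), "no output")
  expect_length(a0, 0)
})

test_that("recognition rate counts matched events per bin, half-open window", {
  cfg <- evaluation_config(match_window_s = 0.02, bin_s = 10)
  truth <- c(1, 2, 3, 4, 5)
  # 4 of 5 events matched within the window
  out <- spike_train(c(1.01, 2.01, 3.01, 4.01), rep(1, 4))
  rr <- recognition_rate(out, truth, 1, cfg)
  expect_equal(rr$mean_rate, 0.8)
  expect_equal(rr$per_bin$n_events, 5)

  # a spike exactly at the event time is not causal -> no recognition
  sim <- spike_train(c(1, 2, 3), c(1, 1, 1))
  expect_equal(recognition_rate(sim, c(1, 2, 3), 1, cfg)$mean_rate, 0)
  # +10 ms spikes match every event
  late <- spike_train(c(1.01, 2.01, 3.01), c(1, 1, 1))
  expect_equal(recognition_rate(late, c(1, 2, 3), 1, cfg)$mean_rate, 1)

  # a silent neuron scores zero
  expect_equal(recognition_rate(spike_train(), truth, 1, cfg)$mean_rate, 0)

  # invariance: extra assigned-neuron spikes outside every window change nothing
  extra <- spike_train(sort(c(late$time_s, 0.5, 1.5, 7)), rep(1, 6))
  expect_equal(recognition_rate(extra, c(1, 2, 3), 1, cfg)$mean_rate, 1)
})

test_that("bins without events are excluded from the mean", {
  cfg <- evaluation_config(bin_s = 10)
  truth <- c(25, 26, 27, 28)          # all events in bin [20, 30)
  out <- spike_train(c(25.01, 26.01), c(1, 1))
  rr <- recognition_rate(out, truth, 1, cfg, t_end = 60)
  expect_equal(nrow(rr$per_bin), 1)   # bins 0-10, 10-20, 30+ excluded
  expect_equal(rr$per_bin$bin_start_s, 20)
  expect_equal(rr$mean_rate, 0.5)
})

test_that("activity histograms count exactly and conserve totals", {
  empty <- activity_histogram(spike_train(), bin_s = 10, duration_s = 30,
                              n_neurons = 5)
  expect_true(all(empty == 0))
  expect_equal(dim(empty), c(5, 3))

  seven <- spike_train(seq(12, 18, along.with = 1:7), rep(2, 7))
  h <- activity_histogram(seven, 10, duration_s = 30, n_neurons = 3)
  expect_equal(h[2, 2], 7)
  expect_equal(sum(h), 7)

  set.seed(6)
  tms <- sort(runif(200, 0, 95))
  ids <- sample(1:5, 200, replace = TRUE)
  h2 <- activity_histogram(spike_train(tms, ids), 10, duration_s = 100)
  expect_equal(sum(h2), 200)
  expect_equal(unname(rowSums(h2)), unname(tabulate(ids, 5)))
})

test_that("the system report reproduces the published energy arithmetic", {
  lg <- ledger_from_counts(n_read = 16.2e6, n_set = 27.5e3, n_reset = 58.6e3,
                           e_read_per_event = 0.39e-12,
                           e_set_per_event = 75e-12,
                           e_reset_per_event = 45e-12)
  rep <- system_report(lg, energy_model(), duration_s = 681, n_devices = 1600)
  e_expected <- 16.2e6 * 0.39e-12 + 27.5e3 * 75e-12 + 58.6e3 * 45e-12
  expect_equal(rep$e_total_j, e_expected)
  expect_equal(rep$power_w, e_expected / 681)
  # Eq. 2 equals the ledger's accumulated energy when pulses are constant
  expect_equal(rep$e_total_j, lg$e_read_j + lg$e_set_j + lg$e_reset_j)
  # neuron energy adds spikes x 2 pJ
  rep2 <- system_report(lg, energy_model(), 681, 1600,
                        neuron_spike_count = 330e3)
  expect_equal(rep2$e_neuron_j, 330e3 * 2e-12)
  expect_error(system_report(lg, energy_model(), 0, 1600), "duration")
})

test_that("data reduction is samples per output event", {
  tr <- signal_trace(rep(0, 2e6), 20000)
  out <- spike_train(seq(0.1, 99.9, length.out = 2000), rep(1, 2000))
  expect_equal(data_reduction(tr, out), 1000)
  expect_equal(data_reduction(tr, spike_train()), Inf)
  half <- spike_train(seq(0.1, 99.9, length.out = 4000), rep(1, 4000))
  expect_equal(data_reduction(tr, half), 500)
})

test_that("precision counts causal matches of the neuron's own spikes", {
  cfg <- evaluation_config()
  truth <- c(1, 2)
  out <- spike_train(c(1.005, 1.5, 2.01), c(1, 1, 1))
  expect_equal(neuron_precision(out, truth, 1, cfg), 2 / 3)
  expect_true(is.na(neuron_precision(spike_train(), truth, 1, cfg)))
})
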