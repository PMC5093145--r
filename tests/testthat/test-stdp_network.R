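test_that("certain potentiation drives a synapse to weight 1, frozen learning changes nothing", {
  dist <- exact_dist()
  set.seed(1)
  bank <- synapse_bank(4, 2, 10, dist, init = "hrs")
  lg <- event_ledger()
  # input 1 fired recently, inputs 2-4 never fired
  last_pre <- c(0.009, -Inf, -Inf, -Inf)
  bank <- apply_stdp(bank, post_neuron = 1, t_post_s = 0.010,
                     last_pre_times = last_pre,
                     params = stdp_params(p_set = 1, p_reset = 1,
                                          t_ltp_s = 0.002),
                     ledger = lg)
  w <- bank_weights(bank)
  expect_equal(w[1, 1], 1)            # LTP branch: all devices Set
  expect_equal(w[2:4, 1], rep(0, 3))  # LTD on never-active inputs (all HRS already)
  expect_equal(w[, 2], rep(0, 4))     # other neuron untouched
  expect_equal(lg$n_set, 10)
  expect_equal(lg$e_set_j, 10 * 75e-12)

  # p = 0 freezes everything
  set.seed(2)
  bank2 <- synapse_bank(4, 2, 10, dist, init = "random")
  lg2 <- event_ledger()
  out <- apply_stdp(bank2, 1, 0.01, last_pre,
                    stdp_params(p_set = 0, p_reset = 0), ledger = lg2)
  expect_identical(out, bank2)
  expect_equal(lg2$n_set + lg2$n_reset, 0)
})

test_that("certain depression resets active LRS devices of non-recent inputs", {
  dist <- exact_dist()
  bank <- synapse_bank(3, 2, 5, dist, init = "lrs")
  lg <- event_ledger()
  bank <- apply_stdp(bank, 2, t_post_s = 1,
                     last_pre_times = c(0.999, 0.5, -Inf),
                     params = stdp_params(p_set = 1, p_reset = 1,
                                          t_ltp_s = 0.01),
                     ledger = lg)
  w <- bank_weights(bank)
  expect_equal(w[, 2], c(1, 0, 0))  # input 1 recent (kept), 2 and 3 depressed
  expect_equal(w[, 1], rep(1, 3))   # neuron 1 untouched
  expect_equal(lg$n_reset, 10)
})

test_that("gradual potentiation follows the Bernoulli closed form", {
  # expected LRS fraction after k LTP events from all-HRS: 1 - (1 - p)^k
  dist <- resistance_distribution()
  p <- 0.1
  n_syn <- 2000; n_dev <- 10
  set.seed(31)
  bank <- synapse_bank(n_syn, 1, n_dev, dist, init = "hrs")
  last_pre <- rep(0, n_syn)
  for (k in 1:6) {
    bank <- apply_stdp(bank, 1, 0, last_pre, stdp_params(p_set = p),
                       ledger = event_ledger())
    f_obs <- mean(bank$state)
    f_exp <- 1 - (1 - p)^k
    se <- sqrt(f_exp * (1 - f_exp) / (n_syn * n_dev))
    expect_lt(abs(f_obs - f_exp), 3 * se)
  }
})

test_that("winner-take-all picks the eligible suprathreshold argmax", {
  expect_equal(winner_take_all(c(0.6, 0.59, 0, 0, 0), 0.58), 1L)
  expect_true(is.na(winner_take_all(c(0.5, 0.57, 0.2, 0, 0), 0.58)))
  expect_equal(winner_take_all(c(0.6, 0.6, 0.6, 0, 0), 0.58), 1L) # tie: low id
  expect_equal(winner_take_all(c(0.6, 0.7, 0), 0.58,
                               eligible = c(TRUE, FALSE, TRUE)), 1L)
  expect_true(is.na(winner_take_all(c(0.6, 0.7), 0.58,
                                    eligible = c(FALSE, FALSE))))
})

test_that("the default topology instantiates 160 synapses and 1600 devices", {
  set.seed(1)
  bank <- synapse_bank()
  expect_equal(bank$n_input * bank$n_output, 160)
  expect_equal(ncol(bank$state), 160)
  expect_equal(length(bank$state), 1600)
  expect_equal(dim(bank$g), c(10, 160))
})

test_that("zero input yields no spikes and an all-zero ledger", {
  ch <- drive_channels(matrix(0, nrow = 2000, ncol = 32))
  run <- run_network(ch, network_config(seed = 3))
  expect_equal(nrow(run$input_spikes), 0)
  expect_equal(nrow(run$output_spikes), 0)
  expect_equal(run$ledger$n_read + run$ledger$n_set + run$ledger$n_reset, 0)
})

test_that("with learning off, reads scale exactly with input spikes and nothing is programmed", {
  rec <- generate_recording(short_recording())
  enc <- encode(normalize_trace(rec$trace), filter_bank_config())
  run <- run_network(enc, network_config(seed = 5), learning = FALSE)
  expect_gt(nrow(run$input_spikes), 0)
  expect_equal(run$ledger$n_set, 0)
  expect_equal(run$ledger$n_reset, 0)
  expect_equal(run$ledger$n_read, nrow(run$input_spikes) * 5 * 10)
  # deterministic under the same seed
  run2 <- run_network(enc, network_config(seed = 5), learning = FALSE)
  expect_identical(run$output_spikes, run2$output_spikes)
})

test_that("learning runs are reproducible and keep weights in [0, 1]", {
  rec <- generate_recording(short_recording())
  enc <- encode(normalize_trace(rec$trace), filter_bank_config())
  run1 <- run_network(enc, network_config(seed = 9), learning = TRUE,
                      snapshot_every_s = 0.5)
  run2 <- run_network(enc, network_config(seed = 9), learning = TRUE,
                      snapshot_every_s = 0.5)
  expect_identical(run1$input_spikes, run2$input_spikes)
  expect_identical(run1$output_spikes, run2$output_spikes)
  expect_identical(run1$bank, run2$bank)
  expect_equal(run1$ledger$e_set_j, run2$ledger$e_set_j)
  for (w in run1$snapshots$weights) {
    expect_true(all(w >= 0 & w <= 1))
  }
  expect_true(all(run1$weights >= 0 & run1$weights <= 1))
  # winner-take-all: at most one output spike per clock step
  expect_false(any(duplicated(run1$output_spikes$time_s)))
})

test_that("the compiled and pure-R engines agree spike-for-spike", {
  rec <- generate_recording(short_recording(duration_s = 1.2, seed = 13,
                                            rates = 10))
  enc <- encode(normalize_trace(rec$trace), filter_bank_config())
  cfg <- network_config(seed = 17)
  rc <- run_network(enc, cfg, learning = TRUE, engine = "cpp")
  rr <- run_network(enc, cfg, learning = TRUE, engine = "r")
  expect_gt(nrow(rc$output_spikes), 0)
  expect_equal(rr$input_spikes, rc$input_spikes)
  expect_equal(rr$output_spikes, rc$output_spikes)
  expect_equal(rr$bank$state, rc$bank$state)
  expect_equal(rr$bank$g, rc$bank$g, tolerance = 1e-15)
  expect_equal(rr$ledger$n_read, rc$ledger$n_read)
  expect_equal(rr$ledger$n_set, rc$ledger$n_set)
  expect_equal(rr$ledger$n_reset, rc$ledger$n_reset)
  expect_equal(rr$ledger$e_read_j, rc$ledger$e_read_j, tolerance = 1e-12)
})

test_that("channel mismatches are rejected", {
  ch <- drive_channels(matrix(0, nrow = 100, ncol = 8))
  expect_error(run_network(ch, network_config(seed = 1)), "n_input")
  tr1 <- signal_trace(rep(0, 100), 1000)
  tr2 <- signal_trace(rep(0, 50), 1000)
  expect_error(run_network(list(tr1, tr2),
                           network_config(n_input = 2, seed = 1)),
               "identical length")
})
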