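test_that("programming pulses cost V*I*t: 75 pJ per Set, 45 pJ per Reset", {
  m <- energy_model()
  expect_equal(pulse_energy(m, "set"), 75e-12)
  expect_equal(pulse_energy(m, "reset"), 45e-12)
  # read energy follows from the device resistance: V^2/R*t
  expect_equal(pulse_energy(m, "read", resistance_ohm = 25640),
               0.1 * (0.1 / 25640) * 1e-6)   # ~0.39 pJ
  expect_equal(pulse_energy(m, "read", resistance_ohm = 2 * 25640),
               pulse_energy(m, "read", resistance_ohm = 25640) / 2)
})

test_that("program_device books every pulse, even into the same state", {
  dist <- exact_dist()
  lg <- event_ledger()
  dev <- oxram_device("HRS", dist)
  dev <- program_device(dev, "LRS", dist, energy_model(), lg)
  expect_equal(dev$state, "LRS")
  expect_equal(dev$conductance_s, 1 / 25e3)  # zero spread: exactly 1/median
  expect_equal(lg$n_set, 1)
  expect_equal(lg$e_set_j, 75e-12)

  # a redundant Set pulse still counts
  dev <- program_device(dev, "LRS", dist, energy_model(), lg)
  expect_equal(lg$n_set, 2)
  expect_equal(lg$e_set_j, 150e-12)

  dev <- program_device(dev, "HRS", dist, energy_model(), lg)
  expect_equal(dev$conductance_s, 1 / 250e3)
  expect_equal(lg$n_reset, 1)
  expect_equal(lg$e_reset_j, 45e-12)
})

test_that("with zero spread the compound weight takes exactly n+1 levels", {
  dist <- exact_dist()
  n <- 10
  weights <- sapply(0:n, function(k) {
    syn <- compound_synapse(n, dist, init = "hrs")
    if (k > 0) {
      syn$state[seq_len(k)] <- TRUE
      syn$g[seq_len(k)] <- 1 / dist$median_lrs_ohm
    }
    synapse_weight(syn)
  })
  expect_equal(weights[1], 0)        # all HRS
  expect_equal(weights[n + 1], 1)    # all LRS
  expect_equal(weights, (0:n) / n, tolerance = 1e-12)
  expect_length(unique(weights), n + 1)
  expect_true(all(diff(weights) > 0))  # monotone in the number of LRS devices
})

test_that("reading a synapse returns the weight and books n device reads", {
  dist <- exact_dist()
  syn <- compound_synapse(10, dist, init = "lrs")
  lg <- event_ledger()
  w <- read_synapse(syn, energy_model(), lg)
  expect_equal(w, 1)
  expect_equal(lg$n_read, 10)
  expect_equal(lg$e_read_j, 10 * 0.1^2 / 25e3 * 1e-6)
  # zero reads -> zero read energy
  expect_equal(event_ledger()$e_read_j, 0)
})

test_that("ledger energies stay linear in event counts for fixed pulses", {
  dist <- resistance_distribution()
  m <- energy_model()
  lg <- event_ledger()
  set.seed(5)
  dev <- oxram_device("HRS", dist)
  targets <- sample(c("LRS", "HRS"), 100, replace = TRUE)
  for (tg in targets) dev <- program_device(dev, tg, dist, m, lg)
  expect_equal(lg$n_set + lg$n_reset, 100)
  expect_equal(lg$e_set_j, lg$n_set * 75e-12)
  expect_equal(lg$e_reset_j, lg$n_reset * 45e-12)
})

test_that("conductances are positive and reproducible under a fixed seed", {
  dist <- resistance_distribution()
  set.seed(42); b1 <- synapse_bank(8, 3, 10, dist)
  set.seed(42); b2 <- synapse_bank(8, 3, 10, dist)
  expect_identical(b1, b2)
  expect_true(all(b1$g > 0))
  # one-decade resistance window: LRS conductance median above HRS median
  expect_gt(1 / dist$median_lrs_ohm, 10 / dist$median_hrs_ohm * 0.999)
  expect_error(resistance_distribution(median_lrs_ohm = 1e5,
                                       median_hrs_ohm = 1e4), "exceed")
})

test_that("endurance extrapolation scales per-device means to the horizon", {
  lg <- ledger_from_counts(n_set = 27.5e3, n_reset = 58.6e3)
  # identity horizon returns the observed per-device means
  obs <- extrapolate_endurance(lg, 1600, duration_s = 681, horizon_s = 681)
  expect_equal(unname(obs), c(27.5e3, 58.6e3) / 1600)
  ten <- extrapolate_endurance(lg, 1600, duration_s = 681)
  expect_equal(unname(ten), c(27.5e3, 58.6e3) / 1600 * (10 * 365 * 86400) / 681)
  expect_error(extrapolate_endurance(lg, 1600, duration_s = 0), "duration")
})
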