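#' Resistance distributions of the binary memory device
#'
#' A binary OxRAM device programmed with fixed pulse conditions lands in one
#' of two non-volatile states, LRS (low resistance) or HRS (high resistance),
#' with cycle-to-cycle variability: each programming event re-samples the
#' device resistance from the state's log-normal distribution. Defaults give
#' a one-decade median-to-median resistance window (25 kOhm vs 250 kOhm);
#' the log-scale spreads are behavioral calibration constants.
#'
#' @param median_lrs_ohm Median LRS resistance (Ohm).
#' @param sigma_log_lrs Log-normal spread (sdlog) of the LRS.
#' @param median_hrs_ohm Median HRS resistance (Ohm), must exceed the LRS
#'   median.
#' @param sigma_log_hrs Log-normal spread (sdlog) of the HRS.
#' @return An object of class `resistance_distribution`.
#' @export
resistance_distribution <- function(median_lrs_ohm = 25e3, sigma_log_lrs = 0.3,
                                    median_hrs_ohm = 250e3,
                                    sigma_log_hrs = 0.5) {
  if (median_hrs_ohm <= median_lrs_ohm) {
    stop("'median_hrs_ohm' must exceed 'median_lrs_ohm'", call. = FALSE)
  }
  if (sigma_log_lrs < 0 || sigma_log_hrs < 0) {
    stop("log-normal spreads must be >= 0", call. = FALSE)
  }
  structure(list(median_lrs_ohm = median_lrs_ohm,
                 sigma_log_lrs = sigma_log_lrs,
                 median_hrs_ohm = median_hrs_ohm,
                 sigma_log_hrs = sigma_log_hrs),
            class = "resistance_distribution")
}

# one conductance sample per requested device; draw order matches the C++
# engine (exp(-(log median + sigma * z)))
sample_conductance <- function(dist, state, n = 1L) {
  if (state == "LRS") {
    exp(-(log(dist$median_lrs_ohm) + dist$sigma_log_lrs * stats::rnorm(n)))
  } else {
    exp(-(log(dist$median_hrs_ohm) + dist$sigma_log_hrs * stats::rnorm(n)))
  }
}

#' Programming and read pulse conditions
#'
#' Per-event energy is `E = V * I * t` for Set and Reset pulses, whose
#' current is fixed by the programming compliance. A read applies `v_read_v`
#' for `t_read_s`; the read current is set by the device resistance
#' (`I = V / R`), so read energy depends on the device state. Defaults are
#' the abrupt-switching pulse conditions (compliance 30 uA, Set 2.5 V, Reset
#' 1.5 V magnitude, 1 us pulses, 0.1 V / 1 us reads), giving 75 pJ per Set
#' and 45 pJ per Reset.
#'
#' @param v_set_v,i_set_a,t_set_s Set pulse voltage (V), current (A), time (s).
#' @param v_reset_v,i_reset_a,t_reset_s Reset pulse conditions (magnitudes).
#' @param v_read_v,t_read_s Read conditions.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(v_set_v = 2.5, i_set_a = 30e-6, t_set_s = 1e-6,
                         v_reset_v = 1.5, i_reset_a = 30e-6, t_reset_s = 1e-6,
                         v_read_v = 0.1, t_read_s = 1e-6) {
  vals <- c(v_set_v, i_set_a, t_set_s, v_reset_v, i_reset_a, t_reset_s,
            v_read_v, t_read_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all pulse magnitudes must be positive and finite", call. = FALSE)
  }
  structure(list(v_set_v = v_set_v, i_set_a = i_set_a, t_set_s = t_set_s,
                 v_reset_v = v_reset_v, i_reset_a = i_reset_a,
                 t_reset_s = t_reset_s, v_read_v = v_read_v,
                 t_read_s = t_read_s),
            class = "energy_model")
}

#' Per-event pulse energy
#'
#' `E_mode = V_mode * I_mode * t_mode` for programming pulses; for reads the
#' current follows from the device resistance, so `resistance_ohm` must be
#' supplied and `E = V^2 / R * t`.
#'
#' @param model An [energy_model()].
#' @param mode One of `"set"`, `"reset"`, `"read"`.
#' @param resistance_ohm Device resistance for read events (Ohm).
#' @return Energy in joules.
#' @examples
#' pulse_energy(energy_model(), "set")   # 7.5e-11 J = 75 pJ
#' pulse_energy(energy_model(), "reset") # 4.5e-11 J = 45 pJ
#' @export
pulse_energy <- function(model, mode = c("set", "reset", "read"),
                         resistance_ohm = NULL) {
  mode <- match.arg(mode)
  switch(mode,
    set = model$v_set_v * model$i_set_a * model$t_set_s,
    reset = model$v_reset_v * model$i_reset_a * model$t_reset_s,
    read = {
      if (is.null(resistance_ohm)) {
        stop("read energy requires 'resistance_ohm'", call. = FALSE)
      }
      model$v_read_v^2 / resistance_ohm * model$t_read_s
    })
}

#' Event ledger for device operations
#'
#' Mutable accumulator (an environment) counting Read/Set/Reset events and
#' their energies across a simulation, mirroring the bookkeeping needed for
#' total-energy and endurance estimates.
#'
#' @return An object of class `event_ledger` with fields `n_read`, `n_set`,
#'   `n_reset` (counts) and `e_read_j`, `e_set_j`, `e_reset_j` (joules).
#' @export
event_ledger <- function() {
  lg <- new.env(parent = emptyenv())
  lg$n_read <- 0; lg$n_set <- 0; lg$n_reset <- 0
  lg$e_read_j <- 0; lg$e_set_j <- 0; lg$e_reset_j <- 0
  class(lg) <- "event_ledger"
  lg
}

#' @export
print.event_ledger <- function(x, ...) {
  cat("<event_ledger>\n")
  cat(sprintf("  Read events  %12g  (%.4g J)\n", x$n_read, x$e_read_j))
  cat(sprintf("  Set events   %12g  (%.4g J)\n", x$n_set, x$e_set_j))
  cat(sprintf("  Reset events %12g  (%.4g J)\n", x$n_reset, x$e_reset_j))
  invisible(x)
}

#' @param n_read,n_set,n_reset Event counts to record.
#' @param e_read_j,e_set_j,e_reset_j Energies (J) to accumulate.
#' @param ledger An [event_ledger()].
#' @rdname event_ledger
#' @export
ledger_add <- function(ledger, n_read = 0, n_set = 0, n_reset = 0,
                       e_read_j = 0, e_set_j = 0, e_reset_j = 0) {
  stopifnot(inherits(ledger, "event_ledger"))
  ledger$n_read <- ledger$n_read + n_read
  ledger$n_set <- ledger$n_set + n_set
  ledger$n_reset <- ledger$n_reset + n_reset
  ledger$e_read_j <- ledger$e_read_j + e_read_j
  ledger$e_set_j <- ledger$e_set_j + e_set_j
  ledger$e_reset_j <- ledger$e_reset_j + e_reset_j
  invisible(ledger)
}

#' Build a ledger from aggregate counts
#'
#' Useful for what-if energy estimates: supplies event counts together with
#' constant per-event energies.
#'
#' @param n_read,n_set,n_reset Event counts.
#' @param e_read_per_event,e_set_per_event,e_reset_per_event Per-event
#'   energies (J).
#' @return An [event_ledger()].
#' @export
ledger_from_counts <- function(n_read = 0, n_set = 0, n_reset = 0,
                               e_read_per_event = 0,
                               e_set_per_event = 0,
                               e_reset_per_event = 0) {
  lg <- event_ledger()
  ledger_add(lg, n_read = n_read, n_set = n_set, n_reset = n_reset,
             e_read_j = n_read * e_read_per_event,
             e_set_j = n_set * e_set_per_event,
             e_reset_j = n_reset * e_reset_per_event)
}

#' A single binary resistive device
#'
#' @param state `"LRS"` or `"HRS"`.
#' @param dist A [resistance_distribution()] used to sample the conductance.
#' @return An object of class `oxram_device` with fields `state` and
#'   `conductance_s` (siemens).
#' @export
oxram_device <- function(state = c("HRS", "LRS"),
                         dist = resistance_distribution()) {
  state <- match.arg(state)
  structure(list(state = state,
                 conductance_s = sample_conductance(dist, state)),
            class = "oxram_device")
}

#' Apply a programming pulse to a device
#'
#' Sets the device to `target`, re-samples its conductance from the target
#' state's distribution (cycle-to-cycle variability) and books one Set or
#' Reset event in the ledger. A pulse applied to a device already in the
#' target state still re-samples and still costs one pulse of energy: a
#' physical pulse is a physical pulse.
#'
#' @param device An [oxram_device()].
#' @param target `"LRS"` (Set) or `"HRS"` (Reset).
#' @param dist A [resistance_distribution()].
#' @param model An [energy_model()].
#' @param ledger An [event_ledger()], updated in place.
#' @return The reprogrammed [oxram_device()].
#' @export
program_device <- function(device, target = c("LRS", "HRS"),
                           dist = resistance_distribution(),
                           model = energy_model(),
                           ledger = event_ledger()) {
  target <- match.arg(target)
  device$state <- target
  device$conductance_s <- sample_conductance(dist, target)
  if (target == "LRS") {
    ledger_add(ledger, n_set = 1, e_set_j = pulse_energy(model, "set"))
  } else {
    ledger_add(ledger, n_reset = 1, e_reset_j = pulse_energy(model, "reset"))
  }
  device
}

#' Compound synapse of parallel binary devices
#'
#' One synaptic weight is realized by `n_devices` binary devices wired in
#' parallel; the number of devices in the low-resistance state sets the total
#' conductance, giving approximately `n_devices + 1` distinct weight levels
#' (exactly so when the device spread is zero). By default each device starts
#' in LRS with probability 1/2, so untrained weights scatter around 0.5.
#'
#' @param n_devices Number of parallel devices (default 10).
#' @param dist A [resistance_distribution()].
#' @param init `"random"` (Bernoulli 1/2 per device), `"hrs"` or `"lrs"`.
#' @return An object of class `compound_synapse`: fields `state` (logical,
#'   TRUE = LRS), `g` (conductances, S) and `dist`.
#' @export
compound_synapse <- function(n_devices = 10,
                             dist = resistance_distribution(),
                             init = c("random", "hrs", "lrs")) {
  init <- match.arg(init)
  stopifnot(n_devices >= 1)
  lrs <- switch(init,
    random = stats::runif(n_devices) < 0.5,
    hrs = rep(FALSE, n_devices),
    lrs = rep(TRUE, n_devices))
  g <- numeric(n_devices)
  for (d in seq_len(n_devices)) {
    g[d] <- sample_conductance(dist, if (lrs[d]) "LRS" else "HRS")
  }
  structure(list(state = lrs, g = g, dist = dist),
            class = "compound_synapse")
}

# expected conductance-sum bounds under the state medians
synapse_g_bounds <- function(n_devices, dist) {
  c(g_min = n_devices / dist$median_hrs_ohm,
    g_max = n_devices / dist$median_lrs_ohm)
}

#' Normalized weight of a compound synapse
#'
#' `(G_total - G_min) / (G_max - G_min)` clipped to \[0, 1\], where `G_total`
#' is the summed device conductance and `G_min` / `G_max` are the all-HRS /
#' all-LRS sums expected from the distribution medians.
#'
#' @param syn A [compound_synapse()].
#' @return Weight in \[0, 1\].
#' @export
synapse_weight <- function(syn) {
  stopifnot(inherits(syn, "compound_synapse"))
  bounds <- synapse_g_bounds(length(syn$state), syn$dist)
  if (bounds["g_max"] <= bounds["g_min"]) {
    stop("degenerate resistance window: G_max must exceed G_min",
         call. = FALSE)
  }
  w <- (sum(syn$g) - bounds[["g_min"]]) / (bounds[["g_max"]] - bounds[["g_min"]])
  min(max(w, 0), 1)
}

#' Read a compound synapse
#'
#' Returns the normalized weight and books one read event per device plus the
#' read energy `sum(V_read^2 / R_d * t_read)` over the devices.
#'
#' @param syn A [compound_synapse()].
#' @param model An [energy_model()].
#' @param ledger An [event_ledger()], updated in place.
#' @return Weight in \[0, 1\].
#' @export
read_synapse <- function(syn, model = energy_model(),
                         ledger = event_ledger()) {
  stopifnot(inherits(syn, "compound_synapse"))
  e <- model$v_read_v^2 * model$t_read_s * sum(syn$g)
  ledger_add(ledger, n_read = length(syn$state), e_read_j = e)
  synapse_weight(syn)
}

#' Extrapolate per-device programming counts to a longer horizon
#'
#' Mean Set/Reset counts per device observed over `duration_s`, scaled
#' linearly to `horizon_s` (default ten years), e.g. to judge whether device
#' cycling endurance suffices for a chronic implant.
#'
#' @param ledger An [event_ledger()].
#' @param n_devices Number of devices sharing the counts.
#' @param duration_s Observed simulation time (s, > 0).
#' @param horizon_s Target application time (s); default 10 years.
#' @return Named vector `c(sets_per_device, resets_per_device)`.
#' @export
extrapolate_endurance <- function(ledger, n_devices, duration_s,
                                  horizon_s = 10 * 365 * 86400) {
  if (duration_s <= 0) stop("'duration_s' must be > 0", call. = FALSE)
  stopifnot(n_devices >= 1)
  scale <- horizon_s / duration_s
  c(sets_per_device = ledger$n_set / n_devices * scale,
    resets_per_device = ledger$n_reset / n_devices * scale)
}
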