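#' Leaky integrate-and-fire parameters
#'
#' Three-parameter LIF neuron: the running integration decays exponentially
#' with time constant `t_leak_s`, accumulates non-negative input drive, and
#' emits a spike when it reaches `i_thres`, after which it is reset to zero
#' and frozen for an absolute refractory period. Defaults for the two network
#' layers are available via `lif_params_layer1()` / `lif_params_layer2()`
#' (input layer: 0.1 a.u., 0.2 ms, 4 ms; output layer: 0.58 a.u., 5.1 ms,
#' 46.1 ms). Thresholds are in the arbitrary units of the normalized trace.
#'
#' @param i_thres Integration threshold (a.u., > 0).
#' @param t_leak_s Leak time constant in seconds (> 0).
#' @param t_refractory_s Absolute refractory period in seconds (>= 0).
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(i_thres, t_leak_s, t_refractory_s) {
  if (!is.finite(i_thres) || i_thres <= 0) {
    stop("'i_thres' must be > 0", call. = FALSE)
  }
  if (!is.finite(t_leak_s) || t_leak_s <= 0) {
    stop("'t_leak_s' must be > 0 (a leak-free neuron is not supported)",
         call. = FALSE)
  }
  if (!is.finite(t_refractory_s) || t_refractory_s < 0) {
    stop("'t_refractory_s' must be >= 0", call. = FALSE)
  }
  structure(list(i_thres = i_thres, t_leak_s = t_leak_s,
                 t_refractory_s = t_refractory_s),
            class = "lif_params")
}

#' @rdname lif_params
#' @export
lif_params_layer1 <- function() lif_params(0.1, 0.2e-3, 4e-3)

#' @rdname lif_params
#' @export
lif_params_layer2 <- function() lif_params(0.58, 5.1e-3, 46.1e-3)

#' Initial LIF state
#'
#' @return An object of class `lif_state` with zero integration, no pending
#'   refractory period and no previous spike.
#' @export
lif_state <- function() {
  structure(list(integration = 0, refractory_until_s = -Inf,
                 last_spike_s = NA_real_),
            class = "lif_state")
}

#' Advance a LIF neuron by one clock step
#'
#' Outside the refractory period the integration first decays by
#' `exp(-dt_s / t_leak_s)` and then increases by `drive`; if it reaches the
#' threshold the neuron fires, the integration is hard-reset to 0 and inputs
#' are ignored until `t_s + t_refractory_s` (inclusive, so the earliest next
#' spike is one step after the refractory period elapses). While refractory
#' the state is frozen: no decay, no input, no spike.
#'
#' @param state A [lif_state()].
#' @param params A [lif_params()].
#' @param drive Non-negative input increment for this step.
#' @param t_s Current time (s).
#' @param dt_s Step size (s, > 0).
#' @return List with elements `state` (updated [lif_state()]) and `fired`
#'   (logical).
#' @examples
#' st <- lif_step(lif_state(), lif_params_layer2(), 0.58, 0, 5e-5)
#' st$fired # TRUE: a single increment equal to the threshold fires at once
#' @export
lif_step <- function(state, params, drive, t_s, dt_s) {
  stopifnot(dt_s > 0, drive >= 0)
  if (t_s <= state$refractory_until_s) {
    return(list(state = state, fired = FALSE))
  }
  integ <- state$integration * exp(-dt_s / params$t_leak_s) + drive
  if (integ >= params$i_thres) {
    state$integration <- 0
    state$refractory_until_s <- t_s + params$t_refractory_s
    state$last_spike_s <- t_s
    return(list(state = state, fired = TRUE))
  }
  state$integration <- integ
  list(state = state, fired = FALSE)
}

#' Simulate a single LIF neuron over a drive vector
#'
#' Convenience clock-driven loop over [lif_step()].
#'
#' @param drive Numeric vector of non-negative per-step input increments.
#' @param params A [lif_params()].
#' @param dt_s Step size (s).
#' @param t0_s Time of the first step.
#' @return List with `spike_times_s`, the final `state` and the per-step
#'   `integration` trajectory.
#' @export
lif_simulate <- function(drive, params, dt_s, t0_s = 0) {
  st <- lif_state()
  n <- length(drive)
  spikes <- numeric(0)
  traj <- numeric(n)
  for (k in seq_len(n)) {
    t <- t0_s + (k - 1) * dt_s
    res <- lif_step(st, params, drive[k], t, dt_s)
    st <- res$state
    if (res$fired) spikes <- c(spikes, t)
    traj[k] <- st$integration
  }
  list(spike_times_s = spikes, state = st, integration = traj)
}
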