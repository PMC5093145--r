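#' Probabilistic STDP parameters
#'
#' Simplified spike-timing-dependent plasticity for binary-device synapses:
#' when an output neuron fires at `t_post`, every afferent synapse is
#' considered. If its input neuron fired recently (`t_post - t_pre < t_ltp_s`)
#' the synapse is potentiated: each of its high-resistance devices is Set
#' independently with probability `p_set`. Otherwise (including inputs that
#' never fired) it is depressed: each low-resistance device is Reset with
#' probability `p_reset`. Per-device coin flips make potentiation and
#' depression gradual even though individual devices are binary.
#'
#' The probabilities and window were tuned by a genetic algorithm in the
#' original system and are exposed here as calibration constants
#' (see [ga_optimize()]).
#'
#' @param p_set Set probability per eligible device per post-spike.
#' @param p_reset Reset probability per eligible device per post-spike.
#' @param t_ltp_s Potentiation time window (s).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(p_set = 0.3, p_reset = 0.05, t_ltp_s = 10e-3) {
  if (p_set < 0 || p_set > 1 || p_reset < 0 || p_reset > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (t_ltp_s <= 0) stop("'t_ltp_s' must be > 0", call. = FALSE)
  structure(list(p_set = p_set, p_reset = p_reset, t_ltp_s = t_ltp_s),
            class = "stdp_params")
}

#' Network topology and simulation constants
#'
#' A fully connected two-layer network: `n_input` neurons (one per filter
#' channel) project onto `n_output` neurons through `n_input * n_output`
#' compound synapses. Recurrent lateral inhibition across the output layer is
#' realized as winner-take-all: when one or more output neurons cross
#' threshold in a step, only the most excited one fires; all others are reset
#' and held for `inhibition_s`.
#'
#' `input_gain` scales the layer-1 drive (rectified channel amplitude x dt x
#' gain); `synaptic_gain` scales what one presynaptic spike delivers to an
#' output integrator (weight x gain). Both are calibration constants of the
#' simulation, playing the role of the analog front-end and synaptic driver
#' gains of a hardware realization.
#'
#' @param n_input Number of input neurons (default 32).
#' @param n_output Number of output neurons (default 5, >= 2 so that
#'   winner-take-all is meaningful).
#' @param inhibition_s Hold time imposed on non-winning output neurons (s).
#' @param input_gain Layer-1 drive gain.
#' @param synaptic_gain Drive delivered per presynaptic spike at weight 1.
#' @param seed Master random seed (fans out to named substreams).
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_input = 32, n_output = 5, inhibition_s = 47e-3,
                           input_gain = 45000, synaptic_gain = 0.10,
                           seed = 1L) {
  stopifnot(n_input >= 1, n_output >= 2, inhibition_s >= 0,
            input_gain > 0, synaptic_gain > 0)
  structure(list(n_input = as.integer(n_input),
                 n_output = as.integer(n_output),
                 inhibition_s = inhibition_s, input_gain = input_gain,
                 synaptic_gain = synaptic_gain, seed = as.integer(seed)),
            class = "network_config")
}

#' Derive a reproducible substream seed
#'
#' A single master seed is fanned out to named substreams (synthetic data,
#' initial device states, plasticity coin flips, ...) so that every source of
#' randomness is reproducible yet streams stay decoupled.
#'
#' @param seed Master seed (integer).
#' @param name Substream name.
#' @return An integer seed in \[0, 2^31).
#' @export
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) * 10007
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

#' Bank of compound synapses for the full network
#'
#' Matrix-layout container for all `n_input * n_output` synapses (synapse
#' `(i, j)` occupies column `i + (j-1) * n_input`), each made of `n_devices`
#' parallel binary devices. Device states are initialized LRS with
#' probability 1/2 (`init = "random"`), so untrained weights scatter around
#' 0.5 and the untrained output activity is unstructured.
#'
#' @param n_input,n_output Layer sizes.
#' @param n_devices Devices per synapse (default 10).
#' @param dist A [resistance_distribution()].
#' @param init `"random"`, `"hrs"` or `"lrs"`.
#' @return An object of class `synapse_bank`: fields `state` (n_devices x
#'   n_synapses, 1 = LRS), `g` (conductances, S), `dist`, `n_input`,
#'   `n_output`, `n_devices`.
#' @export
synapse_bank <- function(n_input = 32, n_output = 5, n_devices = 10,
                         dist = resistance_distribution(),
                         init = c("random", "hrs", "lrs")) {
  init <- match.arg(init)
  n_syn <- n_input * n_output
  lrs <- switch(init,
    random = matrix(stats::runif(n_devices * n_syn) < 0.5, n_devices, n_syn),
    hrs = matrix(FALSE, n_devices, n_syn),
    lrs = matrix(TRUE, n_devices, n_syn))
  z <- stats::rnorm(n_devices * n_syn)
  g <- matrix(ifelse(lrs,
                     exp(-(log(dist$median_lrs_ohm) + dist$sigma_log_lrs * z)),
                     exp(-(log(dist$median_hrs_ohm) + dist$sigma_log_hrs * z))),
              n_devices, n_syn)
  structure(list(state = lrs * 1L, g = g, dist = dist,
                 n_input = as.integer(n_input),
                 n_output = as.integer(n_output),
                 n_devices = as.integer(n_devices)),
            class = "synapse_bank")
}

#' @export
print.synapse_bank <- function(x, ...) {
  cat(sprintf("<synapse_bank> %d x %d synapses, %d devices each (%d devices total)\n",
              x$n_input, x$n_output, x$n_devices,
              x$n_devices * x$n_input * x$n_output))
  invisible(x)
}

#' Weight matrix of a synapse bank
#'
#' @param bank A [synapse_bank()].
#' @return `n_input` x `n_output` matrix of weights in \[0, 1\].
#' @export
bank_weights <- function(bank) {
  stopifnot(inherits(bank, "synapse_bank"))
  b <- synapse_g_bounds(bank$n_devices, bank$dist)
  w <- (colSums(bank$g) - b[["g_min"]]) / (b[["g_max"]] - b[["g_min"]])
  matrix(pmin(pmax(w, 0), 1), bank$n_input, bank$n_output)
}

#' Apply one post-spike worth of probabilistic STDP
#'
#' Updates the afferent synapses of one output neuron after it fires:
#' potentiation (per-device Set coin flips with `p_set`) for inputs active
#' within the LTP window, depression (per-device Reset coin flips with
#' `p_reset`) for all others, including inputs that never fired. Programming
#' events and energies are booked in the ledger. Draw order is input
#' ascending, device ascending, one uniform per eligible device and one
#' normal per reprogrammed device, matching the compiled simulation engine
#' exactly.
#'
#' @param bank A [synapse_bank()].
#' @param post_neuron Output neuron id (1-based).
#' @param t_post_s Time of the post-synaptic spike (s).
#' @param last_pre_times Numeric vector (length `n_input`) of most recent
#'   presynaptic spike times; `-Inf` for inputs that never fired.
#' @param params [stdp_params()].
#' @param model [energy_model()] for programming energies.
#' @param ledger [event_ledger()], updated in place.
#' @return The updated [synapse_bank()].
#' @export
apply_stdp <- function(bank, post_neuron, t_post_s, last_pre_times,
                       params = stdp_params(), model = energy_model(),
                       ledger = event_ledger()) {
  stopifnot(inherits(bank, "synapse_bank"),
            length(last_pre_times) == bank$n_input,
            post_neuron >= 1, post_neuron <= bank$n_output)
  if (any(last_pre_times > t_post_s)) {
    stop("'t_post_s' must be >= all 'last_pre_times'", call. = FALSE)
  }
  e_set <- pulse_energy(model, "set")
  e_reset <- pulse_energy(model, "reset")
  dist <- bank$dist
  for (i in seq_len(bank$n_input)) {
    s <- i + (post_neuron - 1L) * bank$n_input
    ltp <- (t_post_s - last_pre_times[i]) < params$t_ltp_s
    for (d in seq_len(bank$n_devices)) {
      if (ltp) {
        if (bank$state[d, s] == 0L && stats::runif(1) < params$p_set) {
          bank$state[d, s] <- 1L
          bank$g[d, s] <- sample_conductance(dist, "LRS")
          ledger_add(ledger, n_set = 1, e_set_j = e_set)
        }
      } else {
        if (bank$state[d, s] == 1L && stats::runif(1) < params$p_reset) {
          bank$state[d, s] <- 0L
          bank$g[d, s] <- sample_conductance(dist, "HRS")
          ledger_add(ledger, n_reset = 1, e_reset_j = e_reset)
        }
      }
    }
  }
  bank
}

#' Winner-take-all selection
#'
#' Among output neurons that are eligible (not refractory, not inhibited) and
#' whose integration has reached threshold, the most excited one wins; ties
#' go to the lowest id. Returns `NA` when no neuron qualifies.
#'
#' @param integrations Numeric vector of output integrations.
#' @param threshold Firing threshold.
#' @param eligible Logical vector; `FALSE` marks refractory/inhibited neurons.
#' @return Winning neuron id (1-based) or `NA_integer_`.
#' @export
winner_take_all <- function(integrations, threshold,
                            eligible = rep(TRUE, length(integrations))) {
  ok <- eligible & integrations >= threshold
  if (!any(ok)) return(NA_integer_)
  cand <- which(ok)
  cand[which.max(integrations[cand])]
}

#' Run the spike-sorting network on encoded channels
#'
#' Clock-driven simulation at the trace sampling rate. Each step: (1) input
#' LIF neurons integrate their rectified channel drive; (2) every input spike
#' is delivered through the neuron's `n_output` synapses (weight x
#' `synaptic_gain` added to each eligible output integrator), booking one
#' read event per device; (3) output LIF neurons integrate; (4) if any output
#' crosses threshold, the winner-take-all rule lets exactly one fire, resets
#' the others and inhibits them for `inhibition_s`; (5) with learning on,
#' probabilistic STDP updates the winner's afferent synapses.
#'
#' The compiled engine (`engine = "cpp"`) and the pure-R reference engine
#' (`engine = "r"`) draw random numbers in the same order and produce
#' bit-identical results under the same RNG state; the R engine exists as a
#' readable cross-check and is only practical for short traces.
#'
#' @param channels A `channel_set` from [encode()], or a list of rectified
#'   [signal_trace()] objects with equal length and rate.
#' @param config [network_config()].
#' @param lif1,lif2 [lif_params()] for the input and output layers.
#' @param stdp [stdp_params()].
#' @param bank A [synapse_bank()]; defaults to a fresh random bank seeded
#'   from `config$seed` (substream `"bank"`).
#' @param model [energy_model()].
#' @param learning Enable online plasticity.
#' @param engine `"cpp"` (fast) or `"r"` (reference).
#' @param snapshot_every_s If > 0, record the weight matrix every so many
#'   seconds of simulated time.
#' @param set_seed If `TRUE` (default), seed the RNG from `config$seed`
#'   (substream `"run"`) before simulating, making runs self-contained and
#'   reproducible; set to `FALSE` to manage the RNG state yourself.
#' @return An object of class `snn_run`: list with `input_spikes` and
#'   `output_spikes` (data.frames `time_s`, `neuron_id`), `ledger`
#'   ([event_ledger()]), the updated `bank`, final `weights`, `duration_s`,
#'   `n_samples`, and optional `snapshots`.
#' @export
run_network <- function(channels, config = network_config(),
                        lif1 = lif_params_layer1(),
                        lif2 = lif_params_layer2(),
                        stdp = stdp_params(),
                        bank = NULL, model = energy_model(),
                        learning = TRUE, engine = c("cpp", "r"),
                        snapshot_every_s = 0, set_seed = TRUE) {
  engine <- match.arg(engine)
  ch <- as_channel_matrix(channels)
  if (ncol(ch$mat) != config$n_input) {
    stop(sprintf("channel count (%d) does not match n_input (%d)",
                 ncol(ch$mat), config$n_input), call. = FALSE)
  }
  if (is.null(bank)) {
    set.seed(substream_seed(config$seed, "bank"))
    bank <- synapse_bank(config$n_input, config$n_output)
  }
  stopifnot(inherits(bank, "synapse_bank"),
            bank$n_input == config$n_input,
            bank$n_output == config$n_output)
  if (set_seed) set.seed(substream_seed(config$seed, "run"))
  dt <- 1 / ch$rate_hz
  bounds <- synapse_g_bounds(bank$n_devices, bank$dist)
  snap_steps <- if (snapshot_every_s > 0) {
    max(1L, as.integer(round(snapshot_every_s * ch$rate_hz)))
  } else 0L

  if (engine == "cpp") {
    res <- run_network_cpp(
      ch$mat, dt, ch$t0_s,
      lif1$i_thres, lif1$t_leak_s, lif1$t_refractory_s, config$input_gain,
      lif2$i_thres, lif2$t_leak_s, lif2$t_refractory_s, config$synaptic_gain,
      config$inhibition_s,
      bank$state, bank$g, bounds[["g_min"]], bounds[["g_max"]],
      stdp$p_set, stdp$p_reset, stdp$t_ltp_s,
      bank$dist$median_lrs_ohm, bank$dist$sigma_log_lrs,
      bank$dist$median_hrs_ohm, bank$dist$sigma_log_hrs,
      pulse_energy(model, "set"), pulse_energy(model, "reset"),
      model$v_read_v, model$t_read_s,
      learning, snap_steps)
    bank$state <- res$dev_state
    bank$g <- res$dev_g
    ledger <- ledger_from_counts()
    ledger_add(ledger, n_read = res$n_read, n_set = res$n_set,
               n_reset = res$n_reset, e_read_j = res$e_read_j,
               e_set_j = res$e_set_j, e_reset_j = res$e_reset_j)
    input_spikes <- spike_train(res$in_time, res$in_id, layer = "input")
    output_spikes <- spike_train(res$out_time, res$out_id, layer = "output")
    snapshots <- if (snap_steps > 0) {
      list(times_s = res$snapshot_times, weights = res$snapshots)
    } else NULL
  } else {
    r <- run_network_r_engine(ch, config, lif1, lif2, stdp, bank, model,
                              learning, snap_steps)
    bank <- r$bank
    ledger <- r$ledger
    input_spikes <- r$input_spikes
    output_spikes <- r$output_spikes
    snapshots <- r$snapshots
  }

  structure(
    list(input_spikes = input_spikes, output_spikes = output_spikes,
         ledger = ledger, bank = bank, weights = bank_weights(bank),
         duration_s = nrow(ch$mat) / ch$rate_hz, n_samples = nrow(ch$mat),
         rate_hz = ch$rate_hz, t0_s = ch$t0_s, snapshots = snapshots),
    class = "snn_run"
  )
}

#' @export
print.snn_run <- function(x, ...) {
  cat(sprintf(
    "<snn_run> %.1f s simulated: %d input spikes, %d output spikes\n",
    x$duration_s, nrow(x$input_spikes), nrow(x$output_spikes)))
  print(x$ledger)
  invisible(x)
}

# accept a channel_set or a list of equal-length signal_traces
as_channel_matrix <- function(channels) {
  if (inherits(channels, "channel_set")) {
    return(list(mat = channels$channels, rate_hz = channels$rate_hz,
                t0_s = channels$t0_s))
  }
  if (is.list(channels) && all(vapply(channels, inherits, logical(1),
                                      "signal_trace"))) {
    lens <- vapply(channels, function(x) length(x$samples), integer(1))
    rates <- vapply(channels, function(x) x$rate_hz, numeric(1))
    if (length(unique(lens)) != 1L || length(unique(rates)) != 1L) {
      stop("all channels must have identical length and sampling rate",
           call. = FALSE)
    }
    return(list(mat = vapply(channels, function(x) x$samples,
                             numeric(lens[1])),
                rate_hz = rates[1], t0_s = channels[[1]]$t0_s))
  }
  stop("'channels' must be a channel_set or a list of signal_trace objects",
       call. = FALSE)
}

# Pure-R reference engine; mirrors the C++ loop operation-for-operation
# (including RNG draw order) so that results are bit-identical.
run_network_r_engine <- function(ch, config, lif1, lif2, stdp, bank, model,
                                 learning, snap_steps) {
  mat <- ch$mat
  dt <- 1 / ch$rate_hz
  t0 <- ch$t0_s
  n_in <- config$n_input
  n_out <- config$n_output
  n_dev <- bank$n_devices
  bounds <- synapse_g_bounds(n_dev, bank$dist)
  g_min <- bounds[["g_min"]]; wspan <- bounds[["g_max"]] - g_min
  v2t <- model$v_read_v^2 * model$t_read_s
  decay1 <- exp(-dt / lif1$t_leak_s)
  decay2 <- exp(-dt / lif2$t_leak_s)
  g_sum <- colSums(bank$g)

  integ1 <- numeric(n_in); integ2 <- numeric(n_out)
  ref1 <- rep(-Inf, n_in); ref2 <- rep(-Inf, n_out); inh2 <- rep(-Inf, n_out)
  last_pre <- rep(-Inf, n_in)
  ledger <- event_ledger()
  in_t <- numeric(0); in_id <- integer(0)
  out_t <- numeric(0); out_id <- integer(0)
  snapshots <- NULL
  if (snap_steps > 0) snapshots <- list(times_s = numeric(0), weights = list())
  e_set <- pulse_energy(model, "set")
  e_reset <- pulse_energy(model, "reset")

  for (step in seq_len(nrow(mat))) {
    t <- t0 + (step - 1) * dt
    fired <- integer(0)
    for (i in seq_len(n_in)) {
      if (t <= ref1[i]) next
      integ1[i] <- integ1[i] * decay1 + config$input_gain * mat[step, i] * dt
      if (integ1[i] >= lif1$i_thres) {
        integ1[i] <- 0
        ref1[i] <- t + lif1$t_refractory_s
        last_pre[i] <- t
        fired <- c(fired, i)
      }
    }
    if (length(fired)) {
      in_t <- c(in_t, rep(t, length(fired))); in_id <- c(in_id, fired)
    }

    drive2 <- numeric(n_out)
    for (i in fired) {
      s <- i + (seq_len(n_out) - 1L) * n_in
      ledger_add(ledger, n_read = n_dev * n_out,
                 e_read_j = sum(v2t * g_sum[s]))
      w <- pmin(pmax((g_sum[s] - g_min) / wspan, 0), 1)
      drive2 <- drive2 + w * config$synaptic_gain
    }

    eligible <- t > pmax(ref2, inh2)
    integ2[eligible] <- integ2[eligible] * decay2 + drive2[eligible]
    winner <- winner_take_all(integ2, lif2$i_thres, eligible)
    if (!is.na(winner)) {
      out_t <- c(out_t, t); out_id <- c(out_id, winner)
      integ2[winner] <- 0
      ref2[winner] <- t + lif2$t_refractory_s
      integ2[-winner] <- 0
      inh2[-winner] <- t + config$inhibition_s
      if (learning) {
        cols <- (winner - 1L) * n_in + seq_len(n_in)
        g_old <- bank$g[, cols, drop = FALSE]
        bank <- apply_stdp(bank, winner, t, last_pre, stdp, model, ledger)
        g_new <- bank$g[, cols, drop = FALSE]
        # replay the compiled engine's incremental updates in the same
        # (input ascending, device ascending) order for identical rounding
        changed <- which(g_new != g_old)
        for (idx in changed) {
          col <- cols[((idx - 1L) %/% n_dev) + 1L]
          g_sum[col] <- g_sum[col] + (g_new[idx] - g_old[idx])
        }
      }
    }

    if (snap_steps > 0 && step %% snap_steps == 0) {
      w <- matrix(pmin(pmax((g_sum - g_min) / wspan, 0), 1), n_in, n_out)
      snapshots$weights[[length(snapshots$weights) + 1L]] <- w
      snapshots$times_s <- c(snapshots$times_s, t + dt)
    }
  }
  list(bank = bank, ledger = ledger,
       input_spikes = spike_train(in_t, in_id, layer = "input"),
       output_spikes = spike_train(out_t, out_id, layer = "output"),
       snapshots = snapshots)
}

#' Spike train container
#'
#' @param time_s Event times (s), non-decreasing.
#' @param neuron_id 1-based neuron ids.
#' @param layer Layer tag (`"input"`, `"output"`, or a unit label).
#' @return A data.frame of class `spike_train` with columns `time_s`,
#'   `neuron_id` and attribute `layer`.
#' @export
spike_train <- function(time_s = numeric(0), neuron_id = integer(0),
                        layer = "output") {
  time_s <- as.numeric(time_s)
  neuron_id <- as.integer(neuron_id)
  stopifnot(length(time_s) == length(neuron_id))
  if (is.unsorted(time_s)) {
    stop("spike times must be non-decreasing", call. = FALSE)
  }
  df <- data.frame(time_s = time_s, neuron_id = neuron_id)
  class(df) <- c("spike_train", "data.frame")
  attr(df, "layer") <- layer
  df
}
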