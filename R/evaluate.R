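#' Evaluation constants
#'
#' A ground-truth event counts as recognized when the assigned output neuron
#' spikes within `match_window_s` after it (half-open window `(t, t + w]`: a
#' spike exactly at the event time is not causal, hence not a recognition).
#' Rates and activities are reported in bins of `bin_s`.
#'
#' @param match_window_s Recognition window after a ground-truth event
#'   (default 20 ms).
#' @param bin_s Reporting interval (default 10 s).
#' @return An object of class `evaluation_config`.
#' @export
evaluation_config <- function(match_window_s = 0.020, bin_s = 10) {
  stopifnot(match_window_s > 0, bin_s > 0)
  structure(list(match_window_s = match_window_s, bin_s = bin_s),
            class = "evaluation_config")
}

# TRUE per truth event if any spike of `spikes` falls in (t, t + w]
events_matched <- function(event_times, spikes, window_s) {
  if (length(spikes) == 0) return(rep(FALSE, length(event_times)))
  spikes <- sort(spikes)
  # index of last spike <= t + w, first spike > t
  hi <- findInterval(event_times + window_s, spikes)
  lo <- findInterval(event_times, spikes)
  hi > lo
}

#' Assign output neurons to ground-truth units
#'
#' Greedy injective assignment: for every (unit, neuron) pair the score is
#' the number of the unit's ground-truth events followed by a spike of that
#' neuron within the recognition window; pairs are accepted in decreasing
#' score order (ties to the lower neuron id), each unit and each neuron at
#' most once. This is the post-hoc identification step: the network is
#' unsupervised, so which neuron captured which unit is only known by
#' correlating with the reference afterwards.
#'
#' @param output A [spike_train()] of output spikes.
#' @param truth A [ground_truth()].
#' @param config An [evaluation_config()].
#' @return Named integer vector: unit label -> neuron id. Empty (with a
#'   warning) if there are no output spikes.
#' @export
assign_neurons <- function(output, truth, config = evaluation_config()) {
  stopifnot(inherits(truth, "ground_truth"))
  if (nrow(output) == 0) {
    warning("no output spikes; returning empty assignment", call. = FALSE)
    return(stats::setNames(integer(0), character(0)))
  }
  units <- names(truth)
  neurons <- sort(unique(output$neuron_id))
  scores <- expand.grid(unit = units, neuron = neurons,
                        stringsAsFactors = FALSE)
  scores$count <- mapply(function(u, nid) {
    sum(events_matched(truth[[u]],
                       output$time_s[output$neuron_id == nid],
                       config$match_window_s))
  }, scores$unit, scores$neuron)
  scores <- scores[order(-scores$count, scores$neuron), ]
  assignment <- stats::setNames(integer(0), character(0))
  used_neurons <- integer(0)
  for (r in seq_len(nrow(scores))) {
    u <- scores$unit[r]; nid <- scores$neuron[r]
    if (scores$count[r] <= 0) next
    if (u %in% names(assignment) || nid %in% used_neurons) next
    assignment[u] <- nid
    used_neurons <- c(used_neurons, nid)
  }
  assignment
}

#' Recognition rate of one unit by its assigned neuron
#'
#' Per bin of `bin_s` seconds, the fraction of the unit's ground-truth events
#' followed by a spike of the assigned neuron within the recognition window.
#' Bins without truth events are excluded; the mean is the unweighted mean
#' over included bins, which (because empty bins are excluded) starts
#' effectively from the unit's first event.
#'
#' @param output A [spike_train()] of output spikes.
#' @param truth_times Sorted event times of one unit (s).
#' @param neuron_id Assigned output neuron.
#' @param config An [evaluation_config()].
#' @param t_end End of the evaluated period (defaults to the last event or
#'   spike).
#' @return List with `per_bin` (data.frame `bin_start_s`, `n_events`,
#'   `n_recognized`, `rate`) and `mean_rate`.
#' @export
recognition_rate <- function(output, truth_times, neuron_id,
                             config = evaluation_config(), t_end = NULL) {
  spikes <- output$time_s[output$neuron_id == neuron_id]
  if (length(truth_times) == 0) {
    return(list(per_bin = data.frame(bin_start_s = numeric(0),
                                     n_events = integer(0),
                                     n_recognized = integer(0),
                                     rate = numeric(0)),
                mean_rate = NA_real_))
  }
  if (is.null(t_end)) {
    t_end <- max(truth_times, if (length(spikes)) max(spikes) else 0)
  }
  matched <- events_matched(truth_times, spikes, config$match_window_s)
  bins <- seq(0, t_end + config$bin_s, by = config$bin_s)
  idx <- findInterval(truth_times, bins)
  n_events <- tabulate(idx, nbins = length(bins) - 1)
  n_rec <- vapply(seq_along(n_events),
                  function(b) sum(matched[idx == b]), numeric(1))
  keep <- n_events > 0
  per_bin <- data.frame(bin_start_s = bins[-length(bins)][keep],
                        n_events = n_events[keep],
                        n_recognized = n_rec[keep],
                        rate = n_rec[keep] / n_events[keep])
  list(per_bin = per_bin, mean_rate = mean(per_bin$rate))
}

#' Output-neuron activity histogram
#'
#' Spike counts per neuron per time bin; the per-bin activity view in which
#' selectivity (one neuron tracking one unit, the others near-silent) becomes
#' visible.
#'
#' @param train A [spike_train()].
#' @param bin_s Bin width (s).
#' @param duration_s Total duration; defaults to the last spike time.
#' @param n_neurons Number of neurons (rows); defaults to the largest id
#'   observed.
#' @return Matrix of counts, neurons x bins, with `dimnames` giving neuron id
#'   and bin start.
#' @export
activity_histogram <- function(train, bin_s = 10, duration_s = NULL,
                               n_neurons = NULL) {
  if (is.null(duration_s)) {
    duration_s <- if (nrow(train)) max(train$time_s) else bin_s
  }
  if (is.null(n_neurons)) {
    n_neurons <- if (nrow(train)) max(train$neuron_id) else 1L
  }
  starts <- seq(0, duration_s, by = bin_s)
  if (starts[length(starts)] < duration_s) starts <- c(starts, duration_s)
  n_bins <- max(1L, length(starts) - 1L)
  out <- matrix(0L, nrow = n_neurons, ncol = n_bins,
                dimnames = list(neuron = seq_len(n_neurons),
                                bin_start_s = starts[seq_len(n_bins)]))
  if (nrow(train)) {
    b <- pmin(pmax(findInterval(train$time_s, starts,
                                rightmost.closed = TRUE), 1L), n_bins)
    for (k in seq_len(nrow(train))) {
      out[train$neuron_id[k], b[k]] <- out[train$neuron_id[k], b[k]] + 1L
    }
  }
  out
}

#' System-level energy and endurance report
#'
#' Aggregates a run's event ledger into the standard summary: event counts,
#' per-event energies, total synaptic energy `E_total = sum_mode E_mode *
#' N_mode`, mean synaptic power `E_total / duration`, optional neuron energy
#' (`spikes x e_neuron_spike_j`, 2 pJ per spike for a 65 nm analog neuron),
#' per-device mean Set/Reset counts, and their extrapolation to a ten-year
#' application horizon.
#'
#' @param ledger An [event_ledger()].
#' @param model An [energy_model()] (supplies Set/Reset per-event energies).
#' @param duration_s Simulated signal duration (s, > 0).
#' @param n_devices Total device count (for per-device statistics).
#' @param neuron_spike_count Total neuron spikes (input + output) for the
#'   optional neuron-energy estimate.
#' @param e_neuron_spike_j Energy per neuron spike (J), default 2 pJ.
#' @param horizon_s Endurance extrapolation horizon (default 10 years).
#' @return An object of class `snn_report` (a list; see fields in the print
#'   output).
#' @export
system_report <- function(ledger, model = energy_model(), duration_s,
                          n_devices, neuron_spike_count = 0,
                          e_neuron_spike_j = 2e-12,
                          horizon_s = 10 * 365 * 86400) {
  if (duration_s <= 0) stop("'duration_s' must be > 0", call. = FALSE)
  e_set <- pulse_energy(model, "set")
  e_reset <- pulse_energy(model, "reset")
  e_read_mean <- if (ledger$n_read > 0) ledger$e_read_j / ledger$n_read else 0
  e_total <- ledger$e_read_j + ledger$n_set * e_set +
    ledger$n_reset * e_reset
  endur <- extrapolate_endurance(ledger, n_devices, duration_s, horizon_s)
  structure(
    list(duration_s = duration_s, n_devices = n_devices,
         n_read = ledger$n_read, n_set = ledger$n_set,
         n_reset = ledger$n_reset,
         e_set_per_event_j = e_set, e_reset_per_event_j = e_reset,
         e_read_per_event_j = e_read_mean,
         e_total_j = e_total,
         power_w = e_total / duration_s,
         sets_per_device = ledger$n_set / n_devices,
         resets_per_device = ledger$n_reset / n_devices,
         endurance_10y = endur,
         neuron_spike_count = neuron_spike_count,
         e_neuron_j = neuron_spike_count * e_neuron_spike_j,
         e_total_with_neurons_j = e_total +
           neuron_spike_count * e_neuron_spike_j),
    class = "snn_report"
  )
}

#' @export
print.snn_report <- function(x, ...) {
  cat("Network statistics\n")
  cat(sprintf("  Input signal duration  %g s\n", x$duration_s))
  cat(sprintf("  Devices                %g\n", x$n_devices))
  cat(sprintf("  Read events            %g\n", x$n_read))
  cat(sprintf("  Set events             %g\n", x$n_set))
  cat(sprintf("  Reset events           %g\n", x$n_reset))
  cat("Energies per event\n")
  cat(sprintf("  Set   %8.4g pJ\n", x$e_set_per_event_j * 1e12))
  cat(sprintf("  Reset %8.4g pJ\n", x$e_reset_per_event_j * 1e12))
  cat(sprintf("  Read  %8.4g pJ (population mean)\n",
              x$e_read_per_event_j * 1e12))
  cat("Totals\n")
  cat(sprintf("  Synaptic energy        %.4g uJ\n", x$e_total_j * 1e6))
  cat(sprintf("  Synaptic power (E/t)   %.4g nW\n", x$power_w * 1e9))
  if (x$neuron_spike_count > 0) {
    cat(sprintf("  Neuron energy          %.4g uJ (%g spikes)\n",
                x$e_neuron_j * 1e6, x$neuron_spike_count))
  }
  cat("Per-device programming\n")
  cat(sprintf("  Mean Set / Reset       %.3g / %.3g\n",
              x$sets_per_device, x$resets_per_device))
  cat(sprintf("  10-year extrapolation  %.3g Set / %.3g Reset\n",
              x$endurance_10y[["sets_per_device"]],
              x$endurance_10y[["resets_per_device"]]))
  invisible(x)
}

#' Data-reduction ratio
#'
#' Input samples per output event: the compression achieved by emitting
#' sorted spikes instead of the raw trace (ratios around 1000 at typical
#' rates). `Inf` if there are no output events.
#'
#' @param trace A [signal_trace()].
#' @param output A [spike_train()] of output spikes.
#' @return Ratio (samples per event).
#' @export
data_reduction <- function(trace, output) {
  stopifnot(inherits(trace, "signal_trace"))
  n_ev <- nrow(output)
  if (n_ev == 0) return(Inf)
  length(trace$samples) / n_ev
}

#' Precision of an assigned neuron (extension metric)
#'
#' Fraction of the neuron's spikes that fall within the recognition window of
#' some ground-truth event of its unit. Reported alongside the recognition
#' rate for diagnostic purposes.
#'
#' @param output A [spike_train()].
#' @param truth_times Event times of the assigned unit.
#' @param neuron_id Assigned neuron.
#' @param config An [evaluation_config()].
#' @return Precision in \[0, 1\] (NA if the neuron never spiked).
#' @export
neuron_precision <- function(output, truth_times, neuron_id,
                             config = evaluation_config()) {
  spikes <- output$time_s[output$neuron_id == neuron_id]
  if (length(spikes) == 0) return(NA_real_)
  if (length(truth_times) == 0) return(0)
  w <- config$match_window_s
  # spike s is causal-matched if some event t satisfies s - w <= t < s
  ok <- vapply(seq_along(spikes), function(k) {
    j <- findInterval(spikes[k], truth_times, left.open = TRUE)
    j >= 1 && spikes[k] - truth_times[j] <= w && spikes[k] > truth_times[j]
  }, logical(1))
  mean(ok)
}
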