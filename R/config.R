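#' Default run configuration
#'
#' Nested configuration covering every stage, with the published/system
#' defaults: the 100-2000 Hz 32-filter bank (60 Hz bands, 2nd-order
#' Butterworth), layer-1 LIF (0.1 a.u. / 0.2 ms / 4 ms), layer-2 LIF
#' (0.58 a.u. / 5.1 ms / 46.1 ms), 32x5 topology with 10 devices per synapse,
#' the abrupt-switching pulse conditions (Set 2.5 V / 30 uA / 1 us, Reset
#' 1.5 V / 30 uA / 1 us, Read 0.1 V / 1 us), the 20 ms recognition window and
#' 10 s reporting bins, and the desk-scale staged synthetic protocol.
#'
#' @return Nested named list (sections `filterbank`, `layer1`, `layer2`,
#'   `synapse`, `stdp`, `network`, `evaluation`, `synth`, `ga`, plus `seed`).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    filterbank = list(n_filters = 32L, f_low_hz = 100, f_high_hz = 2000,
                      bandwidth_hz = 60, order = 2L),
    layer1 = list(i_thres = 0.1, t_leak_s = 0.2e-3, t_refractory_s = 4e-3),
    layer2 = list(i_thres = 0.58, t_leak_s = 5.1e-3, t_refractory_s = 46.1e-3),
    synapse = list(n_devices = 10L, median_lrs_ohm = 25e3, sigma_log_lrs = 0.3,
                   median_hrs_ohm = 250e3, sigma_log_hrs = 0.5,
                   v_set_v = 2.5, i_set_a = 30e-6, t_set_s = 1e-6,
                   v_reset_v = 1.5, i_reset_a = 30e-6, t_reset_s = 1e-6,
                   v_read_v = 0.1, t_read_s = 1e-6),
    stdp = list(p_set = 0.3, p_reset = 0.05, t_ltp_s = 0.01),
    network = list(n_input = 32L, n_output = 5L, inhibition_s = 0.047,
                   input_gain = 45000, synaptic_gain = 0.10),
    evaluation = list(match_window_s = 0.02, bin_s = 10),
    synth = list(rate_hz = 20000, duration_s = 68.1, unit_rates_hz = 3.3,
                 noise_sigma = 0.05, lf_noise_amp = 0.2, lf_noise_hz = 7.5,
                 refractory_s = 0.01, noise_kind = "white",
                 template_preset = "crayfish_pair"),
    ga = list(population_size = 16L, n_winners = 4L, variation_frac = 0.2,
              generations = 10L, saturation_tol = 0.01)
  )
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration, rejects unknown keys (naming the offending
#' key), fills every omitted field with its default from [default_config()],
#' and validates all invariants by constructing the corresponding parameter
#' objects.
#'
#' @param path Path to a JSON file; sections and keys as in
#'   [default_config()]. An empty JSON object yields all defaults.
#' @return Validated nested configuration list.
#' @export
load_config <- function(path) {
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(user)) user <- list()
  merged <- merge_config(default_config(), user, path = "")
  validate_config(merged)
  merged
}

#' @param config A configuration list to write.
#' @rdname load_config
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) {
    stop("configuration section '", path, "' must be an object", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key: '",
         paste0(sub("^\\.", "", paste0(path, ".", unknown[1]))),
         "'", call. = FALSE)
  }
  out <- defaults
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      out[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]),
                               paste0(path, ".", k))
    } else {
      out[[k]] <- user[[k]]
    }
  }
  out
}

validate_config <- function(cfg) {
  do.call(filter_bank_config, cfg$filterbank)
  do.call(lif_params, cfg$layer1)
  do.call(lif_params, cfg$layer2)
  do.call(resistance_distribution,
          cfg$synapse[c("median_lrs_ohm", "sigma_log_lrs", "median_hrs_ohm",
                        "sigma_log_hrs")])
  do.call(energy_model,
          cfg$synapse[c("v_set_v", "i_set_a", "t_set_s", "v_reset_v",
                        "i_reset_a", "t_reset_s", "v_read_v", "t_read_s")])
  do.call(stdp_params, cfg$stdp)
  do.call(network_config, c(cfg$network, list(seed = cfg$seed)))
  do.call(evaluation_config, cfg$evaluation)
  do.call(ga_config, c(cfg$ga, list(seed = cfg$seed)))
  if (cfg$synapse$n_devices < 1) {
    stop("'synapse.n_devices' must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

# section -> parameter-object builders
config_filterbank <- function(cfg) do.call(filter_bank_config, cfg$filterbank)
config_lif1 <- function(cfg) do.call(lif_params, cfg$layer1)
config_lif2 <- function(cfg) do.call(lif_params, cfg$layer2)
config_stdp <- function(cfg) do.call(stdp_params, cfg$stdp)
config_network <- function(cfg) {
  do.call(network_config, c(cfg$network, list(seed = cfg$seed)))
}
config_evaluation <- function(cfg) do.call(evaluation_config, cfg$evaluation)
config_distribution <- function(cfg) {
  do.call(resistance_distribution,
          cfg$synapse[c("median_lrs_ohm", "sigma_log_lrs", "median_hrs_ohm",
                        "sigma_log_hrs")])
}
config_energy_model <- function(cfg) {
  do.call(energy_model,
          cfg$synapse[c("v_set_v", "i_set_a", "t_set_s", "v_reset_v",
                        "i_reset_a", "t_reset_s", "v_read_v", "t_read_s")])
}
config_synth <- function(cfg) {
  s <- cfg$synth
  synth_config(rate_hz = s$rate_hz, duration_s = s$duration_s,
               templates = make_templates(s$template_preset, s$rate_hz),
               unit_rates_hz = s$unit_rates_hz, noise_sigma = s$noise_sigma,
               lf_noise_amp = s$lf_noise_amp, lf_noise_hz = s$lf_noise_hz,
               refractory_s = s$refractory_s, noise_kind = s$noise_kind,
               seed = cfg$seed)
}

#' Read / write event lists
#'
#' Tab-separated files with a `time_s` / `id` header, one event per row,
#' sorted by time. Ids may be neuron numbers or unit labels.
#'
#' @param path File path.
#' @return `read_events` returns a data.frame with columns `time_s` and `id`;
#'   unsorted or malformed files are rejected with the offending line number.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty event file: ", path, call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(data.frame(time_s = numeric(0), id = character(0)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed event row at line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  }
  time_s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  if (anyNA(time_s)) {
    stop(sprintf("malformed event time at line %d of %s",
                 which(is.na(time_s))[1] + 1L, path), call. = FALSE)
  }
  if (is.unsorted(time_s)) {
    stop("event file must be sorted by time: ", path, call. = FALSE)
  }
  data.frame(time_s = time_s, id = vapply(parts, `[[`, "", 2L))
}

#' @param events A [spike_train()], [ground_truth()], or data.frame with
#'   columns `time_s` and `id`/`neuron_id`.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  if (inherits(events, "ground_truth")) {
    df <- do.call(rbind, lapply(names(events), function(u) {
      data.frame(time_s = events[[u]], id = rep(u, length(events[[u]])))
    }))
    if (is.null(df)) df <- data.frame(time_s = numeric(0), id = character(0))
    df <- df[order(df$time_s), , drop = FALSE]
  } else {
    df <- as.data.frame(events)
    if ("neuron_id" %in% names(df)) names(df)[names(df) == "neuron_id"] <- "id"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s\tid", con)
  if (nrow(df)) {
    writeLines(sprintf("%.9f\t%s", df$time_s, df$id), con)
  }
  invisible(path)
}

#' Provenance record for a run
#'
#' Captures everything needed to reproduce a run bit-identically: the
#' configuration (and its MD5 hash), master seed and package version.
#'
#' @param config Configuration list.
#' @param path If given, the record is written there as JSON.
#' @return The record, invisibly if written.
#' @export
provenance_record <- function(config, path = NULL) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  rec <- list(
    package = "snnsort",
    version = as.character(utils::packageVersion("snnsort")),
    seed = config$seed,
    config_md5 = h,
    config = config
  )
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rec))
  }
  rec
}

#' Run the full spike-sorting pipeline on a trace
#'
#' Normalize, encode through the filter bank, and simulate the network with
#' online learning. This is the one-call interface; the individual stages are
#' exported for finer control.
#'
#' @param trace A [signal_trace()].
#' @param config Configuration list as from [default_config()] /
#'   [load_config()].
#' @param learning Enable STDP (default TRUE).
#' @param bank Optional pre-built [synapse_bank()] (e.g. from a previous
#'   training run); defaults to a fresh random bank.
#' @param snapshot_every_s Weight snapshot interval (0 = none).
#' @return An `snn_run` (see [run_network()]).
#' @export
spike_sort <- function(trace, config = default_config(), learning = TRUE,
                       bank = NULL, snapshot_every_s = 0) {
  stopifnot(inherits(trace, "signal_trace"))
  enc <- encode(normalize_trace(trace), config_filterbank(config))
  run_network(enc, config_network(config), config_lif1(config),
              config_lif2(config), config_stdp(config),
              bank = bank %||% make_bank(config),
              model = config_energy_model(config), learning = learning,
              snapshot_every_s = snapshot_every_s)
}

make_bank <- function(config) {
  set.seed(substream_seed(config$seed, "bank"))
  synapse_bank(config$network$n_input, config$network$n_output,
               config$synapse$n_devices, config_distribution(config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a run against ground truth
#'
#' Assigns output neurons to units, computes per-unit recognition rates,
#' the activity histogram and the data-reduction ratio.
#'
#' @param run An `snn_run` from [run_network()] / [spike_sort()].
#' @param truth A [ground_truth()].
#' @param config An [evaluation_config()].
#' @param trace The input [signal_trace()] (for the data-reduction ratio);
#'   optional.
#' @return List with `assignment`, `recognition` (named list per unit),
#'   `mean_rates`, `activity`, and `data_reduction`.
#' @export
evaluate_run <- function(run, truth, config = evaluation_config(),
                         trace = NULL) {
  assignment <- assign_neurons(run$output_spikes, truth, config)
  recognition <- lapply(names(assignment), function(u) {
    recognition_rate(run$output_spikes, truth[[u]], assignment[[u]], config,
                     t_end = run$duration_s)
  })
  names(recognition) <- names(assignment)
  mean_rates <- vapply(recognition, `[[`, numeric(1), "mean_rate")
  activity <- activity_histogram(run$output_spikes, config$bin_s,
                                 duration_s = run$duration_s,
                                 n_neurons = run$bank$n_output)
  dr <- if (!is.null(trace)) data_reduction(trace, run$output_spikes) else
    run$n_samples / max(1L, nrow(run$output_spikes))
  list(assignment = assignment, recognition = recognition,
       mean_rates = mean_rates, activity = activity, data_reduction = dr)
}
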