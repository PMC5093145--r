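#' Continuous voltage trace
#'
#' Container for a uniformly sampled single-channel voltage time series, the
#' raw material of extracellular spike sorting. Amplitudes are in arbitrary
#' units; the network operates on traces normalized to peak amplitude 1 (see
#' [normalize_trace()]).
#'
#' @param samples Numeric vector of amplitudes (finite, length >= 1).
#' @param rate_hz Sampling frequency in Hz (> 0).
#' @param t0_s Time of the first sample in seconds.
#' @return An object of class `signal_trace`: a list with elements `samples`,
#'   `rate_hz` and `t0_s`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 20000)), 20000)
#' tr
#' @export
signal_trace <- function(samples, rate_hz, t0_s = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("'samples' must contain at least one value", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("'samples' must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("'rate_hz' must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         t0_s = as.numeric(t0_s)),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  dur <- length(x$samples) / x$rate_hz
  cat(sprintf(
    "<signal_trace> %d samples @ %g Hz (%.3f s from t0 = %g s), range [%.4g, %.4g]\n",
    length(x$samples), x$rate_hz, dur, x$t0_s,
    min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Sample times of a trace
#'
#' @param trace A [signal_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  trace$t0_s + (seq_along(trace$samples) - 1) / trace$rate_hz
}

#' Normalize a trace to unit peak amplitude
#'
#' Max-abs normalization: divides by `max(abs(samples))` so the output spans
#' \[-1, 1\]. An all-zero trace is returned unchanged. With
#' `streaming = TRUE` the divisor is instead the running maximum of
#' `abs(samples)` over a trailing window, a causal variant usable online (the
#' first samples are divided by the running max seen so far).
#'
#' @param trace A [signal_trace()].
#' @param streaming Use a causal running-max divisor instead of the global max.
#' @param window_s Trailing window length in seconds for the streaming variant.
#' @return A [signal_trace()] with identical rate, length and t0.
#' @examples
#' normalize_trace(signal_trace(c(0, 2, -4), 1000))$samples # 0, 0.5, -1
#' @export
normalize_trace <- function(trace, streaming = FALSE, window_s = 10) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$samples
  if (!streaming) {
    m <- max(abs(x))
    if (m == 0) return(trace)
    return(signal_trace(x / m, trace$rate_hz, trace$t0_s))
  }
  w <- max(1L, as.integer(round(window_s * trace$rate_hz)))
  m <- running_max_abs(x, w)
  m[m == 0] <- 1
  signal_trace(x / m, trace$rate_hz, trace$t0_s)
}

# trailing-window running maximum of |x| (window w samples, inclusive)
running_max_abs <- function(x, w) {
  ax <- abs(x)
  n <- length(ax)
  out <- numeric(n)
  # monotone deque of indices, O(n)
  dq <- integer(n)
  head <- 1L; tail <- 0L
  for (i in seq_len(n)) {
    while (tail >= head && ax[dq[tail]] <= ax[i]) tail <- tail - 1L
    tail <- tail + 1L
    dq[tail] <- i
    if (dq[head] <= i - w) head <- head + 1L
    out[i] <- ax[dq[head]]
  }
  out
}

#' Read / write a voltage trace
#'
#' Delimited-text format: a header line `# rate_hz=<r> t0_s=<t>` followed by
#' one sample per line. WAV files are 16-bit PCM mono; the sampling rate is
#' taken from (written to) the RIFF header and amplitudes are scaled to
#' \[-1, 1\] on read.
#'
#' @param path File path. Format is inferred from the extension unless given.
#' @param format `"txt"` or `"wav"`.
#' @return `read_trace` returns a [signal_trace()]; `write_trace` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path, format = c("auto", "txt", "wav")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "txt"
  }
  if (format == "wav") return(read_wav_trace(path))
  lines <- readLines(path)
  if (length(lines) < 2L || !grepl("^#", lines[1L])) {
    stop("trace file must start with a '# rate_hz=... t0_s=...' header: ", path,
         call. = FALSE)
  }
  hdr <- lines[1L]
  rate <- as.numeric(sub(".*rate_hz=([0-9.eE+-]+).*", "\\1", hdr))
  t0 <- if (grepl("t0_s=", hdr)) {
    as.numeric(sub(".*t0_s=([0-9.eE+-]+).*", "\\1", hdr))
  } else 0
  body <- lines[-1L]
  body <- body[nzchar(body)]
  x <- suppressWarnings(as.numeric(body))
  if (anyNA(x)) {
    bad <- which(is.na(x))[1L]
    stop(sprintf("malformed sample at line %d of %s", bad + 1L, path),
         call. = FALSE)
  }
  signal_trace(x, rate, t0)
}

#' @param trace A [signal_trace()] to write.
#' @rdname read_trace
#' @export
write_trace <- function(trace, path, format = c("auto", "txt", "wav")) {
  stopifnot(inherits(trace, "signal_trace"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "txt"
  }
  if (format == "wav") return(write_wav_trace(trace, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g t0_s=%.10g", trace$rate_hz, trace$t0_s),
             con)
  writeLines(format(trace$samples, digits = 17, scientific = TRUE, trim = TRUE),
             con)
  invisible(path)
}

# Minimal RIFF/WAVE PCM-16 mono reader. No R WAV package is available in the
# supported dependency set, so the 44-byte canonical header is parsed directly.
read_wav_trace <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      channels <- fmt[2L]
      rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
      invisible(readBin(con, "integer", 1L, size = 2L, endian = "little"))
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("WAV 'data' chunk before 'fmt '", call. = FALSE)
      if (bits != 16L) stop("only 16-bit PCM WAV is supported", call. = FALSE)
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, size = 2L, signed = TRUE,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
    }
  }
  if (is.null(samples)) stop("no 'data' chunk found in ", path, call. = FALSE)
  if (!is.null(channels) && channels != 1L) {
    stop("only mono WAV traces are supported", call. = FALSE)
  }
  signal_trace(samples / 32767, rate)
}

write_wav_trace <- function(trace, path) {
  x <- trace$samples
  m <- max(abs(x))
  if (m > 1) x <- x / m  # clip-free: rescale rather than wrap
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 1L), con, size = 2L, endian = "little")      # PCM, mono
  rate <- as.integer(round(trace$rate_hz))
  writeBin(rate, con, size = 4L, endian = "little")
  writeBin(rate * 2L, con, size = 4L, endian = "little")      # byte rate
  writeBin(2L, con, size = 2L, endian = "little")             # block align
  writeBin(16L, con, size = 2L, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
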