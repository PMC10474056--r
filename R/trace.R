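#' Uniformly sampled voltage trace
#'
#' Container for the microphone-style signal at the whisker base: a uniformly
#' sampled sequence of voltages carrying a DC offset `V_off` (the acquisition
#' chain sits mid-rail; the physical signal is `samples - V_off`).
#'
#' @param samples numeric vector of samples
#' @param sample_rate sampling rate \[samples/s\]; the study-standard rate is
#'   20000
#' @param V_off offset voltage \[V\]
#' @param gain_label free-text description of the gain/calibration state
#' @param t0 time of the first sample \[s\]
#' @param units units of `samples` (default `"V"`)
#' @param clipped logical flag: samples touched the configured rails
#' @return an object of class `voltage_trace`
#' @export
voltage_trace <- function(samples, sample_rate = 20000, V_off = 0,
                          gain_label = "", t0 = 0, units = "V",
                          clipped = FALSE) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 V_off = V_off, gain_label = gain_label, t0 = t0,
                 units = units, clipped = isTRUE(clipped)),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage_trace: %d samples @ %g S/s (%.4g s), V_off = %g %s%s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$V_off, x$units,
              if (x$clipped) " [clipped]" else ""))
  invisible(x)
}

#' Sample times of a trace
#' @param trace a [voltage_trace()]
#' @return numeric vector of sample times \[s\]
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$sample_rate
}

#' Offset-corrected samples
#'
#' @param trace a [voltage_trace()]
#' @param V_off optional override; by default the trace's own recorded
#'   offset. Pass `NA` to estimate it as the mean of the trace (the
#'   free-vibration-interval convention used when no separate offset
#'   measurement exists).
#' @return numeric vector `samples - V_off`
#' @export
offset_correct <- function(trace, V_off = NULL) {
  if (is.null(V_off)) V_off <- trace$V_off
  if (is.na(V_off)) V_off <- mean(trace$samples)
  trace$samples - V_off
}

#' Read / write traces as delimited text
#'
#' One-line `#`-prefixed header (`sample_rate`, `units`, `offset`, `t0`)
#' followed by one sample per line.
#'
#' @param trace a [voltage_trace()]
#' @param path file path
#' @return `read_trace` returns a [voltage_trace()]; `write_trace` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  header <- sprintf("# sample_rate=%.10g units=%s offset=%.10g t0=%.10g",
                    trace$sample_rate, trace$units, trace$V_off, trace$t0)
  writeLines(c(header, sprintf("%.10g", trace$samples)), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#"))
    stop("trace file must start with a '#' header line")
  fields <- strsplit(trimws(sub("^#\\s*", "", lines[1])), "\\s+")[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  voltage_trace(as.numeric(lines[-1]),
                sample_rate = as.numeric(vals[["sample_rate"]]),
                V_off = as.numeric(vals[["offset"]]),
                t0 = as.numeric(vals[["t0"]]),
                units = vals[["units"]])
}
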