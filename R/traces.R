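#' Respiration voltage trace
#'
#' A uniformly sampled open-circuit voltage time series from the mask
#' sensor, with sampling interval `dt`, start time and an optional sleep
#' stage label.
#'
#' @param samples numeric vector of voltages (volts), all finite, length >= 1.
#' @param dt sampling interval in seconds (> 0); the sensor default is
#'   0.017 s.
#' @param start_time start time of the first sample in seconds.
#' @param stage optional sleep stage label (see [stage_levels()]).
#' @return An object of class `resp_trace`: a list with elements `samples`,
#'   `dt`, `start_time`, `stage`.
#' @export
#' @examples
#' tr <- resp_trace(sin(2 * pi * 0.25 * seq(0, 30, by = 0.017)), dt = 0.017)
#' tr
resp_trace <- function(samples, dt = 0.017, start_time = 0, stage = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop_respstage("dt must be a single positive number", "respstage_invalid_parameter")
  if (length(samples) < 1L)
    stop_respstage("trace must contain at least one sample", "respstage_invalid_input")
  check_finite(samples, "samples")
  if (!is.null(stage)) stage <- as.character(as_stage(stage))
  structure(list(samples = as.numeric(samples), dt = dt,
                 start_time = start_time, stage = stage),
            class = "resp_trace")
}

#' @export
print.resp_trace <- function(x, ...) {
  dur <- length(x$samples) * x$dt
  cat(sprintf("<resp_trace> %d samples, dt = %g s (%.1f s)%s\n",
              length(x$samples), x$dt, dur,
              if (is.null(x$stage)) "" else paste0(", stage ", x$stage)))
  invisible(x)
}

#' @export
length.resp_trace <- function(x) length(x$samples)

#' Sample times of a trace
#' @param trace a [resp_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1) * trace$dt
}

#' Read and write respiration traces
#'
#' Traces are stored as two-column delimited text (`time_s`, `voltage_V`)
#' with a mandatory header; lines starting with `#` are comments (used for
#' provenance stamps).
#'
#' @param trace a [resp_trace()].
#' @param path file path.
#' @param comment optional character vector written as `#`-prefixed header
#'   comment lines.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [resp_trace()].
#' @export
write_trace <- function(trace, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("time_s\tvoltage_V", con)
  writeLines(sprintf("%.6f\t%.9g", trace_times(trace), trace$samples), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("time_s", "voltage_V") %in% names(d)))
    stop_respstage(sprintf("'%s' lacks the time_s/voltage_V header", path),
                   "respstage_parse_error")
  dt <- if (nrow(d) > 1) stats::median(diff(d$time_s)) else 0.017
  resp_trace(d$voltage_V, dt = dt, start_time = d$time_s[1])
}

#' Read and write hypnograms
#'
#' A hypnogram is the time course of sleep stages: three-column delimited
#' text (`start_s`, `duration_s`, `stage`), stages spelled as
#' [stage_levels()] tokens.
#'
#' @param hypnogram data frame with columns `start_s`, `duration_s`, `stage`.
#' @param path file path.
#' @param comment optional `#`-prefixed header comment lines.
#' @return `write_hypnogram` returns `path` invisibly; `read_hypnogram`
#'   returns the hypnogram data frame with `stage` as a stage factor.
#' @export
write_hypnogram <- function(hypnogram, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("start_s\tduration_s\tstage", con)
  writeLines(sprintf("%.3f\t%.3f\t%s", hypnogram$start_s,
                     hypnogram$duration_s, as.character(hypnogram$stage)), con)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         colClasses = c("numeric", "numeric", "character"))
  bad <- which(!(d$stage %in% stage_levels()))
  if (length(bad))
    stop_respstage(sprintf("'%s': unknown stage '%s' on data line %d",
                           path, d$stage[bad[1]], bad[1]),
                   "respstage_parse_error")
  d$stage <- as_stage(d$stage)
  d
}

#' Read and write feature tables
#'
#' Delimited text with columns (`window_start_s`, `rate_bpm`, `voltage_V`,
#' `stage`); `stage` may be the empty string for unlabeled windows.
#'
#' @param features data frame as returned by [extract_features()].
#' @param path file path.
#' @param comment optional `#`-prefixed header comment lines.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the feature data frame.
#' @export
write_features <- function(features, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("window_start_s\trate_bpm\tvoltage_V\tstage", con)
  st <- as.character(features$stage)
  st[is.na(st)] <- ""
  writeLines(sprintf("%.3f\t%.9g\t%.9g\t%s", features$window_start_s,
                     features$rate_bpm, features$voltage, st), con)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         colClasses = c("numeric", "numeric", "numeric", "character"),
                         na.strings = "")
  data.frame(window_start_s = d$window_start_s, rate_bpm = d$rate_bpm,
             voltage = d$voltage_V, stage = as_stage(d$stage))
}
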