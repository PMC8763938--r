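# Lightweight S3 containers shared across modules.

#' Construct a conditioned photometry trace
#'
#' @param values Numeric vector of samples.
#' @param fs Sampling rate, Hz.
#' @param channel One of `"green"`, `"red"`, `"autofluorescence"`.
#' @param stage Processing stage: `"demodulated"`, `"downsampled"`,
#'   `"detrended"` or `"zscored"`.
#' @param units `"au"` (arbitrary fluorescence units) or `"z"`.
#' @param start_time Time of the first sample, seconds.
#' @return A `conditioned_trace` object.
#' @export
conditioned_trace <- function(values, fs,
                              channel = c("green", "red", "autofluorescence"),
                              stage = c("demodulated", "downsampled",
                                        "detrended", "zscored"),
                              units = "au", start_time = 0) {
  channel <- match.arg(channel)
  stage <- match.arg(stage)
  stopifnot(is.numeric(values), fs > 0, all(is.finite(values)))
  structure(list(values = as.numeric(values), fs = fs, channel = channel,
                 stage = stage, units = units, start_time = start_time),
            class = "conditioned_trace")
}

#' @export
print.conditioned_trace <- function(x, ...) {
  cat(sprintf("<conditioned_trace> %s | %s | %d samples @ %g Hz (%.1f s) [%s]\n",
              x$channel, x$stage, length(x$values), x$fs,
              length(x$values) / x$fs, x$units))
  invisible(x)
}

#' @export
length.conditioned_trace <- function(x) length(x$values)

trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$values) - 1) / trace$fs
}

#' Construct a frequency-multiplexed photoreceiver recording
#'
#' One column of `samples` per emission sensor. Each sensor's calcium
#' signal rides on its matching LED carrier; the shared autofluorescence
#' artifact appears on both carriers, which is what makes the
#' cross-frequency estimate possible.
#'
#' @param samples Numeric matrix (samples x sensors) with column names
#'   matching carrier roles, or a vector for a single-sensor recording.
#' @param fs_raw Acquisition rate, Hz.
#' @param carriers Data frame with columns `freq` (Hz) and `role`.
#' @param start_time Seconds.
#' @return A `modulated_recording` object.
#' @export
modulated_recording <- function(samples, fs_raw, carriers, start_time = 0) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  stopifnot(is.data.frame(carriers), all(c("freq", "role") %in% names(carriers)),
            fs_raw > 0, all(is.finite(samples)))
  if (fs_raw <= 2 * max(carriers$freq)) {
    stop("fs_raw must exceed twice the highest carrier frequency")
  }
  if (fs_raw < 10 * max(carriers$freq)) {
    warning("fs_raw below 10x the highest carrier frequency; ",
            "demodulation accuracy may suffer")
  }
  if (is.null(colnames(samples)) && ncol(samples) == nrow(carriers)) {
    colnames(samples) <- carriers$role
  }
  structure(list(samples = samples, fs_raw = fs_raw,
                 carriers = carriers, start_time = start_time),
            class = "modulated_recording")
}

#' @export
print.modulated_recording <- function(x, ...) {
  cat(sprintf("<modulated_recording> %d samples x %d sensor(s) @ %g Hz\n",
              nrow(x$samples), ncol(x$samples), x$fs_raw))
  cat("  carriers:", paste(sprintf("%s=%g Hz", x$carriers$role,
                                   x$carriers$freq), collapse = ", "), "\n")
  invisible(x)
}

#' Construct an event table
#'
#' @param time Event times, seconds.
#' @param type Event types (e.g. `"open_entry"`, `"closed_entry"`,
#'   `"rear"`, `"stretch_attend"`, `"head_dip"`, `"arm_end_reached"`).
#' @param animal Optional animal/session identifier.
#' @return A data frame of class `event_table`, ordered by time, with an
#'   `ordinal` column counting events within each type.
#' @export
event_table <- function(time, type, animal = NULL) {
  stopifnot(length(time) == length(type), all(is.finite(time)))
  ord <- order(time)
  df <- data.frame(time = time[ord], type = as.character(type)[ord],
                   stringsAsFactors = FALSE)
  if (!is.null(animal)) df$animal <- rep_len(animal, nrow(df))[ord]
  df$ordinal <- stats::ave(df$time, df$type, FUN = seq_along)
  if (anyDuplicated(df[c("time", "type")])) {
    stop("event times must be strictly increasing within type")
  }
  class(df) <- c("event_table", "data.frame")
  df
}

known_event_types <- c("open_entry", "closed_entry", "rear",
                       "stretch_attend", "head_dip", "arm_end_reached")
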