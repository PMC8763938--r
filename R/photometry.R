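# Frequency-multiplexed photometry conditioning: quadrature lock-in
# demodulation of each LED carrier, cross-frequency autofluorescence
# estimation, 50 Hz downsampling, polynomial detrending and session-wide
# z-scoring of the autofluorescence-corrected signal.

#' Photometry processing configuration
#'
#' @param lowpass_cutoff Lock-in low-pass cutoff, Hz. Must be below half
#'   the smallest carrier-frequency gap (crosstalk) and below half the
#'   output rate (aliasing). Default 20 Hz.
#' @param filter_order Butterworth order of each zero-phase pass.
#' @param poly_order Detrending polynomial order (default 3).
#' @param downsample_fs Output rate, Hz (default 50).
#' @param settle_discard Seconds trimmed from each end of the 50 Hz
#'   traces before statistics, absorbing filter settling (default 0.5).
#' @return A `photometry_config` list.
#' @export
photometry_config <- function(lowpass_cutoff = 20, filter_order = 4,
                              poly_order = 3, downsample_fs = 50,
                              settle_discard = 0.5) {
  stopifnot(lowpass_cutoff > 0, filter_order >= 1, poly_order >= 0,
            downsample_fs > 2 * lowpass_cutoff, settle_discard >= 0)
  structure(list(lowpass_cutoff = lowpass_cutoff,
                 filter_order = filter_order, poly_order = poly_order,
                 downsample_fs = downsample_fs,
                 settle_discard = settle_discard),
            class = "photometry_config")
}

resolve_carrier <- function(rec, carrier) {
  if (is.character(carrier)) {
    i <- match(carrier, rec$carriers$role)
    if (is.na(i)) stop("carrier role not found in recording: ", carrier)
    return(rec$carriers[i, ])
  }
  if (is.numeric(carrier) && length(carrier) == 1) {
    i <- match(carrier, rec$carriers$freq)
    if (is.na(i)) {
      return(data.frame(freq = carrier, role = "green",
                        stringsAsFactors = FALSE))
    }
    return(rec$carriers[i, ])
  }
  stopifnot(is.data.frame(carrier), all(c("freq", "role") %in% names(carrier)))
  carrier
}

check_crosstalk <- function(rec, cfg) {
  f <- sort(rec$carriers$freq)
  if (length(f) >= 2) {
    gap <- min(diff(f))
    if (cfg$lowpass_cutoff >= gap / 2) {
      stop("lowpass_cutoff must be below half the carrier-frequency gap (",
           gap, " Hz) to avoid cross-channel crosstalk")
    }
  }
}

#' Quadrature lock-in demodulation of one carrier
#'
#' Multiplies the sensor trace by sine and cosine references at the
#' carrier frequency, low-passes both products with a zero-phase
#' Butterworth, and returns `4 * sqrt(I^2 + Q^2)` — scaled so that a
#' unit-amplitude offset-sinusoid carrier `env * (1 + sin)/2` recovers
#' `env` exactly. The quadrature magnitude makes the result invariant to
#' any carrier phase offset.
#'
#' @param rec A [modulated_recording()].
#' @param carrier Carrier to demodulate: a role name, a frequency in Hz,
#'   or a one-row data frame (`freq`, `role`).
#' @param cfg A [photometry_config()].
#' @param sensor Sensor column to demodulate; defaults to the one
#'   matching the carrier's role (falling back to the first column).
#' @return A `"demodulated"` [conditioned_trace()] at `fs_raw`.
#' @export
demodulate <- function(rec, carrier, cfg = photometry_config(),
                       sensor = NULL) {
  stopifnot(inherits(rec, "modulated_recording"),
            inherits(cfg, "photometry_config"))
  car <- resolve_carrier(rec, carrier)
  if (rec$fs_raw <= 2 * car$freq) {
    stop("fs_raw must exceed twice the carrier frequency")
  }
  check_crosstalk(rec, cfg)
  if (is.null(sensor)) {
    sensor <- if (car$role %in% colnames(rec$samples)) car$role else 1L
  }
  x <- rec$samples[, sensor]
  n <- length(x)
  t <- (seq_len(n) - 1) / rec$fs_raw
  wt <- 2 * pi * car$freq * t
  i_comp <- lowpass_filtfilt(x * sin(wt), cfg$lowpass_cutoff, rec$fs_raw,
                             cfg$filter_order)
  q_comp <- lowpass_filtfilt(x * cos(wt), cfg$lowpass_cutoff, rec$fs_raw,
                             cfg$filter_order)
  env <- 4 * sqrt(i_comp^2 + q_comp^2)
  channel <- if (car$role %in% c("green", "red")) car$role else "green"
  conditioned_trace(env, rec$fs_raw, channel = channel,
                    stage = "demodulated", start_time = rec$start_time)
}

#' Cross-frequency autofluorescence estimate for one sensor
#'
#' Demodulates a sensor's trace at the carrier frequency that does *not*
#' match the sensor. Because the sensor's indicator rides only on its own
#' carrier while broadband autofluorescence rides on both, the
#' non-matching frequency isolates the autofluorescence.
#'
#' @param rec A [modulated_recording()] with two distinct carriers.
#' @param own_carrier The sensor's matching carrier (role or Hz).
#' @param other_carrier The non-matching carrier; defaults to the other
#'   entry of `rec$carriers`.
#' @param cfg A [photometry_config()].
#' @return An `"autofluorescence"` [conditioned_trace()] at `fs_raw`.
#' @export
extract_autofluorescence <- function(rec, own_carrier, other_carrier = NULL,
                                     cfg = photometry_config()) {
  own <- resolve_carrier(rec, own_carrier)
  if (is.null(other_carrier)) {
    others <- rec$carriers[rec$carriers$freq != own$freq, , drop = FALSE]
    if (nrow(others) == 0) stop("no non-matching carrier available")
    other <- others[1, ]
  } else {
    other <- resolve_carrier(rec, other_carrier)
  }
  if (isTRUE(all.equal(own$freq, other$freq))) {
    stop("own and other carriers must be distinct")
  }
  tr <- demodulate(rec, other, cfg, sensor = own$role)
  tr$channel <- "autofluorescence"
  tr
}

#' Anti-alias filter and decimate a trace
#'
#' @param trace A [conditioned_trace()].
#' @param target_fs Output rate, Hz (default 50). Must not exceed the
#'   input rate and must exceed twice the anti-alias cutoff.
#' @param cfg A [photometry_config()]; the anti-alias cutoff is
#'   `min(lowpass_cutoff, 0.4 * target_fs)`.
#' @return A `"downsampled"` [conditioned_trace()] with
#'   `floor(duration * target_fs)` samples.
#' @export
downsample <- function(trace, target_fs = 50, cfg = photometry_config()) {
  stopifnot(inherits(trace, "conditioned_trace"), target_fs > 0)
  if (target_fs > trace$fs) stop("target_fs must not exceed the input rate")
  cutoff <- min(cfg$lowpass_cutoff, 0.4 * target_fs)
  if (target_fs <= 2 * cutoff) stop("target_fs violates the Nyquist margin")
  y <- if (trace$fs / target_fs > 1.0001) {
    lowpass_filtfilt(trace$values, cutoff, trace$fs, cfg$filter_order)
  } else trace$values
  n_out <- floor(length(trace$values) / trace$fs * target_fs)
  idx <- floor((seq_len(n_out) - 1) * trace$fs / target_fs) + 1L
  conditioned_trace(y[idx], target_fs, channel = trace$channel,
                    stage = "downsampled", units = trace$units,
                    start_time = trace$start_time)
}

#' Subtract a least-squares polynomial trend
#'
#' Fits a polynomial of the given order to the whole trace by least
#' squares (orthogonal polynomial basis for conditioning) and subtracts
#' it; removes slow photobleaching. The residual has mean ~0.
#'
#' @param trace A [conditioned_trace()].
#' @param order Polynomial order (default 3).
#' @return A `"detrended"` [conditioned_trace()].
#' @export
detrend_poly <- function(trace, order = 3) {
  stopifnot(inherits(trace, "conditioned_trace"), order >= 0)
  n <- length(trace$values)
  if (n <= order + 1) stop("trace too short for the requested order")
  if (order == 0) {
    res <- trace$values - mean(trace$values)
  } else {
    tt <- seq_len(n)
    fit <- stats::lm.fit(cbind(1, stats::poly(tt, order)), trace$values)
    res <- fit$residuals
  }
  conditioned_trace(res, trace$fs, channel = trace$channel,
                    stage = "detrended", units = trace$units,
                    start_time = trace$start_time)
}

#' Align the autofluorescence trace to a signal by linear least squares
#'
#' Ordinary least squares of `signal` on `autofluor`; the fitted trace
#' `slope * autofluor + intercept` is what gets subtracted before
#' z-scoring. A zero-variance autofluorescence regressor is degenerate:
#' the slope is undefined and the fitted trace falls back to the signal
#' mean (flagged).
#'
#' @param signal,autofluor [conditioned_trace()]s of equal length and
#'   rate.
#' @return List with `slope`, `intercept`, `fitted` (a
#'   [conditioned_trace()]) and `degenerate` flag.
#' @export
fit_autofluorescence <- function(signal, autofluor) {
  stopifnot(inherits(signal, "conditioned_trace"),
            inherits(autofluor, "conditioned_trace"),
            length(signal$values) == length(autofluor$values),
            isTRUE(all.equal(signal$fs, autofluor$fs)))
  x <- autofluor$values; y <- signal$values
  vx <- stats::var(x)
  if (vx < .Machine$double.eps) {
    fitted <- rep(mean(y), length(y))
    out <- list(slope = NA_real_, intercept = mean(y), degenerate = TRUE)
  } else {
    slope <- stats::cov(x, y) / vx
    intercept <- mean(y) - slope * mean(x)
    fitted <- slope * x + intercept
    out <- list(slope = slope, intercept = intercept, degenerate = FALSE)
  }
  out$fitted <- conditioned_trace(fitted, signal$fs, channel = signal$channel,
                                  stage = signal$stage, units = signal$units,
                                  start_time = signal$start_time)
  out
}

#' Z-score a signal after autofluorescence subtraction
#'
#' Computes `d = signal - fitted_autofluor` and returns
#' `(d - mean(d)) / sd(d)` with statistics over the whole session.
#'
#' @param signal A [conditioned_trace()].
#' @param fitted_autofluor A [conditioned_trace()] of the same geometry,
#'   or `NULL` to z-score the signal alone.
#' @return A `"zscored"` [conditioned_trace()] in z units.
#' @export
zscore_corrected <- function(signal, fitted_autofluor = NULL) {
  stopifnot(inherits(signal, "conditioned_trace"))
  d <- signal$values
  if (!is.null(fitted_autofluor)) {
    stopifnot(length(fitted_autofluor$values) == length(d))
    d <- d - fitted_autofluor$values
  }
  s <- stats::sd(d)
  if (!is.finite(s) || s < .Machine$double.eps) {
    stop("residual has zero variance; z-score undefined")
  }
  conditioned_trace((d - mean(d)) / s, signal$fs, channel = signal$channel,
                    stage = "zscored", units = "z",
                    start_time = signal$start_time)
}

trim_trace <- function(trace, seconds) {
  if (seconds <= 0) return(trace)
  k <- round(seconds * trace$fs)
  n <- length(trace$values)
  if (2 * k >= n) stop("settle_discard longer than the trace")
  conditioned_trace(trace$values[(k + 1):(n - k)], trace$fs,
                    channel = trace$channel, stage = trace$stage,
                    units = trace$units,
                    start_time = trace$start_time + k / trace$fs)
}

#' Full photometry conditioning pipeline for a two-carrier recording
#'
#' For each channel: demodulate its own carrier, demodulate the sensor at
#' the non-matching carrier (autofluorescence), downsample both to 50 Hz,
#' trim the filter settling margin, detrend each with a 3rd-order
#' polynomial, regress the signal on its autofluorescence estimate, and
#' z-score the residual over the whole session. By the viral strategy the
#' green channel reports the deep layer (creOFF GCaMP6f) and the red
#' channel the superficial layer (creON RGeCO1a).
#'
#' @param rec A two-carrier [modulated_recording()].
#' @param cfg A [photometry_config()].
#' @return List with `"zscored"` traces `green` and `red` (attributes
#'   carry the layer mapping), the intermediate autofluorescence fits,
#'   and a per-stage `log`.
#' @export
process_session <- function(rec, cfg = photometry_config()) {
  stopifnot(inherits(rec, "modulated_recording"))
  if (nrow(rec$carriers) != 2) {
    stop("process_session expects exactly two carriers")
  }
  layer_of <- c(green = "deep", red = "superficial")
  out <- list(log = list())
  for (i in seq_len(2)) {
    role <- rec$carriers$role[i]
    sig <- demodulate(rec, rec$carriers[i, ], cfg)
    af <- extract_autofluorescence(rec, rec$carriers[i, ], cfg = cfg)
    sig <- trim_trace(downsample(sig, cfg$downsample_fs, cfg),
                      cfg$settle_discard)
    af <- trim_trace(downsample(af, cfg$downsample_fs, cfg),
                     cfg$settle_discard)
    sig <- detrend_poly(sig, cfg$poly_order)
    af <- detrend_poly(af, cfg$poly_order)
    fit <- fit_autofluorescence(sig, af)
    z <- zscore_corrected(sig, fit$fitted)
    attr(z, "layer") <- layer_of[[role]]
    out[[role]] <- z
    out$log[[role]] <- list(
      stages = c("demodulated", "downsampled", "trimmed", "detrended",
                 "autofluorescence_fit", "zscored"),
      carrier_hz = rec$carriers$freq[i],
      autofluor_slope = fit$slope,
      autofluor_intercept = fit$intercept,
      autofluor_degenerate = fit$degenerate,
      n_samples = length(z$values), fs = z$fs)
  }
  out
}
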