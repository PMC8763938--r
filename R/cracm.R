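# Optogenetic circuit-mapping quantification: light-evoked response
# amplitude (1-ms window around the peak of the averaged trace), the
# 6 x baseline-SD connectivity rule, paired input ratios, and intrinsic
# current-step features (spike counts, bursting, sag, tau_m, AP
# half-width) with fast-spiking classification.

#' Construct a sweep set
#'
#' @param sweeps Numeric matrix, one sweep per row (mV or pA).
#' @param fs Sampling rate, Hz.
#' @param onset Stimulus onset within the sweep, s.
#' @param holding Holding potential, mV (voltage clamp: -70 or 0), or
#'   `NA` for current clamp.
#' @param sweep_info Optional per-sweep metadata data frame (e.g.
#'   `duration_ms`, step `current_pa`).
#' @param baseline_window Length of the pre-stimulus baseline window, s
#'   (default 0.05).
#' @return A `sweep_set` object.
#' @export
sweep_set <- function(sweeps, fs, onset, holding = NA_real_,
                      sweep_info = NULL, baseline_window = 0.05) {
  if (is.null(dim(sweeps))) sweeps <- matrix(sweeps, nrow = 1)
  stopifnot(is.numeric(sweeps), fs > 0, all(is.finite(sweeps)),
            baseline_window > 0)
  dur <- ncol(sweeps) / fs
  if (onset <= 0 || onset >= dur) stop("stimulus onset outside the sweep")
  if (!is.null(sweep_info)) stopifnot(nrow(sweep_info) == nrow(sweeps))
  structure(list(sweeps = sweeps, fs = fs, onset = onset,
                 holding = holding, sweep_info = sweep_info,
                 baseline_window = baseline_window),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples @ %g Hz; onset %g s%s\n",
              nrow(x$sweeps), ncol(x$sweeps), x$fs, x$onset,
              if (is.na(x$holding)) "" else
                sprintf("; holding %g mV", x$holding)))
  invisible(x)
}

subset_sweeps <- function(ss, rows) {
  ss$sweeps <- ss$sweeps[rows, , drop = FALSE]
  if (!is.null(ss$sweep_info)) {
    ss$sweep_info <- ss$sweep_info[rows, , drop = FALSE]
  }
  ss
}

baseline_cols <- function(ss) {
  i1 <- max(1L, round((ss$onset - ss$baseline_window) * ss$fs) + 1L)
  i2 <- round(ss$onset * ss$fs)
  i1:i2
}

#' Light-evoked response amplitude
#'
#' Averages the sweeps, subtracts the pre-stimulus baseline mean,
#' locates the absolute peak of the mean trace within the response
#' window, and returns the mean over a 1-ms window centred on that peak
#' (signed; inward currents at -70 mV are negative).
#'
#' @param ss A [sweep_set()].
#' @param response_window `c(start, end)` seconds relative to stimulus
#'   onset (default `c(0.002, 0.05)`).
#' @param peak_window Averaging window around the peak, s (default
#'   1 ms).
#' @return List with `amplitude`, `peak_time` (s relative to onset),
#'   `baseline_sd` (SD of the averaged trace's baseline window), and
#'   `mean_trace`.
#' @export
response_amplitude <- function(ss, response_window = c(0.002, 0.05),
                               peak_window = 0.001) {
  stopifnot(inherits(ss, "sweep_set"), nrow(ss$sweeps) >= 1,
            response_window[1] >= 0,
            response_window[1] < response_window[2])
  m <- colMeans(ss$sweeps)
  m <- m - mean(m[baseline_cols(ss)])
  i1 <- round((ss$onset + response_window[1]) * ss$fs) + 1L
  i2 <- round((ss$onset + response_window[2]) * ss$fs)
  if (i1 < 1 || i2 > length(m)) stop("response window outside the sweep")
  seg <- m[i1:i2]
  pk <- i1 - 1L + which.max(abs(seg))
  hw <- max(1L, round(peak_window * ss$fs / 2))
  w1 <- max(1L, pk - hw); w2 <- min(length(m), pk + hw)
  list(amplitude = mean(m[w1:w2]),
       peak_time = (pk - 1) / ss$fs - ss$onset,
       baseline_sd = stats::sd(m[baseline_cols(ss)]),
       mean_trace = m)
}

#' Connectivity decision by the 6 x baseline-SD rule
#'
#' A cell is considered connected when the light-evoked amplitude
#' strictly exceeds `factor` times the baseline standard deviation.
#'
#' @param amplitude Signed response amplitude.
#' @param baseline_sd Baseline SD of the averaged trace; must be > 0.
#' @param factor Threshold factor (default 6).
#' @return List `connected` (logical, `NA` when undefined), `ratio`
#'   (`|amplitude| / baseline_sd`).
#' @export
detect_connection <- function(amplitude, baseline_sd, factor = 6) {
  stopifnot(is.finite(amplitude), baseline_sd >= 0, factor > 0)
  if (baseline_sd == 0) {
    return(list(connected = if (amplitude == 0) NA else TRUE,
                ratio = if (amplitude == 0) NaN else Inf))
  }
  ratio <- abs(amplitude) / baseline_sd
  list(connected = ratio > factor, ratio = ratio)
}

#' Paired response ratio (reported on a log axis)
#'
#' Ratio of two response magnitudes — e.g. superficial : deep EPSP
#' amplitude, -70 mV : 0 mV (E/I), or FS- : FS+. Values above 1 mean the
#' input is biased toward the first member of the pair.
#'
#' @param amp_first,amp_second Response amplitudes (magnitudes used).
#' @param epsilon Optional floor applied to zero magnitudes instead of
#'   erroring.
#' @return List with `ratio` and `log10_ratio`.
#' @export
pair_ratio <- function(amp_first, amp_second, epsilon = NULL) {
  a <- abs(amp_first); b <- abs(amp_second)
  if (!is.null(epsilon)) {
    a <- max(a, epsilon); b <- max(b, epsilon)
  }
  if (a <= 0 || b <= 0) {
    stop("pair_ratio requires positive magnitudes ",
         "(supply epsilon to floor zeros)")
  }
  list(ratio = a / b, log10_ratio = log10(a / b))
}

#' Count action potentials during a current step
#'
#' Upward crossings of the threshold (default 0 mV) during the step
#' window, with a refractory rule: crossings closer than `refractory`
#' seconds to the previous accepted spike are not counted.
#'
#' @param trace Membrane-potential vector, mV.
#' @param fs Sampling rate, Hz.
#' @param step_window `c(start, end)` seconds of the current step.
#' @param threshold Crossing threshold, mV (default 0).
#' @param refractory Minimum inter-spike interval, s (default 2 ms).
#' @param rail Voltage magnitude treated as amplifier clipping (flag
#'   only).
#' @return List `count`, `spike_times` (s), `clipped` flag.
#' @export
spike_count <- function(trace, fs, step_window, threshold = 0,
                        refractory = 0.002, rail = 100) {
  stopifnot(is.numeric(trace), fs > 0, length(step_window) == 2)
  i1 <- max(1L, floor(step_window[1] * fs) + 1L)
  i2 <- min(length(trace), ceiling(step_window[2] * fs))
  seg <- trace[i1:i2]
  up <- which(seg[-1] >= threshold & seg[-length(seg)] < threshold)
  times <- (i1 - 1 + up) / fs
  keep <- logical(length(times))
  last <- -Inf
  for (j in seq_along(times)) {
    if (times[j] - last >= refractory) {
      keep[j] <- TRUE
      last <- times[j]
    }
  }
  list(count = sum(keep), spike_times = times[keep],
       clipped = any(abs(seg) >= rail))
}

#' Burst-firing flag
#'
#' A response is classed as bursting when the first inter-spike interval
#' is below `isi_max` (default 10 ms). Fewer than two spikes is not a
#' burst by definition.
#'
#' @param spike_times Spike times, s (e.g. from [spike_count()]).
#' @param isi_max Burst ISI criterion, s.
#' @return Logical.
#' @export
burst_flag <- function(spike_times, isi_max = 0.010) {
  if (length(spike_times) < 2) return(FALSE)
  (spike_times[2] - spike_times[1]) < isi_max
}

#' Sag amplitude of a hyperpolarising current step
#'
#' `sag = steady-state mean (last `steady_window` s of the step) - the
#' minimum within the first `min_window` s of the step`. Positive values
#' indicate sag (h-current rebound). The step must hyperpolarise the
#' cell relative to the pre-step baseline.
#'
#' @param trace Membrane potential, mV.
#' @param fs Sampling rate, Hz.
#' @param step_window `c(start, end)` seconds of the current step.
#' @param min_window Search window for the early minimum, s (default
#'   0.3).
#' @param steady_window Steady-state averaging window at the step end, s
#'   (default 0.1).
#' @return Sag amplitude, mV.
#' @export
sag_amplitude <- function(trace, fs, step_window, min_window = 0.3,
                          steady_window = 0.1) {
  stopifnot(is.numeric(trace), fs > 0, length(step_window) == 2,
            step_window[1] < step_window[2])
  i1 <- floor(step_window[1] * fs) + 1L
  i2 <- min(length(trace), ceiling(step_window[2] * fs))
  if (i1 < 1 || i1 >= i2) stop("step window outside the trace")
  pre <- trace[max(1L, i1 - round(0.05 * fs)):(i1 - 1L)]
  seg <- trace[i1:i2]
  if (mean(seg) >= mean(pre)) {
    stop("sag_amplitude requires a hyperpolarising step")
  }
  early <- seg[seq_len(min(length(seg), round(min_window * fs)))]
  steady <- seg[max(1L, length(seg) - round(steady_window * fs) + 1L):
                  length(seg)]
  mean(steady) - min(early)
}

# single-exponential membrane charging fit on the step onset:
# V(t) = V_ss + (V_0 - V_ss) exp(-t / tau)
fit_membrane_tau <- function(trace, fs, step_window, fit_span = 0.1) {
  i1 <- floor(step_window[1] * fs) + 1L
  i2 <- min(length(trace), ceiling(step_window[2] * fs))
  seg <- trace[i1:i2]
  v_ss <- mean(seg[max(1L, length(seg) - round(0.1 * fs)):length(seg)])
  n_fit <- min(length(seg), round(fit_span * fs))
  t_fit <- (seq_len(n_fit) - 1) / fs
  dv <- seg[seq_len(n_fit)] - v_ss
  sign0 <- sign(dv[1])
  ok <- which(sign0 * dv > 1e-9)
  if (length(ok) < 5) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, t_fit[ok]), log(sign0 * dv[ok]))
  tau <- -1 / fit$coefficients[2]
  if (!is.finite(tau) || tau <= 0) NA_real_ else tau
}

# AP half-width: width at half the peak-to-threshold height of the
# first spike; threshold = voltage where dV/dt first exceeds dvdt_thresh
ap_half_width <- function(trace, fs, spike_time, dvdt_thresh = 20,
                          search = 0.005) {
  i_pk0 <- round(spike_time * fs)
  i1 <- max(2L, i_pk0 - round(search * fs))
  i2 <- min(length(trace), i_pk0 + round(search * fs))
  seg <- trace[i1:i2]
  pk <- which.max(seg)
  dvdt <- diff(seg) * fs / 1000  # mV per ms
  th_i <- which(dvdt[seq_len(max(pk - 1, 1))] > dvdt_thresh)
  if (!length(th_i)) return(NA_real_)
  th_i <- th_i[1]
  v_th <- seg[th_i]; v_pk <- seg[pk]
  half <- (v_pk + v_th) / 2
  # interpolated crossings on each flank
  up <- NA_real_
  for (j in th_i:(pk - 1)) {
    if (seg[j] <= half && seg[j + 1] > half) {
      up <- j + (half - seg[j]) / (seg[j + 1] - seg[j]); break
    }
  }
  down <- NA_real_
  for (j in pk:(length(seg) - 1)) {
    if (seg[j] >= half && seg[j + 1] < half) {
      down <- j + (seg[j] - half) / (seg[j] - seg[j + 1]); break
    }
  }
  if (is.na(up) || is.na(down)) return(NA_real_)
  (down - up) / fs
}

#' Intrinsic features from a current-step protocol
#'
#' Extracts spike counts per step, burst flag, sag at the -160 pA step,
#' membrane time constant (single-exponential fit to the onset of the
#' smallest hyperpolarising step), first-spike action-potential
#' half-width, and resting potential.
#'
#' @param ss A current-clamp [sweep_set()] whose `sweep_info` has a
#'   `current_pa` column; `onset` marks the step start.
#' @param step_duration Step length, s (default 0.5).
#' @return An `intrinsic_features` list: `spike_counts` (data frame),
#'   `burst`, `sag_mv`, `tau_ms`, `half_width_ms`, `resting_mv`,
#'   `flags`.
#' @export
intrinsic_features <- function(ss, step_duration = 0.5) {
  stopifnot(inherits(ss, "sweep_set"), !is.null(ss$sweep_info),
            "current_pa" %in% names(ss$sweep_info))
  step_w <- c(ss$onset, ss$onset + step_duration)
  cur <- ss$sweep_info$current_pa
  counts <- integer(nrow(ss$sweeps))
  spike_times <- vector("list", nrow(ss$sweeps))
  clipped <- logical(nrow(ss$sweeps))
  for (i in seq_len(nrow(ss$sweeps))) {
    sc <- spike_count(ss$sweeps[i, ], ss$fs, step_w)
    counts[i] <- sc$count
    spike_times[[i]] <- sc$spike_times
    clipped[i] <- sc$clipped
  }
  spiking <- which(counts >= 2 & cur > 0)
  burst <- if (length(spiking)) {
    rheo <- spiking[which.min(cur[spiking])]
    burst_flag(spike_times[[rheo]])
  } else FALSE
  sag <- NA_real_
  i_sag <- which(cur == -160)
  if (length(i_sag)) {
    sag <- sag_amplitude(ss$sweeps[i_sag[1], ], ss$fs, step_w)
  }
  tau <- NA_real_
  hyp <- which(cur < 0 & counts == 0)
  if (length(hyp)) {
    i_tau <- hyp[which.max(cur[hyp])]  # smallest-magnitude hyperpolarising
    tau <- fit_membrane_tau(ss$sweeps[i_tau, ], ss$fs, step_w)
  }
  hw <- NA_real_
  sp <- which(counts >= 1)
  if (length(sp)) {
    first <- sp[which.min(cur[sp])]
    hw <- ap_half_width(ss$sweeps[first, ], ss$fs,
                        spike_times[[first]][1])
  }
  resting <- mean(ss$sweeps[, baseline_cols(ss)])
  structure(list(
    spike_counts = data.frame(current_pa = cur, count = counts),
    burst = burst, sag_mv = sag, tau_ms = tau * 1000,
    half_width_ms = hw * 1000, resting_mv = resting,
    flags = list(clipped = any(clipped),
                 no_subthreshold_step = is.na(tau),
                 no_spikes = !length(sp))),
    class = "intrinsic_features")
}

#' Classify cells as fast-spiking or not
#'
#' Two-cluster k-means partition on standardised (membrane time
#' constant, AP half-width); the cluster with the smaller mean
#' half-width is labelled `FS+`.
#'
#' @param features Data frame with columns `tau_ms` and
#'   `half_width_ms` (finite values).
#' @param n_restarts k-means restarts (default 10).
#' @param seed Integer RNG seed.
#' @return List with `labels` (`"FS+"` / `"FS-"`), `centers`,
#'   `degenerate` flag.
#' @export
classify_fs <- function(features, n_restarts = 10, seed = NULL) {
  stopifnot(is.data.frame(features),
            all(c("tau_ms", "half_width_ms") %in% names(features)))
  X <- as.matrix(features[, c("tau_ms", "half_width_ms")])
  if (nrow(X) < 4 || any(!is.finite(X))) {
    stop("need >= 4 cells with finite (tau_ms, half_width_ms)")
  }
  if (any(apply(X, 2, stats::sd) == 0) || nrow(unique(X)) < 2) {
    return(list(labels = rep(NA_character_, nrow(X)), centers = NULL,
                degenerate = TRUE))
  }
  Z <- scale(X)
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(Z, centers = 2, nstart = n_restarts)
  hw_means <- tapply(features$half_width_ms, km$cluster, mean)
  fs_cluster <- as.integer(names(which.min(hw_means)))
  labels <- unname(ifelse(km$cluster == fs_cluster, "FS+", "FS-"))
  list(labels = labels, centers = km$centers, degenerate = FALSE)
}
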