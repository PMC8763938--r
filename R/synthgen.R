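# Seeded generators for every input the pipeline consumes, each returning
# the generated object together with its ground truth so downstream
# modules can be tested for parameter recovery without experimental data.

## ---- photometry sessions ----------------------------------------------

#' Configuration for synthetic dual-colour photometry sessions
#'
#' Defaults reproduce the acquisition described for the dual-sensor rig:
#' 470 nm LED modulated at 210 Hz feeding the green (GCaMP6f, deep layer)
#' channel, 565 nm LED at 500 Hz feeding the red (RGeCO1a, superficial
#' layer) channel, photoreceiver sampled at 100 kHz. `fs_raw` is
#' configurable down to 10 kHz (still >= 10x the highest carrier) to keep
#' simulations desk-scale.
#'
#' @param session_duration Seconds (default 540 s, a 9-min maze session).
#' @param fs_raw Acquisition rate, Hz (default 100000).
#' @param carriers Named numeric vector of carrier frequencies, Hz.
#' @param transient_rate Calcium transient rate per channel, events/s.
#' @param transient_amplitude Transient peak amplitude, arbitrary
#'   fluorescence units (baseline fluorescence is ~1).
#' @param transient_kinetics `c(rise, decay)` seconds of the
#'   difference-of-exponentials transient kernel.
#' @param bleach_poly_coeffs Polynomial coefficients (intercept first) of
#'   the slow bleaching trend, evaluated on normalised session time.
#' @param autofluor_gain Coupling of the shared slow autofluorescence
#'   artifact into each channel (unitless).
#' @param noise_sd Additive Gaussian noise SD on the raw photoreceiver
#'   samples, fluorescence units.
#' @param seed Integer RNG seed; fixed seed gives bit-identical output.
#' @return A `synth_photometry_config` list.
#' @export
photometry_session_config <- function(session_duration = 540,
                                      fs_raw = 100000,
                                      carriers = c(green = 210, red = 500),
                                      transient_rate = c(green = 0.1, red = 0.1),
                                      transient_amplitude = c(green = 1, red = 1),
                                      transient_kinetics = c(rise = 0.05, decay = 0.5),
                                      bleach_poly_coeffs = c(1, -0.2, 0.05, 0),
                                      autofluor_gain = c(green = 0.2, red = 0.2),
                                      noise_sd = 0.02,
                                      seed = NULL) {
  stopifnot(session_duration > 0, fs_raw > 0, length(carriers) == 2,
            all(carriers > 0), all(transient_rate >= 0),
            all(transient_amplitude >= 0), all(transient_kinetics > 0),
            transient_kinetics[["rise"]] < transient_kinetics[["decay"]],
            all(autofluor_gain >= 0), noise_sd >= 0)
  if (fs_raw < 10 * max(carriers)) {
    stop("fs_raw must be at least 10x the highest carrier frequency ",
         "(aliasing hazard)")
  }
  cfg <- list(session_duration = session_duration, fs_raw = fs_raw,
              carriers = carriers,
              transient_rate = rep_named(transient_rate, names(carriers)),
              transient_amplitude = rep_named(transient_amplitude,
                                              names(carriers)),
              transient_kinetics = transient_kinetics,
              bleach_poly_coeffs = bleach_poly_coeffs,
              autofluor_gain = rep_named(autofluor_gain, names(carriers)),
              noise_sd = noise_sd, seed = seed)
  structure(cfg, class = "synth_photometry_config")
}

rep_named <- function(x, nm) {
  if (length(x) == 1) x <- rep(x, length(nm))
  if (is.null(names(x))) names(x) <- nm
  x[nm]
}

# difference-of-exponentials kernel, unit peak
doe_kernel <- function(fs, rise, decay, support = 5 * decay) {
  tk <- seq(0, support, by = 1 / fs)
  k <- exp(-tk / decay) - exp(-tk / rise)
  k / max(k)
}

# transient train: sum of kernels at poisson event times
transient_train <- function(n, fs, times, amplitudes, rise, decay) {
  out <- numeric(n)
  if (length(times) == 0) return(out)
  kern <- doe_kernel(fs, rise, decay)
  lk <- length(kern)
  for (i in seq_along(times)) {
    i0 <- floor(times[i] * fs) + 1L
    idx <- i0:min(n, i0 + lk - 1L)
    out[idx] <- out[idx] + amplitudes[i] * kern[seq_along(idx)]
  }
  out
}

# smooth shared slow artifact: sum of slow random-phase sinusoids,
# SD ~ 1, shifted to stay strictly positive (it is a fluorescence, and
# amplitude demodulation cannot represent a negative envelope)
slow_artifact <- function(n, fs) {
  t <- (seq_len(n) - 1) / fs
  freqs <- stats::runif(6, 0.005, 0.05)
  phases <- stats::runif(6, 0, 2 * pi)
  amps <- 1 / sqrt(freqs)
  x <- numeric(n)
  for (j in seq_along(freqs)) {
    x <- x + amps[j] * sin(2 * pi * freqs[j] * t + phases[j])
  }
  x <- x / stats::sd(x)
  x - min(x) + 0.1
}

#' Generate a synthetic frequency-multiplexed photometry session
#'
#' Builds one emission-sensor trace per channel. Each sensor carries its
#' own noiseless envelope (bleach trend + calcium transient train +
#' autofluorescence coupling) on its matching carrier, plus the shared
#' autofluorescence artifact on the *other* carrier, emulating broadband
#' autofluorescence excited by both LEDs. Carrier waveform is the
#' non-negative offset sinusoid `(1 + sin(2 pi f t)) / 2`.
#'
#' @param config A [photometry_session_config()].
#' @return List with `recording` ([modulated_recording()]) and `truth`, a
#'   list holding per-channel `transient_times`, `transient_amplitudes`,
#'   `true_envelopes` (matrix at `fs_raw`), `bleach_trend` and
#'   `autofluor_trace`.
#' @export
gen_photometry_session <- function(config) {
  stopifnot(inherits(config, "synth_photometry_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$fs_raw
  n <- round(config$session_duration * fs)
  t <- (seq_len(n) - 1) / fs
  tn <- t / config$session_duration
  bleach <- numeric(n)
  for (j in seq_along(config$bleach_poly_coeffs)) {
    bleach <- bleach + config$bleach_poly_coeffs[j] * tn^(j - 1)
  }
  shared <- slow_artifact(n, fs)
  roles <- names(config$carriers)
  env <- matrix(0, n, length(roles), dimnames = list(NULL, roles))
  samples <- matrix(0, n, length(roles), dimnames = list(NULL, roles))
  ev_times <- stats::setNames(vector("list", length(roles)), roles)
  ev_amps <- ev_times
  for (role in roles) {
    rate <- config$transient_rate[[role]]
    n_ev <- if (rate > 0) stats::rpois(1, rate * config$session_duration) else 0L
    times <- sort(stats::runif(n_ev, 0, config$session_duration))
    amps <- rep(config$transient_amplitude[[role]], n_ev)
    ev_times[[role]] <- times
    ev_amps[[role]] <- amps
    train <- transient_train(n, fs, times, amps,
                             config$transient_kinetics[["rise"]],
                             config$transient_kinetics[["decay"]])
    env[, role] <- bleach + train + config$autofluor_gain[[role]] * shared
  }
  for (i in seq_along(roles)) {
    own <- roles[i]; other <- roles[-i][1]
    c_own <- (1 + sin(2 * pi * config$carriers[[own]] * t)) / 2
    c_other <- (1 + sin(2 * pi * config$carriers[[other]] * t)) / 2
    samples[, own] <- env[, own] * c_own +
      config$autofluor_gain[[own]] * shared * c_other
    if (config$noise_sd > 0) {
      samples[, own] <- samples[, own] + stats::rnorm(n, 0, config$noise_sd)
    }
  }
  rec <- modulated_recording(samples, fs,
                             data.frame(freq = unname(config$carriers),
                                        role = roles,
                                        stringsAsFactors = FALSE))
  truth <- list(transient_times = ev_times, transient_amplitudes = ev_amps,
                true_envelopes = env, bleach_trend = bleach,
                autofluor_trace = shared, config = config)
  list(recording = rec, truth = truth)
}

## ---- cell maps ---------------------------------------------------------

#' Configuration for synthetic straightened-axis cell maps
#'
#' The default is the package's documented stated world: two radially
#' separated Gaussian layers (deep at radial 0.15, superficial at 0.85 —
#' radial 0 is the alveus side) centred longitudinally near 0.7 of the
#' straightened CA3-to-subiculum field (the CA1/subiculum border), 500
#' cells, equal weights. The radial separation of 0.7 is ~8.75
#' within-layer SDs, comfortably past the >= 4 SD regime where BIC
#' reliably identifies two components. Default tracer rules: all cells
#' CTXB-positive; rabies-positive with probability 0.8 in the deep layer
#' and 0.2 in the superficial layer.
#'
#' @param n_cells Number of cells.
#' @param component_means List of `c(radial, longitudinal)` means in the
#'   normalised unit square; names give the layer labels.
#' @param component_sds List of per-axis SDs, same order.
#' @param component_weights Mixture weights; must sum to 1.
#' @param subset_rules Named list: tracer flag -> per-component labelling
#'   probability (same order as `component_means`).
#' @param n_slices Number of slice ids cells are spread over.
#' @param seed Integer RNG seed.
#' @return A `synth_cellmap_config` list.
#' @export
cellmap_config <- function(n_cells = 500,
                           component_means = list(deep = c(0.15, 0.7),
                                                  superficial = c(0.85, 0.7)),
                           component_sds = list(deep = c(0.08, 0.15),
                                                superficial = c(0.08, 0.15)),
                           component_weights = c(0.5, 0.5),
                           subset_rules = list(ctxb = c(1, 1),
                                               rabies = c(0.8, 0.2)),
                           n_slices = 1,
                           seed = NULL) {
  stopifnot(n_cells >= 0,
            length(component_means) == length(component_sds),
            length(component_means) == length(component_weights),
            n_slices >= 1)
  if (abs(sum(component_weights) - 1) > 1e-8) {
    stop("component_weights must sum to 1")
  }
  for (m in component_means) {
    stopifnot(length(m) == 2, all(m >= 0), all(m <= 1))
  }
  for (s in component_sds) stopifnot(length(s) == 2, all(s > 0))
  for (r in subset_rules) {
    stopifnot(length(r) == length(component_means), all(r >= 0), all(r <= 1))
  }
  structure(list(n_cells = n_cells, component_means = component_means,
                 component_sds = component_sds,
                 component_weights = component_weights,
                 subset_rules = subset_rules, n_slices = n_slices,
                 seed = seed),
            class = "synth_cellmap_config")
}

#' Generate a synthetic cell map with ground-truth layer labels
#'
#' Cells are drawn from the configured Gaussian mixture over
#' (radial, longitudinal) coordinates, clipped to the unit square; tracer
#' flags are Bernoulli draws per the component-conditional subset rules.
#'
#' @param config A [cellmap_config()].
#' @return List with `cellmap` (data frame: `slice`, `radial`,
#'   `longitudinal`, one logical column per tracer flag) and `truth`
#'   (per-cell `component` labels plus the config).
#' @export
gen_cellmap <- function(config) {
  stopifnot(inherits(config, "synth_cellmap_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_cells
  labels <- names(config$component_means)
  if (is.null(labels)) labels <- paste0("comp", seq_along(config$component_means))
  if (n == 0) {
    cm <- data.frame(slice = integer(0), radial = numeric(0),
                     longitudinal = numeric(0))
    for (fl in names(config$subset_rules)) cm[[fl]] <- logical(0)
    return(list(cellmap = cm,
                truth = list(component = character(0), config = config)))
  }
  comp <- sample.int(length(labels), n, replace = TRUE,
                     prob = config$component_weights)
  mu <- do.call(rbind, config$component_means)
  sd2 <- do.call(rbind, config$component_sds)
  radial <- stats::rnorm(n, mu[comp, 1], sd2[comp, 1])
  longitudinal <- stats::rnorm(n, mu[comp, 2], sd2[comp, 2])
  radial <- pmin(pmax(radial, 0), 1)
  longitudinal <- pmin(pmax(longitudinal, 0), 1)
  cm <- data.frame(slice = sample.int(config$n_slices, n, replace = TRUE),
                   radial = radial, longitudinal = longitudinal)
  for (fl in names(config$subset_rules)) {
    p <- config$subset_rules[[fl]][comp]
    cm[[fl]] <- stats::runif(n) < p
  }
  list(cellmap = cm,
       truth = list(component = labels[comp], config = config))
}

## ---- CRACM sweeps ------------------------------------------------------

#' Configuration for synthetic light-evoked synaptic sweeps
#'
#' Defaults match the optogenetic mapping protocol: light pulses of
#' 0.2, 0.5, 1, 2 and 5 ms, voltage clamp at -70 mV (EPSCs inward,
#' negative). Baseline noise is Gaussian; the evoked response is a
#' difference-of-exponentials at fixed latency after stimulus onset.
#'
#' @param n_sweeps Sweeps per pulse duration.
#' @param pulse_durations_ms Pulse-duration set, ms.
#' @param fs Sampling rate, Hz.
#' @param sweep_duration Sweep length, s.
#' @param onset Stimulus onset within the sweep, s.
#' @param connected Logical; if `FALSE` (or `amplitude == 0`) sweeps are
#'   baseline noise only.
#' @param amplitude Response peak magnitude (pA at -70/0 mV, mV in
#'   current clamp).
#' @param latency Response onset latency after the stimulus, s.
#' @param kinetics `c(rise, decay)` seconds of the response kernel.
#' @param noise_sd Gaussian noise SD per sample.
#' @param holding Holding potential, mV (-70: inward/negative response;
#'   0: outward/positive).
#' @param seed Integer RNG seed.
#' @return A `synth_cracm_config` list.
#' @export
cracm_config <- function(n_sweeps = 10,
                         pulse_durations_ms = c(0.2, 0.5, 1, 2, 5),
                         fs = 10000, sweep_duration = 0.5, onset = 0.1,
                         connected = TRUE, amplitude = 100,
                         latency = 0.005,
                         kinetics = c(rise = 0.002, decay = 0.015),
                         noise_sd = 5, holding = -70, seed = NULL) {
  stopifnot(n_sweeps >= 1, all(pulse_durations_ms > 0), fs > 0,
            sweep_duration > 0, noise_sd >= 0, all(kinetics > 0),
            amplitude >= 0, latency >= 0)
  if (onset <= 0 || onset >= sweep_duration) {
    stop("pulse onset must lie inside the sweep window")
  }
  structure(list(n_sweeps = n_sweeps,
                 pulse_durations_ms = pulse_durations_ms, fs = fs,
                 sweep_duration = sweep_duration, onset = onset,
                 connected = connected, amplitude = amplitude,
                 latency = latency, kinetics = kinetics,
                 noise_sd = noise_sd, holding = holding, seed = seed),
            class = "synth_cracm_config")
}

#' Generate synthetic CRACM sweeps with connectivity ground truth
#'
#' @param config A [cracm_config()].
#' @return List with `sweepset` (a [sweep_set()] pooling all pulse
#'   durations, `sweep_info$duration_ms` identifying each sweep) and
#'   `truth` (`connected`, signed `amplitude`, `latency`, config).
#' @export
gen_cracm_sweeps <- function(config) {
  stopifnot(inherits(config, "synth_cracm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$fs
  n_samp <- round(config$sweep_duration * fs)
  connected <- isTRUE(config$connected) && config$amplitude > 0
  sign <- if (config$holding == -70) -1 else 1
  amp <- if (connected) sign * config$amplitude else 0
  resp <- numeric(n_samp)
  if (connected) {
    kern <- doe_kernel(fs, config$kinetics[["rise"]], config$kinetics[["decay"]])
    i0 <- round((config$onset + config$latency) * fs) + 1L
    if (i0 > n_samp) stop("response onset outside sweep window")
    idx <- i0:min(n_samp, i0 + length(kern) - 1L)
    resp[idx] <- amp * kern[seq_along(idx)]
  }
  durs <- rep(config$pulse_durations_ms, each = config$n_sweeps)
  sweeps <- matrix(stats::rnorm(length(durs) * n_samp, 0, config$noise_sd),
                   nrow = length(durs), ncol = n_samp)
  sweeps <- sweeps + matrix(resp, nrow = length(durs), ncol = n_samp,
                            byrow = TRUE)
  ss <- sweep_set(sweeps, fs = fs, onset = config$onset,
                  holding = config$holding,
                  sweep_info = data.frame(duration_ms = durs))
  truth <- list(connected = connected, amplitude = amp,
                latency = config$latency, config = config)
  list(sweepset = ss, truth = truth)
}

## ---- EPM tracks --------------------------------------------------------

#' Configuration for synthetic elevated-plus-maze sessions
#'
#' The default session is 9 min at 25 frames/s, the zone walk is a
#' discrete-time Markov chain over \{centre, open1, open2, closed1,
#' closed2\} (self-transitions set the dwell times), and positions are
#' rendered as an out-and-back excursion along each visited arm with
#' 1 cm Gaussian jitter.
#'
#' @param duration Session length, s (default 540 = 9 min).
#' @param frame_rate Frames per second.
#' @param geometry An [epm_geometry()].
#' @param transition 5x5 row-stochastic matrix over states
#'   `centre, open1, open2, closed1, closed2` at frame resolution; see
#'   [epm_transition_matrix()].
#' @param jitter_sd Positional jitter SD, cm.
#' @param start_state Initial state (default `"closed1"`).
#' @param seed Integer RNG seed.
#' @return A `synth_epm_config` list.
#' @export
epm_config <- function(duration = 540, frame_rate = 25,
                       geometry = epm_geometry(),
                       transition = epm_transition_matrix(),
                       jitter_sd = 1, start_state = "closed1",
                       seed = NULL) {
  stopifnot(duration > 0, frame_rate > 0, jitter_sd >= 0)
  validate_transition_matrix(transition)
  stopifnot(start_state %in% rownames(transition))
  structure(list(duration = duration, frame_rate = frame_rate,
                 geometry = geometry, transition = transition,
                 jitter_sd = jitter_sd, start_state = start_state,
                 seed = seed),
            class = "synth_epm_config")
}

epm_states <- c("centre", "open1", "open2", "closed1", "closed2")

#' Build the frame-level EPM zone transition matrix
#'
#' Arms connect only through the centre. `p_leave_centre` and
#' `p_leave_arm` are per-frame exit probabilities (geometric dwell
#' times); `p_open` is the probability that a centre exit goes to an open
#' arm (split evenly between the two arms of each class).
#'
#' @param p_leave_centre Per-frame probability of leaving the centre.
#' @param p_leave_arm Per-frame probability of leaving an arm.
#' @param p_open P(open | leaving centre).
#' @return 5x5 row-stochastic matrix with dimnames `epm_states`.
#' @export
epm_transition_matrix <- function(p_leave_centre = 0.02,
                                  p_leave_arm = 0.004,
                                  p_open = 0.3) {
  stopifnot(p_leave_centre >= 0, p_leave_centre <= 1,
            p_leave_arm >= 0, p_leave_arm <= 1, p_open >= 0, p_open <= 1)
  P <- matrix(0, 5, 5, dimnames = list(epm_states, epm_states))
  P["centre", ] <- c(1 - p_leave_centre,
                     p_leave_centre * p_open / 2,
                     p_leave_centre * p_open / 2,
                     p_leave_centre * (1 - p_open) / 2,
                     p_leave_centre * (1 - p_open) / 2)
  for (arm in epm_states[-1]) {
    P[arm, arm] <- 1 - p_leave_arm
    P[arm, "centre"] <- p_leave_arm
  }
  P
}

validate_transition_matrix <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == 5, ncol(P) == 5, all(P >= 0))
  if (any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("transition matrix rows must sum to 1")
  }
  if (is.null(rownames(P))) dimnames(P) <- list(epm_states, epm_states)
  invisible(P)
}

#' Stationary distribution of a zone transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1,
#' normalised to sum to 1.
#'
#' @param P Row-stochastic matrix.
#' @return Named probability vector.
#' @export
markov_stationary <- function(P) {
  validate_transition_matrix(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(P))
}

#' Generate a synthetic EPM session
#'
#' Simulates the zone-level Markov walk, renders head positions inside
#' the zone polygons (arm visits run out toward the arm end and back),
#' and emits ground-truth zone series plus entry / arm-end events.
#'
#' @param config An [epm_config()].
#' @return List with `track` (data frame `t`, `x`, `y`), `events`
#'   (ground-truth [event_table()]) and `truth` (zone series, state
#'   series, transition matrix, config).
#' @export
gen_epm_track <- function(config) {
  stopifnot(inherits(config, "synth_epm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- round(config$duration * config$frame_rate)
  P <- config$transition
  states <- integer(n)
  states[1] <- match(config$start_state, epm_states)
  u <- stats::runif(n)
  cumP <- t(apply(P, 1, cumsum))
  for (i in 2:n) {
    states[i] <- findInterval(u[i], cumP[states[i - 1], ]) + 1L
  }
  state_names <- epm_states[states]
  t <- (seq_len(n) - 1) / config$frame_rate
  xy <- render_epm_positions(state_names, config$geometry, config$jitter_sd)
  track <- data.frame(t = t, x = xy$x, y = xy$y)
  zone <- zone_class_of_state(state_names)
  # ground-truth entries: first frame of each maximal arm run
  runs <- rle(state_names)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev_t <- c(); ev_type <- c()
  for (r in seq_along(runs$values)) {
    st <- runs$values[r]
    if (st == "centre") next
    cls <- if (startsWith(st, "open")) "open_entry" else "closed_entry"
    ev_t <- c(ev_t, t[starts[r]])
    ev_type <- c(ev_type, cls)
    far <- starts[r] + xy$far_offset[r]
    if (!is.na(far)) {
      ev_t <- c(ev_t, t[far]); ev_type <- c(ev_type, "arm_end_reached")
    }
  }
  events <- if (length(ev_t)) event_table(ev_t, ev_type) else
    event_table(numeric(0), character(0))
  truth <- list(zone = zone, state = state_names, transition = P,
                config = config)
  list(track = track, events = events, truth = truth)
}

zone_class_of_state <- function(state) {
  out <- state
  out[startsWith(state, "open")] <- "open"
  out[startsWith(state, "closed")] <- "closed"
  out
}

# positions: centre jitters around the centre; arm visits move smoothly
# out to a random fraction of the arm and back (sine bump), giving a
# well-defined farthest point per visit
render_epm_positions <- function(state_names, geom, jitter_sd) {
  n <- length(state_names)
  x <- numeric(n); y <- numeric(n)
  runs <- rle(state_names)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  far_offset <- rep(NA_integer_, length(runs$values))
  half <- geom$arm_width / 2
  margin <- min(half - 0.5, half * 0.8)
  for (r in seq_along(runs$values)) {
    idx <- starts[r]:ends[r]
    L <- length(idx)
    st <- runs$values[r]
    if (st == "centre") {
      x[idx] <- stats::rnorm(L, 0, jitter_sd)
      y[idx] <- stats::rnorm(L, 0, jitter_sd)
      x[idx] <- pmin(pmax(x[idx], -margin), margin)
      y[idx] <- pmin(pmax(y[idx], -margin), margin)
    } else {
      dir <- geom$arm_directions[[st]]
      s_max <- stats::runif(1, 0.6, 0.95) * geom$arm_length
      prog <- geom$centre_half + s_max * sin(pi * (seq_len(L) - 0.5) / L)
      lat <- stats::rnorm(L, 0, jitter_sd)
      lat <- pmin(pmax(lat, -margin), margin)
      x[idx] <- dir[1] * prog + abs(dir[2]) * lat
      y[idx] <- dir[2] * prog + abs(dir[1]) * lat
      far_offset[r] <- which.max(prog) - 1L
    }
  }
  list(x = x, y = y, far_offset = far_offset)
}

## ---- event-locked pattern sessions ------------------------------------

#' Generate 50 Hz layer-activity traces with a programmed peri-event pattern
#'
#' Emulates the qualitative two-layer pattern around maze-arm entries at
#' the post-demodulation stage: superficial activity rises after open-arm
#' entry; deep activity rises just before entries, falls after open-arm
#' entry and stays elevated after closed-arm entry. Used to test that the
#' peri-event statistics recover a programmed sign pattern; it does not
#' model carriers, bleaching or autofluorescence (those are covered by
#' [gen_photometry_session()]).
#'
#' @param events An [event_table()] with `open_entry` / `closed_entry`
#'   rows, or `NULL` to lay out alternating entries automatically.
#' @param duration Session length, s.
#' @param fs Sampling rate, Hz (default 50).
#' @param amplitude Peak amplitude of each programmed bump.
#' @param noise_sd Additive white-noise SD.
#' @param seed Integer RNG seed.
#' @return List with `sup` and `deep` (50 Hz [conditioned_trace()]s,
#'   stage `"downsampled"`), `events`, and `truth` describing the
#'   programmed window signs.
#' @export
gen_pattern_session <- function(events = NULL, duration = 540, fs = 50,
                                amplitude = 1, noise_sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(events)) {
    times <- seq(30, duration - 30, by = 30)
    types <- rep(c("open_entry", "closed_entry"), length.out = length(times))
    events <- event_table(times, types)
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  bump <- function(centre_t, centre_lag, width) {
    exp(-((t - centre_t - centre_lag)^2) / (2 * width^2))
  }
  sup <- numeric(n); deep <- numeric(n)
  for (i in seq_len(nrow(events))) {
    t0 <- events$time[i]
    if (events$type[i] == "open_entry") {
      sup <- sup + amplitude * bump(t0, 3, 1)        # post rise
      deep <- deep + amplitude * bump(t0, -1, 0.8)   # pre rise
      deep <- deep - amplitude * bump(t0, 3, 1)      # post suppression
    } else if (events$type[i] == "closed_entry") {
      deep <- deep + amplitude * bump(t0, -1, 0.8)   # pre rise
      deep <- deep + amplitude * bump(t0, 2, 1.5)    # sustained post rise
    }
  }
  if (noise_sd > 0) {
    sup <- sup + stats::rnorm(n, 0, noise_sd)
    deep <- deep + stats::rnorm(n, 0, noise_sd)
  }
  list(sup = conditioned_trace(sup, fs, channel = "red",
                               stage = "downsampled"),
       deep = conditioned_trace(deep, fs, channel = "green",
                                stage = "downsampled"),
       events = events,
       truth = list(amplitude = amplitude, noise_sd = noise_sd))
}
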