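# Synthetic electrophysiology fixtures built in code (no binary data).

# passive RC membrane response to a current step: V = V0 + dV*(1-exp(-t/tau))
make_rc_trace <- function(fs = 10000, pre = 0.1, step = 0.5, post = 0.1,
                          v_rest = -70, dv = -10, tau = 0.015,
                          noise_sd = 0) {
  n_pre <- round(pre * fs); n_step <- round(step * fs)
  n_post <- round(post * fs)
  t_step <- (seq_len(n_step) - 1) / fs
  v <- c(rep(v_rest, n_pre),
         v_rest + dv * (1 - exp(-t_step / tau)),
         rep(v_rest, n_post))
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  v
}

# injects triangular action potentials of known geometry at given times
make_spike_trace <- function(fs = 10000, duration = 0.7, spike_times,
                             v_rest = -70, v_thresh = -45, v_peak = 40,
                             rise_ms = 0.4, fall_ms = 0.6) {
  n <- round(duration * fs)
  v <- rep(v_rest, n)
  n_up <- max(2L, round(rise_ms / 1000 * fs))
  n_down <- max(2L, round(fall_ms / 1000 * fs))
  up <- seq(v_thresh, v_peak, length.out = n_up)
  down <- seq(v_peak, v_rest, length.out = n_down)[-1]
  shape <- c(up, down)
  for (ts in spike_times) {
    i0 <- round(ts * fs)
    idx <- i0:min(n, i0 + length(shape) - 1L)
    v[idx] <- shape[seq_along(idx)]
  }
  v
}

# current-step sweep_set for intrinsic_features tests
make_step_sweepset <- function(fs = 10000, currents = c(-160, -40, 80, 160),
                               tau = 0.015, r_m = 0.1, sag_frac = 0,
                               n_spikes_per_pa = 0.05, seed = 1) {
  set.seed(seed)
  onset <- 0.1; step <- 0.5; total <- 0.7
  sweeps <- matrix(NA_real_, length(currents), round(total * fs))
  for (i in seq_along(currents)) {
    cur <- currents[i]
    if (cur <= 0) {
      v <- make_rc_trace(fs, onset, step, total - onset - step,
                         dv = cur * r_m, tau = tau)
      if (sag_frac > 0 && cur <= -160) {
        # add a slow rebound toward baseline after the early minimum
        n_pre <- round(onset * fs); n_step <- round(step * fs)
        t_step <- (seq_len(n_step) - 1) / fs
        reb <- -cur * r_m * sag_frac * (1 - exp(-t_step / 0.1))
        v[n_pre + seq_len(n_step)] <- v[n_pre + seq_len(n_step)] + reb
      }
    } else {
      n_sp <- round(cur * n_spikes_per_pa)
      times <- if (n_sp > 0) onset + 0.02 + (seq_len(n_sp) - 1) * 0.03 else numeric(0)
      v <- make_spike_trace(fs, total, times)
    }
    sweeps[i, ] <- v
  }
  sweep_set(sweeps, fs = fs, onset = onset, holding = NA_real_,
            sweep_info = data.frame(current_pa = currents))
}

# tiny noiseless photometry session used across photometry tests
make_clean_session <- function(duration = 40, seed = 11, gain = 0,
                               noise_sd = 0, rate = 0.15) {
  gen_photometry_session(photometry_session_config(
    session_duration = duration, fs_raw = 10000,
    transient_rate = rate, noise_sd = noise_sd,
    autofluor_gain = gain, seed = seed))
}

# zone series from a scripted state sequence (seconds per state)
make_scripted_zones <- function(script, frame_rate = 25) {
  state <- unlist(lapply(script, function(s) rep(s[[1]], s[[2]] * frame_rate)))
  t <- (seq_along(state) - 1) / frame_rate
  data.frame(t = t, zone = dualpath:::zone_class_of_state(state),
             zone_detail = state, stringsAsFactors = FALSE)
}
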