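# Lock-in demodulation, autofluorescence extraction, downsampling,
# detrending, regression and z-scoring — checked against generator
# ground truth and closed-form oracles.

settle_idx <- function(n, fs, settle = 0.5) {
  k <- round(settle * fs)
  (k + 1):(n - k)
}

test_that("demodulation recovers a constant envelope and is phase invariant", {
  fs <- 10000; t <- (0:(10 * fs - 1)) / fs
  carriers <- data.frame(freq = 210, role = "green")
  for (phase in c(0, pi / 3)) {
    x <- (1 + sin(2 * pi * 210 * t + phase)) / 2
    rec <- modulated_recording(matrix(x), fs, carriers)
    tr <- demodulate(rec, "green", sensor = 1)
    idx <- settle_idx(length(tr$values), fs)
    expect_lt(max(abs(tr$values[idx] - 1)), 1e-3)
    if (phase == 0) base <- tr$values else {
      expect_lt(max(abs(tr$values[idx] - base[idx])), 1e-6)
    }
  }
})

test_that("two-carrier sessions demodulate with low error and low crosstalk", {
  g <- make_clean_session(duration = 40, seed = 21)
  fs <- g$recording$fs_raw
  for (role in c("green", "red")) {
    tr <- demodulate(g$recording, role)
    idx <- settle_idx(length(tr$values), fs)
    truth <- g$truth$true_envelopes[idx, role]
    rel_rmse <- sqrt(mean((tr$values[idx] - truth)^2)) /
      sqrt(mean(truth^2))
    expect_lt(rel_rmse, 0.01)
    # transients of the *other* channel must not leak in
    other <- setdiff(c("green", "red"), role)
    other_train <- g$truth$true_envelopes[idx, other] -
      g$truth$bleach_trend[idx]
    if (sd(other_train) > 0) {
      expect_lt(abs(cor(tr$values[idx] - truth, other_train)), 0.05)
    }
  }
})

test_that("demodulation rejects aliasing and crosstalk hazards", {
  fs <- 10000
  x <- sin(2 * pi * 210 * (0:9999) / fs)
  rec <- modulated_recording(matrix(x), fs,
                             data.frame(freq = 210, role = "green"))
  expect_error(demodulate(rec, 6000), "twice the carrier")
  rec2 <- suppressWarnings(modulated_recording(
    cbind(x, x), fs, data.frame(freq = c(210, 240),
                                role = c("green", "red"))))
  expect_error(demodulate(rec2, "green"), "crosstalk")
})

test_that("autofluorescence extraction isolates the shared artifact", {
  g0 <- make_clean_session(duration = 20, seed = 31, gain = 0, rate = 0)
  af0 <- extract_autofluorescence(g0$recording, "green")
  idx <- settle_idx(length(af0$values), g0$recording$fs_raw)
  expect_lt(max(abs(af0$values[idx])), 1e-3)  # scale: envelopes ~ 1
  expect_equal(af0$channel, "autofluorescence")

  g <- make_clean_session(duration = 40, seed = 32, gain = 0.5, rate = 0)
  af <- extract_autofluorescence(g$recording, "green")
  idx <- settle_idx(length(af$values), g$recording$fs_raw)
  expect_gt(cor(af$values[idx], g$truth$autofluor_trace[idx]), 0.95)
  expect_error(extract_autofluorescence(g$recording, "green", "green"),
               "distinct")
})

test_that("downsample keeps length arithmetic, constants and amplitudes", {
  fs <- 1000
  tr <- conditioned_trace(rep(2.5, 600 * fs), fs, "green", "demodulated")
  dn <- downsample(tr, 50)
  expect_equal(length(dn$values), 30000)
  expect_lt(max(abs(dn$values - 2.5)), 1e-3)  # IIR round-off only

  t <- (0:(60 * fs - 1)) / fs
  tr2 <- conditioned_trace(sin(2 * pi * 0.2 * t), fs, "green",
                           "demodulated")
  dn2 <- downsample(tr2, 50)
  idx <- settle_idx(length(dn2$values), 50, 2)
  # closed form: a pure 0.2 Hz sinusoid keeps amplitude 1
  expect_equal(max(abs(dn2$values[idx])), 1, tolerance = 0.01)
  expect_error(downsample(tr2, 2000), "exceed")
})

test_that("polynomial detrending removes exactly-cubic trends", {
  fs <- 50; n <- 2000
  tt <- seq_len(n) / fs
  cubic <- 2 + 0.5 * tt - 0.01 * tt^2 + 0.001 * tt^3
  tr <- conditioned_trace(cubic, fs, "green", "downsampled")
  out <- detrend_poly(tr, 3)
  expect_lt(max(abs(out$values)), 1e-8 * max(abs(cubic)))
  expect_equal(out$stage, "detrended")

  const <- detrend_poly(conditioned_trace(rep(4, 100), fs, "green",
                                          "downsampled"), 3)
  expect_lt(max(abs(const$values)), 1e-10)
})

test_that("detrending preserves sparse transient amplitudes", {
  fs <- 50; n <- 30000  # 600 s, transients well under 5% duty
  tt <- seq_len(n) / fs
  tn <- tt / max(tt)
  bleach <- 1 - 0.3 * tn + 0.05 * tn^2 - 0.02 * tn^3
  kern <- exp(-(0:99) / 25) - exp(-(0:99) / 2.5)
  kern <- kern / max(kern)
  x <- bleach
  peaks <- seq(2000, 28000, by = 3000)
  for (p in peaks) x[p:(p + 99)] <- x[p:(p + 99)] + kern
  out <- detrend_poly(conditioned_trace(x, fs, "green", "downsampled"), 3)
  # transient height above local baseline preserved within 5%
  for (p in peaks) {
    h <- max(out$values[p:(p + 99)]) - out$values[p - 10]
    expect_lt(abs(h - 1), 0.05)
  }
})

test_that("autofluorescence regression matches the OLS closed form", {
  fs <- 50
  set.seed(2)
  af <- conditioned_trace(rnorm(500), fs, "autofluorescence", "detrended")
  sig_v <- 2 * af$values + 3 + rnorm(500, 0, 0.01)
  sig <- conditioned_trace(sig_v, fs, "green", "detrended")
  fit <- fit_autofluorescence(sig, af)
  # normal-equations oracle
  X <- cbind(1, af$values)
  beta <- solve(t(X) %*% X, t(X) %*% sig_v)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-9)
  expect_equal(fit$slope, beta[2], tolerance = 1e-9)

  ident <- fit_autofluorescence(af, af)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)

  flat <- conditioned_trace(rep(1, 500), fs, "autofluorescence",
                            "detrended")
  deg <- fit_autofluorescence(sig, flat)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$slope))
  expect_equal(deg$fitted$values, rep(mean(sig_v), 500))

  # orthogonal regressor -> slope 0
  x <- rep(c(-1, 1), 250)
  y <- rep(c(1, 1), 250) + rep(c(-1, 1), each = 250) * 0
  orth <- fit_autofluorescence(
    conditioned_trace(y, fs, "green", "detrended"),
    conditioned_trace(x, fs, "autofluorescence", "detrended"))
  expect_equal(orth$slope, 0, tolerance = 1e-12)
})

test_that("z-scoring is exact and rejects degenerate residuals", {
  set.seed(3)
  tr <- conditioned_trace(rnorm(1000, 5, 2), 50, "green", "detrended")
  z <- zscore_corrected(tr)
  expect_lt(abs(mean(z$values)), 1e-9)
  expect_lt(abs(sd(z$values) - 1), 1e-9)
  expect_equal(z$units, "z")
  expect_error(zscore_corrected(
    conditioned_trace(rep(1, 100), 50, "green", "detrended")),
    "zero variance")

  # boxcar oracle: transient z-height = h / sd(d) by direct arithmetic
  d <- rep(0, 1000); d[500:549] <- 2
  s <- sqrt(sum((d - mean(d))^2) / 999)
  z2 <- zscore_corrected(conditioned_trace(d, 50, "green", "detrended"))
  expect_equal(max(z2$values) - min(z2$values), 2 / s, tolerance = 1e-12)
})

test_that("process_session recovers transient trains and ignores bleaching", {
  g <- make_clean_session(duration = 60, seed = 41, gain = 0.2,
                          rate = 0.2)
  out <- process_session(g$recording)
  expect_equal(attr(out$green, "layer"), "deep")
  expect_equal(attr(out$red, "layer"), "superficial")
  fs_raw <- g$recording$fs_raw
  for (role in c("green", "red")) {
    z <- out[[role]]
    # ground-truth transient train resampled to the processed grid
    train <- g$truth$true_envelopes[, role] - g$truth$bleach_trend -
      g$truth$config$autofluor_gain[[role]] * g$truth$autofluor_trace
    idx_raw <- round((trace_times(z) - g$recording$start_time) * fs_raw) + 1
    expect_gt(cor(z$values, train[idx_raw]), 0.95)
  }

  # identical sessions up to bleach coefficients give near-identical output
  mk <- function(coeffs) {
    gen_photometry_session(photometry_session_config(
      session_duration = 60, fs_raw = 10000, transient_rate = 0.2,
      noise_sd = 0, autofluor_gain = 0, bleach_poly_coeffs = coeffs,
      seed = 77))
  }
  za <- process_session(mk(c(1, -0.2, 0.05, 0))$recording)
  zb <- process_session(mk(c(1.2, -0.5, 0.1, -0.05))$recording)
  rmse <- sqrt(mean((za$green$values - zb$green$values)^2)) /
    sqrt(mean(za$green$values^2))
  expect_lt(rmse, 0.02)
})

test_that("process_session is deterministic and validates carriers", {
  g <- make_clean_session(duration = 20, seed = 51)
  a <- process_session(g$recording)
  b <- process_session(g$recording)
  expect_identical(a$green$values, b$green$values)
  rec1 <- modulated_recording(matrix(sin(2 * pi * 210 * (0:9999) / 1e4)),
                              1e4, data.frame(freq = 210, role = "green"))
  expect_error(process_session(rec1), "two carriers")
})

test_that("pipeline is linear in transient amplitude at fixed nuisance", {
  # identical noise realization, doubled transient amplitudes ->
  # baseline-subtracted peri-event responses double within 2%
  # (z-scoring cancels only through SD, so compare detrended traces)
  fs <- 50
  set.seed(7)
  noise <- rnorm(30000, 0, 0.05)
  times <- seq(30, 570, by = 30)
  ev <- event_table(times, rep("open_entry", length(times)))
  resp_of <- function(amp) {
    pat <- gen_pattern_session(events = ev, duration = 600, fs = fs,
                               amplitude = amp, noise_sd = 0, seed = 1)
    tr <- conditioned_trace(pat$sup$values + noise, fs, "red",
                            "downsampled")
    tens <- baseline_subtract(extract_epochs(detrend_poly(tr, 3), ev),
                              c(-6, -4))
    mean(window_stats(tens, window_spec(), "open_entry")$per_event$post)
  }
  r1 <- resp_of(1)
  r2 <- resp_of(2)
  expect_lt(abs(r2 / r1 - 2), 0.02)
})
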