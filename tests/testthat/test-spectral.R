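test_that("band edges validate and the canonical bands are as defined", {
  bands <- frequency_bands()
  expect_equal(bands$theta$low_hz, 4)
  expect_equal(bands$theta$high_hz, 8)
  expect_equal(bands$gamma_high$high_hz, 100)
  expect_error(band_spec("bad", 10, 5), "low < high")
})

test_that("bandpass keeps in-band energy and rejects out-of-band energy", {
  rec6 <- sine_recording(c(6, 6), samplerate = 250)
  theta <- bandpass(rec6, frequency_bands()$theta)
  expect_gte(rms(theta$sessions[[1]]$voltages[, 1]) /
               rms(rec6$sessions[[1]]$voltages[, 1]), 0.9)
  gh <- bandpass(rec6, frequency_bands()$gamma_high)
  expect_lte(rms(gh$sessions[[1]]$voltages[, 1]) /
               rms(rec6$sessions[[1]]$voltages[, 1]), 0.05)

  zero <- recording("z", session_data(matrix(0, 500, 1) + 0, 250),
                    data.frame(electrode_id = "a", x = 0, y = 0, z = 0))
  expect_equal(max(abs(bandpass(zero,
                                frequency_bands()$theta)$sessions[[1]]$voltages)),
               0)
  expect_error(bandpass(sine_recording(5, samplerate = 150),
                        frequency_bands()$gamma_high), "Nyquist")
})

test_that("wavelet spectra peak at the right frequency and scale with amplitude", {
  cfg <- power_spectrum_config()
  rec <- sine_recording(10, samplerate = 250, seconds = 8)
  spec <- wavelet_power(rec, cfg)
  peak_f <- cfg$freqs[which.max(spec[, 1])]
  expect_equal(peak_f, cfg$freqs[which.min(abs(cfg$freqs - 10))])

  rec2 <- recording("x2", session_data(2 * rec$sessions[[1]]$voltages, 250),
                    rec$electrodes)
  spec2 <- wavelet_power(rec2, cfg)
  expect_equal(spec2 - spec, array(log(4), dim(spec)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("white noise has a flat wavelet spectrum", {
  cfg <- power_spectrum_config()
  devs <- vapply(1:3, function(seed) {
    rec <- noise_recording(n_elec = 1, t_len = 10000, samplerate = 250,
                           seed = seed)
    spec <- wavelet_power(rec, cfg)[, 1]
    max(abs(spec - mean(spec)))
  }, 0)
  expect_lt(mean(devs), 0.5) # log units; sampling noise dominates at 2 Hz
})

test_that("broadband power shifts by exactly log(a^2) under scaling", {
  set.seed(14)
  rec <- noise_recording(n_elec = 2, t_len = 4000, samplerate = 250, seed = 14)
  bb1 <- broadband_power(rec)
  rec3 <- recording("x3", session_data(3 * rec$sessions[[1]]$voltages, 250),
                    rec$electrodes)
  bb3 <- broadband_power(rec3)
  diffs <- bb3$sessions[[1]]$voltages - bb1$sessions[[1]]$voltages
  expect_equal(max(abs(diffs - log(9))), 0, tolerance = 1e-8)
  # BB output is a valid recording at the window rate
  expect_s3_class(bb1, "bg_recording")
  expect_equal(samplerate(bb1), 1)
  expect_equal(nrow(bb1$sessions[[1]]$voltages), 4000 %/% 250)
})

test_that("broadband height recovers the analytic log-log line of 1/f noise", {
  # white noise of unit variance: expected wavelet power 1 at every analysis
  # frequency (L2-normalized filters), so the analytic line is flat at 0.
  # Shaping the spectrum by f^(-1/2) makes the expected log power
  # -log(f) + log E[(f/g)^-1 | filter at g] = -log(g) + log(1 + 2/(2*16))
  # to second order (Gaussian filter of relative width 1/4), i.e. a line of
  # slope -1 with a known constant.
  cfg <- power_spectrum_config()
  sr <- 250
  t_len <- 30000
  gamma <- 1
  set.seed(15)
  x <- rnorm(t_len)
  fgrid <- (seq_len(t_len) - 1) / t_len * sr
  fgrid <- pmin(fgrid, sr - fgrid)
  gain <- ifelse(fgrid > 0, fgrid^(-gamma / 2), 0)
  shaped <- Re(fft(fft(x) * gain, inverse = TRUE)) / t_len
  rec <- recording("pink", session_data(cbind(shaped), sr),
                   data.frame(electrode_id = "a", x = 0, y = 0, z = 0))
  bb <- broadband_power(rec, cfg, window = t_len %/% 2)
  analytic <- -gamma * mean(log(cfg$freqs)) + log(1 + gamma * (gamma + 1) / 32)
  expect_equal(mean(bb$sessions[[1]]$voltages), analytic, tolerance = 0.2)
})

test_that("robust broadband resists a narrowband contaminant better than OLS", {
  set.seed(16)
  sr <- 250
  t_len <- 4000
  x <- rnorm(t_len)
  spike <- 4 * sin(2 * pi * 10 * seq(0, by = 1 / sr, length.out = t_len))
  mk <- function(v) recording("r", session_data(cbind(v), sr),
                              data.frame(electrode_id = "a", x = 0, y = 0,
                                         z = 0))
  win <- t_len
  # single-window BB via each estimator, with and without the contaminant
  bb <- function(v, method) {
    r <- broadband_power(mk(c(v, v)), window = win, method = method)
    r$sessions[[1]]$voltages[1, 1]
  }
  shift_robust <- abs(bb(x + spike, "robust") - bb(x, "robust"))
  shift_ols <- abs(bb(x + spike, "ols") - bb(x, "ols"))
  expect_lt(shift_robust, shift_ols)
})

test_that("Hilbert band power tracks the analytic envelope", {
  sr <- 250
  tt <- seq(0, 8 - 1 / sr, by = 1 / sr)
  mk <- function(v) recording("h", session_data(cbind(v), sr),
                              data.frame(electrode_id = "a", x = 0, y = 0,
                                         z = 0))
  theta <- frequency_bands()$theta
  core <- 500:1500 # away from filter edges

  inband <- hilbert_band_power(mk(sin(2 * pi * 6 * tt)), theta)
  expect_equal(mean(inband$sessions[[1]]$voltages[core, 1]), 1,
               tolerance = 0.05)
  outband <- hilbert_band_power(mk(sin(2 * pi * 40 * tt)), theta)
  expect_lt(mean(outband$sessions[[1]]$voltages[core, 1]), 0.01)

  modulator <- 1 + 0.5 * sin(2 * pi * 0.25 * tt)
  am <- hilbert_band_power(mk(modulator * sin(2 * pi * 6 * tt)), theta)
  env <- sqrt(am$sessions[[1]]$voltages[core, 1])
  expect_gt(cor(env, modulator[core]), 0.95)
})

test_that("spectral derivatives feed the correlation model unchanged", {
  gt <- make_ground_truth(n_locations = 10, seed = 17)
  ds <- simulate_dataset(gt, sim_spec(n_patients = 2,
                                      electrodes_per_patient = 4,
                                      n_timepoints = 2000, seed = 17))
  theta_recs <- lapply(ds$recordings, bandpass, band = frequency_bands()$theta)
  for (r in theta_recs) {
    expect_s3_class(r, "bg_recording")
    expect_equal(dim(r$sessions[[1]]$voltages),
                 dim(ds$recordings[[1]]$sessions[[1]]$voltages))
  }
  k <- materialize(build_model(lapply(theta_recs, zscore_sessions)))
  expect_true(all(is.finite(k$matrix)))
})
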