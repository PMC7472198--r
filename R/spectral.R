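#' Canonical frequency band definitions
#'
#' The six named bands: delta 2--4, theta 4--8, alpha 8--12, beta 12--30,
#' low gamma 30--60 and high gamma 60--100 Hz.
#'
#' @return Named list of `bg_band` specs.
#' @export
frequency_bands <- function() {
  defs <- list(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 12),
               beta = c(12, 30), gamma_low = c(30, 60), gamma_high = c(60, 100))
  lapply(stats::setNames(names(defs), names(defs)), function(nm)
    band_spec(nm, defs[[nm]][1], defs[[nm]][2]))
}

#' Construct a frequency band
#'
#' @param name Band label (one of the canonical names, or free text for a
#'   custom band).
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high`.
#' @return A `bg_band`.
#' @export
band_spec <- function(name, low_hz, high_hz) {
  if (!(is.numeric(low_hz) && is.numeric(high_hz) && low_hz > 0 &&
        high_hz > low_hz))
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  structure(list(name = as.character(name), low_hz = low_hz,
                 high_hz = high_hz), class = "bg_band")
}

#' Band-pass filter a recording
#'
#' Second-order Butterworth band pass applied forward-backward (zero
#' phase), per session and electrode. The output keeps
#' the (timepoints x electrodes) shape and is itself a valid recording, so
#' band-limited traces can feed the correlation model and reconstruction
#' unchanged.
#'
#' @param rec A `bg_recording`.
#' @param band A `bg_band` (upper edge must be below Nyquist).
#' @param order Butterworth order (default 2).
#' @return A filtered `bg_recording`.
#' @export
bandpass <- function(rec, band, order = 2) {
  stopifnot(inherits(band, "bg_band"))
  sr <- samplerate(rec)
  if (sr <= 2 * band$high_hz)
    stop(sprintf("band '%s' (%g-%g Hz) is above Nyquist at %g Hz samplerate",
                 band$name, band$low_hz, band$high_hz, sr), call. = FALSE)
  filt <- signal::butter(order, c(band$low_hz, band$high_hz) / (sr / 2),
                         type = "pass")
  map_sessions(rec, function(v, srate)
    apply(v, 2L, function(x) zero_phase_filter(filt, x, srate)))
}

#' Power-spectrum configuration
#'
#' Fifty log-spaced analysis frequencies from 2 to 100 Hz (endpoints
#' inclusive), estimated with a Morlet wavelet of order (wavenumber) 4.
#'
#' @param n_freqs Number of analysis frequencies.
#' @param f_min,f_max Frequency range in Hz.
#' @param wavelet_order Morlet wavenumber; the spectral width of the
#'   wavelet at frequency f is `f / wavelet_order`.
#' @return A `bg_spectrum_config` carrying the frequency grid.
#' @export
power_spectrum_config <- function(n_freqs = 50, f_min = 2, f_max = 100,
                                  wavelet_order = 4) {
  if (!(f_min > 0 && f_max > f_min && n_freqs >= 2 && wavelet_order > 0))
    stop("invalid spectrum configuration", call. = FALSE)
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_freqs))
  structure(list(n_freqs = as.integer(n_freqs), f_min = f_min, f_max = f_max,
                 wavelet_order = wavelet_order, freqs = freqs),
            class = "bg_spectrum_config")
}

# Morlet wavelet power of one channel at the configured frequencies.
# Implemented in the frequency domain: the analytic Morlet at center
# frequency f is a Gaussian over positive frequencies with spectral SD
# f / order. Filters are L2-normalized (mean squared gain 1 across the
# DFT grid), so white noise of variance v has expected time-averaged power
# v at every analysis frequency, and 1/f^g inputs give log-power lines of
# slope -g. Returns a T x n_freqs matrix of instantaneous power.
morlet_power_one <- function(x, sr, cfg) {
  n <- length(x)
  X <- stats::fft(x)
  fgrid <- (seq_len(n) - 1L) / n * sr
  out <- matrix(0, n, length(cfg$freqs))
  for (i in seq_along(cfg$freqs)) {
    f0 <- cfg$freqs[i]
    sigma_f <- f0 / cfg$wavelet_order
    H <- numeric(n)
    pos <- fgrid <= sr / 2 # one-sided (analytic) response
    H[pos] <- exp(-(fgrid[pos] - f0)^2 / (2 * sigma_f^2))
    H <- H / sqrt(mean(H^2))
    w <- stats::fft(X * H, inverse = TRUE) / n
    out[, i] <- Mod(w)^2
  }
  out
}

#' Time-averaged wavelet power spectrum
#'
#' Morlet wavelet power at the configured log-spaced frequencies,
#' averaged over time (and across sessions, weighted by session length),
#' returned in natural-log units per electrode.
#'
#' @param rec A `bg_recording`.
#' @param cfg A [power_spectrum_config()].
#' @return Matrix n_freqs x n_electrodes of log mean power, with the
#'   frequency grid as an attribute.
#' @export
wavelet_power <- function(rec, cfg = power_spectrum_config()) {
  sr <- samplerate(rec)
  min_t <- ceiling(3 * sr / cfg$f_min)
  ts <- vapply(rec$sessions, function(s) nrow(s$voltages), 0L)
  if (any(ts < min_t))
    stop(sprintf("session too short for %g Hz analysis: need T >= %d",
                 cfg$f_min, min_t), call. = FALSE)
  total <- matrix(0, cfg$n_freqs, n_electrodes(rec))
  for (s in rec$sessions) {
    p <- vapply(seq_len(ncol(s$voltages)), function(j)
      colMeans(morlet_power_one(s$voltages[, j], sr, cfg)) * nrow(s$voltages),
      numeric(cfg$n_freqs))
    total <- total + matrix(p, cfg$n_freqs)
  }
  out <- log(total / sum(ts))
  rownames(out) <- sprintf("%.3fHz", cfg$freqs)
  colnames(out) <- rec$electrodes$electrode_id
  attr(out, "freqs") <- cfg$freqs
  out
}

# Mean height of a line fit to log power vs log frequency: the fitted
# value at the mean log-frequency. Robust fit is bisquare IRLS
# (MASS::rlm); a degenerate (perfectly linear or constant) spectrum falls
# back to ordinary least squares, where the fit is exact.
mean_height <- function(logp, logf, method = "robust") {
  if (method == "robust") {
    # stopping at the iteration cap is the intended estimator, so the
    # convergence warning is muffled
    fit <- tryCatch(
      withCallingHandlers(
        MASS::rlm(logp ~ logf, psi = MASS::psi.bisquare, maxit = 50,
                  acc = 1e-8),
        warning = function(w) {
          if (grepl("failed to converge", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (!is.null(fit)) return(mean(fitted(fit)))
  }
  mean(fitted(stats::lm(logp ~ logf)))
}

#' Time-resolved broadband power
#'
#' Broadband (BB) power is the mean height of a robust line fit in log-log
#' space to the Morlet wavelet power spectrum: per time window, log mean
#' power at the 50 log-spaced frequencies is regressed on log frequency
#' (bisquare IRLS) and BB is the mean of the fitted line over the grid --
#' equivalently the fit evaluated at the mean log-frequency. Scaling a
#' signal by `a` shifts its BB by exactly `log(a^2)`. The output is
#' returned as a recording (one BB sample per window, samplerate
#' `samplerate / window`), so BB traces can feed the correlation model
#' like any other derivative.
#'
#' @param rec A `bg_recording`.
#' @param cfg A [power_spectrum_config()].
#' @param window Window length in timepoints; defaults to 1 s of samples.
#' @param method `"robust"` (bisquare IRLS, default) or `"ols"`.
#' @return A `bg_recording` of BB series (windows x electrodes).
#' @export
broadband_power <- function(rec, cfg = power_spectrum_config(),
                            window = NULL, method = c("robust", "ols")) {
  method <- match.arg(method)
  sr <- samplerate(rec)
  if (is.null(window)) window <- as.integer(round(sr))
  if (sr <= 2 * cfg$f_max)
    stop(sprintf("spectrum range exceeds Nyquist at %g Hz samplerate", sr),
         call. = FALSE)
  logf <- log(cfg$freqs)
  map_sessions(rec, function(v, srate) {
    n_win <- nrow(v) %/% window
    if (n_win < 2L)
      stop(sprintf("session too short for window = %d (need >= 2 windows)",
                   window), call. = FALSE)
    bb <- matrix(0, n_win, ncol(v))
    for (j in seq_len(ncol(v))) {
      p <- morlet_power_one(v[, j], srate, cfg)
      for (w in seq_len(n_win)) {
        idx <- ((w - 1L) * window + 1L):(w * window)
        logp <- log(colMeans(p[idx, , drop = FALSE]))
        bb[w, j] <- mean_height(logp, logf, method)
      }
    }
    bb
  }, new_rate = sr / window)
}

#' Hilbert-transform band power
#'
#' Band-passes the recording (second-order Butterworth, zero phase), takes
#' the analytic signal per channel, and squares its amplitude envelope.
#' The output keeps the input shape and samplerate.
#'
#' @param rec A `bg_recording`.
#' @param band A `bg_band`.
#' @param order Butterworth order for the band pass (default 2).
#' @return A `bg_recording` of instantaneous band power.
#' @export
hilbert_band_power <- function(rec, band, order = 2) {
  filtered <- bandpass(rec, band, order)
  map_sessions(filtered, function(v, sr)
    apply(v, 2L, function(x) Mod(analytic_signal(x))^2))
}

# Analytic signal via the one-sided FFT (the Hilbert-transform route):
# doubles positive frequencies, zeroes negative ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
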