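#' Preprocessing configuration
#'
#' Bundles the signal-cleaning parameters: a fourth-order Butterworth notch
#' at 60 +/- 0.5 Hz for line noise, downsampling to 250 Hz, exclusion of
#' electrodes whose maximum excess kurtosis across sessions reaches 10, and
#' exclusion of patients left with fewer than two electrodes.
#'
#' @param notch_hz Line-noise frequency to remove (Hz).
#' @param notch_halfwidth_hz Half-width of the stop band (Hz).
#' @param notch_order Butterworth order of the notch filter.
#' @param target_rate_hz Common samplerate after downsampling (Hz).
#' @param kurtosis_threshold Exclusion threshold on per-electrode maximum
#'   excess (Fisher) kurtosis; Gaussian signals score about 0.
#' @param min_electrodes Minimum surviving electrodes for a patient to be
#'   retained.
#' @param extra_notch_hz Optional additional notch center frequencies
#'   (e.g. harmonics); none by default.
#' @return A `bg_preprocess_config` list.
#' @export
preprocess_config <- function(notch_hz = 60, notch_halfwidth_hz = 0.5,
                              notch_order = 4, target_rate_hz = 250,
                              kurtosis_threshold = 10, min_electrodes = 2,
                              extra_notch_hz = numeric(0)) {
  vals <- c(notch_hz, notch_halfwidth_hz, notch_order, target_rate_hz,
            kurtosis_threshold, min_electrodes)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all preprocessing parameters must be positive and finite", call. = FALSE)
  structure(
    list(notch_hz = notch_hz, notch_halfwidth_hz = notch_halfwidth_hz,
         notch_order = as.integer(notch_order),
         target_rate_hz = target_rate_hz,
         kurtosis_threshold = kurtosis_threshold,
         min_electrodes = as.integer(min_electrodes),
         extra_notch_hz = extra_notch_hz),
    class = "bg_preprocess_config"
  )
}

# Zero-phase IIR filtering, applied exactly in the frequency domain:
# forward-backward filtering has transfer function |H(w)|^2, which is
# multiplied onto the DFT of the signal. Unlike time-domain filtfilt this
# has no startup transients (a narrow 60 Hz notch rings for seconds), at
# the cost of circular boundary conditions, which are negligible for the
# near-allpass stop and pass bands used here.
zero_phase_filter <- function(filt, x, samplerate) {
  n <- length(x)
  w <- 2 * pi * (seq_len(n) - 1L) / n # DFT bin frequencies, rad/sample
  E <- exp(-1i * w)
  num <- 0 + 0i
  for (j in seq_along(filt$b)) num <- num + filt$b[j] * E^(j - 1L)
  den <- 0 + 0i
  for (j in seq_along(filt$a)) den <- den + filt$a[j] * E^(j - 1L)
  Re(stats::fft(stats::fft(x) * Mod(num / den)^2, inverse = TRUE)) / n
}

#' Remove line noise with a zero-phase Butterworth notch
#'
#' Applies a band-stop Butterworth filter (default: fourth order over
#' 59.5--60.5 Hz) forward and backward, so the output is zero-phase; phase
#' distortion would corrupt cross-electrode correlations downstream.
#' Signal length is unchanged. Additional centers in `cfg$extra_notch_hz`
#' (e.g. 120 Hz harmonics) are filtered with the same design; by default
#' only the fundamental is removed.
#'
#' @param rec A `bg_recording`.
#' @param cfg A [preprocess_config()].
#' @return A filtered `bg_recording`; the input is not modified.
#' @export
notch_filter <- function(rec, cfg = preprocess_config()) {
  centers <- c(cfg$notch_hz, cfg$extra_notch_hz)
  sr <- samplerate(rec)
  if (sr <= 2 * (max(centers) + cfg$notch_halfwidth_hz))
    stop(sprintf("samplerate %g Hz is too low to notch at %g Hz", sr,
                 max(centers)), call. = FALSE)
  filts <- lapply(centers, function(f0)
    signal::butter(cfg$notch_order,
                   c(f0 - cfg$notch_halfwidth_hz, f0 + cfg$notch_halfwidth_hz) / (sr / 2),
                   type = "stop"))
  map_sessions(rec, function(v, srate) {
    for (filt in filts) v <- apply(v, 2L, function(x) zero_phase_filter(filt, x, srate))
    v
  })
}

# Fourier-domain resampling of one column to n_out samples (the
# scipy.signal.resample method): truncate the spectrum and inverse
# transform, which is simultaneously the anti-alias filter.
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  keep <- min(floor(n_out / 2), floor(n / 2))
  Y <- complex(length.out = n_out)
  Y[1:(keep + 1L)] <- X[1:(keep + 1L)]
  if (keep > 0L) Y[(n_out - keep + 1L):n_out] <- X[(n - keep + 1L):n]
  if (n_out %% 2L == 0L && keep == n_out / 2) # split Nyquist bin
    Y[keep + 1L] <- Re(Y[keep + 1L])
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Downsample a recording to a target rate
#'
#' Resamples every session to `target_rate` Hz in the Fourier domain
#' (spectrum truncation, which is also the anti-aliasing step). The new
#' session length is `round(T * target_rate / samplerate)`. Upsampling is
#' out of scope and rejected.
#'
#' @param rec A `bg_recording`.
#' @param target_rate Target samplerate in Hz (must not exceed the current
#'   rate).
#' @return A resampled `bg_recording`.
#' @export
resample_to <- function(rec, target_rate) {
  sr <- samplerate(rec)
  if (target_rate > sr)
    stop(sprintf("cannot upsample from %g to %g Hz", sr, target_rate),
         call. = FALSE)
  if (target_rate == sr) return(rec)
  map_sessions(rec, function(v, srate) {
    n_out <- as.integer(round(nrow(v) * target_rate / srate))
    apply(v, 2L, fft_resample, n_out = n_out)
  }, new_rate = target_rate)
}

#' Maximum excess kurtosis per electrode across sessions
#'
#' Excess (Fisher) kurtosis by the moment formula, `m4 / m2^2 - 3`, computed
#' per electrode and session and maximized over sessions. Spike-contaminated
#' channels have heavy tails and large positive values; Gaussian channels
#' score near 0.
#'
#' @param rec A `bg_recording`.
#' @return Named numeric vector, one value per electrode.
#' @export
max_kurtosis <- function(rec) {
  per_session <- vapply(rec$sessions, function(s)
    apply(s$voltages, 2L, e1071::kurtosis, type = 1L),
    numeric(n_electrodes(rec)))
  per_session <- matrix(per_session, nrow = n_electrodes(rec))
  out <- apply(per_session, 1L, max)
  names(out) <- rec$electrodes$electrode_id
  out
}

#' Exclude artifactual electrodes and under-covered patients
#'
#' Drops every electrode whose maximum excess kurtosis across the patient's
#' sessions reaches `cfg$kurtosis_threshold` (putative epileptiform or
#' spike-contaminated channels), then drops every patient left with fewer
#' than `cfg$min_electrodes` electrodes (the correlation model needs at
#' least one electrode pair per patient). The exclusion report lists every
#' electrode with its statistic and fate.
#'
#' @param recs A list of `bg_recording` objects.
#' @param cfg A [preprocess_config()].
#' @return A list with `recordings` (survivors) and `report` (data frame
#'   with columns patient_id, electrode_id, max_kurtosis, excluded,
#'   excluded_reason).
#' @export
kurtosis_exclude <- function(recs, cfg = preprocess_config()) {
  if (inherits(recs, "bg_recording")) recs <- list(recs)
  report <- list()
  kept <- list()
  for (rec in recs) {
    k <- max_kurtosis(rec)
    drop <- which(k >= cfg$kurtosis_threshold)
    reason <- rep("", n_electrodes(rec))
    reason[drop] <- "kurtosis"
    survivors <- n_electrodes(rec) - length(drop)
    patient_dropped <- survivors < cfg$min_electrodes
    if (patient_dropped)
      reason[reason == ""] <- "patient_excluded"
    report[[length(report) + 1L]] <- data.frame(
      patient_id = rec$patient_id,
      electrode_id = rec$electrodes$electrode_id,
      max_kurtosis = unname(k),
      excluded = reason != "",
      excluded_reason = reason,
      stringsAsFactors = FALSE
    )
    if (!patient_dropped)
      kept[[length(kept) + 1L]] <- drop_electrodes(rec, drop)
  }
  report <- do.call(rbind, report)
  if (!length(kept))
    warning("kurtosis exclusion removed every patient", call. = FALSE)
  list(recordings = kept, report = report)
}

#' Z-score each session of a recording
#'
#' Per session and electrode, subtracts the mean and divides by the sample
#' standard deviation, so every channel has mean 0 and SD 1 within each
#' session. All downstream modelling operates in these z-units; the method
#' recovers activity up to this per-channel scaling.
#'
#' @param rec A `bg_recording`.
#' @return A z-scored `bg_recording`.
#' @export
zscore_sessions <- function(rec) {
  map_sessions(rec, function(v, sr) {
    sds <- apply(v, 2L, stats::sd)
    if (any(sds == 0 | !is.finite(sds))) {
      bad <- rec$electrodes$electrode_id[which(sds == 0 | !is.finite(sds))]
      stop(sprintf("zero-variance electrode(s): %s (should have been excluded upstream)",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    z <- scale(v)
    attr(z, "scaled:center") <- NULL
    attr(z, "scaled:scale") <- NULL
    z
  })
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: notch filter, downsampling, kurtosis-based exclusion
#' (computed on the notched, resampled data), and per-session z-scoring.
#' Every step is a pure function of its input.
#'
#' @param recs A list of `bg_recording` objects (or a single one).
#' @param cfg A [preprocess_config()].
#' @return A list with `recordings` (clean, z-scored survivors) and the
#'   exclusion `report`.
#' @export
preprocess <- function(recs, cfg = preprocess_config()) {
  if (inherits(recs, "bg_recording")) recs <- list(recs)
  recs <- lapply(recs, notch_filter, cfg = cfg)
  recs <- lapply(recs, resample_to, target_rate = cfg$target_rate_hz)
  ex <- kurtosis_exclude(recs, cfg)
  ex$recordings <- lapply(ex$recordings, zscore_sessions)
  ex
}
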