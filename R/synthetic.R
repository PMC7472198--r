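#' Ground-truth full-brain correlation structure
#'
#' Draws `n_locations` uniform locations in a brain-sized box and builds a
#' positive-definite correlation matrix from a smooth Gaussian spatial
#' covariance, `exp(-d^2 / (2 * smoothness^2))`, mixed with a random
#' low-rank component that adds long-range (non-spatial) correlations --
#' the two assumptions the model itself makes: activity correlates more
#' strongly nearby, and patients share distributed correlation structure.
#' The mix is floored in eigenvalue and renormalized to unit diagonal.
#'
#' @param n_locations Number of ground-truth locations (M >= 2).
#' @param box 2 x 3 matrix of bounds, MNI mm.
#' @param smoothness Spatial scale of the Gaussian covariance in mm
#'   (default 30). `Inf` gives a near-all-ones matrix, 0 gives identity.
#' @param low_rank Rank of the long-range component (default 3).
#' @param low_rank_weight Mixing weight in \[0, 1\] (default 0.3).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A `bg_ground_truth` with `locations`, `K_true` and the
#'   generation parameters.
#' @export
make_ground_truth <- function(n_locations = 40, box = default_brain_box(),
                              smoothness = 30, low_rank = 3,
                              low_rank_weight = 0.3, seed = 1) {
  if (n_locations < 2L) stop("need at least 2 locations", call. = FALSE)
  if (low_rank_weight < 0 || low_rank_weight > 1)
    stop("`low_rank_weight` must be in [0, 1]", call. = FALSE)
  box <- as.matrix(box)
  set.seed(seed)
  locs <- cbind(runif(n_locations, box[1, 1], box[2, 1]),
                runif(n_locations, box[1, 2], box[2, 2]),
                runif(n_locations, box[1, 3], box[2, 3]))
  d2 <- as.matrix(stats::dist(locs))^2
  K_spatial <- if (is.infinite(smoothness)) {
    matrix(1, n_locations, n_locations)
  } else if (smoothness <= 0) {
    diag(n_locations)
  } else {
    exp(-d2 / (2 * smoothness^2))
  }
  K <- K_spatial
  if (low_rank_weight > 0 && low_rank > 0) {
    A <- matrix(rnorm(n_locations * low_rank), n_locations, low_rank)
    L <- tcrossprod(A) + 1e-8 * diag(n_locations)
    L <- stats::cov2cor(L)
    K <- (1 - low_rank_weight) * K_spatial + low_rank_weight * L
  }
  # eigenvalue floor keeps K strictly positive definite
  eig <- eigen(K, symmetric = TRUE)
  floor_val <- 1e-6
  if (any(eig$values < floor_val)) {
    vals <- pmax(eig$values, floor_val)
    K <- eig$vectors %*% (vals * t(eig$vectors))
    K <- stats::cov2cor(K)
    K <- (K + t(K)) / 2
  }
  diag(K) <- 1
  structure(
    list(locations = locs, K_true = K,
         params = list(n_locations = n_locations, smoothness = smoothness,
                       low_rank = low_rank, low_rank_weight = low_rank_weight,
                       seed = seed)),
    class = "bg_ground_truth"
  )
}

#' Simulation specification
#'
#' The default configuration defines the synthetic study conditions used
#' throughout the package's validation: 8 patients, 12 clustered
#' electrodes each, one session of 10000 samples at 250 Hz, no
#' contaminants, no line noise, Gaussian (white) marginals.
#'
#' @param n_patients Number of simulated patients S.
#' @param electrodes_per_patient Electrodes per patient (>= 2).
#' @param n_timepoints Samples per session T.
#' @param n_sessions Sessions per patient.
#' @param samplerate Samplerate in Hz.
#' @param contaminant_fraction Per-electrode probability of spike
#'   contamination (high-kurtosis channel).
#' @param line_noise_amplitude Amplitude (in SD units) of an additive
#'   60 Hz sinusoid on every channel; 0 disables it.
#' @param spectrum `"white"` (Gaussian, model-matched; default) or
#'   `"pink"` (1/f-shaped marginals via identical per-channel filtering,
#'   which preserves the zero-lag correlation structure).
#' @param spectrum_exponent Power-law exponent for `"pink"` (default 2).
#' @param seed Base integer seed; per-patient seeds derive from it.
#' @return A `bg_sim_spec`.
#' @export
sim_spec <- function(n_patients = 8, electrodes_per_patient = 12,
                     n_timepoints = 10000, n_sessions = 1, samplerate = 250,
                     contaminant_fraction = 0, line_noise_amplitude = 0,
                     spectrum = c("white", "pink"), spectrum_exponent = 2,
                     seed = 1) {
  spectrum <- match.arg(spectrum)
  counts <- c(n_patients, electrodes_per_patient, n_timepoints, n_sessions,
              samplerate)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (electrodes_per_patient < 2L)
    stop("`electrodes_per_patient` must be at least 2", call. = FALSE)
  structure(
    list(n_patients = as.integer(n_patients),
         electrodes_per_patient = as.integer(electrodes_per_patient),
         n_timepoints = as.integer(n_timepoints),
         n_sessions = as.integer(n_sessions),
         samplerate = samplerate,
         contaminant_fraction = contaminant_fraction,
         line_noise_amplitude = line_noise_amplitude,
         spectrum = spectrum, spectrum_exponent = spectrum_exponent,
         seed = as.integer(seed)),
    class = "bg_sim_spec"
  )
}

# 1/f^(g/2) amplitude shaping applied identically to every channel: white
# MVN input keeps its zero-lag correlation matrix in expectation because
# all cross-spectra are scaled by the same factor.
shape_spectrum <- function(v, sr, exponent) {
  n <- nrow(v)
  fgrid <- (seq_len(n) - 1L) / n * sr
  fgrid <- pmin(fgrid, sr - fgrid) # two-sided
  gain <- ifelse(fgrid > 0, fgrid^(-exponent / 2), 0)
  shaped <- apply(v, 2L, function(x)
    Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n)
  z <- scale(shaped)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Simulate one patient's recording from the ground truth
#'
#' Samples a spatially clustered electrode subset (a random anchor location
#' plus its nearest neighbors, mimicking grid/strip implants, so each
#' patient's nearest electrodes are their own -- the geometry behind the
#' within- vs across-patient comparison). Each session is then drawn from
#' a zero-mean multivariate normal with covariance `K_true` restricted to
#' the subset. Optional spike contaminants (1% of samples replaced by
#' +/-20 SD) and 60 Hz line noise are injected afterwards.
#'
#' @param gt A `bg_ground_truth`.
#' @param spec A [sim_spec()].
#' @param patient_seed Integer seed for this patient.
#' @param patient_id Patient label.
#' @return A `bg_recording` with attributes `subset` (ground-truth indices)
#'   and `contaminated` (logical per electrode).
#' @export
simulate_patient <- function(gt, spec, patient_seed,
                             patient_id = sprintf("sim%03d", patient_seed %% 1000L)) {
  n_e <- spec$electrodes_per_patient
  m <- nrow(gt$locations)
  if (n_e > m)
    stop(sprintf("cannot place %d electrodes among %d ground-truth locations",
                 n_e, m), call. = FALSE)
  set.seed(patient_seed)
  anchor <- sample.int(m, 1L)
  d2 <- colSums((t(gt$locations) - gt$locations[anchor, ])^2)
  subset <- order(d2)[seq_len(n_e)]
  K_sub <- gt$K_true[subset, subset, drop = FALSE]
  ch <- chol(K_sub + 1e-10 * diag(n_e))
  contaminated <- runif(n_e) < spec$contaminant_fraction
  sessions <- lapply(seq_len(spec$n_sessions), function(k) {
    v <- matrix(rnorm(spec$n_timepoints * n_e), spec$n_timepoints, n_e) %*% ch
    if (spec$spectrum == "pink")
      v <- shape_spectrum(v, spec$samplerate, spec$spectrum_exponent)
    if (spec$line_noise_amplitude > 0) {
      tt <- (seq_len(spec$n_timepoints) - 1L) / spec$samplerate
      v <- v + spec$line_noise_amplitude * sin(2 * pi * 60 * tt)
    }
    for (j in which(contaminated)) {
      n_spk <- max(1L, round(0.01 * spec$n_timepoints))
      at <- sample.int(spec$n_timepoints, n_spk)
      v[at, j] <- sample(c(-20, 20), n_spk, replace = TRUE) * stats::sd(v[, j])
    }
    session_data(v, spec$samplerate, sprintf("ses%d", k))
  })
  electrodes <- data.frame(
    electrode_id = sprintf("%s_e%02d", patient_id, seq_len(n_e)),
    x = gt$locations[subset, 1], y = gt$locations[subset, 2],
    z = gt$locations[subset, 3], stringsAsFactors = FALSE)
  rec <- recording(patient_id, sessions, electrodes)
  attr(rec, "subset") <- subset
  attr(rec, "contaminated") <- contaminated
  rec
}

#' Simulate a multi-patient dataset
#'
#' Draws `spec$n_patients` recordings from one shared ground truth, each
#' with its own clustered electrode subset, plus a manifest recording
#' every subset, seed and contamination flag so that exact oracle
#' computations are possible downstream.
#'
#' @param gt A `bg_ground_truth`.
#' @param spec A [sim_spec()].
#' @return List with `recordings` (list of `bg_recording`) and `manifest`
#'   (data frame: patient_id, seed, subset, contaminated).
#' @export
simulate_dataset <- function(gt, spec = sim_spec()) {
  seeds <- spec$seed * 1000L + seq_len(spec$n_patients)
  recs <- vector("list", spec$n_patients)
  manifest <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("sim%03d", i)
    recs[[i]] <- simulate_patient(gt, spec, seeds[i], patient_id = pid)
    manifest[[i]] <- data.frame(
      patient_id = pid, seed = seeds[i],
      subset = I(list(attr(recs[[i]], "subset"))),
      contaminated = I(list(attr(recs[[i]], "contaminated"))),
      stringsAsFactors = FALSE)
  }
  list(recordings = recs, manifest = do.call(rbind, manifest))
}

#' Write / read a simulation manifest
#'
#' JSON round trip of the manifest produced by [simulate_dataset()].
#'
#' @param manifest Manifest data frame.
#' @param path JSON file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   manifest.
#' @export
write_manifest <- function(manifest, path) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) list(
    patient_id = manifest$patient_id[i],
    seed = manifest$seed[i],
    subset = manifest$subset[[i]],
    contaminated = manifest$contaminated[[i]]))
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  rows <- jsonlite::read_json(path, simplifyVector = TRUE)
  data.frame(
    patient_id = vapply(rows$patient_id, identity, ""),
    seed = as.integer(rows$seed),
    subset = I(lapply(rows$subset, as.integer)),
    contaminated = I(lapply(rows$contaminated, as.logical)),
    stringsAsFactors = FALSE)
}
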