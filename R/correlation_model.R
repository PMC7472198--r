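#' Gaussian radial basis function weights between location sets
#'
#' `weights[i, j] = exp(-||targets[i, ] - sources[j, ]||^2 / lambda)`.
#' The width `lambda` (squared-mm scale, default 20) governs how far an
#' electrode's information spreads over neighboring brain locations:
#' coincident points get weight 1 and the weight decays with squared MNI
#' distance. Weights are strictly positive.
#'
#' @param targets M x 3 matrix of model locations (MNI mm).
#' @param sources N x 3 matrix of electrode locations (MNI mm).
#' @param lambda RBF width in mm^2 (> 0), default 20.
#' @return M x N weight matrix.
#' @export
rbf_weights <- function(targets, sources, lambda = 20) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("`lambda` must be a single positive number", call. = FALSE)
  targets <- matrix(as.double(targets), ncol = 3L)
  sources <- matrix(as.double(sources), ncol = 3L)
  if (!all(is.finite(targets), is.finite(sources)))
    stop("locations must be finite", call. = FALSE)
  d2 <- outer(rowSums(targets^2), rowSums(sources^2), "+") -
    2 * tcrossprod(targets, sources)
  d2[d2 < 0] <- 0 # numerical noise on coincident points
  exp(-d2 / lambda)
}

#' Fisher z-transformation and its inverse
#'
#' `fisher_z(r) = (log(1 + r) - log(1 - r)) / 2` maps correlations to a
#' scale on which they are approximately additive, so they can be averaged
#' across sessions and patients; `fisher_z_inv` is `tanh`, its exact
#' inverse.
#'
#' @param r Correlations in \[-1, 1\] (finite at the open interval).
#' @param z Values on the Fisher z scale.
#' @return Transformed numeric vector/matrix of the same shape.
#' @export
fisher_z <- function(r) (log(1 + r) - log(1 - r)) / 2

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

# Correlations are clipped into the open interval before the z-transform so
# |r| = 1 never produces infinities.
CLIP_EPS <- 1e-6
clip_correlation <- function(r) pmin(pmax(r, -1 + CLIP_EPS), 1 - CLIP_EPS)

#' Session-averaged interelectrode correlation matrix
#'
#' Computes the Pearson correlation matrix of each session's (z-scored)
#' voltages, averages the matrices on the Fisher z scale across sessions,
#' and back-transforms. The diagonal is forced to exactly 1.
#'
#' @param rec A `bg_recording` with at least 2 electrodes and sessions of
#'   at least 3 timepoints.
#' @return A `bg_patient_correlation`: electrode locations plus the N x N
#'   session-averaged correlation matrix.
#' @export
session_average_correlations <- function(rec) {
  if (n_electrodes(rec) < 2L)
    stop("need at least 2 electrodes to correlate", call. = FALSE)
  zs <- lapply(rec$sessions, function(s) {
    if (nrow(s$voltages) < 3L)
      stop(sprintf("session '%s' is too short to correlate (T < 3)",
                   s$session_id), call. = FALSE)
    sds <- apply(s$voltages, 2L, stats::sd)
    if (any(sds == 0 | !is.finite(sds)))
      stop(sprintf("zero-variance electrode(s) in session '%s': %s",
                   s$session_id,
                   paste(rec$electrodes$electrode_id[sds == 0 | !is.finite(sds)],
                         collapse = ", ")), call. = FALSE)
    fisher_z(clip_correlation(stats::cor(s$voltages)))
  })
  zbar <- Reduce(`+`, zs) / length(zs)
  cmat <- fisher_z_inv(zbar)
  diag(cmat) <- 1
  structure(
    list(patient_id = rec$patient_id, electrodes = rec$electrodes,
         matrix = cmat),
    class = "bg_patient_correlation"
  )
}

#' Expand a patient's correlations to arbitrary model locations
#'
#' Spreads the patient's observed interelectrode correlations over a set of
#' target locations by RBF-weighted averaging on the Fisher z scale. For
#' target pair (x, y) the raw sums run over unordered electrode pairs
#' (i, j < i):
#' numerator `= sum_i sum_{j<i} W(x,i) W(y,j) z(C(i,j))` and denominator
#' the same sum of weight products. Both are symmetrized (raw + transpose,
#' which for the full pair sum equals `W Z W'` with a zero-diagonal `Z`);
#' diagonals are zeroed here and set to 1 only at materialization, so the
#' accumulator stays a pure pair-sum. The patient-level estimate is
#' `fisher_z_inv(numerator / denominator)`.
#'
#' For numerical stability over brain-scale distances (where products of
#' RBF weights underflow double precision), the sums are stored in a
#' scaled representation: the true value of each entry is
#' `numerator * exp(log_scale)` (and likewise for the denominator), with
#' `log_scale[x, y] = -(u_x + u_y) / lambda` where `u_x` is the squared
#' distance from target x to its nearest electrode. The ratio in the
#' back-transform is scale-invariant, so this is the printed math exactly,
#' evaluated stably.
#'
#' @param corr A `bg_patient_correlation` (>= 2 electrodes).
#' @param targets M x 3 matrix of model locations.
#' @param lambda RBF width in mm^2.
#' @return List with M x M `numerator`, `denominator` and `log_scale`
#'   matrices (all symmetric; numerator and denominator have zero
#'   diagonal) plus the patient id.
#' @export
expand_patient <- function(corr, targets, lambda = 20) {
  stopifnot(inherits(corr, "bg_patient_correlation"))
  n <- nrow(corr$matrix)
  if (n < 2L) stop("need at least 2 electrodes to expand", call. = FALSE)
  if (lambda <= 0) stop("`lambda` must be positive", call. = FALSE)
  src <- as.matrix(corr$electrodes[, c("x", "y", "z")])
  targets <- matrix(as.double(targets), ncol = 3L)
  d2 <- outer(rowSums(targets^2), rowSums(src^2), "+") -
    2 * tcrossprod(targets, src)
  d2[d2 < 0] <- 0
  u <- apply(d2, 1L, min) # per-target offset factored out of the weights
  W <- exp(-(d2 - u) / lambda) # rows have maximum exactly 1
  Z <- fisher_z(clip_correlation(corr$matrix))
  diag(Z) <- 0
  ones <- matrix(1, n, n)
  diag(ones) <- 0
  num <- W %*% Z %*% t(W)
  den <- W %*% ones %*% t(W)
  num <- (num + t(num)) / 2 # enforce exact symmetry against round-off
  den <- (den + t(den)) / 2
  diag(num) <- 0
  diag(den) <- 0
  list(numerator = num, denominator = den,
       log_scale = -outer(u, u, "+") / lambda,
       patient_id = corr$patient_id)
}

#' Unscaled numerator/denominator sums of an expansion
#'
#' Multiplies the scaled representation out to the literal pair sums.
#' Useful for comparison against direct evaluations on small problems;
#' underflows for brain-scale distances (which is what the scaled
#' representation exists to avoid).
#'
#' @param part An expansion from [expand_patient()] or a `bg_model`.
#' @return List with raw `numerator` and `denominator`.
#' @export
expansion_raw <- function(part) {
  list(numerator = part$numerator * exp(part$log_scale),
       denominator = part$denominator * exp(part$log_scale))
}

#' Merge per-patient expansions into a model accumulator
#'
#' Sums the per-patient numerator and denominator matrices elementwise.
#' The merge is exactly associative and commutative, so patients can be
#' added in any order or via previously merged accumulators; the combined
#' full-brain correlation matrix is materialized later as
#' `fisher_z_inv(sum(num) / sum(den))`.
#'
#' @param parts List of expansions from [expand_patient()] (all sharing the
#'   same target locations).
#' @param locations The M x 3 target locations the parts were expanded to.
#' @param lambda RBF width used for the expansions.
#' @return A `bg_model` accumulator with fields `locations`, `numerator`,
#'   `denominator`, `n_patients`, `lambda`, `patient_ids`.
#' @export
merge_patients <- function(parts, locations, lambda = 20) {
  locations <- matrix(as.double(locations), ncol = 3L)
  m <- nrow(locations)
  ids <- character(0)
  for (p in parts) {
    if (!all(dim(p$numerator) == c(m, m)))
      stop("expansion does not match the model locations", call. = FALSE)
    if (inherits(p, "bg_model")) {
      if (max(abs(p$locations - locations)) > 1e-9)
        stop("accumulator locations do not match", call. = FALSE)
      ids <- c(ids, p$patient_ids)
    } else {
      ids <- c(ids, p$patient_id)
    }
  }
  if (length(parts)) {
    # common per-entry scale: the elementwise maximum across patients, so
    # every rescaling factor is <= 1 and the dominant contribution is
    # carried at full precision
    scl <- Reduce(pmax, lapply(parts, `[[`, "log_scale"))
    num <- matrix(0, m, m)
    den <- matrix(0, m, m)
    for (p in parts) {
      f <- exp(p$log_scale - scl)
      num <- num + p$numerator * f
      den <- den + p$denominator * f
    }
  } else {
    scl <- matrix(0, m, m)
    num <- matrix(0, m, m)
    den <- matrix(0, m, m)
  }
  structure(
    list(locations = locations, numerator = num, denominator = den,
         log_scale = scl, n_patients = length(ids), lambda = lambda,
         patient_ids = ids),
    class = "bg_model"
  )
}

#' @export
print.bg_model <- function(x, ...) {
  cat(sprintf("<bg_model> %d location(s), %d patient(s), lambda = %g\n",
              nrow(x$locations), x$n_patients, x$lambda))
  invisible(x)
}

#' Materialize the merged full-brain correlation matrix
#'
#' Divides the accumulated numerator by the denominator elementwise,
#' back-transforms from the Fisher z scale, clips into the open interval
#' (-1, 1), and sets the diagonal to exactly 1. Errors if any off-diagonal
#' denominator entry is zero (an uncovered location pair).
#'
#' @param model A `bg_model` with at least one patient.
#' @return A `bg_corrmat`: `locations` plus the symmetric, unit-diagonal
#'   `matrix`.
#' @export
materialize <- function(model) {
  stopifnot(inherits(model, "bg_model"))
  if (model$n_patients < 1L)
    stop("model has no patients; nothing to materialize", call. = FALSE)
  den <- model$denominator
  off <- upper.tri(den)
  if (any(den[off] == 0)) {
    bad <- which(den == 0 & off, arr.ind = TRUE)[1L, ]
    stop(sprintf("no patient covers location pair (%d, %d); cannot estimate their correlation",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  ratio <- model$numerator
  ratio[off] <- ratio[off] / den[off]
  ratio[lower.tri(ratio)] <- t(ratio)[lower.tri(ratio)]
  cmat <- clip_correlation(fisher_z_inv(ratio))
  diag(cmat) <- 1
  structure(
    list(locations = model$locations, matrix = cmat),
    class = "bg_corrmat"
  )
}

#' Collapse near-duplicate locations
#'
#' Rows closer than `tol` (mm, per coordinate after rounding) are collapsed
#' to their first occurrence, preserving first-seen order.
#'
#' @param locs K x 3 matrix of locations.
#' @param tol Collapse tolerance in mm (default 1e-6).
#' @return Deduplicated matrix.
#' @export
dedupe_locations <- function(locs, tol = 1e-6) {
  locs <- matrix(as.double(locs), ncol = 3L)
  key <- apply(round(locs / tol) * tol, 1L, paste, collapse = "|")
  locs[!duplicated(key), , drop = FALSE]
}

#' Build a merged correlation model from recordings
#'
#' Convenience wrapper over [session_average_correlations()],
#' [expand_patient()] and [merge_patients()]. By default the model
#' locations are the union of all patients' electrode locations
#' (near-duplicates collapsed); arbitrary extra query locations may be
#' appended so that reconstruction targets are part of the model.
#'
#' @param recs List of preprocessed, z-scored `bg_recording` objects.
#' @param lambda RBF width in mm^2 (default 20).
#' @param targets Optional explicit M x 3 model locations; `NULL` takes the
#'   union of electrode locations.
#' @param extra_locations Optional locations appended to the union.
#' @return A `bg_model` accumulator.
#' @export
build_model <- function(recs, lambda = 20, targets = NULL,
                        extra_locations = NULL) {
  if (inherits(recs, "bg_recording")) recs <- list(recs)
  if (is.null(targets)) {
    all_locs <- do.call(rbind, lapply(recs, electrode_locs))
    if (!is.null(extra_locations))
      all_locs <- rbind(all_locs, matrix(as.double(extra_locations), ncol = 3L))
    targets <- dedupe_locations(all_locs)
  } else {
    targets <- matrix(as.double(targets), ncol = 3L)
  }
  parts <- lapply(recs, function(rec)
    expand_patient(session_average_correlations(rec), targets, lambda))
  merge_patients(parts, targets, lambda)
}
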