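#' Leave-one-electrode-out reconstruction accuracy
#'
#' Holds out each electrode of each patient in turn, reconstructs its
#' activity from the patient's remaining electrodes via the conditional
#' expectation, and correlates reconstruction with truth per session.
#' Session correlations aggregate on the Fisher z scale.
#'
#' Two modes:
#' \describe{
#'   \item{across}{the correlation model is built from every patient
#'     except the one being reconstructed (so the held-out patient's data
#'     never touch the model numerator or denominator -- the
#'     anti-circularity guarantee, asserted internally against the model's
#'     provenance log).}
#'   \item{within}{the model is built from the held-out patient alone,
#'     excluding the held-out electrode.}
#' }
#'
#' @param patients List of preprocessed, z-scored `bg_recording` objects.
#' @param mode `"across"` or `"within"`.
#' @param lambda RBF width in mm^2.
#' @param ridge Regularizer for the conditional solve.
#' @param train_sessions Optional session indices used to build the
#'   correlation model (test sessions are always all sessions); `NULL`
#'   uses every session. This is the generic train-set/test-set split for
#'   across-recording-set evaluation.
#' @return A `bg_evaluation`: `records` data frame (patient_id,
#'   electrode_id, x, y, z, mode, n_sessions, aggregate_r, with
#'   `per_session_r` as a list column) and the evaluation parameters.
#' @export
loo_accuracy <- function(patients, mode = c("across", "within"), lambda = 20,
                         ridge = 1e-5, train_sessions = NULL) {
  mode <- match.arg(mode)
  if (inherits(patients, "bg_recording")) patients <- list(patients)
  if (mode == "across" && length(patients) < 2L)
    stop("across mode needs at least 2 patients", call. = FALSE)
  if (mode == "within" &&
      any(vapply(patients, n_electrodes, 0L) < 3L))
    stop("within mode needs at least 3 electrodes per patient", call. = FALSE)
  train_of <- function(rec) {
    if (is.null(train_sessions)) return(rec)
    recording(rec$patient_id, rec$sessions[train_sessions], rec$electrodes)
  }
  all_locs <- dedupe_locations(do.call(rbind, lapply(patients, electrode_locs)))
  parts_by_patient <- if (mode == "across") {
    lapply(patients, function(rec)
      expand_patient(session_average_correlations(train_of(rec)), all_locs,
                     lambda))
  } else NULL

  records <- list()
  for (si in seq_along(patients)) {
    rec <- patients[[si]]
    locs <- electrode_locs(rec)
    if (mode == "across") {
      model <- merge_patients(parts_by_patient[-si], all_locs, lambda)
      if (rec$patient_id %in% model$patient_ids)
        stop("internal error: held-out patient leaked into the model",
             call. = FALSE)
      K <- materialize(model)
    }
    for (ei in seq_len(n_electrodes(rec))) {
      rec_obs <- drop_electrodes(rec, ei)
      if (mode == "within") {
        corr <- session_average_correlations(train_of(rec_obs))
        model <- merge_patients(list(expand_patient(corr, locs, lambda)),
                                locs, lambda)
        K <- materialize(model)
      }
      part <- partition(K, electrode_locs(rec_obs))
      target_idx <- match_location(K$locations, locs[ei, ])
      recon <- reconstruct_timeseries(rec_obs, K, part, ridge = ridge)
      per_r <- vapply(seq_along(rec$sessions), function(k)
        stats::cor(recon$values[[k]][, target_idx],
                   rec$sessions[[k]]$voltages[, ei]),
        0)
      records[[length(records) + 1L]] <- data.frame(
        patient_id = rec$patient_id,
        electrode_id = rec$electrodes$electrode_id[ei],
        x = locs[ei, 1], y = locs[ei, 2], z = locs[ei, 3],
        mode = mode, n_sessions = length(per_r),
        aggregate_r = fisher_z_inv(mean(fisher_z(clip_correlation(per_r)))),
        per_session_r = I(list(per_r)),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  structure(
    list(records = records, lambda = lambda, ridge = ridge, mode = mode),
    class = "bg_evaluation"
  )
}

# Index of the model row matching a location (error if none within 0.5 mm).
match_location <- function(locations, loc, tolerance = 0.5) {
  d2 <- colSums((t(locations) - as.double(loc))^2)
  i <- which.min(d2)
  if (sqrt(d2[i]) > tolerance)
    stop("target location is not among the model locations", call. = FALSE)
  i
}

#' @export
print.bg_evaluation <- function(x, ...) {
  cat(sprintf("<bg_evaluation> mode '%s': %d electrode record(s), mean r = %.3f\n",
              x$mode, nrow(x$records), mean(x$records$aggregate_r)))
  invisible(x)
}

#' Combine evaluations from several modes
#'
#' @param ... `bg_evaluation` objects (e.g. one per mode).
#' @return A `bg_evaluation` with the concatenated records.
#' @export
combine_evaluations <- function(...) {
  evs <- list(...)
  records <- do.call(rbind, lapply(evs, function(e) e$records))
  structure(list(records = records, lambda = evs[[1]]$lambda,
                 ridge = evs[[1]]$ridge, mode = "combined"),
            class = "bg_evaluation")
}

#' Per-patient mean accuracy on the Fisher z scale
#' @noRd
patient_z_means <- function(records) {
  tapply(fisher_z(clip_correlation(records$aggregate_r)),
         records$patient_id, mean)
}

#' Compare within- and across-patient accuracy
#'
#' Computes per-patient means of the z-transformed electrode accuracies in
#' each mode, then: a one-sample t-test of each mode's per-patient means
#' against 0, and a paired t-test of across minus within. The pairing uses
#' identical patient (and electrode) sets in both modes.
#'
#' @param summary A `bg_evaluation` containing records for both modes.
#' @return List with `one_sample` (per mode: t, df, p, mean_r) and
#'   `paired` (t, df, p, mean_diff_z).
#' @export
compare_modes <- function(summary) {
  rec <- summary$records
  modes <- unique(rec$mode)
  one_sample <- lapply(stats::setNames(modes, modes), function(m) {
    zm <- patient_z_means(rec[rec$mode == m, ])
    if (length(zm) < 2L) stop("need at least 2 patients per mode", call. = FALSE)
    tt <- stats::t.test(zm)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_r = fisher_z_inv(mean(zm)))
  })
  paired <- NULL
  if (all(c("across", "within") %in% modes)) {
    za <- patient_z_means(rec[rec$mode == "across", ])
    zw <- patient_z_means(rec[rec$mode == "within", ])
    common <- intersect(names(za), names(zw))
    if (length(common) < 2L) stop("need at least 2 paired patients", call. = FALSE)
    d <- za[common] - zw[common]
    tt <- if (stats::sd(d) == 0) {
      list(statistic = c(t = 0), parameter = c(df = length(d) - 1), p.value = 1)
    } else stats::t.test(za[common], zw[common], paired = TRUE)
    paired <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, mean_diff_z = mean(d))
  }
  list(one_sample = one_sample, paired = paired)
}

#' Electrode sampling density map
#'
#' For each in-mask voxel, the proportion of all electrodes whose center
#' lies within `radius` mm (closed ball) of the voxel center.
#'
#' @param all_electrodes Matrix (or data frame with x, y, z) of electrode
#'   locations across the whole dataset.
#' @param grid A `bg_voxel_map` template.
#' @param radius Sphere radius in MNI mm (default 20).
#' @return A `bg_voxel_map` of densities in \[0, 1\].
#' @export
density_map <- function(all_electrodes, grid, radius = 20) {
  locs <- as_loc_matrix(all_electrodes)
  if (!nrow(locs)) stop("need at least one electrode", call. = FALSE)
  centers <- voxel_centers(grid)
  counts <- count_within(centers, locs, radius)
  set_voxel_values(grid, counts / nrow(locs))
}

as_loc_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  matrix(as.double(x), ncol = 3L)
}

count_within <- function(centers, locs, radius) {
  d2 <- outer(rowSums(centers^2), rowSums(locs^2), "+") -
    2 * tcrossprod(centers, locs)
  rowSums(d2 <= radius^2 + 1e-9)
}

#' Sampling density at one electrode
#'
#' The proportion of comparison electrodes (conventionally, other
#' patients' electrodes) within `radius` mm of the given electrode.
#'
#' @param electrode Length-3 location of the electrode (MNI mm).
#' @param other_electrodes Matrix/data frame of comparison electrode
#'   locations (must exclude the electrode's own patient, and be
#'   non-empty).
#' @param radius Sphere radius in mm (default 20).
#' @return Proportion in \[0, 1\].
#' @export
electrode_density <- function(electrode, other_electrodes, radius = 20) {
  others <- as_loc_matrix(other_electrodes)
  if (!nrow(others)) stop("comparison electrode set is empty", call. = FALSE)
  count_within(matrix(as.double(electrode), ncol = 3L), others, radius) /
    nrow(others)
}

#' Information-score map
#'
#' Every electrode inherits its patient's mean reconstruction accuracy
#' (per-patient mean of z-transformed electrode accuracies,
#' back-transformed). Each voxel's score is the mean of these values over
#' all electrodes within `radius` mm of the voxel center -- so patients
#' with more electrodes near a voxel weigh proportionally more. Voxels
#' with no electrode within the radius are left missing.
#'
#' @param summary An across-patient `bg_evaluation`.
#' @param grid A `bg_voxel_map` template.
#' @param radius Sphere radius in mm (default 20).
#' @return A `bg_voxel_map` of information scores (missing where
#'   uncovered).
#' @export
information_scores <- function(summary, grid, radius = 20) {
  rec <- summary$records
  zm <- patient_z_means(rec)
  elec_val <- fisher_z_inv(zm[rec$patient_id])
  locs <- as_loc_matrix(rec[, c("x", "y", "z")])
  centers <- voxel_centers(grid)
  d2 <- outer(rowSums(centers^2), rowSums(locs^2), "+") -
    2 * tcrossprod(centers, locs)
  near <- d2 <= radius^2 + 1e-9
  n_near <- rowSums(near)
  score <- as.vector(near %*% elec_val)
  vals <- ifelse(n_near > 0, score / pmax(n_near, 1L), NA_real_)
  set_voxel_values(grid, vals)
}

#' Intersection of the top fraction of two maps
#'
#' Ranks the non-missing voxels of each map, keeps the top `fraction` of
#' each (ties at the cutoff value are all included, deterministically),
#' and returns their intersection as a boolean map.
#'
#' @param map_a,map_b `bg_voxel_map`s sharing grid and mask.
#' @param fraction Top fraction to keep (default 0.1).
#' @return A boolean-valued `bg_voxel_map` (1 inside the intersection, 0
#'   elsewhere defined, missing where either input is missing).
#' @export
top_fraction_intersection <- function(map_a, map_b, fraction = 0.1) {
  check_same_grid(map_a, map_b)
  top_set <- function(map) {
    v <- map$values
    ok <- !is.na(v)
    n_top <- max(1L, ceiling(fraction * sum(ok)))
    cutoff <- sort(v[ok], decreasing = TRUE)[n_top]
    ok & v >= cutoff
  }
  both <- top_set(map_a) & top_set(map_b)
  vals <- array(NA_real_, map_a$dim)
  defined <- !is.na(map_a$values) & !is.na(map_b$values)
  vals[defined] <- as.double(both[defined])
  voxel_map(map_a$dim, map_a$origin, map_a$spacing, values = vals,
            mask = map_a$mask)
}

check_same_grid <- function(a, b) {
  if (!identical(a$dim, b$dim) || !identical(a$origin, b$origin) ||
      !identical(a$spacing, b$spacing))
    stop("voxel maps are on different grids", call. = FALSE)
  invisible(TRUE)
}

#' Voxelwise correlation of two maps
#'
#' Pearson correlation over the voxels where both maps are defined.
#'
#' @param map_a,map_b `bg_voxel_map`s on the same grid.
#' @return List with `r` and `n` (number of shared voxels).
#' @export
correlate_maps <- function(map_a, map_b) {
  check_same_grid(map_a, map_b)
  shared <- !is.na(map_a$values) & !is.na(map_b$values)
  n <- sum(shared)
  if (n < 3L)
    stop(sprintf("only %d shared voxel(s); need at least 3", n), call. = FALSE)
  list(r = stats::cor(map_a$values[shared], map_b$values[shared]), n = n)
}
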