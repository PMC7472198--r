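#' Write a recording to disk as a CSV pair
#'
#' The on-disk layout is `<name>_locs.csv` (columns electrode_id, x, y, z),
#' one `<name>_ses<k>.csv` per session (rows are timepoints, columns are
#' electrodes), and `<name>_meta.json` carrying the samplerate, patient id
#' and session ids. Electrode order in the files is the in-memory order.
#'
#' @param rec A `bg_recording`.
#' @param dir Output directory (created if missing).
#' @param name File-name stem; defaults to the patient id.
#' @return The stem path, invisibly.
#' @export
write_recording <- function(rec, dir, name = rec$patient_id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, name)
  # 17 significant digits so doubles round-trip exactly through the text file
  fmt17 <- function(m) array(formatC(m, digits = 17, format = "g"), dim(m))
  locs <- rec$electrodes[, c("electrode_id", "x", "y", "z")]
  locs$x <- formatC(locs$x, digits = 17, format = "g")
  locs$y <- formatC(locs$y, digits = 17, format = "g")
  locs$z <- formatC(locs$z, digits = 17, format = "g")
  utils::write.csv(locs, paste0(stem, "_locs.csv"), row.names = FALSE)
  for (k in seq_along(rec$sessions)) {
    v <- fmt17(rec$sessions[[k]]$voltages)
    colnames(v) <- rec$electrodes$electrode_id
    utils::write.csv(v, sprintf("%s_ses%d.csv", stem, k), row.names = FALSE,
                     quote = FALSE)
  }
  meta <- list(patient_id = rec$patient_id,
               samplerate = samplerate(rec),
               n_sessions = length(rec$sessions),
               session_ids = vapply(rec$sessions, function(s) s$session_id, ""))
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Load a recording from disk
#'
#' Reads the CSV-pair layout written by [write_recording()]. Electrode order
#' is taken from the files as-is and never reordered.
#'
#' @param path Stem path (`<dir>/<name>`, without the `_locs.csv` suffix).
#' @param format On-disk format; only `"csv_pair"` is supported.
#' @param na_action Passed to [session_data()] for non-finite samples.
#' @return A validated `bg_recording`.
#' @export
load_recording <- function(path, format = c("csv_pair", "hdf5"),
                           na_action = c("error", "drop")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("the hdf5 recording format is not supported by this build; use \"csv_pair\"",
         call. = FALSE)
  locs_file <- paste0(path, "_locs.csv")
  meta_file <- paste0(path, "_meta.json")
  if (!file.exists(locs_file))
    stop(sprintf("no location table at '%s'", locs_file), call. = FALSE)
  if (!file.exists(meta_file))
    stop(sprintf("no metadata sidecar at '%s'", meta_file), call. = FALSE)
  electrodes <- utils::read.csv(locs_file, stringsAsFactors = FALSE)
  if (!all(c("electrode_id", "x", "y", "z") %in% names(electrodes)))
    stop(sprintf("'%s' must have columns electrode_id, x, y, z", locs_file),
         call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  sessions <- vector("list", meta$n_sessions)
  for (k in seq_len(meta$n_sessions)) {
    f <- sprintf("%s_ses%d.csv", path, k)
    if (!file.exists(f))
      stop(sprintf("missing session file '%s'", f), call. = FALSE)
    v <- as.matrix(utils::read.csv(f, check.names = FALSE))
    if (ncol(v) != nrow(electrodes))
      stop(sprintf("session file '%s' has %d column(s) but the location table has %d row(s)",
                   f, ncol(v), nrow(electrodes)), call. = FALSE)
    sessions[[k]] <- session_data(v, meta$samplerate,
                                  session_id = meta$session_ids[[k]],
                                  na_action = na_action)
  }
  recording(meta$patient_id, sessions, electrodes)
}

#' Save / load a correlation-model accumulator
#'
#' Models round-trip exactly: locations, numerator, denominator, patient
#' count, kernel width and provenance log are preserved to full precision.
#' Files are versioned; loading a file written by an incompatible version
#' raises an error rather than silently misreading it.
#'
#' @param model A `bg_model` accumulator.
#' @param path Output file path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bg_model"))
  payload <- list(format = "braingp-model", version = 1L, model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot parse model file '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  if (!is.list(payload) || !identical(payload$format, "braingp-model"))
    stop(sprintf("'%s' is not a braingp model file", path), call. = FALSE)
  if (!identical(payload$version, 1L))
    stop(sprintf("model file '%s' has version %s; this build reads version 1",
                 path, format(payload$version)), call. = FALSE)
  model <- payload$model
  if (model$n_patients == 0L)
    warning("loaded model contains 0 patients; it cannot be materialized for prediction",
            call. = FALSE)
  model
}

#' Write a voxel map as a NIfTI volume
#'
#' Produces a NIfTI-1 volume whose affine places voxel centers at
#' `origin + spacing * index` in MNI152 mm. Masked-out voxels are written
#' as `NaN`.
#'
#' @param map A `bg_voxel_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_voxel_map <- function(map, path) {
  stopifnot(inherits(map, "bg_voxel_map"))
  if (!any(map$mask))
    warning("voxel map has an empty mask; writing an all-NaN volume",
            call. = FALSE)
  arr <- map$values
  arr[!map$mask] <- NaN
  arr[is.na(arr)] <- NaN
  attr(arr, "pixdim") <- rep(map$spacing, 3)
  img <- RNifti::asNifti(arr, datatype = "double")
  aff <- diag(c(rep(map$spacing, 3), 1))
  aff[1:3, 4] <- map$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a voxel map from a NIfTI volume
#'
#' Inverse of [write_voxel_map()]: `NaN` voxels become the mask complement.
#'
#' @param path A NIfTI file written by [write_voxel_map()].
#' @return A `bg_voxel_map`.
#' @export
read_voxel_map <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- as.array(img)
  spacing <- aff[1, 1]
  origin <- aff[1:3, 4]
  mask <- array(is.finite(arr), dim(arr))
  vals <- array(as.double(arr), dim(arr))
  vals[!mask] <- NA_real_
  voxel_map(dim(arr), origin, spacing, values = vals, mask = mask)
}
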