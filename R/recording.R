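#' Construct a single-session container of voltages
#'
#' A session holds a timepoints-by-electrodes numeric matrix of voltages
#' (microvolts before preprocessing, z-units after per-session z-scoring)
#' together with its sampling rate.
#'
#' @param voltages Numeric matrix, timepoints x electrodes.
#' @param samplerate Sampling rate in Hz (> 0).
#' @param session_id Character label for the session.
#' @param na_action What to do with non-finite samples: `"error"` (default)
#'   rejects the session; `"drop"` removes any timepoint containing a
#'   non-finite value and records the count in the `n_dropped` attribute.
#' @return An object of class `bg_session`.
#' @export
session_data <- function(voltages, samplerate, session_id = "ses1",
                         na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  voltages <- as.matrix(voltages)
  storage.mode(voltages) <- "double"
  if (!is.numeric(samplerate) || length(samplerate) != 1L || samplerate <= 0)
    stop("`samplerate` must be a single positive number", call. = FALSE)
  n_dropped <- 0L
  bad <- !is.finite(voltages)
  if (any(bad)) {
    if (na_action == "error") {
      stop(sprintf("session '%s' contains %d non-finite sample(s); use na_action = \"drop\" to remove affected timepoints",
                   session_id, sum(bad)), call. = FALSE)
    }
    keep <- rowSums(bad) == 0L
    n_dropped <- sum(!keep)
    voltages <- voltages[keep, , drop = FALSE]
  }
  if (nrow(voltages) < 2L)
    stop(sprintf("session '%s' must have at least 2 timepoints", session_id),
         call. = FALSE)
  structure(
    list(voltages = voltages, samplerate = as.numeric(samplerate),
         session_id = as.character(session_id)),
    n_dropped = n_dropped,
    class = "bg_session"
  )
}

#' Construct a patient recording
#'
#' A recording bundles one patient's sessions with the table of electrode
#' locations. Coordinates are MNI152 millimeters (right-handed, floating
#' point); every session must reference the same electrodes in the same
#' column order.
#'
#' @param patient_id Character patient identifier.
#' @param sessions A `bg_session` or list of `bg_session` objects, all with
#'   the same number of electrode columns and the same samplerate.
#' @param electrodes Data frame with columns `electrode_id`, `x`, `y`, `z`.
#' @return An object of class `bg_recording`.
#' @examples
#' elec <- data.frame(electrode_id = c("e1", "e2"), x = c(0, 10),
#'                    y = c(0, 0), z = c(0, 0))
#' ses <- session_data(matrix(rnorm(200), 100, 2), samplerate = 250)
#' rec <- recording("p1", ses, elec)
#' @export
recording <- function(patient_id, sessions, electrodes) {
  if (inherits(sessions, "bg_session")) sessions <- list(sessions)
  if (!length(sessions) || !all(vapply(sessions, inherits, TRUE, "bg_session")))
    stop("`sessions` must be one or more bg_session objects", call. = FALSE)
  electrodes <- as.data.frame(electrodes)
  req <- c("electrode_id", "x", "y", "z")
  if (!all(req %in% names(electrodes)))
    stop("`electrodes` must have columns electrode_id, x, y, z", call. = FALSE)
  electrodes$electrode_id <- as.character(electrodes$electrode_id)
  coords <- as.matrix(electrodes[, c("x", "y", "z")])
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("electrode coordinates must be finite", call. = FALSE)
  if (nrow(electrodes) < 1L)
    stop("recording must have at least one electrode", call. = FALSE)
  n_elec <- nrow(electrodes)
  rates <- vapply(sessions, function(s) s$samplerate, 0)
  for (s in sessions) {
    if (ncol(s$voltages) != n_elec)
      stop(sprintf("session '%s' has %d electrode column(s) but the location table has %d row(s)",
                   s$session_id, ncol(s$voltages), n_elec), call. = FALSE)
  }
  if (length(unique(rates)) != 1L)
    stop("all sessions must share one samplerate", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id), sessions = sessions,
         electrodes = electrodes),
    class = "bg_recording"
  )
}

#' @export
print.bg_recording <- function(x, ...) {
  ts <- vapply(x$sessions, function(s) nrow(s$voltages), 0L)
  cat(sprintf("<bg_recording> patient '%s': %d electrode(s), %d session(s) @ %g Hz\n",
              x$patient_id, n_electrodes(x), length(x$sessions), samplerate(x)))
  cat("  timepoints per session:", paste(ts, collapse = ", "), "\n")
  invisible(x)
}

#' Number of electrodes in a recording
#' @param rec A `bg_recording`.
#' @return Integer count.
#' @export
n_electrodes <- function(rec) nrow(rec$electrodes)

#' Electrode coordinates of a recording
#' @param rec A `bg_recording`.
#' @return Numeric matrix, electrodes x 3 (MNI mm).
#' @export
electrode_locs <- function(rec) {
  m <- as.matrix(rec$electrodes[, c("x", "y", "z")])
  storage.mode(m) <- "double"
  rownames(m) <- rec$electrodes$electrode_id
  m
}

#' Sampling rate of a recording
#' @param rec A `bg_recording`.
#' @return Samplerate in Hz.
#' @export
samplerate <- function(rec) rec$sessions[[1L]]$samplerate

#' Apply a voltage transform to every session of a recording
#'
#' Internal plumbing used by the preprocessing and spectral layers: `fn`
#' receives each session's voltage matrix plus the samplerate and returns a
#' replacement matrix (the samplerate may be changed via `new_rate`).
#'
#' @noRd
map_sessions <- function(rec, fn, new_rate = NULL) {
  sessions <- lapply(rec$sessions, function(s) {
    v <- fn(s$voltages, s$samplerate)
    session_data(v, if (is.null(new_rate)) s$samplerate else new_rate,
                 s$session_id)
  })
  recording(rec$patient_id, sessions, rec$electrodes)
}

#' Drop electrodes from a recording by index
#' @noRd
drop_electrodes <- function(rec, idx) {
  if (!length(idx)) return(rec)
  keep <- setdiff(seq_len(n_electrodes(rec)), idx)
  if (!length(keep)) stop("cannot drop every electrode", call. = FALSE)
  sessions <- lapply(rec$sessions, function(s)
    session_data(s$voltages[, keep, drop = FALSE], s$samplerate, s$session_id))
  recording(rec$patient_id, sessions, rec$electrodes[keep, , drop = FALSE])
}
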