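#' Partition model locations into observed and unobserved sets
#'
#' Matches each electrode to its model location (nearest neighbor within
#' `tolerance` mm; locations normally originate from the same table, so
#' matches are near-exact) and splits the model index set into alpha (the
#' observed rows, in electrode order) and beta (all remaining rows).
#'
#' @param model A `bg_corrmat` (or `bg_model`, for its locations).
#' @param electrode_locs N x 3 matrix of the patient's electrode locations.
#' @param tolerance Match tolerance in mm (default 0.5).
#' @return A `bg_partition` with `observed` (alpha, one index per
#'   electrode), `unobserved` (beta) and `n_model`.
#' @export
partition <- function(model, electrode_locs, tolerance = 0.5) {
  locs <- model$locations
  electrode_locs <- matrix(as.double(electrode_locs), ncol = 3L)
  m <- nrow(locs)
  d2 <- outer(rowSums(electrode_locs^2), rowSums(locs^2), "+") -
    2 * tcrossprod(electrode_locs, locs)
  d2[d2 < 0] <- 0
  nearest <- apply(d2, 1L, which.min)
  dist <- sqrt(d2[cbind(seq_len(nrow(electrode_locs)), nearest)])
  if (any(dist > tolerance)) {
    i <- which.max(dist)
    stop(sprintf("electrode %d has no model location within %g mm (nearest is row %d at %.3f mm)",
                 i, tolerance, nearest[i], dist[i]), call. = FALSE)
  }
  if (anyDuplicated(nearest))
    stop("two electrodes matched the same model location", call. = FALSE)
  structure(
    list(observed = as.integer(nearest),
         unobserved = setdiff(seq_len(m), nearest),
         n_model = m),
    class = "bg_partition"
  )
}

#' Regularize a correlation matrix for inversion
#'
#' Two-stage eigenvalue floor. The weighted-average correlation estimator
#' is not guaranteed positive semi-definite, so any negative eigenvalues
#' are first clipped to zero and the matrix renormalized to unit diagonal
#' (a no-op for PSD input). Then `ridge` is added to the diagonal and the
#' matrix renormalized, `K <- (K + ridge * I) / (1 + ridge)`, flooring the
#' smallest eigenvalue at `ridge / (1 + ridge)` while changing any entry
#' of a PSD input by less than `ridge`. With `ridge = 0` on PSD input this
#' is the identity operation.
#'
#' @param K A `bg_corrmat` or plain symmetric matrix.
#' @param ridge Small non-negative regularizer (default 1e-5).
#' @return Same type as the input.
#' @export
condition_matrix <- function(K, ridge = 1e-5) {
  if (ridge < 0) stop("`ridge` must be non-negative", call. = FALSE)
  if (inherits(K, "bg_corrmat")) {
    K$matrix <- condition_matrix(K$matrix, ridge)
    return(K)
  }
  sym <- (K + t(K)) / 2
  eig <- eigen(sym, symmetric = TRUE)
  if (eig$values[length(eig$values)] < 0) {
    vals <- pmax(eig$values, 0)
    sym <- eig$vectors %*% (vals * t(eig$vectors))
    d <- sqrt(pmax(diag(sym), .Machine$double.eps))
    sym <- sym / tcrossprod(d)
    sym <- (sym + t(sym)) / 2
    diag(sym) <- 1
  }
  if (ridge == 0) return(sym)
  out <- sym / (1 + ridge)
  diag(out) <- diag(out) + ridge / (1 + ridge)
  out
}

#' Reconstruct activity at unobserved model locations
#'
#' The Gaussian-process conditional expectation: per session, the estimate
#' at the unobserved locations is
#' `Yhat_beta = ((K_ba %*% solve(K_aa)) %*% t(Y_alpha))'`, evaluated as a
#' linear solve against the conditioned `K_aa` (never an explicit inverse)
#' and applied chunk-by-chunk over time. Because the estimator is
#' per-timepoint, the result is exactly independent of `chunk_size`.
#' Observed columns pass through unchanged, so the output at observed
#' locations equals the (z-scored) input.
#'
#' @param rec A z-scored `bg_recording` (electrode order must match the
#'   partition's alpha order).
#' @param model A `bg_corrmat` over the model locations.
#' @param part A `bg_partition` from [partition()].
#' @param chunk_size Timepoints per processing chunk (default 10000).
#' @param ridge Regularizer applied to `K_aa` before the solve
#'   (default 1e-5).
#' @return A `bg_reconstruction`: per-session `values` (T x M matrices in
#'   z-units over all model locations), `observed_mask`, `locations` and a
#'   `chunk_log`.
#' @export
reconstruct_timeseries <- function(rec, model, part, chunk_size = 10000,
                                   ridge = 1e-5) {
  stopifnot(inherits(model, "bg_corrmat"), inherits(part, "bg_partition"))
  alpha <- part$observed
  beta <- part$unobserved
  if (n_electrodes(rec) != length(alpha))
    stop("recording electrode count does not match the partition", call. = FALSE)
  m <- part$n_model
  K <- model$matrix
  Kaa <- condition_matrix(K[alpha, alpha, drop = FALSE], ridge)
  Kab <- K[alpha, beta, drop = FALSE]
  B <- NULL
  if (length(beta)) {
    ch <- tryCatch(chol(Kaa), error = function(e) NULL)
    if (is.null(ch))
      stop("K_aa is singular even after conditioning; increase `ridge`",
           call. = FALSE)
    B <- backsolve(ch, backsolve(ch, Kab, transpose = TRUE)) # solve(Kaa, Kab)
  }
  chunk_log <- list()
  values <- lapply(rec$sessions, function(s) {
    Y <- s$voltages
    out <- matrix(0, nrow(Y), m)
    out[, alpha] <- Y
    if (length(beta)) {
      starts <- seq(1L, nrow(Y), by = chunk_size)
      for (st in starts) {
        en <- min(st + chunk_size - 1L, nrow(Y))
        out[st:en, beta] <- Y[st:en, , drop = FALSE] %*% B
      }
      chunk_log[[s$session_id]] <<- data.frame(start = starts,
                                               end = pmin(starts + chunk_size - 1L, nrow(Y)))
    }
    if (anyNA(out)) stop("reconstruction produced NaN values", call. = FALSE)
    out
  })
  names(values) <- vapply(rec$sessions, function(s) s$session_id, "")
  mask <- logical(m)
  mask[alpha] <- TRUE
  structure(
    list(values = values, observed_mask = mask, locations = model$locations,
         patient_id = rec$patient_id, chunk_log = chunk_log),
    class = "bg_reconstruction"
  )
}

#' @export
print.bg_reconstruction <- function(x, ...) {
  cat(sprintf("<bg_reconstruction> patient '%s': %d session(s), %d location(s) (%d observed)\n",
              x$patient_id, length(x$values), length(x$observed_mask),
              sum(x$observed_mask)))
  invisible(x)
}
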