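# Fixtures are generated in code at test time; nothing is read from disk.

# A recording whose channels are pure sinusoids (one frequency per column).
sine_recording <- function(freqs, samplerate = 500, seconds = 4,
                           patient_id = "sine", locs = NULL) {
  tt <- seq(0, seconds - 1 / samplerate, by = 1 / samplerate)
  v <- vapply(freqs, function(f) sin(2 * pi * f * tt), numeric(length(tt)))
  n <- length(freqs)
  if (is.null(locs)) locs <- cbind(seq_len(n) * 10, 0, 0)
  elec <- data.frame(electrode_id = sprintf("e%d", seq_len(n)),
                     x = locs[, 1], y = locs[, 2], z = locs[, 3])
  recording(patient_id, session_data(v, samplerate), elec)
}

# Gaussian-noise recording with optional multiple sessions.
noise_recording <- function(n_elec = 3, t_len = 1000, n_sessions = 1,
                            samplerate = 250, seed = 1, patient_id = "noise") {
  set.seed(seed)
  sessions <- lapply(seq_len(n_sessions), function(k)
    session_data(matrix(rnorm(t_len * n_elec), t_len, n_elec), samplerate,
                 sprintf("ses%d", k)))
  elec <- data.frame(electrode_id = sprintf("e%d", seq_len(n_elec)),
                     x = runif(n_elec, -50, 50), y = runif(n_elec, -50, 50),
                     z = runif(n_elec, -50, 50))
  recording(patient_id, sessions, elec)
}

# Two unit-variance, zero-mean columns with an exact sample correlation r.
exact_corr_pair <- function(r, t_len = 64, seed = 1) {
  set.seed(seed)
  x <- rnorm(t_len)
  e <- rnorm(t_len)
  x <- (x - mean(x)) / sd(x)
  e <- e - mean(e)
  e <- e - x * sum(e * x) / sum(x * x) # exactly orthogonal to x
  e <- e / sd(e)
  cbind(x, r * x + sqrt(1 - r^2) * e)
}

# Literal double-loop evaluation of the pair sums over (i, j < i),
# symmetrized raw + transpose: the independent oracle for expand_patient.
brute_expand <- function(cmat, src, targets, lambda) {
  m <- nrow(targets)
  n <- nrow(src)
  W <- matrix(0, m, n)
  for (x in seq_len(m)) for (i in seq_len(n))
    W[x, i] <- exp(-sum((targets[x, ] - src[i, ])^2) / lambda)
  z <- fisher_z(pmin(pmax(cmat, -1 + 1e-6), 1 - 1e-6))
  num <- matrix(0, m, m)
  den <- matrix(0, m, m)
  for (x in seq_len(m)) for (y in seq_len(m)) {
    for (i in seq_len(n)) {
      j <- seq_len(i - 1L)
      if (length(j)) {
        num[x, y] <- num[x, y] + sum(W[x, i] * W[y, j] * z[i, j])
        den[x, y] <- den[x, y] + sum(W[x, i] * W[y, j])
      }
    }
  }
  num <- num + t(num)
  den <- den + t(den)
  diag(num) <- 0
  diag(den) <- 0
  list(numerator = num, denominator = den)
}

# Patient correlation object from explicit pieces.
patient_corr <- function(cmat, src, patient_id = "p") {
  rec <- recording(patient_id,
                   session_data(matrix(rnorm(10 * nrow(src)), 10), 250),
                   data.frame(electrode_id = sprintf("e%d", seq_len(nrow(src))),
                              x = src[, 1], y = src[, 2], z = src[, 3]))
  structure(list(patient_id = patient_id, electrodes = rec$electrodes,
                 matrix = cmat),
            class = "bg_patient_correlation")
}

# Draw T samples from N(0, K) with a fixed seed.
mvn_draw <- function(K, t_len, seed) {
  set.seed(seed)
  ch <- chol(K + 1e-10 * diag(nrow(K)))
  matrix(rnorm(t_len * nrow(K)), t_len) %*% ch
}

# Closed-form best-case reconstruction accuracy for a held-out index b
# observed from alpha, under the true correlation matrix.
theoretical_accuracy <- function(K, b, alpha) {
  kba <- K[b, alpha]
  sqrt(drop(kba %*% solve(K[alpha, alpha], kba)) / K[b, b])
}

rms <- function(x) sqrt(mean(x^2))
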