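test_that("RBF weights follow the closed form", {
  p <- matrix(c(1, 2, 3), 1)
  expect_equal(rbf_weights(p, p, 20)[1, 1], 1)
  q <- p + c(sqrt(20), 0, 0) # squared distance exactly lambda
  expect_equal(rbf_weights(p, q, 20)[1, 1], exp(-1))
  r <- p + c(10, 0, 0) # 10 mm at lambda = 20
  expect_equal(rbf_weights(p, r, 20)[1, 1], exp(-5))
  expect_error(rbf_weights(p, p, 0), "positive")
  set.seed(2)
  W <- rbf_weights(matrix(rnorm(12), 4), matrix(rnorm(9), 3), 20)
  expect_true(all(W > 0 & W <= 1))
})

test_that("Fisher z and its inverse are exact mutual inverses", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2)
  for (r in c(-0.9, -0.3, 0, 0.3, 0.7, 0.99))
    expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
})

test_that("session averaging matches the single- and two-session closed forms", {
  rec1 <- noise_recording(n_elec = 3, t_len = 120, n_sessions = 1, seed = 4)
  c1 <- session_average_correlations(rec1)
  expect_equal(c1$matrix, {
    m <- cor(rec1$sessions[[1]]$voltages)
    diag(m) <- 1
    dimnames(m) <- NULL
    m
  }, tolerance = 1e-12)

  rec2 <- recording("two", list(rec1$sessions[[1]],
                                session_data(rec1$sessions[[1]]$voltages, 250,
                                             "ses2")),
                    rec1$electrodes)
  expect_equal(session_average_correlations(rec2)$matrix, c1$matrix,
               tolerance = 1e-12)

  # correlations 0 and 0.6 average to exactly 1/3 through the z transform
  elec <- data.frame(electrode_id = c("a", "b"), x = c(0, 10), y = 0, z = 0)
  reca <- recording("ab",
                    list(session_data(exact_corr_pair(0), 250, "s1"),
                         session_data(exact_corr_pair(0.6), 250, "s2")),
                    elec)
  expect_equal(session_average_correlations(reca)$matrix[1, 2], 1 / 3,
               tolerance = 1e-9)
})

test_that("expansion matches the literal nested-loop pair sums", {
  set.seed(9)
  for (case in 1:3) {
    n <- sample(3:5, 1)
    m <- sample(4:6, 1)
    src <- matrix(runif(n * 3, -15, 15), n)
    targets <- matrix(runif(m * 3, -15, 15), m)
    cmat <- cor(matrix(rnorm(60 * n), 60, n))
    oracle <- brute_expand(cmat, src, targets, lambda = 20)
    got <- expansion_raw(expand_patient(patient_corr(cmat, src), targets, 20))
    expect_equal(got$numerator, oracle$numerator, tolerance = 1e-10)
    expect_equal(got$denominator, oracle$denominator, tolerance = 1e-10)
  }
})

test_that("a constant off-diagonal correlation survives expansion unchanged", {
  src <- matrix(runif(12, -10, 10), 4)
  cmat <- matrix(0.4, 4, 4)
  diag(cmat) <- 1
  targets <- matrix(runif(9, -10, 10), 3)
  part <- expand_patient(patient_corr(cmat, src), targets, 20)
  est <- fisher_z_inv(part$numerator / part$denominator)
  expect_equal(est[upper.tri(est)], rep(0.4, 3), tolerance = 1e-10)
})

test_that("expansion at vanishing width recovers the electrode correlations", {
  set.seed(12)
  src <- matrix(runif(12, -10, 10), 4)
  cmat <- cor(matrix(rnorm(200), 50, 4))
  part <- expand_patient(patient_corr(cmat, src), src, lambda = 1e-6)
  k <- materialize(merge_patients(list(part), src, lambda = 1e-6))
  expect_equal(k$matrix[upper.tri(k$matrix)], cmat[upper.tri(cmat)],
               tolerance = 1e-6)
})

test_that("merging matches a from-scratch evaluation of the weighted sums", {
  set.seed(21)
  targets <- matrix(runif(12, -15, 15), 4)
  raw_num <- matrix(0, 4, 4)
  raw_den <- matrix(0, 4, 4)
  parts <- list()
  for (s in 1:3) {
    n <- 3 + s %% 2
    src <- matrix(runif(n * 3, -15, 15), n)
    cmat <- cor(matrix(rnorm(80 * n), 80, n))
    oracle <- brute_expand(cmat, src, targets, 20)
    raw_num <- raw_num + oracle$numerator
    raw_den <- raw_den + oracle$denominator
    parts[[s]] <- expand_patient(patient_corr(cmat, src, paste0("p", s)),
                                 targets, 20)
  }
  k <- materialize(merge_patients(parts, targets, 20))
  expected <- fisher_z_inv(raw_num / raw_den)
  diag(expected) <- 1
  expect_equal(k$matrix, expected, tolerance = 1e-10)

  # single patient: merged model equals that patient's own estimate
  k1 <- materialize(merge_patients(parts[1], targets, 20))
  own <- fisher_z_inv(parts[[1]]$numerator / parts[[1]]$denominator)
  diag(own) <- 1
  expect_equal(k1$matrix, own, tolerance = 1e-10)

  # duplicated patient: sums cancel
  k11 <- materialize(merge_patients(parts[c(1, 1)], targets, 20))
  expect_equal(k11$matrix, k1$matrix, tolerance = 1e-12)
})

test_that("merge order never changes the materialized model", {
  set.seed(31)
  targets <- matrix(runif(15, -80, 80), 5)
  parts <- lapply(1:4, function(s) {
    src <- matrix(runif(9, -80, 80), 3)
    expand_patient(patient_corr(cor(matrix(rnorm(150), 50, 3)), src,
                                paste0("p", s)), targets, 20)
  })
  k_fwd <- materialize(merge_patients(parts, targets, 20))
  k_rev <- materialize(merge_patients(rev(parts), targets, 20))
  k_mix <- materialize(merge_patients(parts[c(3, 1, 4, 2)], targets, 20))
  expect_equal(k_rev$matrix, k_fwd$matrix, tolerance = 1e-12)
  expect_equal(k_mix$matrix, k_fwd$matrix, tolerance = 1e-12)
})

test_that("a far-away (zero-weight) patient leaves the model unchanged", {
  set.seed(41)
  targets <- matrix(runif(12, -10, 10), 4)
  near <- expand_patient(
    patient_corr(cor(matrix(rnorm(120), 40, 3)),
                 matrix(runif(9, -10, 10), 3), "near"), targets, 20)
  far <- expand_patient(
    patient_corr(cor(matrix(rnorm(120), 40, 3)),
                 matrix(runif(9, -10, 10), 3) + 1e5, "far"), targets, 20)
  k_near <- materialize(merge_patients(list(near), targets, 20))
  k_both <- materialize(merge_patients(list(near, far), targets, 20))
  expect_lt(max(abs(k_both$matrix - k_near$matrix)), 1e-6)
})

test_that("materialized models are valid correlation matrices", {
  set.seed(51)
  gt <- make_ground_truth(n_locations = 12, seed = 51)
  ds <- simulate_dataset(gt, sim_spec(n_patients = 3,
                                      electrodes_per_patient = 4,
                                      n_timepoints = 500, seed = 51))
  k <- materialize(build_model(lapply(ds$recordings, zscore_sessions)))
  expect_true(isSymmetric(k$matrix))
  expect_equal(unname(diag(k$matrix)), rep(1, nrow(k$matrix)))
  expect_true(all(abs(k$matrix[upper.tri(k$matrix)]) < 1))

  # all-zero numerator materializes to the identity correlation matrix
  zero <- merge_patients(list(list(
    numerator = matrix(0, 3, 3), denominator = matrix(1, 3, 3) - diag(3),
    log_scale = matrix(0, 3, 3), patient_id = "z")),
    matrix(rnorm(9), 3))
  expect_equal(materialize(zero)$matrix, diag(3))
})

test_that("distant location pairs keep positive denominators at lambda = 20", {
  # brain-scale geometry: raw weight products underflow but the scaled
  # accumulator still carries the dominant patient's contribution
  targets <- rbind(c(-80, -100, -60), c(80, 80, 90), c(0, 0, 0))
  src <- rbind(c(-79, -99, -59), c(79, 79, 89), c(1, 1, 1))
  part <- expand_patient(patient_corr(diag(3) * 0.5 + 0.5, src), targets, 20)
  model <- merge_patients(list(part), targets, 20)
  expect_true(all(model$denominator[upper.tri(model$denominator)] > 0))
  expect_silent(materialize(model))
})
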