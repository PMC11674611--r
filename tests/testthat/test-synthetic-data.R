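test_that("zero-coupling VAR gives independent white series and seeds reproduce", {
  A <- matrix(0, 4, 4)
  S1 <- simulate_var_sources(A, 1, n = 2000, noise_sd = 1, seed = 7)
  S2 <- simulate_var_sources(A, 1, n = 2000, noise_sd = 1, seed = 7)
  expect_identical(S1$data, S2$data)
  n <- ncol(S1$data)
  for (i in 1:3) for (j in (i + 1):4) {
    r <- cor(S1$data[i, -n], S1$data[j, -1])
    expect_lt(abs(r), 3 / sqrt(n))
  }
})

test_that("lag-1 cross-covariance of a 2-node chain matches the Yule-Walker solution", {
  A <- matrix(c(0, 0.5, 0, 0), 2, 2)    # x1 -> x2 with gain 0.5 (col drives row)
  yw <- yule_walker_var1(A, sigma2 = 1)
  S <- simulate_var_sources(A, 1, n = 5000, noise_sd = 1, seed = 3)
  x <- S$data
  n <- ncol(x)
  # sample cov(x2(t), x1(t-1)) vs G1[2, 1]
  emp <- mean((x[2, -1] - mean(x[2, ])) * (x[1, -n] - mean(x[1, ])))
  expect_lt(abs(emp - yw$G1[2, 1]) / abs(yw$G1[2, 1]), 0.05)
})

test_that("unstable VAR and bad arguments are rejected", {
  A <- diag(1.2, 3)
  expect_error(simulate_var_sources(A, 1, n = 500), class = "hbnet_stability_error")
  expect_error(simulate_var_sources(diag(0.5, 3), 1, n = 500, noise_sd = -1),
               class = "hbnet_argument_error")
  expect_error(simulate_var_sources(diag(0.5, 3), 2, n = 15),
               class = "hbnet_argument_error")
})

test_that("implied VAR is stable for many random generator configurations", {
  set.seed(42)
  for (rep_i in 1:100) {
    c_ <- sample(3:10, 1)
    p <- sample(1:3, 1)
    base <- hbnet:::.base_adjacency(c_, sample(2:8, 1), runif(1, 0.2, 0.6),
                                    runif(1, 0.2, 0.5))
    adj <- hbnet:::.stabilize_adjacency(
      hbnet:::.perturb(base, runif(1, 0, 1), 0.2, off_diag_only = TRUE),
      var_order = p)
    expect_lt(var_spectral_radius(adj, p), 1)
  }
})

test_that("scalp projection follows X = L J + noise", {
  S <- simulate_var_sources(diag(0.3, 3), 1, n = 10000, seed = 5)
  # identity lead field, one dipole per region, no noise: X equals S
  X <- project_to_scalp(S, diag(3), 1:3, sensor_noise_sd = 0)
  expect_equal(X, S$data)
  # zero sources: X is pure noise with the requested sd
  S0 <- S; S0$data <- matrix(0, 3, 10000)
  X0 <- project_to_scalp(S0, diag(3), 1:3, sensor_noise_sd = 1, seed = 1)
  expect_lt(abs(sd(X0) - 1) / 1, 0.1)
  # random L: residual X - L J has per-entry sd matching sensor noise
  L <- matrix(rnorm(8 * 20), 8, 20)
  memb <- rep(1:3, length.out = 20)
  Xr <- project_to_scalp(S, L, memb, sensor_noise_sd = 0.7, seed = 2)
  resid <- Xr - L %*% S$data[memb, ]
  expect_lt(abs(sd(resid) - 0.7) / 0.7, 0.05)
  expect_error(project_to_scalp(S, L, rep(5, 20)), class = "hbnet_index_error")
})

test_that("simulated fNIRS is the weight-mixed HRF prediction and is linear in weights", {
  S <- simulate_var_sources(diag(0.3, 2), 1, n = 3000, seed = 11)
  # zero weights -> pure noise with mean ~ 0
  Y0 <- simulate_fnirs(S, matrix(0, 2, 2), noise_sd = 0.5, seed = 4)
  expect_lt(abs(mean(Y0)), 0.05)
  # single source, unit weight, no noise: equals predict_fnirs exactly
  S1 <- source_signals(S$data[1, , drop = FALSE], fs = S$fs)
  y1 <- simulate_fnirs(S1, matrix(1, 1, 1), noise_sd = 0)
  k <- hrf_kernel(S$fs)
  p1 <- timevarying_power(stft_power(S$data[1, ], S$fs))
  expect_equal(as.vector(y1), predict_fnirs(p1, k))
  # superposition: weights (1, 2) = 1*yhat1 + 2*yhat2 to machine precision
  y12 <- simulate_fnirs(S, matrix(c(1, 2), 2, 1), noise_sd = 0)
  ya <- simulate_fnirs(S, matrix(c(1, 0), 2, 1), noise_sd = 0)
  yb <- simulate_fnirs(S, matrix(c(0, 1), 2, 1), noise_sd = 0)
  expect_lt(max(abs(y12 - (ya + 2 * yb))) / max(abs(y12)), 1e-10)
  expect_error(simulate_fnirs(S, matrix(1, 3, 1)), class = "hbnet_argument_error")
})

test_that("dataset generation is balanced, deterministic, and null at zero effect size", {
  cfg <- sim_config(n_classes = 4, trials_per_class = 3, regions = 4,
                    fnirs_channels = 2, electrodes = 6, dipoles_per_region = 2,
                    duration_s = 6)
  ds <- simulate_dataset(cfg, seed = 21)
  expect_length(ds$trials, 12)
  expect_equal(as.integer(table(vapply(ds$trials, `[[`, integer(1), "label"))),
               rep(3L, 4))
  dims <- vapply(ds$trials, function(tr) dim(tr$eeg), integer(2))
  expect_true(all(dims[1, ] == 6) && all(dims[2, ] == dims[2, 1]))
  # equal duration across modalities
  tr <- ds$trials[[1]]
  expect_equal(ncol(tr$eeg) / ds$fs_eeg, ncol(tr$fnirs) / ds$fs_fnirs)
  ds2 <- simulate_dataset(cfg, seed = 21)
  expect_identical(ds$trials, ds2$trials)
  expect_identical(ds$ground_truth$adjacency, ds2$ground_truth$adjacency)
  # zero effect size: all class templates identical
  cfg0 <- sim_config(n_classes = 3, trials_per_class = 1, regions = 4,
                     fnirs_channels = 2, electrodes = 6, dipoles_per_region = 2,
                     duration_s = 6, effect_size = 0)
  ds0 <- simulate_dataset(cfg0, seed = 5)
  expect_equal(ds0$ground_truth$adjacency[[1]], ds0$ground_truth$adjacency[[3]])
  expect_equal(ds0$ground_truth$coupling_weights[[1]],
               ds0$ground_truth$coupling_weights[[2]])
  expect_error(sim_config(effect_size = -1), class = "hbnet_argument_error")
})
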