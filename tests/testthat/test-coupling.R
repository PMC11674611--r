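test_that("STFT power matches a brute-force windowed DFT", {
  set.seed(4)
  s <- rnorm(256)
  fs <- 64
  P <- stft_power(s, fs, win_s = 0.5, hop_s = 0.25)   # win 32, hop 16
  ref <- brute_stft_power(s, fs, win = 32, hop = 16)
  expect_equal(dim(P$power), dim(ref))
  expect_lt(max(abs(P$power - ref)) / max(ref), 1e-8)
  # zero signal -> all-zero spectrogram
  expect_true(all(stft_power(numeric(256), fs, 0.5, 0.25)$power == 0))
  # spectral peak of a 10 Hz tone lands at the bin nearest 10 Hz
  t <- seq(0, 5, by = 1 / 200)
  P10 <- stft_power(sin(2 * pi * 10 * t), 200, 1, 0.1)
  peak_bin <- which.max(colMeans(P10$power))
  expect_equal(peak_bin, which.min(abs(P10$freqs - 10)))
  expect_error(stft_power(rnorm(50), 200, 1, 0.1), class = "hbnet_argument_error")
})

test_that("time-varying power is normalized, ordered, and degenerate-safe", {
  t <- seq(0, 10, by = 1 / 200)
  # constant-amplitude tone: nearly flat frame power
  P <- stft_power(sin(2 * pi * 10 * t), 200, 1, 0.1)
  tv <- timevarying_power(P)
  expect_lt(diff(range(tv$p)), 0.2)
  expect_true(all(tv$p >= 0 & tv$p <= 1))
  expect_length(tv$p, length(t))
  # burst in the second half dominates
  burst <- c(0.2 * sin(2 * pi * 10 * t[1:1000]), sin(2 * pi * 10 * t[1001:2001]))
  tvb <- timevarying_power(stft_power(burst, 200, 1, 0.1))
  expect_gt(mean(tvb$p[1001:2001]), mean(tvb$p[1:1000]))
  # all-zero signal -> all-zero output
  tz <- timevarying_power(stft_power(numeric(2001), 200, 1, 0.1))
  expect_true(all(tz$p == 0))
  expect_error(timevarying_power(P, f_min = 150, f_max = 160),
               class = "hbnet_argument_error")
})

test_that("the HRF kernel matches its closed form: zero onset, ~5 s peak, undershoot", {
  k <- hrf_kernel(100)
  expect_equal(k$samples[1], 0)
  t_grid <- seq(0, 32, by = 1 / 100)
  expect_equal(k$samples, hrf_closed_form(t_grid), tolerance = 1e-12)
  peak_t <- t_grid[which.max(k$samples)]
  ref_peak <- optimize(hrf_closed_form, c(2, 10), maximum = TRUE)$maximum
  expect_gt(peak_t, 4.5); expect_lt(peak_t, 5.5)
  expect_lt(abs(peak_t - ref_peak), 0.02)
  expect_lt(hrf_closed_form(15), 0)
  expect_lt(k$samples[which.min(abs(t_grid - 15))], 0)
  # exactly one sign change after the positive peak within the support
  sgn <- sign(k$samples[-1])
  expect_equal(sum(diff(sgn) != 0), 1)
})

test_that("HRF prediction is the dt-scaled truncated convolution", {
  k <- hrf_kernel(20, duration_s = 10)
  # unit impulse at t = 0 reproduces the kernel (x dt)
  p <- c(1, numeric(99))
  expect_equal(predict_fnirs(p, k), k$samples[1:100] * k$dt, tolerance = 1e-12)
  expect_equal(predict_fnirs(numeric(50), k), numeric(50))
  # brute-force O(n m) sum on a random fixture
  set.seed(9)
  pv <- runif(500)
  expect_equal(predict_fnirs(pv, k), brute_conv(pv, k$samples, k$dt),
               tolerance = 1e-10)
})

test_that("GLM fitting recovers exact coefficients and matches normal equations", {
  set.seed(12)
  D <- matrix(rnorm(600 * 8), 600, 8)
  B <- matrix(rnorm(8 * 3), 8, 3)
  expect_equal(glm_fit(D, D %*% B), B, tolerance = 1e-8)
  # orthonormal design: beta = D' Y
  Q <- qr.Q(qr(matrix(rnorm(100 * 4), 100, 4)))
  Y <- matrix(rnorm(100 * 2), 100, 2)
  expect_equal(glm_fit(Q, Y), t(Q) %*% Y, tolerance = 1e-10)
  # random well-conditioned fixture vs brute-force normal equations
  Yn <- D %*% B + matrix(rnorm(600 * 3, sd = 0.1), 600, 3)
  expect_equal(glm_fit(D, Yn), brute_ols(D, Yn), tolerance = 1e-8)
  expect_error(glm_fit(matrix(0, 10, 2), matrix(rnorm(10), 10, 1)),
               class = "hbnet_degenerate_design_error")
  # all-zero columns are dropped with a warning and zero coefficients
  D0 <- cbind(D[, 1:2], 0)
  expect_warning(b0 <- glm_fit(D0, Yn), "all-zero")
  expect_equal(b0[3, ], c(0, 0, 0))
})

test_that("coupling strengths are absolute coefficients and idempotent", {
  b <- matrix(c(-1, 2), 1, 2)
  cm <- coupling_matrix(b)
  expect_equal(cm$cs, abs(b))
  expect_identical(coupling_matrix(cm), cm)
  set.seed(1)
  expect_true(all(coupling_matrix(matrix(rnorm(12), 3, 4))$cs >= 0))
})

test_that("trial-level coupling recovers forward-model weights without noise", {
  set.seed(22)
  A <- diag(0.3, 4)
  S <- simulate_var_sources(A, 1, n = 6000, seed = 33)
  W <- matrix(runif(8, 0.5, 1.5), 4, 2)
  Y <- simulate_fnirs(S, W, noise_sd = 0)
  cs <- trial_coupling(S, Y)
  expect_length(cs, length(segment_windows(S$data, 200)))
  m <- Reduce(`+`, lapply(cs, `[[`, "cs")) / length(cs)
  expect_gte(cor(as.vector(m), as.vector(W)), 0.95)
  expect_error(trial_coupling(S, Y[, 1:100]), class = "hbnet_alignment_error")
})

test_that("scalar source-channel coupling is recovered in every window", {
  S <- simulate_var_sources(matrix(0.3, 1, 1), 1, n = 4000, seed = 44)
  Y <- simulate_fnirs(S, matrix(2, 1, 1), noise_sd = 0)
  cs <- trial_coupling(S, Y)
  for (w in cs) expect_lt(abs(w$cs[1, 1] - 2) / 2, 0.05)
})
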