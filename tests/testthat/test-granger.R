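test_that("window detrending removes exact lines and matches least squares", {
  fs <- 100
  tt <- seq_len(300)
  line <- 2 + 0.05 * tt
  x <- rbind(line, rev(line))
  w <- detrend_window(make_window(x, fs))
  expect_lt(max(abs(w$data)), 1e-10)
  set.seed(3)
  y <- matrix(rnorm(600), 2, 300)
  wd <- detrend_window(make_window(y, fs))
  expect_lt(max(abs(colMeans(wd$data))), 1e-10)
  # equals input minus brute-force degree-1 polynomial fit
  for (j in 1:2) {
    fit <- lm(y[j, ] ~ tt)
    expect_equal(wd$data[, j], unname(y[j, ] - fitted(fit)), tolerance = 1e-10)
  }
})

test_that("BIC order selection finds a strong VAR(2) and defaults to 1 on noise", {
  hits <- 0L
  for (rep_i in 1:50) {
    S <- simulate_var_sources(diag(0.5, 2), var_order = 2, n = 2000,
                              seed = 100 + rep_i, lag_decay = 0.6)  # lags 0.5, 0.3
    w <- detrend_window(make_window(S$data, 200))
    if (select_order(w, p_max = 4) == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 45L)   # >= 90% of replicates
  noise_hits <- 0L
  for (rep_i in 1:20) {
    set.seed(200 + rep_i)
    w <- detrend_window(make_window(matrix(rnorm(2 * 2000), 2), 200))
    if (select_order(w, p_max = 4) == 1L) noise_hits <- noise_hits + 1L
  }
  expect_gt(noise_hits, 10L)
  w1 <- make_window(matrix(rnorm(400), 2), 100)
  expect_identical(select_order(w1, p_max = 1), 1L)
})

test_that("pairwise Granger strength is small under the null, large for a driven pair", {
  set.seed(31)
  F_null <- replicate(100, granger_pair(rnorm(600), rnorm(600), p = 2))
  expect_lt(mean(F_null), 0.02)
  expect_true(all(F_null >= 0))
  # a(t) = 0.9 b(t-1) + tiny noise
  b <- rnorm(600)
  a <- c(0, 0.9 * b[-600]) + rnorm(600, sd = 0.05)
  expect_gt(granger_pair(a, b, p = 1), 1)
})

test_that("Granger statistic equals brute-force normal-equations OLS", {
  set.seed(8)
  a <- rnorm(400); b <- 0.4 * c(0, a[-400]) + rnorm(400)
  p <- 3; r <- 400
  lag_mat <- function(x) sapply(1:p, function(k) x[(p + 1 - k):(r - k)])
  y <- a[(p + 1):r]
  Xr <- lag_mat(a); Xf <- cbind(Xr, lag_mat(b))
  rss <- function(X) sum((y - X %*% brute_ols(X, y))^2)
  expect_equal(granger_pair(a, b, p), log(rss(Xr) / rss(Xf)), tolerance = 1e-10)
  # scale invariance
  expect_equal(granger_pair(3.7 * a, 3.7 * b, p), granger_pair(a, b, p),
               tolerance = 1e-10)
  expect_error(granger_pair(rep(1, 100), rnorm(100), 2), class = "hbnet_numerical_error")
})

test_that("null calibration: (r-p) * F follows chi-square(p)", {
  set.seed(77)
  r <- 600; p <- 2
  F_null <- replicate(300, granger_pair(rnorm(r), rnorm(r), p))
  q_emp <- unname(quantile((r - p) * F_null, 0.95))
  q_theo <- qchisq(0.95, df = p)
  expect_lt(abs(q_emp - q_theo) / q_theo, 0.25)
})

test_that("the causal matrix is the arrangement of pairwise fits with zero diagonal", {
  set.seed(5)
  x <- matrix(rnorm(2 * 500), 2, 500)
  w <- detrend_window(make_window(x, 100))
  cm <- causal_matrix(w, p = 2)
  expect_equal(cm$g[1, 2], granger_pair(w$data[, 2], w$data[, 1], 2))
  expect_equal(cm$g[2, 1], granger_pair(w$data[, 1], w$data[, 2], 2))
  expect_equal(diag(cm$g), c(0, 0))
  expect_true(all(cm$g >= 0))
})

test_that("independent sources give a near-zero causal matrix on average", {
  set.seed(19)
  maxima <- replicate(60, {
    w <- detrend_window(make_window(matrix(rnorm(4 * 600), 4), 200))
    g <- causal_matrix(w, p = 2)$g
    max(g[row(g) != col(g)])
  })
  expect_lt(mean(maxima), 0.05)
})

test_that("a causal chain is recovered with the right edge ordering", {
  A <- chain_adjacency(3, list(c(1, 2), c(2, 3)), gain = 0.4, self = 0.3)
  gs <- lapply(1:20, function(i) {
    S <- simulate_var_sources(A, 1, n = 600, seed = 400 + i)
    causal_matrix(detrend_window(make_window(S$data, 200)), p = 2)$g
  })
  g_mean <- Reduce(`+`, gs) / length(gs)
  expect_gt(g_mean[1, 2], g_mean[2, 1])
  expect_gt(g_mean[2, 3], g_mean[3, 2])
  expect_gt(g_mean[1, 2], g_mean[1, 3])
  expect_gt(g_mean[2, 3], g_mean[1, 3])
})
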