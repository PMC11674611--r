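# Independent oracles used to freeze expected values: each reimplements the
# quantity under test by a different route (dense algebra, brute-force sums,
# closed forms) and must stay independent of the package internals it checks.

# Stationary covariance of a VAR(1) x_t = A x_{t-1} + e_t via the discrete
# Lyapunov equation vec(G0) = (I - A (x) A)^{-1} vec(Sigma).
yule_walker_var1 <- function(A, sigma2 = 1) {
  c_ <- nrow(A)
  Sig <- diag(sigma2, c_)
  g0 <- solve(diag(c_^2) - kronecker(A, A), as.vector(Sig))
  G0 <- matrix(g0, c_, c_)
  list(G0 = G0, G1 = A %*% G0)   # G1[i, j] = cov(x_i(t), x_j(t-1))
}

# Normal-equations OLS (deliberately the naive route).
brute_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# O(n*m) direct convolution sum, scaled by dt, first n samples.
brute_conv <- function(p, k, dt) {
  n <- length(p); m <- length(k)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (j in seq_len(min(t, m))) acc <- acc + p[t - j + 1] * k[j]
    out[t] <- acc * dt
  }
  out
}

# Direct windowed DFT magnitude-squared spectrogram (Hann window), matching
# frame offsets 1, 1+hop, ... <= n - win (the last partial frame dropped).
brute_stft_power <- function(s, fs, win, hop) {
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, win - 1) / (win - 1))
  starts <- if (length(s) > win) seq(1, length(s) - win, by = hop) else 1
  n_bins <- if (win %% 2 == 1) (win + 1) / 2 else win / 2
  P <- matrix(0, length(starts), n_bins)
  for (fi in seq_len(n_bins)) {
    f <- fi - 1
    for (si in seq_along(starts)) {
      fr <- s[starts[si]:(starts[si] + win - 1)] * hann
      re <- sum(fr * cos(-2 * pi * f * seq(0, win - 1) / win))
      im <- sum(fr * sin(-2 * pi * f * seq(0, win - 1) / win))
      P[si, fi] <- re^2 + im^2
    }
  }
  P
}

# Rank-based AUC of scores against binary truth.
rank_auc <- function(scores, truth) {
  r <- rank(scores)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Closed-form double-gamma HRF evaluated without dgamma().
hrf_closed_form <- function(t) {
  g <- function(t, d) t^(d - 1) * exp(-t) / gamma(d)
  g(t, 6) - g(t, 16) / 16
}

# Small detrended window fixture from a series matrix (series x time).
make_window <- function(x, fs = 200) {
  segment_windows(x, fs, window_s = ncol(x) / fs, step_s = ncol(x) / fs)[[1]]
}

# Stable sparse adjacency used across network tests.
chain_adjacency <- function(c_, edges, gain = 0.3, self = 0.3) {
  A <- diag(self, c_)
  for (e in edges) A[e[2], e[1]] <- gain   # column drives row: e[1] -> e[2]
  A
}
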