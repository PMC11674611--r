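#' Remove linear trends from a window
#'
#' Granger analysis assumes (weak) stationarity; windows are therefore
#' detrended before model fitting. A least-squares straight line is removed
#' from every series, which also zeroes its mean.
#'
#' @param w A `window_sample` (time-major `r x m`) from [segment_windows()].
#' @return The detrended `window_sample`.
#' @export
detrend_window <- function(w) {
  if (!inherits(w, "window_sample"))
    stop_hbnet("`w` must be a window_sample", "hbnet_argument_error")
  r <- nrow(w$data)
  if (r < 3L) stop_hbnet("window too short to detrend (need r >= 3)", "hbnet_argument_error")
  tt <- seq_len(r)
  X <- cbind(1, tt)
  w$data <- w$data - X %*% qr.coef(qr(X), w$data)
  w
}

# Lag design matrix: columns are x(t-1)..x(t-p) aligned with targets x(p+1..r).
.lags <- function(x, p) {
  E <- stats::embed(x, p + 1L)
  E[, -1L, drop = FALSE]
}

.rss <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Pairwise Granger causality
#'
#' Measures how much the past of a driver series `b` improves linear
#' prediction of a target series `a` beyond `a`'s own past. Both models are
#' fit by ordinary least squares on the same `r - p` target points: a
#' restricted autoregression of `a` on its own `p` lags, and a full
#' regression adding the `p` lags of `b`. The statistic is the log ratio of
#' residual variances, `F = ln(var(restricted)/var(full))`, which is
#' nonnegative because the models are nested and share the estimator.
#'
#' @param a Numeric vector, the target series (detrended).
#' @param b Numeric vector, the candidate driver series (detrended).
#' @param p Model order (maximum lag), a positive integer.
#' @return The causality strength `F_{b -> a}`, a nonnegative scalar.
#' @export
granger_pair <- function(a, b, p) {
  a <- as.numeric(a); b <- as.numeric(b)
  r <- length(a)
  if (length(b) != r) stop_hbnet("series lengths differ", "hbnet_argument_error")
  p <- as.integer(p)
  if (p < 1L) stop_hbnet("`p` must be >= 1", "hbnet_argument_error")
  if (r <= 2L * p + 1L) stop_hbnet("series too short for order p", "hbnet_argument_error")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_hbnet("constant series: Granger regression is degenerate", "hbnet_numerical_error")
  y <- a[(p + 1L):r]
  Xa <- .lags(a, p)
  Xf <- cbind(Xa, .lags(b, p))
  rss_r <- .rss(Xa, y)
  rss_f <- .rss(Xf, y)
  if (rss_f <= 0)
    stop_hbnet("full-model residual variance is zero (collinear series?)", "hbnet_numerical_error")
  max(log(rss_r / rss_f), 0)
}

#' Select the VAR model order by BIC
#'
#' Chooses one shared lag order for a window by pooling the Bayesian
#' information criterion over all unordered series pairs. For each candidate
#' `p`, every pair is fit as a bivariate VAR(p) by OLS and scored with
#' `BIC = ln det(residual covariance) + k ln(N)/N` (`k` = coefficient count,
#' `N = r - p` target points); the pooled score is the mean over pairs and
#' ties break toward the smaller order.
#'
#' @param w A detrended `window_sample`.
#' @param p_max Largest candidate order (default 10).
#' @return The selected order, an integer in `1..p_max`.
#' @export
select_order <- function(w, p_max = 10L) {
  if (!inherits(w, "window_sample"))
    stop_hbnet("`w` must be a window_sample", "hbnet_argument_error")
  p_max <- as.integer(p_max)
  if (p_max < 1L) stop_hbnet("`p_max` must be >= 1", "hbnet_argument_error")
  if (p_max == 1L) return(1L)
  r <- nrow(w$data); m <- ncol(w$data)
  if (r <= 10L * p_max)
    stop_hbnet("window too short for requested p_max (need r > 10*p_max)", "hbnet_argument_error")
  pairs <- utils::combn(m, 2L)
  score <- vapply(seq_len(p_max), function(p) {
    N <- r - p
    k <- 4L * p
    bics <- apply(pairs, 2L, function(ij) {
      yi <- w$data[(p + 1L):r, ij[1L]]
      yj <- w$data[(p + 1L):r, ij[2L]]
      X <- cbind(.lags(w$data[, ij[1L]], p), .lags(w$data[, ij[2L]], p))
      res <- cbind(stats::.lm.fit(X, yi)$residuals, stats::.lm.fit(X, yj)$residuals)
      Sig <- crossprod(res) / N
      dt <- det(Sig)
      if (dt <= 0) return(Inf)
      log(dt) + k * log(N) / N
    })
    mean(bics)
  }, numeric(1L))
  which.min(score)  # which.min returns the first (smallest p) on ties
}

#' Directed causal matrix of a window
#'
#' Runs [granger_pair()] over every ordered pair of series in a window,
#' producing the asymmetric adjacency matrix of the causal brain network:
#' entry `(i, j)` is the strength with which series `i` drives series `j`.
#' Self-causality is undefined under the bivariate model, so the diagonal is
#' fixed at zero by convention.
#'
#' @param w A detrended `window_sample` with `c` series.
#' @param p Model order; `NULL` selects it with [select_order()].
#' @param p_max Passed to [select_order()] when `p` is `NULL`.
#' @return An object of class `causal_matrix`: list with `g` (`c x c`
#'   nonnegative matrix), the fitted `order`, and the window's `t_start`,
#'   `trial_id` and `label`.
#' @export
causal_matrix <- function(w, p = NULL, p_max = 10L) {
  if (!inherits(w, "window_sample"))
    stop_hbnet("`w` must be a window_sample", "hbnet_argument_error")
  if (is.null(p)) p <- select_order(w, p_max)
  p <- as.integer(p)
  r <- nrow(w$data); m <- ncol(w$data)
  if (r <= 2L * p + 1L) stop_hbnet("window too short for order p", "hbnet_argument_error")
  lag_blocks <- lapply(seq_len(m), function(i) .lags(w$data[, i], p))
  targets <- w$data[(p + 1L):r, , drop = FALSE]
  rss_restricted <- vapply(seq_len(m), function(j) .rss(lag_blocks[[j]], targets[, j]),
                           numeric(1L))
  g <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      rss_f <- tryCatch(.rss(cbind(lag_blocks[[j]], lag_blocks[[i]]), targets[, j]),
                        error = function(e)
                          stop_hbnet(sprintf("pair (%d, %d): %s", i, j, conditionMessage(e)),
                                     "hbnet_numerical_error"))
      if (rss_f <= 0)
        stop_hbnet(sprintf("pair (%d, %d): zero full-model residual variance", i, j),
                   "hbnet_numerical_error")
      g[i, j] <- max(log(rss_restricted[j] / rss_f), 0)
    }
  }
  structure(list(g = g, order = p, t_start = w$t_start,
                 trial_id = w$trial_id, label = w$label),
            class = "causal_matrix")
}

#' @export
print.causal_matrix <- function(x, ...) {
  cat(sprintf("<causal_matrix> %d x %d, VAR order %d, t_start = %g s\n",
              nrow(x$g), ncol(x$g), x$order, x$t_start))
  invisible(x)
}
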