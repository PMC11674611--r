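#' Short-time Fourier transform power spectrogram
#'
#' Squared-magnitude STFT of one source series, computed with a Hann window
#' (via `signal::specgram`). Defaults of a 1 s window advanced by 0.1 s
#' resolve the 0.5-45 Hz EEG band while still tracking second-scale power
#' fluctuations of emotion-video stimuli.
#'
#' @param s Numeric vector, one source time series.
#' @param fs Sampling rate in Hz.
#' @param win_s STFT window length in seconds (default 1).
#' @param hop_s Hop between successive frames in seconds (default 0.1).
#' @return An object of class `stft_power`: list with `power` (frames x
#'   frequency bins, nonnegative), `freqs` (Hz, spanning 0 to just below
#'   fs/2), `times` (frame-center times in seconds), `fs`, and the input
#'   length `n`.
#' @export
stft_power <- function(s, fs, win_s = 1, hop_s = 0.1) {
  s <- as.numeric(s)
  check_number(fs, "fs", positive = TRUE)
  win <- round(win_s * fs)
  hop <- max(1L, round(hop_s * fs))
  if (win < 8L) stop_hbnet("STFT window must cover at least 8 samples", "hbnet_argument_error")
  if (win > length(s))
    stop_hbnet("STFT window longer than the series", "hbnet_argument_error")
  sp <- signal::specgram(s, n = win, Fs = fs, window = signal::hanning(win),
                         overlap = win - hop)
  starts <- if (length(s) > win) seq(1L, length(s) - win, by = hop) else 1L
  structure(list(power = t(Mod(sp$S)^2),
                 freqs = as.numeric(sp$f),
                 times = (starts - 1 + (win - 1) / 2) / fs,
                 fs = fs, n = length(s)),
            class = "stft_power")
}

#' Normalized time-varying band power
#'
#' Sums spectrogram power over a frequency band, min-max normalizes the
#' frame series to `[0, 1]` (a constant series maps to all zeros, the
#' degenerate-normalization rule), and linearly interpolates the
#' frame-centered values back onto the full sample grid of the source
#' signal. The result models the momentary stimulus intensity carried by
#' that source.
#'
#' @param P An `stft_power` object.
#' @param f_min,f_max Band edges in Hz (defaults 0.5 and 45, the EEG band).
#' @return An object of class `tv_power`: list with `p` (length-`n` vector in
#'   `[0, 1]`) and `fs`.
#' @export
timevarying_power <- function(P, f_min = 0.5, f_max = 45) {
  if (!inherits(P, "stft_power"))
    stop_hbnet("`P` must come from stft_power()", "hbnet_argument_error")
  band <- which(P$freqs >= f_min & P$freqs <= f_max)
  if (length(band) == 0L)
    stop_hbnet("frequency band contains no spectrogram bins", "hbnet_argument_error")
  frame_p <- rowSums(P$power[, band, drop = FALSE])
  rng <- max(frame_p) - min(frame_p)
  # effectively-constant power (incl. machine-level ripple) maps to zeros
  frame_p <- if (rng <= 1e-8 * max(abs(frame_p), 1)) rep(0, length(frame_p))
             else (frame_p - min(frame_p)) / rng
  grid <- (seq_len(P$n) - 1) / P$fs
  p <- if (length(frame_p) == 1L) rep(frame_p, P$n)
       else stats::approx(P$times, frame_p, xout = grid, rule = 2)$y
  structure(list(p = p, fs = P$fs), class = "tv_power")
}

#' Canonical hemodynamic response function kernel
#'
#' Samples the canonical double-gamma HRF
#' `HRF(t) = g(t, 6) - g(t, 16)/16` with `g(t, d) = t^(d-1) e^(-t) / Gamma(d)`
#' (t in seconds) on a uniform grid. The kernel is 0 at `t = 0`, peaks near
#' 5 s, and shows the characteristic post-peak undershoot before decaying
#' within the 32 s support.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Kernel support in seconds (default 32).
#' @return An object of class `hrf_kernel`: list with `samples` and the
#'   sample spacing `dt` in seconds.
#' @export
hrf_kernel <- function(fs, duration_s = 32) {
  check_number(fs, "fs", positive = TRUE)
  check_number(duration_s, "duration_s", positive = TRUE)
  t <- seq(0, duration_s, by = 1 / fs)
  structure(list(samples = stats::dgamma(t, shape = 6) -
                   stats::dgamma(t, shape = 16) / 16,
                 dt = 1 / fs),
            class = "hrf_kernel")
}

#' Predicted fNIRS signal from source power
#'
#' Convolves a normalized time-varying power envelope with the canonical HRF
#' (full discrete convolution scaled by the sample spacing `dt`, making the
#' result invariant to the sampling rate) and keeps the first `n` samples so
#' the prediction stays aligned with the source signal.
#'
#' @param p A `tv_power` object or numeric vector.
#' @param k An `hrf_kernel` from [hrf_kernel()].
#' @return Numeric vector of length `n` (the length of `p`).
#' @export
predict_fnirs <- function(p, k) {
  if (!inherits(k, "hrf_kernel"))
    stop_hbnet("`k` must come from hrf_kernel()", "hbnet_argument_error")
  pv <- if (inherits(p, "tv_power")) p$p else as.numeric(p)
  n <- length(pv)
  full <- stats::convolve(pv, rev(k$samples), type = "open") * k$dt
  full[seq_len(n)]
}

#' General linear model fit of measured fNIRS on predicted fNIRS
#'
#' Solves the least-squares problem `Y = D beta + eps` where the design
#' matrix `D` holds the HRF-convolved source power predictions of a window
#' and `Y` the measured fNIRS window. All-zero design columns (sources with
#' degenerate power normalization) are dropped with a warning and their
#' coefficients reported as 0; a rank-deficient design falls back to the
#' minimum-norm pseudoinverse solution with a warning.
#'
#' @param D Numeric matrix, time points x sources (`r x c`).
#' @param Y Numeric matrix, time points x fNIRS channels (`r x d`).
#' @return Coefficient matrix `beta`, sources x channels (`c x d`).
#' @export
glm_fit <- function(D, Y) {
  check_matrix(D, "D")
  check_matrix(Y, "Y")
  if (nrow(D) != nrow(Y))
    stop_hbnet("D and Y must have the same number of time points", "hbnet_argument_error")
  keep <- colSums(D != 0) > 0L
  if (!any(keep))
    stop_hbnet("design matrix is all zeros: degenerate design", "hbnet_degenerate_design_error")
  if (!all(keep))
    warning(sprintf("dropping %d all-zero design column(s): %s",
                    sum(!keep), paste(which(!keep), collapse = ", ")))
  Dk <- D[, keep, drop = FALSE]
  qrD <- qr(Dk)
  beta <- matrix(0, ncol(D), ncol(Y))
  if (qrD$rank < ncol(Dk)) {
    warning("rank-deficient design; using minimum-norm pseudoinverse solution")
    sv <- svd(Dk)
    pos <- sv$d > max(dim(Dk)) * .Machine$double.eps * sv$d[1L]
    beta[keep, ] <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], Y)) / sv$d[pos])
  } else {
    beta[keep, ] <- qr.coef(qrD, Y)
  }
  if (!is.null(colnames(D)) || !is.null(colnames(Y)))
    dimnames(beta) <- list(colnames(D), colnames(Y))
  beta
}

#' Coupling matrix from GLM coefficients
#'
#' The coupling strength between source `i` and fNIRS channel `j` is the
#' absolute value of the fitted GLM coefficient `beta[i, j]`; signs carry no
#' meaning for edge strength in the coupled network.
#'
#' @param beta Coefficient matrix from [glm_fit()] (`c x d`), or an existing
#'   `coupling_matrix` (returned unchanged, making the operation idempotent).
#' @param t_start,trial_id,label Optional window provenance.
#' @return An object of class `coupling_matrix` with nonnegative `cs`.
#' @export
coupling_matrix <- function(beta, t_start = NA_real_, trial_id = NA_integer_,
                            label = NA) {
  if (inherits(beta, "coupling_matrix")) return(beta)
  check_matrix(beta, "beta")
  structure(list(cs = abs(beta), t_start = t_start,
                 trial_id = trial_id, label = label),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("<coupling_matrix> %d sources x %d channels, t_start = %g s\n",
              nrow(x$cs), ncol(x$cs), x$t_start))
  invisible(x)
}

# Predicted fNIRS series for every source of a trial: n x c matrix.
.predicted_matrix <- function(S, stft_win_s = 1, stft_hop_s = 0.1,
                              f_min = 0.5, f_max = 45, hrf_duration_s = 32) {
  stopifnot(inherits(S, "source_signals"))
  k <- hrf_kernel(S$fs, hrf_duration_s)
  n <- ncol(S$data)
  vapply(seq_len(nrow(S$data)), function(i) {
    P <- stft_power(S$data[i, ], S$fs, stft_win_s, stft_hop_s)
    predict_fnirs(timevarying_power(P, f_min, f_max), k)
  }, numeric(n))
}

#' Per-window coupling matrices of a trial
#'
#' Full coupling-network computation for one trial: the normalized
#' time-varying power of every source signal is convolved with the canonical
#' HRF to give predicted fNIRS series on the whole trial (normalization is
#' per trial, before segmentation), then predicted and measured streams are
#' segmented identically (3 s windows, 1.5 s step by default) and one GLM is
#' fit per window, yielding one coupling matrix per window.
#'
#' @param S A [source_signals()] object (`c x n` at fs, typically 200 Hz).
#' @param Y_measured Numeric matrix of measured fNIRS, channels x samples
#'   (`d x n`), already preprocessed and resampled to the fs of `S`.
#' @param window_s,step_s Segmentation parameters in seconds.
#' @param stft_win_s,stft_hop_s,f_min,f_max,hrf_duration_s Power-modeling
#'   parameters; see [stft_power()], [timevarying_power()], [hrf_kernel()].
#' @param trial_id,label Provenance carried into every window's matrix.
#' @return List of `coupling_matrix` objects, one per window, aligned with
#'   the windows [segment_windows()] produces for the same trial.
#' @export
trial_coupling <- function(S, Y_measured, window_s = 3, step_s = 1.5,
                           stft_win_s = 1, stft_hop_s = 0.1,
                           f_min = 0.5, f_max = 45, hrf_duration_s = 32,
                           trial_id = NA_integer_, label = NA) {
  if (!inherits(S, "source_signals"))
    stop_hbnet("`S` must be a source_signals object", "hbnet_argument_error")
  check_matrix(Y_measured, "Y_measured")
  if (ncol(Y_measured) != ncol(S$data))
    stop_hbnet("source and measured fNIRS streams have different lengths", "hbnet_alignment_error")
  Yhat <- .predicted_matrix(S, stft_win_s, stft_hop_s, f_min, f_max, hrf_duration_s)
  win_pred <- segment_windows(t(Yhat), S$fs, window_s, step_s, trial_id, label)
  win_meas <- segment_windows(Y_measured, S$fs, window_s, step_s, trial_id, label)
  mapply(function(wp, wm) {
    beta <- glm_fit(wp$data, wm$data)
    coupling_matrix(beta, t_start = wp$t_start, trial_id = trial_id, label = label)
  }, win_pred, win_meas, SIMPLIFY = FALSE)
}
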