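#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), giving zero phase distortion — important here because
#' phase shifts would bias lag-based Granger estimates. The EEG band used
#' downstream is 0.5-45 Hz; the fNIRS band is 0.01-0.2 Hz.
#'
#' @param x Numeric matrix (series x samples) or vector.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @return Filtered data, same shape as `x`.
#' @export
bandpass <- function(x, fs, low, high) {
  check_number(fs, "fs", positive = TRUE)
  check_number(low, "low", positive = TRUE)
  check_number(high, "high", positive = TRUE)
  if (low >= high || high >= fs / 2)
    stop_hbnet("band edges must satisfy 0 < low < high < fs/2", "hbnet_argument_error")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1L) else x
  check_matrix(xm, "x")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(xm, 1L, function(row) signal::filtfilt(bf, row)))
  if (vec) drop(out) else out
}

# Fourier-domain band-limited resampling of one series to n_out samples:
# truncating the spectrum is an ideal anti-alias filter, extending it an
# ideal interpolator. A linear trend is removed first and re-added on the
# new grid to tame wrap-around edge effects on non-periodic signals.
.fft_resample <- function(x, n_out) {
  n <- length(x)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), x)$coefficients
  xd <- x - fit[1L] - fit[2L] * tt
  X <- stats::fft(xd)
  Y <- complex(length.out = n_out)
  m <- min(n, n_out)
  half <- m %/% 2L
  Y[1:(half + 1L)] <- X[1:(half + 1L)]
  if (half > 0L && n_out - half + 1L <= n_out && half > 1L)
    Y[(n_out - half + 2L):n_out] <- X[(n - half + 2L):n]
  if (m %% 2L == 0L && n_out > n) {      # split the shared Nyquist bin
    Y[half + 1L] <- X[half + 1L] / 2
    Y[n_out - half + 1L] <- Conj(X[half + 1L]) / 2
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  t_new <- 1 + (seq_len(n_out) - 1L) * n / n_out
  y + fit[1L] + fit[2L] * t_new
}

#' Resample a multichannel signal
#'
#' Band-limited resampling in the Fourier domain: the spectrum is truncated
#' (an ideal anti-alias filter) when downsampling and zero-extended (ideal
#' sinc interpolation) when upsampling, after removing and re-adding a
#' linear trend to suppress wrap-around edge effects. Output length is
#' `round(n * fs_out / fs_in)`. Suited to the offline, already band-limited
#' trial signals this pipeline handles.
#'
#' @param x Numeric matrix (series x samples) or vector.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Resampled data with the same number of series.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  check_number(fs_in, "fs_in", positive = TRUE)
  check_number(fs_out, "fs_out", positive = TRUE)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1L) else x
  check_matrix(xm, "x")
  if (ncol(xm) == 0L) stop_hbnet("empty input signal", "hbnet_argument_error")
  if (fs_in == fs_out) return(x)
  n_out <- round(ncol(xm) * fs_out / fs_in)
  out <- t(apply(xm, 1L, .fft_resample, n_out = n_out))
  rownames(out) <- rownames(xm)
  if (vec) drop(out) else out
}

#' Default hemoglobin extinction coefficients
#'
#' Molar extinction coefficients (1/(mM*cm)) of HbO and HbR at 760 and
#' 850 nm, the wavelength pair of common continuous-wave fNIRS systems.
#' Rows are wavelengths, columns `c("hbo", "hbr")`.
#'
#' @param wavelengths Numeric vector of two wavelengths in nm (760/850 only).
#' @return 2 x 2 numeric matrix.
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  tab <- rbind("760" = c(hbo = 0.1496, hbr = 0.3865),
               "850" = c(hbo = 0.2526, hbr = 0.1798))
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(tab)))
    stop_hbnet("built-in extinction table covers 760 and 850 nm only; supply `extinction` explicitly",
               "hbnet_argument_error")
  tab[key, , drop = FALSE]
}

#' Modified Beer-Lambert conversion of optical density to hemoglobin
#'
#' Converts optical-density changes at two wavelengths into concentration
#' changes of oxygenated (HbO) and deoxygenated (HbR) hemoglobin by inverting
#' the 2x2 extinction system scaled by source-detector distance and the
#' differential pathlength factor (DPF). Only HbO is carried forward by the
#' pipeline; HbR is retained as an attribute.
#'
#' Channel convention: the input matrix interleaves wavelengths per optode
#' pair — rows `2i-1` and `2i` are channel `i` at `wavelengths[1]` and
#' `wavelengths[2]`.
#'
#' @param od A [raw_fnirs()] with `signal_kind = "optical_density"` and an
#'   even number of rows.
#' @param wavelengths Two wavelengths in nm (default 760/850).
#' @param dpf Differential pathlength factor (dimensionless, default 6).
#' @param distance_cm Source-detector separation in cm (default 3).
#' @param extinction Optional 2x2 extinction matrix overriding
#'   [extinction_coefficients()].
#' @return A [raw_fnirs()] with `signal_kind = "hbo"` and `d` rows; the HbR
#'   matrix is attached as attribute `"hbr"`.
#' @export
mbll <- function(od, wavelengths = c(760, 850), dpf = 6, distance_cm = 3,
                 extinction = NULL) {
  if (!inherits(od, "raw_fnirs") || od$signal_kind != "optical_density")
    stop_hbnet("`od` must be a raw_fnirs carrying optical density", "hbnet_argument_error")
  if (nrow(od$data) %% 2L != 0L)
    stop_hbnet("optical-density data must have two wavelength rows per channel",
               "hbnet_argument_error")
  check_number(dpf, "dpf", positive = TRUE)
  check_number(distance_cm, "distance_cm", positive = TRUE)
  E <- if (is.null(extinction)) extinction_coefficients(wavelengths) else extinction
  if (abs(det(E)) < 1e-12)
    stop_hbnet("extinction matrix is numerically singular", "hbnet_numerical_error")
  d <- nrow(od$data) %/% 2L
  scale <- distance_cm * dpf
  Einv <- solve(E)
  hbo <- matrix(0, d, ncol(od$data))
  hbr <- matrix(0, d, ncol(od$data))
  for (i in seq_len(d)) {
    conc <- Einv %*% od$data[c(2L * i - 1L, 2L * i), , drop = FALSE] / scale
    hbo[i, ] <- conc[1L, ]
    hbr[i, ] <- conc[2L, ]
  }
  out <- raw_fnirs(hbo, od$fs,
                   channel_names = paste0("HbO", seq_len(d)),
                   signal_kind = "hbo")
  attr(out, "hbr") <- hbr
  out
}

#' Baseline correction
#'
#' Subtracts, per series, the mean over a baseline time window.
#'
#' @param x Numeric matrix (series x samples) or vector.
#' @param fs Sampling rate in Hz.
#' @param baseline_window Two-element numeric, start and end of the baseline
#'   interval in seconds (relative to sample 1 at t = 0).
#' @return Corrected data, same shape.
#' @export
baseline_correct <- function(x, fs, baseline_window = c(0, 1)) {
  check_number(fs, "fs", positive = TRUE)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1L) else x
  check_matrix(xm, "x")
  idx <- which((seq_len(ncol(xm)) - 1) / fs >= baseline_window[1] &
               (seq_len(ncol(xm)) - 1) / fs < baseline_window[2])
  if (length(idx) == 0L)
    stop_hbnet("baseline window contains no samples", "hbnet_argument_error")
  out <- xm - rowMeans(xm[, idx, drop = FALSE])
  if (vec) drop(out) else out
}

#' Common-average re-reference
#'
#' Subtracts the instantaneous mean across channels from every channel.
#'
#' @param x Numeric matrix, channels x samples.
#' @return Re-referenced matrix.
#' @export
rereference_car <- function(x) {
  check_matrix(x, "x")
  sweep(x, 2L, colMeans(x))
}

#' Sliding-window segmentation
#'
#' Cuts a multichannel signal into rectangular windows of `window_s` seconds
#' advanced by `step_s` seconds (defaults 3 s / 1.5 s, i.e. 50% overlap). The
#' window count is `floor((n - r) / step) + 1` with `r = round(window_s*fs)`.
#' All modality streams of one trial segmented with the same parameters get
#' identical `t_start` sequences, which is what lets causal and coupling
#' windows be paired downstream.
#'
#' @param x Numeric matrix, series x samples.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @param step_s Step between window starts in seconds.
#' @param trial_id,label Carried into every emitted window.
#' @return List of `window_sample` objects; each holds a time-major `r x m`
#'   matrix (rows = time points, columns = series). A signal shorter than one
#'   window yields an empty list with a warning.
#' @export
segment_windows <- function(x, fs, window_s = 3, step_s = 1.5,
                            trial_id = NA_integer_, label = NA) {
  check_matrix(x, "x")
  check_number(fs, "fs", positive = TRUE)
  check_number(window_s, "window_s", positive = TRUE)
  check_number(step_s, "step_s", positive = TRUE)
  n <- ncol(x)
  r <- round(window_s * fs)
  step <- round(step_s * fs)
  if (n < r) {
    warning("signal shorter than one window; returning no windows")
    return(list())
  }
  n_win <- floor((n - r) / step) + 1L
  lapply(seq_len(n_win), function(k) {
    i0 <- (k - 1L) * step + 1L
    new_window_sample(t(x[, i0:(i0 + r - 1L), drop = FALSE]), fs,
                      t_start = (i0 - 1L) / fs, trial_id = trial_id, label = label)
  })
}
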