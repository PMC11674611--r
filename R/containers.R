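#' Multichannel EEG recording
#'
#' Light-weight container for a raw EEG recording: a channels-by-time numeric
#' matrix plus its sampling rate and channel names. All hbnet signal
#' containers are row-major in the series dimension (rows = channels or
#' regions, columns = time samples).
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per channel.
#' @return An object of class `raw_eeg`.
#' @export
raw_eeg <- function(data, fs, channel_names = NULL) {
  check_matrix(data, "data")
  check_number(fs, "fs", positive = TRUE)
  if (is.null(channel_names)) channel_names <- paste0("EEG", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop_hbnet("one channel name per row required", "hbnet_argument_error")
  structure(list(data = data, fs = fs, channel_names = as.character(channel_names)),
            class = "raw_eeg")
}

#' Multichannel fNIRS recording
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per channel.
#' @param signal_kind `"optical_density"` or `"hbo"`; recorded and propagated
#'   so the pipeline knows whether Beer-Lambert conversion is still needed.
#' @return An object of class `raw_fnirs`.
#' @export
raw_fnirs <- function(data, fs, channel_names = NULL,
                      signal_kind = c("hbo", "optical_density")) {
  check_matrix(data, "data")
  check_number(fs, "fs", positive = TRUE)
  signal_kind <- match.arg(signal_kind)
  if (is.null(channel_names)) channel_names <- paste0("NIRS", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop_hbnet("one channel name per row required", "hbnet_argument_error")
  structure(list(data = data, fs = fs, channel_names = as.character(channel_names),
                 signal_kind = signal_kind),
            class = "raw_fnirs")
}

#' Region-level EEG source signals
#'
#' Parcellated cortical activity: one time series per atlas region, obtained
#' by averaging dipole time courses within each region after inverse solution.
#'
#' @param data Numeric matrix, regions x samples.
#' @param fs Sampling rate in Hz.
#' @param region_names Character vector of atlas region names.
#' @return An object of class `source_signals`.
#' @export
source_signals <- function(data, fs, region_names = NULL) {
  check_matrix(data, "data")
  check_number(fs, "fs", positive = TRUE)
  if (is.null(region_names)) region_names <- paste0("R", seq_len(nrow(data)))
  if (length(region_names) != nrow(data))
    stop_hbnet("one region name per row required", "hbnet_argument_error")
  structure(list(data = data, fs = fs, region_names = as.character(region_names)),
            class = "source_signals")
}

new_window_sample <- function(data, fs, t_start, trial_id = NA_integer_, label = NA) {
  structure(list(data = data, fs = fs, t_start = t_start,
                 trial_id = trial_id, label = label),
            class = "window_sample")
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("<raw_eeg> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' @export
print.raw_fnirs <- function(x, ...) {
  cat(sprintf("<raw_fnirs:%s> %d channels x %d samples @ %g Hz\n",
              x$signal_kind, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' @export
print.source_signals <- function(x, ...) {
  cat(sprintf("<source_signals> %d regions x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' @export
print.window_sample <- function(x, ...) {
  cat(sprintf("<window_sample> %d points x %d series @ %g Hz, t_start = %g s\n",
              nrow(x$data), ncol(x$data), x$fs, x$t_start))
  invisible(x)
}
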