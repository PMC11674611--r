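#' Minimum norm estimate (MNE) inverse solution
#'
#' Estimates dipole time courses `J` from scalp EEG `X` under the linear
#' forward model `X = L J + noise`, using the Tikhonov-regularized minimum
#' norm solution with identity source covariance:
#' `J = L' (L L' + alpha^-1 I)^-1 X`.
#' The `u x u` system is solved by Cholesky factorization, never by explicit
#' matrix inversion. The solution is linear in `X`, and for `L = I` and large
#' `alpha` it approaches `X` itself.
#'
#' @param X Numeric matrix, electrodes x samples.
#' @param L Lead-field matrix, electrodes x dipoles.
#' @param alpha Regularization weight (> 0) balancing data fit against source
#'   energy; `NULL` selects a data-scale default via [default_alpha()].
#' @return Numeric matrix `J`, dipoles x samples.
#' @export
mne_inverse <- function(X, L, alpha = NULL) {
  check_matrix(X, "X")
  check_matrix(L, "L")
  if (nrow(X) != nrow(L))
    stop_hbnet("X and L must have the same number of electrode rows", "hbnet_argument_error")
  if (is.null(alpha)) alpha <- default_alpha(L)
  check_number(alpha, "alpha", positive = TRUE)
  u <- nrow(L)
  M <- tcrossprod(L) + diag(1 / alpha, u)
  ch <- tryCatch(chol(M), error = function(e)
    stop_hbnet("regularized gram matrix is numerically singular", "hbnet_numerical_error"))
  # J = L' M^{-1} X via two triangular solves
  crossprod(L, backsolve(ch, forwardsolve(t(ch), X)))
}

#' Default MNE regularization weight
#'
#' Anchors the regularizer to the data scale: `alpha^-1` is set to
#' `trace(L L') / u` divided by an assumed power SNR of 9 (amplitude SNR 3),
#' so the penalty stays commensurate with the lead field regardless of its
#' units.
#'
#' @param L Lead-field matrix.
#' @param snr Assumed amplitude signal-to-noise ratio (default 3).
#' @return Positive scalar `alpha`.
#' @export
default_alpha <- function(L, snr = 3) {
  check_matrix(L, "L")
  snr^2 * nrow(L) / sum(L^2)
}

#' Parcellate dipole activity into region source signals
#'
#' Averages dipole time courses within each atlas region, producing one
#' source signal per region at the full temporal resolution of the input.
#'
#' @param J Numeric matrix, dipoles x samples (as from [mne_inverse()]).
#' @param membership Integer vector, one entry per dipole, giving the region
#'   id in `1..c`; every region must own at least one dipole.
#' @param region_names Optional character vector of region names (length `c`).
#' @param fs Sampling rate in Hz.
#' @return A [source_signals()] object, regions x samples.
#' @export
parcellate <- function(J, membership, region_names = NULL, fs = 200) {
  check_matrix(J, "J")
  membership <- as.integer(membership)
  if (length(membership) != nrow(J))
    stop_hbnet("one membership entry per dipole row required", "hbnet_argument_error")
  n_regions <- if (is.null(region_names)) max(membership) else length(region_names)
  counts <- tabulate(membership, nbins = n_regions)
  if (any(membership < 1L) || any(counts == 0L)) {
    bad <- if (any(membership < 1L)) membership[membership < 1L][1L] else which(counts == 0L)[1L]
    stop_hbnet(sprintf("region %d has no dipoles (or membership out of range)", bad),
               "hbnet_consistency_error")
  }
  S <- rowsum(J, membership) / counts
  source_signals(unname(S), fs = fs, region_names = region_names)
}
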