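#' Spectral radius of a VAR companion matrix
#'
#' The lag-`k` coefficient matrix of the simulated VAR is the adjacency
#' scaled by `lag_decay^(k-1)`. The process is (covariance-)stationary iff
#' the companion-matrix spectral radius is below 1.
#'
#' @param adjacency `c x c` coefficient gain matrix; entry `(i, j)` is the
#'   gain with which series `j` drives series `i` (diagonal = self lags).
#' @param var_order Model order `p`.
#' @param lag_decay Geometric decay of coefficients across lags (default 0.6).
#' @return The spectral radius (largest eigenvalue modulus).
#' @export
var_spectral_radius <- function(adjacency, var_order = 1L, lag_decay = 0.6) {
  check_matrix(adjacency, "adjacency")
  c_ <- nrow(adjacency)
  p <- as.integer(var_order)
  A <- do.call(cbind, lapply(seq_len(p), function(k) adjacency * lag_decay^(k - 1)))
  comp <- rbind(A, cbind(diag(1, c_ * (p - 1L), c_ * (p - 1L)),
                         matrix(0, c_ * (p - 1L), c_)))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# Shrink an adjacency until the implied VAR has spectral radius <= target.
.stabilize_adjacency <- function(adjacency, var_order, lag_decay = 0.6, target = 0.9) {
  rho <- var_spectral_radius(adjacency, var_order, lag_decay)
  while (rho > target) {
    adjacency <- adjacency * (target / rho) * 0.98
    rho <- var_spectral_radius(adjacency, var_order, lag_decay)
  }
  adjacency
}

#' Simulate stable VAR source dynamics
#'
#' Generates `c` coupled region time series from a vector autoregression
#' whose lag-`k` coefficient matrix is `adjacency * lag_decay^(k-1)`, driven
#' by i.i.d. Gaussian innovations. The first `burn_in` samples are discarded
#' so the retained segment is stationary, which the downstream Granger
#' analysis assumes.
#'
#' @param adjacency `c x c` finite matrix of directed coupling gains
#'   (column j drives row i); the implied VAR must be stable.
#' @param var_order Model order `p` (default 1).
#' @param n Number of retained samples; must exceed `10 * var_order`.
#' @param fs Sampling rate in Hz (default 200).
#' @param noise_sd Innovation standard deviation (> 0, default 1).
#' @param seed Optional integer seed; same seed gives bit-identical output.
#' @param burn_in Samples discarded before recording (default 500).
#' @param lag_decay Geometric lag decay (default 0.6).
#' @return A [source_signals()] object, `c x n`.
#' @export
simulate_var_sources <- function(adjacency, var_order = 1L, n, fs = 200,
                                 noise_sd = 1, seed = NULL, burn_in = 500L,
                                 lag_decay = 0.6) {
  check_matrix(adjacency, "adjacency")
  if (nrow(adjacency) != ncol(adjacency))
    stop_hbnet("`adjacency` must be square", "hbnet_argument_error")
  p <- as.integer(var_order)
  if (p < 1L) stop_hbnet("`var_order` must be >= 1", "hbnet_argument_error")
  check_number(noise_sd, "noise_sd", positive = TRUE)
  if (n <= 10L * p)
    stop_hbnet("`n` must exceed 10 * var_order", "hbnet_argument_error")
  rho <- var_spectral_radius(adjacency, p, lag_decay)
  if (rho >= 1)
    stop_hbnet(sprintf("unstable VAR: companion spectral radius %.3f >= 1", rho),
               "hbnet_stability_error")
  c_ <- nrow(adjacency)
  A <- lapply(seq_len(p), function(k) adjacency * lag_decay^(k - 1))
  n_tot <- n + as.integer(burn_in)
  with_seed(seed, {
    eps <- matrix(stats::rnorm(c_ * n_tot, sd = noise_sd), c_, n_tot)
    X <- matrix(0, c_, n_tot)
    X[, seq_len(p)] <- eps[, seq_len(p)]
    for (t in (p + 1L):n_tot) {
      acc <- eps[, t]
      for (k in seq_len(p)) acc <- acc + A[[k]] %*% X[, t - k]
      X[, t] <- acc
    }
    source_signals(X[, (n_tot - n + 1L):n_tot, drop = FALSE], fs = fs)
  })
}

#' Project source signals to scalp electrodes
#'
#' Forward model `X = L J + noise`: every dipole carries the time series of
#' its region, the lead field mixes dipoles into electrode potentials, and
#' i.i.d. Gaussian sensor noise is added.
#'
#' @param S A [source_signals()] object (`c x n`).
#' @param lead_field `u x v` lead-field matrix.
#' @param membership Length-`v` integer vector mapping each dipole to a
#'   region in `1..c`.
#' @param sensor_noise_sd Sensor noise standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return Numeric matrix `X`, electrodes x samples (`u x n`).
#' @export
project_to_scalp <- function(S, lead_field, membership, sensor_noise_sd = 0,
                             seed = NULL) {
  if (!inherits(S, "source_signals"))
    stop_hbnet("`S` must be a source_signals object", "hbnet_argument_error")
  check_matrix(lead_field, "lead_field")
  membership <- as.integer(membership)
  if (length(membership) != ncol(lead_field))
    stop_hbnet("one membership entry per lead-field column required", "hbnet_argument_error")
  if (any(membership < 1L) || any(membership > nrow(S$data)))
    stop_hbnet("membership references a region absent from S", "hbnet_index_error")
  check_number(sensor_noise_sd, "sensor_noise_sd", nonneg = TRUE)
  J <- S$data[membership, , drop = FALSE]
  X <- lead_field %*% J
  if (sensor_noise_sd > 0) {
    X <- with_seed(seed, X + matrix(stats::rnorm(length(X), sd = sensor_noise_sd),
                                    nrow(X), ncol(X)))
  }
  unname(X)
}

#' Simulate fNIRS from source signals and coupling weights
#'
#' Forward neurovascular model: each source's normalized time-varying power
#' (computed exactly as the coupling network does) is convolved with the
#' canonical HRF, channel `j` is the weight-mixed sum
#' `y_j = sum_i w[i, j] * yhat_i` plus Gaussian noise. The output lives on
#' the same sample grid as `S`; resampling to the fNIRS acquisition rate is
#' the dataset generator's job.
#'
#' @param S A [source_signals()] object (`c x n`).
#' @param coupling_weights `c x d` finite nonnegative gain matrix.
#' @param noise_sd Additive noise standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @param stft_win_s,stft_hop_s,f_min,f_max,hrf_duration_s Power-modeling
#'   parameters, matching [trial_coupling()] defaults.
#' @return Numeric matrix, channels x samples (`d x n`).
#' @export
simulate_fnirs <- function(S, coupling_weights, noise_sd = 0, seed = NULL,
                           stft_win_s = 1, stft_hop_s = 0.1,
                           f_min = 0.5, f_max = 45, hrf_duration_s = 32) {
  if (!inherits(S, "source_signals"))
    stop_hbnet("`S` must be a source_signals object", "hbnet_argument_error")
  check_matrix(coupling_weights, "coupling_weights")
  if (nrow(coupling_weights) != nrow(S$data))
    stop_hbnet("coupling_weights must have one row per source", "hbnet_argument_error")
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  Yhat <- .predicted_matrix(S, stft_win_s, stft_hop_s, f_min, f_max, hrf_duration_s)
  Y <- t(Yhat %*% coupling_weights)
  if (noise_sd > 0) {
    Y <- with_seed(seed, Y + matrix(stats::rnorm(length(Y), sd = noise_sd),
                                    nrow(Y), ncol(Y)))
  }
  Y
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic coupled EEG/fNIRS generator with the
#' defaults that define the package's reference study conditions: 4 emotion
#' classes x 15 trials of 30 s, an 8-region atlas observed through 16
#' electrodes and 24 dipoles, EEG at 200 Hz and fNIRS at 11 Hz, VAR(2)
#' source dynamics with 6 directed base edges, and class identity encoded by
#' rectified Gaussian perturbations of both the adjacency and the coupling
#' templates (scaled by `effect_size`).
#'
#' @param n_classes Number of trial classes K (>= 2).
#' @param trials_per_class Trials per class.
#' @param regions Number of atlas regions c.
#' @param fnirs_channels Number of fNIRS channels d.
#' @param electrodes Number of EEG electrodes u.
#' @param dipoles_per_region Dipoles per region (v = regions * this).
#' @param duration_s Trial duration in seconds.
#' @param fs_eeg,fs_fnirs Sampling rates in Hz.
#' @param var_order VAR model order of the source dynamics.
#' @param n_edges Directed off-diagonal edges in the base adjacency.
#' @param edge_gain Gain of each base edge.
#' @param self_gain Diagonal (self-lag) gain.
#' @param effect_size Nonnegative scale of the class-template perturbations;
#'   0 gives a null dataset with identical classes.
#' @param noise_sd VAR innovation standard deviation.
#' @param sensor_noise_sd EEG sensor noise standard deviation.
#' @param fnirs_snr_db fNIRS signal-to-noise ratio in dB.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_classes = 4L, trials_per_class = 15L, regions = 8L,
                       fnirs_channels = 4L, electrodes = 16L,
                       dipoles_per_region = 3L, duration_s = 30,
                       fs_eeg = 200, fs_fnirs = 11, var_order = 2L,
                       n_edges = 6L, edge_gain = 0.5, self_gain = 0.4,
                       effect_size = 0.5, noise_sd = 1,
                       sensor_noise_sd = 0.5, fnirs_snr_db = 10) {
  if (n_classes < 2L) stop_hbnet("need at least 2 classes", "hbnet_argument_error")
  check_number(effect_size, "effect_size", nonneg = TRUE)
  check_number(duration_s, "duration_s", positive = TRUE)
  structure(list(n_classes = as.integer(n_classes),
                 trials_per_class = as.integer(trials_per_class),
                 regions = as.integer(regions),
                 fnirs_channels = as.integer(fnirs_channels),
                 electrodes = as.integer(electrodes),
                 dipoles_per_region = as.integer(dipoles_per_region),
                 duration_s = duration_s, fs_eeg = fs_eeg, fs_fnirs = fs_fnirs,
                 var_order = as.integer(var_order), n_edges = as.integer(n_edges),
                 edge_gain = edge_gain, self_gain = self_gain,
                 effect_size = effect_size, noise_sd = noise_sd,
                 sensor_noise_sd = sensor_noise_sd, fnirs_snr_db = fnirs_snr_db),
            class = "sim_config")
}

# Random sparse off-diagonal adjacency with a self-lag diagonal.
.base_adjacency <- function(regions, n_edges, edge_gain, self_gain) {
  off <- which(diag(regions) == 0)
  A <- diag(self_gain, regions)
  picks <- sample(off, min(n_edges, length(off)))
  A[picks] <- edge_gain
  A
}

# Class template: rectified Gaussian perturbation of a base matrix.
.perturb <- function(base, effect_size, sd_scale, off_diag_only = FALSE) {
  P <- matrix(stats::rnorm(length(base), sd = sd_scale), nrow(base), ncol(base))
  if (off_diag_only) diag(P) <- 0
  pmax(base + effect_size * P, 0)
}

#' Generate a labeled synthetic coupled EEG/fNIRS dataset
#'
#' Emulates a concurrent EEG-fNIRS emotion experiment on one subject: for
#' each class a VAR adjacency template and a neurovascular coupling-weight
#' template are drawn as perturbations of shared base matrices, then every
#' trial simulates stable VAR sources, projects them through a random
#' Gaussian lead field with sensor noise (EEG stream), and mixes
#' HRF-convolved source power through the class coupling weights with noise
#' at the configured SNR, resampled to the fNIRS acquisition rate. All
#' randomness derives from `seed`; two calls with identical arguments return
#' identical datasets.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return An object of class `synthetic_dataset`: list with `trials` (each
#'   `list(eeg, fnirs, label)` with labels in `0..K-1`), `lead_field`,
#'   `membership`, `region_names`, sampling rates, and `ground_truth`
#'   (per-class adjacency and coupling templates, labels, seed, var_order).
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- round(cfg$duration_s * cfg$fs_eeg)
  n_f <- round(cfg$duration_s * cfg$fs_fnirs)
  v <- cfg$regions * cfg$dipoles_per_region
  with_seed(seed, {
    lead_field <- matrix(stats::rnorm(cfg$electrodes * v), cfg$electrodes, v)
    membership <- rep(seq_len(cfg$regions), each = cfg$dipoles_per_region)
    base_adj <- .base_adjacency(cfg$regions, cfg$n_edges, cfg$edge_gain, cfg$self_gain)
    base_w <- matrix(stats::runif(cfg$regions * cfg$fnirs_channels, 0.5, 1.5),
                     cfg$regions, cfg$fnirs_channels)
    adjacencies <- lapply(seq_len(cfg$n_classes), function(k)
      .stabilize_adjacency(.perturb(base_adj, cfg$effect_size, 0.2,
                                    off_diag_only = TRUE),
                           cfg$var_order))
    couplings <- lapply(seq_len(cfg$n_classes), function(k)
      .perturb(base_w, cfg$effect_size, 0.3))
    labels <- rep(seq_len(cfg$n_classes) - 1L, each = cfg$trials_per_class)
    trials <- lapply(seq_along(labels), function(ti) {
      k <- labels[ti] + 1L
      S <- simulate_var_sources(adjacencies[[k]], cfg$var_order, n = n,
                                fs = cfg$fs_eeg, noise_sd = cfg$noise_sd)
      eeg <- project_to_scalp(S, lead_field, membership,
                              sensor_noise_sd = cfg$sensor_noise_sd)
      clean <- simulate_fnirs(S, couplings[[k]], noise_sd = 0)
      # SNR defined per channel on the demeaned signal: offsets are not power
      noise_sd <- apply(clean, 1L, stats::sd) * 10^(-cfg$fnirs_snr_db / 20)
      fnirs200 <- clean + matrix(stats::rnorm(length(clean)), nrow(clean)) * noise_sd
      fnirs <- resample_signal(fnirs200, cfg$fs_eeg, cfg$fs_fnirs)
      if (ncol(fnirs) != n_f) fnirs <- fnirs[, seq_len(n_f), drop = FALSE]
      list(eeg = eeg, fnirs = fnirs, label = labels[ti])
    })
    structure(list(trials = trials, lead_field = lead_field,
                   membership = membership,
                   region_names = paste0("R", seq_len(cfg$regions)),
                   fs_eeg = cfg$fs_eeg, fs_fnirs = cfg$fs_fnirs,
                   config = cfg,
                   ground_truth = structure(list(adjacency = adjacencies,
                                                 coupling_weights = couplings,
                                                 labels = labels, seed = seed,
                                                 var_order = cfg$var_order,
                                                 fs = cfg$fs_eeg),
                                            class = "ground_truth")),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d trials (%d classes), %d regions, %d fNIRS channels\n",
              length(x$trials), x$config$n_classes, x$config$regions,
              x$config$fnirs_channels))
  invisible(x)
}
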