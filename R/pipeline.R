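#' Default pipeline configuration
#'
#' One flat list of every knob of the pipeline, combining the synthetic
#' generator settings ([sim_config()]) with preprocessing, inverse, network
#' and evaluation parameters. `inverse_alpha = NA` means the data-scale
#' default of [default_alpha()]; `granger_fixed_p = NA` means per-window BIC
#' selection up to `granger_p_max`.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  c(unclass(sim_config()),
    list(seed = 1L,
         target_fs = 200,
         eeg_band = c(0.5, 45),
         fnirs_band = c(0.01, 0.2),
         window_s = 3, step_s = 1.5,
         inverse_alpha = NA,
         granger_p_max = 10L, granger_fixed_p = NA,
         stft_win_s = 1, stft_hop_s = 0.1,
         f_min = 0.5, f_max = 45, hrf_duration_s = 32,
         feature_kinds = c("SG", "SC", "SG_SC"),
         classifiers = c("svm_linear", "knn10"),
         k_folds = 5L, repeats = 5L, fold_unit = "sample"))
}

#' Load and validate a pipeline configuration
#'
#' Accepts a named list or a YAML/JSON file, merges it over
#' [default_config()], and rejects unknown keys by name before any
#' computation runs.
#'
#' @param config Named list, path to a `.yaml`/`.yml`/`.json` file, or
#'   `NULL` for pure defaults.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- default_config()
  user <- if (is.null(config)) list()
          else if (is.character(config)) {
            if (!file.exists(config))
              stop_hbnet(sprintf("config file not found: %s", config), "hbnet_config_error")
            if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
            else jsonlite::read_json(config, simplifyVector = TRUE)
          } else if (is.list(config)) config
          else stop_hbnet("`config` must be a list or a file path", "hbnet_config_error")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop_hbnet(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
               "hbnet_config_error")
  cfg <- utils::modifyList(defaults, user)
  for (key in c("duration_s", "fs_eeg", "fs_fnirs", "window_s", "step_s",
                "stft_win_s", "stft_hop_s", "hrf_duration_s", "target_fs"))
    check_number(cfg[[key]], key, positive = TRUE)
  check_number(cfg$effect_size, "effect_size", nonneg = TRUE)
  if (cfg$n_classes < 2L)
    stop_hbnet("n_classes must be >= 2", "hbnet_config_error")
  if (!all(cfg$feature_kinds %in% c("SG", "SC", "SG_SC")))
    stop_hbnet("feature_kinds must be among SG, SC, SG_SC", "hbnet_config_error")
  if (!all(cfg$classifiers %in% c("svm_linear", "knn10")))
    stop_hbnet("classifiers must be among svm_linear, knn10", "hbnet_config_error")
  structure(cfg, class = "pipeline_config")
}

.cfg_sim <- function(cfg) {
  do.call(sim_config, cfg[names(formals(sim_config))])
}

.cfg_hash <- function(cfg) {
  tf <- tempfile()
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              digits = NA, null = "null", na = "null"), tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[hbnet %s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Stage 1: simulate and persist a dataset
#'
#' @param config Anything [pipeline_config()] accepts.
#' @param out_dir Output dataset directory.
#' @param verbose Log per-stage progress.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(config = NULL, out_dir, verbose = FALSE) {
  cfg <- pipeline_config(config)
  .log_stage(verbose, "simulate: %d trials", cfg$n_classes * cfg$trials_per_class)
  ds <- simulate_dataset(.cfg_sim(cfg), seed = cfg$seed)
  write_dataset(ds, out_dir)
  invisible(out_dir)
}

# Preprocess one trial into (source signals, measured fNIRS at target fs).
.prep_trial <- function(eeg, fnirs, lf, cfg) {
  fs <- cfg$target_fs
  X <- eeg
  if (cfg$fs_eeg != fs) X <- resample_signal(X, cfg$fs_eeg, fs)
  X <- bandpass(X, fs, cfg$eeg_band[1L], cfg$eeg_band[2L])
  J <- mne_inverse(X, lf$lead_field,
                   alpha = if (is.na(cfg$inverse_alpha)) NULL else cfg$inverse_alpha)
  S <- parcellate(J, lf$membership, lf$region_names, fs = fs)
  Yf <- bandpass(fnirs, cfg$fs_fnirs, cfg$fnirs_band[1L], cfg$fnirs_band[2L])
  Yf <- resample_signal(Yf, cfg$fs_fnirs, fs)
  n <- min(ncol(S$data), ncol(Yf))
  S$data <- S$data[, seq_len(n), drop = FALSE]
  list(S = S, Y = Yf[, seq_len(n), drop = FALSE])
}

# Causal matrices for one trial's source signals.
.trial_causal <- function(S, cfg, trial_id, label) {
  wins <- segment_windows(S$data, S$fs, cfg$window_s, cfg$step_s, trial_id, label)
  lapply(wins, function(w) {
    w <- detrend_window(w)
    p <- if (is.na(cfg$granger_fixed_p)) NULL else as.integer(cfg$granger_fixed_p)
    causal_matrix(w, p = p, p_max = cfg$granger_p_max)
  })
}

#' Stage 2: compute per-window networks for every trial
#'
#' For each trial: preprocess both modalities, solve the inverse problem and
#' parcellate, then compute causal matrices (detrended windows, BIC order)
#' and coupling matrices (power modeling + GLM) per window. Results are
#' persisted one RDS per trial with a JSON manifest; completed trials are
#' skipped on rerun, and unreadable trial files are skipped with a warning.
#'
#' @param config Anything [pipeline_config()] accepts.
#' @param dataset_dir Dataset directory from [run_simulate()].
#' @param out_dir Networks output directory.
#' @param verbose Log per-stage progress.
#' @return `out_dir`, invisibly; attribute `"n_warnings"` counts skipped trials.
#' @export
run_networks <- function(config = NULL, dataset_dir, out_dir, verbose = FALSE) {
  cfg <- pipeline_config(config)
  ds <- read_dataset(dataset_dir)
  lf <- list(lead_field = ds$lead_field, membership = ds$membership,
             region_names = ds$region_names)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_warn <- 0L
  t0 <- proc.time()[3L]
  for (i in seq_along(ds$trials)) {
    path <- file.path(out_dir, sprintf("trial_%03d.rds", i))
    if (file.exists(path)) next
    tr <- ds$trials[[i]]
    if (is.null(tr)) {
      warning(sprintf("trial %d skipped: unreadable input", i))
      n_warn <- n_warn + 1L
      next
    }
    res <- tryCatch({
      prep <- .prep_trial(tr$eeg, tr$fnirs, lf, cfg)
      causal <- .trial_causal(prep$S, cfg, i, tr$label)
      coupling <- trial_coupling(prep$S, prep$Y, cfg$window_s, cfg$step_s,
                                 cfg$stft_win_s, cfg$stft_hop_s,
                                 cfg$f_min, cfg$f_max, cfg$hrf_duration_s,
                                 trial_id = i, label = tr$label)
      list(causal = causal, coupling = coupling, label = tr$label)
    }, error = function(e) {
      warning(sprintf("trial %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { n_warn <- n_warn + 1L; next }
    saveRDS(res, path)
  }
  jsonlite::write_json(list(config_hash = .cfg_hash(unclass(cfg)),
                            n_trials = length(ds$trials), n_warnings = n_warn,
                            elapsed_s = round(proc.time()[3L] - t0, 2),
                            package_version = as.character(utils::packageVersion("hbnet"))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage(verbose, "networks: %d trials done, %d warnings", length(ds$trials), n_warn)
  out <- out_dir
  attr(out, "n_warnings") <- n_warn
  invisible(out)
}

# Load persisted networks and build a feature set of the requested kind.
.load_networks <- function(networks_dir) {
  files <- sort(list.files(networks_dir, pattern = "^trial_\\d+\\.rds$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop_hbnet("no trial networks found", "hbnet_format_error")
  lapply(files, readRDS)
}

.features_from_networks <- function(nets, kind) {
  causal <- unlist(lapply(nets, `[[`, "causal"), recursive = FALSE)
  coupling <- unlist(lapply(nets, `[[`, "coupling"), recursive = FALSE)
  if (kind %in% c("SC", "SG_SC") && length(coupling) == 0L)
    stop_hbnet(sprintf("feature kind %s needs fNIRS-derived coupling networks, absent here", kind),
               "hbnet_capability_error")
  feature_set(causal = if (length(causal)) causal else NULL,
              coupling = if (length(coupling)) coupling else NULL, kind = kind)
}

#' Stage 3: evaluate classification for every requested cell
#'
#' Builds the feature set of every requested kind from persisted networks
#' and evaluates every requested classifier on it with repeated stratified
#' cross-validation, producing one accuracy cell per (feature kind x
#' classifier), plus per-class accuracies and confusion matrices.
#'
#' @param config Anything [pipeline_config()] accepts.
#' @param networks_dir Networks directory from [run_networks()].
#' @param report_path Optional path stem; when given, the report is written
#'   as `<stem>.json` and `<stem>.md`.
#' @param verbose Log per-stage progress.
#' @return An object of class `hbn_report`: `table` (tibble, one row per
#'   cell) and `results` (named list of `hbn_eval`).
#' @export
run_evaluate <- function(config = NULL, networks_dir, report_path = NULL,
                         verbose = FALSE) {
  cfg <- pipeline_config(config)
  nets <- .load_networks(networks_dir)
  trial_ids <- unlist(lapply(seq_along(nets), function(i)
    rep(i, length(nets[[i]]$causal))))
  results <- list()
  for (kind in cfg$feature_kinds) {
    fset <- .features_from_networks(nets, kind)
    for (clf in cfg$classifiers) {
      key <- paste(kind, clf, sep = "_")
      .log_stage(verbose, "evaluate %s", key)
      results[[key]] <- evaluate_features(fset, clf, cfg$k_folds, cfg$repeats,
                                          seed = cfg$seed,
                                          fold_unit = cfg$fold_unit,
                                          trial_ids = trial_ids)
    }
  }
  table <- do.call(rbind, lapply(results, glance))
  report <- structure(list(table = table, results = results,
                           seed = cfg$seed, config_hash = .cfg_hash(unclass(cfg))),
                      class = "hbn_report")
  if (!is.null(report_path)) write_report(report, report_path)
  report
}

#' Write an evaluation report to JSON and Markdown
#'
#' @param report An `hbn_report`.
#' @param path_stem Output path without extension.
#' @return `path_stem`, invisibly.
#' @export
write_report <- function(report, path_stem) {
  stopifnot(inherits(report, "hbn_report"))
  payload <- list(seed = report$seed, config_hash = report$config_hash,
                  cells = lapply(report$results, function(r)
                    list(feature_kind = r$feature_kind, classifier = r$classifier,
                         accuracy_mean = r$accuracy_mean, accuracy_sd = r$accuracy_sd,
                         per_class = as.list(r$per_class),
                         confusion = r$confusion)))
  jsonlite::write_json(payload, paste0(path_stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  lines <- c("# Classification report", "",
             "| feature kind | classifier | accuracy | sd |",
             "|---|---|---|---|",
             vapply(report$results, function(r)
               sprintf("| %s | %s | %.1f%% | %.2f |", r$feature_kind, r$classifier,
                       100 * r$accuracy_mean, 100 * r$accuracy_sd), ""))
  writeLines(lines, paste0(path_stem, ".md"))
  invisible(path_stem)
}

#' @export
print.hbn_report <- function(x, ...) {
  cat("<hbn_report>\n")
  print(x$table)
  invisible(x)
}

#' Run the complete pipeline
#'
#' simulate -> networks -> evaluate under one root directory. With identical
#' configuration and seed the run is fully deterministic: the persisted
#' feature matrices and the reported accuracies are identical across runs.
#'
#' @param config Anything [pipeline_config()] accepts.
#' @param out_root Root output directory.
#' @param verbose Log per-stage progress.
#' @return The `hbn_report`; dataset and network directories and the report
#'   live under `out_root`.
#' @export
run_all <- function(config = NULL, out_root, verbose = FALSE) {
  cfg <- pipeline_config(config)
  ds_dir <- file.path(out_root, "dataset")
  nw_dir <- file.path(out_root, "networks")
  run_simulate(cfg, ds_dir, verbose)
  run_networks(cfg, ds_dir, nw_dir, verbose)
  report <- run_evaluate(cfg, nw_dir, file.path(out_root, "report"), verbose)
  for (kind in cfg$feature_kinds) {
    fset <- .features_from_networks(.load_networks(nw_dir), kind)
    utils::write.table(format(fset$x, digits = 17, trim = TRUE, scientific = TRUE),
                       file.path(out_root, sprintf("features_%s.tsv", kind)),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  report
}
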