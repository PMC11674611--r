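# Readers and writers for the formats the pipeline touches. The canonical
# interchange format is a delimited matrix (rows = channels, one header line
# of channel names) with a JSON metadata sidecar at "<path>.json". EDF and
# MAT v5 support is a minimal-subset implementation written here because no
# reader package for either format is available to this package: EDF covers
# continuous 16-bit signals in a single data record; MAT v5 covers
# uncompressed double matrices with a user-suppliable variable-name mapping.

.sidecar_path <- function(path) paste0(path, ".json")

.write_delim_matrix <- function(data, names, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names, collapse = "\t"), con)
  utils::write.table(format(data, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

.read_delim_matrix <- function(path) {
  if (!file.exists(path))
    stop_hbnet(sprintf("file not found: %s", path), "hbnet_format_error")
  header <- readLines(path, n = 1L)
  names <- strsplit(header, "\t", fixed = TRUE)[[1L]]
  body <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                            colClasses = "numeric")
  data <- as.matrix(body)
  dimnames(data) <- NULL
  if (nrow(data) != length(names))
    stop_hbnet(sprintf("truncated or malformed delimited matrix: %d header names, %d rows",
                       length(names), nrow(data)), "hbnet_format_error")
  list(data = data, names = names)
}

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write an EEG recording
#'
#' @param x A [raw_eeg()] object.
#' @param path Output file path.
#' @param format `"delimited"` (TSV + JSON sidecar) or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(x, path, format = c("delimited", "edf")) {
  stopifnot(inherits(x, "raw_eeg"))
  format <- match.arg(format)
  if (format == "edf") return(.write_edf(x$data, x$fs, x$channel_names, path))
  .write_delim_matrix(x$data, x$channel_names, path)
  jsonlite::write_json(list(fs = x$fs, kind = "eeg"), .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an fNIRS recording
#'
#' @param x A [raw_fnirs()] object.
#' @param path Output file path (delimited TSV + JSON sidecar).
#' @return `path`, invisibly.
#' @export
write_fnirs <- function(x, path) {
  stopifnot(inherits(x, "raw_fnirs"))
  .write_delim_matrix(x$data, x$channel_names, path)
  jsonlite::write_json(list(fs = x$fs, kind = "fnirs", signal_kind = x$signal_kind),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.check_payload <- function(data, path) {
  if (anyNA(data) || !all(is.finite(data)))
    stop_hbnet(sprintf("non-finite values in %s", path), "hbnet_data_error")
  data
}

#' Read an EEG recording
#'
#' @param path Input file.
#' @param format One of `"delimited"`, `"edf"`, `"mat"`.
#' @param fs Sampling rate in Hz, required when the format carries none
#'   (MAT, or delimited without a sidecar).
#' @param mat_var For MAT input, the variable name holding the
#'   channels-x-samples matrix; defaults to the first matrix in the file.
#' @return A [raw_eeg()] object.
#' @export
read_eeg <- function(path, format = c("delimited", "edf", "mat"),
                     fs = NULL, mat_var = NULL) {
  format <- match.arg(format)
  if (format == "delimited") {
    m <- .read_delim_matrix(path)
    meta <- .read_sidecar(path)
    if (is.null(fs)) fs <- meta$fs
    if (is.null(fs))
      stop_hbnet("no sampling rate: supply `fs` or a JSON sidecar", "hbnet_metadata_error")
    return(raw_eeg(.check_payload(m$data, path), fs, m$names))
  }
  if (format == "edf") {
    e <- .read_edf(path)
    return(raw_eeg(.check_payload(e$data, path), e$fs, e$channel_names))
  }
  vars <- read_mat5(path)
  data <- .pick_mat_var(vars, mat_var, path)
  if (is.null(fs))
    stop_hbnet("MAT files carry no sampling rate: supply `fs`", "hbnet_metadata_error")
  raw_eeg(.check_payload(data, path), fs)
}

#' Read an fNIRS recording
#'
#' SNIRF is an HDF5 container; no HDF5 binding is available to this package,
#' so requesting it raises an explicit capability error.
#'
#' @param path Input file.
#' @param format One of `"delimited"`, `"snirf"`, `"mat"`.
#' @param fs Sampling rate in Hz when the format carries none.
#' @param signal_kind Overrides the sidecar's `"optical_density"`/`"hbo"`.
#' @param mat_var For MAT input, the variable name to extract.
#' @return A [raw_fnirs()] object.
#' @export
read_fnirs <- function(path, format = c("delimited", "snirf", "mat"),
                       fs = NULL, signal_kind = NULL, mat_var = NULL) {
  format <- match.arg(format)
  if (format == "snirf")
    stop_hbnet("SNIRF requires an HDF5 reader, which is not available; convert to the delimited layout",
               "hbnet_capability_error")
  if (format == "delimited") {
    m <- .read_delim_matrix(path)
    meta <- .read_sidecar(path)
    if (is.null(fs)) fs <- meta$fs
    if (is.null(signal_kind)) signal_kind <- meta$signal_kind
    if (is.null(fs))
      stop_hbnet("no sampling rate: supply `fs` or a JSON sidecar", "hbnet_metadata_error")
    if (is.null(signal_kind)) signal_kind <- "hbo"
    return(raw_fnirs(.check_payload(m$data, path), fs, m$names, signal_kind))
  }
  vars <- read_mat5(path)
  data <- .pick_mat_var(vars, mat_var, path)
  if (is.null(fs))
    stop_hbnet("MAT files carry no sampling rate: supply `fs`", "hbnet_metadata_error")
  raw_fnirs(.check_payload(data, path), fs,
            signal_kind = if (is.null(signal_kind)) "hbo" else signal_kind)
}

.pick_mat_var <- function(vars, mat_var, path) {
  if (length(vars) == 0L)
    stop_hbnet(sprintf("no matrix variables in %s", path), "hbnet_format_error")
  if (is.null(mat_var)) return(vars[[1L]])
  if (!mat_var %in% names(vars))
    stop_hbnet(sprintf("variable '%s' not in %s (has: %s)", mat_var, path,
                       paste(names(vars), collapse = ", ")), "hbnet_format_error")
  vars[[mat_var]]
}

#' Write a lead field with its parcellation
#'
#' Stores the lead-field matrix, the dipole-to-region membership and the
#' region names in one JSON file. The region order in `region_names` is the
#' canonical order: it fixes the row/column order of every source-space
#' matrix downstream.
#'
#' @param lead_field `u x v` matrix.
#' @param membership Length-`v` integer vector of region ids in `1..c`.
#' @param region_names Character vector of `c` region names.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_leadfield <- function(lead_field, membership, region_names, path) {
  check_matrix(lead_field, "lead_field")
  jsonlite::write_json(list(lead_field = lead_field,
                            membership = as.integer(membership),
                            region_names = as.character(region_names)),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a lead field with its parcellation
#'
#' @param path JSON file written by [write_leadfield()].
#' @return List with `lead_field` (`u x v`), `membership` (length `v`),
#'   `region_names` (length `c`), dimension-checked: every membership id must
#'   name a defined region and every region must own at least one dipole.
#' @export
read_leadfield <- function(path) {
  if (!file.exists(path))
    stop_hbnet(sprintf("file not found: %s", path), "hbnet_format_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- as.matrix(obj$lead_field)
  membership <- as.integer(obj$membership)
  region_names <- as.character(obj$region_names)
  if (length(membership) != ncol(L))
    stop_hbnet("membership length does not match lead-field columns", "hbnet_consistency_error")
  c_ <- length(region_names)
  if (any(membership < 1L) || any(membership > c_))
    stop_hbnet("membership references an undefined region", "hbnet_consistency_error")
  if (any(tabulate(membership, c_) == 0L))
    stop_hbnet("a region has no dipoles", "hbnet_consistency_error")
  list(lead_field = unname(L), membership = membership, region_names = region_names)
}

## ---- minimal EDF (continuous, one data record) ----

.pad <- function(s, width) {
  s <- substr(s, 1L, width)
  formatC(s, width = -width, flag = " ")
}

.write_edf <- function(data, fs, channel_names, path) {
  ns <- nrow(data); n <- ncol(data)
  dur <- n / fs
  pmin <- apply(data, 1L, min); pmax <- apply(data, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(.pad("0", 8), .pad("hbnet", 80), .pad("hbnet recording", 80),
                   .pad("01.01.26", 8), .pad("00.00.00", 8),
                   .pad(as.character(hdr_bytes), 8), .pad("", 44),
                   .pad("1", 8), .pad(formatC(dur, format = "g", digits = 6), 8),
                   .pad(as.character(ns), 4)),
            con, eos = NULL)
  fld <- function(vals, width) writeChar(paste(vapply(vals, .pad, "", width),
                                               collapse = ""), con, eos = NULL)
  fld(channel_names, 16)
  fld(rep("", ns), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(pmin, format = "g", digits = 6), 8)
  fld(formatC(pmax, format = "g", digits = 6), 8)
  fld(rep(as.character(dmin), ns), 8)
  fld(rep(as.character(dmax), ns), 8)
  fld(rep("", ns), 80)
  fld(rep(as.character(n), ns), 8)
  fld(rep("", ns), 32)
  for (i in seq_len(ns)) {
    dig <- round((data[i, ] - pmin[i]) / (pmax[i] - pmin[i]) * (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

.read_edf <- function(path) {
  if (!file.exists(path))
    stop_hbnet(sprintf("file not found: %s", path), "hbnet_format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L)
    stop_hbnet("malformed or truncated EDF header", "hbnet_format_error")
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fld(16)
  fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  nsamp <- as.integer(fld(8))
  fld(32)
  data <- matrix(0, ns, nsamp[1L] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[i], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < nsamp[i])
        stop_hbnet("truncated EDF data record", "hbnet_format_error")
      data[i, ((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])] <-
        (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
    }
  }
  list(data = data, fs = nsamp[1L] / dur, channel_names = labels)
}

## ---- minimal MAT v5 (uncompressed double matrices) ----

#' Write matrices to a MAT v5 file
#'
#' Minimal writer covering uncompressed double-precision 2-D matrices,
#' sufficient for the per-trial MAT layout of concurrent EEG/fNIRS datasets.
#'
#' @param vars Named list of numeric matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- .pad("MATLAB 5.0 MAT-file, written by hbnet", 116)
  writeChar(desc, con, eos = NULL)
  writeBin(raw(8L), con)                                   # subsystem offset
  writeBin(c(0x00L, 0x01L), con, size = 1L)                # version 0x0100 LE
  writeChar("IM", con, eos = NULL)                         # endianness
  pad8 <- function(nb) (8L - nb %% 8L) %% 8L
  for (nm in names(vars)) {
    m <- as.matrix(vars[[nm]])
    storage.mode(m) <- "double"
    name_raw <- charToRaw(nm)
    sizes <- c(16L,                                        # array flags
               16L,                                        # dimensions
               8L + length(name_raw) + pad8(length(name_raw)),
               8L + 8L * length(m) + pad8(8L * length(m)))
    writeBin(c(14L, sum(sizes)), con, size = 4L, endian = "little")
    writeBin(c(6L, 8L), con, size = 4L, endian = "little") # miUINT32, 8 bytes
    writeBin(c(6L, 0L), con, size = 4L, endian = "little") # mxDOUBLE_CLASS
    writeBin(c(5L, 8L), con, size = 4L, endian = "little") # miINT32, 8 bytes
    writeBin(c(nrow(m), ncol(m)), con, size = 4L, endian = "little")
    writeBin(c(1L, length(name_raw)), con, size = 4L, endian = "little")
    writeBin(name_raw, con)
    writeBin(raw(pad8(length(name_raw))), con)
    writeBin(c(9L, 8L * length(m)), con, size = 4L, endian = "little")
    writeBin(as.vector(m), con, size = 8L, endian = "little")
    writeBin(raw(pad8(8L * length(m))), con)
  }
  invisible(path)
}

#' Read matrices from a MAT v5 file
#'
#' Minimal reader for uncompressed MAT v5 files holding double 2-D matrices
#' (the subset [write_mat5()] emits and the subset per-trial EEG/fNIRS MAT
#' layouts need). Compressed elements and non-double classes raise errors.
#'
#' @param path Input path.
#' @return Named list of numeric matrices.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path))
    stop_hbnet(sprintf("file not found: %s", path), "hbnet_format_error")
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 126L)
  endian_tag <- readChar(con, 2L, useBytes = TRUE)
  if (!identical(endian_tag, "IM"))
    stop_hbnet("big-endian MAT files are not supported", "hbnet_format_error")
  vars <- list()
  pos <- 128L
  read_tag <- function() {
    word1 <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(word1) == 0L) return(NULL)
    small_size <- bitwAnd(bitwShiftR(word1, 16L), 0xFFFFL)
    if (small_size > 0L) {
      list(type = bitwAnd(word1, 0xFFFFL), nbytes = small_size, small = TRUE)
    } else {
      nb <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      list(type = word1, nbytes = nb, small = FALSE)
    }
  }
  while (pos < sz) {
    tag <- read_tag()
    if (is.null(tag)) break
    if (tag$type == 15L)
      stop_hbnet("compressed MAT elements are not supported", "hbnet_format_error")
    if (tag$type != 14L) {
      skip <- tag$nbytes + (8L - tag$nbytes %% 8L) %% 8L
      readBin(con, "raw", skip)
      pos <- pos + 8L + skip
      next
    }
    body <- readBin(con, "raw", tag$nbytes)
    pos <- pos + 8L + tag$nbytes
    vars <- c(vars, .parse_mat_matrix(body))
  }
  vars
}

.parse_mat_matrix <- function(body) {
  off <- 0L
  take <- function(n) { r <- body[(off + 1L):(off + n)]; off <<- off + n; r }
  sub_tag <- function() {
    w1 <- readBin(take(4L), "integer", 1L, size = 4L, endian = "little")
    small <- bitwAnd(bitwShiftR(w1, 16L), 0xFFFFL)
    if (small > 0L) list(type = bitwAnd(w1, 0xFFFFL), nbytes = small, small = TRUE)
    else list(type = w1,
              nbytes = readBin(take(4L), "integer", 1L, size = 4L, endian = "little"),
              small = FALSE)
  }
  aligned <- function(tg) {
    if (tg$small) (4L - tg$nbytes %% 4L) %% 4L else (8L - tg$nbytes %% 8L) %% 8L
  }
  tg <- sub_tag()                                          # array flags
  flags <- readBin(take(tg$nbytes), "integer", 2L, size = 4L, endian = "little")
  take(aligned(tg))
  cls <- bitwAnd(flags[1L], 0xFFL)
  if (cls != 6L)
    stop_hbnet(sprintf("MAT array class %d not supported (double matrices only)", cls),
               "hbnet_format_error")
  tg <- sub_tag()                                          # dimensions
  dims <- readBin(take(tg$nbytes), "integer", tg$nbytes %/% 4L, size = 4L,
                  endian = "little")
  take(aligned(tg))
  tg <- sub_tag()                                          # name
  nm <- rawToChar(take(tg$nbytes))
  take(aligned(tg))
  tg <- sub_tag()                                          # real data
  if (tg$type != 9L)
    stop_hbnet("only miDOUBLE MAT payloads are supported", "hbnet_format_error")
  vals <- readBin(take(tg$nbytes), "double", tg$nbytes %/% 8L, size = 8L,
                  endian = "little")
  out <- list(matrix(vals, dims[1L], dims[2L]))
  names(out) <- nm
  out
}

## ---- dataset directory layout ----

#' Write a synthetic dataset to disk
#'
#' Lays the dataset out the way request-only concurrent EEG/fNIRS corpora
#' document theirs: one directory per subject containing `EEG/` and `FNIRS/`
#' subdirectories with one delimited trial file each, plus a lead-field JSON,
#' a ground-truth JSON sidecar and a manifest (config, seed, package
#' version, config hash).
#'
#' @param ds A `synthetic_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @param subject Subject directory name.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, subject = "sub-01") {
  stopifnot(inherits(ds, "synthetic_dataset"))
  sdir <- file.path(dir, subject)
  dir.create(file.path(sdir, "EEG"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(sdir, "FNIRS"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$trials)) {
    tr <- ds$trials[[i]]
    write_eeg(raw_eeg(tr$eeg, ds$fs_eeg), file.path(sdir, "EEG", sprintf("trial_%03d.tsv", i)))
    write_fnirs(raw_fnirs(tr$fnirs, ds$fs_fnirs, signal_kind = "hbo"),
                file.path(sdir, "FNIRS", sprintf("trial_%03d.tsv", i)))
  }
  write_leadfield(ds$lead_field, ds$membership, ds$region_names,
                  file.path(sdir, "leadfield.json"))
  gt <- ds$ground_truth
  jsonlite::write_json(list(adjacency = gt$adjacency,
                            coupling_weights = gt$coupling_weights,
                            labels = gt$labels, seed = gt$seed,
                            var_order = gt$var_order, fs = gt$fs),
                       file.path(sdir, "ground_truth.json"), digits = NA)
  cfg_json <- jsonlite::toJSON(unclass(ds$config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  jsonlite::write_json(list(config = unclass(ds$config),
                            config_hash = unname(tools::md5sum(tf)),
                            seed = gt$seed, n_trials = length(ds$trials),
                            package_version = as.character(utils::packageVersion("hbnet"))),
                       file.path(sdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  unlink(tf)
  invisible(dir)
}

#' Read a dataset directory
#'
#' @param dir Dataset root written by [write_dataset()].
#' @param subject Subject directory name; defaults to the first one found.
#' @return A `synthetic_dataset`-shaped list (trials, lead field, membership,
#'   region names, sampling rates, ground truth when present).
#' @export
read_dataset <- function(dir, subject = NULL) {
  if (is.null(subject)) {
    subject <- list.dirs(dir, recursive = FALSE, full.names = FALSE)[1L]
    if (is.na(subject)) stop_hbnet("no subject directory found", "hbnet_format_error")
  }
  sdir <- file.path(dir, subject)
  eeg_files <- sort(list.files(file.path(sdir, "EEG"), pattern = "\\.tsv$",
                               full.names = TRUE))
  fnirs_files <- sort(list.files(file.path(sdir, "FNIRS"), pattern = "\\.tsv$",
                                 full.names = TRUE))
  if (length(eeg_files) == 0L || length(eeg_files) != length(fnirs_files))
    stop_hbnet("EEG/FNIRS trial files missing or mismatched", "hbnet_format_error")
  lf <- read_leadfield(file.path(sdir, "leadfield.json"))
  gt_path <- file.path(sdir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) {
    g <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    list(adjacency = lapply(seq_len(dim(g$adjacency)[1L]), function(k) g$adjacency[k, , ]),
         coupling_weights = lapply(seq_len(dim(g$coupling_weights)[1L]),
                                   function(k) g$coupling_weights[k, , ]),
         labels = as.integer(g$labels), seed = g$seed,
         var_order = g$var_order, fs = g$fs)
  } else NULL
  fs_eeg <- fs_fnirs <- NULL
  trials <- lapply(seq_along(eeg_files), function(i) {
    tryCatch({
      e <- read_eeg(eeg_files[i])
      f <- read_fnirs(fnirs_files[i])
      fs_eeg <<- e$fs; fs_fnirs <<- f$fs
      list(eeg = e$data, fnirs = f$data,
           label = if (!is.null(gt)) gt$labels[i] else NA_integer_)
    }, error = function(err) {
      warning(sprintf("trial %d unreadable (%s); carried as NULL",
                      i, conditionMessage(err)))
      NULL
    })
  })
  structure(list(trials = trials, lead_field = lf$lead_field,
                 membership = lf$membership, region_names = lf$region_names,
                 fs_eeg = fs_eeg, fs_fnirs = fs_fnirs, config = NULL,
                 ground_truth = if (!is.null(gt)) structure(gt, class = "ground_truth")),
            class = "synthetic_dataset")
}
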