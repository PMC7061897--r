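#' @title On-disk formats
#' @description
#' The canonical container is one array file per matrix plus a JSON sidecar
#' holding the metadata (schema version, labels, sampling rate, identity).
#' `array_container` stores the matrix as little-endian float64 column-major
#' binary; `delimited` stores it as a headerless TSV (one row per channel),
#' intended for tiny fixtures. The sidecar lives at `<path>.json`. A minimal
#' EDF importer covers generic EEG interchange.
#' @name eeg_io
#' @keywords internal
NULL

SIDE_SCHEMA <- "eegfactors-container/1"

sidecar_path <- function(path) paste0(path, ".json")

write_matrix_payload <- function(mat, path, format) {
  if (format == "array_container") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(mat), con, size = 8L, endian = "little")
  } else {
    utils::write.table(format(mat, digits = 17, scientific = TRUE, trim = TRUE),
                       path, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
}

read_matrix_payload <- function(path, format, n, t) {
  if (format == "array_container") {
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = n * t, size = 8L, endian = "little")
    if (length(v) != n * t)
      stop(sprintf("array file '%s' holds %d values, expected %d x %d",
                   path, length(v), n, t))
    matrix(v, nrow = n, ncol = t)
  } else {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     colClasses = "numeric"))
    dimnames(m) <- NULL
    if (nrow(m) != n || ncol(m) != t)
      stop(sprintf("delimited file '%s' is %d x %d, sidecar says %d x %d",
                   path, nrow(m), ncol(m), n, t))
    m
  }
}

#' Write a Recording to disk
#'
#' Writes the data matrix to `path` and a JSON metadata sidecar to
#' `<path>.json`. The matrix is stored untouched (no scaling); reading the
#' pair back reproduces the object exactly.
#'
#' @param rec a [recording()].
#' @param path data file path (conventionally `.dat` for `array_container`,
#'   `.tsv` for `delimited`).
#' @param format `"array_container"` (binary float64) or `"delimited"` (TSV).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path,
                            format = c("array_container", "delimited")) {
  format <- match.arg(format)
  validate_recording(rec)
  write_matrix_payload(rec$data, path, format)
  meta <- list(schema = SIDE_SCHEMA, kind = "recording", format = format,
               subject_id = rec$subject_id, trial_id = rec$trial_id,
               channel_labels = as.list(rec$channel_labels), fs = rec$fs,
               n = nrow(rec$data), t = ncol(rec$data))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a Recording from disk
#'
#' Reads a container written by [write_recording()] (formats
#' `array_container`/`delimited`; channel order in the file is preserved in
#' memory) or a generic EDF file (format `edf`). All Recording invariants are
#' re-validated on read: duplicate or missing channel labels are a format
#' error, non-finite samples a validation error naming channel and index.
#'
#' @param path data file path (sidecar expected at `<path>.json` for
#'   non-EDF formats).
#' @param format one of `"array_container"`, `"delimited"`, `"edf"`.
#' @return A [recording()].
#' @export
read_recording <- function(path,
                           format = c("array_container", "delimited", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "edf") return(read_edf(path))
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop(sprintf("missing metadata sidecar: %s", sp))
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!identical(meta$kind, "recording"))
    stop(sprintf("sidecar '%s' describes a '%s', not a recording", sp, meta$kind))
  labels <- as.character(meta$channel_labels)
  if (length(labels) != meta$n)
    stop("sidecar channel_labels do not match declared channel count")
  dat <- read_matrix_payload(path, meta$format, meta$n, meta$t)
  recording(dat, labels, meta$fs,
            subject_id = meta$subject_id, trial_id = meta$trial_id)
}

#' Write / read a latent factor sequence
#'
#' Same container convention as recordings: matrix payload at `path`, JSON
#' sidecar at `<path>.json`. The roundtrip preserves the factor matrix to
#' full float64 precision and all metadata including `model_id`.
#'
#' @param fseq a [factor_sequence()].
#' @param path data file path.
#' @param format `"array_container"` or `"delimited"`.
#' @return `path` invisibly (write); a [factor_sequence()] (read).
#' @export
write_factors <- function(fseq, path,
                          format = c("array_container", "delimited")) {
  format <- match.arg(format)
  validate_factor_sequence(fseq)
  write_matrix_payload(fseq$factors, path, format)
  meta <- list(schema = SIDE_SCHEMA, kind = "factors", format = format,
               subject_id = fseq$subject_id, trial_id = fseq$trial_id,
               model_id = fseq$model_id, fs = fseq$fs,
               m = nrow(fseq$factors), t = ncol(fseq$factors))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_factors
#' @export
read_factors <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop(sprintf("missing metadata sidecar: %s", sp))
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!identical(meta$kind, "factors"))
    stop(sprintf("sidecar '%s' describes a '%s', not factors", sp, meta$kind))
  fac <- read_matrix_payload(path, meta$format, meta$m, meta$t)
  factor_sequence(fac, meta$fs, subject_id = meta$subject_id,
                  trial_id = meta$trial_id, model_id = meta$model_id)
}

#' Write / read trial labels as a delimited table
#'
#' Tab-separated with header columns subject_id, trial_id, dimension,
#' rating, klass.
#'
#' @param labels a [trial_labels()] table.
#' @param path file path.
#' @return `path` invisibly (write); a `TrialLabelTable` (read).
#' @export
write_labels <- function(labels, path) {
  validate_trial_labels(labels)
  utils::write.table(labels, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "numeric", "character"))
  trial_labels(df$subject_id, df$trial_id, df$dimension, df$rating, df$klass)
}

# ---- minimal EDF support -------------------------------------------------
# EDF: 256-byte fixed header + 256 bytes per signal, then 16-bit little-endian
# samples in record-major, signal-major order. Only continuous recordings with
# a common sampling rate across signals are supported; annotation channels are
# not. Digital-to-physical scaling follows the header calibration fields.

hdr_field <- function(raw, off, len) {
  trimws(rawToChar(raw[(off + 1):(off + len)]))
}

read_edf <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 256L) stop("not an EDF file (truncated header)")
  n_rec <- as.integer(hdr_field(raw, 236, 8))
  dur <- as.numeric(hdr_field(raw, 244, 8))
  ns <- as.integer(hdr_field(raw, 252, 4))
  if (is.na(ns) || ns < 1L) stop("not an EDF file (bad signal count)")
  sh <- raw[257:(256 + 256 * ns)]
  fld <- function(off, len) {
    vapply(seq_len(ns), function(i)
      trimws(rawToChar(sh[(off * ns + (i - 1) * len + 1):(off * ns + i * len)])),
      character(1))
  }
  labels <- fld(0, 16)
  phys_min <- as.numeric(fld(16 + 80 + 8, 8))      # after transducer+dim
  phys_max <- as.numeric(fld(16 + 80 + 8 + 8, 8))
  dig_min <- as.numeric(fld(16 + 80 + 8 + 16, 8))
  dig_max <- as.numeric(fld(16 + 80 + 8 + 24, 8))
  nsamp <- as.integer(fld(16 + 80 + 8 + 32 + 80, 8))
  if (length(unique(nsamp)) != 1L)
    stop("EDF signals with differing per-record sample counts are unsupported")
  spr <- nsamp[1]
  fs <- spr / dur
  off <- 256L + 256L * ns
  body <- readBin(raw[(off + 1):length(raw)], "integer", size = 2L,
                  n = n_rec * ns * spr, endian = "little", signed = TRUE)
  if (length(body) != n_rec * ns * spr) stop("EDF payload truncated")
  dat <- matrix(0, nrow = ns, ncol = n_rec * spr)
  arr <- array(body, dim = c(spr, ns, n_rec))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (i in seq_len(ns)) {
    dig <- as.vector(arr[, i, ])
    dat[i, ] <- (dig - dig_min[i]) * gain[i] + phys_min[i]
  }
  subj <- hdr_field(raw, 8, 80)
  recording(dat, labels, fs,
            subject_id = if (nzchar(subj)) strsplit(subj, " ")[[1]][1] else "unknown")
}

pad_field <- function(x, len) substr(formatC(as.character(x), width = -len), 1L, len)

# internal EDF writer (test support and data export); 16-bit quantization
write_edf <- function(rec, path, phys_range = NULL) {
  validate_recording(rec)
  n <- nrow(rec$data); t <- ncol(rec$data)
  dur <- 1; spr <- as.integer(round(rec$fs))
  if (t %% spr != 0L) stop("write_edf needs a whole number of 1 s records")
  n_rec <- t %/% spr
  if (is.null(phys_range)) {
    amax <- max(abs(rec$data), 1e-12)
    phys_range <- c(-amax, amax)
  }
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, len) writeChar(pad_field(x, len), con, nchars = len, eos = NULL)
  w("0", 8); w(rec$subject_id, 80); w("Startdate X", 80)
  w("01.01.00", 8); w("00.00.00", 8); w(256 + 256 * n, 8); w("", 44)
  w(n_rec, 8); w(dur, 8); w(n, 4)
  for (lab in rec$channel_labels) w(lab, 16)
  for (i in 1:n) w("", 80)                 # transducer
  for (i in 1:n) w("uV", 8)                # physical dimension
  for (i in 1:n) w(format(phys_range[1], digits = 6), 8)
  for (i in 1:n) w(format(phys_range[2], digits = 6), 8)
  for (i in 1:n) w(dmin, 8)
  for (i in 1:n) w(dmax, 8)
  for (i in 1:n) w("", 80)                 # prefiltering
  for (i in 1:n) w(spr, 8)
  for (i in 1:n) w("", 32)                 # reserved
  gain <- (phys_range[2] - phys_range[1]) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(n)) {
      dig <- round((rec$data[i, idx] - phys_range[1]) / gain + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
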