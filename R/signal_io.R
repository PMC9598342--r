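# On-disk formats. PPG records travel as CSV (`time_s,ppg[,resp]`) or as
# minimal WFDB header+signal pairs (format 16, read/write of a PLETH channel
# only). Window sets are stored in a single RDS container (one N x L matrix
# plus a label/provenance table) so ~3000 windows load in well under a second.
# Time is in seconds everywhere; window coordinates are half-open
# [start, start + window_s).

#' PPG record
#'
#' One subject's PPG waveform plus annotations. Either breath onset times or
#' per-window RR labels may be present (or neither, for unlabelled data).
#'
#' @param samples numeric vector, finite, non-empty (arbitrary PPG units).
#' @param sample_rate_hz positive sampling rate.
#' @param subject_id,record_id identifier strings.
#' @param breath_times_s optional strictly increasing breath onset times (s).
#' @param rr_labels optional data.frame with columns `window_start_s`,
#'   `rr_bpm` (positive).
#' @return object of class `ppg_record`.
#' @export
ppg_record <- function(samples, sample_rate_hz, subject_id = "s1",
                       record_id = "r1", breath_times_s = NULL,
                       rr_labels = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty")
  bad <- which(!is.finite(samples))
  if (length(bad))
    stop(sprintf("non-finite sample at index %d", bad[1L]))
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0)
    stop("sample_rate_hz must be a positive scalar")
  if (!is.null(breath_times_s)) {
    breath_times_s <- as.numeric(breath_times_s)
    if (length(breath_times_s) > 1L && any(diff(breath_times_s) <= 0))
      stop("breath_times_s must be strictly increasing")
  }
  if (!is.null(rr_labels)) {
    stopifnot(is.data.frame(rr_labels),
              all(c("window_start_s", "rr_bpm") %in% names(rr_labels)))
    if (any(rr_labels$rr_bpm <= 0)) stop("rr_bpm labels must be positive")
  }
  structure(list(subject_id = subject_id, record_id = record_id,
                 samples = samples, sample_rate_hz = sample_rate_hz,
                 breath_times_s = breath_times_s, rr_labels = rr_labels),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("ppg_record %s/%s: %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, x$record_id, length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz,
              if (!is.null(x$breath_times_s))
                sprintf(", %d breath onsets", length(x$breath_times_s))
              else ""))
  invisible(x)
}

#' Read a PPG record from disk
#'
#' @param path file path. For CSV: header `time_s,ppg` with an optional
#'   `resp` column (ignored). For WFDB: path to the `.hea` header (or its
#'   basename); the record must contain a PLETH/PPG channel.
#' @param format `"csv"` or `"wfdb"`.
#' @param subject_id,record_id identifiers; default from the file name.
#' @return a [ppg_record()]. The sample rate is inferred from the median time
#'   step (CSV) or taken from the header (WFDB); the signal is never resampled
#'   on read.
#' @export
read_record <- function(path, format = c("csv", "wfdb"),
                        subject_id = NULL, record_id = NULL) {
  format <- match.arg(format)
  if (is.null(record_id))
    record_id <- tools::file_path_sans_ext(basename(path))
  if (is.null(subject_id)) subject_id <- record_id
  switch(format,
         csv = read_record_csv(path, subject_id, record_id),
         wfdb = read_record_wfdb(path, subject_id, record_id))
}

read_record_csv <- function(path, subject_id, record_id) {
  if (!file.exists(path)) stop("missing file: ", path)
  d <- data.table::fread(path, data.table = FALSE)
  if (!all(c("time_s", "ppg") %in% names(d)))
    stop("CSV must have columns time_s,ppg: ", path)
  dt <- diff(d$time_s)
  if (length(dt) == 0L) stop("record has fewer than 2 samples: ", path)
  if (any(dt <= 0))
    stop(sprintf("non-monotonic time column at row %d in %s",
                 which(dt <= 0)[1L] + 1L, path))
  bad <- which(!is.finite(d$ppg))
  if (length(bad))
    stop(sprintf("NaN/non-finite ppg sample at row %d in %s", bad[1L], path))
  # breath annotations travel in an optional sidecar next to the waveform
  bpath <- paste0(tools::file_path_sans_ext(path), ".breaths.csv")
  bt <- NULL
  if (file.exists(bpath)) {
    bd <- data.table::fread(bpath, data.table = FALSE)
    bt <- bd$breath_time_s
  }
  ppg_record(d$ppg, 1 / median(dt), subject_id, record_id,
             breath_times_s = bt)
}

#' Write breath annotations as a sidecar CSV
#'
#' Stored next to the waveform as `<record>.breaths.csv` (single column
#' `breath_time_s`); [read_record()] picks the sidecar up automatically.
#'
#' @param record a [ppg_record()] with `breath_times_s`.
#' @param path path of the waveform CSV the sidecar belongs to.
#' @return sidecar path, invisibly.
#' @export
write_breaths_csv <- function(record, path) {
  stopifnot(!is.null(record$breath_times_s))
  bpath <- paste0(tools::file_path_sans_ext(path), ".breaths.csv")
  data.table::fwrite(data.frame(
    breath_time_s = sprintf("%.10g", record$breath_times_s)), bpath,
    quote = FALSE)
  invisible(bpath)
}

#' Write a PPG record as CSV
#'
#' Format `time_s,ppg`, full `%.10g` precision so round-trips do not drift.
#'
#' @param record a [ppg_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  t <- (seq_along(record$samples) - 1L) / record$sample_rate_hz
  d <- data.frame(time_s = sprintf("%.10g", t),
                  ppg = sprintf("%.10g", record$samples))
  data.table::fwrite(d, path, quote = FALSE)
  invisible(path)
}

# --- minimal WFDB (header + format-16 signal) ------------------------------

#' Write a record as a minimal WFDB pair (format 16)
#'
#' Emits `<name>.hea` + `<name>.dat` with a single PLETH channel, 16-bit
#' little-endian with the stated gain. Intended for fixtures emulating
#' bedside-monitor exports; quantization to 1/gain units applies.
#'
#' @param record a [ppg_record()].
#' @param path output path without extension.
#' @param gain ADC units per physical unit (default 1024).
#' @return `path`, invisibly.
#' @export
write_record_wfdb <- function(record, path, gain = 1024) {
  name <- basename(path)
  adc <- as.integer(round(record$samples * gain))
  if (any(abs(adc) > 32767)) stop("signal exceeds int16 range at gain ", gain)
  hea <- c(sprintf("%s 1 %g %d", name, record$sample_rate_hz,
                   length(adc)),
           sprintf("%s.dat 16 %g(0)/NU 16 0 %d 0 0 PLETH", name, gain,
                   adc[1L]))
  writeLines(hea, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2L, endian = "little")
  invisible(path)
}

read_record_wfdb <- function(path, subject_id, record_id) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("missing file: ", hea_path)
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(top[3L]) else 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  sig <- lapply(lines[2L:(1L + nsig)], function(l)
    strsplit(trimws(l), "\\s+")[[1L]])
  desc <- vapply(sig, function(s)
    paste(s[-(1:8)], collapse = " "), character(1))
  ch <- grep("PLETH|PPG", desc, ignore.case = TRUE)
  if (!length(ch)) stop("no PPG/PLETH channel in ", hea_path)
  ch <- ch[1L]
  fmt <- sig[[ch]][2L]
  if (fmt != "16") stop("unsupported WFDB signal format: ", fmt)
  gain_field <- sig[[ch]][3L]
  gain <- as.numeric(sub("\\(.*", "", gain_field))
  baseline <- if (grepl("\\(", gain_field))
    as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_field)) else 0
  if (!is.finite(gain) || gain == 0) gain <- 200
  dat_path <- file.path(dirname(hea_path), sig[[ch]][1L])
  n_tot <- file.size(dat_path) / 2L
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n_tot, size = 2L, endian = "little",
                 signed = TRUE)
  m <- matrix(raw, nrow = nsig)  # interleaved samples
  x <- (m[ch, ] - baseline) / gain
  if (!is.na(nsamp)) x <- x[seq_len(min(nsamp, length(x)))]
  ppg_record(x, fs, subject_id, record_id)
}

# --- window sets ------------------------------------------------------------

#' Window set
#'
#' Fixed-length signal windows with optional per-window RR labels and
#' provenance (subject, record, start time).
#'
#' @param windows numeric matrix, one window per row (N x L).
#' @param sample_rate_hz positive sampling rate of the windows.
#' @param rr_bpm optional numeric labels, length N, positive and finite.
#' @param subject_id,record_id character vectors, length N (recycled from
#'   scalars).
#' @param start_s numeric window start times (s), length N.
#' @return object of class `window_set`.
#' @export
window_set <- function(windows, sample_rate_hz, rr_bpm = NULL,
                       subject_id = "s1", record_id = "r1", start_s = NULL) {
  if (!is.matrix(windows)) windows <- matrix(windows, nrow = length(windows) > 0)
  n <- nrow(windows)
  if (is.null(start_s)) start_s <- rep(NA_real_, n)
  if (!is.null(rr_bpm)) {
    if (length(rr_bpm) != n) stop("label count != window count")
    if (n > 0 && (!all(is.finite(rr_bpm)) || any(rr_bpm <= 0)))
      stop("rr_bpm labels must be finite and positive")
  }
  structure(list(windows = windows, sample_rate_hz = sample_rate_hz,
                 rr_bpm = rr_bpm,
                 subject_id = rep_len(as.character(subject_id), n),
                 record_id = rep_len(as.character(record_id), n),
                 start_s = rep_len(as.numeric(start_s), n)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows x %d samples @ %g Hz%s\n",
              nrow(x$windows), ncol(x$windows), x$sample_rate_hz,
              if (!is.null(x$rr_bpm)) " (labelled)" else ""))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a [window_set()].
#' @return integer count.
#' @export
n_windows <- function(ws) nrow(ws$windows)

#' Subset a window set by window index
#' @param ws a [window_set()].
#' @param idx integer indices of windows to keep.
#' @return a [window_set()].
#' @export
ws_subset <- function(ws, idx) {
  window_set(ws$windows[idx, , drop = FALSE], ws$sample_rate_hz,
             rr_bpm = if (!is.null(ws$rr_bpm)) ws$rr_bpm[idx],
             subject_id = ws$subject_id[idx], record_id = ws$record_id[idx],
             start_s = ws$start_s[idx])
}

#' Concatenate window sets
#' @param ... [window_set()] objects with equal window length and rate.
#' @return a [window_set()].
#' @export
ws_bind <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "window_set"))
    parts <- parts[[1L]]
  stopifnot(length(parts) >= 1L)
  fs <- parts[[1L]]$sample_rate_hz
  L <- ncol(parts[[1L]]$windows)
  for (p in parts) stopifnot(p$sample_rate_hz == fs, ncol(p$windows) == L)
  labelled <- !vapply(parts, function(p) is.null(p$rr_bpm), logical(1))
  if (any(labelled) && !all(labelled))
    stop("cannot bind labelled with unlabelled window sets")
  window_set(do.call(rbind, lapply(parts, `[[`, "windows")), fs,
             rr_bpm = if (all(labelled))
               unlist(lapply(parts, `[[`, "rr_bpm")),
             subject_id = unlist(lapply(parts, `[[`, "subject_id")),
             record_id = unlist(lapply(parts, `[[`, "record_id")),
             start_s = unlist(lapply(parts, `[[`, "start_s")))
}

#' Write / read a window set
#'
#' Single binary container (RDS): the N x L matrix plus the label/provenance
#' table. Round-trips are bit-exact.
#'
#' @param ws a [window_set()] (all windows the same length by construction).
#' @param path file path.
#' @return `write_windows`: `path` invisibly; `read_windows`: a
#'   [window_set()].
#' @export
write_windows <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  saveRDS(unclass(ws), path)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  x <- readRDS(path)
  structure(x, class = "window_set")
}

# --- manifests, predictions, metrics ---------------------------------------

#' Dataset manifest
#'
#' @param path character vector of record paths (unique).
#' @param subject_id character vector of subject ids.
#' @param fs_hz declared sample rates (positive).
#' @param label_source label provenance tag per record (e.g. "breath_times").
#' @param dataset_name name for the collection.
#' @return object of class `dataset_manifest` (a data.frame with attribute
#'   `dataset_name`).
#' @export
dataset_manifest <- function(path, subject_id, fs_hz, label_source,
                             dataset_name = "dataset") {
  if (anyDuplicated(path)) stop("manifest paths must be unique")
  if (length(path) && any(fs_hz <= 0)) stop("declared sample rates must be positive")
  structure(data.frame(path = as.character(path),
                       subject_id = as.character(subject_id),
                       fs_hz = as.numeric(fs_hz),
                       label_source = as.character(label_source),
                       stringsAsFactors = FALSE),
            dataset_name = dataset_name,
            class = c("dataset_manifest", "data.frame"))
}

#' Write / read a dataset manifest (CSV `path,subject_id,fs_hz,label_source`)
#' @param manifest a [dataset_manifest()].
#' @param path CSV path.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: a
#'   [dataset_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(as.data.frame(manifest), path)
  invisible(path)
}

#' @rdname write_manifest
#' @param dataset_name name attached on read.
#' @export
read_manifest <- function(path, dataset_name = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  d <- data.table::fread(path, data.table = FALSE, colClasses =
                           c(path = "character", subject_id = "character",
                             label_source = "character"))
  if (is.null(dataset_name))
    dataset_name <- tools::file_path_sans_ext(basename(path))
  dataset_manifest(d$path, d$subject_id, d$fs_hz, d$label_source, dataset_name)
}

#' Write predictions as CSV (`window_id,subject_id,rr_true,rr_pred`)
#' @param ps a [prediction_set()].
#' @param path CSV path.
#' @param subject_id optional per-window subject ids.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(ps, path, subject_id = NA_character_) {
  ps <- as_prediction_set(ps)
  d <- data.frame(window_id = seq_len(ps$n),
                  subject_id = rep_len(subject_id, ps$n),
                  rr_true = ps$rr_true, rr_pred = ps$rr_pred)
  data.table::fwrite(d, path)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#' @param path CSV path.
#' @return a [prediction_set()].
#' @export
read_predictions <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  prediction_set(d$rr_pred, d$rr_true)
}

#' Write / read a metrics report as JSON
#' @param report a [metrics_report()].
#' @param path JSON path.
#' @return `write_metrics_json`: `path` invisibly; `read_metrics_json`: the
#'   report as a list.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  out <- unclass(report)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) round(v, 4))  # table precision
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
read_metrics_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
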