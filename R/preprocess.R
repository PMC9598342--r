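# Preprocessing chain: resample -> zero-phase low-pass -> VMD motion-artifact
# removal -> 16 s / 50 % segmentation -> per-window RR labelling.

#' Low-pass filter specification
#'
#' Defaults match the pipeline's denoising stage: 6th-order Butterworth with a
#' 25 Hz cut-off, applied forward-backward (zero phase, effective 12th-order
#' magnitude).
#'
#' @param order positive integer filter order.
#' @param cutoff_hz positive cut-off frequency (must stay below Nyquist when
#'   applied).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(order = 6L, cutoff_hz = 25) {
  stopifnot(order >= 1, cutoff_hz > 0)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 kind = "lowpass"), class = "filter_spec")
}

#' Resample a signal to a new rate
#'
#' FFT-domain resampling: the spectrum is truncated (downsampling, which is
#' inherently anti-aliasing) or zero-padded (upsampling), so band-limited
#' content below both Nyquist frequencies is preserved essentially exactly.
#' Output length is `round(length(x) * to_hz / from_hz)`.
#'
#' @param x numeric signal, length >= 2.
#' @param from_hz,to_hz positive sample rates.
#' @return resampled numeric vector.
#' @export
resample_signal <- function(x, from_hz, to_hz) {
  if (from_hz <= 0 || to_hz <= 0) stop("sample rates must be positive")
  n <- length(x)
  if (n < 2L) stop("signal too short to resample")
  if (from_hz == to_hz) return(x)
  n_out <- round(n * to_hz / from_hz)
  if (n_out < 2L) stop("target rate too low for this signal length")
  X <- fft(x)
  Y <- complex(length.out = n_out)
  # number of positive-frequency bins to carry over (excluding DC)
  keep <- min(floor((n - 1) / 2), floor((n_out - 1) / 2))
  Y[1L] <- X[1L]
  if (keep > 0) {
    Y[2L:(keep + 1L)] <- X[2L:(keep + 1L)]
    Y[n_out - (0:(keep - 1L))] <- X[n - (0:(keep - 1L))]
  }
  # fold the source Nyquist bin if it lands inside the output band
  if (n %% 2L == 0L && n / 2L + 1L <= keep + 1L) {
    # already copied above as an ordinary bin pair; nothing to do
  } else if (n %% 2L == 0L && n_out %% 2L == 0L && n_out / 2L == n / 2L) {
    Y[n_out / 2L + 1L] <- X[n / 2L + 1L]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

# steady-state initial conditions for a direct-form-II-transposed IIR filter,
# scaled by the first sample (the standard lfilter_zi construction)
iir_steady_state <- function(b, a) {
  nfilt <- max(length(a), length(b))
  a <- c(a, numeric(nfilt - length(a)))
  b <- c(b, numeric(nfilt - length(b)))
  b <- b / a[1L]; a <- a / a[1L]
  if (nfilt == 1L) return(numeric(0))
  A <- matrix(0, nfilt - 1L, nfilt - 1L)  # companion of a, transposed
  A[, 1L] <- -a[-1L]
  if (nfilt > 2L) A[cbind(1:(nfilt - 2L), 2:(nfilt - 1L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(nfilt - 1L) - A, B)
}

#' Zero-phase low-pass filtering
#'
#' Butterworth IIR design applied forward then backward, so the magnitude
#' response is squared and the phase response is identically zero. Edge
#' transients are suppressed by odd-symmetric reflection padding with
#' steady-state initial filter conditions.
#'
#' @param x numeric signal.
#' @param fs_hz sampling rate; must exceed twice the cut-off.
#' @param spec a [filter_spec()].
#' @return filtered signal, same length as `x`; DC gain is exactly 1.
#' @export
lowpass_zero_phase <- function(x, fs_hz, spec = filter_spec()) {
  if (fs_hz <= 2 * spec$cutoff_hz)
    stop("cutoff at or above Nyquist: need fs > 2 * cutoff")
  bf <- signal::butter(spec$order, spec$cutoff_hz / (fs_hz / 2), "low")
  b <- bf$b; a <- bf$a
  pad <- 3L * (spec$order + 1L)
  if (length(x) <= pad)
    stop(sprintf("signal too short for edge padding (need > %d samples)", pad))
  # odd-symmetric reflection about the end points
  ext <- c(2 * x[1L] - x[(pad + 1L):2L], x,
           2 * x[length(x)] - x[(length(x) - 1L):(length(x) - pad)])
  zi <- iir_steady_state(b, a)
  y <- iir_df2t(b, a, ext, zi * ext[1L])
  y <- rev(y)
  y <- iir_df2t(b, a, y, zi * y[1L])
  y <- rev(y)
  y[(pad + 1L):(pad + length(x))]
}

#' Segment a signal into fixed windows
#'
#' Sliding windows of `window_s` seconds with fractional `overlap`; the
#' trailing partial window is discarded. Window length is
#' `round(window_s * fs)`, hop is `round(window_s * (1 - overlap) * fs)`.
#'
#' @param x numeric signal.
#' @param fs_hz sampling rate.
#' @param window_s window length in seconds (default 16).
#' @param overlap fraction in [0, 1) (default 0.5).
#' @param subject_id,record_id provenance carried onto every window.
#' @return an unlabelled [window_set()] with `start_s` provenance.
#' @export
segment_windows <- function(x, fs_hz, window_s = 16, overlap = 0.5,
                            subject_id = "s1", record_id = "r1") {
  if (window_s <= 0) stop("window_s must be positive")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  L <- round(window_s * fs_hz)
  if (L < 1) stop("window shorter than one sample")
  hop <- round(window_s * (1 - overlap) * fs_hz)
  n <- length(x)
  n_win <- if (n >= L) (n - L) %/% hop + 1L else 0L
  starts <- (seq_len(n_win) - 1L) * hop
  w <- matrix(0, n_win, L)
  for (i in seq_len(n_win)) w[i, ] <- x[(starts[i] + 1L):(starts[i] + L)]
  window_set(w, fs_hz, subject_id = subject_id, record_id = record_id,
             start_s = starts / fs_hz)
}

#' Label windows with reference RR
#'
#' If the record carries explicit `rr_labels`, each window takes the label
#' whose `window_start_s` matches its start. Otherwise the label is the median
#' instantaneous rate `60 / dt` over the consecutive breath-onset intervals
#' that overlap the half-open window; windows overlapped by no complete
#' interval are dropped. Labels outside the declared plausible range are kept
#' but flagged.
#'
#' @param ws an unlabelled [window_set()] with `start_s` set.
#' @param record the source [ppg_record()] providing the label source.
#' @param window_s window length in seconds (for the half-open interval).
#' @param plausible_range labels outside this range (bpm) are flagged
#'   (default the declared 5-32 bpm cohort range).
#' @return a labelled [window_set()]; attribute `flagged` marks labels outside
#'   `plausible_range`.
#' @export
label_windows <- function(ws, record, window_s = 16,
                          plausible_range = c(5, 32)) {
  if (is.null(record$rr_labels) && is.null(record$breath_times_s))
    stop("record has no label source (rr_labels or breath_times_s)")
  n <- n_windows(ws)
  lab <- rep(NA_real_, n)
  if (!is.null(record$rr_labels)) {
    idx <- match(round(ws$start_s, 6), round(record$rr_labels$window_start_s, 6))
    lab <- record$rr_labels$rr_bpm[idx]
  } else {
    bt <- record$breath_times_s
    if (length(bt) >= 2L) {
      iv_start <- bt[-length(bt)]
      iv_end <- bt[-1L]
      for (i in seq_len(n)) {
        s <- ws$start_s[i]
        j <- which(iv_start < s + window_s & iv_end > s)
        if (length(j)) lab[i] <- median(60 / (iv_end[j] - iv_start[j]))
      }
    }
  }
  keep <- which(is.finite(lab))
  if (!length(keep)) stop("all windows dropped: no usable labels")
  out <- window_set(ws$windows[keep, , drop = FALSE], ws$sample_rate_hz,
                    rr_bpm = lab[keep], subject_id = ws$subject_id[keep],
                    record_id = ws$record_id[keep], start_s = ws$start_s[keep])
  attr(out, "flagged") <- lab[keep] < plausible_range[1L] |
    lab[keep] > plausible_range[2L]
  out
}

#' Per-window z-score normalization
#' @param ws a [window_set()].
#' @return a [window_set()] with each window centred and scaled to unit SD
#'   (constant windows are left centred only).
#' @export
normalize_windows <- function(ws) {
  w <- ws$windows
  mu <- rowMeans(w)
  w <- w - mu
  s <- sqrt(rowMeans(w^2))
  s[s == 0] <- 1
  ws$windows <- w / s
  ws
}

#' Full preprocessing of one record
#'
#' Stages in order: resample to `target_fs`, zero-phase low-pass, VMD
#' motion-artifact removal (drop the highest-frequency mode), segmentation,
#' labelling, and optional per-window z-score normalization.
#'
#' @param record a [ppg_record()] with a label source.
#' @param target_fs target sampling rate (Hz, default 125).
#' @param fspec a [filter_spec()].
#' @param vmd a [vmd_params()]; set `NULL` to skip artifact removal.
#' @param window_s,overlap segmentation parameters.
#' @param normalize one of `"zscore"`, `"none"`.
#' @return a labelled [window_set()].
#' @export
preprocess_record <- function(record, target_fs = 125,
                              fspec = filter_spec(), vmd = vmd_params(),
                              window_s = 16, overlap = 0.5,
                              normalize = c("zscore", "none")) {
  normalize <- match.arg(normalize)
  x <- record$samples
  if (record$sample_rate_hz != target_fs)
    x <- resample_signal(x, record$sample_rate_hz, target_fs)
  x <- lowpass_zero_phase(x, target_fs, fspec)
  if (!is.null(vmd)) x <- remove_motion_artifact(x, target_fs, vmd)
  ws <- segment_windows(x, target_fs, window_s, overlap,
                        subject_id = record$subject_id,
                        record_id = record$record_id)
  ws <- label_windows(ws, record, window_s)
  if (normalize == "zscore") ws <- normalize_windows(ws)
  ws
}

#' Preprocess every record of a manifest into one window set
#'
#' @param manifest a [dataset_manifest()]; record files are resolved relative
#'   to `base_dir` when given.
#' @param base_dir optional directory prefix for manifest paths.
#' @param ... passed to [preprocess_record()].
#' @return a labelled, pooled [window_set()].
#' @export
preprocess_manifest <- function(manifest, base_dir = NULL, ...) {
  paths <- manifest$path
  if (!is.null(base_dir)) paths <- file.path(base_dir, paths)
  parts <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    rec <- read_record(paths[i], format = "csv",
                       subject_id = manifest$subject_id[i])
    parts[[i]] <- preprocess_record(rec, ...)
  }
  ws_bind(parts)
}
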