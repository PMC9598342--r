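# Synthetic PPG with the three respiratory couplings the estimator exploits:
# baseline (intensity) modulation, pulse-amplitude modulation and pulse-
# frequency modulation, plus white noise and transient motion-artifact bursts.
# Beats come from an integrate-and-fire model over the instantaneous heart
# rate; each beat renders a two-Gaussian pulse (systolic peak + dicrotic
# notch) so the morphology is parameterizable and license-free.

#' Synthetic record configuration
#'
#' @param duration_s record length in seconds.
#' @param fs_hz sampling rate (default 125 Hz, the common bedside-monitor
#'   rate the pipeline targets).
#' @param hr_bpm mean heart rate in [50, 100].
#' @param rr_bpm respiration rate in [5, 32] (the declared label range).
#' @param depth_baseline,depth_amplitude,depth_frequency modulation depths of
#'   the respiratory-induced intensity, amplitude and frequency variations
#'   (defaults 0.2, 0.2, 0.05; all < 1).
#' @param noise_sd white-noise standard deviation (signal units).
#' @param artifact_rate_per_min expected transient artifact bursts per minute.
#' @param seed integer RNG seed; every draw derives from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 64, fs_hz = 125, hr_bpm = 70,
                         rr_bpm = 15, depth_baseline = 0.2,
                         depth_amplitude = 0.2, depth_frequency = 0.05,
                         noise_sd = 0.02, artifact_rate_per_min = 0,
                         seed = 1L) {
  stopifnot(duration_s > 0, fs_hz > 0,
            hr_bpm >= 50, hr_bpm <= 100,
            rr_bpm >= 5, rr_bpm <= 32,
            depth_baseline >= 0, depth_baseline < 1,
            depth_amplitude >= 0, depth_amplitude < 1,
            depth_frequency >= 0, depth_frequency < 1,
            noise_sd >= 0, artifact_rate_per_min >= 0,
            fs_hz > 2 * (hr_bpm / 60 * 10))  # pulse harmonics representable
  structure(list(duration_s = duration_s, fs_hz = fs_hz, hr_bpm = hr_bpm,
                 rr_bpm = rr_bpm, depth_baseline = depth_baseline,
                 depth_amplitude = depth_amplitude,
                 depth_frequency = depth_frequency, noise_sd = noise_sd,
                 artifact_rate_per_min = artifact_rate_per_min,
                 seed = as.integer(seed)), class = "synth_config")
}

# two-Gaussian pulse: systolic peak + dicrotic notch, phase in beat units
pulse_template <- function(phase) {
  exp(-((phase - 0.28) / 0.11)^2) + 0.42 * exp(-((phase - 0.62) / 0.16)^2)
}

#' Generate one synthetic PPG record
#'
#' Beat onsets are the integer crossings of the integrated instantaneous rate
#' `hr * (1 + d_f * sin(2 pi f_r t)) / 60` (f_r = rr/60). Each beat renders
#' the two-Gaussian template over its own interval, scaled by
#' `1 + d_a * sin(2 pi f_r t_beat)`; a baseline `d_b * sin(2 pi f_r t)` and
#' white noise are added, plus Poisson-placed high-frequency artifact bursts.
#' Breath onsets are emitted every `60 / rr` seconds.
#'
#' @param cfg a [synth_config()].
#' @param subject_id,record_id identifiers.
#' @return a [ppg_record()] with `breath_times_s` set.
#' @export
generate_ppg <- function(cfg, subject_id = "synth", record_id = "synth-1") {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  n <- round(cfg$duration_s * cfg$fs_hz)
  t <- (seq_len(n) - 1L) / cfg$fs_hz
  f_r <- cfg$rr_bpm / 60

  # integrate-and-fire beat onsets
  inst_rate <- cfg$hr_bpm / 60 * (1 + cfg$depth_frequency * sin(2 * pi * f_r * t))
  phase <- cumsum(inst_rate) / cfg$fs_hz
  n_beats <- floor(phase[n])
  beat_t <- numeric(n_beats)
  for (b in seq_len(n_beats)) {       # linear interpolation of the crossing
    i <- which(phase >= b)[1L]
    if (i == 1L) { beat_t[b] <- t[1L]; next }
    frac <- (b - phase[i - 1L]) / (phase[i] - phase[i - 1L])
    beat_t[b] <- t[i - 1L] + frac / cfg$fs_hz
  }

  x <- numeric(n)
  intervals <- diff(c(beat_t, cfg$duration_s))
  med_T <- median(intervals)
  for (b in seq_len(n_beats)) {
    Tb <- if (b < n_beats) beat_t[b + 1L] - beat_t[b] else med_T
    amp <- 1 + cfg$depth_amplitude * sin(2 * pi * f_r * beat_t[b])
    i0 <- max(1L, ceiling(beat_t[b] * cfg$fs_hz) + 1L)
    i1 <- min(n, floor((beat_t[b] + Tb) * cfg$fs_hz) + 1L)
    if (i1 < i0) next
    ph <- (t[i0:i1] - beat_t[b]) / Tb
    x[i0:i1] <- x[i0:i1] + amp * pulse_template(ph)
  }

  x <- x + cfg$depth_baseline * sin(2 * pi * f_r * t)
  if (cfg$noise_sd > 0) x <- x + rnorm(n, sd = cfg$noise_sd)

  if (cfg$artifact_rate_per_min > 0) {
    n_art <- rpois(1L, cfg$artifact_rate_per_min * cfg$duration_s / 60)
    for (a in seq_len(n_art)) {
      t0 <- runif(1L, 0, cfg$duration_s)
      dur <- runif(1L, 0.5, 1.5)
      f_art <- runif(1L, 8, 15)        # high-frequency burst, inside passband
      i0 <- max(1L, round(t0 * cfg$fs_hz))
      i1 <- min(n, round((t0 + dur) * cfg$fs_hz))
      if (i1 <= i0) next
      tt <- t[i0:i1] - t0
      env <- sin(pi * tt / dur)^2       # Hann envelope
      x[i0:i1] <- x[i0:i1] + 1.5 * env * sin(2 * pi * f_art * tt)
    }
  }

  breaths <- seq(0, cfg$duration_s - 1e-9, by = 60 / cfg$rr_bpm)
  ppg_record(x, cfg$fs_hz, subject_id, record_id, breath_times_s = breaths)
}

#' Parameter ranges for a synthetic cohort
#'
#' Two built-in domains mirror the healthy-volunteer vs ICU contrast the
#' transfer experiments need: `"healthy"` uses the wide RR range 5-32 bpm
#' with baseline noise (SD 0.25), `"icu"` the narrower 5-25 bpm with doubled
#' noise. The noise contrast is calibrated so that a model trained on one
#' domain measurably degrades on the other — the regime the fine-tuning
#' protocol exists for.
#'
#' @param domain `"healthy"` or `"icu"`.
#' @param duration_s record length (s).
#' @param artifact_rate_per_min artifact bursts per minute.
#' @return list of ranges consumed by [generate_dataset()].
#' @export
synth_domain <- function(domain = c("healthy", "icu"), duration_s = 64,
                         artifact_rate_per_min = 0) {
  domain <- match.arg(domain)
  list(domain = domain,
       duration_s = duration_s,
       fs_hz = 125,
       hr_range = c(50, 100),
       rr_range = if (domain == "healthy") c(5, 32) else c(5, 25),
       noise_sd = if (domain == "healthy") 0.25 else 0.5,
       artifact_rate_per_min = artifact_rate_per_min)
}

#' Generate a synthetic dataset on disk
#'
#' Samples per-record heart/respiration rates uniformly from the domain's
#' ranges with a seeded generator, writes each record (plus its breath-onset
#' sidecar) in the package's CSV format and returns the manifest.
#'
#' @param n_records number of records (>= 0).
#' @param dir output directory (created if needed).
#' @param domain a [synth_domain()] list (or its name).
#' @param seed integer master seed; record seeds derive from it.
#' @return a [dataset_manifest()] whose paths are relative to `dir`.
#' @export
generate_dataset <- function(n_records, dir, domain = synth_domain("healthy"),
                             seed = 1L) {
  if (is.character(domain)) domain <- synth_domain(domain)
  stopifnot(n_records >= 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  paths <- character(n_records)
  subjects <- character(n_records)
  for (i in seq_len(n_records)) {
    cfg <- synth_config(
      duration_s = domain$duration_s, fs_hz = domain$fs_hz,
      hr_bpm = runif(1L, domain$hr_range[1L], domain$hr_range[2L]),
      rr_bpm = runif(1L, domain$rr_range[1L], domain$rr_range[2L]),
      noise_sd = domain$noise_sd,
      artifact_rate_per_min = domain$artifact_rate_per_min,
      seed = sample.int(.Machine$integer.max, 1L))
    subj <- sprintf("%s-%03d", domain$domain, i)
    rec <- generate_ppg(cfg, subject_id = subj, record_id = subj)
    paths[i] <- paste0(subj, ".csv")
    subjects[i] <- subj
    write_record_csv(rec, file.path(dir, paths[i]))
    write_breaths_csv(rec, file.path(dir, paths[i]))
  }
  dataset_manifest(paths, subjects, rep(domain$fs_hz, n_records),
                   rep("breath_times", n_records),
                   dataset_name = domain$domain)
}

#' Spectral reference RR estimator
#'
#' Model-free check that the respiratory rate is recoverable from a record:
#' the signal is detrended, and the periodogram peak inside the plausible
#' respiratory band (0.06-0.65 Hz, covering 3.6-39 bpm) is returned in bpm.
#' Used to verify the learning task is well-posed, not as the estimator.
#'
#' @param x numeric signal.
#' @param fs_hz sampling rate.
#' @param band frequency band searched (Hz).
#' @return estimated RR in bpm.
#' @export
rr_spectral_estimate <- function(x, fs_hz, band = c(0.06, 0.65)) {
  x <- x - mean(x)
  n_fft <- nextn(length(x) * 4L, 2)    # zero-pad for a fine frequency grid
  p <- abs(fft(c(x, numeric(n_fft - length(x)))))^2
  fr <- (seq_len(n_fft) - 1L) / n_fft * fs_hz
  sel <- which(fr >= band[1L] & fr <= band[2L])
  fr[sel][which.max(p[sel])] * 60
}
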