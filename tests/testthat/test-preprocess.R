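# Preprocessing chain oracles: analytic resampling and filter responses,
# segmentation arithmetic, labelling rules, and pipeline determinism.

test_that("resampling preserves band-limited content and output length", {
  x <- sin(2 * pi * 1.3 * (0:999) / 125)
  expect_identical(resample_signal(x, 125, 125), x)

  x500 <- sin(2 * pi * 5 * (0:7999) / 500)
  y <- resample_signal(x500, 500, 125)
  expect_length(y, 2000)
  ref <- sin(2 * pi * 5 * (0:1999) / 125)
  expect_lt(max(abs(y[100:1900] - ref[100:1900])), 1e-3)

  expect_error(resample_signal(x, 0, 125), "positive")
  expect_error(resample_signal(numeric(1), 125, 250), "short")
})

test_that("zero-phase Butterworth has unit DC gain, the squared analytic
           magnitude, and no group delay", {
  fs <- 125
  y <- lowpass_zero_phase(rep(3.7, 1000), fs)
  expect_lt(max(abs(y[30:970] - 3.7)), 1e-9)

  # 40 Hz tone: forward-backward application squares |H|
  t <- (0:1999) / fs
  x40 <- sin(2 * pi * 40 * t)
  y40 <- lowpass_zero_phase(x40, fs)
  bf <- signal::butter(6, 25 / (fs / 2), "low")
  h_at <- function(f) {
    w <- 2 * pi * f / fs
    abs(sum(bf$b * exp(-1i * w * (seq_along(bf$b) - 1))) /
          sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1))))
  }
  amp_ratio <- sd(y40[500:1500]) / sd(x40[500:1500])
  expect_equal(amp_ratio, h_at(40)^2, tolerance = 0.05)

  # zero-phase: cross-correlation of a passband tone peaks at lag 0
  x1 <- sin(2 * pi * 1 * t)
  y1 <- lowpass_zero_phase(x1, fs)
  cc <- ccf(y1, x1, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(lowpass_zero_phase(x1, 40), "Nyquist")
  expect_error(lowpass_zero_phase(rnorm(10), fs), "too short")
})

test_that("segmentation follows the window/hop arithmetic", {
  fs <- 125
  ws <- segment_windows(rnorm(480 * fs), fs)
  expect_equal(n_windows(ws), 59)
  expect_equal(ncol(ws$windows), 2000)
  expect_equal(ws$start_s, seq(0, 464, by = 8))

  expect_equal(n_windows(segment_windows(rnorm(16 * fs), fs)), 1)
  expect_equal(n_windows(segment_windows(rnorm(15 * fs), fs)), 0)
  expect_error(segment_windows(rnorm(100), fs, window_s = 0), "positive")

  # 50 % overlap: first halves of consecutive windows tile the signal
  x <- rnorm(40 * fs)
  sw <- segment_windows(x, fs)
  L <- ncol(sw$windows); hop <- L / 2
  rebuilt <- c(t(sw$windows[, 1:hop])[, ], sw$windows[n_windows(sw), (hop + 1):L])
  expect_identical(rebuilt, x[seq_along(rebuilt)])
})

test_that("labelling uses the median instantaneous rate and flags outliers", {
  fs <- 125
  # uniform breathing every 4 s -> 15 bpm everywhere
  rec <- ppg_record(rnorm(480 * fs), fs,
                    breath_times_s = seq(0, 479, by = 4))
  ws <- label_windows(segment_windows(rec$samples, fs), rec)
  expect_true(all(ws$rr_bpm == 15))

  # irregular onsets in a single window
  rec2 <- ppg_record(rnorm(16 * fs), fs, breath_times_s = c(0, 3, 7, 12, 16))
  ws2 <- label_windows(segment_windows(rec2$samples, fs), rec2)
  expect_equal(ws2$rr_bpm, 15)  # median(60/3, 60/4, 60/5)

  # explicit labels outside the plausible range are kept but flagged
  rec3 <- ppg_record(rnorm(32 * fs), fs,
                     rr_labels = data.frame(window_start_s = c(0, 8, 16),
                                            rr_bpm = c(12, 40, 18)))
  ws3 <- label_windows(segment_windows(rec3$samples, fs), rec3)
  expect_equal(ws3$rr_bpm, c(12, 40, 18))
  expect_equal(attr(ws3, "flagged"), c(FALSE, TRUE, FALSE))

  expect_error(label_windows(segment_windows(rnorm(16 * fs), fs),
                             ppg_record(rnorm(16 * fs), fs)),
               "no label source")
})

test_that("preprocess_record composes the stages and is deterministic", {
  cfg <- synth_config(duration_s = 480, fs_hz = 125, rr_bpm = 15,
                      noise_sd = 0.02, seed = 21)
  rec <- generate_ppg(cfg)
  # resample from 500 Hz exercises the rate-conversion stage
  rec500 <- ppg_record(resample_signal(rec$samples, 125, 500), 500,
                       breath_times_s = rec$breath_times_s)
  ws <- preprocess_record(rec500, vmd = vmd_params(k = 3, max_iter = 120))
  expect_equal(n_windows(ws), 59)
  expect_equal(ncol(ws$windows), 2000)
  expect_true(all(abs(ws$rr_bpm - 15) < 0.5))
  # per-window z-scoring
  expect_lt(max(abs(rowMeans(ws$windows))), 1e-10)
  expect_equal(sqrt(rowMeans(ws$windows^2)), rep(1, 59), tolerance = 1e-9)

  ws2 <- preprocess_record(rec500, vmd = vmd_params(k = 3, max_iter = 120))
  expect_identical(ws$windows, ws2$windows)
  expect_identical(ws$rr_bpm, ws2$rr_bpm)

  expect_error(preprocess_record(ppg_record(rnorm(4000), 125)),
               "no label source")
})
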