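# Small fixtures built in code: synthetic window sets with a directly
# learnable frequency-to-label mapping, and reduced model specs for fast
# training tests.

# windows are pure tones whose frequency encodes the label (bpm = f * 60);
# keeps training tests independent of the PPG generator
tone_window_set <- function(n = 60, L = 200, fs = 12.5, rr_range = c(6, 30),
                            noise = 0.05, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rr <- runif(n, rr_range[1], rr_range[2])
  t <- (seq_len(L) - 1) / fs
  w <- t(vapply(seq_len(n), function(i)
    sin(2 * pi * rr[i] / 60 * t + runif(1, 0, 2 * pi)) +
      noise * rnorm(L), numeric(L)))
  normalize_windows(window_set(w, fs, rr_bpm = rr,
                               subject_id = sprintf("s%02d", (seq_len(n) - 1) %/% 6 + 1),
                               start_s = rep(0, n)))
}

tiny_spec <- function(H = 16, depth = 1, L = 200)
  convmixer_spec(patch_size = 10, kernel_size = 7, hidden_channels = H,
                 depth = depth, input_length = L)

random_prediction_set <- function(n = 50, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  truth <- runif(n, 5, 32)
  prediction_set(truth + rnorm(n, 0.3, 1.4), truth)
}
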