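# ppgrr — respiration rate from photoplethysmogram windows

Respiration rate (RR, breaths/min) is one of the four primary vital signs,
yet outside the ICU it is still usually counted by hand. Breathing
modulates the photoplethysmogram (PPG) that every pulse oximeter and
smartwatch already records — the baseline drifts, the pulse amplitude
swells and shrinks, and the beat interval oscillates with respiratory
sinus arrhythmia. `ppgrr` turns those modulations into an RR estimate,
end to end, for researchers in physiological signal processing who want a
self-contained, testable implementation of the whole chain.

The pipeline:

1. **Preprocess** — resample to 125 Hz; zero-phase 6th-order Butterworth
   low-pass at 25 Hz (applied forward–backward, so the magnitude is
   `|H(f)|²` and the phase is identically zero); variational mode
   decomposition (VMD) into K = 5 narrow-band modes, discarding the
   highest-frequency mode as motion artifact; segmentation into 16 s
   windows with 50 % overlap; per-window z-scoring.
2. **Regress** — a 1-D ConvMixer: patch embedding (conv with kernel =
   stride = P) to L/P tokens of H channels, then `depth` blocks of
   residual depthwise convolution followed by pointwise convolution (each
   with GELU + batchnorm), global average pooling, and a single linear
   unit. The reference configuration (P = 10, kernel 7, H = 256, depth 8,
   L = 2000) has **563,201 parameters** (0.56 M) counting batchnorm
   statistics, 554,497 trainable. Forward/backward passes and the Adam
   training loop are implemented in RcppArmadillo.
3. **Evaluate** — MAE, RMSE, coefficient of determination and Pearson r,
   2SD, Bland–Altman 95 % limits of agreement (LOA = mean error ±
   1.96 SD; the half-width equals 2SD exactly), and a paired t-test for
   model comparison.

VMD solves, by ADMM in the Fourier domain,

    min Σ_k || ∂_t [ (δ(t) + j/(πt)) * u_k(t) ] e^{-j ω_k t} ||²
    s.t. Σ_k u_k = f

i.e. it finds K modes u_k with adaptively estimated center frequencies
ω_k that are maximally narrow-band and reconstruct the signal; motion
artifacts concentrate in the highest-ω mode.

A synthetic PPG generator (integrate-and-fire beats, two-Gaussian pulse
template, respiratory baseline/amplitude/frequency modulation, white
noise, Poisson artifact bursts) makes the entire system runnable and
testable without access to clinical waveform databases; two built-in
cohorts emulate a healthy-volunteer vs ICU contrast for the transfer
experiments.

## Worked example

Generate a 120-record synthetic cohort, preprocess it into labelled
windows, train a reduced ConvMixer, and evaluate on held-out windows:

```r
library(ppgrr)

dir <- file.path(tempdir(), "cohort")
man <- generate_dataset(120, dir, synth_domain("healthy", duration_s = 48),
                        seed = 1)
ws  <- preprocess_manifest(man, base_dir = dir)
ws
#> window_set: 600 windows x 2000 samples @ 125 Hz (labelled)

set.seed(1); n <- n_windows(ws); perm <- sample(n)
n_te <- round(0.2 * n); n_va <- round(0.16 * n)
te <- ws_subset(ws, perm[1:n_te])
va <- ws_subset(ws, perm[(n_te + 1):(n_te + n_va)])
tr <- ws_subset(ws, perm[(n_te + n_va + 1):n])

model <- convmixer_build(convmixer_spec(hidden_channels = 32, depth = 2),
                         seed = 1)
fit <- train_convmixer(model, tr, va,
                       train_config(epochs = 30, batch_size = 128,
                                    learning_rate = 1e-2, patience = 30,
                                    seed = 1))
report <- metrics_report(prediction_set(predict(fit$model, te), te$rr_bpm),
                         scenario = "held-out windows")
report
#> RR metrics (n = 120, held-out windows)
#>   MAE  1.7528 bpm   RMSE 1.9442 bpm
#>   R2   0.9260       Pearson r 0.9924
#>   bias 1.7229 bpm   LOA [-0.0430, 3.4888]   2SD 1.7659
```

Reading the output: MAE below 2 bpm is the usual bar for a good RR
estimator in this literature. Here nearly all of the residual error is a
systematic +1.7 bpm bias (the LOA interval barely crosses zero) while the
correlation with truth is 0.99 — exactly the kind of structure the
Bland–Altman decomposition is there to expose; a larger cohort and longer
schedule (the package defaults) shrink it. `count_parameters()` gives the
exact parameter accounting quoted above; fivefold cross-validation,
cross-dataset testing, combined-dataset training and 10/10/80 fine-tuning
are available through `run_experiment()`.

A command-line wrapper is installed at `exec/ppgrr`:

```sh
Rscript exec/ppgrr synth --out data/ --n 10 --domain healthy --seed 1
Rscript exec/ppgrr experiment --config run.yaml
```

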