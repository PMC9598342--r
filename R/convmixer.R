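# 1-D ConvMixer for RR regression. Architecture:
#   patch embedding (conv, kernel = stride = P, H filters) -> GELU -> BN
#   depth x [ residual{ depthwise conv (kernel k, 'same') -> GELU -> BN }
#             -> pointwise conv (H -> H) -> GELU -> BN ]
#   global average pooling -> linear head (1 output)
# The residual combines the block input with the first batchnorm output by
# element-wise addition (channel concatenation would double the channels per
# block and contradict the 0.56 M parameter budget of the default model).

#' ConvMixer architecture hyperparameters
#'
#' Defaults are the published configuration: patch 10, kernel 7, 256 hidden
#' channels, depth 8, on 2000-sample (16 s at 125 Hz) single-channel windows.
#'
#' @param patch_size patch length P; the input length must be divisible by it.
#' @param kernel_size depthwise kernel size, odd so 'same' padding is
#'   symmetric.
#' @param hidden_channels channel width H.
#' @param depth number of mixer blocks (0 gives patch stage + head only).
#' @param input_length window length L in samples.
#' @param input_channels number of input channels (1: single-channel PPG).
#' @return object of class `convmixer_spec`.
#' @export
convmixer_spec <- function(patch_size = 10L, kernel_size = 7L,
                           hidden_channels = 256L, depth = 8L,
                           input_length = 2000L, input_channels = 1L) {
  patch_size <- as.integer(patch_size); kernel_size <- as.integer(kernel_size)
  hidden_channels <- as.integer(hidden_channels); depth <- as.integer(depth)
  input_length <- as.integer(input_length)
  input_channels <- as.integer(input_channels)
  if (patch_size < 1L) stop("patch_size must be positive")
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop("kernel_size must be a positive odd integer")
  if (hidden_channels < 1L) stop("hidden_channels must be positive")
  if (depth < 0L) stop("depth must be non-negative")
  if (input_channels != 1L) stop("only single-channel input is supported")
  if (input_length %% patch_size != 0L)
    stop(sprintf("input_length %d not divisible by patch_size %d",
                 input_length, patch_size))
  structure(list(patch_size = patch_size, kernel_size = kernel_size,
                 hidden_channels = hidden_channels, depth = depth,
                 input_length = input_length, input_channels = input_channels),
            class = "convmixer_spec")
}

bn_names <- function(depth) {
  c("bn0", if (depth > 0) c(paste0("bn", seq_len(depth), "a"),
                            paste0("bn", seq_len(depth), "b")))
}

#' Closed-form parameter count
#'
#' @param spec a [convmixer_spec()].
#' @param include_norm_statistics if `TRUE` each batchnorm contributes 4H
#'   values (scale, shift and the two running statistics, the framework-style
#'   "total params"); if `FALSE` only the 2H trainable ones.
#' @return integer parameter count. The default spec gives 563,201 with
#'   statistics (0.56 M) and 554,497 trainable.
#' @export
count_parameters <- function(spec, include_norm_statistics = TRUE) {
  P <- spec$patch_size; H <- spec$hidden_channels
  k <- spec$kernel_size; d <- spec$depth
  bn <- if (include_norm_statistics) 4L * H else 2L * H
  patch <- P * spec$input_channels * H + H + bn
  block <- (k * H + H) + bn + (H * H + H) + bn
  head <- H + 1L
  as.integer(patch + d * block + head)
}

# uniform fan-in init, the standard default for convolution layers
init_mat <- function(nr, nc, fan_in) {
  b <- sqrt(1 / fan_in)
  matrix(runif(nr * nc, -b, b), nr, nc)
}

#' Build a ConvMixer model
#'
#' Initializes all weights (uniform fan-in) and running normalization
#' statistics from the given seed.
#'
#' @param spec a [convmixer_spec()].
#' @param seed integer RNG seed for the initialization.
#' @return object of class `convmixer`: list with `spec`, `params` (named
#'   flat list of weight arrays), `rstats` (running batchnorm statistics),
#'   `bn_eps`, `bn_momentum`, `normalize` flag.
#' @export
convmixer_build <- function(spec = convmixer_spec(), seed = 1L) {
  stopifnot(inherits(spec, "convmixer_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  P <- spec$patch_size; H <- spec$hidden_channels; k <- spec$kernel_size
  params <- list(patch_w = init_mat(P, H, P),
                 patch_b = numeric(H),
                 bn0_g = rep(1, H), bn0_b = numeric(H))
  for (i in seq_len(spec$depth)) {
    params[[paste0("dw", i, "_w")]] <- init_mat(k, H, k)
    params[[paste0("dw", i, "_b")]] <- numeric(H)
    params[[paste0("bn", i, "a_g")]] <- rep(1, H)
    params[[paste0("bn", i, "a_b")]] <- numeric(H)
    params[[paste0("pw", i, "_w")]] <- init_mat(H, H, H)
    params[[paste0("pw", i, "_b")]] <- numeric(H)
    params[[paste0("bn", i, "b_g")]] <- rep(1, H)
    params[[paste0("bn", i, "b_b")]] <- numeric(H)
  }
  params$head_w <- as.numeric(init_mat(H, 1L, H))
  params$head_b <- 0
  rstats <- list()
  for (nm in bn_names(spec$depth)) {
    rstats[[paste0(nm, "_m")]] <- numeric(H)
    rstats[[paste0(nm, "_v")]] <- rep(1, H)
  }
  structure(list(spec = spec, params = params, rstats = rstats,
                 bn_eps = 1e-5, bn_momentum = 0.1, normalize = "zscore"),
            class = "convmixer")
}

#' @export
print.convmixer <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "convmixer: L=%d P=%d (tokens %d), H=%d, kernel %d, depth %d\n",
    s$input_length, s$patch_size, s$input_length / s$patch_size,
    s$hidden_channels, s$kernel_size, s$depth))
  cat(sprintf("  parameters: %d trainable, %d with norm statistics\n",
              count_parameters(s, FALSE), count_parameters(s, TRUE)))
  invisible(x)
}

#' Introspected parameter count of a built model
#'
#' Sums the actual array sizes held by the model, as a cross-check of
#' [count_parameters()].
#'
#' @param model a [convmixer_build()] model.
#' @param include_norm_statistics include the running statistics arrays.
#' @return integer count.
#' @export
model_parameter_count <- function(model, include_norm_statistics = TRUE) {
  n <- sum(vapply(model$params, length, integer(1)))
  if (include_norm_statistics)
    n <- n + sum(vapply(model$rstats, length, integer(1)))
  as.integer(n)
}

windows_matrix <- function(windows) {
  if (inherits(windows, "window_set")) windows$windows
  else if (is.matrix(windows)) windows
  else matrix(windows, nrow = 1L)
}

#' Predict RR for a batch of windows
#'
#' Inference-mode forward pass with frozen normalization statistics, so each
#' prediction is independent of the rest of the batch.
#'
#' @param object a `convmixer` model.
#' @param windows a [window_set()], an N x L matrix, or a single length-L
#'   vector. Windows must be normalized the same way as in training.
#' @param chunk maximum windows per internal forward pass (memory bound).
#' @param ... unused.
#' @return numeric vector of RR predictions (bpm), one per window.
#' @export
predict.convmixer <- function(object, windows, chunk = 512L, ...) {
  X <- windows_matrix(windows)
  if (ncol(X) != object$spec$input_length)
    stop(sprintf("window length %d does not match model input length %d",
                 ncol(X), object$spec$input_length))
  out <- numeric(nrow(X))
  for (i0 in seq(1L, nrow(X), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(X))
    out[i0:i1] <- cm_predict_cpp(object$params, object$rstats,
                                 X[i0:i1, , drop = FALSE],
                                 object$spec$patch_size,
                                 object$spec$kernel_size,
                                 object$spec$hidden_channels,
                                 object$spec$depth, object$bn_eps)
  }
  out
}

#' Save / load a model checkpoint
#'
#' Losslessly serializes weights, running statistics, the architecture spec
#' and the normalization flag.
#'
#' @param model a `convmixer` model.
#' @param path checkpoint path.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "convmixer"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "convmixer"))
  m
}
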