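# Variational mode decomposition: concurrently extracts K narrow-band modes
# u_k and their center frequencies omega_k by ADMM in the Fourier domain.
# Per iteration, each mode spectrum is a Wiener-filtered residual
#   u_k = (f - sum_{j != k} u_j + lambda/2) / (1 + 2 alpha (w - w_k)^2)
# and each center frequency is the power-weighted mean frequency of its mode.
# The input is mirror-extended by half its length on both ends to reduce
# boundary error, and modes are returned sorted by ascending center frequency.

#' VMD parameters
#'
#' @param k number of modes (default 5; the pipeline discards the highest-
#'   frequency one as motion artifact).
#' @param alpha bandwidth penalty (default 2000).
#' @param tau Lagrangian ascent step (default 0, i.e. no exact data-fidelity
#'   enforcement; robust in the presence of noise).
#' @param tol convergence tolerance on the summed relative change of the mode
#'   spectra (default 1e-7).
#' @param max_iter iteration cap (default 500).
#' @param init center-frequency initialization: `"peaks"` (default) seeds the
#'   K frequencies at the K largest well-separated peaks of the input
#'   spectrum, which keeps every mode anchored to real signal content and
#'   makes the ascending mode order deterministic; `"uniform"` spreads them
#'   evenly over the half band; `"zero"` starts all at 0.
#' @return object of class `vmd_params`.
#' @export
vmd_params <- function(k = 5L, alpha = 2000, tau = 0, tol = 1e-7,
                       max_iter = 500L, init = c("peaks", "uniform", "zero")) {
  init <- match.arg(init)
  stopifnot(k >= 1, alpha > 0, tau >= 0, tol > 0, max_iter >= 1)
  structure(list(k = as.integer(k), alpha = alpha, tau = tau, tol = tol,
                 max_iter = as.integer(max_iter), init = init),
            class = "vmd_params")
}

#' Variational mode decomposition
#'
#' @param x numeric signal, finite, length >= 2k.
#' @param fs_hz sampling rate (Hz), used only to express center frequencies.
#' @param params a [vmd_params()].
#' @return object of class `vmd_result`: list with `modes` (K x N matrix, one
#'   mode per row, summing approximately to `x` for band-limited input),
#'   `center_freqs_hz` (ascending), `n_iter`.
#' @export
vmd_decompose <- function(x, fs_hz, params = vmd_params()) {
  if (!all(is.finite(x))) stop("non-finite input signal")
  K <- params$k
  n <- length(x)
  if (n < 2L * K) stop("signal too short for ", K, " modes")

  # mirror extension by half the length on each side
  half <- n %/% 2L
  f <- c(x[half:1L], x, x[n:(n - half + 1L)])
  T_len <- length(f)
  freqs <- (seq_len(T_len) - 1L) / T_len - 0.5

  f_hat <- fft_shift(fft(f))
  f_hat_plus <- f_hat
  f_hat_plus[seq_len(T_len %/% 2L)] <- 0  # keep the analytic (positive) half

  omega <- switch(params$init,
                  peaks = init_omega_peaks(f_hat, T_len, K),
                  uniform = (0.5 / K) * (seq_len(K) - 1L),
                  zero = numeric(K))
  admm <- vmd_admm_cpp(f_hat_plus, freqs, omega, params$alpha, params$tau,
                       params$tol, params$max_iter)
  u_hat <- admm$u_hat                    # T x K mode spectra (positive half)
  omega <- as.numeric(admm$omega)
  n_iter <- admm$n_iter

  # back to the time domain: rebuild two-sided spectra by conjugate symmetry
  modes <- matrix(0, K, n)
  for (k in seq_len(K)) {
    spec <- u_hat[, k]
    # conjugate mirror about the DC bin (index T/2 + 1)
    spec[2L:(T_len %/% 2L + 1L)] <- Conj(rev(spec[(T_len %/% 2L + 1L):T_len]))
    spec[1L] <- Conj(spec[T_len])
    m <- Re(fft(fft_ishift(spec), inverse = TRUE)) / T_len
    modes[k, ] <- m[(half + 1L):(half + n)]
  }
  ord <- order(omega)
  structure(list(modes = modes[ord, , drop = FALSE],
                 center_freqs_hz = pmax(omega[ord], 0) * fs_hz,
                 n_iter = n_iter),
            class = "vmd_result")
}

# greedy selection of the K strongest spectral peaks with a minimum
# separation, on the positive half of the (shifted) spectrum; falls back to
# a uniform spread for any unfilled slots (e.g. near-empty spectra)
init_omega_peaks <- function(f_hat, T_len, K) {
  pos <- (T_len %/% 2L + 1L):T_len
  mag <- abs(f_hat[pos])
  freqs_pos <- (seq_along(pos) - 1L) / T_len
  min_sep <- max(3L, floor(length(pos) / (8L * K)))
  omega <- rep(NA_real_, K)
  mag_work <- mag
  mag_work[1L] <- 0  # DC is not an oscillatory mode center
  for (k in seq_len(K)) {
    i <- which.max(mag_work)
    if (mag_work[i] <= 0) break
    omega[k] <- freqs_pos[i]
    lo <- max(1L, i - min_sep); hi <- min(length(mag_work), i + min_sep)
    mag_work[lo:hi] <- 0
  }
  fill <- which(is.na(omega))
  if (length(fill)) omega[fill] <- (0.5 / K) * (fill - 1L)
  sort(omega)
}

fft_shift <- function(v) {
  n <- length(v)
  c(v[(n %/% 2L + 1L):n], v[seq_len(n %/% 2L)])
}

fft_ishift <- function(v) {
  n <- length(v)
  c(v[(n - n %/% 2L + 1L):n], v[seq_len(n - n %/% 2L)])
}

#' Remove motion artifact via VMD
#'
#' Decomposes the signal into `params$k` modes and reconstructs it from all
#' but the highest-center-frequency mode, which carries most of the motion
#' artifact energy in PPG.
#'
#' @inheritParams vmd_decompose
#' @return cleaned signal, same length as `x`.
#' @export
remove_motion_artifact <- function(x, fs_hz, params = vmd_params()) {
  res <- vmd_decompose(x, fs_hz, params)
  if (params$k == 1L) return(drop(res$modes))
  colSums(res$modes[-params$k, , drop = FALSE])
}
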