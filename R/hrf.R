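# Canonical double-gamma HRF, its temporal and dispersion derivatives, and
# causal block-local convolution of feature matrices.

#' Sample a double-gamma hemodynamic response function
#'
#' The kernel is the difference of two gamma densities,
#' `dgamma(t, shape = delay/dispersion, rate = 1/dispersion)` for the positive
#' response lobe minus `1/ratio` times the analogous density for the
#' undershoot, sampled at the response rate over `[0, duration]` and
#' peak-normalized to a maximum of 1. Defaults are the conventional
#' parameters (response delay 6 s, undershoot delay 16 s, unit dispersions,
#' response:undershoot ratio 6, 32 s support).
#'
#' @param sampling_interval sampling interval in seconds (> 0).
#' @param duration kernel support in seconds (default 32).
#' @param delay_response,delay_undershoot gamma "delay" parameters in seconds.
#' @param dispersion_response,dispersion_undershoot gamma dispersions.
#' @param ratio response:undershoot amplitude ratio.
#' @return an object of class `hrf_kernel`: list with `samples` (length
#'   `duration/dt + 1`, lag 0 first), `lags` (seconds) and `params`.
#' @export
canonical_hrf <- function(sampling_interval = 1, duration = 32,
                          delay_response = 6, delay_undershoot = 16,
                          dispersion_response = 1, dispersion_undershoot = 1,
                          ratio = 6) {
  assert_that(sampling_interval > 0, "sampling_interval must be positive")
  assert_that(duration > 0, "duration must be positive")
  params <- list(delay_response = delay_response, delay_undershoot = delay_undershoot,
                 dispersion_response = dispersion_response,
                 dispersion_undershoot = dispersion_undershoot,
                 ratio = ratio, duration = duration,
                 sampling_interval = sampling_interval)
  lags <- seq(0, duration, by = sampling_interval)
  samples <- hrf_shape(lags, params)
  samples <- samples / max(samples)
  structure(list(samples = samples, lags = lags, params = params), class = "hrf_kernel")
}

# Unnormalized double-gamma evaluated at arbitrary lags (seconds).
hrf_shape <- function(lags, params, onset_shift = 0, dispersion_shift = 0) {
  t <- lags - onset_shift
  d1 <- params$dispersion_response + dispersion_shift
  stats::dgamma(t, shape = params$delay_response / d1, rate = 1 / d1) -
    stats::dgamma(t, shape = params$delay_undershoot / params$dispersion_undershoot,
                  rate = 1 / params$dispersion_undershoot) / params$ratio
}

#' Temporal and dispersion derivatives of an HRF kernel
#'
#' The temporal derivative is the finite difference of the kernel with
#' respect to an onset shift (`(h(t) - h(t - dt_onset)) / dt_onset`); the
#' dispersion derivative is the finite difference with respect to the
#' response-lobe dispersion. Both are scaled to unit Euclidean norm (the
#' regression absorbs amplitude) and sampled on the kernel's own lag grid.
#'
#' @param kernel an [canonical_hrf()] kernel (must carry analytic `params`).
#' @param dt_onset onset-shift step in seconds (default 1).
#' @param dt_dispersion dispersion step (default 0.01).
#' @return list with `temporal` and `dispersion`, both `hrf_kernel` objects.
#' @export
hrf_derivatives <- function(kernel, dt_onset = 1, dt_dispersion = 0.01) {
  assert_that(!is.null(kernel$params), "kernel lacks analytic parameters")
  assert_that(dt_onset != 0 && dt_dispersion != 0, "finite-difference steps must be nonzero")
  base <- hrf_shape(kernel$lags, kernel$params)
  scale0 <- max(base)
  td <- (base - hrf_shape(kernel$lags, kernel$params, onset_shift = dt_onset)) /
    (dt_onset * scale0)
  dd <- (base - hrf_shape(kernel$lags, kernel$params, dispersion_shift = dt_dispersion)) /
    (dt_dispersion * scale0)
  unitize <- function(v) v / sqrt(sum(v^2))
  mk <- function(v) structure(list(samples = unitize(v), lags = kernel$lags, params = NULL),
                              class = "hrf_kernel")
  list(temporal = mk(td), dispersion = mk(dd))
}

#' Causal convolution of a feature matrix with an HRF kernel
#'
#' Implements multiplication by the Toeplitz matrix of the kernel:
#' `out[t] = sum_{tau = 0..min(t, L)} kernel[tau] * F[t - tau]`, applied
#' column-wise. The convolution is block-local — callers pass one block at a
#' time and the first `L` samples use zero-padded history.
#'
#' @param kernel an `hrf_kernel`.
#' @param f numeric matrix `T x p` (one block of features).
#' @return numeric matrix `T x p`.
#' @export
toeplitz_convolve <- function(kernel, f) {
  f <- as.matrix(f)
  assert_that(nrow(f) >= 1 && ncol(f) >= 1, "empty feature matrix")
  k <- kernel$samples
  tt <- nrow(f)
  # FFT-based linear convolution, truncated back to the block length.
  n <- stats::nextn(tt + length(k) - 1, 2)
  kf <- stats::fft(c(k, rep(0, n - length(k))))
  out <- matrix(0, tt, ncol(f))
  for (j in seq_len(ncol(f))) {
    xf <- stats::fft(c(f[, j], rep(0, n - tt)))
    full <- Re(stats::fft(xf * kf, inverse = TRUE)) / n
    out[, j] <- full[seq_len(tt)]
  }
  out
}
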