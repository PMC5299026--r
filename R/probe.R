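# Voxel-specific HRF estimation by impulse stimulation of a trained response
# model: simulate the response to a single all-ones feature frame, normalize
# baseline and scale, and read off response/undershoot delays.

#' Simulate a model's raw impulse response
#'
#' The model is driven with a feature sequence that is zero everywhere except
#' a single frame of ones at time 0, preceded by a `baseline` pre-period that
#' stabilizes the state of recurrent models and followed by a `horizon`
#' post-period. The whole sequence is treated as one block.
#'
#' @param model a fitted [fit_model()] object (either family).
#' @param horizon seconds simulated after the impulse (default 32).
#' @param baseline seconds before the impulse (default 32).
#' @param amplitude impulse amplitude (default 1, a vector of ones as such;
#'   scale to the empirical feature scale if the trained model is strongly
#'   nonlinear).
#' @return list with `response` (`(baseline + horizon)/dt + 1` rows x m),
#'   `lags` (seconds, negative before the impulse).
#' @export
impulse_response <- function(model, horizon = 32, baseline = 32, amplitude = 1) {
  dt <- model$sampling_interval
  assert_that(horizon >= dt, "horizon too short")
  n_pre <- as.integer(round(baseline / dt))
  n_post <- as.integer(round(horizon / dt))
  p <- model$n_features
  x <- matrix(0, n_pre + n_post + 1L, p)
  x[n_pre + 1L, ] <- amplitude
  resp <- predict_response(model, x)
  if (anyNA(resp) || !all(is.finite(resp))) {
    stop("model produced non-finite impulse response")
  }
  list(response = resp, lags = (seq_len(nrow(resp)) - 1L - n_pre) * dt)
}

#' Normalize a raw impulse response into an estimated HRF
#'
#' Subtracts the baseline value at lag -1, divides by the post-subtraction
#' maximum, and keeps lags `0..horizon`. Voxels whose maximum after baseline
#' subtraction is not positive cannot be normalized and are flagged
#' degenerate (their samples are returned as `NA`), not errored.
#'
#' @param raw output of [impulse_response()].
#' @return object of class `estimated_hrf_set`: list with `samples`
#'   (`L+1 x m`, peak 1 per column), `lags`, `degenerate` (logical per voxel).
#' @export
normalize_hrf <- function(raw) {
  i0 <- which(raw$lags == 0)
  assert_that(length(i0) == 1 && i0 >= 2, "raw response must cover lags -1..0")
  base <- raw$response[i0 - 1L, ]
  shifted <- sweep(raw$response, 2, base, "-")
  post <- shifted[i0:nrow(shifted), , drop = FALSE]
  mx <- apply(post, 2, max)
  degenerate <- mx <= 0 | !is.finite(mx)
  norm <- sweep(post, 2, ifelse(degenerate, 1, mx), "/")
  norm[, degenerate] <- NA_real_
  structure(list(samples = norm, lags = raw$lags[i0:length(raw$lags)],
                 degenerate = degenerate),
            class = "estimated_hrf_set")
}

#' Response and undershoot delays of estimated HRFs
#'
#' The delay of response is the lag of the HRF maximum (earliest on ties);
#' the delay of undershoot is the lag of the minimum over lags strictly after
#' the response delay (earliest on ties). The undershoot is flagged undefined
#' when there is no dip below baseline after the peak (post-peak minimum
#' `>= 0`) or when the peak sits at the final lag.
#'
#' @param hrf an [normalize_hrf()] object (or a single normalized kernel
#'   vector plus `lags`).
#' @return data.frame with one row per voxel: `delay_response`,
#'   `delay_undershoot` (`NA` when undefined), `undershoot_defined`,
#'   `degenerate`.
#' @export
extract_delays <- function(hrf) {
  if (is.numeric(hrf)) {
    hrf <- list(samples = matrix(hrf, ncol = 1),
                lags = seq(0, length.out = length(hrf)), degenerate = FALSE)
  }
  m <- ncol(hrf$samples)
  out <- data.frame(voxel = seq_len(m), delay_response = NA_real_,
                    delay_undershoot = NA_real_, undershoot_defined = FALSE,
                    degenerate = hrf$degenerate)
  for (v in seq_len(m)) {
    if (out$degenerate[v]) next
    s <- hrf$samples[, v]
    ipk <- which.max(s)                      # earliest tie by which.max
    out$delay_response[v] <- hrf$lags[ipk]
    if (ipk < length(s)) {
      tail_s <- s[(ipk + 1L):length(s)]
      imin <- which.min(tail_s)
      if (tail_s[imin] < 0) {
        out$delay_undershoot[v] <- hrf$lags[ipk + imin]
        out$undershoot_defined[v] <- TRUE
      }
    }
  }
  out
}

#' Select voxels with above-chance model performance for HRF estimation
#'
#' A voxel qualifies when any model's correlation is significantly above
#' chance by a one-sided Student's t test on
#' `t = r * sqrt((n - 2) / (1 - r^2))`, Bonferroni-corrected over voxels.
#'
#' @param performance per-voxel correlations: a numeric vector or a
#'   `models x voxels` matrix (any model may qualify a voxel).
#' @param n number of test samples behind each correlation.
#' @param alpha familywise significance level (default 0.05).
#' @return integer vector of selected voxel indices.
#' @export
select_voxels_for_hrf <- function(performance, n, alpha = 0.05) {
  assert_that(n > 2, "need more than 2 samples for a correlation t-test")
  if (is.null(dim(performance))) performance <- matrix(performance, nrow = 1)
  m <- ncol(performance)
  r <- pmin(pmax(performance, -1 + 1e-12), 1 - 1e-12)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p_min <- apply(p, 2, min)
  which(p_min * m < alpha)
}
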