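# Synthetic block-structured encoding datasets with known ground truth:
# AR(1) feature sequences with configurable persistence, voxel-specific
# gamma-difference HRFs, linear (optionally saturating) hemodynamic
# convolution and white Gaussian measurement noise, organized into the
# standard continuous-design layout (long training blocks, short test blocks
# presented repeatedly).

#' Generate stationary AR(1) feature blocks
#'
#' Features follow `x_t = rho * x_{t-1} + e_t` with `rho = exp(-1/tau)`
#' (`tau` in samples; `tau = 0` gives white noise), emulating slow
#' "semantic-like" versus fast "structural-like" stimulus statistics. Each
#' block is z-scored per feature.
#'
#' @param block_lengths integer vector of block lengths in samples.
#' @param p number of features.
#' @param tau autocorrelation time constant in samples (`>= 0`).
#' @param seed integer seed.
#' @param roles block roles (recycled; default `"train"`).
#' @param id_prefix block id prefix.
#' @return list of [feature_block()] objects.
#' @export
generate_features <- function(block_lengths, p, tau = 0, seed = 1,
                              roles = "train", id_prefix = "blk") {
  assert_that(tau >= 0 && is.finite(tau), "invalid autocorrelation time constant")
  assert_that(p >= 1 && all(block_lengths >= 1), "T and p must be positive")
  set.seed(seed)
  rho <- if (tau == 0) 0 else exp(-1 / tau)
  roles <- rep_len(roles, length(block_lengths))
  innov_sd <- sqrt(1 - rho^2)
  lapply(seq_along(block_lengths), function(i) {
    tt <- block_lengths[i]
    x <- matrix(stats::rnorm(tt * p), tt, p)
    if (rho > 0) {
      x[1, ] <- x[1, ]                      # stationary start, unit variance
      for (t in 2:tt) x[t, ] <- rho * x[t - 1, ] + innov_sd * x[t, ]
    }
    feature_block(zscore_cols(x)$values, sprintf("%s%02d", id_prefix, i), roles[i])
  })
}

#' Draw voxel ground truth: weights, HRFs, noise levels
#'
#' Each voxel gets sparse half-normal (non-negative) feature weights — the
#' features stand in for energy-like quantities that drive responses
#' excitatorily, which also keeps impulse-based HRF estimation well-posed
#' (a voxel with negative net drive would yield a sign-inverted impulse
#' response) — a gamma-difference HRF
#' whose response delay is drawn uniformly from `delay_range` (undershoot
#' delay at response delay + `undershoot_offset`), and a noise standard
#' deviation set from `snr_range` (signal SD over noise SD). The realized
#' delays stored in the truth are the argmax/argmin of the sampled kernels
#' themselves, so recovery can be judged against what was actually generated.
#'
#' @param m voxels.
#' @param p features.
#' @param delay_range response-delay range in seconds (default `c(4, 8)`).
#' @param undershoot_offset range added to the response delay for the
#'   undershoot delay (default `c(8, 12)`).
#' @param snr_range signal-to-noise range (default `c(2, 2)`); `Inf` for
#'   noiseless voxels.
#' @param n_nonzero nonzero weights per voxel (default `max(1, p %/% 4)`).
#' @param seed integer seed.
#' @param sampling_interval seconds per sample.
#' @param duration HRF support in seconds (default 32).
#' @return object of class `ground_truth`: `weights` (`p x m`), `kernels`
#'   (`L+1 x m`, peak-normalized), `delays` (data.frame with the gamma
#'   parameters and realized delays), `snr`, `seed`.
#' @export
generate_voxels <- function(m, p, delay_range = c(4, 8),
                            undershoot_offset = c(8, 12),
                            snr_range = c(2, 2), n_nonzero = NULL, seed = 1,
                            sampling_interval = 1, duration = 32) {
  assert_that(length(delay_range) == 2 && diff(delay_range) >= 0, "invalid delay range")
  assert_that(length(snr_range) == 2 && snr_range[2] >= snr_range[1], "invalid SNR range")
  set.seed(seed)
  if (is.null(n_nonzero)) n_nonzero <- max(1L, p %/% 4L)
  weights <- matrix(0, p, m)
  for (v in seq_len(m)) {
    nz <- sample.int(p, n_nonzero)
    weights[nz, v] <- abs(stats::rnorm(n_nonzero))
  }
  delay_r <- stats::runif(m, delay_range[1], delay_range[2])
  delay_u <- delay_r + stats::runif(m, undershoot_offset[1], undershoot_offset[2])
  snr <- if (all(is.infinite(snr_range))) rep(Inf, m) else
    stats::runif(m, snr_range[1], snr_range[2])
  lags <- seq(0, duration, by = sampling_interval)
  kernels <- matrix(0, length(lags), m)
  true_delay <- numeric(m); true_under <- numeric(m)
  dense <- seq(0, duration, by = 0.01)
  for (v in seq_len(m)) {
    pr <- list(delay_response = delay_r[v], delay_undershoot = delay_u[v],
               dispersion_response = 1, dispersion_undershoot = 1, ratio = 6)
    kv <- hrf_shape(lags, pr)
    kernels[, v] <- kv / max(kv)
    kd <- hrf_shape(dense, pr)
    true_delay[v] <- dense[which.max(kd)]
    post <- which(dense > true_delay[v])
    true_under[v] <- dense[post[which.min(kd[post])]]
  }
  structure(list(weights = weights, kernels = kernels,
                 delays = data.frame(voxel = seq_len(m),
                                     param_delay_response = delay_r,
                                     param_delay_undershoot = delay_u,
                                     delay_response = true_delay,
                                     delay_undershoot = true_under),
                 snr = snr, lags = lags, sampling_interval = sampling_interval,
                 seed = seed),
            class = "ground_truth")
}

#' Generate response blocks from features and ground truth
#'
#' Per voxel, the noiseless signal is the causal convolution of the weighted
#' feature drive `F w_v` (optionally passed through a saturating nonlinearity
#' first) with the voxel's HRF; measurement noise is white Gaussian with SD
#' `sd(signal)/SNR`. Test blocks receive `n_repeats` independent noise
#' realizations around the shared noiseless signal, stored as a repeat stack
#' with `values` equal to their mean.
#'
#' @param features list of [feature_block()] objects.
#' @param truth a [generate_voxels()] object.
#' @param nonlinearity `"none"` (default), `"tanh"` (saturation
#'   `tanh(x / s) * s` with `s` = `nonlinearity_scale`), or `"threshold"`
#'   (half-wave rectification), applied to the neural drive before
#'   convolution.
#' @param nonlinearity_scale saturation scale (default 1).
#' @param n_repeats repeats for test-role blocks (default 10).
#' @param seed integer seed for the noise.
#' @return list of [response_block()] objects (raw, not yet z-scored).
#' @export
generate_responses <- function(features, truth,
                               nonlinearity = c("none", "tanh", "threshold"),
                               nonlinearity_scale = 1, n_repeats = 10, seed = 1) {
  nonlinearity <- match.arg(nonlinearity)
  assert_that(nrow(truth$weights) == ncol(features[[1]]$values),
              "truth feature dimension does not match features")
  set.seed(seed)
  m <- ncol(truth$weights)
  kern <- function(v) structure(list(samples = truth$kernels[, v],
                                     lags = truth$lags, params = NULL),
                                class = "hrf_kernel")
  lapply(features, function(fb) {
    drive <- fb$values %*% truth$weights             # T x m neural drive
    drive <- switch(nonlinearity,
                    none = drive,
                    tanh = tanh(drive / nonlinearity_scale) * nonlinearity_scale,
                    threshold = pmax(drive, 0))
    signal <- matrix(0, nrow(drive), m)
    for (v in seq_len(m)) {
      signal[, v] <- toeplitz_convolve(kern(v), drive[, v, drop = FALSE])
    }
    sd_sig <- apply(signal, 2, stats::sd)
    sigma <- ifelse(is.finite(truth$snr), sd_sig / truth$snr, 0)
    tt <- nrow(signal)
    if (fb$role == "test" && n_repeats >= 2) {
      reps <- array(0, c(n_repeats, tt, m))
      for (r in seq_len(n_repeats)) {
        reps[r, , ] <- signal + matrix(stats::rnorm(tt * m), tt, m) %*% diag(sigma, m)
      }
      response_block(apply(reps, c(2, 3), mean), fb$block_id, reps)
    } else {
      noise <- matrix(stats::rnorm(tt * m), tt, m) %*% diag(sigma, m)
      response_block(signal + noise, fb$block_id)
    }
  })
}

#' Default synthetic-dataset configuration
#'
#' The defaults reproduce the standard continuous-design layout: twelve
#' 600 s training blocks, nine 60 s test blocks presented 10 times, 6 s
#' discarded at each block start, the last 45 s of each training block held
#' out for validation, sampled at 1 s. `scale` shrinks all durations
#' proportionally (discard at least 1 sample, validation tail at least 2).
#'
#' @param scale duration scaling factor (default 1).
#' @param p features (default 8).
#' @param m voxels (default 40).
#' @param tau feature autocorrelation time constant in samples (default 2).
#' @param delay_range,snr_range,undershoot_offset see [generate_voxels()].
#' @param nonlinearity,nonlinearity_scale see [generate_responses()].
#' @param n_groups voxel groups, labelled `"area1"..` (default 1).
#' @param n_repeats test repeats (default 10).
#' @return named list of generator settings.
#' @export
synthetic_config <- function(scale = 1, p = 8, m = 40, tau = 2,
                             delay_range = c(4, 8), snr_range = c(2, 2),
                             undershoot_offset = c(8, 12),
                             nonlinearity = "none", nonlinearity_scale = 1,
                             n_groups = 1, n_repeats = 10) {
  assert_that(scale > 0, "scale must be positive")
  list(n_train_blocks = 12L, train_block_s = max(20, round(600 * scale)),
       n_test_blocks = 9L, test_block_s = max(4, round(60 * scale)),
       discard_s = max(1, round(6 * scale)), validation_tail_s = max(2, round(45 * scale)),
       sampling_interval = 1, p = p, m = m, tau = tau,
       delay_range = delay_range, snr_range = snr_range,
       undershoot_offset = undershoot_offset,
       nonlinearity = nonlinearity, nonlinearity_scale = nonlinearity_scale,
       n_groups = n_groups, n_repeats = n_repeats)
}

#' Generate a complete synthetic encoding dataset with ground truth
#'
#' Assembles feature and response blocks under a [synthetic_config()],
#' applies the preprocessing conventions (initial-sample discard, per-block
#' z-scoring of responses) and carves the validation tails off the training
#' blocks. All randomness derives from `seed` via fixed substreams.
#'
#' @param config a [synthetic_config()] list.
#' @param seed master integer seed.
#' @return list with `train`, `validation`, `dataset` (preprocessed full
#'   dataset incl. test blocks with repeats) and `truth`.
#' @export
generate_dataset <- function(config = synthetic_config(), seed = 1) {
  assert_that(config$validation_tail_s <
                config$train_block_s - config$discard_s,
              "validation tail does not fit in the training blocks")
  feats <- c(
    generate_features(rep(config$train_block_s, config$n_train_blocks),
                      config$p, config$tau, derive_seed(seed, "feat-train"),
                      roles = "train", id_prefix = "train"),
    generate_features(rep(config$test_block_s, config$n_test_blocks),
                      config$p, config$tau, derive_seed(seed, "feat-test"),
                      roles = "test", id_prefix = "test"))
  truth <- generate_voxels(config$m, config$p, config$delay_range,
                           config$undershoot_offset, config$snr_range,
                           seed = derive_seed(seed, "voxels"),
                           sampling_interval = config$sampling_interval)
  resps <- generate_responses(feats, truth, config$nonlinearity,
                              config$nonlinearity_scale, config$n_repeats,
                              seed = derive_seed(seed, "noise"))
  groups <- rep(sprintf("area%d", seq_len(config$n_groups)),
                length.out = config$m)
  ds <- encoding_dataset(feats, resps, config$sampling_interval, sort(groups))
  ds <- preprocess(ds, config$discard_s, zscore = TRUE)
  sp <- split_validation(ds, config$validation_tail_s)
  list(train = subset_role(sp$train, "train"),
       validation = sp$validation,
       dataset = sp$train,
       truth = truth)
}
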