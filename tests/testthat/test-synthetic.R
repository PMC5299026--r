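test_that("AR(1) features match their nominal autocorrelation", {
  # white noise: negligible lag-1 autocorrelation
  fb0 <- generate_features(1000, p = 2, tau = 0, seed = 91)[[1]]
  ac0 <- cor(fb0$values[-1000, 1], fb0$values[-1, 1])
  expect_lt(abs(ac0), 0.1)
  # tau = 4 -> lag-1 autocorrelation ~ exp(-1/4)
  fb <- generate_features(5000, p = 2, tau = 4, seed = 92)[[1]]
  ac <- cor(fb$values[-5000, 1], fb$values[-1, 1])
  expect_lt(abs(ac - exp(-1 / 4)), 0.05)
  # per-block z-scoring
  expect_lt(max(abs(colMeans(fb$values))), 1e-10)
  # fixed seed -> bit-identical output
  fb2 <- generate_features(5000, p = 2, tau = 4, seed = 92)[[1]]
  expect_identical(fb$values, fb2$values)
  expect_error(generate_features(100, 2, tau = -1), class = "rebold_input_error")
})

test_that("voxel ground truth honors its configured ranges", {
  tr <- generate_voxels(50, p = 6, delay_range = c(6, 6),
                        undershoot_offset = c(10, 10), seed = 93)
  # degenerate range: all parameter delays exactly 6 s
  expect_true(all(tr$delays$param_delay_response == 6))
  expect_true(all(abs(tr$delays$delay_response - tr$delays$delay_response[1]) < 1e-9))
  # kernels peak-normalized, non-negative weights, undershoot after response
  expect_true(all(abs(apply(tr$kernels, 2, max) - 1) < 1e-12))
  expect_true(all(tr$weights >= 0))
  expect_true(all(tr$delays$delay_undershoot > tr$delays$delay_response))
  # infinite SNR -> zero noise downstream
  trI <- generate_voxels(3, p = 4, snr_range = c(Inf, Inf), seed = 94)
  expect_true(all(is.infinite(trI$snr)))
  expect_error(generate_voxels(5, 4, delay_range = c(8, 4)),
               class = "rebold_input_error")
})

test_that("drawn delays are uniform over the configured range", {
  tr <- generate_voxels(1000, p = 4, delay_range = c(4, 8), seed = 95)
  ks <- suppressWarnings(ks.test(tr$delays$param_delay_response, "punif", 4, 8))
  expect_gt(ks$p.value, 0.01)
})

test_that("noiseless responses equal the direct convolution oracle", {
  feats <- generate_features(c(80, 30), p = 4, tau = 2, seed = 96,
                             roles = c("train", "test"))
  tr <- generate_voxels(3, p = 4, snr_range = c(Inf, Inf), seed = 97)
  resp <- generate_responses(feats, tr, n_repeats = 0, seed = 98)
  drive <- feats[[1]]$values %*% tr$weights
  for (v in 1:3) {
    oracle <- reference_convolve(tr$kernels[, v], drive[, v, drop = FALSE])
    expect_lt(max(abs(resp[[1]]$values[, v] - oracle)), 1e-10)
  }
  # zero-weight voxel with finite SNR is pure noise around zero signal
  tr0 <- generate_voxels(1, p = 4, snr_range = c(2, 2), seed = 99)
  tr0$weights[] <- 0
  resp0 <- generate_responses(feats, tr0, n_repeats = 0, seed = 99)
  expect_true(all(resp0[[1]]$values == 0))    # sd(signal) = 0 -> sigma = 0
})

test_that("repeat stacks have the theoretical SEM", {
  feats <- generate_features(500, p = 4, tau = 2, seed = 100, roles = "test")
  tr <- generate_voxels(2, p = 4, snr_range = c(1, 1), seed = 101)
  resp <- generate_responses(feats, tr, n_repeats = 10, seed = 102)
  av <- average_repeats(resp[[1]])
  drive <- feats[[1]]$values %*% tr$weights
  for (v in 1:2) {
    sigma_v <- sd(reference_convolve(tr$kernels[, v], drive[, v, drop = FALSE]))
    expect_lt(abs(mean(av$sem[, v]) - sigma_v / sqrt(10)) / (sigma_v / sqrt(10)), 0.1)
  }
})

test_that("the default layout mirrors the continuous-design conventions", {
  cfg <- synthetic_config(scale = 0.1, m = 6)
  data <- generate_dataset(cfg, seed = 103)
  expect_equal(cfg$train_block_s, 60)
  expect_equal(cfg$test_block_s, 6)
  roles_full <- vapply(data$dataset$features, `[[`, "", "role")
  expect_equal(sum(roles_full == "train"), 12)
  expect_equal(sum(roles_full == "test"), 9)
  test_blk <- data$dataset$responses[[which(roles_full == "test")[1]]]
  expect_equal(dim(test_blk$repeats)[1], 10)
  # same seed -> identical dataset
  data2 <- generate_dataset(cfg, seed = 103)
  expect_identical(object_checksum(data$dataset), object_checksum(data2$dataset))
  expect_identical(object_checksum(data$truth), object_checksum(data2$truth))
})

test_that("ridge with the true kernel recovers the planted weights", {
  # generative kernels equal the canonical kernel; R-C is correctly specified
  cfg <- synthetic_config(scale = 0.25, m = 10, delay_range = c(6, 6),
                          undershoot_offset = c(10, 10), snr_range = c(8, 8))
  data <- generate_dataset(cfg, seed = 104)
  fit <- fit_model("R-C", data$train, data$validation, seed = 1)
  cosines <- vapply(1:10, function(v) {
    bv <- fit$model$b[v, ]
    wv <- data$truth$weights[, v]
    sum(bv * wv) / sqrt(sum(bv^2) * sum(wv^2))
  }, 0)
  expect_gt(median(cosines), 0.95)
})

test_that("noise ceilings from generated repeats match the SNR prediction", {
  cfg <- synthetic_config(scale = 0.25, m = 8, snr_range = c(2, 2))
  data <- generate_dataset(cfg, seed = 105)
  test <- subset_role(data$dataset, "test")
  reps <- do.call(rebold:::abind_time, lapply(test$responses, `[[`, "repeats"))
  set.seed(1)
  nc <- noise_ceiling(reps, n_sim = 500)
  # SNR 2 with 10 repeats: sem^2 = sigma^2/10, signal var = sd_sig^2,
  # ceiling ~ 1/sqrt(1 + (1/4)/10)
  pred <- 1 / sqrt(1 + 0.25 / 10)
  expect_lt(max(abs(nc$ceiling - pred)), 0.05)
})
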