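test_that("preprocessing discards the settling period and z-scores per block", {
  ds <- make_tiny_dataset(block_lengths = c(600, 600), seed = 3, noise_sd = 0.5)
  pp <- preprocess(ds, discard_seconds = 6, zscore = TRUE)
  expect_equal(nrow(pp$features[[1]]$values), 594)
  expect_equal(nrow(pp$responses[[2]]$values), 594)
  for (b in pp$responses) {
    expect_lt(max(abs(colMeans(b$values))), 1e-8)
    expect_lt(max(abs(apply(b$values, 2, sd) - 1)), 1e-8)
  }
  # idempotence: z-scoring an already z-scored block changes nothing
  pp2 <- preprocess(pp, discard_seconds = 0, zscore = TRUE)
  expect_lt(max(abs(pp2$responses[[1]]$values - pp$responses[[1]]$values)), 1e-8)
  # input untouched (pure-function contract)
  sum_before <- object_checksum(ds)
  invisible(preprocess(ds, 6, TRUE))
  expect_identical(object_checksum(ds), sum_before)
})

test_that("degenerate preprocessing inputs are handled", {
  ds <- make_tiny_dataset(block_lengths = c(10, 10), seed = 1)
  expect_error(preprocess(ds, discard_seconds = 10), class = "rebold_input_error")
  # constant channel -> zeros with warning
  ds$responses[[1]]$values[, 2] <- 7
  expect_warning(pp <- preprocess(ds, 2, TRUE), "constant")
  expect_true(all(pp$responses[[1]]$values[, 2] == 0))
})

test_that("validation splitting takes exact tails and reassembles losslessly", {
  ds <- make_tiny_dataset(block_lengths = c(594, 594), seed = 5)
  sp <- split_validation(ds, 45)
  expect_equal(nrow(sp$train$features[[1]]$values), 549)
  expect_equal(nrow(sp$validation$features[[1]]$values), 45)
  rebuilt <- rbind(sp$train$features[[1]]$values, sp$validation$features[[1]]$values)
  expect_identical(rebuilt, ds$features[[1]]$values)
  rebuilt_y <- rbind(sp$train$responses[[2]]$values, sp$validation$responses[[2]]$values)
  expect_identical(rebuilt_y, ds$responses[[2]]$values)
  # tail 0 -> untouched
  sp0 <- split_validation(ds, 0)
  expect_null(sp0$validation)
  expect_identical(object_checksum(sp0$train), object_checksum(ds))
  expect_error(split_validation(ds, 594), class = "rebold_input_error")
})

test_that("repeat averaging matches the elementwise formulas", {
  # two-point case: repeats {1, 3} -> mean 2, sem 1
  reps <- array(0, c(2, 1, 1)); reps[1, 1, 1] <- 1; reps[2, 1, 1] <- 3
  rb <- response_block(matrix(2, 1, 1), "b", reps)
  av <- average_repeats(rb)
  expect_equal(av$mean[1, 1], 2)
  expect_equal(av$sem[1, 1], 1)
  # identical repeats -> sem 0
  reps2 <- array(5, c(3, 4, 2))
  rb2 <- response_block(matrix(5, 4, 2), "b", reps2)
  expect_true(all(average_repeats(rb2)$sem == 0))
  # random stack vs brute-force per-element computation
  set.seed(9)
  reps3 <- array(rnorm(10 * 6 * 3), c(10, 6, 3))
  rb3 <- response_block(apply(reps3, c(2, 3), mean), "b", reps3)
  av3 <- average_repeats(rb3)
  for (t in 1:6) for (v in 1:3) {
    expect_equal(av3$mean[t, v], mean(reps3[, t, v]))
    expect_equal(av3$sem[t, v], sd(reps3[, t, v]) / sqrt(10))
  }
  expect_error(average_repeats(response_block(matrix(0, 2, 2), "b")),
               class = "rebold_input_error")
})

test_that("response blocks enforce the mean-of-repeats invariant", {
  reps <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  expect_error(response_block(matrix(99, 3, 2), "b", reps),
               class = "rebold_input_error")
})

test_that("datasets round-trip through the on-disk container bit-exactly", {
  ds <- make_tiny_dataset(block_lengths = c(30, 20, 15), roles = c("train", "train", "test"),
                          seed = 11, noise_sd = 0.3, repeats_for_test = 4)
  path <- tempfile("ds")
  save_dataset(ds, path)
  back <- load_dataset(path)
  expect_identical(back$features[[1]]$values, ds$features[[1]]$values)
  expect_identical(back$responses[[3]]$values, ds$responses[[3]]$values)
  expect_identical(back$responses[[3]]$repeats, ds$responses[[3]]$repeats)
  expect_identical(back$voxel_groups, ds$voxel_groups)
  expect_identical(vapply(back$features, `[[`, "", "role"),
                   vapply(ds$features, `[[`, "", "role"))
  # missing response matrix -> parse error naming the block
  unlink(file.path(path, "responses_b2.tsv"))
  expect_error(load_dataset(path), "b2")
  unlink(path, recursive = TRUE)
})

test_that("block pairing and grouping invariants are enforced", {
  f <- list(feature_block(matrix(0, 5, 2), "a", "train"))
  r <- list(response_block(matrix(0, 5, 1), "zzz"))
  expect_error(encoding_dataset(f, r), class = "rebold_input_error")
  r2 <- list(response_block(matrix(0, 5, 2), "a"))
  expect_error(encoding_dataset(f, r2, voxel_groups = "only_one"),
               class = "rebold_input_error")
})
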