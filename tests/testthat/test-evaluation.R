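test_that("voxelwise correlation matches the two-pass formula", {
  set.seed(61)
  y <- matrix(rnorm(60), 20, 3)
  expect_equal(voxel_performance(y, y)$r, rep(1, 3))
  expect_equal(voxel_performance(-y, y)$r, rep(-1, 3))
  p <- matrix(rnorm(60), 20, 3)
  vp <- voxel_performance(p, y)
  for (v in 1:3) {
    expect_lt(abs(vp$r[v] - cor(p[, v], y[, v])), 1e-12)
  }
  # constant predictions are flagged with r = 0
  p[, 2] <- 3
  vp2 <- voxel_performance(p, y)
  expect_equal(vp2$r[2], 0)
  expect_true(vp2$constant[2])
  expect_error(voxel_performance(p[1:2, ], y[1:2, ]), class = "rebold_input_error")
})

test_that("noise ceilings track the closed-form bivariate-Gaussian limit", {
  set.seed(62)
  tt <- 300; R <- 10
  # noiseless repeats -> ceiling 1
  sig <- rnorm(tt)
  reps0 <- matrix(rep(sig, R), R, tt, byrow = TRUE)
  expect_gt(noise_ceiling(reps0, n_sim = 200)$ceiling[1], 1 - 1e-6)
  # zero signal variance (flat mean response, large SEM) -> flagged ceiling 0
  repsC <- matrix(0, R, tt) + rnorm(R) * 10
  ncC <- noise_ceiling(repsC, n_sim = 100)
  expect_true(ncC$flagged[1])
  expect_equal(ncC$ceiling[1], 0)
  # sigma_s = sigma_n = 1 -> ceiling ~ 1/sqrt(2)
  reps <- matrix(rep(rnorm(tt), R), R, tt, byrow = TRUE) +
    matrix(rnorm(R * tt, sd = sqrt(R)), R, tt)  # per-repeat noise sd sqrt(R) -> sem^2 ~ 1
  nc <- noise_ceiling(reps, n_sim = 1000)
  expect_lt(abs(nc$ceiling[1] - 1 / sqrt(2)), 0.05)
})

test_that("noise ceilings decrease with the noise level", {
  set.seed(63)
  tt <- 200; R <- 8
  sig <- rnorm(tt)
  prev <- Inf
  for (noise_sd in c(0.5, 1.5, 4)) {
    reps <- matrix(rep(sig, R), R, tt, byrow = TRUE) +
      matrix(rnorm(R * tt, sd = noise_sd), R, tt)
    cur <- noise_ceiling(reps, n_sim = 400)$ceiling[1]
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("ceiling correction divides by the group median ceiling", {
  expect_equal(as.numeric(ceiling_correct(0.3, 0.6)), 0.5)
  expect_equal(as.numeric(ceiling_correct(0.42, 1)), 0.42)
  flagged <- ceiling_correct(0.3, 0)
  expect_true(is.na(as.numeric(flagged)))
  expect_true(attr(flagged, "flagged"))
})

test_that("permutation p-values hit their boundary cases", {
  ds <- make_tiny_dataset(block_lengths = c(60, 60, 30), roles = c("train", "train", "test"),
                          p = 3, m = 4, seed = 64, noise_sd = 0.1,
                          weights = matrix(abs(rnorm(12)), 3, 4), repeats_for_test = 2)
  sp <- split_validation(ds, 12)
  train <- subset_role(sp$train, "train")
  # stub whose performance never varies: observed can never exceed permutations
  stub <- function(train, validation, dataset, seed) rep(0.5, 4)
  pt <- permutation_test(stub, train, sp$validation, sp$train, n_perm = 5, seed = 1)
  expect_equal(pt$p, 1)
  # a strongly planted linear signal is destroyed by any permutation
  cfgS <- synthetic_config(scale = 0.15, m = 4, delay_range = c(6, 6),
                           undershoot_offset = c(10, 10), snr_range = c(8, 8),
                           n_repeats = 2)
  dataS <- generate_dataset(cfgS, seed = 67)
  fe <- make_fit_eval("R-C")
  pt2 <- permutation_test(fe, dataS$train, dataS$validation, dataS$dataset,
                          n_perm = 20, seed = 2)
  expect_equal(pt2$p, 0)
  expect_match(pt2$p_label, "^< ")
  expect_true(pt2$significant)
  expect_error(permutation_test(stub, train, sp$validation, sp$train, n_perm = 0),
               class = "rebold_input_error")
})

test_that("bootstrap comparison honors shift invariance of medians", {
  set.seed(65)
  a <- rnorm(100, 0.4, 0.1)
  same <- bootstrap_compare(a, a, n_boot = 500, seed = 1)
  expect_equal(same$delta, 0)
  expect_false(same$significant)
  shifted <- bootstrap_compare(a + 0.3, a, n_boot = 2000, seed = 2)
  expect_equal(shifted$delta, 0.3)
  expect_true(shifted$significant)
  expect_lt(abs(shifted$ci[1] - 0.3), 0.1)
  expect_error(bootstrap_compare(1, 1), class = "rebold_input_error")
})

test_that("threshold analysis partitions voxels like a brute-force count", {
  a <- c(0.5, 0.5, 0.1, 0.1)
  b <- c(0.3, 0.3, 0.1, 0.1)
  th <- threshold_diff_analysis(a, b, threshold = 0.1)
  expect_equal(th$fraction_differing, 0.5)
  expect_equal(th$fraction_favoring_a, 1)
  expect_equal(th$delta_a, 0.2)
  expect_equal(threshold_diff_analysis(a, a)$fraction_differing, 0)
  set.seed(66)
  ra <- runif(200, -0.2, 0.8); rb <- runif(200, -0.2, 0.8)
  th2 <- threshold_diff_analysis(ra, rb, 0.1)
  brute <- sum(abs(ra - rb) > 0.1)
  expect_equal(th2$n_differing, brute)
  expect_equal(th2$fraction_favoring_a, sum(ra - rb > 0.1) / brute)
})
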