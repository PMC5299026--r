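test_that("design construction matches each variant's layout", {
  set.seed(31)
  kernels <- ridge_kernels(1)
  f300 <- matrix(rnorm(30 * 300), 30, 300)
  expect_equal(ncol(build_design(f300, "R-CTD", kernels)$x), 900)
  f512 <- matrix(rnorm(20 * 512), 20, 512)
  dF <- build_design(f512, "R-F")
  expect_equal(ncol(dF$x), 2048)
  # at t <= smallest lag every lagged copy reaches before the block start
  expect_true(all(dF$x[1:3, ] == 0))
  expect_false(all(dF$x[4, ] == 0))
  # R-F at lag 3 reproduces the features shifted by 3 samples
  expect_equal(dF$x[4:20, 1:512], f512[1:17, ])
  expect_error(build_design(f300, "R-X"), class = "rebold_input_error")
})

test_that("ridge solutions match the normal equations", {
  set.seed(32)
  x <- matrix(rnorm(200 * 50), 200, 50)
  y <- matrix(rnorm(200 * 4), 200, 4)
  mod <- ridge_solve(x, y, 1)
  bref <- solve(crossprod(x) + diag(50), crossprod(x, y))
  expect_lt(max(abs(t(mod$b) - bref)) / max(abs(bref)), 1e-8)
  # shrinkage limit
  big <- ridge_solve(x, y, 1e12)
  expect_lt(max(abs(big$b)), 1e-6)
  # OLS limit on a full-rank tall design
  ols <- ridge_solve(x, y, 0)
  expect_lt(max(abs(t(ols$b) - qr.solve(x, y))), 1e-8)
  expect_error(ridge_solve(x, y, -1), class = "rebold_input_error")
  y[1, 1] <- NA
  expect_error(ridge_solve(x, y, 1), class = "rebold_input_error")
})

test_that("validation-based penalty selection recovers planted linear models", {
  set.seed(33)
  x <- matrix(rnorm(300 * 8), 300, 8)
  b <- matrix(rnorm(8 * 3), 8, 3)
  y <- x %*% b
  xv <- matrix(rnorm(100 * 8), 100, 8)
  yv <- xv %*% b
  sel <- select_lambda(x, y, xv, yv)
  expect_true(all(sel$val_r > 0.99))
  expect_true(all(sel$lambda <= sel$grid[3]))  # at or near the grid minimum
  # chosen penalty maximizes validation correlation over the grid
  for (v in 1:3) {
    expect_gte(sel$val_r[v] + 1e-12, max(sel$grid_r[, v]))
  }
})

test_that("penalty ties break toward the stronger penalty and degenerate voxels warn", {
  # constant validation response -> grid max with warning
  set.seed(34)
  x <- matrix(rnorm(50 * 3), 50, 3); y <- matrix(rnorm(50 * 2), 50, 2)
  xv <- matrix(rnorm(20 * 3), 20, 3)
  yv <- cbind(rnorm(20), rep(1, 20))
  expect_warning(sel <- select_lambda(x, y, xv, yv), "constant")
  expect_equal(sel$lambda[2], max(sel$grid))
  # exact ties (all-zero validation design -> identical r on the whole grid)
  # resolve toward the stronger penalty
  sel2 <- select_lambda(x, y, matrix(0, 20, 3), cbind(rnorm(20), rnorm(20)),
                        grid = c(0.1, 10, 1000))
  expect_equal(sel2$lambda, c(1000, 1000))
})

test_that("prediction reproduces planted coefficients exactly", {
  set.seed(35)
  kernels <- ridge_kernels(1)
  f <- matrix(rnorm(80 * 5), 80, 5)
  des <- build_design(f, "R-C", kernels)
  b <- matrix(rnorm(2 * 5), 2, 5)
  y <- des$x %*% t(b)
  fit <- ridge_solve(des, y, 0)
  expect_lt(max(abs(predict_ridge(fit, des) - y)), 1e-10)
  # zero coefficients -> zero predictions
  fit$b[] <- 0
  expect_true(all(predict_ridge(fit, des) == 0))
  # variant mismatch is rejected
  desF <- build_design(f, "R-F")
  expect_error(predict_ridge(fit, desF), class = "rebold_input_error")
})

test_that("the richer HRF basis never fits the training set worse", {
  set.seed(36)
  kernels <- ridge_kernels(1)
  f <- matrix(rnorm(120 * 4), 120, 4)
  y <- matrix(rnorm(120 * 3), 120, 3)
  for (lam in c(0, 1, 100)) {
    rc <- ridge_solve(build_design(f, "R-C", kernels), y, lam)
    rctd <- ridge_solve(build_design(f, "R-CTD", kernels), y, lam)
    res_c <- colSums((y - predict_ridge(rc, build_design(f, "R-C", kernels)))^2)
    res_ctd <- colSums((y - predict_ridge(rctd, build_design(f, "R-CTD", kernels)))^2)
    expect_true(all(res_ctd <= res_c + 1e-8))
  }
})
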