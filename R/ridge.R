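# Feedforward response models: design construction from HRF basis sets or
# FIR lags, per-voxel ridge estimation via a shared SVD, and validation-based
# regularization selection.

RIDGE_VARIANTS <- c("R-C", "R-CTD", "R-F")

#' Build the HRF kernel set used by the ridge designs
#' @param sampling_interval seconds per sample.
#' @return list with `canonical`, `temporal`, `dispersion` kernels.
#' @export
ridge_kernels <- function(sampling_interval = 1) {
  canon <- canonical_hrf(sampling_interval)
  dervs <- hrf_derivatives(canon)
  list(canonical = canon, temporal = dervs$temporal, dispersion = dervs$dispersion)
}

#' Construct a ridge design matrix from one block of features
#'
#' Variants:
#' * `R-C` — features convolved with the canonical HRF (`T x p`);
#' * `R-CTD` — column-concatenation of convolutions with the canonical HRF,
#'   its temporal derivative and its dispersion derivative (`T x 3p`);
#' * `R-F` — finite-impulse-response design: features lagged 3, 4, 5 and 6 s
#'   and concatenated (`T x 4p`), zero-filled where a lag reaches before the
#'   block start. There is no lag-0 term.
#'
#' Designs are built block-locally and row-bound by callers; no information
#' crosses block boundaries.
#'
#' @param features numeric matrix `T x p` (one block).
#' @param variant one of `"R-C"`, `"R-CTD"`, `"R-F"`.
#' @param kernels output of [ridge_kernels()] (ignored for `R-F`).
#' @param sampling_interval seconds per sample (used by `R-F`).
#' @return an object of class `ridge_design`: list with `x` (design matrix),
#'   `variant`, `column_map` (data.frame feature index x component).
#' @export
build_design <- function(features, variant, kernels = NULL, sampling_interval = 1) {
  assert_that(variant %in% RIDGE_VARIANTS, "unknown ridge variant '", variant, "'")
  features <- as.matrix(features)
  p <- ncol(features)
  if (variant %in% c("R-C", "R-CTD") && is.null(kernels)) {
    kernels <- ridge_kernels(sampling_interval)
  }
  if (variant == "R-C") {
    x <- toeplitz_convolve(kernels$canonical, features)
    comp <- rep("canonical", p)
  } else if (variant == "R-CTD") {
    x <- cbind(toeplitz_convolve(kernels$canonical, features),
               toeplitz_convolve(kernels$temporal, features),
               toeplitz_convolve(kernels$dispersion, features))
    comp <- rep(c("canonical", "temporal", "dispersion"), each = p)
  } else {
    lags <- c(3, 4, 5, 6)
    lag_n <- as.integer(round(lags / sampling_interval))
    tt <- nrow(features)
    x <- matrix(0, tt, 4 * p)
    for (i in seq_along(lag_n)) {
      ln <- lag_n[i]
      if (ln < tt) {
        x[(ln + 1):tt, ((i - 1) * p + 1):(i * p)] <- features[1:(tt - ln), , drop = FALSE]
      }
    }
    comp <- rep(paste0("lag", lags), each = p)
  }
  structure(list(x = x, variant = variant,
                 column_map = data.frame(feature = rep(seq_len(p), times = ncol(x) / p),
                                         component = comp)),
            class = "ridge_design")
}

# Economy SVD of a design, reused across the lambda grid and all voxels.
design_svd <- function(x) {
  sv <- svd(x)
  keep <- sv$d > max(sv$d) * .Machine$double.eps * max(dim(x))
  list(u = sv$u[, keep, drop = FALSE], d = sv$d[keep], v = sv$v[, keep, drop = FALSE])
}

#' Per-voxel ridge solutions
#'
#' Minimizes `||y_v - X b||^2 + lambda_v ||b||^2` for every voxel, sharing one
#' SVD of the design across voxels and regularization values.
#'
#' @param design a [build_design()] object or plain matrix.
#' @param y response matrix `T x m`.
#' @param lambda scalar or length-`m` vector of non-negative penalties.
#' @return an object of class `ridge_model` with `b` (`m x d` coefficients),
#'   `lambda`, `variant`.
#' @export
ridge_solve <- function(design, y, lambda) {
  x <- if (inherits(design, "ridge_design")) design$x else as.matrix(design)
  variant <- if (inherits(design, "ridge_design")) design$variant else NA_character_
  y <- as.matrix(y)
  assert_that(!anyNA(x) && !anyNA(y), "NaN/NA in ridge inputs")
  assert_that(nrow(x) == nrow(y), "design and response row counts differ")
  m <- ncol(y)
  lambda <- rep_len(lambda, m)
  assert_that(all(lambda >= 0), "lambda must be non-negative")
  sv <- design_svd(x)
  uty <- crossprod(sv$u, y)                       # k x m
  b <- matrix(0, m, ncol(x))
  for (lam in unique(lambda)) {
    idx <- which(lambda == lam)
    shrink <- sv$d / (sv$d^2 + lam)
    b[idx, ] <- t(sv$v %*% (shrink * uty[, idx, drop = FALSE]))
  }
  structure(list(b = b, lambda = lambda, variant = variant), class = "ridge_model")
}

#' Select a per-voxel ridge penalty on a validation set
#'
#' Sweeps a log-spaced grid, computing validation-set predictions for every
#' grid value from a single SVD of the training design, and picks per voxel
#' the value maximizing the validation Pearson correlation (ties broken
#' toward the larger penalty). A voxel whose validation response is constant
#' gets the grid maximum with a warning.
#'
#' @param design_train,y_train training design and responses.
#' @param design_val,y_val validation design and responses.
#' @param grid non-empty vector of candidate penalties (default 20 log-spaced
#'   values in `[1e-3, 1e6]`).
#' @return list with `lambda` (length `m`), `val_r` (validation correlation at
#'   the chosen penalty) and `grid_r` (`length(grid) x m` matrix).
#' @export
select_lambda <- function(design_train, y_train, design_val, y_val,
                          grid = 10^seq(-3, 6, length.out = 20)) {
  assert_that(length(grid) >= 1, "empty lambda grid")
  grid <- sort(grid)
  xt <- if (inherits(design_train, "ridge_design")) design_train$x else as.matrix(design_train)
  xv <- if (inherits(design_val, "ridge_design")) design_val$x else as.matrix(design_val)
  y_train <- as.matrix(y_train); y_val <- as.matrix(y_val)
  sv <- design_svd(xt)
  uty <- crossprod(sv$u, y_train)
  xvv <- xv %*% sv$v
  m <- ncol(y_train)
  grid_r <- matrix(NA_real_, length(grid), m)
  const_val <- apply(y_val, 2, stats::sd) < .Machine$double.eps * 1e2
  for (i in seq_along(grid)) {
    shrink <- sv$d / (sv$d^2 + grid[i])
    pred <- xvv %*% (shrink * uty)
    grid_r[i, ] <- pearson_cols(pred, y_val)
  }
  # ties -> larger lambda: walk the ascending grid keeping >= the running best
  best <- rep(1L, m); best_r <- grid_r[1, ]
  if (length(grid) > 1) {
    for (i in 2:length(grid)) {
      upd <- !is.na(grid_r[i, ]) & (is.na(best_r) | grid_r[i, ] >= best_r)
      best[upd] <- i; best_r[upd] <- grid_r[i, upd]
    }
  }
  lambda <- grid[best]
  if (any(const_val)) {
    warning("constant validation response for voxel(s) ",
            paste(which(const_val), collapse = ", "), "; lambda set to grid max")
    lambda[const_val] <- max(grid)
    best_r[const_val] <- NA_real_
  }
  list(lambda = lambda, val_r = best_r, grid_r = grid_r, grid = grid)
}

# Column-wise Pearson correlation between two equally-shaped matrices;
# returns 0 for degenerate (constant) columns.
pearson_cols <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2) * colSums(b^2))
  r <- ifelse(den > 0, num / den, 0)
  pmin(pmax(r, -1), 1)
}

#' Predict responses from a ridge model
#' @param model a [ridge_solve()] model.
#' @param design a design of the matching variant.
#' @return predicted responses, `T x m`.
#' @export
predict_ridge <- function(model, design) {
  x <- if (inherits(design, "ridge_design")) design$x else as.matrix(design)
  if (inherits(design, "ridge_design") && !is.na(model$variant)) {
    assert_that(identical(design$variant, model$variant),
                "design variant '", design$variant, "' does not match model '", model$variant, "'")
  }
  assert_that(ncol(x) == ncol(model$b), "design/coefficient dimension mismatch")
  x %*% t(model$b)
}
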