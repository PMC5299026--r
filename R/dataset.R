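# Block-structured encoding datasets: paired feature/response blocks with
# train/validation/test roles, repeat stacks for test blocks, preprocessing
# and plain-text serialization.

#' Construct a feature block
#'
#' A feature block holds one continuous run of stimulus features, one row per
#' sample (1 sample per second by default). Sample `t` (0-based) covers the
#' interval `[t, t+1)` seconds; nothing crosses block boundaries.
#'
#' @param values numeric matrix, `T x p`.
#' @param block_id character label, unique within a dataset.
#' @param role one of `"train"`, `"validation"`, `"test"`.
#' @return an object of class `feature_block`.
#' @export
feature_block <- function(values, block_id, role = c("train", "validation", "test")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  assert_that(nrow(values) >= 1, "feature block '", block_id, "' must have at least one sample")
  assert_that(!anyNA(values) && all(is.finite(values)),
              "feature block '", block_id, "' contains missing or non-finite values")
  structure(list(values = values, block_id = as.character(block_id), role = role),
            class = "feature_block")
}

#' Construct a response block
#'
#' Holds z-scored BOLD amplitudes for one run, optionally with the stack of
#' repeated measurements the run was averaged from (test runs presented
#' several times). When `repeats` is given, `values` must equal its mean over
#' the repeat axis.
#'
#' @param values numeric matrix, `T x m`.
#' @param block_id character label matching the paired feature block.
#' @param repeats optional numeric array `R x T x m` with `R >= 2`.
#' @return an object of class `response_block`.
#' @export
response_block <- function(values, block_id, repeats = NULL) {
  values <- as.matrix(values)
  assert_that(!anyNA(values), "response block '", block_id, "' contains missing values")
  if (!is.null(repeats)) {
    assert_that(length(dim(repeats)) == 3, "repeats must be an R x T x m array")
    assert_that(dim(repeats)[1] >= 2, "repeats requires R >= 2")
    assert_that(dim(repeats)[2] == nrow(values) && dim(repeats)[3] == ncol(values),
                "repeats dimensions must match values")
    mu <- apply(repeats, c(2, 3), mean)
    assert_that(max(abs(mu - values)) < 1e-10,
                "response block '", block_id, "' values must equal the mean over repeats")
  }
  structure(list(values = values, block_id = as.character(block_id), repeats = repeats),
            class = "response_block")
}

#' Assemble an encoding dataset
#'
#' Pairs feature and response blocks 1:1 by `block_id` and attaches per-voxel
#' group labels (e.g. cortical area, or area-by-subject). All feature blocks
#' must share the same feature dimension and all response blocks the same
#' voxel count.
#'
#' @param features list of [feature_block()] objects.
#' @param responses list of [response_block()] objects.
#' @param sampling_interval sampling interval in seconds (default 1, the TR).
#' @param voxel_groups character vector, one group label per voxel.
#' @return an object of class `encoding_dataset`.
#' @export
encoding_dataset <- function(features, responses, sampling_interval = 1,
                             voxel_groups = NULL) {
  fid <- vapply(features, `[[`, "", "block_id")
  rid <- vapply(responses, `[[`, "", "block_id")
  assert_that(!anyDuplicated(fid) && !anyDuplicated(rid), "block ids must be unique")
  assert_that(setequal(fid, rid), "feature and response blocks must pair 1:1 by block_id")
  responses <- responses[match(fid, rid)]
  p <- unique(vapply(features, function(b) ncol(b$values), 0L))
  m <- unique(vapply(responses, function(b) ncol(b$values), 0L))
  assert_that(length(p) == 1, "feature dimension must be constant across blocks")
  assert_that(length(m) == 1, "voxel count must be constant across blocks")
  for (i in seq_along(features)) {
    assert_that(nrow(features[[i]]$values) == nrow(responses[[i]]$values),
                "paired blocks '", fid[i], "' differ in length")
  }
  if (is.null(voxel_groups)) voxel_groups <- rep("all", m)
  assert_that(length(voxel_groups) == m, "one group label per voxel required")
  structure(list(features = features, responses = responses,
                 sampling_interval = sampling_interval,
                 voxel_groups = as.character(voxel_groups)),
            class = "encoding_dataset")
}

#' @export
print.encoding_dataset <- function(x, ...) {
  roles <- vapply(x$features, `[[`, "", "role")
  cat("<encoding_dataset>\n")
  cat(sprintf("  %d blocks (%s), dt = %g s\n", length(x$features),
              paste(sprintf("%d %s", tabulate(factor(roles)), levels(factor(roles))),
                    collapse = ", "), x$sampling_interval))
  cat(sprintf("  p = %d features, m = %d voxels in %d group(s)\n",
              ncol(x$features[[1]]$values), ncol(x$responses[[1]]$values),
              length(unique(x$voxel_groups))))
  invisible(x)
}

n_voxels <- function(dataset) ncol(dataset$responses[[1]]$values)
n_features <- function(dataset) ncol(dataset$features[[1]]$values)
block_roles <- function(dataset) vapply(dataset$features, `[[`, "", "role")

#' Select the blocks of a dataset playing a given role
#' @param dataset an [encoding_dataset()].
#' @param role `"train"`, `"validation"` or `"test"`.
#' @return an `encoding_dataset` restricted to the matching blocks.
#' @export
subset_role <- function(dataset, role) {
  keep <- block_roles(dataset) == role
  assert_that(any(keep), "dataset has no '", role, "' blocks")
  encoding_dataset(dataset$features[keep], dataset$responses[keep],
                   dataset$sampling_interval, dataset$voxel_groups)
}

# Concatenate block matrices row-wise (features or responses) for a role.
concat_role <- function(dataset, role, what = c("features", "responses")) {
  what <- match.arg(what)
  keep <- which(block_roles(dataset) == role)
  do.call(rbind, lapply(dataset[[what]][keep], `[[`, "values"))
}

#' Discard initial samples and z-score responses within each block
#'
#' Continuous-design acquisitions settle over the first seconds of every run:
#' those samples are dropped from both the feature and the response block.
#' Responses are then optionally z-scored per block and per voxel (the data
#' are assumed detrended upstream; no detrending is applied here). The same
#' affine transform applied to a block's mean response is applied to its
#' repeat stack so that the mean-of-repeats invariant is preserved.
#'
#' @param dataset an [encoding_dataset()].
#' @param discard_seconds seconds to drop at the start of every block
#'   (default 6).
#' @param zscore if `TRUE` (default), z-score each voxel within each block.
#'   Constant voxels are set to zero with a warning.
#' @return a new `encoding_dataset`; the input is not modified.
#' @export
preprocess <- function(dataset, discard_seconds = 6, zscore = TRUE) {
  drop_n <- as.integer(round(discard_seconds / dataset$sampling_interval))
  feats <- lapply(dataset$features, function(b) {
    assert_that(nrow(b$values) > drop_n,
                "block '", b$block_id, "' shorter than discard_seconds")
    feature_block(b$values[(drop_n + 1):nrow(b$values), , drop = FALSE], b$block_id, b$role)
  })
  resps <- lapply(dataset$responses, function(b) {
    v <- b$values[(drop_n + 1):nrow(b$values), , drop = FALSE]
    reps <- if (!is.null(b$repeats)) b$repeats[, (drop_n + 1):dim(b$repeats)[2], , drop = FALSE]
    if (zscore) {
      z <- zscore_cols(v)
      if (any(z$constant)) {
        warning("constant response channel(s) in block '", b$block_id,
                "' left at zero: ", paste(which(z$constant), collapse = ", "))
      }
      v <- z$values
      if (!is.null(reps)) {
        for (r in seq_len(dim(reps)[1])) {
          m2 <- sweep(sweep(reps[r, , , drop = TRUE], 2, z$center, "-"), 2, z$scale, "/")
          m2[, z$constant] <- 0
          reps[r, , ] <- m2
        }
      }
    }
    response_block(v, b$block_id, reps)
  })
  encoding_dataset(feats, resps, dataset$sampling_interval, dataset$voxel_groups)
}

#' Carve a validation set from the tails of the training blocks
#'
#' The final `tail_seconds` of every training block become a validation block
#' (block id suffixed `"_val"`); the remainder stays in the training set.
#' Non-training blocks pass through untouched. With `tail_seconds = 0` the
#' dataset is returned with an empty validation component.
#'
#' @param dataset an [encoding_dataset()].
#' @param tail_seconds seconds to reserve at the end of each training block
#'   (default 45).
#' @return list with elements `train` and `validation` (the latter `NULL`
#'   when `tail_seconds == 0`).
#' @export
split_validation <- function(dataset, tail_seconds = 45) {
  tail_n <- as.integer(round(tail_seconds / dataset$sampling_interval))
  if (tail_n == 0) return(list(train = dataset, validation = NULL))
  tr_feats <- list(); tr_resps <- list(); va_feats <- list(); va_resps <- list()
  for (i in seq_along(dataset$features)) {
    fb <- dataset$features[[i]]; rb <- dataset$responses[[i]]
    if (fb$role != "train") {
      tr_feats <- c(tr_feats, list(fb)); tr_resps <- c(tr_resps, list(rb)); next
    }
    tt <- nrow(fb$values)
    assert_that(tail_n < tt, "validation tail longer than training block '", fb$block_id, "'")
    head_idx <- seq_len(tt - tail_n); tail_idx <- (tt - tail_n + 1):tt
    tr_feats <- c(tr_feats, list(feature_block(fb$values[head_idx, , drop = FALSE], fb$block_id, "train")))
    tr_resps <- c(tr_resps, list(response_block(rb$values[head_idx, , drop = FALSE], rb$block_id)))
    vid <- paste0(fb$block_id, "_val")
    va_feats <- c(va_feats, list(feature_block(fb$values[tail_idx, , drop = FALSE], vid, "validation")))
    va_resps <- c(va_resps, list(response_block(rb$values[tail_idx, , drop = FALSE], vid)))
  }
  list(train = encoding_dataset(tr_feats, tr_resps, dataset$sampling_interval, dataset$voxel_groups),
       validation = encoding_dataset(va_feats, va_resps, dataset$sampling_interval, dataset$voxel_groups))
}

#' Mean and standard error over repeated measurements
#'
#' @param block a [response_block()] carrying a repeat stack.
#' @return list with `mean` (`T x m`) and `sem` (`T x m`, sample SD over
#'   repeats divided by `sqrt(R)`).
#' @export
average_repeats <- function(block) {
  assert_that(!is.null(block$repeats), "response block '", block$block_id, "' has no repeats")
  reps <- block$repeats
  r <- dim(reps)[1]
  assert_that(r >= 2, "need at least 2 repeats")
  mu <- apply(reps, c(2, 3), mean)
  sem <- apply(reps, c(2, 3), stats::sd) / sqrt(r)
  list(mean = mu, sem = sem)
}

#' Save / load an encoding dataset as a plain-text directory
#'
#' The container is a directory holding a JSON manifest plus one TSV per
#' matrix (`features_<id>.tsv`, `responses_<id>.tsv`, and
#' `repeats_<id>_<r>.tsv` for each repeat). Doubles are written with 17
#' significant digits so the round trip is bit-exact.
#'
#' @param dataset an [encoding_dataset()].
#' @param path directory to create (overwritten if it exists).
#' @export
save_dataset <- function(dataset, path) {
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)
  manifest <- list(
    format = "rebold-dataset", version = 1L,
    sampling_interval = dataset$sampling_interval,
    voxel_groups = dataset$voxel_groups,
    blocks = lapply(seq_along(dataset$features), function(i) {
      fb <- dataset$features[[i]]; rb <- dataset$responses[[i]]
      list(block_id = fb$block_id, role = fb$role,
           n_repeats = if (is.null(rb$repeats)) 0L else dim(rb$repeats)[1])
    }))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(dataset$features)) {
    fb <- dataset$features[[i]]; rb <- dataset$responses[[i]]
    write_matrix_tsv(fb$values, file.path(path, paste0("features_", fb$block_id, ".tsv")))
    write_matrix_tsv(rb$values, file.path(path, paste0("responses_", rb$block_id, ".tsv")))
    if (!is.null(rb$repeats)) {
      for (r in seq_len(dim(rb$repeats)[1])) {
        write_matrix_tsv(rb$repeats[r, , , drop = TRUE],
                         file.path(path, paste0("repeats_", rb$block_id, "_", r, ".tsv")))
      }
    }
  }
  invisible(path)
}

#' @rdname save_dataset
#' @return `load_dataset` returns the reconstructed [encoding_dataset()].
#' @export
load_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  assert_that(file.exists(mf), "no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  assert_that(identical(manifest$format, "rebold-dataset"), "not a rebold dataset directory")
  feats <- list(); resps <- list()
  for (blk in manifest$blocks) {
    fpath <- file.path(path, paste0("features_", blk$block_id, ".tsv"))
    rpath <- file.path(path, paste0("responses_", blk$block_id, ".tsv"))
    assert_that(file.exists(fpath), "missing feature matrix for block '", blk$block_id, "'")
    assert_that(file.exists(rpath), "missing response matrix for block '", blk$block_id, "'")
    fv <- read_matrix_tsv(fpath)
    rv <- read_matrix_tsv(rpath)
    reps <- NULL
    if (blk$n_repeats > 0) {
      reps <- array(NA_real_, c(blk$n_repeats, nrow(rv), ncol(rv)))
      for (r in seq_len(blk$n_repeats)) {
        reps[r, , ] <- read_matrix_tsv(file.path(path, paste0("repeats_", blk$block_id, "_", r, ".tsv")))
      }
    }
    feats <- c(feats, list(feature_block(fv, blk$block_id, blk$role)))
    resps <- c(resps, list(response_block(rv, blk$block_id, reps)))
  }
  encoding_dataset(feats, resps, manifest$sampling_interval,
                   unlist(manifest$voxel_groups))
}
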