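# Analyses of trained-model internals: representational dissimilarity
# matrices across pipeline stages and per-unit optimal temporal lags.

#' Representational dissimilarity matrix over time points
#'
#' Entry `(i, j)` is one minus the Pearson correlation between the
#' `k`-dimensional activity patterns at time points `i` and `j` (correlation
#' distance, range `[0, 2]`). Time points with constant patterns yield
#' undefined correlations; their entries are `NA` and flagged.
#'
#' @param patterns `T x k` matrix (`T >= 2` conditions, `k >= 2` channels).
#' @param stage label, e.g. `"features"`, `"layer1"`, `"layer2"`,
#'   `"predictions"`.
#' @return object of class `rdm`: list with `d` (`T x T`), `stage`,
#'   `constant` (logical per time point).
#' @export
compute_rdm <- function(patterns, stage = "patterns") {
  patterns <- as.matrix(patterns)
  assert_that(nrow(patterns) >= 2 && ncol(patterns) >= 2,
              "need at least 2 time points and 2 channels")
  sdv <- apply(patterns, 1, stats::sd)
  const <- sdv < .Machine$double.eps * 1e2
  d <- 1 - suppressWarnings(stats::cor(t(patterns)))
  d[const, ] <- NA_real_; d[, const] <- NA_real_
  diag(d) <- 0
  structure(list(d = d, stage = stage, constant = const), class = "rdm")
}

#' Correlation between the upper triangles of two RDMs
#'
#' @param rdm_a,rdm_b [compute_rdm()] objects (or plain square matrices) of
#'   the same size, at least 3 conditions.
#' @return Pearson correlation over strictly-upper-triangular entries
#'   (pairwise-complete over any flagged entries).
#' @export
rdm_correlation <- function(rdm_a, rdm_b) {
  da <- if (inherits(rdm_a, "rdm")) rdm_a$d else as.matrix(rdm_a)
  db <- if (inherits(rdm_b, "rdm")) rdm_b$d else as.matrix(rdm_b)
  assert_that(all(dim(da) == dim(db)), "RDM sizes differ")
  assert_that(nrow(da) >= 3, "need at least 3 conditions for an RDM correlation")
  ut <- upper.tri(da)
  stats::cor(da[ut], db[ut], use = "pairwise.complete.obs")
}

#' Average a list of RDMs (e.g. over dataset groups)
#' @param rdms list of [compute_rdm()] objects of equal size.
#' @return an `rdm` with the elementwise mean dissimilarities.
#' @export
average_rdms <- function(rdms) {
  ds <- lapply(rdms, function(r) if (inherits(r, "rdm")) r$d else as.matrix(r))
  d <- Reduce(`+`, ds) / length(ds)
  structure(list(d = d, stage = "average", constant = rep(FALSE, nrow(d))),
            class = "rdm")
}

#' Optimal temporal lags of hidden units
#'
#' Each unit's activity is cross-correlated with each stimulus feature at
#' lags `-max_lag..0` seconds (unit activity at time `t` against features at
#' `t + lag`), on z-scored sequences and block-locally when `blocks` is
#' given; the cross-correlations are averaged over features and, for each
#' unit, the lag with the maximal mean correlation is its optimal lag
#' (earliest, i.e. most negative, on ties). Constant units are flagged.
#'
#' @param states `T x h` hidden-state (or any unit-activity) matrix.
#' @param features `T x p` feature matrix on the same time base.
#' @param max_lag largest lag searched, in seconds (default 30).
#' @param sampling_interval seconds per sample.
#' @return data.frame per unit: `unit`, `optimal_lag` (seconds, `<= 0`),
#'   `peak_correlation`, `flagged`.
#' @export
optimal_lags <- function(states, features, max_lag = 30, sampling_interval = 1) {
  states <- as.matrix(states); features <- as.matrix(features)
  tt <- nrow(states)
  assert_that(nrow(features) == tt, "states/features length mismatch")
  lag_n <- as.integer(round(max_lag / sampling_interval))
  assert_that(lag_n < tt, "max_lag must be shorter than the sequence")
  zs <- zscore_cols(states); zf <- zscore_cols(features)
  s <- zs$values; f <- zf$values
  h <- ncol(s); lags <- -(lag_n:0)
  mean_cc <- matrix(NA_real_, length(lags), h)
  for (li in seq_along(lags)) {
    shift <- -lags[li]                       # samples the features lead by
    ts_idx <- (shift + 1L):tt
    tf_idx <- 1L:(tt - shift)
    sa <- s[ts_idx, , drop = FALSE]
    fa <- f[tf_idx, , drop = FALSE]
    sa <- sweep(sa, 2, colMeans(sa)); fa <- sweep(fa, 2, colMeans(fa))
    denom <- outer(sqrt(colSums(sa^2)), sqrt(colSums(fa^2)))
    cc <- crossprod(sa, fa) / ifelse(denom > 0, denom, Inf)   # h x p
    mean_cc[li, ] <- rowMeans(cc)
  }
  best <- apply(mean_cc, 2, which.max)       # earliest (most negative) on ties
  data.frame(unit = seq_len(h),
             optimal_lag = lags[best] * sampling_interval,
             peak_correlation = mean_cc[cbind(best, seq_len(h))],
             flagged = zs$constant)
}

#' Compare mean optimal lags between two feature conditions
#'
#' Convenience unpaired two-sample t test on the per-unit optimal lags of two
#' fitted models (e.g. driven by slow vs. fast features).
#'
#' @param lags_a,lags_b `optimal_lag` columns from [optimal_lags()].
#' @return `htest` from [stats::t.test()].
#' @export
compare_lag_means <- function(lags_a, lags_b) {
  stats::t.test(lags_a, lags_b, var.equal = FALSE)
}
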