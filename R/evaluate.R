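# Performance assessment: cross-validated correlations, median aggregation
# over voxel groups, Monte-Carlo noise ceilings, permutation tests against
# chance, bootstrap model comparisons, and the threshold-difference analysis.

#' Per-voxel prediction performance
#'
#' Pearson correlation between predicted and observed response sequences,
#' column by column. Constant predictions get `r = 0` and are flagged.
#'
#' @param predicted,observed `T x m` matrices, `T >= 3`.
#' @return list with `r` (length m) and `constant` (logical flags).
#' @export
voxel_performance <- function(predicted, observed) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  assert_that(all(dim(predicted) == dim(observed)), "prediction/observation shape mismatch")
  assert_that(nrow(predicted) >= 3, "need at least 3 samples")
  sd_p <- apply(predicted, 2, stats::sd)
  list(r = pearson_cols(predicted, observed),
       constant = sd_p < .Machine$double.eps * 1e2)
}

#' Median performance per voxel group
#'
#' @param r per-voxel correlations.
#' @param groups per-voxel group labels.
#' @return named numeric vector of group medians.
#' @export
group_medians <- function(r, groups) {
  vapply(split(r, groups), stats::median, 0)
}

#' Monte-Carlo noise ceiling from repeated measurements
#'
#' For each voxel, the noise variance is estimated from the standard errors
#' of the repeat-averaged response (default: mean squared SEM over time
#' points) and the signal variance as the variance of the mean response minus
#' the noise variance, floored at zero. Each simulation draws a length-`T`
#' Gaussian signal and noise, and the ceiling is the median over simulations
#' of `cor(signal, signal + noise)` — the best correlation any model could
#' attain given the measurement noise.
#'
#' @param repeats `R x T` matrix for one voxel, or an `R x T x m` array.
#' @param n_sim simulations per voxel (default 1000).
#' @param sem_variance `"mean_square"` (default) aggregates SEMs as the mean
#'   squared SEM; `"variance"` uses the variance of the SEMs.
#' @return list with `ceiling` (per voxel, in `[0, 1]`), `flagged` (signal
#'   variance zero), `sigma_s2`, `sigma_n2`.
#' @export
noise_ceiling <- function(repeats, n_sim = 1000, sem_variance = c("mean_square", "variance")) {
  sem_variance <- match.arg(sem_variance)
  if (length(dim(repeats)) == 2) repeats <- array(repeats, c(dim(repeats), 1))
  r <- dim(repeats)[1]; tt <- dim(repeats)[2]; m <- dim(repeats)[3]
  assert_that(r >= 2, "need at least 2 repeats")
  ceiling_v <- numeric(m); s2 <- numeric(m); n2 <- numeric(m)
  flagged <- logical(m)
  for (v in seq_len(m)) {
    reps <- matrix(repeats[, , v], r, tt)
    mu <- colMeans(reps)
    sem <- apply(reps, 2, stats::sd) / sqrt(r)
    sigma_n2 <- if (sem_variance == "mean_square") mean(sem^2) else stats::var(sem)
    sigma_s2 <- max(stats::var(mu) - sigma_n2, 0)
    s2[v] <- sigma_s2; n2[v] <- sigma_n2
    if (sigma_s2 <= 0) {
      flagged[v] <- TRUE
      ceiling_v[v] <- 0
      next
    }
    sims <- vapply(seq_len(n_sim), function(i) {
      sig <- stats::rnorm(tt, mean(mu), sqrt(sigma_s2))
      stats::cor(sig, sig + stats::rnorm(tt, 0, sqrt(sigma_n2)))
    }, 0)
    ceiling_v[v] <- stats::median(sims)
  }
  list(ceiling = pmin(pmax(ceiling_v, 0), 1), flagged = flagged,
       sigma_s2 = s2, sigma_n2 = n2)
}

#' Noise-ceiling correction of a group median
#'
#' Divides the group's median correlation by the group's median ceiling.
#'
#' @param median_r group median correlation.
#' @param median_ceiling group median noise ceiling.
#' @return corrected median; `NA` with a flag attribute when the ceiling is
#'   not positive.
#' @export
ceiling_correct <- function(median_r, median_ceiling) {
  out <- ifelse(median_ceiling > 0, median_r / median_ceiling, NA_real_)
  attr(out, "flagged") <- median_ceiling <= 0
  out
}

# Permute response rows over time within the concatenated blocks of a role,
# one shared permutation across voxels, preserving block lengths.
permute_responses_role <- function(dataset, role, perm) {
  idx <- which(block_roles(dataset) == role)
  lens <- vapply(idx, function(i) nrow(dataset$responses[[i]]$values), 0L)
  all_y <- do.call(rbind, lapply(dataset$responses[idx], `[[`, "values"))
  assert_that(length(perm) == nrow(all_y), "permutation length mismatch")
  all_y <- all_y[perm, , drop = FALSE]
  offset <- 0L
  for (k in seq_along(idx)) {
    i <- idx[k]
    rows <- (offset + 1L):(offset + lens[k])
    dataset$responses[[i]] <- response_block(all_y[rows, , drop = FALSE],
                                             dataset$responses[[i]]$block_id)
    offset <- offset + lens[k]
  }
  dataset
}

#' Permutation test of model performance against chance
#'
#' Response time indices are permuted (a single permutation shared across
#' voxels, applied separately within the concatenated training set and the
#' concatenated test set), the model is refitted on each permutation, and the
#' group-median test performance is recomputed. The p-value per group is the
#' fraction of permutations whose median meets or exceeds the observed one;
#' exact zeros are reported as `< 1/n_perm`. Significance is assessed at
#' `alpha` Bonferroni-corrected over groups.
#'
#' @param fit_eval function `(train, validation, test_dataset, seed)` that
#'   fits a model and returns per-voxel test correlations. Build one with
#'   [make_fit_eval()].
#' @param train,validation,dataset the training, validation and test-carrying
#'   datasets used for the observed fit.
#' @param n_perm number of permutations (default 200).
#' @param alpha familywise level (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return data.frame per group: observed median, `p`, `p_label`,
#'   `significant`.
#' @export
permutation_test <- function(fit_eval, train, validation, dataset,
                             n_perm = 200, alpha = 0.05, seed = 1) {
  assert_that(n_perm >= 1, "n_perm must be at least 1")
  groups <- train$voxel_groups
  obs_r <- fit_eval(train, validation, dataset, seed)
  obs_med <- group_medians(obs_r, groups)
  n_tr <- sum(vapply(which(block_roles(train) == "train"),
                     function(i) nrow(train$responses[[i]]$values), 0L))
  n_te <- sum(vapply(which(block_roles(dataset) == "test"),
                     function(i) nrow(dataset$responses[[i]]$values), 0L))
  set.seed(seed)
  perm_med <- matrix(NA_real_, n_perm, length(obs_med))
  for (b in seq_len(n_perm)) {
    ptr <- sample.int(n_tr); pte <- sample.int(n_te)
    tr_b <- permute_responses_role(train, "train", ptr)
    ds_b <- permute_responses_role(dataset, "test", pte)
    r_b <- fit_eval(tr_b, validation, ds_b, seed + b)
    perm_med[b, ] <- group_medians(r_b, groups)
  }
  exceed <- colSums(sweep(perm_med, 2, obs_med, ">=") * 1)
  p <- exceed / n_perm
  data.frame(group = names(obs_med), observed_median = unname(obs_med),
             p = unname(p),
             p_label = ifelse(p == 0, paste0("< ", format(1 / n_perm)), format(p)),
             significant = unname(p < alpha / length(obs_med)),
             row.names = NULL)
}

#' Build a fit-and-evaluate closure for permutation testing
#'
#' @param name model roster name.
#' @param hyper,lambda_grid passed to [fit_model()].
#' @return function `(train, validation, dataset, seed)` returning per-voxel
#'   test correlations.
#' @export
make_fit_eval <- function(name, hyper = rnn_hyperparams(),
                          lambda_grid = 10^seq(-3, 6, length.out = 20)) {
  function(train, validation, dataset, seed) {
    model <- fit_model(name, train, validation, seed = seed, hyper = hyper,
                       lambda_grid = lambda_grid)
    evaluate_model(model, dataset)$r
  }
}

#' Bootstrap comparison of two models over a voxel set
#'
#' Voxels are resampled with replacement; the statistic is the difference of
#' the median correlations (`a` minus `b`). The percentile confidence
#' interval is taken at level `alpha / n_models` (Bonferroni over the number
#' of model comparisons); the difference is significant when the interval
#' excludes zero.
#'
#' @param perf_a,perf_b matched per-voxel correlation vectors.
#' @param n_boot bootstrap repetitions (default 10000).
#' @param alpha nominal level (default 0.05).
#' @param n_models Bonferroni divisor (default 1).
#' @param seed RNG seed.
#' @return list with `delta` (observed median difference), `ci`,
#'   `significant`, `samples`.
#' @export
bootstrap_compare <- function(perf_a, perf_b, n_boot = 10000, alpha = 0.05,
                              n_models = 1, seed = 1) {
  m <- length(perf_a)
  assert_that(m == length(perf_b), "voxel sets must match")
  assert_that(m >= 2, "need at least 2 voxels")
  set.seed(seed)
  idx <- matrix(sample.int(m, m * n_boot, replace = TRUE), m, n_boot)
  sa <- matrix(perf_a[idx], m, n_boot)
  sb <- matrix(perf_b[idx], m, n_boot)
  samples <- apply(sa, 2, stats::median) - apply(sb, 2, stats::median)
  level <- alpha / n_models
  ci <- unname(stats::quantile(samples, c(level / 2, 1 - level / 2), type = 6))
  delta <- stats::median(perf_a) - stats::median(perf_b)
  list(delta = delta, ci = ci, significant = ci[1] > 0 || ci[2] < 0,
       samples = samples)
}

#' Threshold analysis of a pairwise performance difference
#'
#' Partitions voxels by whether the two models' correlations differ by more
#' than `threshold`, and on each side reports the fraction and the median
#' absolute difference.
#'
#' @param perf_a,perf_b matched per-voxel correlations.
#' @param threshold difference threshold (default 0.1).
#' @return list with `fraction_differing`, `fraction_favoring_a` (of the
#'   differing voxels), `delta_a` / `delta_b` (median |difference| among
#'   voxels favoring each side), `n_differing`.
#' @export
threshold_diff_analysis <- function(perf_a, perf_b, threshold = 0.1) {
  assert_that(length(perf_a) == length(perf_b), "voxel sets must match")
  d <- perf_a - perf_b
  differing <- abs(d) > threshold
  fav_a <- differing & d > 0
  fav_b <- differing & d < 0
  list(fraction_differing = mean(differing),
       fraction_favoring_a = if (any(differing)) sum(fav_a) / sum(differing) else NA_real_,
       delta_a = if (any(fav_a)) stats::median(d[fav_a]) else NA_real_,
       delta_b = if (any(fav_b)) stats::median(-d[fav_b]) else NA_real_,
       n_differing = sum(differing))
}
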