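# End-to-end orchestration: fit a roster of response models on a dataset,
# evaluate and compare them, probe HRFs of significant voxels, summarize
# internal representations, and write plain-text report tables.

#' Assemble a run configuration
#'
#' @param synthetic a [synthetic_config()] (or `NULL` when `dataset_path`
#'   points at a saved dataset directory).
#' @param dataset_path optional path to a [save_dataset()] directory.
#' @param models roster subset of
#'   `c("R-C","R-CTD","R-F","L-10","L-50","L-100","G-10","G-50","G-100")`.
#' @param n_perm permutations for the chance test (0 disables it).
#' @param n_boot bootstrap repetitions for model comparisons.
#' @param alpha familywise significance level.
#' @param threshold pairwise difference threshold for the threshold
#'   analysis.
#' @param hyper recurrent training hyperparameters.
#' @param seed master seed.
#' @return named list, class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(scale = 0.1, m = 20),
                       dataset_path = NULL,
                       models = c("R-C", "G-10"), n_perm = 0, n_boot = 2000,
                       alpha = 0.05, threshold = 0.1,
                       hyper = rnn_hyperparams(), seed = 1) {
  assert_that(length(models) >= 1, "model roster must be non-empty")
  for (mdl in models) parse_model_name(mdl)
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  structure(list(synthetic = synthetic, dataset_path = dataset_path,
                 models = models, n_perm = n_perm, n_boot = n_boot,
                 alpha = alpha, threshold = threshold, hyper = hyper,
                 seed = seed),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full experiment described by a configuration
#'
#' Fits every roster model, computes per-voxel and group-median test
#' performance with noise ceilings and ceiling-corrected medians, bootstrap
#' comparisons and threshold analyses for every model pair, optional
#' permutation tests, estimated HRFs (with delays) for voxels with
#' significant performance, and RDM/optimal-lag summaries for recurrent
#' models. Tables are written under `out_dir` as TSV plus a JSON run log
#' carrying the seed and a configuration checksum.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; pass `NULL` to skip writing).
#' @return (invisibly) list with all result objects.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  checksum <- object_checksum(config[setdiff(names(config), "hyper")])
  if (!is.null(config$dataset_path)) {
    full <- load_dataset(config$dataset_path)
    sp <- split_validation(full, 45)
    data <- list(train = subset_role(sp$train, "train"), validation = sp$validation,
                 dataset = sp$train, truth = NULL)
  } else {
    data <- generate_dataset(config$synthetic, seed = config$seed)
  }
  groups <- data$dataset$voxel_groups
  n_test <- nrow(concat_role(data$dataset, "test", "responses"))

  fits <- list(); perf <- list()
  for (name in config$models) {
    fit <- fit_model(name, data$train, data$validation,
                     seed = derive_seed(config$seed, paste0("fit-", name)),
                     hyper = config$hyper)
    fits[[name]] <- fit
    perf[[name]] <- evaluate_model(fit, data$dataset)
  }
  r_mat <- do.call(rbind, lapply(perf, `[[`, "r"))   # models x voxels

  # noise ceilings from the test repeats
  test <- subset_role(data$dataset, "test")
  rep_list <- lapply(test$responses, `[[`, "repeats")
  ceilings <- rep(NA_real_, length(groups))
  if (!any(vapply(rep_list, is.null, TRUE))) {
    reps <- do.call(abind_time, rep_list)
    set.seed(derive_seed(config$seed, "ceiling"))
    ceilings <- noise_ceiling(reps, n_sim = 500)$ceiling
  }

  summary_rows <- NULL
  for (name in config$models) {
    med <- group_medians(perf[[name]]$r, groups)
    med_ceil <- group_medians(ceilings, groups)
    corrected <- mapply(ceiling_correct, med, med_ceil)
    summary_rows <- rbind(summary_rows,
                          data.frame(model = name, group = names(med),
                                     median_r = unname(med),
                                     median_ceiling = unname(med_ceil),
                                     corrected_median_r = as.numeric(corrected),
                                     row.names = NULL))
  }

  comparisons <- NULL
  pairs <- if (length(config$models) >= 2) utils::combn(config$models, 2, simplify = FALSE) else list()
  for (pr in pairs) {
    bc <- bootstrap_compare(perf[[pr[1]]]$r, perf[[pr[2]]]$r,
                            n_boot = config$n_boot, alpha = config$alpha,
                            n_models = length(pairs),
                            seed = derive_seed(config$seed, paste0("boot-", pr[1], pr[2])))
    th <- threshold_diff_analysis(perf[[pr[1]]]$r, perf[[pr[2]]]$r, config$threshold)
    comparisons <- rbind(comparisons,
                         data.frame(model_a = pr[1], model_b = pr[2],
                                    delta_median = bc$delta, ci_lo = bc$ci[1],
                                    ci_hi = bc$ci[2], significant = bc$significant,
                                    fraction_differing = th$fraction_differing,
                                    fraction_favoring_a = th$fraction_favoring_a,
                                    row.names = NULL))
  }

  perm_tables <- list()
  if (config$n_perm > 0) {
    for (name in config$models) {
      fe <- make_fit_eval(name, hyper = config$hyper)
      perm_tables[[name]] <- permutation_test(fe, data$train, data$validation,
                                              data$dataset, n_perm = config$n_perm,
                                              alpha = config$alpha,
                                              seed = derive_seed(config$seed, paste0("perm-", name)))
    }
  }

  sel <- select_voxels_for_hrf(r_mat, n = n_test, alpha = config$alpha)
  hrfs <- NULL; delays <- NULL
  best_name <- config$models[which.max(vapply(perf, function(p) stats::median(p$r), 0))]
  if (length(sel) > 0) {
    raw <- impulse_response(fits[[best_name]])
    est <- normalize_hrf(raw)
    dl <- extract_delays(est)
    delays <- cbind(dl[sel, , drop = FALSE], model = best_name)
    hrfs <- list(samples = est$samples[, sel, drop = FALSE], lags = est$lags,
                 voxels = sel, model = best_name)
  }

  representations <- NULL
  if (parse_model_name(best_name)$family == "rnn" && length(test$features) > 0) {
    fb <- test$features[[1]]
    hs <- hidden_states(fits[[best_name]], fb$values)
    stages <- list(features = fb$values, layer1 = hs$h1, layer2 = hs$h2,
                   predictions = hs$predictions)
    rdms <- lapply(names(stages), function(nm) compute_rdm(stages[[nm]], nm))
    names(rdms) <- names(stages)
    rr <- function(a, b) rdm_correlation(rdms[[a]], rdms[[b]])
    representations <- list(
      rdm_correlations = data.frame(
        pair = c("layer1-predictions", "layer2-predictions",
                 "layer1-features", "layer2-features"),
        r = c(rr("layer1", "predictions"), rr("layer2", "predictions"),
              rr("layer1", "features"), rr("layer2", "features"))),
      lags = optimal_lags(rbind(hs$h1, hs$h2),
                          rbind(fb$values, fb$values),
                          max_lag = min(30, nrow(fb$values) - 2),
                          sampling_interval = data$dataset$sampling_interval))
  }

  results <- list(config = config, checksum = checksum,
                  performance = lapply(perf, `[[`, "r"),
                  summary = summary_rows, comparisons = comparisons,
                  permutations = perm_tables, hrfs = hrfs, delays = delays,
                  representations = representations,
                  best_model = best_name, fits = fits, data = data)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    perf_df <- data.frame(voxel = seq_along(groups), group = groups,
                          ceiling = ceilings)
    for (name in config$models) perf_df[[name]] <- perf[[name]]$r
    write_tsv(perf_df, file.path(out_dir, "performance.tsv"))
    write_tsv(cbind(summary_rows, config_checksum = checksum),
              file.path(out_dir, "group_summary.tsv"))
    if (!is.null(comparisons)) {
      write_tsv(cbind(comparisons, config_checksum = checksum),
                file.path(out_dir, "comparisons.tsv"))
    }
    if (length(perm_tables)) {
      pt <- do.call(rbind, Map(cbind, model = names(perm_tables), perm_tables))
      write_tsv(pt, file.path(out_dir, "permutations.tsv"))
    }
    if (!is.null(delays)) write_tsv(delays, file.path(out_dir, "hrf_delays.tsv"))
    if (!is.null(hrfs)) write_matrix_tsv(hrfs$samples, file.path(out_dir, "hrf_curves.tsv"))
    if (!is.null(representations)) {
      write_tsv(representations$rdm_correlations, file.path(out_dir, "rdm_correlations.tsv"))
      write_tsv(representations$lags, file.path(out_dir, "optimal_lags.tsv"))
    }
    jsonlite::write_json(list(seed = config$seed, models = config$models,
                              checksum = checksum,
                              r_version = as.character(getRversion()),
                              package_version = as.character(utils::packageVersion("rebold"))),
                         file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    summary_txt <- utils::capture.output({
      cat("rebold experiment summary\n")
      cat("models:", paste(config$models, collapse = ", "), "\n")
      print(summary_rows)
      if (!is.null(comparisons)) print(comparisons)
    })
    writeLines(summary_txt, file.path(out_dir, "summary.txt"))
  }
  invisible(results)
}

# rbind repeat stacks (R x T x m) along time.
abind_time <- function(...) {
  arrs <- list(...)
  r <- dim(arrs[[1]])[1]; m <- dim(arrs[[1]])[3]
  tt <- sum(vapply(arrs, function(a) dim(a)[2], 0L))
  out <- array(0, c(r, tt, m))
  off <- 0L
  for (a in arrs) {
    out[, (off + 1):(off + dim(a)[2]), ] <- a
    off <- off + dim(a)[2]
  }
  out
}
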