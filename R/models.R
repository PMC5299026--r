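# A uniform surface over both response-model families: parse a roster name
# ("R-C", "R-CTD", "R-F", "L-10/50/100", "G-10/50/100"), fit on a dataset,
# and predict block-locally from raw feature matrices.

# Validation blocks are the tails of training blocks; their responses carry
# the hemodynamic history of the whole block. Scoring them cold (zero state
# or zero-padded design at the tail's start) would misstate validation
# performance, so each validation block is evaluated in the context of its
# parent training block ("<id>_val" after "<id>") and only the tail rows are
# scored.
#' @keywords internal
validation_contexts <- function(train, validation) {
  train_ids <- vapply(train$features, `[[`, "", "block_id")
  lapply(seq_along(validation$features), function(i) {
    vb <- validation$features[[i]]
    parent <- sub("_val$", "", vb$block_id)
    j <- match(parent, train_ids)
    ctx <- if (!is.na(j)) train$features[[j]]$values else NULL
    list(features = rbind(ctx, vb$values), n_tail = nrow(vb$values),
         observed = validation$responses[[i]]$values)
  })
}

#' Parse a response-model roster name
#'
#' @param name one of `"R-C"`, `"R-CTD"`, `"R-F"`, `"L-10"`, `"L-50"`,
#'   `"L-100"`, `"G-10"`, `"G-50"`, `"G-100"`.
#' @return list describing the family and, for recurrent models, cell type
#'   and width.
#' @export
parse_model_name <- function(name) {
  if (name %in% RIDGE_VARIANTS) {
    return(list(name = name, family = "ridge", variant = name))
  }
  mm <- regmatches(name, regexec("^([LG])-(10|50|100)$", name))[[1]]
  assert_that(length(mm) == 3, "unknown model name '", name, "'")
  list(name = name, family = "rnn",
       cell_type = if (mm[2] == "L") "lstm" else "gru",
       hidden = as.integer(mm[3]))
}

#' Fit a response model by roster name
#'
#' Ridge models select their per-voxel penalty on the validation set and are
#' estimated on the training set; recurrent models are trained with truncated
#' BPTT and early-stopped on the validation set. One model is fitted per
#' voxel group (recurrent trunks are shared within a group); ridge fits are
#' global since coefficients are per-voxel anyway.
#'
#' @param name roster name, see [parse_model_name()].
#' @param train train-role [encoding_dataset()].
#' @param validation validation [encoding_dataset()].
#' @param seed integer seed (initialization and dropout for RNNs).
#' @param hyper recurrent hyperparameters ([rnn_hyperparams()]).
#' @param lambda_grid ridge penalty grid (see [select_lambda()]).
#' @param candidate_tanh LSTM candidate activation flag.
#' @return an object of class `response_model` wrapping the fitted family
#'   model(s); pass to [predict_response()] and [evaluate_model()].
#' @export
fit_model <- function(name, train, validation, seed = 1,
                      hyper = rnn_hyperparams(),
                      lambda_grid = 10^seq(-3, 6, length.out = 20),
                      candidate_tanh = FALSE) {
  spec <- parse_model_name(name)
  dt <- train$sampling_interval
  if (spec$family == "ridge") {
    kernels <- ridge_kernels(dt)
    xt <- do.call(rbind, lapply(train$features, function(fb) {
      build_design(fb$values, spec$variant, kernels, dt)$x
    }))
    yt <- concat_role(train, "train", "responses")
    ctxs <- validation_contexts(train, validation)
    xv <- do.call(rbind, lapply(ctxs, function(cx) {
      x <- build_design(cx$features, spec$variant, kernels, dt)$x
      x[(nrow(x) - cx$n_tail + 1):nrow(x), , drop = FALSE]
    }))
    yv <- do.call(rbind, lapply(ctxs, `[[`, "observed"))
    sel <- select_lambda(xt, yt, xv, yv, grid = lambda_grid)
    model <- ridge_solve(structure(list(x = xt, variant = spec$variant), class = "ridge_design"),
                         yt, sel$lambda)
    fitted <- list(model = model, kernels = kernels, selection = sel)
  } else {
    groups <- unique(train$voxel_groups)
    nets <- list()
    for (g in groups) {
      vox <- which(train$voxel_groups == g)
      sub_resp <- function(ds) {
        encoding_dataset(ds$features,
                         lapply(ds$responses, function(b) {
                           response_block(b$values[, vox, drop = FALSE], b$block_id)
                         }),
                         ds$sampling_interval, ds$voxel_groups[vox])
      }
      net <- rnn_response_model(spec$cell_type, n_features(train), spec$hidden,
                                length(vox), candidate_tanh = candidate_tanh,
                                seed = derive_seed(seed, paste0("init-", g)),
                                group = g)
      net <- train_rnn(net, sub_resp(train), sub_resp(validation), hyper,
                       seed = derive_seed(seed, paste0("train-", g)))
      nets[[g]] <- list(net = net, voxels = vox)
    }
    fitted <- list(nets = nets)
  }
  structure(c(list(name = name, spec = spec, sampling_interval = dt,
                   n_voxels = n_voxels(train), n_features = n_features(train)),
              fitted),
            class = "response_model")
}

#' Predict voxel responses from raw features, block-locally
#'
#' @param model a fitted [fit_model()] object.
#' @param features one block's feature matrix (`T x p`).
#' @return predictions `T x m` (voxels in dataset order).
#' @export
predict_response <- function(model, features) {
  features <- as.matrix(features)
  if (model$spec$family == "ridge") {
    design <- build_design(features, model$spec$variant, model$kernels,
                           model$sampling_interval)
    return(predict_ridge(model$model, design))
  }
  out <- matrix(0, nrow(features), model$n_voxels)
  for (entry in model$nets) {
    out[, entry$voxels] <- forward_rnn(entry$net, features)$predictions
  }
  out
}

#' Hidden-state trajectories of a fitted recurrent model over one block
#'
#' @param model a fitted recurrent [fit_model()] object.
#' @param features one block's feature matrix.
#' @param group voxel group whose trunk to unroll (default: first).
#' @return list with `h1`, `h2` (`T x h`) and `predictions` for that group's
#'   voxels.
#' @export
hidden_states <- function(model, features, group = NULL) {
  assert_that(model$spec$family == "rnn", "hidden states exist only for recurrent models")
  if (is.null(group)) group <- names(model$nets)[1]
  forward_rnn(model$nets[[group]]$net, as.matrix(features))
}

#' Evaluate a fitted model on the test blocks of a dataset
#'
#' Predictions are made block-locally on every test block and concatenated;
#' the per-voxel score is the Pearson correlation with the observed
#' (repeat-averaged) responses.
#'
#' @param model a fitted [fit_model()] object.
#' @param dataset dataset containing test-role blocks.
#' @return list with `r` (per-voxel), `predictions`, `observed`.
#' @export
evaluate_model <- function(model, dataset) {
  test <- subset_role(dataset, "test")
  preds <- do.call(rbind, lapply(test$features, function(fb) predict_response(model, fb$values)))
  obs <- do.call(rbind, lapply(test$responses, `[[`, "values"))
  list(r = pearson_cols(preds, obs), predictions = preds, observed = obs)
}
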