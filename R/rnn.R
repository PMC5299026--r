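# Recurrent response models: LSTM and GRU cells, two stacked recurrent
# layers with a per-voxel linear readout, and training by truncated
# backpropagation through time with Adam, dropout and early stopping.
#
# The LSTM candidate activation is a sigmoid by default (`candidate_tanh =
# FALSE`) with a flag to switch to the conventional tanh; the GRU candidate
# is always tanh.

GATE_SETS <- list(lstm = c("o", "f", "i", "c"), gru = c("z", "r", "h"))

#' Initialize one recurrent layer
#'
#' Weights are drawn uniformly in `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`; biases
#' start at zero except the LSTM forget-gate bias, which starts at +1 so the
#' cell initially retains its state. Draws come from the current RNG state.
#'
#' @param cell_type `"lstm"` or `"gru"`.
#' @param input_dim input dimension.
#' @param size number of hidden units.
#' @param candidate_tanh for LSTM only: use tanh for the candidate cell
#'   update instead of the default sigmoid.
#' @return an object of class `rnn_layer`.
#' @export
rnn_layer <- function(cell_type = c("lstm", "gru"), input_dim, size,
                      candidate_tanh = FALSE) {
  cell_type <- match.arg(cell_type)
  assert_that(input_dim >= 1 && size >= 1, "layer dimensions must be positive")
  gates <- GATE_SETS[[cell_type]]
  runif_mat <- function(nr, nc, fan) {
    s <- 1 / sqrt(fan)
    matrix(stats::runif(nr * nc, -s, s), nr, nc)
  }
  params <- list()
  for (g in gates) {
    params[[paste0("W", g)]] <- runif_mat(input_dim, size, input_dim)
    params[[paste0("U", g)]] <- runif_mat(size, size, size)
    b <- rep(0, size)
    if (cell_type == "lstm" && g == "f") b <- rep(1, size)
    params[[paste0("b", g)]] <- b
  }
  structure(list(cell_type = cell_type, input_dim = input_dim, size = size,
                 candidate_tanh = candidate_tanh, params = params),
            class = "rnn_layer")
}

as_row <- function(x, width) {
  if (is.matrix(x)) x else matrix(x, ncol = width, byrow = TRUE)
}

check_finite_gates <- function(vals) {
  bad <- names(vals)[!vapply(vals, function(v) all(is.finite(v)), TRUE)]
  if (length(bad)) {
    stop("non-finite activation in gate(s): ", paste(bad, collapse = ", "))
  }
}

#' One LSTM step
#'
#' Gates `o`, `f`, `i` and the candidate `cbar` are sigmoid (or tanh for the
#' candidate when the layer was built with `candidate_tanh = TRUE`) functions
#' of the previous hidden state and the current input; the cell state is
#' `c = f * c_prev + i * cbar` and the hidden state `h = o * tanh(c)`.
#' Inputs may be vectors or row-batched matrices.
#'
#' @param layer an [rnn_layer()] with `cell_type == "lstm"`.
#' @param h_prev,c_prev previous hidden and cell state (`B x h`).
#' @param x current input (`B x input_dim`).
#' @return list with `h` and `c`.
#' @export
lstm_step <- function(layer, h_prev, c_prev, x) {
  assert_that(layer$cell_type == "lstm", "layer is not an LSTM layer")
  p <- layer$params
  h_prev <- as_row(h_prev, layer$size); c_prev <- as_row(c_prev, layer$size)
  x <- as_row(x, layer$input_dim)
  o <- sigmoid(add_bias(h_prev %*% p$Uo + x %*% p$Wo, p$bo))
  f <- sigmoid(add_bias(h_prev %*% p$Uf + x %*% p$Wf, p$bf))
  i <- sigmoid(add_bias(h_prev %*% p$Ui + x %*% p$Wi, p$bi))
  pre_c <- add_bias(h_prev %*% p$Uc + x %*% p$Wc, p$bc)
  cbar <- if (layer$candidate_tanh) tanh(pre_c) else sigmoid(pre_c)
  check_finite_gates(list(o = o, f = f, i = i, cbar = cbar))
  cc <- f * c_prev + i * cbar
  h <- o * tanh(cc)
  list(h = h, c = cc, cache = list(x = x, h_prev = h_prev, c_prev = c_prev,
                                   o = o, f = f, i = i, cbar = cbar, c = cc))
}

#' One GRU step
#'
#' Update gate `z` and reset gate `r` are sigmoids of the previous hidden
#' state and current input; the candidate is
#' `hbar = tanh(Uh (r * h_prev) + Wh x + bh)` and the new state
#' `h = (1 - z) * h_prev + z * hbar`.
#'
#' @param layer an [rnn_layer()] with `cell_type == "gru"`.
#' @param h_prev previous hidden state (`B x h`).
#' @param x current input (`B x input_dim`).
#' @return list with `h`.
#' @export
gru_step <- function(layer, h_prev, x) {
  assert_that(layer$cell_type == "gru", "layer is not a GRU layer")
  p <- layer$params
  h_prev <- as_row(h_prev, layer$size); x <- as_row(x, layer$input_dim)
  z <- sigmoid(add_bias(h_prev %*% p$Uz + x %*% p$Wz, p$bz))
  r <- sigmoid(add_bias(h_prev %*% p$Ur + x %*% p$Wr, p$br))
  hbar <- tanh(add_bias((r * h_prev) %*% p$Uh + x %*% p$Wh, p$bh))
  check_finite_gates(list(z = z, r = r, hbar = hbar))
  h <- (1 - z) * h_prev + z * hbar
  list(h = h, cache = list(x = x, h_prev = h_prev, z = z, r = r, hbar = hbar))
}

rnn_cell_step <- function(layer, state, x) {
  if (layer$cell_type == "lstm") {
    st <- lstm_step(layer, state$h, state$c, x)
    list(h = st$h, state = list(h = st$h, c = st$c), cache = st$cache)
  } else {
    st <- gru_step(layer, state$h, x)
    list(h = st$h, state = list(h = st$h), cache = st$cache)
  }
}

zero_state <- function(layer, batch) {
  s <- list(h = matrix(0, batch, layer$size))
  if (layer$cell_type == "lstm") s$c <- matrix(0, batch, layer$size)
  s
}

#' Construct an untrained two-layer recurrent response model
#'
#' Both recurrent layers have the same width; voxels in the model's group
#' share the recurrent trunk and differ only in their linear readout of the
#' second-layer hidden states (`yhat_t = h2_t %*% w_out`, no intercept — the
#' responses are z-scored).
#'
#' @param cell_type `"lstm"` or `"gru"`.
#' @param input_dim feature dimension `p`.
#' @param hidden units per layer (10, 50 or 100 in the standard roster).
#' @param n_voxels voxels sharing the trunk.
#' @param candidate_tanh see [rnn_layer()].
#' @param seed optional integer; when given, initialization is reproducible.
#' @param group label of the voxel group the model serves.
#' @return an object of class `rnn_response_model`.
#' @export
rnn_response_model <- function(cell_type = c("lstm", "gru"), input_dim, hidden,
                               n_voxels, candidate_tanh = FALSE, seed = NULL,
                               group = "all") {
  cell_type <- match.arg(cell_type)
  if (!is.null(seed)) set.seed(seed)
  layer1 <- rnn_layer(cell_type, input_dim, hidden, candidate_tanh)
  layer2 <- rnn_layer(cell_type, hidden, hidden, candidate_tanh)
  s <- 1 / sqrt(hidden)
  w_out <- matrix(stats::runif(hidden * n_voxels, -s, s), hidden, n_voxels)
  structure(list(cell_type = cell_type, input_dim = input_dim, hidden = hidden,
                 n_voxels = n_voxels, layer1 = layer1, layer2 = layer2,
                 w_out = w_out, group = group, history = NULL),
            class = "rnn_response_model")
}

#' Unroll a recurrent response model over one block
#'
#' Hidden and cell states start at zero at the block boundary; dropout is
#' never applied at inference. Hidden-state trajectories of both layers are
#' returned for representational analyses.
#'
#' @param model an [rnn_response_model()].
#' @param features numeric matrix `T x p` (one block).
#' @return list with `predictions` (`T x m`), `h1` (`T x h`), `h2` (`T x h`).
#' @export
forward_rnn <- function(model, features) {
  features <- as.matrix(features)
  assert_that(ncol(features) == model$input_dim, "feature dimension mismatch")
  tt <- nrow(features)
  s1 <- zero_state(model$layer1, 1L); s2 <- zero_state(model$layer2, 1L)
  h1 <- matrix(0, tt, model$hidden); h2 <- matrix(0, tt, model$hidden)
  for (t in seq_len(tt)) {
    st1 <- rnn_cell_step(model$layer1, s1, features[t, , drop = FALSE])
    s1 <- st1$state
    st2 <- rnn_cell_step(model$layer2, s2, st1$h)
    s2 <- st2$state
    h1[t, ] <- st1$h; h2[t, ] <- st2$h
  }
  list(predictions = h2 %*% model$w_out, h1 = h1, h2 = h2)
}

# ---- backpropagation through one truncation window -------------------------

# Batched forward over a window; xs is a list of B x d inputs per step.
window_forward <- function(layer, state, xs, masks = NULL) {
  tw <- length(xs)
  caches <- vector("list", tw); hs <- vector("list", tw)
  for (t in seq_len(tw)) {
    st <- rnn_cell_step(layer, state, xs[[t]])
    state <- st$state
    h <- st$h
    if (!is.null(masks)) h <- h * masks[[t]]
    hs[[t]] <- h
    caches[[t]] <- st$cache
  }
  list(h_dropped = hs, caches = caches, state = state)
}

zero_grads <- function(params) lapply(params, function(p) p * 0)

# dh_seq: list of B x h gradients w.r.t. the (post-dropout) hidden states.
# masks multiply into dh before entering the cell. Gradients are truncated at
# the window boundary (no flow into the initial state).
window_backward <- function(layer, caches, dh_seq, masks = NULL) {
  p <- layer$params
  g <- zero_grads(p)
  tw <- length(caches)
  size <- layer$size
  batch <- nrow(caches[[1]]$h_prev)
  dh_next <- matrix(0, batch, size)
  dc_next <- matrix(0, batch, size)
  dx_seq <- vector("list", tw)
  for (t in rev(seq_len(tw))) {
    dh <- dh_seq[[t]]
    if (!is.null(masks)) dh <- dh * masks[[t]]
    dh <- dh + dh_next
    ca <- caches[[t]]
    if (layer$cell_type == "gru") {
      dz <- dh * (ca$hbar - ca$h_prev)
      dhbar <- dh * ca$z
      dh_prev <- dh * (1 - ca$z)
      a_h <- dhbar * (1 - ca$hbar^2)
      g$Wh <- g$Wh + crossprod(ca$x, a_h)
      rh <- ca$r * ca$h_prev
      g$Uh <- g$Uh + crossprod(rh, a_h)
      g$bh <- g$bh + colSums(a_h)
      drh <- a_h %*% t(p$Uh)
      dr <- drh * ca$h_prev
      dh_prev <- dh_prev + drh * ca$r
      a_z <- dz * ca$z * (1 - ca$z)
      a_r <- dr * ca$r * (1 - ca$r)
      g$Wz <- g$Wz + crossprod(ca$x, a_z); g$Uz <- g$Uz + crossprod(ca$h_prev, a_z)
      g$bz <- g$bz + colSums(a_z)
      g$Wr <- g$Wr + crossprod(ca$x, a_r); g$Ur <- g$Ur + crossprod(ca$h_prev, a_r)
      g$br <- g$br + colSums(a_r)
      dh_prev <- dh_prev + a_z %*% t(p$Uz) + a_r %*% t(p$Ur)
      dx_seq[[t]] <- a_z %*% t(p$Wz) + a_r %*% t(p$Wr) + a_h %*% t(p$Wh)
      dh_next <- dh_prev
    } else {
      tc <- tanh(ca$c)
      do_ <- dh * tc
      dc <- dc_next + dh * ca$o * (1 - tc^2)
      df <- dc * ca$c_prev
      di <- dc * ca$cbar
      dcbar <- dc * ca$i
      dc_next <- dc * ca$f
      a_o <- do_ * ca$o * (1 - ca$o)
      a_f <- df * ca$f * (1 - ca$f)
      a_i <- di * ca$i * (1 - ca$i)
      a_c <- if (layer$candidate_tanh) dcbar * (1 - ca$cbar^2) else dcbar * ca$cbar * (1 - ca$cbar)
      dh_prev <- matrix(0, batch, size)
      dx <- matrix(0, batch, layer$input_dim)
      for (pair in list(list("o", a_o), list("f", a_f), list("i", a_i), list("c", a_c))) {
        gname <- pair[[1]]; a <- pair[[2]]
        g[[paste0("W", gname)]] <- g[[paste0("W", gname)]] + crossprod(ca$x, a)
        g[[paste0("U", gname)]] <- g[[paste0("U", gname)]] + crossprod(ca$h_prev, a)
        g[[paste0("b", gname)]] <- g[[paste0("b", gname)]] + colSums(a)
        dh_prev <- dh_prev + a %*% t(p[[paste0("U", gname)]])
        dx <- dx + a %*% t(p[[paste0("W", gname)]])
      }
      dx_seq[[t]] <- dx
      dh_next <- dh_prev
    }
  }
  list(grads = g, dx_seq = dx_seq)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Default training hyperparameters for recurrent response models
#'
#' @param truncation truncated-BPTT window length in samples (default 60).
#' @param learning_rate Adam step size (default 1e-3).
#' @param dropout rate applied to both hidden layers' outputs during training
#'   (default 0.5); disabled at inference.
#' @param max_epochs maximum training epochs (default 500).
#' @param patience epochs without validation improvement before stopping
#'   (default 50; the returned model is always the best-validation snapshot).
#' @param lr_patience epochs without improvement before the learning rate is
#'   halved and training resumes from the best snapshot (reduce-on-plateau;
#'   default 25).
#' @param lr_decay multiplicative learning-rate decay at each plateau
#'   (default 0.5).
#' @return named list of hyperparameters.
#' @export
rnn_hyperparams <- function(truncation = 60, learning_rate = 1e-3,
                            dropout = 0.5, max_epochs = 500, patience = 50,
                            lr_patience = 25, lr_decay = 0.5) {
  list(truncation = truncation, learning_rate = learning_rate,
       dropout = dropout, max_epochs = max_epochs, patience = patience,
       lr_patience = lr_patience, lr_decay = lr_decay)
}

# Stack a list of equally-sized T x d block matrices into a list of per-step
# B x d matrices (batch over blocks).
stack_steps <- function(blocks) {
  tt <- nrow(blocks[[1]]); d <- ncol(blocks[[1]]); b <- length(blocks)
  arr <- array(unlist(blocks), c(tt, d, b))
  lapply(seq_len(tt), function(t) t(matrix(arr[t, , ], d, b)))
}

#' Train a recurrent response model
#'
#' Minimizes mean squared prediction error over the training blocks by
#' truncated backpropagation through time with Adam. Hidden states carry
#' across windows within a block (gradients do not); states reset to zero at
#' every block boundary. Blocks of equal length are processed as one batch.
#' After each epoch the model is evaluated on the validation blocks (dropout
#' off) by the median Pearson correlation over voxels; the parameter snapshot
#' from the best validation epoch is returned.
#'
#' @param model an [rnn_response_model()].
#' @param train a train-role [encoding_dataset()].
#' @param validation a validation [encoding_dataset()] (may be `NULL`, in
#'   which case the final epoch is returned).
#' @param hyper list from [rnn_hyperparams()].
#' @param seed integer controlling dropout and any shuffling; with fixed seed
#'   and hyperparameters training is bit-reproducible.
#' @return the trained model; `$history` holds per-epoch training loss and
#'   validation median correlation, `$best_epoch` the selected epoch.
#' @export
train_rnn <- function(model, train, validation = NULL,
                      hyper = rnn_hyperparams(), seed = 1) {
  set.seed(seed)
  feats <- lapply(train$features, `[[`, "values")
  resps <- lapply(train$responses, `[[`, "values")
  lens <- vapply(feats, nrow, 0L)
  groups <- split(seq_along(feats), lens)
  batches <- lapply(groups, function(idx) {
    list(x = stack_steps(feats[idx]), y = stack_steps(resps[idx]),
         batch = length(idx), t = lens[idx[1]])
  })
  params <- c(
    stats::setNames(model$layer1$params, paste0("l1.", names(model$layer1$params))),
    stats::setNames(model$layer2$params, paste0("l2.", names(model$layer2$params))),
    list(w_out = model$w_out))
  opt <- adam_init(params)
  tw <- hyper$truncation
  drop_rate <- hyper$dropout
  best <- list(val = -Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = double(), val_r = double())
  if (hyper$max_epochs < 1) {
    model$history <- history
    model$best_epoch <- 0L
    return(model)
  }
  unpack <- function(model, params) {
    model$layer1$params <- stats::setNames(
      params[paste0("l1.", names(model$layer1$params))], names(model$layer1$params))
    model$layer2$params <- stats::setNames(
      params[paste0("l2.", names(model$layer2$params))], names(model$layer2$params))
    model$w_out <- params$w_out
    model
  }
  ctxs <- if (!is.null(validation)) validation_contexts(train, validation)
  validate <- function(params) {
    if (is.null(validation)) return(NA_real_)
    mcur <- unpack(model, params)
    preds <- do.call(rbind, lapply(ctxs, function(cx) {
      out <- forward_rnn(mcur, cx$features)$predictions
      out[(nrow(out) - cx$n_tail + 1):nrow(out), , drop = FALSE]
    }))
    obs <- do.call(rbind, lapply(ctxs, `[[`, "observed"))
    stats::median(pearson_cols(preds, obs))
  }
  m <- model$n_voxels
  since_best <- 0L
  since_decay <- 0L
  lr <- hyper$learning_rate
  lr_patience <- hyper$lr_patience %||% Inf
  lr_decay <- hyper$lr_decay %||% 0.5
  for (epoch in seq_len(hyper$max_epochs)) {
    epoch_loss <- 0; n_windows <- 0L
    for (bt in batches) {
      l1 <- unpack(model, params)$layer1
      l2 <- unpack(model, params)$layer2
      w_out <- params$w_out
      s1 <- zero_state(l1, bt$batch); s2 <- zero_state(l2, bt$batch)
      starts <- seq(1L, bt$t, by = tw)
      for (t0 in starts) {
        t1 <- min(t0 + tw - 1L, bt$t)
        idx <- t0:t1
        xs <- bt$x[idx]; ys <- bt$y[idx]
        nw <- length(idx)
        masks1 <- masks2 <- NULL
        if (drop_rate > 0) {
          mk <- function() lapply(seq_len(nw), function(i) {
            matrix(stats::rbinom(bt$batch * l1$size, 1, 1 - drop_rate),
                   bt$batch, l1$size) / (1 - drop_rate)
          })
          masks1 <- mk(); masks2 <- mk()
        }
        f1 <- window_forward(l1, s1, xs, masks1)
        f2 <- window_forward(l2, s2, f1$h_dropped, masks2)
        n_el <- nw * bt$batch * m
        loss <- 0
        dh2 <- vector("list", nw)
        g_out <- matrix(0, l2$size, m)
        for (i in seq_len(nw)) {
          yhat <- f2$h_dropped[[i]] %*% w_out
          resid <- yhat - ys[[i]]
          loss <- loss + sum(resid^2)
          dh2[[i]] <- (2 / n_el) * resid %*% t(w_out)
          g_out <- g_out + (2 / n_el) * crossprod(f2$h_dropped[[i]], resid)
        }
        loss <- loss / n_el
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        b2 <- window_backward(l2, f2$caches, dh2, masks2)
        b1 <- window_backward(l1, f1$caches, b2$dx_seq, masks1)
        grads <- c(
          stats::setNames(b1$grads, paste0("l1.", names(b1$grads))),
          stats::setNames(b2$grads, paste0("l2.", names(b2$grads))),
          list(w_out = g_out))
        upd <- adam_update(params, grads, opt, lr)
        params <- upd$params; opt <- upd$state
        # refresh layer views and carry states (detached) into the next window
        l1 <- unpack(model, params)$layer1
        l2 <- unpack(model, params)$layer2
        w_out <- params$w_out
        s1 <- f1$state; s2 <- f2$state
        epoch_loss <- epoch_loss + loss; n_windows <- n_windows + 1L
      }
    }
    val_r <- validate(params)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss / n_windows,
                                         val_r = val_r))
    if (is.na(val_r) || val_r > best$val) {
      best <- list(val = ifelse(is.na(val_r), -Inf, val_r), params = params,
                   epoch = epoch)
      since_best <- 0L
      since_decay <- 0L
    } else {
      since_best <- since_best + 1L
      since_decay <- since_decay + 1L
      if (!is.null(hyper$patience) && since_best >= hyper$patience) break
      if (since_decay >= lr_patience) {
        lr <- lr * lr_decay
        params <- best$params
        since_decay <- 0L
      }
    }
  }
  model <- unpack(model, best$params)
  model$history <- history
  model$best_epoch <- best$epoch
  model$best_val_r <- if (is.finite(best$val)) best$val else NA_real_
  model
}
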