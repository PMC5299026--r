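# Shared fixtures and independent reference implementations used as oracles.

# A small paired dataset with given block layout; responses optionally a
# planted linear function of features (plus noise).
make_tiny_dataset <- function(block_lengths = c(40, 40), roles = c("train", "train"),
                              p = 3, m = 4, seed = 1, noise_sd = 0,
                              weights = NULL, repeats_for_test = 0) {
  set.seed(seed)
  if (is.null(weights)) weights <- matrix(rnorm(p * m), p, m)
  feats <- list(); resps <- list()
  for (i in seq_along(block_lengths)) {
    tt <- block_lengths[i]
    fv <- matrix(rnorm(tt * p), tt, p)
    id <- paste0("b", i)
    feats[[i]] <- feature_block(fv, id, roles[i])
    signal <- fv %*% weights
    if (roles[i] == "test" && repeats_for_test >= 2) {
      reps <- array(0, c(repeats_for_test, tt, m))
      for (r in seq_len(repeats_for_test)) {
        reps[r, , ] <- signal + matrix(rnorm(tt * m, sd = noise_sd), tt, m)
      }
      resps[[i]] <- response_block(apply(reps, c(2, 3), mean), id, reps)
    } else {
      resps[[i]] <- response_block(signal + matrix(rnorm(tt * m, sd = noise_sd), tt, m), id)
    }
  }
  encoding_dataset(feats, resps, 1, rep("area1", m))
}

# Loop-based, per-unit reference LSTM step (independent of the package's
# vectorized implementation).
reference_lstm_step <- function(params, h_prev, c_prev, x, candidate_tanh = FALSE) {
  h <- length(h_prev)
  hn <- numeric(h); cn <- numeric(h)
  sig <- function(v) 1 / (1 + exp(-v))
  for (j in seq_len(h)) {
    o <- sig(sum(params$Uo[, j] * h_prev) + sum(params$Wo[, j] * x) + params$bo[j])
    f <- sig(sum(params$Uf[, j] * h_prev) + sum(params$Wf[, j] * x) + params$bf[j])
    i <- sig(sum(params$Ui[, j] * h_prev) + sum(params$Wi[, j] * x) + params$bi[j])
    pre <- sum(params$Uc[, j] * h_prev) + sum(params$Wc[, j] * x) + params$bc[j]
    cb <- if (candidate_tanh) tanh(pre) else sig(pre)
    cn[j] <- f * c_prev[j] + i * cb
    hn[j] <- o * tanh(cn[j])
  }
  list(h = hn, c = cn)
}

reference_gru_step <- function(params, h_prev, x) {
  h <- length(h_prev)
  hn <- numeric(h)
  sig <- function(v) 1 / (1 + exp(-v))
  z <- r <- numeric(h)
  for (j in seq_len(h)) {
    z[j] <- sig(sum(params$Uz[, j] * h_prev) + sum(params$Wz[, j] * x) + params$bz[j])
    r[j] <- sig(sum(params$Ur[, j] * h_prev) + sum(params$Wr[, j] * x) + params$br[j])
  }
  rh <- r * h_prev
  for (j in seq_len(h)) {
    hb <- tanh(sum(params$Uh[, j] * rh) + sum(params$Wh[, j] * x) + params$bh[j])
    hn[j] <- (1 - z[j]) * h_prev[j] + z[j] * hb
  }
  hn
}

# Direct O(T L) causal convolution, the oracle for toeplitz_convolve.
reference_convolve <- function(kernel, f) {
  tt <- nrow(f); L <- length(kernel) - 1
  out <- matrix(0, tt, ncol(f))
  for (j in seq_len(ncol(f))) {
    for (t in seq_len(tt)) {
      for (l in 0:min(t - 1, L)) {
        out[t, j] <- out[t, j] + kernel[l + 1] * f[t - l, j]
      }
    }
  }
  out
}

# Build a fitted R-C response model with prescribed coefficients, bypassing
# estimation — used to probe linear models whose kernel is known exactly.
make_linear_rc_model <- function(b, p, sampling_interval = 1) {
  kernels <- ridge_kernels(sampling_interval)
  rm <- ridge_solve(diag(p), matrix(0, p, nrow(b)), 0)
  rm$b <- b
  rm$variant <- "R-C"
  structure(list(name = "R-C", spec = parse_model_name("R-C"),
                 sampling_interval = sampling_interval, n_voxels = nrow(b),
                 n_features = p, model = rm, kernels = kernels),
            class = "response_model")
}

# Desk-scale RNN training configuration shared across tests.
test_rnn_hyper <- function(max_epochs = 600, dropout = 0.2) {
  rnn_hyperparams(learning_rate = 3e-3, dropout = dropout,
                  max_epochs = max_epochs, patience = 150, lr_patience = 60)
}
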