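# Training protocol: per-subject leave-one-seizure-out folds, SMOTE
# oversampling of the minority class, gradient-harmonizing (GHM) weighted
# binary cross-entropy, Adam with a 10%-per-epoch learning-rate decay, and
# dropout on the fully connected head.

#' Training configuration
#'
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative decay per epoch (0.9 = minus 10\% each
#'   epoch).
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param ghm_bins number of gradient-density bins of the GHM loss.
#' @param ghm_momentum momentum of the GHM bin-density running estimate.
#' @param smote_k number of minority neighbours SMOTE interpolates between.
#' @param early_stop_patience stop when the epoch training loss has not
#'   improved for this many epochs; \code{Inf} disables early stopping (used
#'   by determinism tests).
#' @param seed RNG seed.
#' @return a list of class \code{train_config}.
#' @export
train_config <- function(lr0 = 0.01, lr_decay = 0.9, epochs = 50L,
                         batch_size = 32L, ghm_bins = 10L, ghm_momentum = 0.75,
                         smote_k = 5L, early_stop_patience = 10L, seed = 1L) {
  stopifnot(lr0 > 0, lr_decay > 0, lr_decay <= 1, epochs >= 1, batch_size >= 1,
            ghm_bins >= 1, ghm_momentum >= 0, ghm_momentum < 1, smote_k >= 1)
  structure(list(lr0 = lr0, lr_decay = lr_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 ghm_bins = as.integer(ghm_bins), ghm_momentum = ghm_momentum,
                 smote_k = as.integer(smote_k),
                 early_stop_patience = early_stop_patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' \code{lr0 * lr_decay^epoch} with 0-based epochs: 0.01, 0.009, 0.0081, ...
#' under the defaults.
#'
#' @param epoch 0-based epoch index.
#' @param cfg a \code{\link{train_config}}.
#' @return the learning rate.
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  stopifnot(all(epoch >= 0))
  cfg$lr0 * cfg$lr_decay^epoch
}

#' Leave-one-seizure-out fold plan
#'
#' One fold per preictal seizure group: the group's preictal segments plus
#' the interictal segments assigned to it (nearest seizure in time) form the
#' test set; all other segments train. Requires at least two distinct
#' preictal groups.
#'
#' @param meta data.frame with one row per segment and columns \code{label}
#'   (1 preictal / 0 interictal) and \code{seizure_group}.
#' @return list of folds, each \code{list(group, train, test)} with integer
#'   row indices into \code{meta}.
#' @export
make_loocv_folds <- function(meta) {
  stopifnot(all(c("label", "seizure_group") %in% names(meta)))
  groups <- sort(unique(meta$seizure_group[meta$label == 1L]))
  if (length(groups) < 2L) {
    stopf("leave-one-seizure-out needs at least 2 seizures with preictal data; use a plain holdout instead")
  }
  idx <- seq_len(nrow(meta))
  lapply(groups, function(g) {
    test <- idx[!is.na(meta$seizure_group) & meta$seizure_group == g]
    list(group = g, train = setdiff(idx, test), test = test)
  })
}

# -- SMOTE --------------------------------------------------------------------

flatten_graph <- function(s) c(as.vector(s$x), s$a[upper.tri(s$a)])

unflatten_graph <- function(v, nn, nf, y) {
  x <- matrix(v[seq_len(nn * nf)], nn, nf)
  a <- matrix(0, nn, nn)
  a[upper.tri(a)] <- v[-seq_len(nn * nf)]
  a <- a + t(a)
  a <- pmin(pmax(a, 0), 1) # interpolation stays in range; clamp for safety
  as_graph_sample(x, a, y)
}

#' SMOTE oversampling of graph samples
#'
#' Balances the two classes by synthesizing minority-class samples: each
#' synthetic sample is a convex combination (uniform lambda in [0, 1]) of a
#' random minority sample and one of its k nearest minority neighbours in the
#' flattened representation (node features concatenated with the adjacency
#' upper triangle, so synthesized adjacencies stay symmetric with zero
#' diagonal). Already balanced input is returned unchanged.
#'
#' @param graphs list of graph samples (see \code{\link{as_graph_sample}})
#'   with binary labels \code{y}.
#' @param k number of nearest neighbours (truncated to minority size - 1 when
#'   needed).
#' @param seed RNG seed.
#' @return list of graph samples with equal class counts (original samples
#'   first, synthetic ones appended).
#' @export
smote_balance <- function(graphs, k = 5L, seed = 1L) {
  y <- vapply(graphs, `[[`, numeric(1), "y")
  if (any(!y %in% c(0, 1))) stopf("smote_balance needs binary labels")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  if (n1 == n0) return(graphs)
  minority <- if (n1 < n0) 1 else 0
  need <- abs(n0 - n1)
  min_idx <- which(y == minority)
  if (length(min_idx) < 2L) stopf("minority class needs at least 2 samples for SMOTE")
  k <- min(k, length(min_idx) - 1L)
  flat <- do.call(rbind, lapply(graphs[min_idx], flatten_graph))
  d <- as.matrix(stats::dist(flat))
  diag(d) <- Inf
  nn_idx <- do.call(rbind, lapply(seq_len(nrow(d)),
                                  function(i) order(d[i, ])[seq_len(k)]))
  nn <- nrow(graphs[[1L]]$x)
  nf <- ncol(graphs[[1L]]$x)
  set.seed(seed)
  base <- sample.int(length(min_idx), need, replace = TRUE)
  pick <- if (k == 1L) rep(1L, need) else sample.int(k, need, replace = TRUE)
  lam <- stats::runif(need)
  synth <- lapply(seq_len(need), function(s) {
    v <- flat[base[s], ] + lam[s] * (flat[nn_idx[base[s], pick[s]], ] - flat[base[s], ])
    unflatten_graph(v, nn, nf, minority)
  })
  c(graphs, synth)
}

# -- GHM loss -----------------------------------------------------------------

#' Gradient-harmonizing (GHM-C) weighted binary cross-entropy
#'
#' Each example's gradient norm \code{g = |p - y|} falls into one of
#' \code{bins} equal bins of [0, 1]; examples are weighted inversely to the
#' (momentum-smoothed) population of their bin and the weights are normalized
#' to mean 1, so easy examples crowding one bin are down-weighted relative to
#' the rare hard ones. With every example in a single bin the loss reduces to
#' the plain mean binary cross-entropy.
#'
#' @param p predicted probabilities in (0, 1).
#' @param y binary labels.
#' @param bins number of gradient-density bins.
#' @param momentum running-density momentum (0 = stateless).
#' @param state previous bin-density state (NULL on the first batch).
#' @return list with \code{loss}, per-example \code{weights} (mean 1),
#'   \code{state} (updated densities) and \code{dz} (gradient of the loss
#'   w.r.t. the pre-sigmoid outputs).
#' @export
ghm_loss <- function(p, y, bins = 10L, momentum = 0.75, state = NULL) {
  n <- length(p)
  if (n == 0L) stopf("empty batch")
  stopifnot(length(y) == n, all(p > 0), all(p < 1))
  g <- abs(p - y)
  bin <- pmin(floor(g * bins) + 1L, bins)
  counts <- tabulate(bin, nbins = bins)
  state <- if (is.null(state) || momentum == 0) counts
           else momentum * state + (1 - momentum) * counts
  density <- state[bin]
  w <- 1 / pmax(density, .Machine$double.eps)
  w <- w / mean(w)
  bce <- -(y * log(p) + (1 - y) * log(1 - p))
  list(loss = mean(w * bce), weights = w, state = state, dz = w * (p - y) / n)
}

# -- Adam ---------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) lapply(x, function(l) lapply(l, function(v) v * 0))
  list(m = list(conv = zero_like(params$conv), fc = zero_like(params$fc)),
       v = list(conv = zero_like(params$conv), fc = zero_like(params$fc)),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (part in c("conv", "fc")) {
    for (l in seq_along(params[[part]])) {
      for (nm in c("w", "b")) {
        gmat <- grads[[part]][[l]][[nm]]
        state$m[[part]][[l]][[nm]] <- beta1 * state$m[[part]][[l]][[nm]] + (1 - beta1) * gmat
        state$v[[part]][[l]][[nm]] <- beta2 * state$v[[part]][[l]][[nm]] + (1 - beta2) * gmat^2
        mhat <- state$m[[part]][[l]][[nm]] / corr1
        vhat <- state$v[[part]][[l]][[nm]] / corr2
        params[[part]][[l]][[nm]] <- params[[part]][[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(params = params, state = state)
}

# -- fold training ------------------------------------------------------------

#' Train the GCN on one fold
#'
#' SMOTE-balances the training graphs, then minimizes the GHM-weighted binary
#' cross-entropy with Adam under the 10\%-per-epoch learning-rate decay.
#' Dropout is active; batch-norm running statistics are accumulated for
#' evaluation mode. Deterministic given \code{cfg$seed}.
#'
#' @param graphs list of labeled graph samples (the training portion of a
#'   fold; the caller must never pass test segments here).
#' @param cfg a \code{\link{train_config}}.
#' @param model_cfg a \code{\link{model_config}}.
#' @param balance apply SMOTE before training (default TRUE).
#' @return list with \code{params} (fitted \code{gcn_params}), \code{cfg}
#'   (the model config) and \code{history} (data.frame epoch/lr/loss).
#' @export
train_fold <- function(graphs, cfg = train_config(), model_cfg = model_config(),
                       balance = TRUE) {
  if (!length(graphs)) stopf("empty training set")
  if (balance) graphs <- smote_balance(graphs, cfg$smote_k, seed = child_seed(cfg$seed, 1L))
  y <- vapply(graphs, `[[`, numeric(1), "y")
  if (length(unique(y)) < 2L) stopf("training set must contain both classes")
  set.seed(child_seed(cfg$seed, 2L))
  params <- gcn_init(model_cfg, seed = child_seed(cfg$seed, 3L))
  opt <- adam_init(params)
  ghm_state <- NULL
  n <- length(graphs)
  history <- data.frame(epoch = integer(), lr = numeric(), loss = numeric())
  best <- Inf; since_best <- 0L
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_schedule(epoch, cfg)
    ord <- sample.int(n)
    losses <- numeric()
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      sel <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      if (length(sel) < 2L) next # BN needs more than one row of statistics
      fwd <- gcn_forward(graphs[sel], params, model_cfg, training = TRUE, keep_cache = TRUE)
      params <- fwd$params
      gl <- ghm_loss(fwd$p, y[sel], cfg$ghm_bins, cfg$ghm_momentum, ghm_state)
      ghm_state <- gl$state
      if (!is.finite(gl$loss)) stopf("training diverged (non-finite loss) at epoch %d", epoch)
      grads <- gcn_backward(gl$dz, fwd$cache, params, model_cfg)
      st <- adam_step(params, grads, opt, lr)
      params <- st$params; opt <- st$state
      losses <- c(losses, gl$loss)
    }
    epoch_loss <- mean(losses)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr, loss = epoch_loss))
    if (epoch_loss < best - 1e-6) { best <- epoch_loss; since_best <- 0L } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$early_stop_patience) break
    }
  }
  list(params = params, cfg = model_cfg, history = history)
}

#' Predict preictal probabilities for graph samples
#'
#' Evaluation-mode forward pass (frozen BN statistics, no dropout).
#'
#' @param fit result of \code{\link{train_fold}} (or a list with
#'   \code{params} and \code{cfg}).
#' @param graphs list of graph samples.
#' @return numeric vector of probabilities.
#' @export
predict_gcn <- function(fit, graphs) {
  gcn_forward(graphs, fit$params, fit$cfg, training = FALSE)$p
}
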