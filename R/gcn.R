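# The graph convolutional classifier.
#
# Propagation follows the first-order GCN rule with the renormalization
# trick: self-loops are added to the adjacency and both sides are scaled by
# the inverse square root of the resulting degree, so each layer computes
# sigma(BN(Ahat H W + b)). The architecture is three graph-conv layers
# (32/64/128 channels), global average pooling over the nodes, and a
# 128 -> 32 -> 16 -> 1 fully connected head with a sigmoid output. The whole
# forward/backward pass is implemented here (no deep-learning framework);
# gradients are exercised against numerical differentiation in the tests.

#' Model architecture configuration
#'
#' @param in_dim node feature dimension F (default 9: six band energies plus
#'   three Hjorth parameters).
#' @param conv_widths channel widths of the graph-conv layers.
#' @param fc_widths widths of the hidden fully connected layers (the head input
#'   is the pooled last conv width; the output is \code{out_dim}).
#' @param out_dim output width (1: preictal probability).
#' @param n_nodes number of graph nodes (18 bipolar derivations).
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @param dropout_p dropout probability on the fully connected layers
#'   (training mode only).
#' @param bn_affine whether batch normalization carries trainable scale/shift
#'   (off by default to respect the parameter budget).
#' @param bn_eps,bn_momentum batch-norm variance floor and running-statistics
#'   update rate.
#' @return a list of class \code{model_config}.
#' @export
model_config <- function(in_dim = 9L, conv_widths = c(32L, 64L, 128L),
                         fc_widths = c(32L, 16L), out_dim = 1L, n_nodes = 18L,
                         leaky_slope = 0.01, dropout_p = 0.5,
                         bn_affine = FALSE, bn_eps = 1e-5, bn_momentum = 0.1) {
  stopifnot(in_dim >= 1, all(conv_widths >= 1), all(fc_widths >= 1),
            out_dim >= 1, n_nodes >= 1, dropout_p >= 0, dropout_p < 1)
  structure(list(in_dim = as.integer(in_dim),
                 conv_widths = as.integer(conv_widths),
                 fc_widths = as.integer(fc_widths),
                 out_dim = as.integer(out_dim), n_nodes = as.integer(n_nodes),
                 leaky_slope = leaky_slope, dropout_p = dropout_p,
                 bn_affine = isTRUE(bn_affine), bn_eps = bn_eps,
                 bn_momentum = bn_momentum),
            class = "model_config")
}

#' Renormalized adjacency
#'
#' The renormalization trick: add self-loops, then symmetrically normalize,
#' \code{Ahat = D^{-1/2} (A + I) D^{-1/2}} with \code{D} the diagonal of row
#' sums of \code{A + I}. The result is symmetric with spectrum in [-1, 1].
#'
#' @param a symmetric, non-negative adjacency matrix.
#' @return the renormalized adjacency \code{Ahat}.
#' @export
normalize_adjacency <- function(a) {
  a <- as.matrix(a)
  if (!isSymmetric(unname(a), tol = 1e-9)) stopf("adjacency must be symmetric")
  if (any(a < 0)) stopf("adjacency must be non-negative")
  at <- a + diag(nrow(a))
  dinv <- 1 / sqrt(rowSums(at))
  ahat <- at * tcrossprod(dinv)
  (ahat + t(ahat)) / 2
}

#' Graph Fourier transform (spectral test oracle)
#'
#' Projects a node signal onto the orthonormal eigenbasis \code{U} of a
#' symmetric graph Laplacian: \code{coef = t(U) phi}. Kept as an independent
#' oracle for the spectral view of graph convolution; the runtime model uses
#' only the renormalized propagation rule.
#'
#' @param phi numeric node signal (length n) or n x k matrix.
#' @param lap symmetric n x n Laplacian matrix.
#' @return list with \code{coef} (spectral coefficients), \code{values}
#'   (eigenvalues, increasing) and \code{vectors} (the eigenbasis U).
#' @export
graph_fourier_transform <- function(phi, lap) {
  lap <- as.matrix(lap)
  if (!isSymmetric(unname(lap), tol = 1e-9)) stopf("Laplacian must be symmetric")
  e <- eigen(lap, symmetric = TRUE)
  ord <- order(e$values)
  u <- e$vectors[, ord, drop = FALSE]
  list(coef = crossprod(u, phi), values = e$values[ord], vectors = u)
}

#' Inverse graph Fourier transform
#'
#' @param coef spectral coefficients as returned by
#'   \code{\link{graph_fourier_transform}}.
#' @param lap the same symmetric Laplacian used for the forward transform.
#' @return the reconstructed node signal.
#' @export
inverse_graph_fourier_transform <- function(coef, lap) {
  g <- graph_fourier_transform(matrix(0, nrow(as.matrix(lap)), 1L), lap)
  g$vectors %*% coef
}

leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

dleaky_relu <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

#' One graph convolution layer
#'
#' \code{activation(Ahat \%*\% h \%*\% w + bias)} for a single graph; the
#' building block of the model, exposed for inspection and testing (the full
#' model adds batch normalization between the linear map and the activation).
#'
#' @param h node feature matrix (n x c_in).
#' @param ahat renormalized adjacency (n x n).
#' @param w weight matrix (c_in x c_out).
#' @param bias bias vector (length c_out, default 0).
#' @param activation activation function (default LeakyReLU slope 0.01; pass
#'   \code{identity} for the bare linear map).
#' @return the transformed node features (n x c_out).
#' @export
gcn_layer <- function(h, ahat, w, bias = 0, activation = function(x) leaky_relu(x, 0.01)) {
  h <- as.matrix(h); w <- as.matrix(w)
  if (ncol(h) != nrow(w)) stopf("shape mismatch: h is %dx%d but w is %dx%d",
                                nrow(h), ncol(h), nrow(w), ncol(w))
  if (nrow(ahat) != nrow(h)) stopf("shape mismatch: ahat is %dx%d but h has %d rows",
                                   nrow(ahat), ncol(ahat), nrow(h))
  z <- ahat %*% h %*% w
  z <- sweep(z, 2L, rep_len(bias, ncol(z)), "+")
  activation(z)
}

# -- parameters ---------------------------------------------------------------

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, batch-norm running statistics at
#' mean 0 / variance 1 (and unit scale / zero shift when affine).
#'
#' @param cfg a \code{\link{model_config}}.
#' @param seed RNG seed for reproducible initialization.
#' @return a list of class \code{gcn_params} with elements \code{conv},
#'   \code{fc} (each a list of \code{list(w, b)}) and \code{bn} (running
#'   statistics per conv layer).
#' @export
gcn_init <- function(cfg = model_config(), seed = 1L) {
  set.seed(seed)
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  dims <- c(cfg$in_dim, cfg$conv_widths)
  conv <- lapply(seq_along(cfg$conv_widths), function(l) {
    list(w = glorot(dims[l], dims[l + 1L]), b = numeric(dims[l + 1L]))
  })
  fdims <- c(cfg$conv_widths[length(cfg$conv_widths)], cfg$fc_widths, cfg$out_dim)
  fc <- lapply(seq_len(length(fdims) - 1L), function(l) {
    list(w = glorot(fdims[l], fdims[l + 1L]), b = numeric(fdims[l + 1L]))
  })
  bn <- lapply(cfg$conv_widths, function(cw) {
    st <- list(mean = numeric(cw), var = rep(1, cw))
    if (cfg$bn_affine) { st$gamma <- rep(1, cw); st$beta <- numeric(cw) }
    st
  })
  structure(list(conv = conv, fc = fc, bn = bn), class = "gcn_params")
}

#' Trainable parameter count (closed form)
#'
#' Sum over conv layers of \code{c_in * c_out + c_out}, over FC layers of
#' \code{d_in * d_out + d_out}, plus \code{2 * c_out} per conv layer when
#' batch norm is affine. The default configuration gives 15,425 parameters,
#' inside the 15.52 k budget.
#'
#' @param cfg a \code{\link{model_config}}.
#' @return integer parameter count.
#' @export
param_count <- function(cfg = model_config()) {
  dims <- c(cfg$in_dim, cfg$conv_widths)
  n <- sum(dims[-length(dims)] * dims[-1L] + dims[-1L])
  fdims <- c(cfg$conv_widths[length(cfg$conv_widths)], cfg$fc_widths, cfg$out_dim)
  n <- n + sum(fdims[-length(fdims)] * fdims[-1L] + fdims[-1L])
  if (cfg$bn_affine) n <- n + 2L * sum(cfg$conv_widths)
  as.integer(n)
}

#' Trainable parameter count by enumeration
#'
#' Counts every element of the instantiated weight/bias (and affine BN)
#' tensors; must agree with \code{\link{param_count}}.
#'
#' @param params a \code{gcn_params} object.
#' @return integer parameter count.
#' @export
count_params <- function(params) {
  n <- sum(vapply(params$conv, function(l) length(l$w) + length(l$b), numeric(1)))
  n <- n + sum(vapply(params$fc, function(l) length(l$w) + length(l$b), numeric(1)))
  n <- n + sum(vapply(params$bn, function(s) length(s$gamma) + length(s$beta), numeric(1)))
  as.integer(n)
}

#' Print the layer table and parameter count
#'
#' @param cfg a \code{\link{model_config}}.
#' @return the total parameter count, invisibly.
#' @export
describe_gcn <- function(cfg = model_config()) {
  dims <- c(cfg$in_dim, cfg$conv_widths)
  for (l in seq_along(cfg$conv_widths)) {
    cat(sprintf("GCNConv %d: %4d -> %4d  (BN%s + LeakyReLU)  params %d\n",
                l, dims[l], dims[l + 1L], if (cfg$bn_affine) "(affine)" else "",
                dims[l] * dims[l + 1L] + dims[l + 1L] +
                  if (cfg$bn_affine) 2L * dims[l + 1L] else 0L))
  }
  cat(sprintf("GlobalAvgPool over %d nodes -> %d\n", cfg$n_nodes,
              cfg$conv_widths[length(cfg$conv_widths)]))
  fdims <- c(cfg$conv_widths[length(cfg$conv_widths)], cfg$fc_widths, cfg$out_dim)
  for (l in seq_len(length(fdims) - 1L)) {
    act <- if (l < length(fdims) - 1L) sprintf("LeakyReLU + dropout %.2f", cfg$dropout_p) else "sigmoid"
    cat(sprintf("FC %d: %4d -> %4d  (%s)  params %d\n", l, fdims[l], fdims[l + 1L],
                act, fdims[l] * fdims[l + 1L] + fdims[l + 1L]))
  }
  total <- param_count(cfg)
  cat(sprintf("total trainable parameters: %d (%.2f k)\n", total, total / 1000))
  invisible(total)
}

# -- forward ------------------------------------------------------------------

batch_stack <- function(graphs, what) do.call(rbind, lapply(graphs, `[[`, what))

# Ahat %*% block for every sample; graphs supply `ahat`, h_all is the stacked
# (B * n_nodes) x c matrix.
block_prop <- function(graphs, h_all, nn) {
  out <- matrix(0, nrow(h_all), ncol(h_all))
  for (i in seq_along(graphs)) {
    rows <- ((i - 1L) * nn + 1L):(i * nn)
    out[rows, ] <- graphs[[i]]$ahat %*% h_all[rows, , drop = FALSE]
  }
  out
}

#' Forward pass of the GCN classifier
#'
#' @param graphs list of graph samples; each a list with \code{x} (n_nodes x F
#'   node features) and \code{ahat} (renormalized adjacency) — see
#'   \code{\link{as_graph_sample}}.
#' @param params a \code{gcn_params} object.
#' @param cfg the matching \code{\link{model_config}}.
#' @param training logical; training mode uses batch BN statistics (updating
#'   the running ones) and active dropout, evaluation mode uses frozen running
#'   statistics and no dropout.
#' @param keep_cache keep intermediate activations for
#'   \code{\link{gcn_backward}}.
#' @return list with \code{p} (per-sample probabilities, strictly inside
#'   (0, 1)), \code{params} (with updated BN running statistics when
#'   training) and, if requested, \code{cache}.
#' @export
gcn_forward <- function(graphs, params, cfg = model_config(), training = FALSE,
                        keep_cache = FALSE) {
  nn <- cfg$n_nodes
  b <- length(graphs)
  h <- batch_stack(graphs, "x")
  if (ncol(h) != cfg$in_dim) stopf("node feature dim %d != model in_dim %d", ncol(h), cfg$in_dim)
  if (nrow(h) != b * nn) stopf("each graph must have %d nodes", nn)
  cache <- list(conv = vector("list", length(params$conv)), fc = list())

  for (l in seq_along(params$conv)) {
    m_all <- block_prop(graphs, h, nn)
    z <- m_all %*% params$conv[[l]]$w
    z <- sweep(z, 2L, params$conv[[l]]$b, "+")
    if (training) {
      mu <- colMeans(z)
      va <- colMeans(z^2) - mu^2
      mom <- cfg$bn_momentum
      params$bn[[l]]$mean <- (1 - mom) * params$bn[[l]]$mean + mom * mu
      params$bn[[l]]$var <- (1 - mom) * params$bn[[l]]$var + mom * va
    } else {
      mu <- params$bn[[l]]$mean
      va <- params$bn[[l]]$var
    }
    s_inv <- 1 / sqrt(va + cfg$bn_eps)
    zhat <- sweep(sweep(z, 2L, mu, "-"), 2L, s_inv, "*")
    act_in <- if (cfg$bn_affine) {
      sweep(sweep(zhat, 2L, params$bn[[l]]$gamma, "*"), 2L, params$bn[[l]]$beta, "+")
    } else zhat
    h_new <- leaky_relu(act_in, cfg$leaky_slope)
    if (any(is.nan(h_new))) stopf("NaN activations in conv layer %d", l)
    if (keep_cache) {
      cache$conv[[l]] <- list(h_in = h, m_all = m_all, zhat = zhat,
                              act_in = act_in, s_inv = s_inv)
    }
    h <- h_new
  }

  gi <- rep(seq_len(b), each = nn)
  g <- rowsum(h, gi) / nn
  cache$g <- g
  u <- g
  nfc <- length(params$fc)
  for (l in seq_len(nfc)) {
    pre <- sweep(u %*% params$fc[[l]]$w, 2L, params$fc[[l]]$b, "+")
    if (any(is.nan(pre))) stopf("NaN activations in FC layer %d", l)
    if (l < nfc) {
      a <- leaky_relu(pre, cfg$leaky_slope)
      mask <- if (training && cfg$dropout_p > 0) {
        matrix(stats::rbinom(length(a), 1L, 1 - cfg$dropout_p), nrow(a)) / (1 - cfg$dropout_p)
      } else matrix(1, nrow(a), ncol(a))
      u_new <- a * mask
      if (keep_cache) cache$fc[[l]] <- list(u_in = u, pre = pre, mask = mask)
      u <- u_new
    } else {
      if (keep_cache) cache$fc[[l]] <- list(u_in = u, pre = pre)
      u <- pre
    }
  }
  p <- 1 / (1 + exp(-u[, 1L]))
  # keep probabilities strictly inside (0,1) for the log-loss
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  out <- list(p = p, params = params)
  if (keep_cache) { cache$graphs <- graphs; out$cache <- cache }
  out
}

#' Backward pass: gradients of the loss w.r.t. every trainable parameter
#'
#' @param dz gradient of the loss w.r.t. the pre-sigmoid output (length B; for
#'   weighted binary cross-entropy this is \code{w * (p - y) / B}).
#' @param cache forward cache from \code{\link{gcn_forward}} with
#'   \code{keep_cache = TRUE}.
#' @param params,cfg the parameters and configuration used in the forward
#'   pass.
#' @return a list shaped like \code{params} holding gradients (\code{conv},
#'   \code{fc}, and \code{bn} gamma/beta when affine).
#' @export
gcn_backward <- function(dz, cache, params, cfg = model_config()) {
  nn <- cfg$n_nodes
  graphs <- cache$graphs
  b <- length(graphs)
  grads <- list(conv = vector("list", length(params$conv)),
                fc = vector("list", length(params$fc)),
                bn = vector("list", length(params$conv)))

  du <- matrix(dz, ncol = cfg$out_dim)
  for (l in rev(seq_along(params$fc))) {
    cc <- cache$fc[[l]]
    if (l < length(params$fc)) {
      du <- du * cc$mask
      du <- du * dleaky_relu(cc$pre, cfg$leaky_slope)
    }
    grads$fc[[l]] <- list(w = crossprod(cc$u_in, du), b = colSums(du))
    du <- du %*% t(params$fc[[l]]$w)
  }

  dh <- du[rep(seq_len(b), each = nn), , drop = FALSE] / nn
  n_rows <- b * nn
  for (l in rev(seq_along(params$conv))) {
    cc <- cache$conv[[l]]
    dact <- dh * dleaky_relu(cc$act_in, cfg$leaky_slope)
    if (cfg$bn_affine) {
      grads$bn[[l]] <- list(gamma = colSums(dact * cc$zhat), beta = colSums(dact))
      dzhat <- sweep(dact, 2L, params$bn[[l]]$gamma, "*")
    } else {
      dzhat <- dact
    }
    # batch-norm backward (training-mode batch statistics, biased variance)
    s1 <- colSums(dzhat)
    s2 <- colSums(dzhat * cc$zhat)
    dzl <- sweep(n_rows * dzhat -
                   matrix(s1, n_rows, length(s1), byrow = TRUE) -
                   cc$zhat * matrix(s2, n_rows, length(s2), byrow = TRUE),
                 2L, cc$s_inv / n_rows, "*")
    grads$conv[[l]] <- list(w = crossprod(cc$m_all, dzl), b = colSums(dzl))
    dm <- dzl %*% t(params$conv[[l]]$w)
    dh <- block_prop(graphs, dm, nn) # Ahat is symmetric: Ahat^T = Ahat
  }
  grads
}

#' Package a node-feature matrix and adjacency as a graph sample
#'
#' @param x node feature matrix (n_nodes x F).
#' @param a symmetric adjacency matrix (not yet renormalized).
#' @param y optional binary label.
#' @return list with \code{x}, \code{a}, \code{ahat}
#'   (= \code{\link{normalize_adjacency}(a)}) and \code{y}.
#' @export
as_graph_sample <- function(x, a, y = NA_integer_) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stopf("non-finite node features")
  list(x = x, a = a, ahat = normalize_adjacency(a), y = y)
}

# -- checkpoints --------------------------------------------------------------

#' Save a fitted model as a single JSON checkpoint
#'
#' Stores config, weights and BN running statistics with a format-version
#' field; plain text, loadable with \code{\link{load_gcn}}.
#'
#' @param params a \code{gcn_params} object.
#' @param cfg the matching \code{\link{model_config}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_gcn <- function(params, cfg, path) {
  obj <- list(format_version = 1L, config = unclass(cfg),
              params = rapply(unclass(params), identity, how = "list"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by \code{\link{save_gcn}}
#'
#' @param path checkpoint path.
#' @return list with \code{params} (a \code{gcn_params}) and \code{cfg}.
#' @export
load_gcn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stopf("unsupported checkpoint format in %s", path)
  }
  cfg <- do.call(model_config, obj$config[names(obj$config) %in% names(formals(model_config))])
  params <- obj$params
  params$conv <- lapply(params$conv, function(l) list(w = as.matrix(l$w), b = as.numeric(l$b)))
  params$fc <- lapply(params$fc, function(l) list(w = as.matrix(l$w), b = as.numeric(l$b)))
  class(params) <- "gcn_params"
  list(params = params, cfg = cfg)
}
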