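# Renormalized propagation, spectral oracle, forward/backward passes and the
# parameter budget.

test_that("graph Fourier transform round-trips and localizes energy", {
  set.seed(31)
  lap <- random_adjacency(6); diag(lap) <- -rowSums(lap); lap <- -lap # Laplacian
  phi <- stats::rnorm(6)
  g <- graph_fourier_transform(phi, lap)
  expect_equal(as.numeric(inverse_graph_fourier_transform(g$coef, lap)), phi,
               tolerance = 1e-8)
  # zero Laplacian: an orthonormal change of basis preserves the norm
  g0 <- graph_fourier_transform(phi, matrix(0, 6, 6))
  expect_equal(sum(g0$coef^2), sum(phi^2), tolerance = 1e-10)
  # 2-node path, phi = (1, -1): all energy on the eigenvalue-2 mode
  lap2 <- matrix(c(1, -1, -1, 1), 2)
  g2 <- graph_fourier_transform(c(1, -1), lap2)
  expect_equal(g2$values, c(0, 2))
  expect_equal(abs(as.numeric(g2$coef)), c(0, sqrt(2)), tolerance = 1e-12)
  expect_error(graph_fourier_transform(phi, matrix(1:36, 6)), "symmetric")
})

test_that("renormalized adjacency matches hand cases and spectral bounds", {
  expect_equal(normalize_adjacency(matrix(0, 3, 3)), diag(3))
  a2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(normalize_adjacency(a2), matrix(0.5, 2, 2))
  set.seed(32)
  for (i in 1:100) {
    ah <- normalize_adjacency(random_adjacency(sample(3:18, 1)))
    ev <- eigen(ah, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-9 & ev <= 1 + 1e-9))
  }
  # renormalization is not idempotent: re-normalizing changes the matrix
  a <- random_adjacency(8, seed = 33)
  once <- normalize_adjacency(a)
  expect_gt(max(abs(normalize_adjacency(once) - once)), 1e-3)
  expect_error(normalize_adjacency(matrix(c(0, -1, -1, 0), 2)), "non-negative")
  expect_error(normalize_adjacency(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("a single graph-conv layer reduces to its algebraic special cases", {
  h <- matrix(c(1, 3, 2, 4), 2)
  w <- matrix(c(2, 0, 0, 1), 2)
  # identity propagation: per-node linear map
  expect_equal(gcn_layer(h, diag(2), w, activation = identity), h %*% w)
  # identity weights: pure neighborhood smoothing
  ahat <- matrix(0.5, 2, 2)
  expect_equal(gcn_layer(h, ahat, diag(2), activation = identity), ahat %*% h)
  # hand case
  expect_equal(gcn_layer(matrix(c(1, 3), 2), ahat, matrix(2), activation = identity),
               matrix(c(4, 4), 2))
  expect_error(gcn_layer(h, ahat, matrix(1, 3, 2)), "shape mismatch")
  expect_error(gcn_layer(h, diag(3), w), "shape mismatch")
})

test_that("forward pass respects range, permutation symmetry and batch independence", {
  cfg <- model_config()
  params <- gcn_init(cfg, seed = 34)
  set.seed(35)
  graphs <- lapply(1:6, function(i) random_graph(i %% 2))
  p <- gcn_forward(graphs, params, cfg)$p
  expect_true(all(p > 0 & p < 1))
  # deterministic in evaluation mode
  expect_identical(p, gcn_forward(graphs, params, cfg)$p)
  # joint node permutation leaves the output unchanged
  perm <- sample(18)
  gp <- as_graph_sample(graphs[[1]]$x[perm, ], graphs[[1]]$a[perm, perm], graphs[[1]]$y)
  expect_equal(gcn_forward(list(gp), params, cfg)$p,
               gcn_forward(graphs[1], params, cfg)$p, tolerance = 1e-6)
  # duplicating the batch leaves per-sample outputs unchanged (frozen BN)
  p2 <- gcn_forward(c(graphs, graphs), params, cfg)$p
  expect_equal(p2[seq_along(graphs)], p, tolerance = 1e-6)
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- model_config(in_dim = 2, conv_widths = c(3, 4), fc_widths = 3,
                      out_dim = 1, n_nodes = 4, dropout_p = 0)
  params <- gcn_init(cfg, seed = 36)
  set.seed(37)
  graphs <- lapply(1:5, function(i) random_graph(i %% 2, n = 4, f = 2))
  y <- vapply(graphs, `[[`, numeric(1), "y")
  loss_of <- function(pp) {
    ghm_loss(gcn_forward(graphs, pp, cfg, training = TRUE)$p, y, momentum = 0)$loss
  }
  fwd <- gcn_forward(graphs, params, cfg, training = TRUE, keep_cache = TRUE)
  gl <- ghm_loss(fwd$p, y, momentum = 0)
  grads <- gcn_backward(gl$dz, fwd$cache, params, cfg)
  eps <- 1e-6
  for (part in c("conv", "fc")) {
    for (l in seq_along(params[[part]])) {
      for (nm in c("w", "b")) {
        for (idx in seq_len(min(4L, length(params[[part]][[l]][[nm]])))) {
          p_hi <- params; p_hi[[part]][[l]][[nm]][idx] <- p_hi[[part]][[l]][[nm]][idx] + eps
          p_lo <- params; p_lo[[part]][[l]][[nm]][idx] <- p_lo[[part]][[l]][[nm]][idx] - eps
          num <- (loss_of(p_hi) - loss_of(p_lo)) / (2 * eps)
          ana <- grads[[part]][[l]][[nm]][idx]
          # relative agreement; the floor absorbs coordinates whose true
          # gradient is exactly zero (conv biases cancel under batch norm)
          expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-4), 1e-4)
        }
      }
    }
  }
})

test_that("parameter count matches the closed form, enumeration and budget", {
  expect_identical(param_count(), 15425L)
  expect_identical(count_params(gcn_init()), 15425L)
  expect_lte(param_count(), 15520L) # the printed 15.52 k budget
  # closed form by independent arithmetic
  expect_identical(param_count(),
                   as.integer((9 * 32 + 32) + (32 * 64 + 64) + (64 * 128 + 128) +
                                (128 * 32 + 32) + (32 * 16 + 16) + (16 * 1 + 1)))
  # doubling every width roughly quadruples the count
  cfg2 <- model_config(in_dim = 18, conv_widths = c(64, 128, 256),
                       fc_widths = c(64, 32), out_dim = 1)
  expect_identical(param_count(cfg2),
                   as.integer((18 * 64 + 64) + (64 * 128 + 128) + (128 * 256 + 256) +
                                (256 * 64 + 64) + (64 * 32 + 32) + (32 * 1 + 1)))
  expect_gt(param_count(cfg2) / param_count(), 3.5)
  expect_lt(param_count(cfg2) / param_count(), 4.5)
  # affine batch norm adds 2 parameters per conv channel
  expect_identical(param_count(model_config(bn_affine = TRUE)) - param_count(),
                   2L * (32L + 64L + 128L))
  expect_identical(count_params(gcn_init(model_config(bn_affine = TRUE))),
                   param_count(model_config(bn_affine = TRUE)))
})

test_that("checkpoints round-trip through the JSON format", {
  cfg <- model_config(in_dim = 3, conv_widths = c(4, 5), fc_widths = 3, n_nodes = 5)
  params <- gcn_init(cfg, seed = 38)
  f <- withr::local_tempfile(fileext = ".json")
  save_gcn(params, cfg, f)
  back <- load_gcn(f)
  set.seed(39)
  g <- list(random_graph(1, n = 5, f = 3))
  expect_equal(gcn_forward(g, back$params, back$cfg)$p,
               gcn_forward(g, params, cfg)$p, tolerance = 1e-12)
})
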