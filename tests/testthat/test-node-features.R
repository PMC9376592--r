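# Per-channel node features against closed forms and brute-force oracles.

test_that("band energy localizes tones and conserves energy", {
  fs <- 256
  expect_equal(unname(band_energy(numeric(fs * 60), fs)), rep(0, 6))

  # a pure alpha tone concentrates in the alpha band (direct periodogram
  # oracle for the attainable share)
  x <- make_sine(10)
  be <- band_energy(x, fs)
  expect_length(be, 6L)
  expect_gte(be[["alpha_energy"]] / sum(be), 0.8)
  # periodogram oracle: the direct bandpass energy share upper-bounds what
  # the packet tree can attain (finite filters leak into adjacent bins)
  px <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  oracle <- sum(px[f >= 8 & f < 12 | f > fs - 12 & f <= fs - 8]) / sum(px)
  share <- be[["alpha_energy"]] / sum(be)
  expect_lte(share, oracle + 1e-9)
  expect_gte(share, 0.8 * oracle)

  set.seed(1)
  wn <- stats::rnorm(fs * 60)
  bw <- band_energy(wn, fs)
  expect_true(all(bw > 0))
  # orthogonal decomposition: band sum never exceeds total signal energy
  expect_lte(sum(bw), sum(wn^2) + 1e-8)
  # a 1-40 Hz band-limited signal keeps >= 90% of its energy in the six bands
  xf <- Mod(stats::fft(wn))
  spec <- stats::fft(wn)
  mask <- f >= 1 & f <= 40 | f >= fs - 40 & f <= fs - 1
  xb <- Re(stats::fft(spec * mask, inverse = TRUE)) / length(wn)
  expect_gte(sum(band_energy(xb, fs)), 0.9 * sum(xb^2))
})

test_that("hjorth parameters match the closed forms and the naive oracle", {
  expect_warning(h0 <- hjorth(rep(2, 100)), "zero-variance")
  expect_equal(unname(h0), c(0, 0, 0))
  hs <- hjorth(make_sine(10))
  expect_equal(hs[["hjorth_activity"]], 0.5, tolerance = 1e-2)
  expect_equal(hs[["hjorth_complexity"]], 1, tolerance = 1e-2)

  naive_hjorth <- function(x) { # independent direct-formula evaluation
    v <- function(z) sum((z - sum(z) / length(z))^2) / length(z)
    d1 <- x[-1] - x[-length(x)]
    d2 <- d1[-1] - d1[-length(d1)]
    mob <- sqrt(v(d1) / v(x))
    c(v(x), mob, sqrt(v(d2) / v(d1)) / mob)
  }
  set.seed(7)
  for (i in 1:20) {
    x <- stats::rnorm(100)
    expect_equal(unname(hjorth(x)), naive_hjorth(x), tolerance = 1e-9)
  }
})

test_that("higher-order crossings match direct counting", {
  x_alt <- rep(c(1, -1), 30)
  expect_equal(hoc(x_alt, k = 1)[[1]], length(x_alt) - 1L)
  expect_equal(hoc(seq_len(100), k = 1)[[1]], 1L) # centered ramp crosses once
  f0 <- 7
  expect_lte(abs(hoc(make_sine(f0, dur = 10), k = 1)[[1]] - 2 * f0 * 10), 2)

  naive_hoc <- function(x, k) { # brute-force loop oracle
    z <- x - mean(x)
    out <- integer(k)
    for (j in seq_len(k)) {
      s <- sign(z); s <- s[s != 0]
      out[j] <- sum(head(s, -1) * s[-1] < 0)
      z <- z[-1] - z[-length(z)]
    }
    out
  }
  set.seed(8)
  for (i in 1:20) {
    x <- stats::rnorm(100)
    expect_identical(unname(hoc(x, 10)), naive_hoc(x, 10))
  }
})

test_that("difference features follow direct arithmetic", {
  expect_equal(unname(diff_features(rep(3, 50))), c(0, 0))
  expect_equal(unname(diff_features(seq(0, 9.8, by = 0.2))), c(0.2, 0))
  expect_equal(unname(diff_features(c(0, 1, 0))), c(1, 2))
  naive <- function(x) c(mean(abs(diff(x))), mean(abs(diff(diff(x)))))
  set.seed(9)
  for (i in 1:10) {
    x <- stats::rnorm(100)
    expect_equal(unname(diff_features(x)), naive(x), tolerance = 1e-9)
  }
})

test_that("differential entropy has the Gaussian closed form", {
  set.seed(10)
  expect_equal(differential_entropy(stats::rnorm(2e5))[[1]],
               0.5 * log(2 * pi * exp(1)), tolerance = 0.05)
  x0 <- c(-1, 1) * sqrt(1 / (2 * pi * exp(1))) # biased variance exactly 1/(2*pi*e)
  expect_equal(differential_entropy(x0)[[1]], 0, tolerance = 1e-12)
  x <- stats::rnorm(1000)
  for (cc in c(0.1, 3, 42)) {
    expect_equal(differential_entropy(cc * x)[[1]] - differential_entropy(x)[[1]],
                 log(cc), tolerance = 1e-6)
  }
  expect_warning(de0 <- differential_entropy(rep(1, 10)), "zero variance")
  expect_equal(de0[[1]], -20)
})

test_that("fractal dimensions hit their known values", {
  line <- seq(0, 5, length.out = 2000)
  fd <- fractal_dimensions(line)
  expect_equal(fd[["fd_higuchi"]], 1, tolerance = 0.05)
  expect_identical(fd[["fd_katz"]], 1) # d/L degenerates exactly for a line
  expect_identical(fd[["fd_petrosian"]], 1) # no sign change in the derivative
  set.seed(11)
  expect_equal(fractal_dimensions(stats::rnorm(15360))[["fd_higuchi"]], 2,
               tolerance = 0.15)
  expect_warning(fdc <- fractal_dimensions(rep(1, 100)), "constant")
  expect_equal(unname(fdc), c(1, 1, 1))
})

test_that("node feature assembly has the declared dimensions", {
  set.seed(12)
  seg <- list(data = matrix(stats::rnorm(18 * 256 * 60), 18))
  m_default <- assemble_node_features(seg)
  expect_equal(dim(m_default), c(18L, 9L))
  expect_equal(colnames(m_default)[1:6], paste0(eeg_bands()$band, "_energy"))
  m_hjorth <- assemble_node_features(seg, feature_config("hjorth"))
  expect_equal(dim(m_hjorth), c(18L, 3L))
  all_feats <- c("band_energy", "hjorth", "hoc", "diff1", "diff2", "de", "fd")
  m_all <- assemble_node_features(seg, feature_config(all_feats, hoc_order = 10))
  expect_equal(ncol(m_all), 6L + 3L + 10L + 1L + 1L + 1L + 3L) # = 25
  expect_true(all(is.finite(m_all)))
})

test_that("magnitude features are invariant to time reversal", {
  set.seed(13)
  x <- stats::rnorm(256 * 60)
  xr <- rev(x)
  # band energies are reversal-invariant only up to the asymmetry of the db4
  # subband boundaries (reversal mirrors the filters' phase, not magnitude)
  expect_equal(band_energy(x), band_energy(xr), tolerance = 0.15)
  expect_equal(hjorth(x)[["hjorth_activity"]], hjorth(xr)[["hjorth_activity"]],
               tolerance = 1e-12)
  expect_equal(differential_entropy(x), differential_entropy(xr), tolerance = 1e-12)
})
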