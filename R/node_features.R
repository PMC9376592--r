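# Per-channel (graph node) features.
#
# Seven feature families are available; the default combination used by the
# classifier is band energy + Hjorth (F = 9 per node), selected for the best
# sensitivity among all pairings.

#' Node feature configuration
#'
#' @param enabled character subset of \code{band_energy}, \code{hjorth},
#'   \code{hoc}, \code{diff1}, \code{diff2}, \code{de}, \code{fd}.
#' @param hoc_order number of higher-order crossing counts.
#' @param higuchi_kmax maximum delay for the Higuchi curve-length regression.
#' @param wavelet wavelet name (only \code{"db4"} is implemented).
#' @param wpd_level wavelet packet decomposition depth.
#' @return a list of class \code{feature_config}.
#' @export
feature_config <- function(enabled = c("band_energy", "hjorth"), hoc_order = 10L,
                           higuchi_kmax = 8L, wavelet = "db4", wpd_level = 6L) {
  all_feats <- c("band_energy", "hjorth", "hoc", "diff1", "diff2", "de", "fd")
  enabled <- match.arg(enabled, all_feats, several.ok = TRUE)
  if (!length(enabled)) stopf("at least one node feature must be enabled")
  if (wavelet != "db4") stopf("only the db4 wavelet is implemented")
  stopifnot(hoc_order >= 1, higuchi_kmax >= 2, wpd_level >= 1)
  structure(list(enabled = enabled, hoc_order = as.integer(hoc_order),
                 higuchi_kmax = as.integer(higuchi_kmax), wavelet = wavelet,
                 wpd_level = as.integer(wpd_level)),
            class = "feature_config")
}

#' Band energies by wavelet packet decomposition
#'
#' Energy of the six canonical EEG bands (see \code{\link{eeg_bands}}),
#' computed as the sum of squared terminal-node coefficients of a level-6 db4
#' wavelet packet decomposition, with terminal bins assigned to bands by
#' their nominal midpoint frequency.
#'
#' @param x single-channel segment.
#' @param fs sampling rate, Hz.
#' @param cfg a \code{\link{feature_config}}.
#' @return named 6-vector of non-negative band energies.
#' @export
band_energy <- function(x, fs = 256, cfg = feature_config()) {
  wp <- wpd_terminal_nodes(x, fs, cfg$wpd_level)
  idx <- band_of_bins(wp$f_lo, wp$f_hi)
  e_node <- vapply(wp$coefs, function(v) sum(v^2), numeric(1))
  out <- numeric(6)
  for (b in 1:6) out[b] <- sum(e_node[which(idx == b)])
  names(out) <- paste0(eeg_bands()$band, "_energy")
  out
}

# All channels at once (channels x samples input), compiled packet tree;
# returns a channels x 6 energy matrix.
band_energy_all <- function(dat, fs = 256, cfg = feature_config()) {
  n <- ncol(dat)
  if (n < 2^cfg$wpd_level || n %% 2^cfg$wpd_level != 0) {
    stopf("signal length %d is not divisible by 2^%d", n, cfg$wpd_level)
  }
  bins <- wpd_bins(fs, cfg$wpd_level)
  idx <- band_of_bins(bins$f_lo, bins$f_hi)
  e_node <- cpp_wpd_energy(t(dat), .db4_dec_lo, .db4_dec_hi, cfg$wpd_level)
  out <- matrix(0, nrow(dat), 6L)
  for (b in 1:6) out[, b] <- colSums(e_node[which(idx == b), , drop = FALSE])
  colnames(out) <- paste0(eeg_bands()$band, "_energy")
  out
}

#' Hjorth parameters
#'
#' Activity is the biased variance of the signal; mobility the ratio of the
#' first difference's standard deviation to the signal's; complexity the
#' mobility of the first difference divided by the mobility of the signal
#' (derivatives realized as first sample differences). A constant signal has
#' activity 0 and, by convention, mobility and complexity 0 (flagged).
#'
#' @param x single-channel segment (length >= 3).
#' @return named 3-vector (activity, mobility, complexity).
#' @export
hjorth <- function(x) {
  if (length(x) < 3L) stopf("hjorth needs at least 3 samples")
  v0 <- biased_var(x)
  if (v0 == 0) {
    warnf("hjorth: zero-variance signal; mobility/complexity set to 0")
    return(c(hjorth_activity = 0, hjorth_mobility = 0, hjorth_complexity = 0))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- biased_var(d1)
  v2 <- biased_var(d2)
  mob <- sqrt(v1 / v0)
  mob_d <- if (v1 == 0) 0 else sqrt(v2 / v1)
  c(hjorth_activity = v0, hjorth_mobility = mob,
    hjorth_complexity = if (mob == 0) 0 else mob_d / mob)
}

#' Higher-order crossings
#'
#' Zero-crossing counts of the successively differenced, mean-removed signal:
#' entry j is the number of sign changes of the (j-1)-times differenced
#' sequence, j = 1..k.
#'
#' @param x single-channel segment.
#' @param k number of crossing counts (difference orders 0..k-1).
#' @return integer k-vector.
#' @export
hoc <- function(x, k = 10L) {
  if (length(x) <= k) stopf("hoc needs more than k samples")
  z <- x - mean(x)
  out <- integer(k)
  for (j in seq_len(k)) {
    out[j] <- count_sign_changes(z)
    z <- diff(z)
  }
  names(out) <- paste0("hoc_", seq_len(k))
  out
}

#' First- and second-difference magnitudes
#'
#' Mean absolute first difference and mean absolute second difference of the
#' segment.
#'
#' @param x single-channel segment (length >= 3).
#' @return named 2-vector (diff1, diff2), both non-negative.
#' @export
diff_features <- function(x) {
  if (length(x) < 3L) stopf("diff_features needs at least 3 samples")
  d1 <- diff(x)
  c(diff1 = mean(abs(d1)), diff2 = mean(abs(diff(d1))))
}

#' Differential entropy (Gaussian closed form)
#'
#' \code{0.5 * log(2 * pi * e * var(x))} in nats, with the biased sample
#' variance; this is the standard EEG usage of continuous entropy and may be
#' negative. A zero-variance signal is capped at -20 (flagged) rather than
#' returning -Inf.
#'
#' @param x single-channel segment (length >= 2).
#' @return scalar entropy in nats.
#' @export
differential_entropy <- function(x) {
  if (length(x) < 2L) stopf("differential_entropy needs at least 2 samples")
  v <- biased_var(x)
  if (v <= 0) {
    warnf("differential_entropy: zero variance; capped at -20")
    return(c(de = -20))
  }
  c(de = 0.5 * log(2 * pi * exp(1) * v))
}

# -- fractal dimensions -------------------------------------------------------

higuchi_fd <- function(x, kmax = 8L) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      nm <- length(idx) - 1L
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }
    lk[k] <- mean(lm)
  }
  if (any(lk <= 0)) return(1)
  stats::coef(stats::lm(log(lk) ~ log(seq_len(kmax))))[[2L]] * -1
}

katz_fd <- function(x) {
  d1 <- abs(diff(x))
  L <- sum(d1)
  if (L == 0) return(1)
  d <- max(abs(x - x[1L]))
  n <- length(x) - 1L
  if (d == 0) return(1)
  log10(n) / (log10(n) + log10(d / L))
}

petrosian_fd <- function(x) {
  n <- length(x)
  ndelta <- count_sign_changes(diff(x))
  log10(n) / (log10(n) + log10(n / (n + 0.4 * ndelta)))
}

#' Fractal dimensions (Higuchi, Katz, Petrosian)
#'
#' Higuchi via the curve-length regression over delays 1..kmax; Katz from the
#' waveform's diameter-to-length ratio; Petrosian from the sign changes of the
#' first difference. Each estimator returns 1 for a degenerate (constant)
#' signal, flagged with a warning.
#'
#' @param x single-channel segment.
#' @param cfg a \code{\link{feature_config}} (supplies \code{higuchi_kmax}).
#' @return named 3-vector (higuchi, katz, petrosian).
#' @export
fractal_dimensions <- function(x, cfg = feature_config()) {
  if (length(x) < 2L * cfg$higuchi_kmax) stopf("segment too short for Higuchi kmax = %d", cfg$higuchi_kmax)
  if (biased_var(x) == 0) {
    warnf("fractal_dimensions: constant signal; returning (1, 1, 1)")
    return(c(fd_higuchi = 1, fd_katz = 1, fd_petrosian = 1))
  }
  c(fd_higuchi = higuchi_fd(x, cfg$higuchi_kmax),
    fd_katz = katz_fd(x),
    fd_petrosian = petrosian_fd(x))
}

# -- assembly -----------------------------------------------------------------

feature_dims <- function(cfg) {
  c(band_energy = 6L, hjorth = 3L, hoc = cfg$hoc_order, diff1 = 1L,
    diff2 = 1L, de = 1L, fd = 3L)
}

# `be_row`: precomputed band-energy row for this channel (the packet tree is
# run for all channels at once); NULL when band_energy is disabled.
channel_features <- function(x, fs, cfg, be_row = NULL) {
  out <- list()
  for (f in cfg$enabled) {
    out[[f]] <- switch(f,
      band_energy = be_row %||% band_energy(x, fs, cfg),
      hjorth = hjorth(x),
      hoc = hoc(x, cfg$hoc_order),
      diff1 = diff_features(x)["diff1"],
      diff2 = diff_features(x)["diff2"],
      de = differential_entropy(x),
      fd = fractal_dimensions(x, cfg))
  }
  unlist(out, use.names = TRUE)
}

#' Assemble the node-feature matrix of a segment
#'
#' Row i holds the concatenated enabled features of channel i, in the fixed
#' declared order of \code{feature_config}'s \code{enabled} vector.
#'
#' @param segment a labeled segment (list with \code{data}) or a plain
#'   channels x samples matrix.
#' @param cfg a \code{\link{feature_config}}.
#' @param fs sampling rate, Hz.
#' @return an n_channels x F numeric matrix with feature names as colnames.
#' @export
assemble_node_features <- function(segment, cfg = feature_config(), fs = 256) {
  dat <- if (is.list(segment)) segment$data else segment
  dat <- as.matrix(dat)
  be <- if ("band_energy" %in% cfg$enabled) band_energy_all(dat, fs, cfg) else NULL
  rows <- lapply(seq_len(nrow(dat)), function(i) {
    be_row <- if (is.null(be)) NULL else structure(be[i, ], names = colnames(be))
    channel_features(dat[i, ], fs, cfg, be_row)
  })
  m <- do.call(rbind, rows)
  expect_f <- sum(feature_dims(cfg)[cfg$enabled])
  if (ncol(m) != expect_f) stopf("feature dimension mismatch: got %d, expected %d", ncol(m), expect_f)
  if (!all(is.finite(m))) stopf("non-finite node feature value")
  colnames(m) <- sub("^[^.]*\\.", "", colnames(m))
  m
}
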