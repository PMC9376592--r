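# Edge features: scalp geometry and spectral coherence, fused into the
# per-segment adjacency matrix.

#' Geodesic (great-circle) distance between two points on a sphere
#'
#' \code{acos(p_i . p_j / r^2)}, in radians; the dot product is clipped to
#' [-1, 1] before the arccosine to absorb rounding.
#'
#' @param p_i,p_j numeric 3-vectors on the sphere of radius \code{r}.
#' @param r sphere radius.
#' @return angle in [0, pi].
#' @export
geodesic_distance <- function(p_i, p_j, r = 1) {
  ni <- sqrt(sum(p_i^2)) / r
  nj <- sqrt(sum(p_j^2)) / r
  if (abs(ni - 1) > 1e-6 || abs(nj - 1) > 1e-6) {
    stopf("point is not on the sphere of radius %g", r)
  }
  acos(max(-1, min(1, sum(p_i * p_j) / r^2)))
}

#' Pairwise geodesic distance matrix of montage nodes
#'
#' @param pos n x 3 matrix of unit vectors (see
#'   \code{\link{montage_positions}}).
#' @return symmetric n x n matrix of angles (radians), zero diagonal.
#' @export
geodesic_matrix <- function(pos = montage_positions()) {
  g <- tcrossprod(pos)
  g[g > 1] <- 1
  g[g < -1] <- -1
  g <- acos(g)
  diag(g) <- 0
  dimnames(g) <- list(rownames(pos), rownames(pos))
  g
}

# -- spectral coherence -------------------------------------------------------

# Hann-windowed, 50%-overlap segment FFTs of every channel of `dat`
# (channels x samples). Returns a 3-d complex array [freq bin, window,
# channel]; frequency bin k covers (k-1) * fs / nfft Hz.
welch_fft <- function(dat, nfft = 256L) {
  n <- ncol(dat)
  if (n < 2L * nfft) stopf("need at least two spectral windows (%d samples)", 2L * nfft)
  step <- nfft %/% 2L
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nfft - 1L) / nfft)
  nb <- nfft %/% 2L + 1L
  idx <- outer(seq_len(nfft) - 1L, starts, `+`) # nfft x nwin sample indices
  out <- array(0i, dim = c(nb, length(starts), nrow(dat)))
  for (ch in seq_len(nrow(dat))) {
    seg <- matrix(dat[ch, ][idx], nfft) * w
    out[, , ch] <- stats::mvfft(seg)[seq_len(nb), , drop = FALSE]
  }
  out
}

#' Magnitude-squared spectral coherence of two channels
#'
#' Welch estimate (256-sample Hann windows, 50% overlap):
#' \code{|<Sxy>|^2 / (<Sxx> <Syy>)} per frequency, averaged over the
#' requested band. Symmetric in its arguments and invariant to rescaling
#' either channel. A zero-power channel yields 0 with a warning.
#'
#' @param x_i,x_j equal-length numeric signals.
#' @param fs sampling rate, Hz.
#' @param band two-element frequency band (Hz) to average over.
#' @param nfft spectral window length.
#' @return scalar coherence in [0, 1].
#' @export
spectral_coherence <- function(x_i, x_j, fs = 256, band = c(1, 40), nfft = 256L) {
  stopifnot(length(x_i) == length(x_j))
  co <- coherence_matrix(rbind(x_i, x_j), fs = fs, band = band, nfft = nfft)
  co[1L, 2L]
}

#' Band-averaged coherence matrix of a multi-channel segment
#'
#' @param dat channels x samples matrix.
#' @inheritParams spectral_coherence
#' @return symmetric matrix with unit diagonal, entries in [0, 1].
#' @export
coherence_matrix <- function(dat, fs = 256, band = c(1, 40), nfft = 256L) {
  dat <- as.matrix(dat)
  nch <- nrow(dat)
  fx <- welch_fft(dat, nfft)
  freqs <- (seq_len(dim(fx)[1L]) - 1L) * fs / nfft
  sel <- which(freqs >= band[1L] & freqs <= band[2L])
  if (!length(sel)) stopf("no frequency bins inside the band [%g, %g] Hz", band[1], band[2])
  pxx <- matrix(0, length(sel), nch)
  for (ch in seq_len(nch)) pxx[, ch] <- rowMeans(Mod(fx[sel, , ch, drop = FALSE])^2)
  dead <- which(apply(pxx, 2L, max) <= 0)
  if (length(dead)) warnf("zero-power channel(s): coherence set to 0 for %s",
                          paste(dead, collapse = ", "))
  co <- diag(1, nch)
  for (i in seq_len(nch - 1L)) {
    for (j in (i + 1L):nch) {
      if (i %in% dead || j %in% dead) { co[i, j] <- co[j, i] <- 0; next }
      sxy <- rowMeans(fx[sel, , i, drop = FALSE] * Conj(fx[sel, , j, drop = FALSE]))
      cxy <- Mod(sxy)^2 / (pxx[, i] * pxx[, j])
      co[i, j] <- co[j, i] <- mean(cxy)
    }
  }
  dimnames(co) <- list(rownames(dat), rownames(dat))
  co
}

# -- adjacency ----------------------------------------------------------------

#' Fuse spatial and functional edge features into an adjacency matrix
#'
#' \code{A = w_spatial * exp(-dist^2 / sigma^2) + w_func * coh}, diagonal
#' forced to zero. With the default equal weights and sigma set to the mean
#' off-diagonal geodesic distance, entries lie in [0, 1]. The spatial part
#' depends only on the montage and is typically cached across segments.
#'
#' @param dist symmetric geodesic-angle matrix (radians).
#' @param coh symmetric coherence matrix.
#' @param w_spatial,w_func non-negative weights summing to 1.
#' @param sigma spatial kernel width (radians); defaults to the mean
#'   off-diagonal geodesic distance.
#' @return symmetric adjacency matrix with zero diagonal, entries in [0, 1].
#' @export
build_adjacency <- function(dist, coh, w_spatial = 0.5, w_func = 0.5, sigma = NULL) {
  stopifnot(nrow(dist) == nrow(coh), w_spatial >= 0, w_func >= 0)
  if (abs(w_spatial + w_func - 1) > 1e-9) stopf("w_spatial + w_func must equal 1")
  if (is.null(sigma)) sigma <- mean(dist[upper.tri(dist)])
  if (!is_scalar_num(sigma) || sigma <= 0) stopf("sigma must be positive")
  a <- w_spatial * exp(-dist^2 / sigma^2) + w_func * coh
  diag(a) <- 0
  (a + t(a)) / 2
}

#' Chord-diagram edge list from a coherence matrix
#'
#' Upper-triangle entries at or above the threshold, sorted by decreasing
#' weight; suitable for circular connectivity plots where line width encodes
#' coherence strength.
#'
#' @param coh symmetric coherence matrix with named dimensions.
#' @param threshold minimum weight to keep.
#' @return data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
#' Draw a chord diagram of functional connectivity
#'
#' Circular plot with the montage names on the circumference and one line
#' per retained edge, line width proportional to coherence strength. Useful
#' for eyeballing which derivations share synchronous activity (e.g. around
#' a suspected focus).
#'
#' @param coh symmetric coherence matrix with named dimensions.
#' @param threshold minimum coherence to draw.
#' @param file optional path; when given, the plot is written as a PNG.
#' @return the plotted edge list (as \code{\link{chord_data}}), invisibly.
#' @export
plot_chord <- function(coh, threshold = 0.5, file = NULL) {
  edges <- chord_data(coh, threshold)
  nms <- rownames(coh) %||% paste0("node", seq_len(nrow(coh)))
  ang <- seq(0, 2 * pi, length.out = nrow(coh) + 1L)[-1L]
  px <- cos(ang); py <- sin(ang)
  if (!is.null(file)) grDevices::png(file, width = 900, height = 900)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() }, add = TRUE)
  plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), axes = FALSE,
       xlab = "", ylab = "", asp = 1,
       main = sprintf("spectral coherence >= %.2f", threshold))
  if (nrow(edges)) {
    i <- match(edges$from, nms); j <- match(edges$to, nms)
    graphics::segments(px[i], py[i], px[j], py[j],
                       lwd = 0.5 + 6 * edges$weight,
                       col = grDevices::adjustcolor("steelblue", 0.6))
  }
  graphics::points(px, py, pch = 19)
  graphics::text(1.15 * px, 1.15 * py, nms, cex = 0.7,
                 srt = 0, xpd = NA)
  invisible(edges)
}

chord_data <- function(coh, threshold = 0.5) {
  stopifnot(isSymmetric(unname(coh)))
  nms <- rownames(coh) %||% paste0("node", seq_len(nrow(coh)))
  ut <- which(upper.tri(coh), arr.ind = TRUE)
  w <- coh[ut]
  keep <- w >= threshold
  out <- data.frame(from = nms[ut[keep, 1L]], to = nms[ut[keep, 2L]],
                    weight = w[keep], stringsAsFactors = FALSE)
  out[order(-out$weight), , drop = FALSE]
}
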