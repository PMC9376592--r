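# Wavelet packet decomposition (Daubechies db4, periodic extension).
#
# Implemented in-package: the terminal-node energies are the spectral node
# feature, and the frequency ordering of packet nodes (children of a
# high-pass branch swap their low/high halves because of aliasing under
# decimation) has to be tracked explicitly to map nodes onto EEG bands.

# db4 decomposition low-pass filter (8 taps); the high-pass is its QMF mirror.
.db4_dec_lo <- c(-0.010597401784997278, 0.032883011666982945,
                 0.030841381835986965, -0.187034811718881140,
                 -0.027983769416983850, 0.630880767929590400,
                 0.714846570552541500, 0.230377813308855230)
.db4_dec_hi <- rev(.db4_dec_lo) * (-1)^(seq_along(.db4_dec_lo) - 1L)

# Circular correlation with `f` followed by dyadic downsampling. With an
# orthonormal QMF pair this analysis step conserves energy exactly. `x` may
# be a vector or a samples x channels matrix (all channels at once).
conv_down <- function(x, f) {
  L <- length(f)
  if (is.matrix(x)) {
    n <- nrow(x)
    xe <- rbind(x, x[seq_len(L - 1L), , drop = FALSE])
    z <- matrix(0, n, ncol(x))
    for (m in seq_len(L)) z <- z + f[m] * xe[m:(m + n - 1L), , drop = FALSE]
    z[seq(1L, n, by = 2L), , drop = FALSE]
  } else {
    n <- length(x)
    xe <- c(x, x[seq_len(L - 1L)])
    z <- numeric(n)
    for (m in seq_len(L)) z <- z + f[m] * xe[m:(m + n - 1L)]
    z[seq(1L, n, by = 2L)]
  }
}

#' Wavelet packet terminal nodes with frequency ordering
#'
#' Full wavelet packet decomposition of \code{x} to the given level with db4
#' filters and periodic extension. Returns the \code{2^level} terminal
#' coefficient vectors together with the nominal frequency interval each node
#' covers, already corrected for the low/high swap that decimation induces in
#' high-pass branches.
#'
#' @param x numeric signal; length must be divisible by \code{2^level}.
#' @param fs sampling rate, Hz.
#' @param level decomposition depth.
#' @return list with \code{coefs} (list of numeric vectors, or matrices when
#'   \code{x} is a samples x channels matrix; frequency order is given by
#'   \code{f_lo}), \code{f_lo}, \code{f_hi} (numeric vectors, Hz).
#' @export
wpd_terminal_nodes <- function(x, fs, level = 6L) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n < 2^level || n %% 2^level != 0) {
    stopf("signal length %d is not divisible by 2^%d", n, level)
  }
  nodes <- list(list(v = x, lo = 0, hi = fs / 2, rev = FALSE))
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (j in seq_along(nodes)) {
      nd <- nodes[[j]]
      mid <- (nd$lo + nd$hi) / 2
      a <- conv_down(nd$v, .db4_dec_lo)
      d <- conv_down(nd$v, .db4_dec_hi)
      if (!nd$rev) {
        nxt[[2L * j - 1L]] <- list(v = a, lo = nd$lo, hi = mid, rev = FALSE)
        nxt[[2L * j]] <- list(v = d, lo = mid, hi = nd$hi, rev = TRUE)
      } else {
        # spectrum inside a high-pass branch is mirrored after decimation
        nxt[[2L * j - 1L]] <- list(v = a, lo = mid, hi = nd$hi, rev = TRUE)
        nxt[[2L * j]] <- list(v = d, lo = nd$lo, hi = mid, rev = FALSE)
      }
    }
    nodes <- nxt
  }
  list(coefs = lapply(nodes, `[[`, "v"),
       f_lo = vapply(nodes, `[[`, numeric(1), "lo"),
       f_hi = vapply(nodes, `[[`, numeric(1), "hi"))
}

# Nominal frequency intervals of the terminal nodes in natural (tree) order,
# including the high-pass mirroring; data-independent companion of
# wpd_terminal_nodes / cpp_wpd_energy.
wpd_bins <- function(fs, level) {
  nodes <- list(list(lo = 0, hi = fs / 2, rev = FALSE))
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (j in seq_along(nodes)) {
      nd <- nodes[[j]]
      mid <- (nd$lo + nd$hi) / 2
      if (!nd$rev) {
        nxt[[2L * j - 1L]] <- list(lo = nd$lo, hi = mid, rev = FALSE)
        nxt[[2L * j]] <- list(lo = mid, hi = nd$hi, rev = TRUE)
      } else {
        nxt[[2L * j - 1L]] <- list(lo = mid, hi = nd$hi, rev = TRUE)
        nxt[[2L * j]] <- list(lo = nd$lo, hi = mid, rev = FALSE)
      }
    }
    nodes <- nxt
  }
  list(f_lo = vapply(nodes, `[[`, numeric(1), "lo"),
       f_hi = vapply(nodes, `[[`, numeric(1), "hi"))
}

#' The six EEG band definitions
#'
#' Delta 1-4, theta 4-7.5, alpha 7.5-13, lower beta 13-16, higher beta 16-30,
#' gamma 30-40 Hz.
#' @return data.frame with columns \code{band}, \code{f_lo}, \code{f_hi}.
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta_low", "beta_high", "gamma"),
             f_lo = c(1, 4, 7.5, 13, 16, 30),
             f_hi = c(4, 7.5, 13, 16, 30, 40))
}

# Assignment of terminal bins to bands by bin midpoint (bands treated as
# half-open [lo, hi); with 2 Hz bins at fs = 256 / level 6 this realizes
# delta 0-4, theta 4-8, alpha 8-12, lower beta 12-16, higher beta 16-30,
# gamma 30-40: the 7.5 and 13 Hz boundaries snap to the nearest bin edge.
band_of_bins <- function(f_lo, f_hi) {
  bands <- eeg_bands()
  mid <- (f_lo + f_hi) / 2
  idx <- rep(NA_integer_, length(mid))
  for (b in seq_len(nrow(bands))) {
    sel <- mid >= bands$f_lo[b] & mid < bands$f_hi[b]
    idx[sel] <- b
  }
  # the delta band opens at 1 Hz: the 0-2 Hz bin's midpoint (1 Hz) is on the
  # boundary and belongs to delta by the half-open rule above
  idx
}
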