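# Filtering, normalization and preictal/interictal labeling.
#
# The labeling rules follow the seizure-prediction convention: the hour
# ending 5 minutes before each annotated onset is preictal (the 5 min gap is
# the prediction horizon); interictal windows must lie at least 4 hours from
# every seizure; everything else (ictal, post-ictal, buffer zones) is
# excluded.

#' Preprocessing configuration
#'
#' @param hp_cutoff_hz high-pass cutoff (Hz).
#' @param notch_hz mains frequencies to notch out (Hz).
#' @param norm_range two-element target range of min-max normalization.
#' @param segment_s window length in seconds.
#' @param preictal_len_s length of the preictal period before the horizon.
#' @param horizon_s prediction horizon: gap between the end of the preictal
#'   window and the annotated onset.
#' @param interictal_margin_s minimum distance of interictal windows from any
#'   seizure.
#' @return a list of class \code{preprocess_config}.
#' @export
preprocess_config <- function(hp_cutoff_hz = 1, notch_hz = c(50, 100),
                              norm_range = c(0, 1), segment_s = 60,
                              preictal_len_s = 3600, horizon_s = 300,
                              interictal_margin_s = 14400) {
  stopifnot(hp_cutoff_hz > 0, segment_s > 0, preictal_len_s > 0,
            horizon_s >= 0, interictal_margin_s > 0,
            length(norm_range) == 2L, norm_range[1] < norm_range[2])
  structure(list(hp_cutoff_hz = hp_cutoff_hz, notch_hz = notch_hz,
                 norm_range = norm_range, segment_s = segment_s,
                 preictal_len_s = preictal_len_s, horizon_s = horizon_s,
                 interictal_margin_s = interictal_margin_s),
            class = "preprocess_config")
}

# -- IIR filter design --------------------------------------------------------

# Coefficients of the polynomial with the given (complex) roots, leading
# coefficient 1, returned highest order first.
poly_from_roots <- function(roots) {
  p <- 1
  for (r in roots) p <- c(p, 0) - c(0, r * p)
  p
}

#' Butterworth high-pass design (bilinear transform)
#'
#' @param cutoff_hz cutoff frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param order filter order (default 4).
#' @return list with numerator \code{b} and denominator \code{a} coefficients.
#' @export
butter_highpass <- function(cutoff_hz, fs, order = 4L) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2, order >= 1)
  k <- seq_len(order)
  # analog low-pass prototype poles on the unit circle, left half-plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  wc <- 2 * fs * tan(pi * cutoff_hz / fs) # prewarped analog cutoff
  p_hp <- wc / p                          # low-pass -> high-pass: s -> wc/s
  z_p <- (2 * fs + p_hp) / (2 * fs - p_hp)
  a <- Re(poly_from_roots(z_p))
  b0 <- poly_from_roots(rep(1, order))    # zeros at z = 1 (block DC)
  # unit gain at Nyquist (z = -1)
  sgn <- (-1)^(0:order)
  gain <- sum(a * sgn) / sum(b0 * sgn)
  list(b = b0 * gain, a = a)
}

#' Second-order IIR notch design
#'
#' Standard biquad notch with the given quality factor.
#' @param freq_hz notch frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param q quality factor (default 30).
#' @return list with \code{b} and \code{a} coefficients.
#' @export
iir_notch <- function(freq_hz, fs, q = 30) {
  stopifnot(freq_hz > 0, freq_hz < fs / 2)
  w0 <- 2 * pi * freq_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Single-pass IIR filtering (direct form, compiled), zero initial conditions.
iir_filter <- function(b, a, x) {
  cpp_iir(as.numeric(b), as.numeric(a), as.numeric(x))
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward and then backward, with odd-symmetric edge
#' padding to suppress startup transients; the result has zero phase and the
#' squared magnitude response of the one-pass filter.
#'
#' @param b,a filter coefficients.
#' @param x numeric signal.
#' @return filtered signal, same length as \code{x}.
#' @export
filtfilt <- function(b, a, x) {
  npad <- 3L * (max(length(a), length(b)) - 1L) * 4L
  cpp_filtfilt(as.numeric(b), as.numeric(a), as.numeric(x), npad)
}

#' High-pass and notch filter a recording
#'
#' A zero-phase 4th-order Butterworth high-pass removes drift and DC, then
#' zero-phase biquad notches (Q = 30) attenuate each mains frequency. Notch
#' frequencies at or above Nyquist are skipped with a warning.
#'
#' @param rec a \code{\link{recording}}.
#' @param cfg a \code{\link{preprocess_config}}.
#' @return the filtered recording.
#' @export
filter_signal <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "recording"))
  if (!all(is.finite(rec$data))) stopf("recording contains non-finite samples")
  hp <- butter_highpass(cfg$hp_cutoff_hz, rec$fs)
  notches <- list()
  for (f0 in cfg$notch_hz) {
    if (f0 >= rec$fs / 2) {
      warnf("skipping infeasible notch at %g Hz (fs = %g Hz)", f0, rec$fs)
    } else {
      notches[[length(notches) + 1L]] <- iir_notch(f0, rec$fs)
    }
  }
  td <- t(rec$data) # contiguous per-channel columns for the filter passes
  for (i in seq_len(ncol(td))) {
    y <- filtfilt(hp$b, hp$a, td[, i])
    for (nf in notches) y <- filtfilt(nf$b, nf$a, y)
    td[, i] <- y
  }
  rec$data <- t(td)
  rec
}

#' Min-max normalize a recording
#'
#' Affine per-channel map over the whole recording: the channel minimum maps
#' to \code{range[1]} and the maximum to \code{range[2]}. Constant channels
#' cannot be rescaled; they are set to all zeros and flagged with a warning.
#'
#' @param rec a \code{\link{recording}}.
#' @param range two-element numeric target range (default \code{c(0, 1)}).
#' @return the normalized recording.
#' @export
minmax_normalize <- function(rec, range = c(0, 1)) {
  stopifnot(inherits(rec, "recording"), length(range) == 2L, range[1] < range[2])
  if (ncol(rec$data) < 2L) stopf("need at least 2 samples per channel")
  rr <- cpp_row_range(rec$data)
  lo <- rr[1L, ]
  hi <- rr[2L, ]
  flat <- hi - lo < .Machine$double.eps
  if (any(flat)) {
    warnf("constant channel(s) normalized to all zeros: %s",
          paste(rec$channel_labels[flat], collapse = ", "))
  }
  span <- ifelse(flat, 1, hi - lo)
  # per-channel affine map; length-n_channels vectors recycle down columns
  scale <- (range[2] - range[1]) / span
  rec$data <- (rec$data - lo) * scale + range[1]
  rec$data[flat, ] <- 0
  rec
}

# -- labeling and segmentation ------------------------------------------------

# Gap (s) from the half-open window [t0, t1) to the closed interval [on, off].
interval_gap <- function(t0, t1, on, off) {
  pmax(0, pmax(on - t1, t0 - off))
}

#' Label and segment a recording into 60 s preictal/interictal windows
#'
#' Preictal windows tile, without overlap, the span from
#' \code{onset - horizon - preictal_len} to \code{onset - horizon} of each
#' seizure; interictal windows are those lying at least
#' \code{interictal_margin_s} from every seizure. Windows straddling a span
#' boundary (or truncated by the recording edge) are dropped. Each preictal
#' segment carries the integer id of its seizure (\code{seizure_group});
#' interictal segments carry the id of the temporally nearest seizure so that
#' leave-one-seizure-out folds can pair them with a held-out seizure.
#'
#' @param rec a \code{\link{recording}} (typically montaged, filtered and
#'   normalized).
#' @param cfg a \code{\link{preprocess_config}}.
#' @param subject_events optional data.frame of all of the subject's seizures
#'   on the absolute timeline (\code{onset_s}, \code{offset_s}, optional
#'   \code{group}); defaults to this recording's own events shifted by
#'   \code{rec$start_s}. Supply it when the subject spans several files.
#' @return list of labeled segments; each is a list with elements \code{data}
#'   (channels x samples), \code{label} (1 preictal, 0 interictal),
#'   \code{subject_id}, \code{seizure_group}, \code{t_start} (absolute s).
#' @export
label_and_segment <- function(rec, cfg = preprocess_config(), subject_events = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(subject_events)) {
    subject_events <- rec$events
    if (nrow(subject_events)) {
      subject_events$onset_s <- subject_events$onset_s + rec$start_s
      subject_events$offset_s <- subject_events$offset_s + rec$start_s
    }
  }
  ev <- subject_events[order(subject_events$onset_s), , drop = FALSE]
  if (is.null(ev$group)) ev$group <- seq_len(nrow(ev))
  seg_len <- cfg$segment_s
  nsamp <- round(seg_len * rec$fs)
  rec_start <- rec$start_s
  rec_end <- rec$start_s + recording_duration(rec)

  segments <- list()
  grab <- function(t_abs, label, group) {
    i0 <- round((t_abs - rec_start) * rec$fs) + 1L
    list(data = rec$data[, i0:(i0 + nsamp - 1L), drop = FALSE],
         label = label, subject_id = rec$subject_id,
         seizure_group = group, t_start = t_abs)
  }

  # preictal: tile each span [onset - horizon - len, onset - horizon) from its
  # left edge. The whole span must fit inside this recording: a span truncated
  # by the recording edge (e.g. a seizure too close to the start of the data)
  # is dropped in full, so every seizure contributes either its complete hour
  # or nothing. Spans entirely outside this recording belong to another file.
  n_truncated <- 0L
  for (k in seq_len(nrow(ev))) {
    span0 <- ev$onset_s[k] - cfg$horizon_s - cfg$preictal_len_s
    span1 <- ev$onset_s[k] - cfg$horizon_s
    if (span0 >= rec_start && span1 <= rec_end) {
      starts <- seq(span0, span1 - seg_len, by = seg_len)
      if (span1 - span0 < seg_len) starts <- numeric()
      for (t0 in starts) {
        segments[[length(segments) + 1L]] <- grab(t0, 1L, ev$group[k])
      }
    } else if (span1 > rec_start && span0 < rec_end) {
      n_truncated <- n_truncated + 1L
    }
  }
  if (n_truncated > 0L) {
    message(sprintf("%d preictal span(s) truncated by recording boundaries were dropped", n_truncated))
  }

  # interictal: tile the recording; a window qualifies if its distance to
  # every seizure is at least the margin (and it overlaps no preictal span)
  all_starts <- seq(rec_start, rec_end - seg_len, by = seg_len)
  if (rec_end - rec_start < seg_len) all_starts <- numeric()
  for (t0 in all_starts) {
    t1 <- t0 + seg_len
    if (nrow(ev)) {
      gaps <- interval_gap(t0, t1, ev$onset_s, ev$offset_s)
      if (any(gaps < cfg$interictal_margin_s)) next
      group <- ev$group[which.min(gaps)]
    } else {
      group <- NA_integer_
    }
    segments[[length(segments) + 1L]] <- grab(t0, 0L, group)
  }
  segments
}
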