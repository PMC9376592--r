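# Synthetic scalp-EEG cohort generator.
#
# The generator emulates the statistical structure the pipeline consumes —
# 1/f background with a rhythmic alpha component, weak inter-channel coupling
# through a shared source, and a controllable preictal signature (a
# multiplicative delta/theta band-power shift and a synchrony raise on a
# focal channel subset) — not physiological morphology. Timelines are laid
# out so every labeling rule is exercised: each seizure owns a full 65 min of
# preceding data and interictal records sit at least 4 h from any seizure.
#
# Two deliberate choices keep the null world (delta = 0, rho = rho0) exactly
# exchangeable under the per-recording min-max normalization downstream:
# every channel is clipped at a fixed multiple of its theoretical SD (an
# ADC-saturation analogue that pins record extremes), and interictal records
# share the seizure-record duration so realized extremes have identical
# distributions in both record types.

#' Synthetic cohort specification
#'
#' @param n_subjects number of subjects.
#' @param seizures_per_subject seizures (and hence leave-one-out folds) per
#'   subject.
#' @param fs sampling rate, Hz.
#' @param channels electrode names; must cover the 18-pair montage.
#' @param beta spectral exponent of the 1/f^beta background (1 = pink).
#' @param alpha_amp,alpha_freq amplitude (relative to unit background SD) and
#'   frequency of the rhythmic alpha component.
#' @param delta fractional preictal increase of delta/theta-band power on the
#'   focal channels (0 = null world).
#' @param rho preictal shared-source mixing coefficient on focal channels.
#' @param rho0 baseline shared-source mixing coefficient.
#' @param focal electrode subset carrying the preictal effect (default: the
#'   electrodes of the four frontal montage nodes).
#' @param noise_scale output amplitude scale (microvolt-like units per
#'   background SD).
#' @param clip_sigma saturation level in units of each channel's theoretical
#'   SD.
#' @param seizure_len_s ictal duration.
#' @param record_s duration of every record; must exceed onset_s +
#'   seizure_len_s.
#' @param onset_s seizure onset within a seizure record (default 3960 s, so
#'   the full 1 h preictal span plus 5 min horizon fits).
#' @param seed cohort RNG seed.
#' @return a list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 3L, seizures_per_subject = 4L, fs = 256,
                        channels = c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8",
                                     "T7", "C3", "CZ", "C4", "T8",
                                     "P7", "P3", "PZ", "P4", "P8", "O1", "O2"),
                        beta = 1, alpha_amp = 1, alpha_freq = 10,
                        delta = 1, rho = 0.6, rho0 = 0.2,
                        focal = c("FP1", "F7", "F3", "FP2", "F4", "F8"),
                        noise_scale = 50, clip_sigma = 4,
                        seizure_len_s = 30, record_s = 4020, onset_s = 3960,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, seizures_per_subject >= 1, fs > 0, delta >= 0,
            rho >= 0, rho <= 1, rho0 >= 0, rho0 <= 1, clip_sigma > 0,
            record_s > onset_s + seizure_len_s)
  channels <- canonical_label(channels)
  focal <- canonical_label(focal)
  mspec <- chb_bipolar_montage()
  missing_el <- setdiff(unique(c(mspec$anode, mspec$cathode)), channels)
  if (length(missing_el)) {
    stopf("channels must cover the 18-pair montage; missing: %s",
          paste(missing_el, collapse = ", "))
  }
  if (!all(focal %in% channels)) stopf("focal electrodes must be among channels")
  structure(list(n_subjects = as.integer(n_subjects),
                 seizures_per_subject = as.integer(seizures_per_subject),
                 fs = fs, channels = channels, beta = beta,
                 alpha_amp = alpha_amp, alpha_freq = alpha_freq,
                 delta = delta, rho = rho, rho0 = rho0, focal = focal,
                 noise_scale = noise_scale, clip_sigma = clip_sigma,
                 seizure_len_s = seizure_len_s, record_s = record_s,
                 onset_s = onset_s, seed = as.integer(seed)),
            class = "cohort_spec")
}

# -- spectral synthesis -------------------------------------------------------

# Bank of k independent unit-SD noises with the given spectral envelope,
# two per inverse FFT: with independent complex-Gaussian coefficients at all
# frequencies (no Hermitian symmetry) the real and imaginary parts of the
# inverse transform are independent processes with the same spectrum.
spectral_noise_bank <- function(n, fs, envelope, k) {
  n2 <- 2^ceiling(log2(max(n, 2L)))
  half <- n2 %/% 2L
  f_abs <- c(seq_len(half), seq(half - 1L, 1L)) * fs / n2
  amp <- envelope(f_abs)
  out <- matrix(0, n, k)
  for (j in seq_len(ceiling(k / 2))) {
    sp <- complex(real = stats::rnorm(n2 - 1L), imaginary = stats::rnorm(n2 - 1L)) * amp
    z <- stats::fft(c(0i, sp), inverse = TRUE)[seq_len(n)]
    re <- Re(z)
    out[, 2L * j - 1L] <- re / stats::sd(re)
    if (2L * j <= k) {
      im <- Im(z)
      out[, 2L * j] <- im / stats::sd(im)
    }
  }
  out
}

# Fraction of 1/f^beta background variance lying inside [lo, hi] Hz, computed
# from the same discrete synthesis grid used by spectral_noise_bank.
pink_band_fraction <- function(n, fs, beta, lo, hi) {
  n2 <- 2^ceiling(log2(max(n, 2L)))
  f <- seq_len(n2 %/% 2L - 1L) * fs / n2
  p <- f^(-beta)
  sum(p[f >= lo & f <= hi]) / sum(p)
}

# -- recording synthesis ------------------------------------------------------

#' Generate one synthetic recording
#'
#' Background everywhere; inside each span [onset - 3900 s, onset) the focal
#' channels' delta/theta power is scaled by (1 + delta) and their
#' shared-source mixing is raised from rho0 to rho; a 3 Hz high-amplitude
#' burst marks each [onset, onset + seizure_len_s]. Channels are clipped at
#' \code{clip_sigma} theoretical SDs and scaled to \code{noise_scale} units.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param duration_s recording duration (default \code{spec$record_s}).
#' @param onsets_s seizure onsets in seconds relative to the recording start
#'   (possibly empty).
#' @param start_s absolute start of the recording on the subject timeline.
#' @param subject_id subject identifier.
#' @param seed RNG seed (fixed seed gives bit-identical output).
#' @return a \code{\link{recording}} with annotated events.
#' @export
generate_recording <- function(spec = cohort_spec(), duration_s = spec$record_s,
                               onsets_s = numeric(), start_s = 0,
                               subject_id = "sub01", seed = spec$seed) {
  set.seed(seed)
  fs <- spec$fs
  n <- round(duration_s * fs)
  nch <- length(spec$channels)
  if (length(onsets_s) && any(onsets_s + spec$seizure_len_s > duration_s)) {
    stopf("seizure extends past the end of the recording")
  }
  tt <- seq_len(n) / fs
  beta <- spec$beta

  # one pink-noise bank: the shared source plus one process per electrode
  bank <- spectral_noise_bank(n, fs, function(f) f^(-beta / 2), nch + 1L)
  common <- bank[, 1L]

  # binary preictal gate: samples inside any [onset - 3900 s, onset) span
  gate_idx <- integer()
  for (on in onsets_s) {
    i0 <- max(1L, floor((on - 3900) * fs) + 1L)
    i1 <- min(n, ceiling((on - 1e-9) * fs))
    if (i1 >= i0) gate_idx <- c(gate_idx, i0:i1)
  }
  focal_ch <- which(spec$channels %in% spec$focal)
  frac_low <- pink_band_fraction(n, fs, beta, 1, 7.5)
  boost_sd <- sqrt(spec$delta * frac_low)
  boost <- if (spec$delta > 0 && length(gate_idx)) {
    spectral_noise_bank(n, fs, function(f) as.numeric(f >= 1 & f <= 7.5),
                        length(focal_ch))
  } else NULL
  # alpha rhythm: narrowband noise around alpha_freq, one independent process
  # per electrode. Real alpha is not an hour-long phase-coherent sinusoid; a
  # fixed per-electrode phase would also give every record a rigid bipolar
  # alpha-amplitude fingerprint by which a classifier can recognize records
  # instead of brain states.
  f0 <- spec$alpha_freq
  alpha_bank <- if (spec$alpha_amp > 0) {
    spectral_noise_bank(n, fs, function(f) exp(-0.5 * ((f - f0) / 0.8)^2), nch)
  } else NULL

  # Slow drifts (unit-mean log-normal, standardized slow Gaussian inside):
  # alpha power waxes and wanes (~20 s), the overall amplitude follows a
  # vigilance-like drift (~40 s), and the shared source projects with slowly
  # wandering gains (~60 s). All three are realistic, and all three keep the
  # null world honest by turning would-be per-record constants into
  # within-record variation.
  slow_gauss <- function(smooth_s) {
    nsec <- ceiling(duration_s) + 2L * smooth_s
    slow <- as.numeric(stats::filter(stats::rnorm(nsec), rep(1 / smooth_s, smooth_s),
                                     method = "convolution", sides = 1L))
    slow <- slow[!is.na(slow)]
    slow <- (slow - mean(slow)) / max(stats::sd(slow), 1e-12)
    stats::approx(seq_along(slow) - 1, slow, xout = tt, rule = 2)$y
  }
  slow_envelope <- function(smooth_s, sigma) exp(sigma * slow_gauss(smooth_s) - sigma^2 / 2)
  # one phase per discharge, shared by all channels: ictal activity is
  # hypersynchronous, and a common phase keeps the bipolar-difference burst
  # small (gain differences only) so it never sets a record's min/max
  burst_phase <- stats::runif(length(onsets_s), 0, 2 * pi)

  # assemble channel by channel (column-sized temporaries keep the memory
  # footprint small; they are recycled by the allocator)
  s0 <- sqrt(1 - spec$rho0^2)
  s1 <- sqrt(1 - spec$rho^2)
  x_all <- matrix(0, n, nch) # samples x channels while assembling
  for (c_i in seq_len(nch)) {
    gain_t <- 1 + 0.35 * slow_gauss(60L) # wandering shared-source projection
    x <- s0 * bank[, c_i + 1L] + (spec$rho0 * gain_t) * common
    if (!is.null(alpha_bank)) {
      x <- x + (spec$alpha_amp / sqrt(2) * slow_envelope(20L, 0.5)) * alpha_bank[, c_i]
    }
    fi <- match(c_i, focal_ch)
    if (!is.na(fi) && length(gate_idx)) {
      # preictal signature on focal channels: synchrony raise + low-band boost
      x[gate_idx] <- x[gate_idx] + (s1 - s0) * bank[gate_idx, c_i + 1L] +
        ((spec$rho - spec$rho0) * gain_t[gate_idx]) * common[gate_idx]
      if (!is.null(boost)) {
        x[gate_idx] <- x[gate_idx] + boost_sd * boost[gate_idx, fi]
      }
    }
    x <- x * slow_envelope(40L, 0.3) # vigilance-like overall amplitude drift
    for (k in seq_along(onsets_s)) { # ictal burst: large rhythmic 3 Hz discharge
      i0 <- floor(onsets_s[k] * fs) + 1L
      i1 <- min(n, ceiling((onsets_s[k] + spec$seizure_len_s) * fs))
      seg <- i0:i1
      env <- sin(pi * seq_along(seg) / length(seg))
      x[seg] <- x[seg] + 3 * (0.5 + gain_t[seg] / 2) * env *
        sin(2 * pi * 3 * tt[seg] + burst_phase[k])
    }
    # fixed theoretical-SD clip: pins every record's extremes to the same
    # level so downstream per-record min-max normalization is comparable
    cl <- spec$clip_sigma * sqrt(1 + spec$alpha_amp^2 / 2)
    x[x > cl] <- cl
    x[x < -cl] <- -cl
    x_all[, c_i] <- x * spec$noise_scale
  }
  dat <- t(x_all)
  ev <- seizure_events(onsets_s, onsets_s + spec$seizure_len_s)
  recording(dat, fs = fs, channel_labels = spec$channels, events = ev,
            subject_id = subject_id, start_s = start_s)
}

#' Generate baseline background only
#'
#' Convenience wrapper: a recording with no seizures and no preictal effect
#' (mixing at rho0 throughout).
#'
#' @inheritParams generate_recording
#' @return a \code{\link{recording}} without events.
#' @export
generate_background <- function(spec = cohort_spec(), duration_s = 60,
                                seed = spec$seed) {
  generate_recording(spec, duration_s = duration_s, onsets_s = numeric(),
                     seed = seed)
}

# -- cohort layout ------------------------------------------------------------

#' Record plan of a synthetic cohort
#'
#' Each seizure gets one record hosting its full preictal hour plus horizon,
#' followed by one interictal record placed 4 h after the seizure's offset
#' and far enough from the next seizure that every one of its windows is
#' nearest to — and hence grouped with — its own seizure. A fold therefore
#' holds out two whole records (the seizure record and its interictal
#' record), so no record is ever split between training and test: with
#' per-recording normalization, splitting a record across folds would let a
#' classifier exploit record-level scale fingerprints. Interictal records
#' share the seizure-record duration so normalization sees identically
#' distributed extremes in both record kinds. Records are generated on
#' demand from this plan (they are large), see
#' \code{\link{generate_planned_recording}}.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return data.frame with one row per record: \code{subject},
#'   \code{record}, \code{kind}, \code{start_s}, \code{duration_s},
#'   \code{onset_s} (recording-relative, NA for interictal records),
#'   \code{seizure_group}, \code{seed}.
#' @export
cohort_plan <- function(spec = cohort_spec()) {
  margin <- 14400
  dur <- spec$record_s
  # subject-timeline stride between consecutive seizures: must leave the
  # interictal record >= 4 h from its seizure and strictly nearer to it than
  # to the next one
  stride <- dur + spec$onset_s + spec$seizure_len_s + 2 * margin + 2000
  rows <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("sub%02d", s)
    for (k in seq_len(spec$seizures_per_subject)) {
      t_k <- (k - 1) * stride
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid, record = sprintf("%s_rec%02d", sid, 2L * k - 1L),
        kind = "seizure", start_s = t_k, duration_s = dur,
        onset_s = spec$onset_s, seizure_group = k,
        seed = child_seed(spec$seed, 1000L * s + 2L * k - 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid, record = sprintf("%s_rec%02d", sid, 2L * k),
        kind = "interictal",
        start_s = t_k + spec$onset_s + spec$seizure_len_s + margin,
        duration_s = dur, onset_s = NA_real_, seizure_group = k,
        seed = child_seed(spec$seed, 1000L * s + 2L * k))
    }
  }
  do.call(rbind, rows)
}

#' Generate one record of a cohort plan
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param plan_row one row of \code{\link{cohort_plan}}.
#' @return a \code{\link{recording}}.
#' @export
generate_planned_recording <- function(spec, plan_row) {
  onsets <- if (is.na(plan_row$onset_s)) numeric() else plan_row$onset_s
  generate_recording(spec, duration_s = plan_row$duration_s, onsets_s = onsets,
                     start_s = plan_row$start_s, subject_id = plan_row$subject,
                     seed = plan_row$seed)
}

#' Absolute seizure timeline of one subject in a cohort plan
#'
#' @param plan a \code{\link{cohort_plan}}.
#' @param subject subject id.
#' @param spec the matching \code{\link{cohort_spec}}.
#' @return data.frame with \code{onset_s}, \code{offset_s}, \code{group} on
#'   the absolute timeline.
#' @export
plan_subject_events <- function(plan, subject, spec = cohort_spec()) {
  pr <- plan[plan$subject == subject & plan$kind == "seizure", , drop = FALSE]
  data.frame(onset_s = pr$start_s + pr$onset_s,
             offset_s = pr$start_s + pr$onset_s + spec$seizure_len_s,
             group = pr$seizure_group)
}

#' Write a synthetic cohort to disk
#'
#' Each record becomes a quantized plain-text CSV plus JSON header (see
#' \code{\link{write_text_recording}}); per subject a CHB-MIT-dialect
#' summary file and a CSV annotation file are written, loadable by
#' \code{\link{read_chb_summary}} / \code{\link{read_annotations_csv}}.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param out_dir output directory (created if needed).
#' @return the cohort plan with a \code{path} column, invisibly.
#' @export
write_cohort <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plan <- cohort_plan(spec)
  plan$path <- file.path(out_dir, paste0(plan$record, ".csv"))
  for (i in seq_len(nrow(plan))) {
    rec <- generate_planned_recording(spec, plan[i, ])
    write_text_recording(rec, plan$path[i])
  }
  for (sid in unique(plan$subject)) {
    pr <- plan[plan$subject == sid, , drop = FALSE]
    lines <- character()
    ann <- list()
    for (i in seq_len(nrow(pr))) {
      n_seiz <- as.integer(!is.na(pr$onset_s[i]))
      lines <- c(lines, sprintf("File Name: %s", basename(pr$path[i])),
                 sprintf("Number of Seizures in File: %d", n_seiz))
      if (n_seiz) {
        lines <- c(lines,
                   sprintf("Seizure Start Time: %d seconds", as.integer(pr$onset_s[i])),
                   sprintf("Seizure End Time: %d seconds",
                           as.integer(pr$onset_s[i] + spec$seizure_len_s)))
        ann[[length(ann) + 1L]] <- data.frame(file = basename(pr$path[i]),
                                              onset_s = pr$onset_s[i],
                                              offset_s = pr$onset_s[i] + spec$seizure_len_s)
      }
      lines <- c(lines, "")
    }
    writeLines(lines, file.path(out_dir, paste0(sid, "-summary.txt")))
    ann_df <- if (length(ann)) do.call(rbind, ann) else
      data.frame(file = character(), onset_s = numeric(), offset_s = numeric())
    utils::write.csv(ann_df, file.path(out_dir, paste0(sid, "-annotations.csv")),
                     row.names = FALSE)
  }
  invisible(plan)
}
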