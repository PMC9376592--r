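# Electrode geometry and bipolar montage construction.
#
# Channels of the graph are bipolar derivations (anode minus cathode) of
# 10-20 scalp electrodes; the 18-pair double-banana subset used for CHB-MIT
# style recordings is the package default.

# -- label canonicalization ---------------------------------------------------

# Older 10-20 temporal names map onto the modified (10-10 consistent) names.
.label_synonyms <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Canonicalize an electrode label
#'
#' Matching is case-insensitive and dialect-insensitive: \code{"T3"} is the
#' same electrode as \code{"T7"}, \code{"T5"} as \code{"P7"}, and so on.
#'
#' @param label character vector of electrode names.
#' @return upper-case canonical names (modern temporal naming).
#' @export
canonical_label <- function(label) {
  up <- toupper(trimws(label))
  hit <- up %in% names(.label_synonyms)
  up[hit] <- .label_synonyms[up[hit]]
  up
}

# -- atlas --------------------------------------------------------------------

#' Unit-sphere coordinates of 10-20 electrodes
#'
#' Idealized spherical head model (radius 1): x to the right preauricular
#' point, y to the nasion, z to the vertex. Outer-ring electrodes sit on the
#' equator at the canonical 10-20 azimuths; C3/C4 lie 45 degrees down the
#' coronal arc, Fz/Pz 36 degrees down the midline, and F3/F4/P3/P4 are
#' spherical midpoints of their neighbouring ring/midline electrodes, as the
#' 10-20 placement rules prescribe.
#'
#' @return a numeric matrix with one row per electrode (rownames are canonical
#'   labels) and columns x, y, z; every row has unit norm.
#' @export
electrode_atlas <- function() {
  eq <- function(az_deg) {
    a <- az_deg * pi / 180
    c(-sin(a), cos(a), 0) # positive azimuth = toward the left ear
  }
  mid <- function(incl_deg, front = TRUE) {
    a <- incl_deg * pi / 180
    c(0, if (front) sin(a) else -sin(a), cos(a))
  }
  slerp_mid <- function(p, q) {
    m <- (p + q) / 2
    m / sqrt(sum(m^2))
  }
  pos <- list(
    FPZ = eq(0), FP1 = eq(18), F7 = eq(54), T7 = eq(90), P7 = eq(126),
    O1 = eq(162), OZ = eq(180), O2 = eq(-162), P8 = eq(-126), T8 = eq(-90),
    F8 = eq(-54), FP2 = eq(-18),
    CZ = c(0, 0, 1),
    FZ = mid(36, front = TRUE), PZ = mid(36, front = FALSE),
    C3 = c(-sin(pi / 4), 0, cos(pi / 4)), C4 = c(sin(pi / 4), 0, cos(pi / 4))
  )
  pos$F3 <- slerp_mid(pos$F7, pos$FZ)
  pos$F4 <- slerp_mid(pos$F8, pos$FZ)
  pos$P3 <- slerp_mid(pos$P7, pos$PZ)
  pos$P4 <- slerp_mid(pos$P8, pos$PZ)
  m <- do.call(rbind, pos)
  colnames(m) <- c("x", "y", "z")
  m
}

# -- montage spec -------------------------------------------------------------

#' Define a bipolar montage
#'
#' @param pairs two-column character matrix or data.frame (anode, cathode), or
#'   a character vector of \code{"ANODE-CATHODE"} strings.
#' @return an object of class \code{montage_spec}: a data.frame with columns
#'   \code{anode}, \code{cathode}, \code{label}.
#' @export
montage_spec <- function(pairs) {
  if (is.character(pairs)) {
    sp <- strsplit(pairs, "-", fixed = TRUE)
    bad <- lengths(sp) != 2L
    if (any(bad)) stopf("malformed montage pair(s): %s", paste(pairs[bad], collapse = ", "))
    pairs <- do.call(rbind, sp)
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stopf("montage pairs need exactly two electrodes")
  anode <- canonical_label(pairs[, 1L])
  cathode <- canonical_label(pairs[, 2L])
  atlas <- rownames(electrode_atlas())
  unknown <- setdiff(unique(c(anode, cathode)), atlas)
  if (length(unknown)) {
    stopf("electrode(s) not in the 10-20 system: %s", paste(unknown, collapse = ", "))
  }
  label <- paste0(anode, "-", cathode)
  if (anyDuplicated(label)) {
    stopf("duplicate montage pair(s): %s", paste(unique(label[duplicated(label)]), collapse = ", "))
  }
  structure(data.frame(anode = anode, cathode = cathode, label = label,
                       stringsAsFactors = FALSE),
            class = c("montage_spec", "data.frame"))
}

#' The 18-pair double-banana bipolar montage
#'
#' The standard longitudinal bipolar chains plus the midline pair, i.e. the
#' 18 derivations used throughout the pipeline: Fp1-F7, F7-T7, T7-P7, P7-O1,
#' Fp1-F3, F3-C3, C3-P3, P3-O1, Fp2-F4, F4-C4, C4-P4, P4-O2, Fp2-F8, F8-T8,
#' T8-P8, P8-O2, Fz-Cz, Cz-Pz.
#'
#' @return a \code{\link{montage_spec}} of length 18.
#' @export
chb_bipolar_montage <- function() {
  montage_spec(c(
    "FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ"
  ))
}

#' Re-reference a recording to a bipolar montage
#'
#' Each output channel is the anode signal minus the cathode signal. When the
#' recording is already stored as bipolar derivations (labels containing
#' \code{"-"}) the matching derivations are passed through unchanged.
#'
#' @param rec a \code{\link{recording}}.
#' @param spec a \code{\link{montage_spec}} (default: the 18-pair montage).
#' @return a recording whose channels follow \code{spec}, labelled
#'   \code{"ANODE-CATHODE"}.
#' @export
apply_bipolar_montage <- function(rec, spec = chb_bipolar_montage()) {
  stopifnot(inherits(rec, "recording"))
  labs <- canonical_label(rec$channel_labels)
  if (anyDuplicated(labs)) {
    stopf("duplicate channel label(s) in recording: %s",
          paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  already_bipolar <- any(grepl("-", labs, fixed = TRUE))
  td <- t(rec$data) # samples x channels: column ops on large recordings
  out <- matrix(0, nrow = nrow(td), ncol = nrow(spec))
  for (i in seq_len(nrow(spec))) {
    if (already_bipolar) {
      j <- match(spec$label[i], labs)
      if (is.na(j)) stopf("bipolar derivation %s missing from recording", spec$label[i])
      out[, i] <- td[, j]
    } else {
      ja <- match(spec$anode[i], labs)
      jc <- match(spec$cathode[i], labs)
      if (is.na(ja)) stopf("electrode %s missing from recording", spec$anode[i])
      if (is.na(jc)) stopf("electrode %s missing from recording", spec$cathode[i])
      out[, i] <- td[, ja] - td[, jc]
    }
  }
  rec$data <- t(out)
  rec$channel_labels <- spec$label
  rec
}

#' Node positions of a bipolar montage
#'
#' A bipolar node is placed at the spherical midpoint of its two electrodes
#' (midpoint of the chord, re-projected onto the unit sphere).
#'
#' @param atlas electrode coordinate matrix from \code{\link{electrode_atlas}}.
#' @param spec a \code{\link{montage_spec}}.
#' @return an n x 3 matrix of unit vectors, rownames the montage labels.
#' @export
montage_positions <- function(atlas = electrode_atlas(), spec = chb_bipolar_montage()) {
  missing_el <- setdiff(unique(c(spec$anode, spec$cathode)), rownames(atlas))
  if (length(missing_el)) {
    stopf("electrode(s) missing from atlas: %s", paste(missing_el, collapse = ", "))
  }
  pos <- matrix(0, nrow(spec), 3L, dimnames = list(spec$label, c("x", "y", "z")))
  for (i in seq_len(nrow(spec))) {
    m <- (atlas[spec$anode[i], ] + atlas[spec$cathode[i], ]) / 2
    nm <- sqrt(sum(m^2))
    if (nm < 1e-9) stopf("antipodal electrode pair %s has no spherical midpoint", spec$label[i])
    pos[i, ] <- m / nm
  }
  pos
}
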