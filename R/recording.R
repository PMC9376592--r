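# Recording container and plain-text I/O.
#
# A recording is a channels x samples matrix with a sampling rate, channel
# labels, seizure annotations (onset/offset in seconds relative to the start
# of the recording) and an absolute start offset `start_s` that places it on
# the subject's timeline (clinical archives split a subject over many files;
# labeling rules need the absolute distances to every seizure).

#' Construct a recording
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one per row of \code{data}.
#' @param events data.frame with columns \code{onset_s}, \code{offset_s}
#'   (seconds from the start of this recording), possibly empty.
#' @param subject_id subject identifier.
#' @param start_s absolute start time of this recording on the subject's
#'   timeline, in seconds.
#' @return an object of class \code{recording}.
#' @export
recording <- function(data, fs = 256, channel_labels = NULL,
                      events = seizure_events(), subject_id = "anon",
                      start_s = 0) {
  data <- as.matrix(data)
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be a positive number")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data)) {
    stopf("channel_labels length (%d) != number of data rows (%d)",
          length(channel_labels), nrow(data))
  }
  events <- seizure_events(events$onset_s, events$offset_s)
  structure(list(subject_id = subject_id, fs = fs,
                 channel_labels = channel_labels, data = data,
                 events = events, start_s = start_s),
            class = "recording")
}

#' Seizure annotation table
#'
#' @param onset_s,offset_s numeric vectors of equal length; each event must
#'   have \code{onset_s < offset_s}, events must be non-overlapping and are
#'   returned sorted by onset.
#' @return data.frame with columns \code{onset_s}, \code{offset_s}.
#' @export
seizure_events <- function(onset_s = numeric(), offset_s = numeric()) {
  if (length(onset_s) != length(offset_s)) stopf("onset/offset length mismatch")
  if (any(!is.finite(onset_s)) || any(!is.finite(offset_s))) stopf("non-finite event times")
  if (any(offset_s <= onset_s)) stopf("every seizure needs onset_s < offset_s")
  o <- order(onset_s)
  onset_s <- onset_s[o]; offset_s <- offset_s[o]
  if (length(onset_s) > 1L && any(onset_s[-1L] < offset_s[-length(offset_s)])) {
    stopf("seizure events overlap")
  }
  data.frame(onset_s = as.numeric(onset_s), offset_s = as.numeric(offset_s))
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s), %d seizure(s), start %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, nrow(x$events), x$start_s))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a \code{\link{recording}}.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

# -- annotation readers -------------------------------------------------------

#' Read seizure annotations in the CHB-MIT summary dialect
#'
#' Parses the plain-text `*-summary.txt` layout: blocks introduced by
#' \code{File Name:}, followed by \code{Number of Seizures in File:} and
#' pairs of \code{Seizure [N ]Start Time: <x> seconds} /
#' \code{Seizure [N ]End Time: <x> seconds}.
#'
#' @param path path to the summary file.
#' @return data.frame with columns \code{file}, \code{onset_s}, \code{offset_s}
#'   (one row per seizure; files without seizures contribute no rows).
#' @export
read_chb_summary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  current <- NA_character_
  starts <- numeric()
  num <- function(s) as.numeric(sub("^.*?:\\s*([-0-9.]+).*$", "\\1", s))
  for (ln in lines) {
    if (grepl("^\\s*File Name\\s*:", ln)) {
      current <- trimws(sub("^\\s*File Name\\s*:\\s*", "", ln))
    } else if (grepl("^\\s*Seizure(\\s+\\d+)?\\s+Start Time\\s*:", ln)) {
      starts <- c(starts, num(ln))
    } else if (grepl("^\\s*Seizure(\\s+\\d+)?\\s+End Time\\s*:", ln)) {
      if (!length(starts)) stopf("summary file %s: End Time before Start Time", path)
      out[[length(out) + 1L]] <- data.frame(file = current,
                                            onset_s = starts[length(starts)],
                                            offset_s = num(ln))
      starts <- starts[-length(starts)]
    }
  }
  if (!length(out)) {
    return(data.frame(file = character(), onset_s = numeric(), offset_s = numeric()))
  }
  do.call(rbind, out)
}

#' Read seizure annotations from a simple CSV dialect
#'
#' Expects a header \code{file,onset_s,offset_s}.
#' @param path path to the CSV file.
#' @return data.frame with columns \code{file}, \code{onset_s}, \code{offset_s}.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "onset_s", "offset_s")
  if (!all(need %in% names(df))) {
    stopf("annotation CSV %s must have columns: %s", path, paste(need, collapse = ", "))
  }
  df[, need]
}

# -- plain-text recording I/O -------------------------------------------------

#' Write a recording as quantized plain text
#'
#' Samples are quantized per channel to 16-bit integers over the channel's
#' physical range (the same resolution as EDF storage) and written as a CSV of
#' integers, one column per channel, together with a JSON sidecar header
#' carrying rate, labels, physical ranges, start offset and annotations.
#'
#' @param rec a \code{\link{recording}}.
#' @param path output path of the CSV (a \code{.json} sidecar is written next
#'   to it).
#' @return \code{path}, invisibly.
#' @export
write_text_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  nch <- nrow(rec$data)
  rr <- cpp_row_range(rec$data)
  phys_min <- rr[1L, ]
  phys_max <- rr[2L, ]
  span <- pmax(phys_max - phys_min, .Machine$double.eps)
  dig <- matrix(0L, nrow = ncol(rec$data), ncol = nch)
  for (i in seq_len(nch)) {
    dig[, i] <- as.integer(round((rec$data[i, ] - phys_min[i]) / span[i] * 65535) - 32768)
  }
  colnames(dig) <- rec$channel_labels
  data.table::fwrite(data.table::as.data.table(dig), path)
  header <- list(subject_id = rec$subject_id, fs = rec$fs,
                 channel_labels = rec$channel_labels,
                 phys_min = phys_min, phys_max = phys_max,
                 start_s = rec$start_s,
                 events = list(onset_s = rec$events$onset_s,
                               offset_s = rec$events$offset_s))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by \code{\link{write_text_recording}}
#'
#' @param path path to the CSV file.
#' @return a \code{\link{recording}}.
#' @export
read_text_recording <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dig <- as.matrix(data.table::fread(path))
  nch <- length(header$channel_labels)
  span <- pmax(header$phys_max - header$phys_min, .Machine$double.eps)
  dat <- matrix(0, nrow = nch, ncol = nrow(dig))
  for (i in seq_len(nch)) {
    dat[i, ] <- (dig[, i] + 32768) / 65535 * span[i] + header$phys_min[i]
  }
  ev <- header$events
  recording(dat, fs = header$fs, channel_labels = header$channel_labels,
            events = seizure_events(as.numeric(ev$onset_s), as.numeric(ev$offset_s)),
            subject_id = header$subject_id, start_s = header$start_s)
}
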