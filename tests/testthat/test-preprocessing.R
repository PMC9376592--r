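# Montage construction, filtering, normalization and the preictal/interictal
# labeling rules.

test_that("bipolar montage resolves dialects and computes differences", {
  rec <- make_referential_recording(dur = 10, extra_channels = c("ECG", "LOC", "ROC", "EMG"))
  out <- apply_bipolar_montage(rec)
  expect_equal(nrow(out$data), 18L)
  expect_equal(out$channel_labels, chb_bipolar_montage()$label)
  # T7-P7 must equal the referential T3 - T5 difference (old dialect labels)
  i_t3 <- match("T3", rec$channel_labels)
  i_t5 <- match("T5", rec$channel_labels)
  expect_equal(out$data[match("T7-P7", out$channel_labels), ],
               rec$data[i_t3, ] - rec$data[i_t5, ])
})

test_that("montage arithmetic, degenerate pairs and errors", {
  rec <- recording(rbind(c(1, 2), c(0.5, 1)), fs = 1,
                   channel_labels = c("Fp1", "F7"))
  out <- apply_bipolar_montage(rec, montage_spec("FP1-F7"))
  expect_equal(as.numeric(out$data), c(0.5, 1))
  same <- apply_bipolar_montage(rec, montage_spec("F7-F7"))
  expect_true(all(same$data == 0))
  expect_error(apply_bipolar_montage(rec, montage_spec("FP1-O1")),
               "O1 missing")
  expect_error(montage_spec(c("FP1-F7", "Fp1-f7")), "duplicate")
  expect_error(montage_spec("FP1-XX9"), "not in the 10-20 system")
})

test_that("already-bipolar recordings pass through by derivation name", {
  base <- matrix(stats::rnorm(18 * 20), 18)
  rec <- recording(base, fs = 2, channel_labels = tolower(chb_bipolar_montage()$label))
  out <- apply_bipolar_montage(rec)
  expect_equal(out$data, base)
})

test_that("high-pass and notch filters realize their stated responses", {
  fs <- 256
  tgrid <- 1000:14000 # interior, away from edge transients
  rms <- function(x) sqrt(mean(x^2))
  hp <- butter_highpass(1, fs)
  nf <- iir_notch(50, fs)
  x50 <- make_sine(50)
  att <- 20 * log10(rms(filtfilt(nf$b, nf$a, x50)[tgrid]) / rms(x50[tgrid]))
  expect_lt(att, -20)
  x10 <- make_sine(10)
  y10 <- filtfilt(nf$b, nf$a, filtfilt(hp$b, hp$a, x10))
  passband <- 20 * log10(rms(y10[tgrid]) / rms(x10[tgrid]))
  expect_lt(abs(passband), 1)
})

test_that("filter_signal removes DC, is linear, and guards bad input", {
  fs <- 256
  rec <- recording(matrix(5, 1, fs * 60), fs = fs)
  y <- filter_signal(rec)$data[1, ]
  expect_lt(mean(abs(y)), 1e-3 * 5)
  set.seed(3)
  x <- stats::rnorm(2000)
  r1 <- filter_signal(recording(rbind(x), fs = fs))$data[1, ]
  r2 <- filter_signal(recording(rbind(4.2 * x), fs = fs))$data[1, ]
  expect_lt(max(abs(r2 - 4.2 * r1)) / max(abs(r2)), 1e-9)
  bad <- recording(rbind(c(1, NA, 3)), fs = fs)
  expect_error(filter_signal(bad), "non-finite")
  low_fs <- recording(rbind(stats::rnorm(600)), fs = 120)
  expect_warning(filter_signal(low_fs), "infeasible notch at 100")
})

test_that("min-max normalization maps ranges and flags constant channels", {
  rec <- recording(rbind(c(2, 4, 6)), fs = 1)
  expect_equal(as.numeric(minmax_normalize(rec)$data), c(0, 0.5, 1))
  rec2 <- recording(rbind(c(-1, 0, 3)), fs = 1)
  expect_equal(as.numeric(minmax_normalize(rec2, c(-1, 1))$data), c(-1, -0.5, 1))
  rec3 <- recording(rbind(c(5, 5, 5), c(0, 1, 2)), fs = 1)
  expect_warning(out <- minmax_normalize(rec3), "constant")
  expect_equal(as.numeric(out$data[1, ]), c(0, 0, 0))
  expect_equal(as.numeric(out$data[2, ]), c(0, 0.5, 1))
})

test_that("labeling realizes the preictal window arithmetic", {
  fs <- 16
  rec <- make_referential_recording(dur = 8000, fs = fs,
                                    events = seizure_events(7200, 7230))
  segs <- label_and_segment(rec)
  lab <- vapply(segs, `[[`, integer(1), "label")
  ts <- vapply(segs, `[[`, numeric(1), "t_start")
  expect_equal(sum(lab == 1), 60L) # one hour of non-overlapping 60 s windows
  expect_equal(range(ts[lab == 1]), c(3300, 6840))
  expect_equal(sum(lab == 0), 0L) # everything else is within 4 h of the seizure
  expect_true(all(vapply(segs, function(s) ncol(s$data), numeric(1)) == 60 * fs))
})

test_that("margin rule, truncation rule, and labeling invariants hold", {
  fs <- 16
  # no seizure within 4 h: every complete window is interictal
  rec <- make_referential_recording(dur = 330, fs = fs)
  segs <- label_and_segment(rec)
  expect_equal(length(segs), 5L) # 330 s -> 5 whole windows, remainder dropped
  expect_true(all(vapply(segs, `[[`, integer(1), "label") == 0L))

  # a seizure whose preictal hour precedes the recording start yields nothing
  rec2 <- make_referential_recording(dur = 5000, fs = fs,
                                     events = seizure_events(600, 630))
  expect_message(segs2 <- label_and_segment(rec2), "truncated")
  expect_equal(sum(vapply(segs2, `[[`, integer(1), "label") == 1L), 0L)

  # invariants on a two-seizure timeline
  rec3 <- make_referential_recording(dur = 40000, fs = fs,
                                     events = seizure_events(c(8000, 36000), c(8030, 36030)))
  segs3 <- label_and_segment(rec3)
  ts <- vapply(segs3, `[[`, numeric(1), "t_start")
  lab <- vapply(segs3, `[[`, integer(1), "label")
  # no labeled window intrudes into [onset - 300, offset] of any seizure
  for (k in 1:2) {
    on <- c(8000, 36000)[k]; off <- on + 30
    expect_true(all(ts + 60 <= on - 300 | ts >= off))
  }
  # interictal windows at least 4 h from both seizures
  for (t0 in ts[lab == 0]) {
    gaps <- pmax(pmax(c(8000, 36000) - (t0 + 60), t0 - c(8030, 36030)), 0)
    expect_true(all(gaps >= 14400))
  }
  # windows are pairwise disjoint in time and fit the recording
  expect_false(any(duplicated(ts)))
  expect_true(all(diff(sort(ts)) >= 60))
  expect_lte(length(segs3) * 60, recording_duration(rec3))
  # idempotence
  segs3b <- label_and_segment(rec3)
  expect_identical(lapply(segs3, `[`, c("label", "seizure_group", "t_start")),
                   lapply(segs3b, `[`, c("label", "seizure_group", "t_start")))
})

test_that("interictal segments are assigned to the temporally nearest seizure", {
  fs <- 16
  rec <- make_referential_recording(dur = 60000, fs = fs,
                                    events = seizure_events(c(4000, 50000), c(4030, 50030)))
  segs <- label_and_segment(rec)
  lab <- vapply(segs, `[[`, integer(1), "label")
  ts <- vapply(segs, `[[`, numeric(1), "t_start")
  grp <- vapply(segs, `[[`, numeric(1), "seizure_group")
  ii <- lab == 0
  # independent recomputation: distance from the window to each seizure
  # interval, nearest one wins
  gap_to <- function(t0, on, off) pmax(on - (t0 + 60), t0 - off, 0)
  nearest <- vapply(ts[ii], function(t0) {
    which.min(c(gap_to(t0, 4000, 4030), gap_to(t0, 50000, 50030)))
  }, integer(1))
  expect_equal(grp[ii], nearest)
})

test_that("annotation readers parse both dialects", {
  summary_txt <- c(
    "Data Sampling Rate: 256 Hz", "",
    "File Name: subA_rec01.csv",
    "Number of Seizures in File: 2",
    "Seizure 1 Start Time: 2996 seconds",
    "Seizure 1 End Time: 3036 seconds",
    "Seizure 2 Start Time: 5000 seconds",
    "Seizure 2 End Time: 5050 seconds",
    "",
    "File Name: subA_rec02.csv",
    "Number of Seizures in File: 0")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(summary_txt, f)
  ann <- read_chb_summary(f)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$onset_s, c(2996, 5000))
  expect_equal(ann$offset_s, c(3036, 5050))
  expect_true(all(ann$file == "subA_rec01.csv"))

  fcsv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(file = "r1.csv", onset_s = 10, offset_s = 20),
                   fcsv, row.names = FALSE)
  ann2 <- read_annotations_csv(fcsv)
  expect_equal(ann2$onset_s, 10)
})

test_that("plain-text recording round trip stays within quantization", {
  set.seed(5)
  rec <- recording(matrix(stats::rnorm(3 * 500, sd = 40), 3), fs = 100,
                   channel_labels = c("FP1", "CZ", "O2"),
                   events = seizure_events(1.5, 2.25), subject_id = "subX",
                   start_s = 1234)
  f <- withr::local_tempfile(fileext = ".csv")
  write_text_recording(rec, f)
  back <- read_text_recording(f)
  span <- max(rec$data[1, ]) - min(rec$data[1, ])
  expect_lt(max(abs(back$data - rec$data)), span / 65535 * 1.01)
  expect_identical(back$events, rec$events) # annotations round trip exactly
  expect_identical(back$subject_id, "subX")
  expect_equal(back$start_s, 1234)
})
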