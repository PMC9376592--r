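# The synthetic-EEG cohort generator: spectral shape, preictal signatures,
# timeline layout and disk round trips.

test_that("background has the requested 1/f spectral slope and alpha peak", {
  spec0 <- cohort_spec(alpha_amp = 0)
  rec <- generate_background(spec0, duration_s = 120, seed = 61)
  ch <- rec$data[1, ]
  n <- length(ch)
  px <- Mod(stats::fft(ch))^2
  f <- (seq_len(n) - 1) * spec0$fs / n
  sel <- f >= 2 & f <= 40
  slope <- stats::coef(stats::lm(log(px[sel]) ~ log(f[sel])))[[2]]
  expect_equal(slope, -spec0$beta, tolerance = 0.3)

  # with the rhythm on, the alpha bin stands clearly above the 1/f trend
  peak_score <- function(r) {
    x <- r$data[1, ]
    p <- Mod(stats::fft(x))^2
    fr <- (seq_along(x) - 1) * 256 / length(x)
    mean(p[fr >= 9.5 & fr <= 10.5]) / mean(p[(fr >= 7 & fr <= 8.5) | (fr >= 11.5 & fr <= 13)])
  }
  withalpha <- generate_background(cohort_spec(alpha_amp = 1), duration_s = 120, seed = 61)
  expect_gt(peak_score(withalpha), 5)
  expect_lt(peak_score(rec), 2)
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- cohort_spec()
  r1 <- generate_recording(spec, duration_s = 30, seed = 62)
  r2 <- generate_recording(spec, duration_s = 30, seed = 62)
  expect_identical(r1$data, r2$data)
  r3 <- generate_recording(spec, duration_s = 30, seed = 63)
  expect_false(identical(r1$data, r3$data))
})

test_that("signals are bounded by the declared saturation level", {
  spec <- cohort_spec()
  rec <- generate_recording(spec, duration_s = 90,
                            onsets_s = 40, seed = 64)
  expect_true(all(is.finite(rec$data)))
  cl <- spec$clip_sigma * sqrt(1 + spec$alpha_amp^2 / 2)
  expect_lte(max(abs(rec$data)), cl * spec$noise_scale + 1e-9)
  expect_equal(nrow(rec$events), 1L)
})

test_that("a preictal band-power shift raises low-band energy on focal nodes", {
  # short records with the onset placed so the whole record is inside the
  # preictal gate, against an ungated twin; the focal/posterior low-band
  # ratio within each record cancels the slow amplitude envelopes
  spec_eff <- cohort_spec(delta = 1.5, rho = 0.6)
  focal_nodes <- match(c("FP1-F7", "FP1-F3", "FP2-F4", "FP2-F8"),
                       chb_bipolar_montage()$label)
  post_nodes <- match(c("P7-O1", "P3-O1", "P4-O2", "P8-O2"),
                      chb_bipolar_montage()$label)
  focal_contrast <- function(rec) {
    # montage + 1 Hz high-pass as in the pipeline: the boost targets
    # 1-7.5 Hz, and unfiltered pink noise buries it under sub-1 Hz power
    r <- filter_signal(apply_bipolar_montage(rec))
    lowband <- function(nodes, t0) {
      seg <- r$data[, (t0 * 256 + 1):((t0 + 60) * 256)]
      be <- assemble_node_features(seg)
      mean(be[nodes, "delta_energy"] + be[nodes, "theta_energy"])
    }
    t0s <- seq(30, 630, by = 75)
    mean(vapply(t0s, function(t0) lowband(focal_nodes, t0), numeric(1))) /
      mean(vapply(t0s, function(t0) lowband(post_nodes, t0), numeric(1)))
  }
  gated <- generate_recording(spec_eff, duration_s = 760, onsets_s = 700,
                              seed = 65, subject_id = "s")
  calm <- generate_recording(spec_eff, duration_s = 760, seed = 66, subject_id = "s")
  expect_gt(focal_contrast(gated), 1.25 * focal_contrast(calm))
})

test_that("inter-channel coherence rises monotonically with the mixing level", {
  cohs <- vapply(c(0, 0.5, 0.9), function(rho) {
    r <- generate_background(cohort_spec(rho0 = rho), duration_s = 60, seed = 67)
    i <- match(c("FP1", "FP2"), r$channel_labels)
    spectral_coherence(r$data[i[1], ], r$data[i[2], ])
  }, numeric(1))
  expect_true(all(diff(cohs) > 0))
})

test_that("the cohort plan honours every labeling margin", {
  spec <- cohort_spec(n_subjects = 2, seizures_per_subject = 3)
  plan <- cohort_plan(spec)
  # one seizure record plus one interictal record per seizure
  expect_equal(nrow(plan), 2L * 3L * 2L)
  # leave-one-seizure-out folds hold out whole records: every interictal
  # record's windows must all be nearest to its own seizure
  for (i in which(plan$kind == "interictal")) {
    ev <- plan_subject_events(plan, plan$subject[i], spec)
    own <- plan$seizure_group[i]
    for (t0 in c(plan$start_s[i], plan$start_s[i] + plan$duration_s[i] - 60)) {
      gaps <- pmax(ev$onset_s - (t0 + 60), t0 - ev$offset_s)
      expect_equal(ev$group[which.min(gaps)], own)
    }
  }
  for (sid in unique(plan$subject)) {
    ev <- plan_subject_events(plan, sid, spec)
    expect_equal(nrow(ev), 3L)
    pr <- plan[plan$subject == sid, ]
    for (i in which(pr$kind == "interictal")) {
      lo <- pr$start_s[i]; hi <- pr$start_s[i] + pr$duration_s[i]
      gaps <- pmax(ev$onset_s - hi, lo - ev$offset_s)
      expect_gte(min(gaps), 14400) # every interictal window at least 4 h away
    }
    for (i in which(pr$kind == "seizure")) {
      onset_abs <- pr$start_s[i] + pr$onset_s[i]
      expect_gte(onset_abs - pr$start_s[i], 3900 + 60) # full preictal span fits
    }
  }
})

test_that("a written cohort round-trips through the plain-text formats", {
  spec <- cohort_spec(n_subjects = 1, seizures_per_subject = 1,
                      record_s = 200, onset_s = 120, seizure_len_s = 20)
  dir <- withr::local_tempdir()
  plan <- write_cohort(spec, dir)
  expect_equal(nrow(plan), 2L)
  expect_true(all(file.exists(plan$path)))
  expect_true(file.exists(file.path(dir, "sub01-summary.txt")))

  back <- read_text_recording(plan$path[1])
  orig <- generate_planned_recording(spec, plan[1, ])
  span <- max(orig$data[1, ]) - min(orig$data[1, ])
  expect_lt(max(abs(back$data[1, ] - orig$data[1, ])), span / 65535 * 1.01)
  expect_identical(back$events, orig$events)

  ann <- read_chb_summary(file.path(dir, "sub01-summary.txt"))
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$onset_s, 120)
  expect_equal(ann$offset_s, 140)
  ann2 <- read_annotations_csv(file.path(dir, "sub01-annotations.csv"))
  expect_equal(ann2$onset_s, 120)
})
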