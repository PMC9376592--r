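# Shared fixture builders: everything is generated in code at test time.

fs_default <- 256

# Sine segment of the given frequency/duration.
make_sine <- function(freq, dur = 60, fs = fs_default, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq_len(dur * fs) / fs + phase)
}

# Random symmetric adjacency with zero diagonal, entries in [0, 1].
random_adjacency <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# Random graph sample with n nodes, f features and label y.
random_graph <- function(y, n = 18, f = 9, shift = 0) {
  as_graph_sample(matrix(stats::rnorm(n * f, mean = shift), n, f),
                  random_adjacency(n), y)
}

# A referential recording carrying all 10-20 electrodes needed for the
# 18-pair montage (plus extras), with optional seizure events.
make_referential_recording <- function(dur = 300, fs = 16, events = seizure_events(),
                                       extra_channels = character(), seed = 1) {
  set.seed(seed)
  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
              "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2",
              extra_channels)
  recording(matrix(stats::rnorm(length(labels) * dur * fs), length(labels)),
            fs = fs, channel_labels = labels, events = events)
}

# Micro run configuration: full pipeline shape at a small scale (short
# records via a scaled-down labeling config).
micro_run_config <- function(out_dir, seed = 7, epochs = 3) {
  list(
    seed = seed, out_dir = out_dir,
    synthetic = list(n_subjects = 1, seizures_per_subject = 2,
                     record_s = 760, onset_s = 700, delta = 2, rho = 0.8),
    preprocess = list(preictal_len_s = 600, horizon_s = 60,
                      interictal_margin_s = 600),
    training = list(epochs = epochs, early_stop_patience = Inf),
    pipeline = list(interictal_stride = 1)
  )
}
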