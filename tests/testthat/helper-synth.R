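# Shared fixtures, all generated in code.

# A referential recording over the 19 montage electrodes with random noise.
random_referential <- function(n_samples = 512, fs = 256, seed = 1,
                               source_id = "ref") {
  set.seed(seed)
  recording(matrix(rnorm(19 * n_samples), 19), fs, electrodes_1020(),
            source_id = source_id)
}

# Two long single-channel recordings giving perfectly separable classes:
# high-amplitude 5 Hz rhythm ("ictal") vs low-amplitude noise.
separable_segments <- function(n_per_class = 200, seed = 3, amp = 50,
                               noise_sd = 10) {
  set.seed(seed)
  n <- n_per_class * 1024
  tt <- seq_len(n) / 256
  rec_i <- recording(matrix(amp * sin(2 * pi * 5 * tt) + rnorm(n, sd = noise_sd), 1),
                     256, "ch", source_id = "ict")
  rec_n <- recording(matrix(rnorm(n, sd = noise_sd), 1), 256, "ch",
                     source_id = "int")
  si <- segment_and_label(rec_i,
                          seizure_annotation(rbind(c(0, n_per_class * 4)),
                                             source_id = "ict"),
                          step_samples = 1024)
  sn <- segment_and_label(rec_n, seizure_annotation(NULL, source_id = "int"),
                          step_samples = 1024)
  combine_segment_sets(si, sn)
}

# Small model configuration for fast tests.
fast_config <- function(seed = 5, max_epochs = 10, epoch_batches = 20,
                        batch_size = 16, ...) {
  model_config(seed = seed, max_epochs = max_epochs,
               epoch_batches = epoch_batches, batch_size = batch_size, ...)
}

# The desk-scale synthetic study case: 4 files of 0.25 h, 2 with seizures.
study_case <- function(seed, dominant = "P8-O2", snr = 5) {
  generate_case(synth_config(seed = seed, dominant_derivation = dominant,
                             snr_ictal = snr))
}

run_case_fast <- function(case, channel, seed = 5) {
  run_case(case$recordings, case$annotations,
           channel_policy("single", single_channel = channel),
           model_cfg = fast_config(seed = seed))
}

expect_same_numbers <- function(a, b, tol = 1e-12) {
  expect_equal(a, b, tolerance = tol)
}

# A labeled segment set that is cheap to materialize: fs 16 Hz, 0.5-s windows
# of 8 samples at a 1-sample step; exactly n_ictal ictal windows.
make_tiny_segments <- function(n_ictal = 10, n_interictal = 10000) {
  fs <- 16
  w <- 8
  # w - 1 straddling windows separate the classes; account for them so the
  # set holds exactly the requested counts
  n_total <- n_ictal + n_interictal + 2 * (w - 1)
  rec <- recording(matrix(rnorm(n_total), 1), fs, "ch", source_id = "r")
  ann <- seizure_annotation(rbind(c(0, (w + n_ictal - 1) / fs)),
                            source_id = "r")
  s <- segment_and_label(rec, ann, window_s = w / fs, step_samples = 1)
  stopifnot(sum(s$segments$label == "ictal") == n_ictal,
            sum(s$segments$label == "interictal") == n_interictal)
  s
}
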