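# Preprocessing: 1-30 Hz band-pass, fixed-length windowing with ictal /
# interictal labeling, and class-balanced batch sampling.

#' Band-pass filter specification
#'
#' @param low_hz,high_hz band edges in Hz (defaults 1 and 30, the band that
#'   captures most rhythmic scalp seizure activity from delta to beta).
#' @param order Butterworth order of the underlying filter (default 4).
#' @param zero_phase apply forward-backward (zero-phase) filtering so filtered
#'   features stay aligned with annotated onsets (default TRUE).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 1, high_hz = 30, order = 4, zero_phase = TRUE) {
  stopifnot(low_hz > 0, low_hz < high_hz, order >= 1)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = zero_phase),
            class = "filter_spec")
}

#' Band-pass filter a recording
#'
#' Butterworth band-pass applied per channel; with `zero_phase = TRUE` the
#' filter runs forward and backward (`signal::filtfilt`), squaring its
#' magnitude response and cancelling phase delay.
#'
#' @param rec an `eeg_recording`.
#' @param spec a `filter_spec`.
#' @return the filtered `eeg_recording`.
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  if (spec$high_hz >= rec$fs / 2)
    stop_monoseize("high edge %g Hz >= Nyquist (%g Hz)", spec$high_hz,
                   rec$fs / 2, class = "monoseize_filter_error")
  bf <- signal::butter(spec$order,
                       c(spec$low_hz, spec$high_hz) / (rec$fs / 2),
                       type = "pass")
  out <- rec$signal
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- if (spec$zero_phase) {
      signal::filtfilt(bf, rec$signal[ch, ])
    } else {
      as.numeric(signal::filter(bf, rec$signal[ch, ]))
    }
  }
  recording(out, rec$fs, rec$channel_labels, rec$start_offset, rec$source_id)
}

## ---- Segmentation ----------------------------------------------------------

new_segment_set <- function(sources, fs, window_samples, segments,
                            n_straddling = 0L) {
  structure(list(sources = sources, fs = fs,
                 window_samples = as.integer(window_samples),
                 window_s = window_samples / fs,
                 segments = segments,
                 n_straddling = as.integer(n_straddling)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "<segment_set> %d window(s) of %d samples (%g s) @ %g Hz from %d source(s)\n",
    nrow(x$segments), x$window_samples, x$window_s, x$fs, length(x$sources)))
  cat(sprintf("  ictal: %d, interictal: %d, straddling excluded: %d\n",
              sum(x$segments$label == "ictal"),
              sum(x$segments$label == "interictal"), x$n_straddling))
  invisible(x)
}

#' Number of segments in a segment set
#' @param segs a `segment_set`.
#' @export
n_segments <- function(segs) nrow(segs$segments)

#' Cut a recording into labeled fixed-length windows
#'
#' Windows start at sample 0, `step_samples`, `2 * step_samples`, ... for as
#' long as a full window fits. A window is *ictal* iff it lies entirely inside
#' one annotated interval and *interictal* iff it overlaps no interval;
#' boundary-straddling windows are excluded and counted in `n_straddling`.
#' Time convention: the window starting at sample `s` covers
#' `[s/fs, (s + W)/fs)` seconds, half-open, with `W = round(window_s * fs)`.
#'
#' @param rec an `eeg_recording` (typically band-passed and montaged).
#' @param ann the recording's `seizure_annotation`.
#' @param window_s window length in seconds (default 4, i.e. 1024 samples at
#'   256 Hz).
#' @param step_samples step between window starts in samples (1 reproduces
#'   maximal overlap of 3.996 s at 256 Hz; `fs` gives the 1-s event step).
#' @return a `segment_set`.
#' @export
segment_and_label <- function(rec, ann, window_s = 4, step_samples = 64L) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(ann, "seizure_annotation"))
  step_samples <- as.integer(step_samples)
  stopifnot(step_samples >= 1)
  w <- as.integer(round(window_s * rec$fs))
  t_total <- ncol(rec$signal)
  if (t_total < w)
    stop_monoseize("recording (%d samples) shorter than one window (%d)",
                   t_total, w, class = "monoseize_segment_error")
  starts <- seq.int(0L, t_total - w, by = step_samples)
  t0 <- starts / rec$fs
  t1 <- (starts + w) / rec$fs
  iv <- ann$intervals
  inside <- rep(FALSE, length(starts))
  touching <- rep(FALSE, length(starts))
  for (k in seq_len(nrow(iv))) {
    inside <- inside | (t0 >= iv[k, 1] & t1 <= iv[k, 2])
    touching <- touching | (t0 < iv[k, 2] & iv[k, 1] < t1)
  }
  straddle <- touching & !inside
  label <- ifelse(inside, "ictal", "interictal")
  keep <- !straddle
  segments <- data.frame(source_id = rec$source_id,
                         start_sample = starts[keep],
                         start_s = t0[keep],
                         label = label[keep],
                         stringsAsFactors = FALSE)
  sources <- stats::setNames(list(rec$signal), rec$source_id)
  new_segment_set(sources, rec$fs, w, segments, sum(straddle))
}

#' Concatenate segment sets (matching fs and window length)
#' @param ... `segment_set` objects.
#' @return a single `segment_set` holding all segments.
#' @export
combine_segment_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "segment_set")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1,
            all(vapply(sets, inherits, TRUE, "segment_set")))
  fs <- sets[[1]]$fs
  w <- sets[[1]]$window_samples
  if (!all(vapply(sets, function(s) s$fs == fs && s$window_samples == w, TRUE)))
    stop_monoseize("segment sets differ in fs or window length")
  sources <- do.call(c, unname(lapply(sets, `[[`, "sources")))
  sources <- sources[!duplicated(names(sources))]
  segments <- do.call(rbind, lapply(sets, `[[`, "segments"))
  rownames(segments) <- NULL
  new_segment_set(sources, fs, w, segments,
                  sum(vapply(sets, `[[`, 0L, "n_straddling")))
}

#' Subset a segment set by segment index
#' @param segs a `segment_set`.
#' @param idx integer indices into its segments.
#' @return a `segment_set` restricted to `idx` (sources retained as needed).
#' @export
subset_segment_set <- function(segs, idx) {
  segments <- segs$segments[idx, , drop = FALSE]
  rownames(segments) <- NULL
  new_segment_set(segs$sources[unique(segments$source_id)], segs$fs,
                  segs$window_samples, segments, 0L)
}

#' Materialize segment windows as an array
#'
#' @param segs a `segment_set`.
#' @param idx which segments (default all).
#' @return numeric array, N channels x W samples x length(idx).
#' @export
segment_windows <- function(segs, idx = seq_len(n_segments(segs))) {
  w <- segs$window_samples
  n_ch <- nrow(segs$sources[[1]])
  out <- array(0, c(n_ch, w, length(idx)))
  seg <- segs$segments
  for (j in seq_along(idx)) {
    row <- idx[j]
    s0 <- seg$start_sample[row]
    out[, , j] <- segs$sources[[seg$source_id[row]]][, (s0 + 1):(s0 + w),
                                                     drop = FALSE]
  }
  out
}

## ---- Balanced batches ------------------------------------------------------

#' Balanced batch plan
#'
#' @param batch_size even total batch size; each batch holds exactly
#'   `batch_size/2` ictal and `batch_size/2` interictal segments.
#' @param epoch_batches batches per epoch.
#' @param seed RNG seed for the sampling stream.
#' @return an object of class `batch_plan`.
#' @export
batch_plan <- function(batch_size = 32L, epoch_batches = 50L, seed = 1L) {
  batch_size <- as.integer(batch_size)
  if (batch_size < 2 || batch_size %% 2 != 0)
    stop_monoseize("batch_size must be even and >= 2")
  structure(list(batch_size = batch_size,
                 epoch_batches = as.integer(epoch_batches),
                 seed = as.integer(seed)),
            class = "batch_plan")
}

# Per-class sampling pools: the majority class is drawn without replacement
# until exhausted, then reshuffled; the minority class is resampled (with
# replacement across epochs) the same way but cycles much faster. Both reduce
# to "shuffle, deal, reshuffle", which realizes exactly that contract.
make_pool <- function(idx) {
  pool <- sample(idx)
  pos <- 0L
  function(n) {
    out <- integer(0)
    while (n > 0L) {
      if (pos >= length(pool)) {
        pool <<- sample(idx)
        pos <<- 0L
      }
      take <- min(n, length(pool) - pos)
      out <- c(out, pool[(pos + 1L):(pos + take)])
      pos <<- pos + take
      n <- n - take
    }
    out
  }
}

# Draw one epoch of balanced batch index pairs; assumes the RNG is already
# seeded by the caller. Returns a list of integer vectors (each a batch).
balanced_epoch_indices <- function(labels, batch_size, epoch_batches,
                                   ictal_pool = NULL, inter_pool = NULL) {
  ict <- which(labels == "ictal")
  int <- which(labels == "interictal")
  if (length(ict) == 0 || length(int) == 0)
    stop_monoseize("both classes must be present for balanced batches",
                   class = "monoseize_batch_error")
  half <- batch_size %/% 2L
  if (is.null(ictal_pool)) ictal_pool <- make_pool(ict)
  if (is.null(inter_pool)) inter_pool <- make_pool(int)
  lapply(seq_len(epoch_batches),
         function(i) c(ictal_pool(half), inter_pool(half)))
}

#' Class-balanced batch stream
#'
#' Materializes `epoch_batches` batches, each holding `batch_size/2` randomly
#' selected ictal and `batch_size/2` interictal segments. The minority class
#' is oversampled by cycling with reshuffling; deterministic under the plan's
#' seed.
#'
#' @param segs a `segment_set` containing both classes.
#' @param plan a `batch_plan`.
#' @return list of batches; each batch is `list(windows, labels, idx)` with
#'   `windows` an N x W x batch_size array.
#' @export
balanced_batches <- function(segs, plan = batch_plan()) {
  stopifnot(inherits(segs, "segment_set"), inherits(plan, "batch_plan"))
  idx_batches <- with_seed(plan$seed,
    balanced_epoch_indices(segs$segments$label, plan$batch_size,
                           plan$epoch_batches))
  lapply(idx_batches, function(ii)
    list(windows = segment_windows(segs, ii),
         labels = segs$segments$label[ii],
         idx = ii))
}
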