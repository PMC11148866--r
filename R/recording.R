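# Recording container, bipolar montage derivation and channel-subset policies.
#
# A recording holds an N x T signal matrix in microvolts together with ordered
# channel labels and the sampling rate. Channels are either referential 10-20
# electrodes (Fp1, F3, ...) or bipolar derivations named "A-B". All label
# matching is case-insensitive with surrounding whitespace stripped, because
# real EDF headers are inconsistent about both.

#' Construct an EEG recording
#'
#' @param signal numeric matrix, N channels x T samples, microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of length N.
#' @param start_offset seconds from the start of the session (default 0).
#' @param source_id file identity string used to pair recordings with
#'   annotations.
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(signal, fs, channel_labels,
                      start_offset = 0, source_id = "recording") {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  stopifnot(is.matrix(signal), is.numeric(signal))
  if (nrow(signal) < 1 || ncol(signal) < 1)
    stop_monoseize("recording needs at least 1 channel and 1 sample")
  if (!all(is.finite(signal)))
    stop_monoseize("recording contains non-finite samples")
  if (length(channel_labels) != nrow(signal))
    stop_monoseize("channel_labels length (%d) != number of signal rows (%d)",
                   length(channel_labels), nrow(signal))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_monoseize("fs must be a positive scalar")
  structure(
    list(channel_labels = as.character(channel_labels),
         fs = as.numeric(fs),
         signal = signal,
         start_offset = as.numeric(start_offset),
         source_id = as.character(source_id)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$source_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @export
duration_s <- function(rec) ncol(rec$signal) / rec$fs

norm_label <- function(x) toupper(trimws(x))

# Resolve requested labels against a recording, case-insensitively; first
# occurrence wins for duplicated header labels (CHB-MIT "T8-P8-0/-1" style).
match_labels <- function(wanted, available, what = "channel") {
  idx <- match(norm_label(wanted), norm_label(available))
  if (anyNA(idx)) {
    stop_monoseize("missing %s label(s): %s", what,
                   paste(wanted[is.na(idx)], collapse = ", "),
                   class = "monoseize_missing_channel")
  }
  idx
}

## ---- Montage ---------------------------------------------------------------

#' Bipolar montage specification
#'
#' An ordered list of (anode, cathode) electrode pairs. Each derived channel is
#' anode minus cathode and is displayed as `"anode-cathode"`.
#'
#' @param anodes,cathodes character vectors of equal length of 10-20
#'   electrode labels.
#' @return an object of class `montage_spec`.
#' @export
montage_spec <- function(anodes, cathodes) {
  stopifnot(length(anodes) == length(cathodes), length(anodes) >= 1)
  display <- paste0(anodes, "-", cathodes)
  if (anyDuplicated(norm_label(display)))
    stop_monoseize("duplicate montage display names")
  structure(list(anodes = as.character(anodes),
                 cathodes = as.character(cathodes),
                 display = display),
            class = "montage_spec")
}

#' The 18-derivation longitudinal bipolar montage
#'
#' Standard double-banana ordering: left parasagittal, right parasagittal,
#' left temporal, right temporal, midline.
#' @return a `montage_spec` with 18 derivations.
#' @export
montage_18 <- function() {
  pairs <- c("Fp1-F3", "F3-C3", "C3-P3", "P3-O1",
             "Fp2-F4", "F4-C4", "C4-P4", "P4-O2",
             "Fp1-F7", "F7-T7", "T7-P7", "P7-O1",
             "Fp2-F8", "F8-T8", "T8-P8", "P8-O2",
             "Fz-Cz", "Cz-Pz")
  parts <- strsplit(pairs, "-", fixed = TRUE)
  montage_spec(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

#' The four wearable-candidate derivations, in canonical order
#'
#' Two forehead channels and two behind-the-ear (parieto-occipital) channels,
#' the positions where wearable electrodes attach most easily.
#' @return character vector of display names.
#' @export
wearable_channels <- function() c("Fp1-F3", "Fp2-F4", "P7-O1", "P8-O2")

#' Derive bipolar channels from a referential recording
#'
#' Each output channel i is `anode_i - cathode_i`, labeled `"anode-cathode"`,
#' in the order of the montage spec. If every display name of the montage is
#' already present as a channel label (an already-bipolar recording), the
#' channels are selected as-is instead of re-derived.
#'
#' @param rec an `eeg_recording` with referential electrode channels.
#' @param montage a `montage_spec` (default the full 18-derivation montage).
#' @return an `eeg_recording` with derived bipolar channels.
#' @export
apply_montage <- function(rec, montage = montage_18()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "montage_spec"))
  have <- norm_label(rec$channel_labels)
  if (all(norm_label(montage$display) %in% have)) {
    idx <- match(norm_label(montage$display), have)
    return(recording(rec$signal[idx, , drop = FALSE], rec$fs, montage$display,
                     rec$start_offset, rec$source_id))
  }
  ai <- match_labels(montage$anodes, rec$channel_labels, "electrode")
  ci <- match_labels(montage$cathodes, rec$channel_labels, "electrode")
  sig <- rec$signal[ai, , drop = FALSE] - rec$signal[ci, , drop = FALSE]
  recording(sig, rec$fs, montage$display, rec$start_offset, rec$source_id)
}

## ---- Channel subset policy -------------------------------------------------

#' Channel-subset policy: 18-channel, 4-channel wearable, or single channel
#'
#' @param mode one of `"full18"`, `"wearable4"`, `"single"`.
#' @param single_channel for `mode = "single"`, one of the four
#'   wearable-candidate display names (`wearable_channels()`).
#' @return an object of class `channel_policy`.
#' @export
channel_policy <- function(mode = c("full18", "wearable4", "single"),
                           single_channel = NULL) {
  mode <- match.arg(mode)
  if (mode == "single") {
    if (is.null(single_channel))
      stop_monoseize("mode 'single' requires single_channel")
    ok <- norm_label(single_channel) %in% norm_label(wearable_channels())
    if (length(single_channel) != 1 || !ok)
      stop_monoseize(
        "single_channel must be one of %s",
        paste(wearable_channels(), collapse = ", "),
        class = "monoseize_policy_error")
  } else if (!is.null(single_channel)) {
    stop_monoseize("single_channel is only meaningful with mode 'single'")
  }
  structure(list(mode = mode, single_channel = single_channel),
            class = "channel_policy")
}

#' Display names selected by a policy
#' @param policy a `channel_policy`.
#' @return character vector of bipolar display names, in canonical order.
#' @export
policy_channels <- function(policy) {
  stopifnot(inherits(policy, "channel_policy"))
  switch(policy$mode,
         full18 = montage_18()$display,
         wearable4 = wearable_channels(),
         single = policy$single_channel)
}

#' Select the channel subset named by a policy from a montaged recording
#'
#' @param rec a bipolar (montaged) `eeg_recording`.
#' @param policy a `channel_policy`.
#' @return an `eeg_recording` with 18, 4 or 1 channels in canonical order.
#' @export
select_channels <- function(rec, policy) {
  stopifnot(inherits(rec, "eeg_recording"))
  wanted <- policy_channels(policy)
  idx <- match_labels(wanted, rec$channel_labels)
  recording(rec$signal[idx, , drop = FALSE], rec$fs, wanted,
            rec$start_offset, rec$source_id)
}
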