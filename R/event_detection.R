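# Event-level detection: sliding-window ictal probabilities over a continuous
# recording, Savitzky-Golay smoothing, threshold/run-length event extraction
# with interval merging, overlap matching against annotations, and
# sensitivity / false-alarm-rate / latency scoring.

#' Probability trace over a continuous recording
#'
#' @param times window start times in seconds (strictly increasing, constant
#'   step).
#' @param probs ictal probabilities in \[0, 1\], one per window.
#' @param source_id recording identity.
#' @param step_s step between windows (default 1 s).
#' @param window_s window length (default 4 s).
#' @return an object of class `probability_trace`.
#' @export
probability_trace <- function(times, probs, source_id = "recording",
                              step_s = 1, window_s = 4) {
  stopifnot(length(times) == length(probs), length(probs) >= 1)
  if (any(probs < -1e-9 | probs > 1 + 1e-9))
    stop_monoseize("probabilities outside [0, 1]")
  if (length(times) > 1) {
    d <- diff(times)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-9)
      stop_monoseize("times must be strictly increasing with constant step")
  }
  structure(list(times = as.numeric(times),
                 probs = pmin(pmax(as.numeric(probs), 0), 1),
                 source_id = as.character(source_id),
                 step_s = step_s, window_s = window_s),
            class = "probability_trace")
}

#' Sliding-window ictal probabilities for a whole recording
#'
#' Classifies 4-s windows at a 1-s step across the recording: one probability
#' per start 0, 1, ..., duration - 4 s (so an integer-duration recording of
#' `D` seconds yields `D - 3` steps).
#'
#' @param model a trained `seizure_cnn`.
#' @param rec the continuous `eeg_recording` (already montaged/filtered to
#'   the model's channel set).
#' @param step_s step between window starts in seconds (default 1).
#' @return a `probability_trace`.
#' @export
sliding_probabilities <- function(model, rec, step_s = 1) {
  stopifnot(inherits(model, "seizure_cnn"), inherits(rec, "eeg_recording"))
  w <- model$input_samples
  if (ncol(rec$signal) < w)
    stop_monoseize("recording (%d samples) shorter than one window (%d)",
                   ncol(rec$signal), w, class = "monoseize_segment_error")
  step <- as.integer(round(step_s * rec$fs))
  segs <- segment_and_label(rec, seizure_annotation(source_id = rec$source_id),
                            window_s = w / rec$fs, step_samples = step)
  probs <- numeric(n_segments(segs))
  chunk <- max(1L, 4096L %/% model$n_channels)
  for (s in seq.int(1L, length(probs), by = chunk)) {
    e <- min(s + chunk - 1L, length(probs))
    probs[s:e] <- predict_proba(model, segment_windows(segs, s:e))
  }
  probability_trace(segs$segments$start_s, probs, rec$source_id,
                    step_s = step_s, window_s = w / rec$fs)
}

#' Event post-processing parameters
#'
#' @param Th probability threshold; steps with smoothed probability strictly
#'   above `Th` are candidate ictal steps (tuned over 0.2-0.9).
#' @param L minimum run length in steps (tuned over 5-10).
#' @param merge_gap_s events closer than this gap are merged (default 10 s).
#' @param sg_window,sg_order Savitzky-Golay window length and polynomial
#'   order (defaults 10 and 3).
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(Th = 0.5, L = 5L, merge_gap_s = 10,
                             sg_window = 10L, sg_order = 3L) {
  stopifnot(Th > 0, Th < 1, L >= 1, merge_gap_s >= 0,
            sg_order < sg_window, sg_order >= 0)
  structure(list(Th = Th, L = as.integer(L), merge_gap_s = merge_gap_s,
                 sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order)),
            class = "detection_params")
}

## ---- Savitzky-Golay --------------------------------------------------------

# Weights of the local least-squares polynomial fit evaluated at offset 0:
# first row of (X'X)^{-1} X' for the Vandermonde X of the window offsets.
savgol_weights <- function(offsets, order) {
  X <- outer(offsets, 0:order, `^`)
  qr.solve(crossprod(X), t(X))[1, ]
}

#' Savitzky-Golay smoothing of a probability trace
#'
#' Each point is replaced by the value at that point of the least-squares
#' polynomial of degree `sg_order` fitted over a window of `sg_window`
#' samples. The default even window of 10 is split asymmetrically (5 samples
#' left of the point, 4 right); near the edges the window is truncated to the
#' available samples. Output is clipped to \[0, 1\].
#'
#' @param trace a `probability_trace` of length >= `sg_window`.
#' @param params a `detection_params` (uses `sg_window`, `sg_order`).
#' @param clip clip the smoothed values to \[0, 1\] (default TRUE).
#' @return the smoothed `probability_trace`.
#' @export
savgol_smooth <- function(trace, params = detection_params(), clip = TRUE) {
  stopifnot(inherits(trace, "probability_trace"))
  w <- params$sg_window
  ord <- params$sg_order
  n <- length(trace$probs)
  if (n < w)
    stop_monoseize("trace length %d shorter than smoothing window %d", n, w,
                   class = "monoseize_smooth_error")
  left <- ceiling((w - 1) / 2)           # 5 for the even default window of 10
  right <- w - 1L - left                 # 4
  x <- trace$probs
  out <- numeric(n)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    lo <- max(1L, i - left)
    hi <- min(n, i + right)
    offsets <- (lo:hi) - i
    key <- paste0(offsets[1], ":", offsets[length(offsets)])
    wts <- cache[[key]]
    if (is.null(wts)) {
      wts <- savgol_weights(offsets, min(ord, length(offsets) - 1L))
      cache[[key]] <- wts
    }
    out[i] <- sum(wts * x[lo:hi])
  }
  if (clip) out <- pmin(pmax(out, 0), 1)
  trace$probs <- out
  trace
}

## ---- Event extraction and matching -----------------------------------------

#' Detected seizure events
#'
#' @param intervals numeric n x 2 matrix of `[onset, offset)` seconds.
#' @param source_id recording identity.
#' @return an object of class `event_set` (sorted, non-overlapping).
#' @export
event_set <- function(intervals = NULL, source_id = "recording") {
  ann <- seizure_annotation(intervals, source_id)
  structure(list(intervals = ann$intervals, source_id = ann$source_id),
            class = c("event_set", "seizure_annotation"))
}

#' Extract seizure events from a smoothed probability trace
#'
#' Maximal runs of consecutive steps with probability strictly above `Th` and
#' length at least `L` become events covering `[first window start,
#' last window start + window_s)`. Events whose gap to the previous event is
#' less than `merge_gap_s` are merged, transitively.
#'
#' @param trace a (smoothed) `probability_trace`.
#' @param params a `detection_params`.
#' @return an `event_set`.
#' @export
extract_events <- function(trace, params) {
  stopifnot(inherits(trace, "probability_trace"),
            inherits(params, "detection_params"))
  above <- trace$probs > params$Th
  if (!any(above)) return(event_set(NULL, trace$source_id))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$L
  if (!any(keep)) return(event_set(NULL, trace$source_id))
  iv <- cbind(trace$times[starts[keep]],
              trace$times[ends[keep]] + trace$window_s)
  merged <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[k, 1] - merged[last, 2] < params$merge_gap_s) {
      merged[last, 2] <- max(merged[last, 2], iv[k, 2])
    } else {
      merged <- rbind(merged, iv[k, ])
    }
  }
  event_set(merged, trace$source_id)
}

overlaps <- function(a_on, a_off, b_on, b_off) a_on < b_off & b_on < a_off

#' Match detected events against annotated seizures
#'
#' An annotated seizure with at least one overlapping detected event is
#' correct (latency = earliest overlapping detected onset minus annotated
#' onset, possibly negative); with none it is missed. A detected event
#' overlapping no annotated seizure is a false alarm; one overlapping two
#' seizures credits both and is not a false alarm.
#'
#' @param detected an `event_set`.
#' @param annotated a `seizure_annotation` for the same recording.
#' @return list with counts `correct`, `missed`, `false_alarms`, vector
#'   `latencies_s`, and `n_annotated`, `n_detected`.
#' @export
match_events <- function(detected, annotated) {
  stopifnot(inherits(detected, "event_set"),
            inherits(annotated, "seizure_annotation"))
  if (!identical(detected$source_id, annotated$source_id))
    stop_monoseize("source mismatch: detected '%s' vs annotated '%s'",
                   detected$source_id, annotated$source_id,
                   class = "monoseize_match_error")
  det <- detected$intervals
  ann <- annotated$intervals
  lat <- numeric(0)
  correct <- 0L
  det_hit <- rep(FALSE, nrow(det))
  for (k in seq_len(nrow(ann))) {
    hit <- which(overlaps(det[, 1], det[, 2], ann[k, 1], ann[k, 2]))
    if (length(hit) > 0) {
      correct <- correct + 1L
      det_hit[hit] <- TRUE
      lat <- c(lat, unname(min(det[hit, 1]) - ann[k, 1]))
    }
  }
  list(correct = correct,
       missed = nrow(ann) - correct,
       false_alarms = sum(!det_hit),
       latencies_s = lat,
       n_annotated = nrow(ann),
       n_detected = nrow(det))
}

#' Event-level performance metrics
#'
#' @param match result of [match_events()].
#' @param recording_hours length of the scored recording in hours.
#' @return list with `sensitivity` (%; 100 when there are no annotated
#'   seizures and none missed), `far` (false alarms per hour),
#'   `mean_latency_s` (NA when nothing was detected correctly), and
#'   `recording_hours`.
#' @export
event_metrics <- function(match, recording_hours) {
  if (!is.numeric(recording_hours) || recording_hours <= 0)
    stop_monoseize("recording_hours must be positive")
  sens <- if (match$n_annotated == 0) 100 else
    100 * match$correct / match$n_annotated
  list(sensitivity = sens,
       far = match$false_alarms / recording_hours,
       mean_latency_s = if (length(match$latencies_s) > 0)
         mean(match$latencies_s) else NA_real_,
       recording_hours = recording_hours)
}

#' Tune the threshold and run-length on training traces
#'
#' Evaluates every (Th, L) grid point on the supplied (already smoothed or
#' raw) traces against their annotations, pooling correct/missed/false-alarm
#' counts across traces. Returns the point maximizing pooled event
#' sensitivity, ties broken by minimal pooled FAR, then larger L, then larger
#' Th (the most conservative of the equally sensitive settings, minimizing
#' false alarms first as the reference protocol prescribes). Deterministic.
#'
#' @param traces list of `probability_trace` objects (training folds).
#' @param annotations list of matching `seizure_annotation`s.
#' @param Th_grid,L_grid candidate thresholds and run lengths.
#' @param params base `detection_params` supplying smoothing and merge
#'   settings.
#' @param smooth apply [savgol_smooth()] to each trace first (default TRUE).
#' @return the selected `detection_params`.
#' @export
tune_postprocessing <- function(traces, annotations,
                                Th_grid = seq(0.2, 0.9, by = 0.1),
                                L_grid = 5:10,
                                params = detection_params(),
                                smooth = TRUE) {
  stopifnot(length(traces) == length(annotations), length(traces) >= 1,
            length(Th_grid) >= 1, length(L_grid) >= 1)
  if (sum(vapply(annotations, n_seizures, 0L)) < 1)
    stop_monoseize("tuning needs at least one annotated seizure",
                   class = "monoseize_tune_error")
  if (smooth)
    traces <- lapply(traces, savgol_smooth, params = params)
  hours <- vapply(traces, function(tr)
    (tr$times[length(tr$times)] + tr$window_s) / 3600, 0)
  best <- NULL
  for (Th in Th_grid) for (L in L_grid) {
    cand <- detection_params(Th = Th, L = L,
                             merge_gap_s = params$merge_gap_s,
                             sg_window = params$sg_window,
                             sg_order = params$sg_order)
    correct <- missed <- fa <- 0L
    for (i in seq_along(traces)) {
      m <- match_events(extract_events(traces[[i]], cand), annotations[[i]])
      correct <- correct + m$correct
      missed <- missed + m$missed
      fa <- fa + m$false_alarms
    }
    sens <- if (correct + missed == 0) 100 else 100 * correct / (correct + missed)
    far <- fa / sum(hours)
    score <- c(sens, -far, L, Th)
    if (is.null(best) || isTRUE(vector_gt(score, best$score))) {
      best <- list(score = score, params = cand)
    }
  }
  best$params
}

# lexicographic strictly-greater with tolerance on the numeric entries
vector_gt <- function(a, b, tol = 1e-12) {
  for (i in seq_along(a)) {
    if (a[i] > b[i] + tol) return(TRUE)
    if (a[i] < b[i] - tol) return(FALSE)
  }
  FALSE
}

#' Export a probability trace as CSV (time_s, prob)
#' @param trace a `probability_trace`.
#' @param path output path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times, prob = trace$probs),
                   path, row.names = FALSE)
  invisible(path)
}
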