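# Patient-specific evaluation protocol: file-wise k-fold plans, 7:2:1
# train/validation/test splits, segment-level metrics (including rank-based
# AUC), the full per-case pipeline, and manifest summaries.

#' File-wise k-fold plan
#'
#' k equals the number of files with at least one annotated seizure; each
#' such file is the event-level test file of exactly one fold, with the other
#' seizure files on the training side. Seizure-free files contribute
#' interictal data to every fold.
#'
#' @param annotations named list of `seizure_annotation`s, one per file
#'   (names or `source_id`s identify the files).
#' @return an object of class `fold_plan`: list with `k`, `folds` (list of
#'   `list(test_file, train_files)`), and `seizure_free_files`.
#' @export
make_fold_plan <- function(annotations) {
  stopifnot(length(annotations) >= 1,
            all(vapply(annotations, inherits, TRUE, "seizure_annotation")))
  ids <- names(annotations)
  if (is.null(ids))
    ids <- vapply(annotations, `[[`, "", "source_id")
  nsz <- vapply(annotations, n_seizures, 0L)
  seiz <- ids[nsz > 0]
  free <- ids[nsz == 0]
  if (length(seiz) == 0)
    stop_monoseize("no files contain seizures", class = "monoseize_fold_error")
  if (length(seiz) == 1)
    warning("only one seizure file: k = 1, no held-out training seizures")
  folds <- lapply(seiz, function(f)
    list(test_file = f, train_files = setdiff(seiz, f)))
  structure(list(k = length(seiz), folds = folds,
                 seizure_free_files = free),
            class = "fold_plan")
}

#' Split a segment set 7:2:1 into train/validation/test
#'
#' `random_segments` mode assigns shuffled segments to parts in exact 70/20/10
#' proportion (largest-remainder rounding). `grouped_blocks` mode (the
#' default) assigns contiguous time blocks per source file and then drops the
#' few boundary segments of a later part that still overlap the previous part
#' in time, so overlapping windows never leak across parts.
#'
#' @param segs a `segment_set`.
#' @param ratios positive weights for train/validation/test (default 7:2:1).
#' @param mode `"grouped_blocks"` or `"random_segments"`.
#' @param seed RNG seed (random mode only).
#' @return list of three `segment_set`s: `train`, `val`, `test`.
#' @export
split_train_val_test <- function(segs, ratios = c(7, 2, 1),
                                 mode = c("grouped_blocks", "random_segments"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(segs, "segment_set"), length(ratios) == 3,
            all(ratios > 0))
  n <- n_segments(segs)
  if (n < 3)
    stop_monoseize("too few segments (%d) to split", n,
                   class = "monoseize_split_error")
  frac <- ratios / sum(ratios)
  if (mode == "random_segments") {
    target <- n * frac
    sizes <- floor(target)
    rem <- order(target - sizes, decreasing = TRUE)
    short <- n - sum(sizes)
    if (short > 0) sizes[rem[seq_len(short)]] <- sizes[rem[seq_len(short)]] + 1
    idx <- with_seed(seed, sample.int(n))
    parts <- split(idx, rep(1:3, times = sizes))
  } else {
    # contiguous time blocks per (source, class) group; ictal and interictal
    # windows of one source never overlap in time (straddlers are excluded),
    # so grouping by class preserves the zero-leakage guarantee while keeping
    # both classes represented in every part whenever counts allow
    seg <- segs$segments
    parts <- list(integer(0), integer(0), integer(0))
    for (grp in unique(paste(seg$source_id, seg$label))) {
      rows <- which(paste(seg$source_id, seg$label) == grp)
      rows <- rows[order(seg$start_sample[rows])]
      ns <- length(rows)
      if (ns < 3) {                       # too small to split: train only
        parts[[1]] <- c(parts[[1]], rows)
        next
      }
      c1 <- max(1L, round(frac[1] * ns))
      c2 <- max(c1 + 1L, round((frac[1] + frac[2]) * ns))
      c2 <- min(c2, ns - 1L)
      blocks <- list(rows[seq_len(c1)],
                     if (c2 > c1) rows[(c1 + 1L):c2] else integer(0),
                     if (ns > c2) rows[(c2 + 1L):ns] else integer(0))
      # purge later-part segments overlapping any earlier block in time
      for (p in 2:3) {
        prev <- unlist(blocks[seq_len(p - 1)])
        if (length(prev) == 0 || length(blocks[[p]]) == 0) next
        cutoff <- max(seg$start_s[prev]) + segs$window_s
        blocks[[p]] <- blocks[[p]][seg$start_s[blocks[[p]]] >= cutoff]
      }
      for (p in 1:3) parts[[p]] <- c(parts[[p]], blocks[[p]])
    }
  }
  if (any(lengths(parts) == 0))
    stop_monoseize("a split part is empty; too few segments",
                   class = "monoseize_split_error")
  list(train = subset_segment_set(segs, parts[[1]]),
       val = subset_segment_set(segs, parts[[2]]),
       test = subset_segment_set(segs, parts[[3]]))
}

#' Segment-level classification metrics
#'
#' Sensitivity = correctly classified ictal / true ictal; specificity =
#' correctly classified interictal / true interictal; accuracy = correct /
#' all, each in percent at the `prob >= threshold` rule. AUC uses the rank
#' (Mann-Whitney) formulation with midranks for ties.
#'
#' @param labels character vector of `"ictal"` / `"interictal"` truth labels.
#' @param probs ictal probabilities.
#' @param threshold classification threshold (default 0.5; ties ictal).
#' @return list with `sensitivity`, `specificity`, `accuracy`, `auc`, all in
#'   percent.
#' @export
segment_level_metrics <- function(labels, probs, threshold = 0.5) {
  stopifnot(length(labels) == length(probs))
  pos <- labels == "ictal"
  if (!any(pos) || all(pos))
    stop_monoseize("both classes required for segment-level metrics",
                   class = "monoseize_metric_error")
  pred <- probs >= threshold
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(probs)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(sensitivity = 100 * sum(pred & pos) / n1,
       specificity = 100 * sum(!pred & !pos) / n0,
       accuracy = 100 * mean(pred == pos),
       auc = 100 * auc)
}

## ---- per-case orchestration ------------------------------------------------

montage_from_channels <- function(display) {
  parts <- strsplit(display, "-", fixed = TRUE)
  montage_spec(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

prepare_recording <- function(rec, policy, fspec) {
  rec <- apply_montage(rec, montage_from_channels(policy_channels(policy)))
  bandpass(rec, fspec)
}

#' Run the full patient-specific protocol on one case
#'
#' For each fold of the file-wise k-fold plan: gather ictal segments from the
#' k-1 training seizure files and interictal segments from all seizure-free
#' files, split 7:2:1 (grouped blocks), train the classifier, score the
#' held-out split at segment level, tune (Th, L) on the training files'
#' continuous traces, and score the held-out file at event level.
#'
#' @param recordings named list of `eeg_recording`s (one per file).
#' @param annotations named list of matching `seizure_annotation`s.
#' @param policy a `channel_policy`.
#' @param model_cfg a `model_config`.
#' @param det_params base `detection_params` (smoothing and merge settings).
#' @param fspec a `filter_spec`.
#' @param train_step_samples window step for training segmentation (event
#'   traces always use the 1-s step).
#' @param Th_grid,L_grid post-processing tuning grids.
#' @param split_mode 7:2:1 split granularity, see [split_train_val_test()].
#' @param verbose print per-fold progress.
#' @return an object of class `case_result`: list with `folds` (per-fold data
#'   frame), `summary` (mean and SD per metric), `k`, and `policy`.
#' @export
run_case <- function(recordings, annotations, policy,
                     model_cfg = model_config(),
                     det_params = detection_params(),
                     fspec = filter_spec(),
                     train_step_samples = 256L,
                     Th_grid = seq(0.2, 0.9, by = 0.1), L_grid = 5:10,
                     split_mode = "grouped_blocks",
                     verbose = FALSE) {
  stopifnot(length(recordings) == length(annotations))
  ids <- names(recordings)
  if (is.null(ids)) {
    ids <- vapply(recordings, `[[`, "", "source_id")
    names(recordings) <- ids
    names(annotations) <- ids
  }
  plan <- make_fold_plan(annotations)
  prepped <- lapply(recordings, prepare_recording, policy = policy,
                    fspec = fspec)
  fold_rows <- list()
  for (fi in seq_len(plan$k)) {
    fold <- plan$folds[[fi]]
    if (verbose)
      message(sprintf("fold %d/%d: held-out %s", fi, plan$k, fold$test_file))
    train_ids <- fold$train_files
    if (length(train_ids) == 0) train_ids <- fold$test_file  # k = 1 fallback
    seiz_sets <- lapply(train_ids, function(f) {
      s <- segment_and_label(prepped[[f]], annotations[[f]],
                             step_samples = train_step_samples)
      subset_segment_set(s, which(s$segments$label == "ictal"))
    })
    free_sets <- lapply(plan$seizure_free_files, function(f)
      segment_and_label(prepped[[f]], annotations[[f]],
                        step_samples = train_step_samples))
    segs <- combine_segment_sets(c(seiz_sets, free_sets))
    split <- split_train_val_test(segs, mode = split_mode,
                                  seed = model_cfg$seed)
    model <- build_model(model_cfg, n_channels = nrow(prepped[[1]]$signal))
    model <- train_model(model, split$train, split$val)
    test_probs <- predict_proba(model, segment_windows(split$test))
    seg_ok <- length(unique(split$test$segments$label)) == 2
    seg_m <- if (seg_ok) {
      segment_level_metrics(split$test$segments$label, test_probs)
    } else {
      # flagged, never silently dropped: a degenerate test split (one class)
      # yields NA segment metrics while event-level scoring proceeds
      list(sensitivity = NA_real_, specificity = NA_real_,
           accuracy = NA_real_, auc = NA_real_)
    }
    tune_traces <- lapply(train_ids, function(f)
      sliding_probabilities(model, prepped[[f]]))
    tuned <- tune_postprocessing(tune_traces, annotations[train_ids],
                                 Th_grid = Th_grid, L_grid = L_grid,
                                 params = det_params)
    held <- prepped[[fold$test_file]]
    trace <- savgol_smooth(sliding_probabilities(model, held), tuned)
    match <- match_events(extract_events(trace, tuned),
                          annotations[[fold$test_file]])
    ev <- event_metrics(match, duration_s(held) / 3600)
    fold_rows[[fi]] <- data.frame(
      fold = fi, test_file = fold$test_file,
      seg_sensitivity = seg_m$sensitivity, seg_specificity = seg_m$specificity,
      seg_accuracy = seg_m$accuracy, seg_auc = seg_m$auc,
      ev_sensitivity = ev$sensitivity, far = ev$far,
      mean_latency_s = ev$mean_latency_s,
      correct = match$correct, missed = match$missed,
      false_alarms = match$false_alarms,
      recording_hours = ev$recording_hours,
      Th = tuned$Th, L = tuned$L,
      epochs = nrow(model$history),
      seg_metrics_ok = seg_ok,
      stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, fold_rows)
  metric_cols <- c("seg_sensitivity", "seg_specificity", "seg_accuracy",
                   "seg_auc", "ev_sensitivity", "far", "mean_latency_s",
                   "correct", "missed", "false_alarms")
  summary <- do.call(rbind, lapply(metric_cols, function(mc) {
    ms <- mean_sd(folds[[mc]])
    data.frame(metric = mc, mean = ms["mean"], sd = ms["sd"],
               row.names = NULL)
  }))
  structure(list(folds = folds, summary = summary, k = plan$k,
                 policy = policy),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result> %d fold(s), policy %s%s\n", x$k, x$policy$mode,
              if (!is.null(x$policy$single_channel))
                paste0(" (", x$policy$single_channel, ")") else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

## ---- manifest --------------------------------------------------------------

#' The 13-case study manifest
#'
#' Per-case patient information of the reference cohort: age, sex, seizure
#' counts and lengths, recording hours and the neurologist-assigned
#' single channel. Shipped as CSV in `extdata`.
#'
#' @return data frame with one row per case.
#' @export
chbmit_manifest <- function() {
  path <- system.file("extdata", "chbmit_case_manifest.csv",
                      package = "monoseize", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Summarize a case manifest: totals and per-case means with SD
#'
#' Totals are sums over cases (seizure count, total seizure seconds,
#' recording hours). Per-case means use the sample SD (n-1). The per-seizure
#' length statistic pools all seizures: its mean is total seizure seconds /
#' total seizures, and its SD combines the per-case means and SDs into the
#' pooled sample SD over all seizures.
#'
#' @param manifest data frame with columns `n_seizures`,
#'   `mean_seizure_length_s`, `sd_seizure_length_s`, `total_seizure_length_s`,
#'   `recording_length_h` and optionally `age_years`.
#' @return list with `totals` and `means` (data frame metric/mean/sd),
#'   including mean ictal and interictal hours per case.
#' @export
summarize_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1)
  need <- c("n_seizures", "mean_seizure_length_s", "total_seizure_length_s",
            "recording_length_h")
  if (!all(need %in% names(manifest)))
    stop_monoseize("manifest lacks columns: %s",
                   paste(setdiff(need, names(manifest)), collapse = ", "))
  n <- manifest$n_seizures
  tot_seiz <- sum(n)
  tot_len <- sum(manifest$total_seizure_length_s)
  pooled_mean <- tot_len / tot_seiz
  pooled_sd <- if (tot_seiz > 1 && "sd_seizure_length_s" %in% names(manifest)) {
    ss <- sum((n - 1) * manifest$sd_seizure_length_s^2 +
                n * (manifest$mean_seizure_length_s - pooled_mean)^2)
    sqrt(ss / (tot_seiz - 1))
  } else NA_real_
  ictal_h <- manifest$total_seizure_length_s / 3600
  rows <- list(
    c("n_seizures", mean_sd(n)),
    c("seizure_length_s", pooled_mean, pooled_sd),
    c("total_seizure_length_s", mean_sd(manifest$total_seizure_length_s)),
    c("recording_length_h", mean_sd(manifest$recording_length_h)),
    c("ictal_h", mean_sd(ictal_h)),
    c("interictal_h", mean_sd(manifest$recording_length_h - ictal_h)))
  if ("age_years" %in% names(manifest))
    rows <- c(rows, list(c("age_years", mean_sd(manifest$age_years))))
  means <- data.frame(
    metric = vapply(rows, `[`, "", 1),
    mean = as.numeric(vapply(rows, `[`, "", 2)),
    sd = as.numeric(vapply(rows, `[`, "", 3)),
    stringsAsFactors = FALSE)
  list(totals = list(n_seizures = tot_seiz,
                     total_seizure_length_s = tot_len,
                     recording_length_h = sum(manifest$recording_length_h)),
       means = means)
}
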