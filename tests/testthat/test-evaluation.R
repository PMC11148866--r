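# Fold plans, 7:2:1 splits, segment metrics, manifest summaries, and the
# per-case protocol contracts.

mk_ann <- function(id, n_seiz) {
  iv <- if (n_seiz == 0) NULL else cbind(seq(10, by = 100, length.out = n_seiz),
                                         seq(40, by = 100, length.out = n_seiz))
  seizure_annotation(iv, source_id = id)
}

test_that("fold plans put every seizure file in test exactly once", {
  anns <- c(lapply(1:5, function(i) mk_ann(paste0("s", i), i)),
            lapply(1:3, function(i) mk_ann(paste0("f", i), 0)))
  names(anns) <- vapply(anns, `[[`, "", "source_id")
  plan <- make_fold_plan(anns)
  expect_equal(plan$k, 5)
  expect_setequal(vapply(plan$folds, `[[`, "", "test_file"), paste0("s", 1:5))
  for (fold in plan$folds) {
    expect_length(fold$train_files, 4)
    expect_false(fold$test_file %in% fold$train_files)
  }
  expect_setequal(plan$seizure_free_files, paste0("f", 1:3))

  expect_error(make_fold_plan(lapply(1:3, function(i) mk_ann(paste0("f", i), 0))),
               class = "monoseize_fold_error")
  expect_warning(make_fold_plan(list(a = mk_ann("a", 1))), "k = 1")
})

test_that("fold plans partition random file sets", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    counts <- sample(0:3, n, replace = TRUE)
    if (all(counts == 0)) counts[1] <- 1
    anns <- lapply(seq_len(n), function(i) mk_ann(paste0("x", i), counts[i]))
    names(anns) <- paste0("x", seq_len(n))
    plan <- suppressWarnings(make_fold_plan(anns))
    tests <- vapply(plan$folds, `[[`, "", "test_file")
    expect_setequal(tests, paste0("x", which(counts > 0)))
    expect_equal(anyDuplicated(tests), 0L)
  }
})

test_that("random-mode split gives exact 70/20/10 sizes and is seeded", {
  segs <- make_tiny_segments(20, 80)        # 100 segments
  sp <- split_train_val_test(segs, mode = "random_segments", seed = 5)
  expect_equal(n_segments(sp$train), 70)
  expect_equal(n_segments(sp$val), 20)
  expect_equal(n_segments(sp$test), 10)
  # disjoint and exhaustive
  key <- function(s) paste(s$segments$source_id, s$segments$start_sample)
  all_keys <- c(key(sp$train), key(sp$val), key(sp$test))
  expect_equal(anyDuplicated(all_keys), 0L)
  expect_setequal(all_keys, paste(segs$segments$source_id,
                                  segs$segments$start_sample))
  sp2 <- split_train_val_test(segs, mode = "random_segments", seed = 5)
  expect_identical(sp$train$segments, sp2$train$segments)
})

test_that("grouped split has zero cross-part time overlap with step < window", {
  segs <- make_tiny_segments(50, 400)       # 1-sample step, 8-sample windows
  sp <- split_train_val_test(segs, mode = "grouped_blocks")
  rng <- function(s) cbind(s$segments$start_s, s$segments$start_s + s$window_s)
  audit <- function(a, b) {
    ra <- rng(a); rb <- rng(b)
    for (i in seq_len(nrow(ra)))
      if (any(ra[i, 1] < rb[, 2] & rb[, 1] < ra[i, 2])) return(FALSE)
    TRUE
  }
  expect_true(audit(sp$train, sp$val))
  expect_true(audit(sp$val, sp$test))
  expect_true(audit(sp$train, sp$test))
  # proportions approximately honored despite the purge
  fr <- n_segments(sp$train) / n_segments(segs)
  expect_gt(fr, 0.6)
  expect_lt(fr, 0.8)
})

test_that("segment metrics match hand arithmetic and the pair-count AUC", {
  labels <- c(rep("ictal", 10), rep("interictal", 90))
  probs <- c(rep(0.9, 8), rep(0.1, 2), rep(0.8, 5), rep(0.2, 85))
  m <- segment_level_metrics(labels, probs)
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 100 * 85 / 90, tolerance = 1e-9)
  expect_equal(m$accuracy, 93)

  # perfectly separated probabilities give AUC 100
  sep <- segment_level_metrics(c(rep("ictal", 5), rep("interictal", 5)),
                               c(runif(5, 0.6, 1), runif(5, 0, 0.4)))
  expect_equal(sep$auc, 100)

  # rank AUC equals O(n^2) concordant-pair counting with tie halves
  set.seed(67)
  for (rep in 1:20) {
    lab <- sample(c("ictal", "interictal"), 50, replace = TRUE,
                  prob = c(0.3, 0.7))
    if (length(unique(lab)) < 2) next
    pr <- round(runif(50), 1)               # coarse grid forces ties
    a <- segment_level_metrics(lab, pr)$auc
    pos <- pr[lab == "ictal"]; neg <- pr[lab == "interictal"]
    conc <- 0
    for (p in pos) for (q in neg)
      conc <- conc + (p > q) + 0.5 * (p == q)
    expect_equal(a, 100 * conc / (length(pos) * length(neg)), tolerance = 1e-9)
  }
  expect_error(segment_level_metrics(rep("ictal", 5), runif(5)),
               class = "monoseize_metric_error")
})

test_that("manifest summaries aggregate totals, means and pooled seizure SD", {
  one <- data.frame(case_id = "c1", age_years = 10, n_seizures = 4,
                    mean_seizure_length_s = 50, sd_seizure_length_s = 5,
                    total_seizure_length_s = 200, recording_length_h = 12)
  s <- summarize_manifest(one)
  expect_equal(s$totals$n_seizures, 4)
  expect_equal(s$totals$total_seizure_length_s, 200)
  expect_equal(s$totals$recording_length_h, 12)
  m <- s$means
  expect_equal(m$mean[m$metric == "n_seizures"], 4)
  expect_equal(m$sd[m$metric == "n_seizures"], 0)
  expect_equal(m$mean[m$metric == "seizure_length_s"], 50)
  # interictal hours = recording hours minus ictal hours
  expect_equal(m$mean[m$metric == "interictal_h"], 12 - 200 / 3600)

  # mean +/- SD recomputed by an independent streaming oracle
  set.seed(71)
  mani <- data.frame(case_id = paste0("c", 1:6), age_years = runif(6, 3, 20),
                     n_seizures = rpois(6, 5) + 1,
                     mean_seizure_length_s = runif(6, 30, 90),
                     sd_seizure_length_s = runif(6, 5, 40),
                     recording_length_h = runif(6, 10, 60))
  mani$total_seizure_length_s <- mani$n_seizures * mani$mean_seizure_length_s
  s2 <- summarize_manifest(mani)
  stream <- function(x) {    # Welford
    m <- 0; s <- 0; k <- 0
    for (v in x) { k <- k + 1; d <- v - m; m <- m + d / k; s <- s + d * (v - m) }
    c(m, sqrt(s / (k - 1)))
  }
  for (col in c("n_seizures", "recording_length_h", "age_years")) {
    o <- stream(mani[[col]])
    row <- s2$means[s2$means$metric == sub("_years", "_years", col), ]
    got <- s2$means[s2$means$metric == ifelse(col == "age_years", "age_years", col), ]
    expect_equal(got$mean, o[1], tolerance = 1e-9)
    expect_equal(got$sd, o[2], tolerance = 1e-9)
  }
})

test_that("case runs are deterministic and leakage-audited end to end", {
  case <- generate_case(synth_config(seed = 91, n_files = 3,
                                     n_seizure_files = 2,
                                     file_hours = 0.1,
                                     seizure_length_s = c(20, 40),
                                     min_gap_s = 30))
  cfg <- fast_config(seed = 4, max_epochs = 3, epoch_batches = 8)
  pol <- channel_policy("single", single_channel = case$ground_truth_channel)
  r1 <- run_case(case$recordings, case$annotations, pol, model_cfg = cfg,
                 train_step_samples = 512)
  r2 <- run_case(case$recordings, case$annotations, pol, model_cfg = cfg,
                 train_step_samples = 512)
  expect_identical(r1$folds, r2$folds)
  expect_equal(r1$k, 2)
  expect_equal(nrow(r1$folds), 2)
  # per-case mean of every metric lies within [min, max] of its fold values
  # (degenerate single-class test splits report NA and are flagged)
  expect_true("seg_metrics_ok" %in% names(r1$folds))
  for (mc in c("seg_accuracy", "ev_sensitivity", "far")) {
    vals <- r1$folds[[mc]][is.finite(r1$folds[[mc]])]
    if (length(vals) == 0) next
    mu <- r1$summary$mean[r1$summary$metric == mc]
    expect_gte(mu, min(vals) - 1e-12)
    expect_lte(mu, max(vals) + 1e-12)
  }
  # each fold was tuned and scored on a distinct held-out seizure file
  expect_equal(anyDuplicated(r1$folds$test_file), 0L)
})
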