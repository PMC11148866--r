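# Probability traces, Savitzky-Golay smoothing, event extraction/matching,
# metrics and post-processing tuning — each checked against an independent
# brute-force oracle.

test_that("sliding probabilities cover starts 0..duration-4 at 1-s steps", {
  mdl <- build_model(model_config(seed = 2), n_channels = 1)
  rec10 <- recording(matrix(rnorm(10 * 256), 1), 256, "ch", source_id = "r")
  tr <- sliding_probabilities(mdl, rec10)
  expect_equal(tr$times, 0:6)
  expect_length(tr$probs, 7)
  # constant signal: every window identical, probabilities all equal
  recc <- recording(matrix(1, 1, 12 * 256), 256, "ch", source_id = "c")
  trc <- sliding_probabilities(mdl, recc)
  expect_equal(max(trc$probs) - min(trc$probs), 0)
  # integer-duration recording of D seconds yields D - 3 steps
  rec60 <- recording(matrix(rnorm(60 * 256), 1), 256, "ch", source_id = "r")
  expect_length(sliding_probabilities(mdl, rec60)$probs, 57)
  expect_error(sliding_probabilities(mdl,
                 recording(matrix(rnorm(512), 1), 256, "ch")),
               class = "monoseize_segment_error")
})

# Brute-force local polynomial fit: per point, explicit lm on the truncated
# window, evaluated at the point.
savgol_oracle <- function(x, window = 10, order = 3) {
  n <- length(x)
  left <- ceiling((window - 1) / 2)
  right <- window - 1 - left
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - left)
    hi <- min(n, i + right)
    off <- (lo:hi) - i
    fit <- stats::lm.fit(outer(off, 0:min(order, length(off) - 1), `^`),
                         x[lo:hi])
    out[i] <- fit$coefficients[1]
  }
  out
}

test_that("Savitzky-Golay equals the brute-force local fit on random traces", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    x <- runif(n)
    tr <- probability_trace(seq_len(n) - 1, x, "r")
    sm <- savgol_smooth(tr, detection_params(), clip = FALSE)
    expect_lt(max(abs(sm$probs - savgol_oracle(x))), 1e-9)
  }
})

test_that("cubic traces are reproduced exactly; constants are fixed points", {
  n <- 40
  t0 <- seq_len(n) - 1
  cub <- 0.5 + 0.4 * ((t0 - 20) / 25)^3      # stays within [0, 1]
  tr <- probability_trace(t0, cub, "r")
  sm <- savgol_smooth(tr, detection_params())
  expect_lt(max(abs(sm$probs - cub)), 1e-9)
  cn <- probability_trace(t0, rep(0.3, n), "r")
  expect_equal(savgol_smooth(cn, detection_params())$probs, rep(0.3, n))
  expect_error(savgol_smooth(probability_trace(0:5, runif(6), "r"),
                             detection_params()),
               class = "monoseize_smooth_error")
})

# Independent event enumerator: scan runs explicitly, then merge pairwise
# until a fixed point.
events_oracle <- function(probs, times, Th, L, gap, window_s = 4) {
  runs <- list()
  i <- 1
  n <- length(probs)
  while (i <= n) {
    if (probs[i] > Th) {
      j <- i
      while (j < n && probs[j + 1] > Th) j <- j + 1
      if (j - i + 1 >= L)
        runs[[length(runs) + 1]] <- c(times[i], times[j] + window_s)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) == 0) return(matrix(numeric(0), ncol = 2))
  iv <- do.call(rbind, runs)
  repeat {
    merged <- FALSE
    for (k in seq_len(nrow(iv) - 1)) {
      if (iv[k + 1, 1] - iv[k, 2] < gap) {
        iv[k, 2] <- max(iv[k, 2], iv[k + 1, 2])
        iv <- iv[-(k + 1), , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  iv
}

test_that("event extraction boundary cases follow the run-length rule", {
  p <- detection_params(Th = 0.5, L = 5)
  zero <- probability_trace(0:19, rep(0, 20), "r")
  expect_equal(nrow(extract_events(zero, p)$intervals), 0L)
  # L - 1 supra-threshold steps: nothing; exactly L: one event
  x4 <- c(rep(0, 5), rep(0.9, 4), rep(0, 11))
  x5 <- c(rep(0, 5), rep(0.9, 5), rep(0, 10))
  expect_equal(nrow(extract_events(probability_trace(0:19, x4, "r"), p)$intervals), 0L)
  ev <- extract_events(probability_trace(0:19, x5, "r"), p)
  expect_equal(unname(ev$intervals[1, ]), c(5, 13))    # last start 9 + 4 s
  # probability exactly at Th does not count (strict exceedance)
  xeq <- c(rep(0.5, 10), rep(0, 10))
  expect_equal(nrow(extract_events(probability_trace(0:19, xeq, "r"), p)$intervals), 0L)
})

test_that("two runs separated by less than 10 s merge into one event", {
  # 6 steps up, 8 s below threshold, 6 steps up again
  x <- c(rep(0.9, 6), rep(0.1, 8), rep(0.9, 6), rep(0.1, 5))
  tr <- probability_trace(seq_along(x) - 1, x, "r")
  ev <- extract_events(tr, detection_params(Th = 0.5, L = 5))
  expect_equal(nrow(ev$intervals), 1L)
  expect_equal(unname(ev$intervals[1, ]), c(0, 23))
  oracle <- events_oracle(x, seq_along(x) - 1, 0.5, 5, 10)
  expect_equal(unname(ev$intervals), unname(oracle))
})

test_that("event extraction equals the exhaustive enumerator on random traces", {
  set.seed(41)
  for (rep in 1:1000) {
    n <- sample(15:60, 1)
    x <- round(runif(n), 2)
    Th <- sample(seq(0.2, 0.9, 0.1), 1)
    L <- sample(5:10, 1)
    tr <- probability_trace(seq_len(n) - 1, x, "r")
    ev <- extract_events(tr, detection_params(Th = Th, L = L))
    oracle <- events_oracle(x, seq_len(n) - 1, Th, L, 10)
    expect_equal(unname(ev$intervals), unname(oracle))
  }
})

test_that("extracted events never overlap and honor the merge gap", {
  set.seed(43)
  for (rep in 1:50) {
    x <- runif(80)
    ev <- extract_events(probability_trace(0:79, x, "r"),
                         detection_params(Th = 0.4, L = 5))$intervals
    if (nrow(ev) > 1) {
      gaps <- ev[-1, 1] - ev[-nrow(ev), 2]
      expect_true(all(gaps >= 10))
    }
  }
})

test_that("event count is monotone non-increasing in L; zero above the max", {
  set.seed(47)
  x <- runif(100)
  tr <- probability_trace(0:99, x, "r")
  counts <- vapply(5:10, function(L)
    nrow(extract_events(tr, detection_params(Th = 0.3, L = L))$intervals), 0L)
  expect_true(all(diff(counts) <= 0))
  high <- detection_params(Th = 0.999, L = 5)
  expect_equal(nrow(extract_events(tr, high)$intervals), 0L)
})

# Exhaustive all-pairs overlap matcher.
match_oracle <- function(det, ann) {
  hit_det <- rep(FALSE, nrow(det))
  correct <- 0
  lat <- numeric(0)
  for (a in seq_len(nrow(ann))) {
    ov <- which(det[, 1] < ann[a, 2] & ann[a, 1] < det[, 2])
    if (length(ov)) {
      correct <- correct + 1
      hit_det[ov] <- TRUE
      lat <- c(lat, unname(min(det[ov, 1]) - ann[a, 1]))
    }
  }
  list(correct = correct, missed = nrow(ann) - correct,
       false_alarms = sum(!hit_det), latencies = lat)
}

test_that("event matching handles overlap, miss and false alarm cases", {
  ann <- seizure_annotation(rbind(c(110, 150)), source_id = "r")
  det1 <- event_set(rbind(c(115, 140)), source_id = "r")
  m1 <- match_events(det1, ann)
  expect_equal(m1$correct, 1L)
  expect_equal(m1$missed, 0L)
  expect_equal(m1$false_alarms, 0L)
  expect_equal(m1$latencies_s, 5)

  det2 <- event_set(rbind(c(200, 210)), source_id = "r")
  m2 <- match_events(det2, ann)
  expect_equal(c(m2$correct, m2$missed, m2$false_alarms), c(0L, 1L, 1L))

  # one detected event spanning two seizures credits both, no false alarm
  ann2 <- seizure_annotation(rbind(c(10, 20), c(25, 35)), source_id = "r")
  det3 <- event_set(rbind(c(15, 30)), source_id = "r")
  m3 <- match_events(det3, ann2)
  expect_equal(c(m3$correct, m3$missed, m3$false_alarms), c(2L, 0L, 0L))

  expect_error(match_events(event_set(NULL, "a"),
                            seizure_annotation(NULL, "b")),
               class = "monoseize_match_error")
})

test_that("event matching equals the all-pairs oracle on random instances", {
  set.seed(53)
  mk_iv <- function(k) {
    if (k == 0) return(matrix(numeric(0), ncol = 2))
    gaps <- runif(k, 1, 30)
    lens <- runif(k, 1, 20)
    on <- cumsum(gaps + c(0, lens[-k]))
    cbind(on, on + lens)
  }
  for (rep in 1:1000) {
    det <- mk_iv(sample(0:5, 1))
    ann <- mk_iv(sample(0:5, 1))
    m <- match_events(event_set(det, "r"), seizure_annotation(ann, "r"))
    o <- match_oracle(det, ann)
    expect_equal(m$correct, o$correct)
    expect_equal(m$missed, o$missed)
    expect_equal(m$false_alarms, o$false_alarms)
    expect_equal(m$latencies_s, o$latencies)
    # conservation invariants
    expect_equal(m$correct + m$missed, nrow(ann))
    expect_lte(m$false_alarms, nrow(det))
  }
})

test_that("event metrics arithmetic and degenerate definitions", {
  m <- list(correct = 3L, missed = 1L, false_alarms = 2L,
            latencies_s = c(2, 4, 6), n_annotated = 4L, n_detected = 5L)
  em <- event_metrics(m, 10)
  expect_equal(em$sensitivity, 75)
  expect_equal(em$far, 0.2)
  expect_equal(em$mean_latency_s, 4)

  perfect <- list(correct = 4L, missed = 0L, false_alarms = 0L,
                  latencies_s = rep(0, 4), n_annotated = 4L, n_detected = 4L)
  expect_equal(event_metrics(perfect, 5)$sensitivity, 100)
  expect_equal(event_metrics(perfect, 5)$far, 0)

  none <- list(correct = 0L, missed = 0L, false_alarms = 0L,
               latencies_s = numeric(0), n_annotated = 0L, n_detected = 0L)
  expect_equal(event_metrics(none, 1)$sensitivity, 100)
  expect_true(is.na(event_metrics(none, 1)$mean_latency_s))
  expect_error(event_metrics(m, 0))
})

test_that("tuning returns the dominant optimum and honors tie-breaks", {
  # a trace where Th >= 0.5 detects the one seizure with no false alarms
  x <- c(rep(0.05, 20), rep(0.95, 8), rep(0.05, 20))
  tr <- probability_trace(seq_along(x) - 1, x, "r")
  ann <- seizure_annotation(rbind(c(20, 28)), source_id = "r")
  best <- tune_postprocessing(list(tr), list(ann), smooth = FALSE)
  m <- match_events(extract_events(tr, best), ann)
  expect_equal(m$correct, 1L)
  expect_equal(m$false_alarms, 0L)
  # ties resolved toward larger L then larger Th
  expect_equal(best$L, 8L)       # largest L still covering the 8-step run
  expect_equal(best$Th, 0.9)
})

test_that("tuning equals exhaustive grid evaluation on random traces", {
  set.seed(59)
  for (rep in 1:20) {
    n <- 60
    x <- runif(n)
    x[20:30] <- pmin(x[20:30] + 0.5, 1)
    tr <- probability_trace(seq_len(n) - 1, x, "r")
    ann <- seizure_annotation(rbind(c(20, 34)), source_id = "r")
    got <- tune_postprocessing(list(tr), list(ann), smooth = FALSE)
    # exhaustive re-evaluation
    hours <- (n - 1 + 4) / 3600
    best <- NULL
    for (Th in seq(0.2, 0.9, 0.1)) for (L in 5:10) {
      m <- match_events(extract_events(tr,
             detection_params(Th = Th, L = L)), ann)
      sens <- if (m$n_annotated == 0) 100 else 100 * m$correct / m$n_annotated
      sc <- c(sens, -m$false_alarms / hours, L, Th)
      if (is.null(best) || monoseize:::vector_gt(sc, best$sc))
        best <- list(sc = sc, Th = Th, L = L)
    }
    expect_equal(got$Th, best$Th)
    expect_equal(got$L, best$L)
  }
})

test_that("tuning prefers the lower-FAR point among equal sensitivities", {
  # seizure at [10, 22]; a spurious 5-step bump that only Th = 0.2 picks up
  x <- rep(0.05, 60)
  x[11:22] <- 0.95                       # real seizure, any Th detects
  x[41:45] <- 0.3                        # false bump above 0.2 only
  tr <- probability_trace(seq_along(x) - 1, x, "r")
  ann <- seizure_annotation(rbind(c(10, 26)), source_id = "r")
  best <- tune_postprocessing(list(tr), list(ann), smooth = FALSE)
  m <- match_events(extract_events(tr, best), ann)
  expect_equal(m$false_alarms, 0L)
  expect_gt(best$Th, 0.2)
})
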