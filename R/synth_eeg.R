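# Synthetic-EEG generator: referential 10-20 recordings with 1/f background
# and spatially localized rhythmic seizure bursts, so the whole detection
# pipeline is exercisable without any data download.
#
# Seizure bursts are injected on the electrodes of the four wearable
# derivations with antisymmetric gains: the dominant derivation's electrode
# pair receives +1/2 / -1/2 of the burst, the other three wearable pairs
# +-attenuation/2. After bipolar derivation the dominant channel therefore
# carries the full burst amplitude and every other wearable channel exactly
# `spatial_attenuation` of it. Full-montage derivations sharing an electrode
# with an injected pair pick up a partial projection, as focal discharges
# spread on real recordings.

#' Synthetic case configuration
#'
#' Defaults emulate a desk-scale version of a pediatric long-term monitoring
#' case: 256 Hz referential recordings, a minority of files with seizures,
#' seizures 30-90 s of 3-7 Hz rhythmic activity dominant on one wearable
#' derivation. `snr_ictal` is the amplitude ratio of the burst to the
#' background of the *derived* (bipolar) channel.
#'
#' @param fs sampling rate in Hz.
#' @param n_files number of EDF-sized files in the case.
#' @param file_hours recording length per file in hours (scalar or range;
#'   default 0.25 h; the reference data regime of 1-4 h is configuration
#'   only).
#' @param n_seizure_files how many files contain seizures (>= 1; at least one
#'   seizure-free file is kept when `n_files >= 3`).
#' @param seizures_per_file range of seizure counts per seizure file.
#' @param seizure_length_s seizure duration range in seconds.
#' @param ictal_freq_hz rhythmic burst frequency range in Hz (within the
#'   1-30 Hz analysis band).
#' @param dominant_derivation the wearable derivation carrying the seizure.
#' @param spatial_attenuation burst amplitude on non-dominant wearable
#'   derivations relative to the dominant one, in (0, 1).
#' @param snr_ictal burst-to-background amplitude ratio on the dominant
#'   derived channel.
#' @param background_rms_uv RMS of the 1/f background per electrode.
#' @param background_exponent 1/f^a power-spectrum exponent.
#' @param line_noise_hz optional mains frequency added to every electrode.
#' @param line_noise_uv mains amplitude in microvolts.
#' @param min_gap_s minimum spacing between seizures in one file.
#' @param seed RNG seed; file i is generated under `seed + i`.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(fs = 256, n_files = 4L, file_hours = 0.25,
                         n_seizure_files = 2L,
                         seizures_per_file = c(1L, 2L),
                         seizure_length_s = c(30, 90),
                         ictal_freq_hz = c(3, 7),
                         dominant_derivation = "P8-O2",
                         spatial_attenuation = 0.2,
                         snr_ictal = 5,
                         background_rms_uv = 20,
                         background_exponent = 1,
                         line_noise_hz = NULL,
                         line_noise_uv = 2,
                         min_gap_s = 60,
                         seed = 1L) {
  rng2 <- function(x) if (length(x) == 1) c(x, x) else sort(x[1:2])
  file_hours <- rng2(file_hours)
  seizures_per_file <- rng2(seizures_per_file)
  seizure_length_s <- rng2(seizure_length_s)
  ictal_freq_hz <- rng2(ictal_freq_hz)
  stopifnot(fs > 2 * ictal_freq_hz[2], n_files >= 1,
            n_seizure_files >= 1, n_seizure_files <= n_files,
            spatial_attenuation > 0, spatial_attenuation < 1,
            snr_ictal > 0, file_hours[1] > 0)
  if (!norm_label(dominant_derivation) %in% norm_label(wearable_channels()))
    stop_monoseize("dominant_derivation must be one of %s",
                   paste(wearable_channels(), collapse = ", "))
  if (n_files >= 3 && n_seizure_files >= n_files)
    stop_monoseize("keep at least one seizure-free file when n_files >= 3")
  structure(list(fs = fs, n_files = as.integer(n_files),
                 file_hours = file_hours,
                 n_seizure_files = as.integer(n_seizure_files),
                 seizures_per_file = as.integer(seizures_per_file),
                 seizure_length_s = seizure_length_s,
                 ictal_freq_hz = ictal_freq_hz,
                 dominant_derivation = dominant_derivation,
                 spatial_attenuation = spatial_attenuation,
                 snr_ictal = snr_ictal,
                 background_rms_uv = background_rms_uv,
                 background_exponent = background_exponent,
                 line_noise_hz = line_noise_hz,
                 line_noise_uv = line_noise_uv,
                 min_gap_s = min_gap_s,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' The 19 referential 10-20 electrodes used by the 18-derivation montage
#' @return character vector of electrode labels.
#' @export
electrodes_1020 <- function() {
  c("Fp1", "F3", "C3", "P3", "O1", "Fp2", "F4", "C4", "P4", "O2",
    "F7", "T7", "P7", "F8", "T8", "P8", "Fz", "Cz", "Pz")
}

# 1/f^a background noise via spectral shaping of white Gaussian noise,
# normalized to the requested RMS. Consumes exactly n normal draws.
one_over_f_noise <- function(n, fs, exponent, rms) {
  white <- stats::rnorm(n)
  if (exponent == 0) return(white / stats::sd(white) * rms)
  f <- c(1, seq_len(n - 1)) * fs / n          # guard DC bin
  f <- pmin(f, fs - f)                        # two-sided frequency axis
  shape <- 1 / f^(exponent / 2)
  shape[1] <- 0                               # remove DC
  x <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / n
  x / stats::sd(x) * rms
}

# Amplitude-ramped rhythmic burst with slow linear frequency drift.
ictal_burst <- function(n_samples, fs, f0, drift = 0.15) {
  tt <- seq_len(n_samples) / fs
  f_inst <- f0 * seq(1 - drift, 1 + drift, length.out = n_samples)
  phase <- 2 * pi * cumsum(f_inst) / fs
  ramp_n <- min(round(5 * fs), n_samples %/% 4)
  env <- rep(1, n_samples)
  if (ramp_n > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    env[seq_len(ramp_n)] <- up
    env[n_samples - ramp_n + seq_len(ramp_n)] <- rev(up)
  }
  sin(phase + stats::runif(1, 0, 2 * pi)) * env
}

draw_seizure_intervals <- function(n_seiz, dur_s, len_range, min_gap_s) {
  if (n_seiz == 0) return(matrix(numeric(0), ncol = 2))
  margin <- 10
  for (attempt in seq_len(200)) {
    lens <- stats::runif(n_seiz, len_range[1], len_range[2])
    if (sum(lens) + (n_seiz - 1) * min_gap_s + 2 * margin > dur_s) {
      if (attempt == 200)
        stop_monoseize("requested seizures do not fit the file",
                       class = "monoseize_synth_error")
      next
    }
    onsets <- sort(stats::runif(n_seiz, margin, dur_s - margin - lens))
    iv <- cbind(onsets, onsets + lens)
    gaps_ok <- n_seiz == 1 ||
      all(iv[-1, 1] - iv[-n_seiz, 2] >= min_gap_s)
    if (gaps_ok && all(iv[, 2] <= dur_s - margin)) return(iv)
  }
  stop_monoseize("could not place non-overlapping seizures (min gap %g s)",
                 min_gap_s, class = "monoseize_synth_error")
}

#' Generate one synthetic referential recording with its annotation
#'
#' Background is independent 1/f noise per electrode (plus optional mains
#' line); each seizure is a ramped rhythmic burst injected on the wearable
#' derivations' electrodes with the spatial gain pattern described in
#' [synth_config()]. Bitwise reproducible: file `i` of a config is always
#' generated under seed `seed + i`.
#'
#' @param cfg a `synth_config`.
#' @param file_index 1-based file number within the case.
#' @param n_seizures seizures to inject (default: drawn from
#'   `cfg$seizures_per_file`).
#' @return list with `recording` (referential `eeg_recording`) and
#'   `annotation` (`seizure_annotation`).
#' @export
generate_recording <- function(cfg, file_index = 1L, n_seizures = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + as.integer(file_index), {
    dur_s <- round(stats::runif(1, cfg$file_hours[1] * 3600,
                                cfg$file_hours[2] * 3600))
    n_samp <- as.integer(dur_s * cfg$fs)
    if (is.null(n_seizures)) {
      vals <- cfg$seizures_per_file[1]:cfg$seizures_per_file[2]
      n_seizures <- vals[sample.int(length(vals), 1)]
    }
    els <- electrodes_1020()
    sig <- matrix(0, length(els), n_samp)
    for (e in seq_along(els))
      sig[e, ] <- one_over_f_noise(n_samp, cfg$fs, cfg$background_exponent,
                                   cfg$background_rms_uv)
    if (!is.null(cfg$line_noise_hz)) {
      tt <- seq_len(n_samp) / cfg$fs
      line <- cfg$line_noise_uv * sin(2 * pi * cfg$line_noise_hz * tt)
      sig <- sweep(sig, 2, line, `+`)
    }
    iv <- draw_seizure_intervals(n_seizures, dur_s, cfg$seizure_length_s,
                                 cfg$min_gap_s)
    # derived-channel background RMS is sqrt(2) x the electrode RMS
    amp <- cfg$snr_ictal * sqrt(2) * cfg$background_rms_uv
    gains <- burst_gains(cfg$dominant_derivation, cfg$spatial_attenuation)
    for (k in seq_len(nrow(iv))) {
      s0 <- as.integer(round(iv[k, 1] * cfg$fs))
      len <- as.integer(round((iv[k, 2] - iv[k, 1]) * cfg$fs))
      f0 <- stats::runif(1, cfg$ictal_freq_hz[1], cfg$ictal_freq_hz[2])
      burst <- amp * ictal_burst(len, cfg$fs, f0)
      cols <- s0 + seq_len(len)
      for (el in names(gains))
        sig[match(norm_label(el), norm_label(els)), cols] <-
          sig[match(norm_label(el), norm_label(els)), cols] +
          gains[[el]] * burst
    }
    src <- sprintf("synthcase_%02d.edf", file_index)
    list(recording = recording(sig, cfg$fs, els, source_id = src),
         annotation = seizure_annotation(iv, source_id = src,
                                         duration_s = dur_s))
  })
}

# Antisymmetric electrode gains realizing the wearable-channel burst pattern.
burst_gains <- function(dominant, attenuation) {
  gains <- list()
  for (ch in wearable_channels()) {
    parts <- strsplit(ch, "-", fixed = TRUE)[[1]]
    g <- if (norm_label(ch) == norm_label(dominant)) 0.5 else attenuation / 2
    gains[[parts[1]]] <- g
    gains[[parts[2]]] <- -g
  }
  gains
}

#' Generate a complete synthetic case
#'
#' Files `1..n_seizure_files` carry seizures; the remainder are seizure-free
#' (when `n_files >= 3` at least one is guaranteed by construction). The
#' manifest row aggregates the generated annotations.
#'
#' @param cfg a `synth_config`.
#' @param case_id case identifier used in the manifest row.
#' @return an object of class `synth_case`: list with `recordings`,
#'   `annotations` (named by file), `ground_truth_channel`, and
#'   `manifest_row`.
#' @export
generate_case <- function(cfg, case_id = "synthcase") {
  stopifnot(inherits(cfg, "synth_config"), cfg$n_files >= 2)
  recs <- list()
  anns <- list()
  for (i in seq_len(cfg$n_files)) {
    n_sz <- if (i <= cfg$n_seizure_files) NULL else 0L
    g <- generate_recording(cfg, i, n_seizures = n_sz)
    recs[[g$recording$source_id]] <- g$recording
    anns[[g$annotation$source_id]] <- g$annotation
  }
  lens <- unlist(lapply(anns, function(a)
    if (n_seizures(a) > 0) a$intervals[, 2] - a$intervals[, 1] else numeric(0)))
  total_h <- sum(vapply(recs, duration_s, 0)) / 3600
  manifest_row <- data.frame(
    case_id = case_id,
    age_years = NA_real_, sex = NA_character_,
    n_seizures = length(lens),
    mean_seizure_length_s = mean(lens),
    sd_seizure_length_s = if (length(lens) > 1) stats::sd(lens) else 0,
    total_seizure_length_s = sum(lens),
    recording_length_h = total_h,
    single_channel = cfg$dominant_derivation,
    stringsAsFactors = FALSE)
  structure(list(recordings = recs, annotations = anns,
                 ground_truth_channel = cfg$dominant_derivation,
                 manifest_row = manifest_row, cfg = cfg),
            class = "synth_case")
}

#' Write a synthetic case to disk (EDF + JSON annotations + manifest CSV)
#'
#' @param case a `synth_case`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "synth_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(case$recordings)) {
    write_edf(case$recordings[[id]], file.path(dir, id))
    write_annotations(case$annotations[[id]],
                      file.path(dir, sub("\\.edf$", ".json", id)),
                      fs = case$recordings[[id]]$fs)
  }
  utils::write.csv(case$manifest_row, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
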