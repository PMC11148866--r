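# Minimal EDF (European Data Format) codec, 16-bit integer samples.
#
# Implements the fixed-layout ASCII header (256 bytes + 256 per signal) and
# little-endian 16-bit data records of the EDF standard; enough to round-trip
# the package's own recordings and to read plain continuous EDF files such as
# CHB-MIT's. EDF+ annotation channels and discontinuous files are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  # shortest decimal representation that fits the fixed-width ASCII field
  s <- format(x, trim = TRUE, scientific = FALSE, digits = 8)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file (16-bit)
#'
#' Each channel is scaled to the signed 16-bit digital range over a symmetric
#' physical range covering its amplitude extrema, so quantization error is at
#' most one digital step of the written physical range. Record duration is 1 s
#' when the sample count divides evenly, otherwise a single record holding the
#' whole signal.
#'
#' @param rec an `eeg_recording` (microvolts).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ch <- nrow(rec$signal)
  n_samp <- ncol(rec$signal)
  if (n_samp %% rec$fs == 0 && rec$fs == round(rec$fs)) {
    rec_dur <- 1
    spr <- as.integer(rec$fs)            # samples per record per channel
    n_rec <- n_samp %/% spr
  } else {
    rec_dur <- n_samp / rec$fs
    spr <- n_samp
    n_rec <- 1L
  }
  pmax_v <- apply(abs(rec$signal), 1, max)
  pmax_v[pmax_v == 0] <- 1
  phys_min <- -pmax_v
  phys_max <- pmax_v
  dig_min <- -32768L
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste("Startdate X X X", rec$source_id), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_num(256 * (1 + n_ch), 8),
    edf_pad("", 44),
    edf_num(n_rec, 8),
    edf_num(rec_dur, 8),
    edf_num(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  nfield <- function(vals, width)
    writeChar(paste(vapply(vals, edf_num, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", n_ch), 80)                       # transducer
  field(rep("uV", n_ch), 8)                      # physical dimension
  nfield(phys_min, 8)
  nfield(phys_max, 8)
  nfield(rep(dig_min, n_ch), 8)
  nfield(rep(dig_max, n_ch), 8)
  field(rep("", n_ch), 80)                       # prefiltering
  nfield(rep(spr, n_ch), 8)
  field(rep("", n_ch), 32)                       # reserved

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  dig <- round((rec$signal - phys_min) * scale) + dig_min
  dig[dig > dig_max] <- dig_max
  dig[dig < dig_min] <- dig_min
  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    block <- t(dig[, cols, drop = FALSE])        # channel-major within record
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con, path) {
  raw_hdr <- readBin(con, "raw", 256)
  if (length(raw_hdr) < 256)
    stop_monoseize("malformed EDF header in '%s': file shorter than 256 bytes",
                   path, class = "monoseize_edf_error")
  hdr <- rawToChar(raw_hdr)
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1))
  n_rec <- suppressWarnings(as.numeric(fld(237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(245, 8)))
  n_ch <- suppressWarnings(as.integer(fld(253, 4)))
  if (is.na(n_ch) || n_ch < 1 || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0)
    stop_monoseize("malformed EDF header in '%s'", path,
                   class = "monoseize_edf_error")
  sig_raw <- readBin(con, "raw", 256 * n_ch)
  if (length(sig_raw) < 256 * n_ch)
    stop_monoseize("malformed EDF header in '%s': truncated signal headers",
                   path, class = "monoseize_edf_error")
  sh <- rawToChar(sig_raw)
  take <- function(offset_units, width) {
    start <- offset_units * n_ch
    vapply(seq_len(n_ch) - 1L, function(i)
      trimws(substr(sh, start + i * width + 1, start + (i + 1) * width)), "")
  }
  # cumulative byte offsets of the per-signal field blocks
  labels <- take(0, 16)
  # offsets: label 16, transducer 80, dim 8, pmin 8, pmax 8, dmin 8, dmax 8,
  #          prefilter 80, spr 8, reserved 32
  off <- cumsum(c(0, 16, 80, 8, 8, 8, 8, 80, 8))
  g <- function(k, w) {
    start <- off[k] * n_ch
    vapply(seq_len(n_ch) - 1L, function(i)
      trimws(substr(sh, start + i * w + 1, start + (i + 1) * w)), "")
  }
  list(n_records = n_rec, record_duration = rec_dur, n_channels = n_ch,
       labels = labels,
       phys_dim = g(3, 8),
       phys_min = as.numeric(g(4, 8)), phys_max = as.numeric(g(5, 8)),
       dig_min = as.numeric(g(6, 8)), dig_max = as.numeric(g(7, 8)),
       spr = as.integer(g(9, 8)))
}

#' Read an EDF recording
#'
#' Returns the signal in microvolts (millivolt/volt channels are converted;
#' unrecognized physical dimensions are taken as microvolts). All data
#' channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @param expected_fs if given, error unless the file's sampling rate equals
#'   this value (Hz).
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, expected_fs = NULL) {
  if (!file.exists(path))
    stop_monoseize("file not found: '%s'", path, class = "monoseize_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con, path)
  if (any(is.na(h$spr)) || any(h$spr < 1) ||
      any(is.na(h$phys_min)) || any(is.na(h$phys_max)) ||
      any(h$phys_max <= h$phys_min) || any(h$dig_max <= h$dig_min))
    stop_monoseize("malformed EDF header in '%s'", path,
                   class = "monoseize_edf_error")
  fs_all <- h$spr / h$record_duration
  if (length(unique(fs_all)) != 1)
    stop_monoseize("non-uniform per-channel sampling rates in '%s'", path,
                   class = "monoseize_edf_error")
  fs <- fs_all[1]
  if (!is.null(expected_fs) && !isTRUE(all.equal(fs, expected_fs)))
    stop_monoseize("sampling rate mismatch in '%s': file %g Hz, expected %g Hz",
                   path, fs, expected_fs, class = "monoseize_fs_error")
  n_rec <- h$n_records
  spr <- h$spr
  rec_words <- sum(spr)
  if (n_rec < 0) {  # -1 marks "unknown"; infer from file size
    bytes <- file.size(path) - 256 * (1 + h$n_channels)
    n_rec <- floor(bytes / (2 * rec_words))
  }
  if (n_rec < 1)
    stop_monoseize("EDF file '%s' contains no data records", path,
                   class = "monoseize_edf_error")
  data <- readBin(con, "integer", n_rec * rec_words, size = 2,
                  signed = TRUE, endian = "little")
  if (length(data) < n_rec * rec_words)
    stop_monoseize("truncated EDF data in '%s'", path,
                   class = "monoseize_edf_error")
  n_ch <- h$n_channels
  sig <- matrix(0, n_ch, n_rec * spr[1])
  # channels may in principle have distinct spr, but uniform fs guarantees
  # identical spr here
  per_rec <- matrix(data, nrow = rec_words)
  row_of <- rep(seq_len(n_ch), times = spr)
  for (ch in seq_len(n_ch)) {
    sig[ch, ] <- as.vector(per_rec[row_of == ch, , drop = FALSE])
  }
  scale <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  sig <- (sig - h$dig_min) * scale + h$phys_min
  unit_mult <- ifelse(norm_label(h$phys_dim) == "MV", 1e3,
                      ifelse(norm_label(h$phys_dim) == "V", 1e6, 1))
  sig <- sig * unit_mult
  recording(sig, fs, h$labels, source_id = basename(path))
}
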