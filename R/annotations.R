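# Seizure annotations: ordered, non-overlapping [onset, offset) intervals in
# seconds from file start. JSON is the native dialect; CHB-MIT "-summary.txt"
# blocks can be parsed read-only.

#' Construct a seizure annotation
#'
#' Intervals are half-open `[onset, offset)` in seconds from the start of the
#' recording. Construction validates ordering and pairwise disjointness, so an
#' invalid annotation can never exist (and can never be written out).
#'
#' @param intervals numeric n x 2 matrix (or an empty/NULL value for a
#'   seizure-free file); column 1 onsets, column 2 offsets, seconds.
#' @param source_id recording identity the annotation refers to.
#' @param duration_s optional recording duration; when given, intervals must
#'   fall inside `[0, duration_s]`.
#' @return an object of class `seizure_annotation`.
#' @export
seizure_annotation <- function(intervals = NULL, source_id = "recording",
                               duration_s = NULL) {
  if (is.null(intervals) || length(intervals) == 0) {
    intervals <- matrix(numeric(0), ncol = 2)
  } else {
    intervals <- matrix(as.numeric(intervals), ncol = 2)
  }
  colnames(intervals) <- c("onset_s", "offset_s")
  if (nrow(intervals) > 0) {
    if (any(!is.finite(intervals)))
      stop_monoseize("non-finite annotation interval",
                     class = "monoseize_annotation_error")
    if (any(intervals[, 1] >= intervals[, 2]))
      stop_monoseize("annotation onset must precede offset",
                     class = "monoseize_annotation_error")
    if (any(intervals[, 1] < 0))
      stop_monoseize("annotation onset before recording start",
                     class = "monoseize_annotation_error")
    intervals <- intervals[order(intervals[, 1]), , drop = FALSE]
    if (nrow(intervals) > 1 &&
        any(intervals[-1, 1] < intervals[-nrow(intervals), 2]))
      stop_monoseize("overlapping annotation intervals",
                     class = "monoseize_annotation_error")
    if (!is.null(duration_s) && any(intervals[, 2] > duration_s + 1e-9))
      stop_monoseize("annotation extends past recording end (%g s)", duration_s,
                     class = "monoseize_annotation_error")
  }
  structure(list(intervals = intervals, source_id = as.character(source_id)),
            class = "seizure_annotation")
}

#' @export
print.seizure_annotation <- function(x, ...) {
  cat(sprintf("<seizure_annotation> %s: %d seizure(s)\n",
              x$source_id, nrow(x$intervals)))
  if (nrow(x$intervals) > 0)
    cat(paste(sprintf("  [%g, %g) s", x$intervals[, 1], x$intervals[, 2]),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Number of annotated seizures
#' @param ann a `seizure_annotation`.
#' @export
n_seizures <- function(ann) nrow(ann$intervals)

#' Write an annotation to the package's JSON dialect
#'
#' The dialect is `{"source_id": str, "fs": number, "intervals": [[onset_s,
#' offset_s], ...]}`; round-trips losslessly at millisecond precision.
#'
#' @param ann a `seizure_annotation`.
#' @param path output path.
#' @param fs optional sampling rate recorded alongside (informational).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, fs = 256) {
  stopifnot(inherits(ann, "seizure_annotation"))
  obj <- list(source_id = ann$source_id, fs = fs,
              intervals = unname(apply(ann$intervals, 1, as.numeric,
                                       simplify = FALSE)))
  if (nrow(ann$intervals) == 0) obj$intervals <- list()
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

parse_chbmit_summary <- function(lines) {
  # Blocks look like:
  #   File Name: chb01_03.edf
  #   Number of Seizures in File: 1
  #   Seizure 1 Start Time: 2996 seconds
  #   Seizure 1 End Time: 3036 seconds
  file_idx <- grep("^\\s*File Name\\s*:", lines)
  if (length(file_idx) == 0)
    stop_monoseize("no 'File Name:' blocks found in summary",
                   class = "monoseize_annotation_error")
  ends <- c(file_idx[-1] - 1, length(lines))
  out <- list()
  num_after <- function(x) as.numeric(sub(".*?:\\s*([-0-9.]+).*", "\\1", x))
  for (b in seq_along(file_idx)) {
    block <- lines[file_idx[b]:ends[b]]
    fname <- trimws(sub(".*?:\\s*", "", block[1]))
    starts <- num_after(grep("Seizure.*Start Time\\s*:", block, value = TRUE))
    stops <- num_after(grep("Seizure.*End Time\\s*:", block, value = TRUE))
    if (length(starts) != length(stops))
      stop_monoseize("unpaired seizure start/end times for '%s'", fname,
                     class = "monoseize_annotation_error")
    n_line <- grep("Number of Seizures in File\\s*:", block, value = TRUE)
    if (length(n_line) == 1 && num_after(n_line) != length(starts))
      stop_monoseize("seizure count mismatch for '%s'", fname,
                     class = "monoseize_annotation_error")
    out[[fname]] <- seizure_annotation(cbind(starts, stops), source_id = fname)
  }
  out
}

#' Read seizure annotations
#'
#' @param path annotation file path.
#' @param dialect `"json"` (the package dialect) or `"chbmit_summary"`
#'   (a CHB-MIT `-summary.txt`, read-only).
#' @param source_id for multi-file summaries, which file's block to return;
#'   defaults to the only block if there is exactly one.
#' @return a validated `seizure_annotation`.
#' @export
read_annotations <- function(path, dialect = c("json", "chbmit_summary"),
                             source_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_monoseize("file not found: '%s'", path, class = "monoseize_io_error")
  if (dialect == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    iv <- obj$intervals
    if (is.list(iv)) iv <- do.call(rbind, iv)
    return(seizure_annotation(iv, source_id = obj$source_id %||% "recording"))
  }
  anns <- parse_chbmit_summary(readLines(path, warn = FALSE))
  if (is.null(source_id)) {
    if (length(anns) != 1)
      stop_monoseize(
        "summary lists %d files; pass source_id (one of: %s)",
        length(anns), paste(names(anns), collapse = ", "))
    return(anns[[1]])
  }
  hit <- match(norm_label(source_id), norm_label(names(anns)))
  if (is.na(hit))
    stop_monoseize("no block for '%s' in summary", source_id,
                   class = "monoseize_annotation_error")
  anns[[hit]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
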