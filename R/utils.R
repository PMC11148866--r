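# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Band power of a single signal by periodogram summation
#'
#' Average power (uV^2) of `x` contributed by frequencies in `[lo, hi]` Hz,
#' computed from the raw periodogram. Used by the synthetic-EEG localization
#' checks and by tests; not a calibrated spectral estimator.
#'
#' @param x numeric vector, one channel.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz.
#' @return scalar band power.
#' @export
band_power <- function(x, fs, lo, hi) {
  stopifnot(is.numeric(x), length(x) > 8, fs > 0, lo < hi)
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n^2        # power per frequency bin
  freq <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2) + 1)
  sel <- half[freq[half] >= lo & freq[half] <= hi]
  2 * sum(p[sel])                        # fold negative frequencies
}

#' Sample mean and sample SD (n-1), NA-safe for length-1 input (SD = 0)
#' @noRd
mean_sd <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
}

stop_monoseize <- function(fmt, ..., class = "monoseize_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}
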