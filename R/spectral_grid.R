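#' Spectral analysis grid
#'
#' Bundles the discretization on which all frequency-domain quantities live:
#' the segment length `2T+1` (an odd number of samples, so that the time index
#' of a segment runs symmetrically `t = -T, ..., T`), the sampling period
#' (seconds), the implied spectral resolution `1 / ((2T+1) * sampling_period)`
#' (Hz), the analysis frequencies (Hz, a subset of the nonnegative DFT bins),
#' and the number of data segments `M` used for cross-spectral averaging.
#'
#' @param num_samples_per_segment odd positive integer, samples per segment.
#' @param sampling_period sampling period in seconds.
#' @param frequencies analysis frequencies in Hz. Must sit on the DFT bin grid
#'   (integer multiples of the spectral resolution), be nonnegative, strictly
#'   increasing, and below the Nyquist frequency. Default: all nonnegative
#'   bins.
#' @param num_segments number of segments `M` (default 1; updated by
#'   estimators that know the true segment count).
#'
#' @return An object of class `spectral_grid` with fields
#'   `num_samples_per_segment`, `sampling_period`, `spectral_resolution`,
#'   `frequencies`, `bins` (integer DFT bin indices of `frequencies`) and
#'   `num_segments`.
#' @export
spectral_grid <- function(num_samples_per_segment, sampling_period,
                          frequencies = NULL, num_segments = 1L) {
  n <- as.integer(num_samples_per_segment)
  if (n < 1L || n %% 2L == 0L)
    stop_invalid("num_samples_per_segment must be a positive odd integer (2T+1), got ", n)
  if (!is.numeric(sampling_period) || sampling_period <= 0)
    stop_invalid("sampling_period must be positive")
  dnu <- 1 / (n * sampling_period)
  half_t <- (n - 1L) %/% 2L
  if (is.null(frequencies)) {
    bins <- 0:half_t
    frequencies <- bins * dnu
  } else {
    bins <- as.integer(round(frequencies / dnu))
    if (any(abs(bins * dnu - frequencies) > 1e-8 * max(dnu, frequencies)))
      stop_invalid("frequencies must be integer multiples of the spectral resolution ",
                   signif(dnu, 6), " Hz")
    if (any(bins < 0L) || any(bins > half_t))
      stop_invalid("frequencies must lie in [0, Nyquist)")
    if (any(diff(bins) <= 0L))
      stop_invalid("frequencies must be strictly increasing")
  }
  structure(list(num_samples_per_segment = n,
                 sampling_period = sampling_period,
                 spectral_resolution = dnu,
                 frequencies = as.numeric(frequencies),
                 bins = bins,
                 num_segments = as.integer(num_segments)),
            class = "spectral_grid")
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("spectral_grid: 2T+1 = %d samples @ %.4g s, resolution %.4g Hz, %d frequencies, M = %d\n",
              x$num_samples_per_segment, x$sampling_period,
              x$spectral_resolution, length(x$frequencies), x$num_segments))
  invisible(x)
}

#' Named frequency bands
#'
#' Conventional EEG band edges on the closed-open interval convention
#' `[lo, hi)`. The defaults cover delta through gamma; the paper-style
#' five-band split used throughout the benchmark harness.
#'
#' @param bands named list of length-2 numeric vectors `c(lo, hi)` in Hz.
#' @return the validated named list, classed `frequency_bands`.
#' @export
frequency_bands <- function(bands = list(delta = c(1, 4), theta = c(4, 8),
                                         alpha = c(8, 12), beta = c(12, 30),
                                         gamma = c(30, 45))) {
  if (is.null(names(bands)) || any(names(bands) == ""))
    stop_invalid("bands must be a named list")
  for (b in bands) {
    if (length(b) != 2L || !is.numeric(b) || b[1] >= b[2])
      stop_invalid("each band must be c(lo, hi) with lo < hi")
  }
  structure(bands, class = "frequency_bands")
}
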