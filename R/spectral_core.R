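#' Segment a multichannel time series
#'
#' Cuts a `channels x time` matrix into fixed-length segments with a given
#' overlap; the trailing remainder that does not fill a whole segment is
#' discarded. The number of segments is
#' `floor((Ttot - overlap) / (segment_length - overlap))`.
#'
#' @param data numeric matrix, channels x samples.
#' @param segment_length samples per segment.
#' @param overlap samples shared by consecutive segments,
#'   `0 <= overlap < segment_length`.
#' @return list of `channels x segment_length` matrices.
#' @export
segment_time_series <- function(data, segment_length, overlap = 0L) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  n_tot <- ncol(data)
  segment_length <- as.integer(segment_length)
  overlap <- as.integer(overlap)
  if (segment_length < 1L || segment_length > n_tot)
    stop_invalid("segment_length (", segment_length,
                 ") must be in [1, total samples = ", n_tot, "]")
  if (overlap < 0L || overlap >= segment_length)
    stop_invalid("overlap must satisfy 0 <= overlap < segment_length")
  step <- segment_length - overlap
  n_seg <- (n_tot - overlap) %/% step
  lapply(seq_len(n_seg) - 1L, function(m) {
    data[, (m * step + 1L):(m * step + segment_length), drop = FALSE]
  })
}

#' Discrete Fourier transform of a centered segment
#'
#' Computes, per channel, `x(f) = sum_{t=-T}^{T} x(t) exp(-i 2 pi (f dnu)(t ds))`
#' for the frequencies of `grid`. The segment midpoint is the time origin
#' (the index runs `t = -T..T`), which differs from 0-based FFT output by a
#' per-frequency phase factor; the FFT is used internally with that phase
#' correction applied.
#'
#' @param segment numeric matrix channels x (2T+1); a vector is treated as one
#'   channel.
#' @param grid a [spectral_grid()] with matching segment length.
#' @param taper `"rectangular"` (default; the plain DFT) or `"hann"`.
#' @return complex matrix channels x length(grid$frequencies).
#' @export
discrete_fourier_transform <- function(segment, grid,
                                       taper = c("rectangular", "hann")) {
  taper <- match.arg(taper)
  if (!is.matrix(segment)) segment <- matrix(segment, nrow = 1L)
  n <- grid$num_samples_per_segment
  if (ncol(segment) != n)
    stop_invalid("segment length (", ncol(segment),
                 ") must equal grid$num_samples_per_segment (", n, ")")
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
    segment <- sweep(segment, 2L, w, `*`)
  }
  half_t <- (n - 1L) %/% 2L
  # rows are channels; fft along time
  X <- t(apply(segment, 1L, fft))
  if (nrow(segment) == 1L) X <- matrix(X, nrow = 1L)
  bins <- grid$bins
  phase <- exp(2i * pi * bins * half_t / n)  # recenters the time origin
  out <- X[, bins + 1L, drop = FALSE] * matrix(phase, nrow(segment), length(bins),
                                               byrow = TRUE)
  out
}

#' Fourier instances from a multichannel time series
#'
#' Segments the data, applies the centered discrete Fourier transform to each
#' segment, and collects the coefficients into a [fourier_instances()]
#' container whose grid records the realized segment count `M`.
#'
#' @inheritParams segment_time_series
#' @param sampling_period sampling period in seconds.
#' @param frequencies analysis frequencies (Hz); default all nonnegative bins.
#' @param taper see [discrete_fourier_transform()].
#' @return a [fourier_instances()] object.
#' @export
fourier_transform_series <- function(data, segment_length, sampling_period,
                                     overlap = 0L, frequencies = NULL,
                                     taper = "rectangular") {
  segs <- segment_time_series(data, segment_length, overlap)
  grid <- spectral_grid(segment_length, sampling_period, frequencies,
                        num_segments = length(segs))
  vals <- vapply(segs, discrete_fourier_transform, grid = grid, taper = taper,
                 FUN.VALUE = matrix(0i, nrow(segs[[1L]]), length(grid$frequencies)))
  if (length(dim(vals)) == 2L) vals <- array(vals, c(1L, dim(vals)))
  fourier_instances(vals, grid, names = rownames(data))
}

#' Sample cross-spectrum of Fourier instances
#'
#' The averaged outer product `(1/M) sum_m x_m(f) x_m(f)^H` per frequency,
#' which is Hermitian positive-semidefinite by construction.
#'
#' @param instances a [fourier_instances()] object.
#' @param space_tag `"sensor"` or `"source"`.
#' @return a [cross_spectrum()] with `sample_size = M`.
#' @export
sample_cross_spectrum <- function(instances, space_tag = "sensor") {
  v <- instances$values
  d <- dim(v)
  if (d[3] < 1L) stop_invalid("need at least one Fourier instance")
  out <- array(0i, c(d[1], d[1], d[2]))
  for (k in seq_len(d[2])) {
    Xk <- v[, k, , drop = TRUE]
    if (d[1] == 1L) Xk <- matrix(Xk, nrow = 1L)
    if (d[3] == 1L) Xk <- matrix(Xk, ncol = 1L)
    out[, , k] <- hermitianize(Xk %*% Conj(t(Xk)) / d[3])
  }
  cross_spectrum(out, instances$grid, sample_size = d[3],
                 space_tag = space_tag, names = instances$names)
}

#' Circularly symmetric complex Gaussian log-density
#'
#' `log N_C(x | 0, Sigma) = -log|pi Sigma| - x^H Sigma^{-1} x` for a
#' zero-mean circularly symmetric complex Gaussian vector; integrates to one
#' over C^R.
#'
#' @param x complex vector.
#' @param sigma Hermitian positive-definite matrix.
#' @return real scalar log-density.
#' @export
complex_gaussian_logdensity <- function(x, sigma) {
  if (!is.matrix(sigma)) sigma <- matrix(sigma, 1L, 1L)
  x <- as.vector(x)
  r <- length(x)
  if (nrow(sigma) != r) stop_invalid("dimension mismatch between x and sigma")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-14 * max(ev)) stop_rank("sigma is not positive definite")
  logdet <- sum(log(ev))
  q <- Re(Conj(x) %*% solve(sigma, x))[1L]
  -r * log(pi) - logdet - q
}

#' Complex Wishart log-likelihood of a sample cross-spectrum
#'
#' Per frequency, the log of the complex Wishart density of the sample
#' estimator `S_bar` given scale `Sigma` and `M` degrees of freedom,
#' `(M - R) log|S_bar| - M log|Sigma| - M tr(Sigma^{-1} S_bar)`,
#' up to an additive constant independent of `Sigma` (the `S_bar`-dependent
#' normalization of the density is dropped; it never affects estimation of
#' `Sigma`).
#'
#' @param sample_cs [cross_spectrum()] holding `S_bar(f)`.
#' @param scale [cross_spectrum()] holding `Sigma(f)` (positive definite).
#' @param dof degrees of freedom `M >= R`.
#' @return numeric vector, one log-likelihood per frequency.
#' @export
complex_wishart_loglik <- function(sample_cs, scale, dof) {
  r <- dim(sample_cs$matrices)[1]
  if (dof < r) stop_invalid("degrees of freedom M (", dof,
                            ") must be >= dimension R (", r, ")")
  if (!all(dim(sample_cs$matrices) == dim(scale$matrices)))
    stop_invalid("sample and scale cross-spectra must have equal dimensions")
  nf <- dim(sample_cs$matrices)[3]
  out <- numeric(nf)
  for (k in seq_len(nf)) {
    Sb <- cs_slice(sample_cs, k)
    Sg <- cs_slice(scale, k)
    evb <- eigen(Sb, symmetric = TRUE, only.values = TRUE)$values
    evg <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
    if (min(evg) <= 0) stop_rank("scale matrix singular at frequency index ", k)
    ldb <- if (min(evb) <= 0) -Inf else sum(log(evb))
    tr <- Re(sum(diag(solve(Sg, Sb))))
    out[k] <- (dof - r) * ldb - dof * sum(log(evg)) - dof * tr
  }
  out
}

#' Gaussianity test for Fourier coefficients
#'
#' Tests, per channel and frequency, whether the real and imaginary parts of
#' the Fourier coefficients across segments are univariate Gaussian
#' (Shapiro-Wilk), with Benjamini-Hochberg correction across all
#' channel x frequency x part tests at level `alpha`. Degenerate
#' (numerically constant) coefficient sets are flagged and excluded.
#'
#' @param instances [fourier_instances()] with `M >= 20` segments.
#' @param alpha nominal level of the corrected test.
#' @return a data.frame with one row per (channel, frequency, part) carrying
#'   the raw and adjusted p-values, the rejection indicator and a degeneracy
#'   flag, plus attributes `rejection_fraction` (over non-degenerate tests)
#'   and `alpha`.
#' @export
gaussianity_test <- function(instances, alpha = 0.05) {
  v <- instances$values
  d <- dim(v)
  if (d[3] < 20L) stop_invalid("need at least M = 20 segments, got ", d[3])
  rows <- expand.grid(channel = seq_len(d[1]), freq_index = seq_len(d[2]),
                      part = c("real", "imag"), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  pvals <- rep(NA_real_, nrow(rows))
  degen <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    xi <- v[rows$channel[i], rows$freq_index[i], ]
    z <- if (rows$part[i] == "real") Re(xi) else Im(xi)
    if (sd(z) < 1e-12 * (abs(mean(z)) + 1e-300)) {
      degen[i] <- TRUE
    } else {
      pvals[i] <- shapiro.test(z)$p.value
    }
  }
  padj <- rep(NA_real_, length(pvals))
  padj[!degen] <- p.adjust(pvals[!degen], method = "BH")
  rows$p_value <- pvals
  rows$p_adjusted <- padj
  rows$degenerate <- degen
  rows$reject <- !degen & !is.na(padj) & padj < alpha
  attr(rows, "rejection_fraction") <-
    if (all(degen)) NA_real_ else mean(rows$reject[!degen])
  # calibration diagnostic: per-test rejections before the BH correction
  attr(rows, "raw_rejection_fraction") <-
    if (all(degen)) NA_real_ else mean(pvals[!degen] < alpha)
  attr(rows, "alpha") <- alpha
  rows
}

#' Band-average a cross-spectrum
#'
#' Per named band, the arithmetic mean of the per-frequency matrices over the
#' grid frequencies in `[lo, hi)` (closed-open convention). Every band must
#' contain at least one grid frequency.
#'
#' @param cs a [cross_spectrum()].
#' @param bands a [frequency_bands()] object or compatible named list.
#' @return named list of [cross_spectrum()] objects, one per band (each with a
#'   single "frequency" equal to the band's first grid frequency, tagged with
#'   attribute `band`).
#' @export
band_average <- function(cs, bands = frequency_bands()) {
  freqs <- cs$grid$frequencies
  out <- list()
  for (nm in names(bands)) {
    b <- bands[[nm]]
    idx <- which(freqs >= b[1] & freqs < b[2])
    if (length(idx) == 0L)
      stop_invalid("band '", nm, "' [", b[1], ", ", b[2],
                   ") contains no grid frequency")
    avg <- apply(cs$matrices[, , idx, drop = FALSE], c(1L, 2L), mean)
    g <- spectral_grid(cs$grid$num_samples_per_segment, cs$grid$sampling_period,
                       frequencies = freqs[idx[1L]],
                       num_segments = cs$grid$num_segments)
    bcs <- cross_spectrum(hermitianize(avg), g, sample_size = cs$sample_size,
                          space_tag = cs$space_tag, names = cs$names)
    attr(bcs, "band") <- nm
    out[[nm]] <- bcs
  }
  out
}
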