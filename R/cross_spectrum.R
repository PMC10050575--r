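#' Cross-spectrum container
#'
#' A cross-spectral density estimate: one Hermitian positive-semidefinite
#' `R x R` complex matrix per analysis frequency, stored as an
#' `R x R x F` array, together with the sample size `M` that produced it
#' and a tag saying whether it lives in sensor or source space.
#'
#' @param matrices complex (or real) array `R x R x F`, or a single `R x R`
#'   matrix for one frequency.
#' @param grid a [spectral_grid()] whose frequencies index the third dimension.
#' @param sample_size number of Fourier instances averaged (`M`).
#' @param space_tag `"sensor"` or `"source"`.
#' @param names optional channel / source names.
#' @param validate check Hermitian-PSD invariants (default `TRUE`).
#'
#' @return object of class `cross_spectrum`.
#' @export
cross_spectrum <- function(matrices, grid, sample_size = grid$num_segments,
                           space_tag = c("sensor", "source"), names = NULL,
                           validate = TRUE) {
  space_tag <- match.arg(space_tag)
  if (is.matrix(matrices)) matrices <- array(matrices, c(dim(matrices), 1L))
  if (length(dim(matrices)) != 3L || dim(matrices)[1] != dim(matrices)[2])
    stop_invalid("matrices must be an R x R x F array")
  if (dim(matrices)[3] != length(grid$frequencies))
    stop_invalid("third dimension (", dim(matrices)[3],
                 ") must match the number of grid frequencies (",
                 length(grid$frequencies), ")")
  storage.mode(matrices) <- "complex"
  obj <- structure(list(matrices = matrices, grid = grid,
                        sample_size = as.integer(sample_size),
                        space_tag = space_tag, names = names),
                   class = "cross_spectrum")
  if (validate) validate_cross_spectrum(obj)
  obj
}

#' Validate the Hermitian-PSD invariants of a cross-spectrum
#'
#' Checks, per frequency: Hermitian symmetry to relative tolerance `1e-10`,
#' minimum eigenvalue not below `-1e-8` times the maximum eigenvalue, and a
#' real nonnegative diagonal.
#'
#' @param cs a [cross_spectrum()].
#' @param herm_tol,psd_tol relative tolerances.
#' @return `cs`, invisibly; errors on violation.
#' @export
validate_cross_spectrum <- function(cs, herm_tol = 1e-10, psd_tol = 1e-8) {
  for (k in seq_len(dim(cs$matrices)[3])) {
    S <- cs_slice(cs, k)
    scale <- max(Mod(S), 1e-300)
    if (max(Mod(S - Conj(t(S)))) > herm_tol * scale)
      stop_invalid("cross-spectrum matrix at frequency index ", k, " is not Hermitian")
    if (any(abs(Im(diag(S))) > herm_tol * scale) ||
        any(Re(diag(S)) < -psd_tol * scale))
      stop_invalid("cross-spectrum diagonal at frequency index ", k,
                   " is not real nonnegative")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -psd_tol * max(ev, 0, na.rm = TRUE) - 1e-300)
      stop_invalid("cross-spectrum matrix at frequency index ", k,
                   " is not positive semidefinite (min eigenvalue ", min(ev), ")")
  }
  invisible(cs)
}

#' @export
print.cross_spectrum <- function(x, ...) {
  d <- dim(x$matrices)
  cat(sprintf("cross_spectrum [%s space]: %d x %d, %d frequencies, M = %d\n",
              x$space_tag, d[1], d[2], d[3], x$sample_size))
  invisible(x)
}

#' @export
dim.cross_spectrum <- function(x) dim(x$matrices)

# force exact Hermitian symmetry (averages with the conjugate transpose)
hermitianize <- function(S) (S + Conj(t(S))) / 2

# frequency slice as a matrix even when R = 1 (guards the diag(scalar) trap)
cs_slice <- function(cs, k) {
  d <- dim(cs$matrices)
  matrix(cs$matrices[, , k], d[1], d[2])
}

#' Fourier instance container
#'
#' Complex Fourier coefficients indexed (channel, frequency, segment) as an
#' `R x F x M` array, paired with the [spectral_grid()] that defines the
#' frequencies. These are the per-segment discrete Fourier transforms whose
#' outer products average into a sample cross-spectrum.
#'
#' @param values complex `R x F x M` array.
#' @param grid a [spectral_grid()]; `grid$num_segments` must equal `M`.
#' @param names optional channel names.
#' @return object of class `fourier_instances`.
#' @export
fourier_instances <- function(values, grid, names = NULL) {
  if (length(dim(values)) != 3L)
    stop_invalid("values must be an R x F x M array")
  if (dim(values)[2] != length(grid$frequencies))
    stop_invalid("frequency dimension mismatch with grid")
  if (dim(values)[3] != grid$num_segments)
    stop_invalid("segment count (", dim(values)[3],
                 ") must equal grid$num_segments (", grid$num_segments, ")")
  storage.mode(values) <- "complex"
  structure(list(values = values, grid = grid, names = names),
            class = "fourier_instances")
}

#' @export
print.fourier_instances <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("fourier_instances: %d channels x %d frequencies x %d segments\n",
              d[1], d[2], d[3]))
  invisible(x)
}
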