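#' Resolution operator
#'
#' `R = T L`: the source-to-source map of an inverse solution. Column `g0` is
#' the source-space image (point spread) of a unit point source at `g0`.
#'
#' @param op a [quasilinear_operator()] (or plain `G x E` matrix).
#' @param L a [lead_field()] (or plain `E x G` matrix).
#' @return object of class `resolution_operator` with fields `R` and `method`.
#' @export
resolution_operator <- function(op, L) {
  T <- if (inherits(op, "quasilinear_operator")) op$T else as.matrix(op)
  Lm <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  if (ncol(T) != nrow(Lm))
    stop_invalid("operator columns (", ncol(T), ") must match lead field rows (",
                 nrow(Lm), ")")
  structure(list(R = T %*% Lm,
                 method = if (inherits(op, "quasilinear_operator")) op$method else "matrix"),
            class = "resolution_operator")
}

#' @export
print.resolution_operator <- function(x, ...) {
  cat(sprintf("resolution_operator [%s]: %d x %d\n", x$method,
              nrow(x$R), ncol(x$R)))
  invisible(x)
}

#' Reference set: most active fraction of a reference CST
#'
#' The `ceiling(fraction * G)` grid points with the largest reference values
#' (default: the most active 25%). Ties are broken toward the lowest index,
#' deterministically.
#'
#' @param reference_cst nonnegative length-`G` vector.
#' @param fraction in `(0, 1]`.
#' @return integer vector of 1-based indices, sorted increasingly.
#' @export
reference_set <- function(reference_cst, fraction = 0.25) {
  if (fraction <= 0 || fraction > 1) stop_invalid("fraction must be in (0, 1]")
  if (all(reference_cst == 0)) stop_invalid("reference CST is all zero")
  g <- length(reference_cst)
  k <- ceiling(fraction * g)
  ord <- order(reference_cst, seq_len(g), decreasing = c(TRUE, FALSE),
               method = "radix")
  sort(ord[seq_len(k)])
}

#' Generalized point spread function (GPSF)
#'
#' `r(g) = (1/|G0|) sum_{g0 in G0} |R(g, g0)|^2`: the mean squared point
#' spread of the resolution operator over a reference set.
#'
#' @param R a [resolution_operator()] (or plain matrix).
#' @param G0 nonempty integer index set (1-based).
#' @return nonnegative length-`G` vector.
#' @export
gpsf <- function(R, G0) {
  Rm <- if (inherits(R, "resolution_operator")) R$R else as.matrix(R)
  if (length(G0) == 0L) stop_invalid("reference set G0 must be nonempty")
  rowMeans(abs(Rm[, G0, drop = FALSE])^2)
}

#' Spatial dispersion of one point spread column
#'
#' `theta2(g0) = (1/G) sum_g |R(g, g0)| d(g, g0)^2` with `d` the geodesic
#' distance (mm): the distance-weighted spread of the image of a point source
#' at `g0`. The magnitude (not squared magnitude) weighting is used; set
#' `normalize = TRUE` to divide by `sum_g |R(g, g0)|` (a gain-invariant
#' variant common in the point-spread literature).
#'
#' @param R a [resolution_operator()] (or matrix).
#' @param g0 1-based column index.
#' @param distances `G x G` geodesic distance matrix (mm).
#' @param normalize divide by the column's total magnitude (default `FALSE`).
#' @return nonnegative scalar (mm^2).
#' @export
spatial_dispersion <- function(R, g0, distances, normalize = FALSE) {
  Rm <- if (inherits(R, "resolution_operator")) R$R else as.matrix(R)
  col <- abs(Rm[, g0])
  val <- sum(col * distances[, g0]^2)
  if (normalize) {
    tot <- sum(col)
    if (tot == 0) return(0)
    val / tot
  } else {
    val / nrow(Rm)
  }
}

#' BLUR: mean spatial dispersion over the reference set
#'
#' `b = (1/|G0|) sum_{g0 in G0} theta2(g0)`. Zero exactly when every reference
#' column of the resolution operator is concentrated at its own source (as for
#' the identity operator: a perfect inverse solution).
#'
#' @inheritParams spatial_dispersion
#' @param G0 nonempty reference index set.
#' @return nonnegative scalar (mm^2).
#' @export
blur <- function(R, G0, distances, normalize = FALSE) {
  if (length(G0) == 0L) stop_invalid("reference set G0 must be nonempty")
  mean(vapply(G0, function(g0) spatial_dispersion(R, g0, distances, normalize),
              numeric(1L)))
}

#' Earth mover's distance between two CSTs
#'
#' The optimal-transport cost between the two topographies, each normalized
#' to unit mass, with the geodesic distance as ground cost, solved exactly as
#' a transportation linear program (network simplex). Symmetric; zero iff the
#' normalized inputs coincide; satisfies the triangle inequality.
#'
#' @param cst_a,cst_b nonnegative length-`G` vectors with positive total mass.
#' @param distances `G x G` geodesic distance matrix (mm).
#' @return scalar transport cost in mm.
#' @export
emd <- function(cst_a, cst_b, distances) {
  if (length(cst_a) != length(cst_b))
    stop_invalid("CSTs must have equal length")
  if (any(cst_a < 0) || any(cst_b < 0))
    stop_invalid("CSTs must be nonnegative")
  sa <- sum(cst_a); sb <- sum(cst_b)
  if (sa <= 0 || sb <= 0) stop_invalid("CSTs must have positive total mass")
  a <- cst_a / sa
  b <- cst_b / sb
  # restrict to the union support to keep the LP small
  keep <- which(a > 0 | b > 0)
  transport_cost_cpp(a[keep], b[keep],
                     distances[keep, keep, drop = FALSE])
}

#' Correlation distance between two CSTs
#'
#' `1 - Pearson correlation` of the two topographies (in `[0, 2]`); with
#' `log_scale = TRUE` the correlation is computed on `log` values (requires
#' strictly positive inputs).
#'
#' @param cst_a,cst_b non-constant length-`G` vectors.
#' @param log_scale compute on the log scale (default `FALSE`).
#' @return scalar in `[0, 2]`.
#' @export
corr_distance <- function(cst_a, cst_b, log_scale = FALSE) {
  if (log_scale) {
    if (any(cst_a <= 0) || any(cst_b <= 0))
      stop_invalid("log-scale correlation requires strictly positive CSTs")
    cst_a <- log(cst_a); cst_b <- log(cst_b)
  }
  if (sd(cst_a) == 0 || sd(cst_b) == 0)
    stop_invalid("correlation distance undefined for a constant CST")
  1 - cor(cst_a, cst_b)
}

#' Peak localization error
#'
#' Geodesic distance (mm) between the peak of an estimated CST and a true
#' source vertex. Ties in the argmax resolve to the lowest index.
#'
#' @param estimated_cst non-constant length-`G` vector.
#' @param true_index 1-based vertex index of the true source.
#' @param distances `G x G` geodesic distance matrix (mm).
#' @return scalar distance in mm.
#' @export
localization_error <- function(estimated_cst, true_index, distances) {
  if (sd(estimated_cst) == 0)
    stop_invalid("localization error undefined for a constant CST")
  peak <- which.max(estimated_cst)  # ties: lowest index
  distances[peak, true_index]
}

#' Distortion report for one method and band
#'
#' Bundles every distortion measure of a tested CST against a reference CST:
#' the GPSF vector and BLUR of the method's resolution operator over the
#' reference set, the earth mover's distance and correlation distance between
#' the two topographies, and (when a true peak vertex is supplied) the peak
#' localization error.
#'
#' @param op a [quasilinear_operator()] for the tested method.
#' @param L a [lead_field()].
#' @param tested_cst length-`G` estimated topography.
#' @param reference_cst length-`G` reference topography.
#' @param distances `G x G` geodesic distance matrix.
#' @param band band tag recorded in the report.
#' @param fraction reference-set fraction (default 0.25).
#' @param true_index optional true peak vertex for localization error.
#' @return object of class `distortion_report`: a list with `gpsf`, `blur`,
#'   `emd`, `corr_distance`, `localization_error`, `reference_set`, `band`,
#'   `method`.
#' @export
distortion_report <- function(op, L, tested_cst, reference_cst, distances,
                              band = NA_character_, fraction = 0.25,
                              true_index = NULL) {
  R <- resolution_operator(op, L)
  G0 <- reference_set(reference_cst, fraction)
  structure(list(
    gpsf = gpsf(R, G0),
    blur = blur(R, G0, distances),
    emd = emd(tested_cst, reference_cst, distances),
    corr_distance = corr_distance(tested_cst, reference_cst),
    localization_error = if (is.null(true_index)) NA_real_ else
      localization_error(tested_cst, true_index, distances),
    reference_set = G0, band = band,
    method = if (inherits(op, "quasilinear_operator")) op$method else "matrix"),
    class = "distortion_report")
}

#' @export
print.distortion_report <- function(x, ...) {
  cat(sprintf("distortion_report [%s, band %s]: blur %.4g mm^2, emd %.4g mm, 1-corr %.4g\n",
              x$method, x$band, x$blur, x$emd, x$corr_distance))
  invisible(x)
}
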