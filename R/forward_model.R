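#' Cortical source space
#'
#' A triangulated source mesh: `G x 3` vertex coordinates in mm, 0-based
#' integer triangle triples, and (lazily computed) graph-geodesic distances
#' along mesh edges.
#'
#' @param vertices numeric `G x 3` matrix (mm).
#' @param triangles integer `n x 3` matrix of 0-based vertex indices.
#' @param geodesic optional precomputed `G x G` distance matrix (mm).
#' @return object of class `source_space` with fields `vertices`, `triangles`,
#'   `geodesic` (possibly `NULL` until [geodesic_distances()] is called) and
#'   `normals` (outward unit vertex normals, area-weighted from incident
#'   triangles; radial fallback for isolated vertices).
#' @export
source_space <- function(vertices, triangles, geodesic = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  if (ncol(vertices) != 3L) stop_invalid("vertices must be G x 3")
  if (ncol(triangles) != 3L) stop_invalid("triangles must be n x 3")
  storage.mode(triangles) <- "integer"
  g <- nrow(vertices)
  if (any(triangles < 0L) || any(triangles >= g))
    stop_invalid("triangle indices must be 0-based in [0, G-1]")
  if (!is.null(geodesic)) {
    geodesic <- as.matrix(geodesic)
    if (!all(dim(geodesic) == c(g, g)))
      stop_invalid("geodesic matrix must be G x G")
  }
  normals <- vertex_normals(vertices, triangles)
  structure(list(vertices = vertices, triangles = triangles,
                 geodesic = geodesic, normals = normals),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("source_space: %d vertices, %d triangles, geodesics %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is.null(x$geodesic)) "not computed" else "cached"))
  invisible(x)
}

# area-weighted outward vertex normals; falls back to the radial direction
# (vertex minus centroid) for vertices with no incident triangle.
vertex_normals <- function(vertices, triangles) {
  g <- nrow(vertices)
  nrm <- matrix(0, g, 3L)
  if (nrow(triangles) > 0L) {
    for (i in seq_len(nrow(triangles))) {
      tri <- triangles[i, ] + 1L
      e1 <- vertices[tri[2], ] - vertices[tri[1], ]
      e2 <- vertices[tri[3], ] - vertices[tri[1], ]
      fn <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      for (v in tri) nrm[v, ] <- nrm[v, ] + fn
    }
  }
  centroid <- colMeans(vertices)
  for (v in seq_len(g)) {
    n2 <- sqrt(sum(nrm[v, ]^2))
    if (n2 < 1e-12) {
      rad <- vertices[v, ] - centroid
      nrm[v, ] <- rad / max(sqrt(sum(rad^2)), 1e-12)
    } else {
      nrm[v, ] <- nrm[v, ] / n2
      # orient outward relative to the centroid
      if (sum(nrm[v, ] * (vertices[v, ] - centroid)) < 0) nrm[v, ] <- -nrm[v, ]
    }
  }
  nrm
}

#' Graph-geodesic distances on a mesh
#'
#' Shortest-path distances along mesh edges, with each edge weighted by its
#' Euclidean length (mm). This is the standard graph approximation to surface
#' geodesics; the result is symmetric with a zero diagonal. Errors if the mesh
#' edge graph is disconnected, naming the components.
#'
#' @param space a [source_space()].
#' @return the `G x G` distance matrix; also cached when assigned back, e.g.
#'   `space$geodesic <- geodesic_distances(space)`.
#' @export
geodesic_distances <- function(space) {
  if (!is.null(space$geodesic)) return(space$geodesic)
  tri <- space$triangles + 1L
  edges <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(1L, 3L)])
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  w <- sqrt(rowSums((space$vertices[edges[, 1L], , drop = FALSE] -
                     space$vertices[edges[, 2L], , drop = FALSE])^2))
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, nrow(space$vertices) - igraph::vcount(gr)))
  comp <- igraph::components(gr)
  if (comp$no > 1L)
    stop_invalid("mesh is disconnected: ", comp$no, " components with sizes ",
                 paste(comp$csize, collapse = ", "))
  d <- igraph::distances(gr, weights = w)
  dimnames(d) <- NULL
  d
}

#' Sensor montage
#'
#' Named sensor positions (mm) on a scalp sphere.
#'
#' @param names character vector of unique sensor names.
#' @param positions `E x 3` coordinates in mm.
#' @param head_radius nominal scalp radius (mm); positions are checked to sit
#'   at this radius within `radius_tol` relative tolerance.
#' @param radius_tol relative tolerance on the radius check.
#' @return object of class `sensor_montage`.
#' @export
sensor_montage <- function(names, positions, head_radius = 90,
                           radius_tol = 0.05) {
  positions <- as.matrix(positions)
  if (anyDuplicated(names)) stop_invalid("sensor names must be unique")
  if (nrow(positions) != length(names) || ncol(positions) != 3L)
    stop_invalid("positions must be length(names) x 3")
  r <- sqrt(rowSums(positions^2))
  if (any(abs(r - head_radius) > radius_tol * head_radius))
    stop_invalid("sensor positions must lie at the head radius (",
                 head_radius, " mm) within ", 100 * radius_tol, "%")
  dimnames(positions) <- NULL
  structure(list(names = as.character(names), positions = positions,
                 head_radius = head_radius),
            class = "sensor_montage")
}

#' @export
print.sensor_montage <- function(x, ...) {
  cat(sprintf("sensor_montage: %d sensors at radius %.1f mm\n",
              length(x$names), x$head_radius))
  invisible(x)
}

#' Lead field (forward operator)
#'
#' The real `E x G` matrix mapping unit source currents at mesh vertices to
#' sensor potentials. Every source must be visible to at least one sensor
#' (no all-zero column); the intended regime is ill-conditioned with
#' `E < G` (a warning, not an error, if violated).
#'
#' @param matrix real `E x G` matrix.
#' @param channel_names sensor names (length `E`).
#' @param source_space_id free-form reference to the source space used.
#' @param normalized logical flag recording whether columns were scaled to
#'   unit norm.
#' @return object of class `lead_field`.
#' @export
lead_field <- function(matrix, channel_names = NULL, source_space_id = NULL,
                       normalized = FALSE) {
  matrix <- as.matrix(matrix)
  dimnames(matrix) <- NULL
  if (!all(is.finite(matrix))) stop_invalid("lead field entries must be finite")
  cn <- sqrt(colSums(matrix^2))
  if (any(cn == 0)) stop_invalid("lead field has an all-zero column (source ",
                                 which(cn == 0)[1L], " invisible to all sensors)")
  if (nrow(matrix) >= ncol(matrix))
    warning("lead field has E >= G; the intended regime is under-determined (E < G)")
  if (!is.null(channel_names) && length(channel_names) != nrow(matrix))
    stop_invalid("channel_names length must equal the number of rows")
  structure(list(matrix = matrix, channel_names = channel_names,
                 source_space_id = source_space_id, normalized = normalized),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("lead_field: %d sensors x %d sources%s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$normalized) " (unit-norm columns)" else ""))
  invisible(x)
}

# potential of a current dipole at r0 with moment q, in an infinite
# homogeneous conductor: phi(r) = (1/(4 pi sigma)) q . (r - r0) / |r - r0|^3
dipole_potential <- function(sensors, r0, q, conductivity) {
  dr <- sweep(sensors, 2L, r0)
  d3 <- rowSums(dr^2)^1.5
  (dr %*% q) / (4 * pi * conductivity * d3)
}

#' Toy dipole lead field on a spherical head
#'
#' Column `g` is the electric potential, at the montage sensors, of a unit
#' current dipole at mesh vertex `g` oriented along the vertex normal, in an
#' infinite homogeneous medium, then average-referenced so every column has
#' zero mean across sensors. This closed-form model preserves the smoothness
#' and severe ill-conditioning that realistic head models exhibit while
#' remaining fully testable.
#'
#' @param montage a [sensor_montage()].
#' @param space a [source_space()]; vertices must be strictly inside the
#'   sensor sphere and not coincide with any sensor.
#' @param conductivity scalar conductivity (S/m), default 0.33.
#' @param normalize_columns scale each column to unit norm after average
#'   referencing (default `FALSE`); recorded in the result's metadata.
#' @return a [lead_field()].
#' @export
make_toy_leadfield <- function(montage, space, conductivity = 0.33,
                               normalize_columns = FALSE) {
  sens <- montage$positions
  verts <- space$vertices
  rs <- sqrt(rowSums(verts^2))
  if (any(rs >= montage$head_radius))
    stop_invalid("all sources must lie strictly inside the sensor sphere")
  L <- matrix(0, nrow(sens), nrow(verts))
  for (g in seq_len(nrow(verts))) {
    dmin <- min(sqrt(rowSums(sweep(sens, 2L, verts[g, ])^2)))
    if (dmin < 1e-9)
      stop_invalid("source ", g, " coincides with a sensor")
    L[, g] <- dipole_potential(sens, verts[g, ], space$normals[g, ], conductivity)
  }
  L <- sweep(L, 2L, colMeans(L))  # average reference
  if (normalize_columns) L <- sweep(L, 2L, sqrt(colSums(L^2)), `/`)
  lead_field(L, channel_names = montage$names, normalized = normalize_columns)
}

#' Project a source cross-spectrum to the sensors
#'
#' The route-3 forward relation `Sigma_vv(f) = L Sigma_ii(f) L' + Sigma_xi(f)`
#' applied per frequency. Hermitian positive-semidefiniteness is preserved.
#'
#' @param src_cs source-space [cross_spectrum()] (`G x G x F`).
#' @param L a [lead_field()] (`E x G`).
#' @param noise_cs sensor-space noise [cross_spectrum()] (`E x E x F`), or
#'   `NULL` for noiseless projection.
#' @return sensor-space [cross_spectrum()].
#' @export
project_source_cross_spectrum <- function(src_cs, L, noise_cs = NULL) {
  Lm <- L$matrix
  if (dim(src_cs$matrices)[1] != ncol(Lm))
    stop_invalid("source cross-spectrum dimension (", dim(src_cs$matrices)[1],
                 ") must match lead field columns (", ncol(Lm), ")")
  nf <- dim(src_cs$matrices)[3]
  if (!is.null(noise_cs)) {
    if (dim(noise_cs$matrices)[1] != nrow(Lm) ||
        dim(noise_cs$matrices)[3] != nf)
      stop_invalid("noise cross-spectrum must be E x E x F")
  }
  out <- array(0i, c(nrow(Lm), nrow(Lm), nf))
  for (k in seq_len(nf)) {
    S <- Lm %*% cs_slice(src_cs, k) %*% t(Lm)
    if (!is.null(noise_cs)) S <- S + cs_slice(noise_cs, k)
    out[, , k] <- hermitianize(S)
  }
  cross_spectrum(out, src_cs$grid, sample_size = src_cs$sample_size,
                 space_tag = "sensor", names = L$channel_names)
}
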