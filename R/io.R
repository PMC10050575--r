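#' Read and write multichannel time series as delimited text
#'
#' CSV with one column per channel (header row of channel names) and one row
#' per sample; in memory the series is a `channels x samples` matrix with
#' `rownames` the channel names.
#'
#' @param data `channels x samples` numeric matrix with rownames.
#' @param path file path.
#' @return `write_time_series_csv` returns `path` invisibly;
#'   `read_time_series_csv` returns the matrix.
#' @export
write_time_series_csv <- function(data, path) {
  df <- as.data.frame(t(data))
  names(df) <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_time_series_csv
#' @export
read_time_series_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 1L || nrow(df) < 1L)
    stop_invalid("time series file '", path, "' is empty")
  m <- t(as.matrix(df))
  if (!is.numeric(m)) stop_invalid("non-numeric values in '", path, "'")
  m
}

#' Read and write a triangulated mesh in OFF format
#'
#' Standard text OFF: a header line `OFF`, a count line
#' `n_vertices n_triangles 0`, vertex coordinate lines, then triangle lines
#' `3 i j k` with 0-based indices.
#'
#' @param space a [source_space()].
#' @param path file path.
#' @return `write_mesh_off` returns `path` invisibly; `read_mesh_off` returns
#'   a [source_space()] (without cached geodesics).
#' @export
write_mesh_off <- function(space, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(space$vertices), nrow(space$triangles)), con)
  writeLines(apply(space$vertices, 1L,
                   function(v) paste(format(v, digits = 17), collapse = " ")), con)
  writeLines(apply(space$triangles, 1L,
                   function(t) paste(c(3L, t), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (toupper(trimws(lines[1L])) != "OFF")
    stop_invalid("'", path, "' line 1: missing OFF header")
  counts <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  nv <- counts[1L]; nt <- counts[2L]
  if (length(lines) < 2L + nv + nt)
    stop_invalid("'", path, "': truncated file (expected ", nv, " vertices and ",
                 nt, " triangles)")
  verts <- do.call(rbind, lapply(lines[3:(2L + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
  tris <- do.call(rbind, lapply(lines[(3L + nv):(2L + nv + nt)], function(l) {
    f <- as.integer(strsplit(trimws(l), "\\s+")[[1L]])
    if (f[1L] != 3L) stop_invalid("'", path, "': non-triangle face")
    f[2:4]
  }))
  if (any(tris < 0L) || any(tris >= nv))
    stop_invalid("'", path, "': triangle index out of range [0, ", nv - 1L, "]")
  source_space(verts, tris)
}

#' Read and write a sensor montage as CSV
#'
#' Columns `name, x, y, z` (mm).
#'
#' @param montage a [sensor_montage()].
#' @param path file path.
#' @param head_radius radius used to validate on read.
#' @return `write_montage_csv` returns `path` invisibly; `read_montage_csv`
#'   returns a [sensor_montage()].
#' @export
write_montage_csv <- function(montage, path) {
  df <- data.frame(name = montage$names, x = montage$positions[, 1L],
                   y = montage$positions[, 2L], z = montage$positions[, 3L])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage_csv
#' @export
read_montage_csv <- function(path, head_radius = NULL) {
  df <- read.csv(path)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop_invalid("'", path, "': montage CSV must have columns name,x,y,z")
  pos <- as.matrix(df[, c("x", "y", "z")])
  r <- head_radius %||% mean(sqrt(rowSums(pos^2)))
  sensor_montage(df$name, pos, head_radius = r)
}

#' Read and write a lead field
#'
#' The CSV mirror stores the `E x G` matrix with channel names as the first
#' column; the container form (`write_leadfield` / `read_leadfield`) keeps
#' all metadata via RDS serialization.
#'
#' @param L a [lead_field()].
#' @param path file path.
#' @return writers return `path` invisibly; readers the [lead_field()].
#' @export
write_leadfield_csv <- function(L, path) {
  df <- data.frame(channel = L$channel_names %||% paste0("ch", seq_len(nrow(L$matrix))),
                   L$matrix, check.names = FALSE)
  names(df)[-1L] <- paste0("s", seq_len(ncol(L$matrix)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_leadfield_csv
#' @export
read_leadfield_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  lead_field(as.matrix(df[, -1L]), channel_names = df[[1L]])
}

#' @rdname write_leadfield_csv
#' @export
write_leadfield <- function(L, path) { saveRDS(L, path); invisible(path) }

#' @rdname write_leadfield_csv
#' @export
read_leadfield <- function(path) {
  L <- readRDS(path)
  if (!inherits(L, "lead_field")) stop_invalid("'", path, "' is not a lead field container")
  lead_field(L$matrix, L$channel_names, L$source_space_id, L$normalized)
}

#' Read and write a cross-spectrum container
#'
#' Serializes the per-frequency complex matrices, the frequency grid, the
#' sample size and the space tag; the load path re-validates the
#' Hermitian-PSD invariants. [write_spectra_csv()] exports the per-frequency
#' diagonal (the spectra) as a CSV mirror.
#'
#' @param cs a [cross_spectrum()].
#' @param path file path.
#' @return writers return `path` invisibly; `read_cross_spectrum` the
#'   validated [cross_spectrum()].
#' @export
write_cross_spectrum <- function(cs, path) { saveRDS(cs, path); invisible(path) }

#' @rdname write_cross_spectrum
#' @export
read_cross_spectrum <- function(path) {
  cs <- readRDS(path)
  if (!inherits(cs, "cross_spectrum"))
    stop_invalid("'", path, "' is not a cross-spectrum container")
  validate_cross_spectrum(cs)
  cs
}

#' @rdname write_cross_spectrum
#' @export
write_spectra_csv <- function(cs, path) {
  spec <- cst_from_cross_spectrum(cs)
  df <- data.frame(index = seq_len(nrow(spec)), spec)
  names(df)[-1L] <- sprintf("f_%g", cs$grid$frequencies)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write a solver result container
#'
#' Stores the operator (or operator set), any iterative state and the
#' estimated source cross-spectrum as one RDS container.
#'
#' @param result list as returned by [sssbl_solve()] or a single operator.
#' @param path file path.
#' @return writer returns `path` invisibly; reader the deserialized object.
#' @export
write_solver_result <- function(result, path) { saveRDS(result, path); invisible(path) }

#' @rdname write_solver_result
#' @export
read_solver_result <- function(path) readRDS(path)

#' Export a benchmark report
#'
#' CSV (one row per method x band) and JSON mirrors of a distortion report
#' table produced by [run_benchmark()].
#'
#' @param report data.frame from [run_benchmark()].
#' @param path output file path (`.csv` or `.json` decided by `format`).
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(report, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(schema = "cesi-report-v1", rows = report), path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
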