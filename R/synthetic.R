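#' Toy spherical-cap cortical mesh
#'
#' A deterministic source space on a spherical cap: `n_rings` colatitude rings
#' of `per_ring` vertices each on a sphere of radius `radius` (mm), cap
#' opening `cap_degrees`, triangulated between consecutive rings. The default
#' yields exactly `G = 200` vertices, the desk-scale analog of a cortical
#' surface under a scalp sensor sphere.
#'
#' @param n_rings number of colatitude rings (default 10).
#' @param per_ring vertices per ring (default 20).
#' @param radius sphere radius in mm (default 70).
#' @param cap_degrees colatitude of the last ring (default 75).
#' @return a [source_space()].
#' @export
toy_source_space <- function(n_rings = 10L, per_ring = 20L, radius = 70,
                             cap_degrees = 75) {
  if (n_rings < 2L || per_ring < 3L)
    stop_invalid("need n_rings >= 2 and per_ring >= 3 for a triangulated cap")
  thetas <- seq_len(n_rings) * (cap_degrees / n_rings) * pi / 180
  phis <- (seq_len(per_ring) - 1L) * 2 * pi / per_ring
  verts <- do.call(rbind, lapply(thetas, function(th) {
    cbind(radius * sin(th) * sin(phis),
          radius * sin(th) * cos(phis),
          radius * cos(th))
  }))
  tris <- list()
  for (r in 0:(n_rings - 2L)) {
    for (a in 0:(per_ring - 1L)) {
      v1 <- r * per_ring + a
      v2 <- r * per_ring + (a + 1L) %% per_ring
      v3 <- (r + 1L) * per_ring + a
      v4 <- (r + 1L) * per_ring + (a + 1L) %% per_ring
      tris[[length(tris) + 1L]] <- c(v1, v2, v3)
      tris[[length(tris) + 1L]] <- c(v2, v4, v3)
    }
  }
  source_space(verts, do.call(rbind, tris))
}

# spherical linear interpolation between unit vectors
slerp <- function(u, v, t = 0.5) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  om <- acos(max(-1, min(1, sum(u * v))))
  if (om < 1e-12) return(u)
  (sin((1 - t) * om) * u + sin(t * om) * v) / sin(om)
}

#' Toy 19-channel 10-20 montage
#'
#' An idealized spherical layout of the 19 standard 10-20 electrodes: the
#' outer ring on the equator every 36 degrees, midline and central electrodes
#' at 45 degrees from the vertex, and the intermediate electrodes (F3/F4,
#' P3/P4) as spherical midpoints of their neighbors.
#'
#' @param head_radius scalp sphere radius in mm (default 90).
#' @return a [sensor_montage()] with 19 sensors.
#' @export
toy_montage_1020 <- function(head_radius = 90) {
  unit <- function(theta_deg, phi_deg) {
    th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
    c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
  }
  pos <- list(
    Fp1 = unit(90, -18), Fp2 = unit(90, 18),
    F7 = unit(90, -54), F8 = unit(90, 54),
    T3 = unit(90, -90), T4 = unit(90, 90),
    T5 = unit(90, -126), T6 = unit(90, 126),
    O1 = unit(90, -162), O2 = unit(90, 162),
    Fz = unit(45, 0), Cz = unit(0, 0), Pz = unit(45, 180),
    C3 = unit(45, -90), C4 = unit(45, 90))
  pos$F3 <- slerp(pos$Fz, pos$F7)
  pos$F4 <- slerp(pos$Fz, pos$F8)
  pos$P3 <- slerp(pos$Pz, pos$T5)
  pos$P4 <- slerp(pos$Pz, pos$T6)
  order_1020 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                  "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  P <- head_radius * do.call(rbind, pos[order_1020])
  sensor_montage(order_1020, P, head_radius = head_radius)
}

#' Benchmark scenario specification
#'
#' Declares a full synthetic validation scenario: problem dimensions, the
#' active patches (center vertex, geodesic radius, spectral band, power), the
#' dense smooth background, the sensor signal-to-noise ratio, the spectral
#' grid, the band definitions and the master seed. The defaults are the
#' desk-scale study conditions used throughout: a 19-channel 10-20 montage,
#' 200 cortical sources, 600 segments, three coherent patches (alpha, theta,
#' beta) over a weak 1/f background at 10 dB sensor SNR.
#'
#' @param num_sensors `E` (default 19).
#' @param num_sources `G` (default 200).
#' @param num_segments `M` (default 600).
#' @param patches list of lists with fields `center` (1-based vertex),
#'   `radius_mm`, `band` (name in `bands`), `power`.
#' @param background_power mean diagonal background power (default 0.1).
#' @param snr_db sensor signal-to-noise ratio in dB (default 10); sets the
#'   white sensor noise power from the projected signal power at build time.
#' @param bands a [frequency_bands()] list.
#' @param sampling_period seconds (default 1/201 s, giving exactly 1 Hz
#'   resolution with 201-sample segments).
#' @param num_samples_per_segment odd segment length (default 201).
#' @param frequencies analysis frequencies in Hz (default 1:45).
#' @param seed master integer seed (default 20230315).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(num_sensors = 19L, num_sources = 200L,
                          num_segments = 600L,
                          patches = list(
                            list(center = 46L, radius_mm = 20, band = "alpha", power = 1),
                            list(center = 111L, radius_mm = 20, band = "theta", power = 1),
                            list(center = 176L, radius_mm = 20, band = "beta", power = 1)),
                          background_power = 0.1, snr_db = 10,
                          bands = frequency_bands(),
                          sampling_period = 1 / 201,
                          num_samples_per_segment = 201L,
                          frequencies = 1:45, seed = 20230315L) {
  if (num_sensors >= num_sources)
    stop_invalid("scenario requires E < G")
  if (background_power < 0 || any(vapply(patches, `[[`, numeric(1), "power") < 0))
    stop_invalid("powers must be nonnegative")
  for (p in patches) {
    if (p$center < 1L || p$center > num_sources)
      stop_invalid("patch center ", p$center, " outside [1, G]")
    if (!p$band %in% names(bands))
      stop_invalid("patch band '", p$band, "' not among the named bands")
  }
  structure(list(num_sensors = as.integer(num_sensors),
                 num_sources = as.integer(num_sources),
                 num_segments = as.integer(num_segments),
                 patches = patches, background_power = background_power,
                 snr_db = snr_db, bands = bands,
                 sampling_period = sampling_period,
                 num_samples_per_segment = as.integer(num_samples_per_segment),
                 frequencies = frequencies, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec: E=%d, G=%d, M=%d, %d patches, %g dB SNR, seed %d\n",
              x$num_sensors, x$num_sources, x$num_segments, length(x$patches),
              x$snr_db, x$seed))
  invisible(x)
}

# unit-peak spectral profile supported inside [lo, hi): Gaussian bump at the
# band center, truncated to the band
band_shape <- function(freqs, band_interval) {
  lo <- band_interval[1]; hi <- band_interval[2]
  mid <- (lo + hi) / 2
  sdv <- (hi - lo) / 4
  s <- exp(-(freqs - mid)^2 / (2 * sdv^2))
  s[freqs < lo | freqs >= hi] <- 0
  s
}

#' Ground-truth source cross-spectrum for a scenario
#'
#' Per frequency `Sigma_ii(f)` is a diagonal, spatially smooth background
#' (a seeded random field smoothed by a geodesic Gaussian kernel, scaled to
#' mean `background_power`, with a `1/f` spectral profile) plus, for each
#' patch, a rank-1 coherent term `power * bandshape(f) * u u'` where `u` is a
#' unit-peak geodesic Gaussian bump at the patch center with length scale
#' `radius_mm / 2`. Hermitian PSD by construction.
#'
#' @param spec a [scenario_spec()].
#' @param space a [source_space()] with `spec$num_sources` vertices.
#' @return source-space [cross_spectrum()] over `spec$frequencies`.
#' @export
make_source_cross_spectrum <- function(spec, space) {
  g <- spec$num_sources
  if (nrow(space$vertices) != g)
    stop_invalid("source space has ", nrow(space$vertices),
                 " vertices, scenario expects ", g)
  d <- geodesic_distances(space)
  dmax <- max(d)
  for (p in spec$patches) {
    if (p$radius_mm > dmax)
      stop_invalid("patch radius ", p$radius_mm,
                   " mm exceeds the mesh diameter (", signif(dmax, 4), " mm)")
  }
  freqs <- spec$frequencies
  grid <- spectral_grid(spec$num_samples_per_segment, spec$sampling_period,
                        frequencies = freqs, num_segments = spec$num_segments)
  # smooth background profile: seeded uniform field, geodesic Gaussian taper
  set.seed(spec$seed)
  raw <- runif(g, 0.5, 1.5)
  W <- exp(-d^2 / (2 * 30^2))
  bg_profile <- as.numeric(W %*% raw) / rowSums(W)
  bg_profile <- bg_profile / mean(bg_profile) * spec$background_power
  bg_spec <- (1 / freqs) / max(1 / freqs)     # unit-peak 1/f profile
  out <- array(0i, c(g, g, length(freqs)))
  bumps <- lapply(spec$patches, function(p) {
    u <- exp(-d[, p$center]^2 / (2 * (p$radius_mm / 2)^2))
    u / max(u)
  })
  for (k in seq_along(freqs)) {
    S <- diag(bg_profile * bg_spec[k], g)
    for (j in seq_along(spec$patches)) {
      p <- spec$patches[[j]]
      w <- p$power * band_shape(freqs[k], spec$bands[[p$band]])
      if (w > 0) S <- S + w * tcrossprod(bumps[[j]])
    }
    out[, , k] <- S
  }
  cross_spectrum(out, grid, sample_size = spec$num_segments,
                 space_tag = "source", validate = FALSE)
}

#' Sample circularly symmetric complex Gaussian Fourier instances
#'
#' Per frequency, draws `M` independent vectors `x = A z` with `A A^H =
#' Sigma(f)` (eigenvalue square root) and `z = (z_re + i z_im)/sqrt(2)`,
#' `z_re, z_im` standard normal — so `E[x x^H] = Sigma(f)` and the
#' pseudo-covariance `E[x x^T]` vanishes (circular symmetry). Reproducible by
#' seed.
#'
#' @param cs a PSD [cross_spectrum()].
#' @param M number of instances.
#' @param seed integer seed.
#' @return a [fourier_instances()] object with `M` segments.
#' @export
sample_fourier_instances <- function(cs, M, seed = 1L) {
  d <- dim(cs$matrices)
  r <- d[1]; nf <- d[3]
  set.seed(seed)
  vals <- array(0i, c(r, nf, M))
  for (k in seq_len(nf)) {
    S <- cs$matrices[, , k]
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values), 1e-300))
      stop_invalid("cross-spectrum not PSD at frequency index ", k)
    A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), r)
    Z <- (matrix(rnorm(r * M), r, M) + 1i * matrix(rnorm(r * M), r, M)) / sqrt(2)
    vals[, k, ] <- A %*% Z
  }
  grid <- cs$grid
  grid$num_segments <- as.integer(M)
  fourier_instances(vals, grid, names = cs$names)
}

#' Stationary AR(2) oscillator time series
#'
#' Gaussian AR(2) realizations `x_t = a1 x_{t-1} + a2 x_{t-2} + eps_t` per
#' channel, with innovation variance `sigma2`. These have the closed-form
#' spectral density of [ar2_spectral_density()], making them the standard
#' test bed for checking that sample cross-spectra of stationary series
#' converge to the analytic spectrum.
#'
#' @param ar_params numeric matrix `channels x 2` of `(a1, a2)` per channel
#'   (a length-2 vector for one channel). Roots of the AR polynomial must lie
#'   outside the unit circle (stationarity).
#' @param length number of samples.
#' @param sigma2 innovation variance (default 1).
#' @param seed integer seed.
#' @return numeric `channels x length` matrix.
#' @export
make_oscillator_series <- function(ar_params, length, sigma2 = 1, seed = 1L) {
  if (is.vector(ar_params)) ar_params <- matrix(ar_params, nrow = 1L)
  if (ncol(ar_params) != 2L) stop_invalid("ar_params must be channels x 2")
  set.seed(seed)
  out <- matrix(0, nrow(ar_params), length)
  for (ch in seq_len(nrow(ar_params))) {
    a <- ar_params[ch, ]
    # stationarity: roots of 1 - a1 z - a2 z^2 outside the unit circle
    if (any(abs(polyroot(c(1, -a[1], -a[2]))) <= 1))
      stop_invalid("AR(2) parameters (", a[1], ", ", a[2],
                   ") are not stationary")
    if (all(a == 0)) {
      out[ch, ] <- rnorm(length, sd = sqrt(sigma2))
    } else {
      out[ch, ] <- as.numeric(stats::arima.sim(
        model = list(ar = a), n = length, sd = sqrt(sigma2)))
    }
  }
  out
}

#' Analytic AR(2) spectral density
#'
#' `S(nu) = sigma2 / |1 - a1 e^{-i w} - a2 e^{-2 i w}|^2` with
#' `w = 2 pi nu sampling_period`: the discrete-time power spectral density of
#' a stationary AR(2) process (per-sample normalization). The sample
#' cross-spectrum of segmented realizations, divided by the segment length
#' `2T+1`, is a consistent estimator of this quantity.
#'
#' @param freqs_hz frequencies in Hz.
#' @param a1,a2 AR coefficients.
#' @param sigma2 innovation variance.
#' @param sampling_period seconds.
#' @return numeric vector of spectral densities.
#' @export
ar2_spectral_density <- function(freqs_hz, a1, a2, sigma2 = 1,
                                 sampling_period = 1) {
  w <- 2 * pi * freqs_hz * sampling_period
  den <- Mod(1 - a1 * exp(-1i * w) - a2 * exp(-2i * w))^2
  sigma2 / den
}

#' AR(2) parameters resonant at a target frequency
#'
#' `a1 = 2 rho cos(2 pi f0 ds)`, `a2 = -rho^2`: complex conjugate poles of
#' modulus `rho` at the target frequency, giving a spectral peak near `f0`.
#'
#' @param f0_hz resonance frequency (Hz).
#' @param rho pole modulus in (0, 1); closer to 1 is sharper.
#' @param sampling_period seconds.
#' @return numeric `c(a1, a2)`.
#' @export
ar2_resonant <- function(f0_hz, rho = 0.95, sampling_period = 1) {
  c(2 * rho * cos(2 * pi * f0_hz * sampling_period), -rho^2)
}

#' Build a complete synthetic benchmark bundle
#'
#' Composes the toy forward model and the generators: ground-truth source
#' cross-spectrum, route-3 projection to the sensors with white noise at the
#' scenario's SNR, `M` sampled complex Gaussian Fourier instances, and their
#' sample cross-spectrum — everything needed to run any solver and score it
#' against the truth. Fully deterministic given `spec$seed`.
#'
#' @param spec a [scenario_spec()].
#' @param space optional [source_space()] (default [toy_source_space()]).
#' @param montage optional [sensor_montage()] (default [toy_montage_1020()]).
#' @return list with `space`, `montage`, `leadfield`, `src_cs` (truth),
#'   `noise_power`, `sensor_cs` (analytic sensor cross-spectrum), `instances`,
#'   `sample_cs` (the estimator the solvers see), `truth_cst` (`G x F`), and
#'   `spec`.
#' @export
build_benchmark <- function(spec = scenario_spec(), space = NULL,
                            montage = NULL) {
  space <- space %||% toy_source_space(
    n_rings = spec$num_sources %/% 20L, per_ring = 20L)
  montage <- montage %||% toy_montage_1020()
  if (length(montage$names) != spec$num_sensors)
    stop_invalid("montage has ", length(montage$names),
                 " sensors, scenario expects ", spec$num_sensors)
  space$geodesic <- geodesic_distances(space)
  L <- make_toy_leadfield(montage, space)
  src_cs <- make_source_cross_spectrum(spec, space)
  nf <- length(spec$frequencies)
  e <- spec$num_sensors
  # white sensor noise at the requested SNR relative to projected signal power
  clean <- project_source_cross_spectrum(src_cs, L)
  sig_pow <- mean(vapply(seq_len(nf),
                         function(k) Re(sum(diag(clean$matrices[, , k]))) / e,
                         numeric(1L)))
  noise_power <- sig_pow / 10^(spec$snr_db / 10)
  noise <- cross_spectrum(
    array(diag(noise_power + 0i, e), c(e, e, nf)), src_cs$grid,
    sample_size = spec$num_segments, space_tag = "sensor", validate = FALSE)
  sensor_cs <- project_source_cross_spectrum(src_cs, L, noise)
  instances <- sample_fourier_instances(sensor_cs, spec$num_segments,
                                        seed = spec$seed + 1L)
  sample_cs <- sample_cross_spectrum(instances)
  list(space = space, montage = montage, leadfield = L, src_cs = src_cs,
       noise_power = noise_power, sensor_cs = sensor_cs,
       instances = instances, sample_cs = sample_cs,
       truth_cst = cst_from_cross_spectrum(src_cs), spec = spec)
}
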