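test_that("ground-truth source cross-spectra have the declared structure", {
  space <- toy_source_space(n_rings = 2, per_ring = 10)  # G = 20 toy
  # zero patches, zero background: all-zero matrices
  sp0 <- scenario_spec(num_sources = 20L, patches = list(),
                       background_power = 0, frequencies = 1:6)
  cs0 <- make_source_cross_spectrum(sp0, space)
  expect_true(all(cs0$matrices == 0))
  # single patch: CST peaks at the patch center in its band
  sp1 <- scenario_spec(num_sources = 20L,
                       patches = list(list(center = 7L, radius_mm = 30,
                                           band = "alpha", power = 1)),
                       background_power = 0.01, frequencies = 1:15)
  cs1 <- make_source_cross_spectrum(sp1, space)
  cst <- cst_from_cross_spectrum(cs1)
  expect_identical(which.max(cst[, 10]), 7L)  # 10 Hz is mid-alpha
  # oversized patch radius is rejected
  expect_error(make_source_cross_spectrum(
    scenario_spec(num_sources = 20L,
                  patches = list(list(center = 1L, radius_mm = 1e5,
                                      band = "alpha", power = 1)),
                  frequencies = 1:15), space),
    class = "cesi_invalid_argument")
})

test_that("generated cross-spectra are Hermitian PSD across random scenarios", {
  space <- toy_source_space(n_rings = 2, per_ring = 10)
  set.seed(71)
  for (i in 1:25) {
    np <- sample(0:3, 1)
    patches <- lapply(seq_len(np), function(j)
      list(center = sample(20, 1), radius_mm = runif(1, 10, 60),
           band = sample(c("theta", "alpha", "beta"), 1),
           power = runif(1, 0.1, 3)))
    sp <- scenario_spec(num_sources = 20L, patches = patches,
                        background_power = runif(1, 0, 0.5),
                        frequencies = seq(2, 30, by = 4),
                        seed = 7000L + i)
    cs <- make_source_cross_spectrum(sp, space)
    for (k in seq_len(dim(cs$matrices)[3])) {
      ev <- eigen(cs$matrices[, , k], symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-10 * max(ev, 0))
    }
  }
})

test_that("complex Gaussian sampling is circular, consistent, and reproducible", {
  set.seed(72)
  S <- random_hpsd(3) + 0.3 * diag(3)
  cs <- one_freq_cs(S)
  # zero covariance gives all-zero draws
  z <- sample_fourier_instances(one_freq_cs(matrix(0, 2, 2)), 10, seed = 1)
  expect_true(all(z$values == 0))
  # pseudo-covariance vanishes at rate ~ 1/sqrt(M)
  pseudo_norm <- function(M, seed) {
    x <- sample_fourier_instances(cs, M, seed = seed)$values[, 1, ]
    max(Mod(x %*% t(x) / M))
  }
  p_small <- mean(vapply(1:4, function(s) pseudo_norm(100, s), numeric(1)))
  p_large <- mean(vapply(1:4, function(s) pseudo_norm(6400, s + 9), numeric(1)))
  expect_lt(p_large, p_small / 3)          # expected factor 8, generous slack
  # sample cross-spectrum of draws approaches the target
  M <- 4000
  cs_hat <- sample_cross_spectrum(sample_fourier_instances(cs, M, seed = 3))
  rel <- sqrt(sum(Mod(cs_hat$matrices[, , 1] - S)^2)) / sqrt(sum(Mod(S)^2))
  expect_lt(rel, 9 / sqrt(M))
  # identical seeds give identical draws
  expect_identical(sample_fourier_instances(cs, 20, seed = 5)$values,
                   sample_fourier_instances(cs, 20, seed = 5)$values)
})

test_that("AR(2) oscillators: white-noise limit, resonance location, determinism", {
  ds <- 0.01
  # a1 = a2 = 0: flat spectrum within tolerance
  x <- make_oscillator_series(c(0, 0), 101 * 150, seed = 8)
  cs <- sample_cross_spectrum(fourier_transform_series(x, 101, ds))
  spec <- Re(vapply(seq_along(cs$grid$frequencies),
                    function(k) cs$matrices[1, 1, k], complex(1))) / 101
  expect_lt(sd(spec) / mean(spec), 0.25)
  expect_equal(mean(spec), 1, tolerance = 0.1)
  # resonant AR(2): spectral peak within one bin of 10 Hz at M = 200
  a <- ar2_resonant(10, rho = 0.95, sampling_period = ds)
  xr <- make_oscillator_series(a, 101 * 200, seed = 9)
  csr <- sample_cross_spectrum(fourier_transform_series(xr, 101, ds))
  specr <- Re(vapply(seq_along(csr$grid$frequencies),
                     function(k) csr$matrices[1, 1, k], complex(1)))
  fpeak <- csr$grid$frequencies[which.max(specr)]
  expect_lt(abs(fpeak - 10), csr$grid$spectral_resolution + 1e-9)
  # fixed seed reruns bit-identically; unstable parameters are rejected
  expect_identical(make_oscillator_series(a, 500, seed = 4),
                   make_oscillator_series(a, 500, seed = 4))
  expect_error(make_oscillator_series(c(1.5, 0.6), 100, seed = 1),
               class = "cesi_invalid_argument")
})

test_that("benchmark bundles are internally consistent and deterministic", {
  spec <- scenario_spec(num_sources = 40L, num_segments = 150L,
                        patches = list(list(center = 11L, radius_mm = 25,
                                            band = "alpha", power = 1)),
                        frequencies = seq(2, 34, by = 4), seed = 99L)
  space <- toy_source_space(n_rings = 2, per_ring = 20)
  b <- build_benchmark(spec, space = space)
  expect_s3_class(b$leadfield, "lead_field")
  expect_silent(validate_cross_spectrum(b$src_cs))
  expect_silent(validate_cross_spectrum(b$sample_cs))
  expect_equal(dim(b$truth_cst), c(40L, length(spec$frequencies)))
  # route consistency: sample CS of projected instances approaches the
  # analytic sensor cross-spectrum
  rel <- sqrt(sum(Mod(b$sample_cs$matrices - b$sensor_cs$matrices)^2)) /
    sqrt(sum(Mod(b$sensor_cs$matrices)^2))
  expect_lt(rel, 3 / sqrt(spec$num_segments))
  # same seed twice: identical bundles
  b2 <- build_benchmark(spec, space = space)
  expect_identical(b$sample_cs$matrices, b2$sample_cs$matrices)
  expect_identical(b$leadfield$matrix, b2$leadfield$matrix)
})
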