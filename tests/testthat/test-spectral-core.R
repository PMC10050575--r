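test_that("segmentation counts, starts and remainder handling follow the floor rule", {
  x <- matrix(seq_len(100), nrow = 1)
  expect_length(segment_time_series(x, 50, 0), 2L)
  segs <- segment_time_series(x, 60, 30)
  expect_length(segs, 2L)                       # remainder of 10 dropped
  expect_equal(segs[[2]][1, 1], 31)
  set.seed(4)
  y <- matrix(rnorm(3 * 500), 3)
  segs <- segment_time_series(y, 100, 50)
  expect_length(segs, 9L)
  for (m in seq_along(segs))                    # segment m starts at 50*(m-1)
    expect_identical(segs[[m]], y[, (50 * (m - 1) + 1):(50 * (m - 1) + 100)])
  expect_error(segment_time_series(y, 600), class = "cesi_invalid_argument")
  expect_error(segment_time_series(y, 100, 100), class = "cesi_invalid_argument")
})

test_that("centered DFT matches the direct summation oracle and is linear", {
  gr <- spectral_grid(101, 0.01)
  # constant series: all mass at zero frequency
  Xc <- discrete_fourier_transform(matrix(3, 1, 101), gr)
  expect_equal(Re(Xc[1, 1]), 101 * 3, tolerance = 1e-12)
  expect_lt(max(Mod(Xc[1, -1])), 1e-9)
  set.seed(11)
  seg <- matrix(rnorm(2 * 101), 2)
  X <- discrete_fourier_transform(seg, gr)
  for (ch in 1:2)
    expect_lt(max(Mod(X[ch, ] - brute_dft(seg[ch, ], gr))), 1e-10)
  # linearity
  seg2 <- matrix(rnorm(2 * 101), 2)
  X2 <- discrete_fourier_transform(seg2, gr)
  X12 <- discrete_fourier_transform(2 * seg - 3 * seg2, gr)
  expect_equal(X12, 2 * X - 3 * X2, tolerance = 1e-10)
  expect_error(discrete_fourier_transform(seg[, 1:50], gr),
               class = "cesi_invalid_argument")
})

test_that("sample cross-spectrum equals the averaged outer product and is Hermitian PSD", {
  gr <- spectral_grid(11, 0.1, frequencies = c(0, 1 / 1.1),
                      num_segments = 1L)
  v <- array(c(1 + 0i, 1i), c(2, 1, 1))
  vals <- array(0i, c(2, 2, 1)); vals[, , 1] <- cbind(v[, 1, 1], c(2i, 1))
  inst <- fourier_instances(array(v, c(2, 2, 1))[, , 1, drop = FALSE][, 1:2, , drop = FALSE],
                            gr)
  # single instance (1, i): rank-1 outer product
  inst1 <- fourier_instances(array(c(1 + 0i, 1i, 1 + 0i, 1i), c(2, 2, 1)), gr)
  cs1 <- sample_cross_spectrum(inst1)
  expect_equal(cs1$matrices[, , 1],
               matrix(c(1 + 0i, 1i, -1i, 1 + 0i), 2, 2), tolerance = 1e-12)
  # zero instances give the zero matrix
  gz <- spectral_grid(11, 0.1, frequencies = 0, num_segments = 3L)
  cs0 <- sample_cross_spectrum(fourier_instances(array(0i, c(2, 1, 3)), gz))
  expect_true(all(cs0$matrices == 0))
  # random instances: matches explicit enumeration; invariants hold
  set.seed(5)
  M <- 7
  vals <- array(complex(real = rnorm(3 * 2 * M), imaginary = rnorm(3 * 2 * M)),
                c(3, 2, M))
  gM <- spectral_grid(11, 0.1, frequencies = c(0, 1 / 1.1), num_segments = M)
  cs <- sample_cross_spectrum(fourier_instances(vals, gM))
  manual <- Reduce(`+`, lapply(seq_len(M), function(m)
    vals[, 1, m] %*% Conj(t(vals[, 1, m])))) / M
  expect_equal(cs$matrices[, , 1], manual, tolerance = 1e-12)
  expect_silent(validate_cross_spectrum(cs))
})

test_that("sample cross-spectrum is consistent for complex Gaussian draws", {
  # Monte-Carlo bound for M=1000 draws from Sigma = diag(2, 1), frozen from
  # repeated-draw calibration of the Frobenius error (~ sqrt(tr(S^2)+..)/sqrt(M))
  sig <- diag(c(2, 1)) + 0i
  cs_true <- one_freq_cs(sig)
  inst <- sample_fourier_instances(cs_true, 1000, seed = 42)
  cs_hat <- sample_cross_spectrum(inst)
  err <- sqrt(sum(Mod(cs_hat$matrices[, , 1] - sig)^2))
  expect_lt(err, 0.35)
})

test_that("complex Gaussian log-density: plug-in value, unitary invariance, unit mass", {
  expect_equal(complex_gaussian_logdensity(0 + 0i, 1), -log(pi))
  set.seed(2)
  S <- random_hpsd(3) + diag(3) * 0.5
  x <- complex(real = rnorm(3), imaginary = rnorm(3))
  # unitary invariance via QR of a random complex matrix
  Q <- qr.Q(qr(matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)))
  expect_equal(complex_gaussian_logdensity(Q %*% x, Q %*% S %*% Conj(t(Q))),
               complex_gaussian_logdensity(x, S), tolerance = 1e-10)
  # R = 1: quadrature over the complex plane integrates to 1
  s <- 0.7
  grid <- seq(-6, 6, length.out = 301)
  h <- grid[2] - grid[1]
  dens <- outer(grid, grid, function(a, b)
    exp(-log(pi * s) - (a^2 + b^2) / s))
  expect_equal(sum(dens) * h^2, 1, tolerance = 1e-4)
  expect_equal(complex_gaussian_logdensity(1 + 2i, s),
               log(1 / (pi * s) * exp(-(1 + 4) / s)), tolerance = 1e-12)
  expect_error(complex_gaussian_logdensity(0i, matrix(0, 1, 1)),
               class = "cesi_numerical_rank")
})

test_that("complex Wishart log-likelihood: maximizer, invariance, Gaussian link at M=R=1", {
  # R = 1: over sigma the maximizer is sigma = sbar
  sbar <- 1.7; M <- 12
  gr1 <- function(sig) complex_wishart_loglik(one_freq_cs(matrix(sbar, 1, 1), M = M),
                                              one_freq_cs(matrix(sig, 1, 1), M = M),
                                              dof = M)
  sigs <- seq(0.5, 4, by = 0.01)
  expect_equal(sigs[which.max(vapply(sigs, gr1, numeric(1)))], sbar,
               tolerance = 0.02)
  # unitary invariance
  set.seed(3)
  Sb <- random_hpsd(3) + 0.2 * diag(3)
  Sg <- random_hpsd(3) + 0.5 * diag(3)
  Q <- qr.Q(qr(matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3)))
  rot <- function(S) Q %*% S %*% Conj(t(Q))
  expect_equal(complex_wishart_loglik(one_freq_cs(rot(Sb)), one_freq_cs(rot(Sg)), 5),
               complex_wishart_loglik(one_freq_cs(Sb), one_freq_cs(Sg), 5),
               tolerance = 1e-8)
  expect_error(complex_wishart_loglik(one_freq_cs(Sb), one_freq_cs(Sg), 2),
               class = "cesi_invalid_argument")
  # M = R = 1: agrees with the complex Gaussian log-density up to -log(pi)
  x <- 0.8 + 0.3i
  sig <- 1.3
  w <- complex_wishart_loglik(one_freq_cs(matrix(Mod(x)^2, 1, 1), M = 1),
                              one_freq_cs(matrix(sig, 1, 1), M = 1), dof = 1)
  expect_equal(w - log(pi), complex_gaussian_logdensity(x, sig),
               tolerance = 1e-12)
})

test_that("M sigma_bar / sigma is Gamma(M, 1) distributed for scalar Wishart data", {
  set.seed(9)
  M <- 8; sig <- 2; n <- 400
  stat <- replicate(n, {
    x <- complex(real = rnorm(M, sd = sqrt(sig / 2)),
                 imaginary = rnorm(M, sd = sqrt(sig / 2)))
    M * mean(Mod(x)^2) / sig
  })
  ks <- suppressWarnings(stats::ks.test(stat, "pgamma", shape = M, rate = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("Gaussianity test is calibrated on Gaussian draws and catches heavy tails", {
  set.seed(21)
  M <- 200
  gr <- spectral_grid(11, 0.1, frequencies = c(0, 1 / 1.1), num_segments = M)
  # 25 channels x 2 frequencies x 2 parts = 100 tests on true Gaussians
  vals <- array(complex(real = rnorm(25 * 2 * M), imaginary = rnorm(25 * 2 * M)),
                c(25, 2, M))
  res <- gaussianity_test(fourier_instances(vals, gr), alpha = 0.05)
  raw <- attr(res, "raw_rejection_fraction")
  expect_lt(abs(raw - 0.05), 3 * sqrt(0.05 * 0.95 / 100))
  # BH-corrected fraction under the global null stays near zero
  expect_lt(attr(res, "rejection_fraction"), 0.05)
  # heavy-tailed coefficients reject far more often
  hv <- array(complex(real = rnorm(25 * 2 * M)^3, imaginary = rnorm(25 * 2 * M)^3),
              c(25, 2, M))
  res_h <- gaussianity_test(fourier_instances(hv, gr), alpha = 0.05)
  expect_gt(attr(res_h, "raw_rejection_fraction"), raw + 0.3)
  # all-zero instances are flagged degenerate
  z <- gaussianity_test(fourier_instances(array(0i, c(2, 2, M)), gr))
  expect_true(all(z$degenerate))
  expect_true(is.na(attr(z, "rejection_fraction")))
})

test_that("band averaging equals the enumerated per-band mean", {
  set.seed(7)
  nfreq <- 10
  gr <- spectral_grid(201, 1 / 201, frequencies = 1:nfreq, num_segments = 4L)
  mats <- array(0i, c(3, 3, nfreq))
  for (k in seq_len(nfreq)) mats[, , k] <- random_hpsd(3)
  cs <- cross_spectrum(mats, gr, space_tag = "sensor", validate = FALSE)
  bands <- frequency_bands(list(lo = c(1, 4), hi = c(4, 11)))
  ba <- band_average(cs, bands)
  expect_equal(ba$lo$matrices[, , 1],
               apply(mats[, , 1:3, drop = FALSE], c(1, 2), mean),
               tolerance = 1e-12)
  expect_equal(ba$hi$matrices[, , 1],
               apply(mats[, , 4:10, drop = FALSE], c(1, 2), mean),
               tolerance = 1e-12)
  # one frequency per band is the identity mapping; constants stay put
  b1 <- band_average(cs, frequency_bands(list(one = c(2, 3))))
  expect_equal(b1$one$matrices[, , 1], mats[, , 2], tolerance = 1e-12)
  expect_error(band_average(cs, frequency_bands(list(empty = c(50, 60)))),
               class = "cesi_invalid_argument")
})

test_that("sample spectra of AR(2) oscillators converge to the analytic spectrum", {
  ds <- 0.01
  n_seg <- 101
  a <- ar2_resonant(10, rho = 0.7, sampling_period = ds)
  # closed-form AR(2) autocovariance by Yule-Walker recursion
  r1 <- a[1] / (1 - a[2])
  r2 <- a[1] * r1 + a[2]
  R0 <- 1 / (1 - a[1] * r1 - a[2] * r2)
  R <- numeric(n_seg); R[1] <- R0; R[2] <- r1 * R0
  for (k in 3:n_seg) R[k] <- a[1] * R[k - 1] + a[2] * R[k - 2]
  # finite-segment expectation of the sample spectrum: Fejer-weighted
  # autocovariance transform (the exact mean of |x(f)|^2 / n)
  taus <- c(0:(n_seg - 1), -(n_seg - 1):-1)
  wts <- 1 - abs(taus) / n_seg
  Racv <- R[abs(taus) + 1]
  exact_mean <- function(f) Re(sum(wts * Racv * exp(-2i * pi * f * taus / n_seg)))
  err_for <- function(M, seed) {
    x <- make_oscillator_series(a, length = n_seg * M, seed = seed)
    cs <- sample_cross_spectrum(fourier_transform_series(x, n_seg, ds))
    hat <- Re(vapply(seq_along(cs$grid$frequencies), function(k)
      cs$matrices[1, 1, k], complex(1)))[-1] / n_seg
    truth <- vapply(cs$grid$bins[-1], exact_mean, numeric(1))
    mean(abs(hat - truth) / truth)
  }
  e_small <- mean(vapply(1:3, function(s) err_for(60, s), numeric(1)))
  e_large <- mean(vapply(1:3, function(s) err_for(240, s + 10), numeric(1)))
  # quadrupling M halves the sampling error, within Monte-Carlo slack
  expect_lt(e_large, 0.7 * e_small)
  # and the finite-segment mean is itself close to the asymptotic AR density
  asym <- ar2_spectral_density((1:50) * (1 / (n_seg * ds)), a[1], a[2],
                               sampling_period = ds)
  fin <- vapply(1:50, exact_mean, numeric(1))
  expect_lt(mean(abs(fin - asym) / asym), 0.12)
})
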