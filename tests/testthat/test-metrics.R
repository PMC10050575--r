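test_that("resolution operator is the product of its factors", {
  set.seed(61)
  Tm <- matrix(rnorm(15), 5, 3)
  Lm <- matrix(rnorm(15), 3, 5)
  R <- resolution_operator(quasilinear_operator(Tm, method = "smne"),
                           lead_field(Lm))
  expect_equal(R$R, Tm %*% Lm, tolerance = 1e-12)
  # pseudo-inverse of a square invertible L gives the identity
  Lsq <- suppressWarnings(lead_field(matrix(rnorm(16), 4, 4) + 4 * diag(4)))
  Rid <- resolution_operator(quasilinear_operator(solve(Lsq$matrix),
                                                  method = "smne"), Lsq)
  expect_equal(Rid$R, diag(4), tolerance = 1e-10)
  expect_true(all(resolution_operator(quasilinear_operator(matrix(0, 5, 3),
                                                           method = "smne"),
                                      lead_field(Lm))$R == 0))
  expect_error(resolution_operator(quasilinear_operator(Tm, method = "smne"),
                                   lead_field(matrix(1, 2, 3))),
               class = "cesi_invalid_argument")
})

test_that("reference set keeps the top fraction with deterministic ties", {
  v <- c(5, 1, 9, 3, 7, 2, 8, 4)           # G = 8, distinct: top-2 are 3 and 7
  expect_identical(reference_set(v, 0.25), c(3L, 7L))
  expect_identical(reference_set(v, 1), 1:8)
  # ties break toward the lowest index
  expect_identical(reference_set(c(1, 2, 2, 0), 0.5), c(2L, 3L))
  expect_identical(reference_set(c(2, 2, 2, 0), 0.25), 1L)
  # random vector matches full-sort enumeration
  set.seed(62)
  r <- runif(37)
  k <- ceiling(0.25 * 37)
  expect_identical(reference_set(r, 0.25), sort(order(r, decreasing = TRUE)[1:k]))
  expect_error(reference_set(rep(0, 5)), class = "cesi_invalid_argument")
  expect_error(reference_set(r, 0), class = "cesi_invalid_argument")
})

test_that("GPSF follows its defining average of squared point spreads", {
  # identity resolution: 1/|G0| on G0, zero elsewhere
  r <- gpsf(diag(5), c(1, 3))
  expect_equal(r, c(0.5, 0, 0.5, 0, 0))
  expect_equal(gpsf(matrix(0, 4, 4), c(1, 2)), rep(0, 4))
  set.seed(63)
  R <- matrix(rnorm(25), 5, 5)
  G0 <- c(1, 3)
  manual <- sapply(1:5, function(g) mean(abs(R[g, G0])^2))
  expect_equal(gpsf(R, G0), manual, tolerance = 1e-12)
  expect_error(gpsf(R, integer(0)), class = "cesi_invalid_argument")
})

test_that("spatial dispersion and BLUR match enumeration and vanish for a perfect solution", {
  ms <- tiny_strip_mesh(5)
  d <- geodesic_distances(ms)
  # identity column: the only nonzero term sits at distance zero
  expect_equal(spatial_dispersion(diag(5), 3, d), 0)
  # single off-center unit entry at distance d: contributes d^2 / G
  R1 <- matrix(0, 5, 5); R1[4, 2] <- 1
  expect_equal(spatial_dispersion(R1, 2, d), d[4, 2]^2 / 5, tolerance = 1e-12)
  # random column matches the enumerated sum
  set.seed(64)
  R <- matrix(rnorm(25), 5, 5)
  g0 <- 2
  expect_equal(spatial_dispersion(R, g0, d),
               sum(abs(R[, g0]) * d[, g0]^2) / 5, tolerance = 1e-12)
  # normalized variant divides by the column magnitude
  expect_equal(spatial_dispersion(R, g0, d, normalize = TRUE),
               sum(abs(R[, g0]) * d[, g0]^2) / sum(abs(R[, g0])),
               tolerance = 1e-12)
  # BLUR: zero for the identity, linear in a rescaling of R
  expect_equal(blur(diag(5), c(1, 2, 5), d), 0)
  b1 <- blur(R, c(1, 4), d)
  expect_equal(blur(3 * R, c(1, 4), d), 3 * b1, tolerance = 1e-12)
  expect_equal(b1, mean(c(spatial_dispersion(R, 1, d),
                          spatial_dispersion(R, 4, d))), tolerance = 1e-12)
})

test_that("EMD solves the transportation program exactly on small supports", {
  ms <- tiny_strip_mesh(4)
  d <- geodesic_distances(ms)
  # identical distributions cost nothing; point masses cost their distance
  set.seed(65)
  a <- runif(4)
  expect_lt(emd(a, a, d), 1e-8)
  expect_equal(emd(c(1, 0, 0, 0), c(0, 0, 1, 0), d), d[1, 3], tolerance = 1e-9)
  # the printed 4-vertex example vs the brute-force LP oracle
  a4 <- c(.5, .5, 0, 0); b4 <- c(0, 0, .5, .5)
  expect_equal(emd(a4, b4, d), brute_force_transport(a4, b4, d),
               tolerance = 1e-8)
  # random pairs vs the oracle (3-point supports keep enumeration exact)
  d3 <- d[1:3, 1:3]
  for (i in 1:5) {
    x <- runif(3); y <- runif(3)
    expect_equal(emd(x, y, d3),
                 brute_force_transport(x / sum(x), y / sum(y), d3),
                 tolerance = 1e-7)
  }
  expect_error(emd(c(0, 0, 0, 0), a, d), class = "cesi_invalid_argument")
  expect_error(emd(c(-1, 1, 1, 1), a, d), class = "cesi_invalid_argument")
})

test_that("EMD is a metric on normalized topographies", {
  set.seed(66)
  ms <- tiny_strip_mesh(7)
  d <- geodesic_distances(ms)
  for (i in 1:6) {
    x <- runif(7); y <- runif(7); z <- runif(7)
    exy <- emd(x, y, d); eyx <- emd(y, x, d)
    expect_equal(exy, eyx, tolerance = 1e-6)
    expect_lte(exy, emd(x, z, d) + emd(z, y, d) + 1e-6)
    # scale invariance: common positive rescaling changes nothing
    expect_equal(emd(5 * x, 0.2 * y, d), exy, tolerance = 1e-9)
  }
})

test_that("correlation distance covers collinearity, anticorrelation, and the textbook formula", {
  set.seed(67)
  x <- runif(20)
  expect_equal(corr_distance(2 * x + 1, x), 0, tolerance = 1e-12)
  expect_equal(corr_distance(-x + max(x), x), 2, tolerance = 1e-12)
  y <- runif(20)
  manual <- 1 - sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(corr_distance(x, y), manual, tolerance = 1e-12)
  expect_equal(corr_distance(x, y), corr_distance(3 * x, 7 * y), tolerance = 1e-12)
  expect_error(corr_distance(rep(1, 20), y), class = "cesi_invalid_argument")
  expect_error(corr_distance(exp(x), -y, log_scale = TRUE),
               class = "cesi_invalid_argument")
})

test_that("localization error is the geodesic distance from the CST peak to the truth", {
  ms <- tiny_strip_mesh(6)
  d <- geodesic_distances(ms)
  est <- c(0, 0, 5, 1, 0, 0)
  expect_equal(localization_error(est, 3, d), 0)
  est2 <- c(0, 5, 0, 1, 0, 0)
  expect_equal(localization_error(est2, 3, d), d[2, 3])
  # random estimates match the argmax + lookup oracle; ties take lowest index
  set.seed(68)
  for (i in 1:5) {
    e <- runif(6)
    expect_equal(localization_error(e, 4, d), d[which.max(e), 4])
  }
  expect_equal(localization_error(c(1, 3, 3, 0, 0, 0), 2, d), 0)
  expect_error(localization_error(rep(2, 6), 1, d),
               class = "cesi_invalid_argument")
})
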