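# shared fixtures and independent oracles, all built in code

# tiny planar triangle-strip mesh with n vertices on a slightly bent line
tiny_strip_mesh <- function(n = 6, step = 2) {
  stopifnot(n >= 3)
  verts <- cbind(seq_len(n) * step, rep(c(0, 0.5), length.out = n), 0)
  tris <- do.call(rbind, lapply(seq_len(n - 2), function(i) c(i - 1, i, i + 1)))
  source_space(verts, tris)
}

# independent all-pairs shortest path (Floyd-Warshall) over mesh edges
floyd_warshall_geodesics <- function(space) {
  g <- nrow(space$vertices)
  d <- matrix(Inf, g, g)
  diag(d) <- 0
  tri <- space$triangles + 1L
  for (r in seq_len(nrow(tri))) {
    for (pair in list(tri[r, c(1, 2)], tri[r, c(2, 3)], tri[r, c(1, 3)])) {
      w <- sqrt(sum((space$vertices[pair[1], ] - space$vertices[pair[2], ])^2))
      d[pair[1], pair[2]] <- min(d[pair[1], pair[2]], w)
      d[pair[2], pair[1]] <- d[pair[1], pair[2]]
    }
  }
  for (k in seq_len(g)) for (i in seq_len(g)) for (j in seq_len(g))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# brute-force O(T^2) direct summation of the centered DFT
brute_dft <- function(x, grid) {
  n <- grid$num_samples_per_segment
  half_t <- (n - 1L) %/% 2L
  tt <- (-half_t):half_t
  vapply(grid$bins, function(f) sum(x * exp(-2i * pi * f * tt / n)),
         complex(1))
}

# brute-force transportation LP by enumerating basic solutions: every subset
# of m + n - 1 cells whose flow system has a unique nonnegative solution is a
# vertex of the polytope; the optimum is their minimum cost
brute_force_transport <- function(a, b, cost) {
  a <- a / sum(a); b <- b / sum(b)
  m <- length(a); n <- length(b)
  cells <- expand.grid(i = seq_len(m), j = seq_len(n))
  k <- m + n - 1L
  combs <- utils::combn(nrow(cells), k)
  best <- Inf
  # constraint matrix rows: m supplies then first n-1 demands (last redundant)
  for (c_idx in seq_len(ncol(combs))) {
    sel <- combs[, c_idx]
    A <- matrix(0, m + n - 1L, k)
    for (t in seq_len(k)) {
      A[cells$i[sel[t]], t] <- 1
      if (cells$j[sel[t]] < n) A[m + cells$j[sel[t]], t] <- 1
    }
    rhs <- c(a, b[-n])
    x <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(x) || any(x < -1e-9)) next
    cst <- sum(x * cost[cbind(cells$i[sel], cells$j[sel])])
    best <- min(best, cst)
  }
  best
}

# random Hermitian PSD matrix
random_hpsd <- function(r, rank = r) {
  A <- matrix(complex(real = rnorm(r * rank), imaginary = rnorm(r * rank)),
              r, rank)
  (A %*% Conj(t(A))) / rank
}

# wrap a single matrix as a one-frequency cross-spectrum
one_freq_cs <- function(S, M = 100L, freq = 10, space_tag = "sensor") {
  gr <- spectral_grid(201, 1 / 201, frequencies = freq, num_segments = M)
  cross_spectrum(array(S, c(dim(S), 1L)), gr, sample_size = M,
                 space_tag = space_tag, validate = FALSE)
}
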