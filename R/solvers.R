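#' Quasilinear inverse operator
#'
#' A frequency-domain inverse operator `T` (`G x E`, real) with its posterior
#' covariance `Pi` (full matrix or its diagonal), the method that produced it,
#' and its hyperparameters. For the minimum-norm family (sMNE, seLORETA,
#' ssSBL) the structure `T = Pi L' B^{-1}` holds.
#'
#' @param T real `G x E` matrix.
#' @param Pi `G x G` matrix or length-`G` diagonal vector (posterior
#'   covariance), may be `NULL` for methods without one (sLCMV).
#' @param method one of `"smne"`, `"seloreta"`, `"slcmv"`, `"sssbl"`.
#' @param hyperparameters named list (alpha, descriptions of A and B, ...).
#' @param frequency frequency in Hz or a band tag, `NA` if frequency-independent.
#' @return object of class `quasilinear_operator`.
#' @export
quasilinear_operator <- function(T, Pi = NULL, method, hyperparameters = list(),
                                 frequency = NA) {
  T <- as.matrix(T)
  structure(list(T = T, Pi = Pi, method = method,
                 hyperparameters = hyperparameters, frequency = frequency),
            class = "quasilinear_operator")
}

#' @export
print.quasilinear_operator <- function(x, ...) {
  cat(sprintf("quasilinear_operator [%s]: %d sources x %d sensors%s\n",
              x$method, nrow(x$T), ncol(x$T),
              if (is.na(x$frequency[1])) "" else paste0(" @ ", x$frequency)))
  invisible(x)
}

#' Solver configuration
#'
#' Tunable knobs shared by the inverse solvers. All penalties are
#' dimensionless: solvers rescale the lead field to `trace(L L')/E = 1` and
#' the data cross-spectrum to `trace(S)/E = 1` per frequency before solving,
#' so the defaults transfer across units.
#'
#' @param alpha regularization temperature of the quasilinear (MAP1) family.
#' @param alpha1 sparse (square-root trace) penalty weight of ssSBL.
#' @param alpha2 smooth (trace) penalty weight of ssSBL.
#' @param max_iter maximum iterations for iterative solvers.
#' @param tol relative convergence tolerance.
#' @param seed optional integer seed recorded in results.
#' @param noise_update logical; update the ssSBL noise spectrum `beta` from
#'   the sensor-space residual each iteration (default `FALSE`: `beta` stays
#'   at its initial eigenvalue-floor estimate).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(alpha = 1e-2, alpha1 = 1, alpha2 = 1e-2,
                          max_iter = 500L, tol = 1e-5, seed = NULL,
                          noise_update = FALSE) {
  stopifnot(is.finite(alpha), alpha >= 0, is.finite(alpha1), alpha1 >= 0,
            is.finite(alpha2), alpha2 >= 0, max_iter >= 1L, tol > 0)
  structure(list(alpha = alpha, alpha1 = alpha1, alpha2 = alpha2,
                 max_iter = as.integer(max_iter), tol = tol, seed = seed,
                 noise_update = isTRUE(noise_update)),
            class = "solver_config")
}

# scale factor making trace(L L')/E = 1
leadfield_scale <- function(Lm) sqrt(sum(Lm^2) / nrow(Lm))

# symmetric pseudo-inverse with relative eigenvalue cutoff
sym_pinv <- function(S, rel_cutoff = 1e-12) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- e$values > rel_cutoff * max(abs(e$values))
  if (!any(keep)) stop_rank("matrix is numerically zero")
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Spectral minimum-norm (sMNE) operator
#'
#' The Tikhonov-regularized generalized inverse
#' `T = Pi L' B^{-1}` with `Pi = (L' B^{-1} L + alpha A^{-1})^{-1}`, where `A`
#' is the source prior covariance (identity for plain MNE) and `B` a sensor
#' noise matrix. The lead field is internally rescaled to
#' `trace(L L')/E = 1` so that `alpha` is dimensionless; the returned operator
#' applies to the original-scale data. For `G > E` the numerically preferred
#' dual (Woodbury) form `T = A L' (L A L' + alpha B)^{-1}` is used.
#'
#' @param L a [lead_field()] or a plain `E x G` matrix.
#' @param B sensor noise matrix (`E x E` positive definite), default identity.
#' @param alpha positive regularization temperature.
#' @param A source weight matrix (`G x G` or length-`G` diagonal), default
#'   identity.
#' @param form `"auto"` (dual when `G > E`), `"primal"`, or `"dual"`.
#' @return a [quasilinear_operator()].
#' @export
smne_operator <- function(L, B = NULL, alpha = 1e-2, A = NULL,
                          form = c("auto", "primal", "dual")) {
  form <- match.arg(form)
  Lm <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  e <- nrow(Lm); g <- ncol(Lm)
  if (alpha <= 0) stop_invalid("alpha must be positive")
  if (is.null(B)) B <- diag(e)
  if (is.null(A)) A <- diag(g)
  if (is.vector(A)) A <- diag(A, g)
  ev_b <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_b) <= 1e-14 * max(ev_b)) stop_rank("B is singular")
  sL <- leadfield_scale(Lm)
  Ls <- Lm / sL
  if (form == "auto") form <- if (g > e) "dual" else "primal"
  if (form == "primal") {
    Binv <- solve(B)
    Pi_s <- solve(t(Ls) %*% Binv %*% Ls + alpha * solve(A))
    T_s <- Pi_s %*% t(Ls) %*% Binv
  } else {
    M <- Ls %*% A %*% t(Ls) + alpha * B
    T_s <- A %*% t(Ls) %*% solve(M)
    # Woodbury: (L'B^{-1}L + alpha A^{-1})^{-1} = (A - A L' M^{-1} L A)/alpha
    Pi_s <- (A - A %*% t(Ls) %*% solve(M, Ls %*% A)) / alpha
  }
  quasilinear_operator(T_s / sL, Pi = Pi_s / sL^2, method = "smne",
                       hyperparameters = list(alpha = alpha,
                                              A = "source prior covariance",
                                              B = "sensor noise matrix",
                                              leadfield_scale = sL,
                                              B_matrix = B))
}

#' Spectral eLORETA operator
#'
#' The exact low-resolution tomography weights: a diagonal source covariance
#' `A = diag(1/a)` whose weights satisfy the fixed point
#' `a_g = sqrt(l_g' (L diag(a)^{-1} L' + alpha B)^+ l_g)` at convergence,
#' plugged into the sMNE dual form. The fixed point gives zero localization
#' error for a single noiseless point source. Iteration uses damping 0.5 and
#' an eigenvalue pseudo-inverse with relative cutoff `1e-12`.
#'
#' @inheritParams smne_operator
#' @param config a [solver_config()] providing `max_iter` and `tol`.
#' @return a [quasilinear_operator()] whose hyperparameters record the
#'   converged weights `a` and the final fixed-point residual.
#' @export
seloreta_operator <- function(L, B = NULL, alpha = 1e-2,
                              config = solver_config()) {
  Lm <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  e <- nrow(Lm); g <- ncol(Lm)
  if (alpha <= 0) stop_invalid("alpha must be positive")
  if (is.null(B)) B <- diag(e)
  sL <- leadfield_scale(Lm)
  Ls <- Lm / sL
  a <- rep(1, g)
  resid <- Inf
  for (it in seq_len(config$max_iter)) {
    M <- Ls %*% (t(Ls) / a) + alpha * B
    Minv <- sym_pinv(M)
    a_new <- sqrt(pmax(colSums(Ls * (Minv %*% Ls)), 1e-300))
    resid <- max(abs(a_new - a) / pmax(a, 1e-300))
    a <- 0.5 * a + 0.5 * a_new  # damped update
    if (resid < config$tol) break
  }
  if (resid >= config$tol)
    stop("seLORETA weight iteration did not converge within ", config$max_iter,
         " iterations (last relative residual ", signif(resid, 3), ")")
  Avec <- 1 / a
  M <- Ls %*% (t(Ls) * Avec) + alpha * B
  Minv <- sym_pinv(M)
  T_s <- (Avec * t(Ls)) %*% Minv
  Pi_s <- (diag(Avec, g) -
             (Avec * t(Ls)) %*% Minv %*% (Ls * rep(Avec, each = e))) / alpha
  quasilinear_operator(T_s / sL, Pi = Pi_s / sL^2, method = "seloreta",
                       hyperparameters = list(alpha = alpha, a = a,
                                              residual = resid,
                                              A = "diag(1/a), eLORETA fixed point",
                                              B = "sensor noise matrix",
                                              leadfield_scale = sL,
                                              B_matrix = B))
}

#' Spectral LCMV beamformer operators
#'
#' Per frequency, the unit-gain minimum-variance beamformer: row `g` of `T`
#' is `w_g' = (l_g' C^{-1} l_g)^{-1} l_g' C^{-1}` with
#' `C = Re(S(f)) + loading * I`. The real part of the data cross-spectrum is
#' used so the operator stays real (it is a valid sensor covariance and equals
#' `C` when the data are real). Default diagonal loading is
#' `1e-3 * trace(S)/E`.
#'
#' @param L a [lead_field()] or `E x G` matrix.
#' @param data_cs sensor [cross_spectrum()].
#' @param regularization diagonal loading; `NULL` for the default.
#' @return list of [quasilinear_operator()] (one per frequency), classed
#'   `quasilinear_operator_set`.
#' @export
slcmv_operator <- function(L, data_cs, regularization = NULL) {
  Lm <- if (inherits(L, "lead_field")) L$matrix else as.matrix(L)
  e <- nrow(Lm)
  nf <- dim(data_cs$matrices)[3]
  ops <- vector("list", nf)
  for (k in seq_len(nf)) {
    S <- Re(cs_slice(data_cs, k))
    load_k <- regularization %||% (1e-3 * sum(diag(S)) / e)
    C <- (S + t(S)) / 2 + load_k * diag(e)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-14 * max(ev))
      stop_rank("data covariance singular at frequency index ", k,
                "; increase the diagonal loading")
    Cinv <- solve(C)
    CL <- Cinv %*% Lm
    gain <- colSums(Lm * CL)           # l_g' C^{-1} l_g
    T <- t(CL) / gain
    ops[[k]] <- quasilinear_operator(T, Pi = NULL, method = "slcmv",
                                     hyperparameters = list(loading = load_k),
                                     frequency = data_cs$grid$frequencies[k])
  }
  structure(ops, class = "quasilinear_operator_set")
}

#' Apply an inverse operator to a data cross-spectrum
#'
#' The quasilinear push-through `S_hat_src(f) = T S(f) T'` per frequency.
#' Accepts a single operator (applied at every frequency) or an operator set
#' with one operator per frequency.
#'
#' @param op a [quasilinear_operator()] or `quasilinear_operator_set`.
#' @param data_cs sensor [cross_spectrum()].
#' @return source-space [cross_spectrum()].
#' @export
apply_operator <- function(op, data_cs) {
  nf <- dim(data_cs$matrices)[3]
  ops <- if (inherits(op, "quasilinear_operator_set")) {
    if (length(op) != nf)
      stop_invalid("operator set length (", length(op),
                   ") must match the number of frequencies (", nf, ")")
    op
  } else rep(list(op), nf)
  g <- nrow(ops[[1L]]$T)
  if (ncol(ops[[1L]]$T) != dim(data_cs$matrices)[1])
    stop_invalid("operator expects ", ncol(ops[[1L]]$T), " sensors, data has ",
                 dim(data_cs$matrices)[1])
  out <- array(0i, c(g, g, nf))
  for (k in seq_len(nf)) {
    T <- ops[[k]]$T
    out[, , k] <- hermitianize(T %*% cs_slice(data_cs, k) %*% t(T))
  }
  cross_spectrum(out, data_cs$grid, sample_size = data_cs$sample_size,
                 space_tag = "source", validate = FALSE)
}

#' Cortical spectral topography (CST) of a cross-spectrum
#'
#' The real diagonal per frequency: the spatial map of spectral power.
#'
#' @param src_cs a [cross_spectrum()].
#' @return numeric `G x F` matrix of nonnegative spectra.
#' @export
cst_from_cross_spectrum <- function(src_cs) {
  nf <- dim(src_cs$matrices)[3]
  out <- vapply(seq_len(nf),
                function(k) Re(diag(cs_slice(src_cs, k))),
                numeric(dim(src_cs$matrices)[1]))
  if (!is.matrix(out)) out <- matrix(out, ncol = nf)
  out
}
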