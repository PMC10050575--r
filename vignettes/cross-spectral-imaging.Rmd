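---
title: "Cross-spectral source imaging: models, solvers, and distortion measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-spectral source imaging: models, solvers, and distortion measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Multichannel electrophysiological data `v(t)` (EEG/MEG/ECoG, `E` sensors)
arise from cortical source currents `i(t)` (`G` mesh vertices, `G >> E`)
through a linear, stationary lead field `L`:

    v(t) = L i(t) + xi(t).

`cesi` targets the *source cross-spectrum* `S_ii(f)`, whose diagonal is the
cortical spectral topography (CST) and whose off-diagonal entries encode
linear coupling. Three facts organize the package:

1. **Asymptotic Gaussianity.** For stationary, strongly mixing series the
   discrete Fourier coefficients of distinct frequencies become independent
   circularly symmetric complex Gaussian vectors, and the segment-averaged
   sample cross-spectrum `S_bar(f)` with `M` segments is complex Wishart with
   scale `S(f)` and `M` degrees of freedom. `complex_gaussian_logdensity()`,
   `complex_wishart_loglik()` and `gaussianity_test()` implement exactly
   these objects; `make_oscillator_series()` provides AR(2) test beds whose
   spectra are known in closed form so the machinery can be checked against
   analytic answers.
2. **The cross-spectral forward relation.** Independence of sources and noise
   gives `S_vv(f) = L S_ii(f) L' + S_xi(f)`, so the sensor cross-spectrum is
   itself a linear image of the unknown.
3. **Quasilinearity.** All estimators here apply a (possibly data-dependent)
   real matrix `T(f)` linearly: `S_ii_hat(f) = T S_bar_vv(f) T'`. This
   preserves amplitude/phase structure and Gaussianity ("F-invariance") and
   makes Hermitian positive-semidefiniteness of the estimate automatic.

## The solver family

With sensor noise proxy `B(f)` and source prior covariance `A(f)`, the
regularized generalized inverse is

    T = Pi L' B^{-1},  Pi = (L' B^{-1} L + alpha A^{-1})^{-1}.

* `smne_operator()` takes `A = I` (spectral minimum norm). For `G > E` it
  uses the dual (Woodbury) form `T = A L'(L A L' + alpha B)^{-1}`, which the
  tests verify against the primal form to 1e-8.
* `seloreta_operator()` estimates diagonal weights by the eLORETA fixed
  point `a_g = sqrt(l_g' (L diag(a)^{-1} L' + alpha B)^+ l_g)` and sets
  `A = diag(1/a)`. The fixed point gives exact peak localization for a
  single noiseless point source — an acceptance property of the suite. The
  iteration is damped by 0.5 and uses an eigenvalue pseudo-inverse with
  relative cutoff 1e-12; non-convergence within `max_iter` is an error, not
  a silent return.
* `slcmv_operator()` is the unit-gain minimum-variance beamformer per
  source, `w_g' = (l_g' C^{-1} l_g)^{-1} l_g' C^{-1}` with
  `C = Re(S_bar(f)) + loading I` and default loading
  `1e-3 trace(S_bar)/E`. The real part keeps `T` real — it is the
  covariance of the real representation of the data and coincides with `C`
  for real signals; the imaginary part of a Hermitian matrix contributes
  nothing to the quadratic forms used here.
* `sssbl_solve()` is the package's main contribution-bearing solver, a
  spectral structured sparse Bayesian learner described next.

### ssSBL: gamma-MAP with an Elastic-Net hyper-penalty

Each source carries a per-frequency prior variance `gamma_g(f)` (the
"variational spectrum") and each sensor a noise variance `beta_e(f)`. The
marginal likelihood of the Fourier instances under
`Sigma_v = diag(beta) + L diag(gamma) L'` is maximized in `gamma` by EM:
the E-step forms the posterior operator (the same quasilinear structure as
above with `A = diag(gamma)`, `B = diag(beta)`) and the posterior second
moments `m2_g = [T S_bar T']_gg + Pi_gg`; the M-step maximizes, per source,

    Q(g) = -M log g - M m2_g / g - a1 sqrt(g) - a2 g ,

where `a1` weights the sparse square-root-trace penalty (the structured
1,2-quasinorm of the source cross-spectrum — a group-LASSO across segments)
and `a2` the trace penalty (nuclear norm, a ridge on the spectrum). At
`a1 = a2 = 0` the update collapses to the classic sparse-Bayesian-learning
fixed point `gamma <- m2`, which the tests verify against an independent
implementation. The stationary point of `Q` lies in `(0, m2]` and is found
by 60 bisection steps, vectorized over sources; because the M-step is exact
and the penalty does not involve the latent instances, the penalized
evidence is non-decreasing across iterations — asserted on every run via
`state$objective_trace`.

**Scaling.** The problem is solved on a dimensionless scale
(`trace(L L')/E = 1`, `trace(S_bar)/E = 1` per frequency), so
`alpha`, `alpha1`, `alpha2` transfer across units. Defaults
`alpha = 1e-2`, `alpha1 = 1`, `alpha2 = 1e-2` were fixed by the package's
parameter-recovery property suite on the default synthetic benchmark and
are not adapted at run time.

**Noise spectrum.** `beta` defaults to the mean of the smallest
`floor(E/4)` eigenvalues of the scaled data matrix (a conservative noise
floor); a fixed value can be supplied, and an EM residual update is
available behind `noise_update = TRUE` (with it, monotonicity of the
recorded objective is no longer guaranteed, since the residual update is
not the exact `beta` M-step).

**Convergence.** The loop stops when `max |delta gamma| / max gamma < tol`
or after `max_iter` iterations. The change is measured against the
*largest* source power deliberately: SBL drives most `gamma_g`
multiplicatively toward zero, so per-element relative change never
settles. Defaults `max_iter = 500`, `tol = 1e-5`: on the default benchmark
the support of `gamma` stabilizes around 400-500 iterations, and the
per-frequency solve stays well under a second at `E = 19`, `G = 200`.

**Initialization and ties.** `gamma` starts uniform with total source power
trace-matched to the data; there is no random initialization, so results
are bit-reproducible. Argmax ties anywhere in the package resolve to the
lowest index.

## Distortion measures

With resolution operator `R = T L` (column `g0` = image of a unit point
source at `g0`) and a reference set `G0` of the most active 25% of a
reference CST:

* **GPSF** `r(g) = mean_{g0 in G0} |R(g, g0)|^2` — where reference activity
  leaks to;
* **spatial dispersion** `theta2(g0) = (1/G) sum_g |R(g,g0)| d(g,g0)^2`
  (geodesic `d` in mm) and **BLUR** `b = mean_{G0} theta2` — zero exactly
  for the identity resolution operator. The default uses the magnitude
  weighting `|R|` (not `|R|^2`) without per-column mass normalization;
  since that form scales with operator gain, a normalized variant (divide
  by `sum_g |R(g,g0)|`, common in the point-spread literature) is available
  via `normalize = TRUE`;
* **EMD** — the exact optimal-transport cost between the two CSTs, each
  normalized to unit mass, with geodesic ground cost, solved by a
  transportation simplex written in C++ (no approximate regularized
  transport); it is a true metric, verified by symmetry and
  triangle-inequality property tests against a brute-force LP oracle;
* **1-CORR** — one minus the Pearson correlation of the raw band-averaged
  topographies (log-scale variant behind a flag);
* **peak localization error** — geodesic distance from the CST argmax to the
  true vertex.

Both mass normalization for EMD and raw-scale correlation are package
choices among reasonable conventions; they are recorded here and held
fixed.

## The synthetic benchmark

`scenario_spec()` declares the study conditions; the defaults are the ones
every multi-seed result in this package uses: a 19-channel idealized 10-20
montage on a 90 mm scalp sphere, `G = 200` sources on a 70 mm spherical-cap
mesh (10 colatitude rings of 20 — a regular cap grid is used rather than an
icosphere because no icosahedral subdivision has exactly 200 vertices),
`M = 600` segments at 1 Hz spectral resolution (201-sample segments at
201 Hz), frequencies 1-45 Hz, and three coherent patches (geodesic Gaussian
bumps, 20 mm radius, unit power) in the alpha, theta and beta bands over a
diagonal background of mean power 0.1 with a smooth geodesic-kernel spatial
profile and `1/f` spectral shape, at 10 dB sensor SNR (white noise). The
ground truth emulates the smooth-plus-focal character of a dense-recording
minimum-norm reference map.

What the generator does **not** emulate: realistic head geometry and
conductivity layers, correlated (off-diagonal) background sources, line
noise and artifacts, non-stationarity. Passing tests therefore demonstrate
correctness of the estimators and the claimed qualitative orderings under
idealized Gaussian stationary conditions — not performance on real
recordings.

Two empirical orderings from the multi-seed suite are worth spelling out
(both computed by the tests themselves):

* ssSBL's leakage (BLUR) is far below seLORETA's and sLCMV's, and its
  CST-truth correlation beats spectral MNE's on every seed — the qualitative
  pattern the method was designed for.
* On EMD the diffuse beamformer map can score *better* than the sparse
  ssSBL map against this particular truth: roughly half of each band's
  diagonal mass lies in the 200-vertex diffuse background, and a sparse
  estimator must pay the transport cost of concentrating that mass, while
  any spatially spread map matches the background for free. The EMD
  ordering between sparse and diffuse estimators is therefore a property of
  the truth's mass split as much as of the estimators, which is why the
  suite reports all four measures side by side.

## Numerical choices and degenerate inputs

* Hermitian-PSD validation: Hermitian to 1e-10 relative, minimum eigenvalue
  at least `-1e-8` of the maximum; estimators symmetrize their outputs
  exactly.
* Zero-power frequencies short-circuit to zero operators in `sssbl_solve()`.
* `segment_time_series()` discards the trailing remainder; segment counts
  follow the floor formula exactly.
* The EMD solver perturbs supplies by 1e-11 against simplex degeneracy; the
  induced cost error is below the 1e-6 tolerances used anywhere.
* Geodesics are graph shortest paths along mesh edges (deterministic,
  exact for the graph metric) rather than exact polyhedral geodesics.
* The Gaussianity test applies Shapiro-Wilk per coefficient and part with
  Benjamini-Hochberg correction across all tests; the per-test (raw)
  rejection fraction is reported alongside, since under a global null the
  corrected fraction is near zero by design while the raw fraction sits at
  the nominal level.

## Known limitations

* The exact matrix-variate (Wishart-likelihood) inverse solution is out of
  scope; ssSBL is the variational route via instances.
* Sources are scalar (normal-oriented); free-orientation sources are not
  modeled.
* `beta` estimation is deliberately simple; on data whose "noise floor"
  contains structured signal it will absorb diffuse source power (the
  trade-off is visible in the EMD discussion above).
* Per-frequency independence of ssSBL is the default; pooling across a band
  is available by solving on band-averaged cross-spectra.
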