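---
title: "Evaluating MEG sensor arrays for deep, folded sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating MEG sensor arrays for deep, folded sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Magnetoencephalography (MEG) struggles with the cerebellar cortex for two
reasons: the cerebellum sits deep under the skull, so every sensor is far
from it, and its surface is folded on a millimeter scale, so neighboring
dipoles point in nearly opposite directions and their fields cancel.
On-scalp sensors (optically pumped magnetometers, OPMs) can be placed ~5 mm
from the scalp instead of the ~2 cm a cryogenic SQUID helmet requires, and
triaxial OPMs measure all three field components at each site. `megarray`
quantifies what this buys, using three complementary forward-model metrics:

1. **Sensitivity maps** — per-source topography norms,
   `s_j = m * ||L[, j]||_2` for a reference dipole moment `m` (default
   100 nAm).
2. **Subspace-correlation maps** — cosines of the principal angles between
   the lead-field subspaces of a cortical patch and cerebellar
   patches (or the whole cerebellum), i.e. how well cortical activity can
   mimic cerebellar field patterns.
3. **Total information capacity** —
   `Itot = 1/2 * sum_i log2(SNR'_i + 1)` over noise-whitened, orthogonalized
   channels.

All three consume only the lead-field matrix `L` (channels x sources,
`b = L j`), so they apply unchanged to imported gain matrices computed with
anatomical boundary-element models.

## Forward model

The package's own forward model is the closed-form field of a current dipole
in a spherically symmetric conductor. This preserves the two physical facts
the metrics depend on — radially oriented dipoles are externally silent, and
sensitivity decays steeply with source depth — while remaining exactly
computable and testable against an independent quadrature oracle (a
Geselowitz single-layer surface integral with a Legendre-series surface
potential; the test suite verifies 20 random tangential dipoles to < 1%).
Multi-compartment boundary-element modeling on real anatomy is explicitly
out of scope: for anatomical work, import the externally computed gain
matrix (`import_leadfield()`, dense TSV + JSON sidecar with declared units)
and run the same metrics.

Sensor integration schemes are configuration knobs, defaulting to: a 4-point
square pick-up loop (21 mm edge) for SQUID magnetometers, a two-point
(+1, −1) pair with a 50 mm baseline for axial gradiometers, and a single
point for OPMs. Internally everything is SI (tesla, A·m, meters); displays
use pT and nAm.

## Synthetic geometry: what it emulates and what it does not

`make_head_fixture()` generates the study geometry: a 9 cm scalp sphere, an
8.3 cm inner conductor boundary (sources within 3 mm of it are excluded, by
exact point-to-triangle distance), a superficial, gently folded cortex-like
cap (7.2 cm base radius, fold frequency 3), and a deep, highly folded
cerebellum-like cap in the posterior-inferior direction (5.5 cm base radius,
fold frequency 12, smaller extent). Folding is a seeded, band-limited radial
perturbation (eight oriented sinusoidal modes in cap-local coordinates,
tapered at the rim); it reproduces the one property the metrics care about —
orientation disorder of surface-normal dipoles increases field cancellation —
with two interpretable knobs (amplitude, frequency). The dimensions are
adult-head scale so sensitivities land in the pT range; they are fixture
defaults, not anatomical claims, and the fold frequencies are free
parameters reported with every run rather than fitted to anatomy.

What the fixture does **not** emulate: real sulcal/gyral geometry and its
spatial statistics, left–right cerebellar hemispheres, skull conductivity
(the sphere model is conductivity-profile independent), sensor calibration
errors, and environmental noise. Passing the directional tests on the
fixture therefore shows the *pipeline* orders arrays correctly under
depth + cancellation physics; it does not certify effect sizes on real
anatomy. The absolute numbers (e.g. bits) are fixture-scale, roughly an
order of magnitude below values on full anatomical source spaces with
10^5 sources.

## Array construction

Helmet-like layouts are generated procedurally (a deterministic Fibonacci
spiral over a cap extending below the equator) because vendor coordinates
are proprietary; real layouts can be loaded from TSV. `project_to_scalp()`
moves positions to nearest-scalp-point + standoff x outward normal (5 mm
OPM, 22 mm SQUID) and sets the radial axis to that normal; the tangential
frame is `tan1 = normalize(z x radial)` with an x-axis fallback near the
poles, `tan2 = radial x tan1`. Using the query-to-closest-point direction as
the normal makes projection exactly idempotent, including above mesh edges.

Uniform layouts of arbitrary count compose four steps:

```{r}
arr <- make_uniform_array(scalp, helmet_seed_positions(102), k = 150,
                          sensor_type = "opm")
```

1. `build_candidate_mesh()`: a 2D Delaunay triangulation (Bowyer–Watson, on
   a stereographic projection of the cap) of the seed positions, midpoint-
   subdivided until ~5821 vertices (default), each new vertex re-projected
   to the standoff surface.
2. `laplace_embedding()`: the first `n_basis` (default 100) eigenfunctions
   of the mesh Laplacian with zero Dirichlet boundary values. The
   discretization is finite-element (cotangent stiffness + lumped mass), so
   eigenvalues converge to continuum Dirichlet eigenvalues under refinement
   (the tests track the unit square's first eigenvalue toward 2*pi^2);
   consequently the embedding columns are orthogonal in the lumped-mass
   inner product — exactly plain-orthogonal when the mass is uniform, as in
   the path-graph reference case. Each function is scaled to unit variance
   over interior vertices (uniform variance on each basis function) and
   sign-fixed by its largest-magnitude entry.
3. `farthest_point_sample()`: greedy maximin in embedding coordinates. The
   default start vertex is the interior vertex farthest (in graph distance)
   from the boundary, making layouts deterministic; greedy prefixes are
   nested, which is what makes information capacity provably non-decreasing
   along a sweep. The number of basis functions and the start rule are
   reported in outputs since layouts depend on them.
4. `project_to_scalp()` at the sensor type's standoff.

`mean_neighbor_distance()` flags layouts whose mean nearest-neighbor
distance falls below the physical sensor length (28 mm SQUID, 17 mm OPM):
beyond that density, rigid hardware could not realize the layout and
capacity estimates are optimistic.

## Metric conventions

* Sensitivity ratios are **ratios of means** over regions, not means of
  ratios; per-sensor normalization divides by the *sensor* count (a
  triaxial 102-sensor array divides by 102, not by its 306 channels).
* Density peaks are the argmax of a Gaussian KDE with Silverman bandwidth on
  a 512-point grid; peak-based comparisons are qualitative since any peak
  depends on the bandwidth.
* Principal angles use the Björck–Golub algorithm: SVD bases truncated at
  numerical rank (`max(dim) * eps * sigma_max`), cosines = singular values
  of the basis cross-product, clipped to [0, 1]. The "correlation" of a
  comparison is the arithmetic mean of **all** r cosines (the truncation-
  free convention; flagged here because a top-k mean is also defensible).
* Patches are Dijkstra balls of 10 mm geodesic radius, seeds greedily chosen
  in ascending vertex order at 15 mm spacing (equal patch sizes across
  regions are justified by approximately uniform dipole moment density per
  cortical area). The high-correlation fraction is the percentage of cosines
  above 0.5.
* A known degeneracy: when one region's lead field reaches full numerical
  channel rank (small source counts push the rank tolerance far below the
  spectrum floor), every patch-to-whole comparison returns 1.0 by
  containment. On the fixture this happens for single-axis 102-channel
  arrays against the 397-source cerebellar cap; the patch-to-patch map,
  whose subspaces are low-rank, is the informative comparison there and is
  what the directional claims are asserted on.
* Forward-error metrics: `topography_error(t_test, t_ref)` returns
  `RE = 100 * ||t_test - t_ref|| / ||t_ref||` and the Pearson correlation;
  the *second* argument is the reference (more complete) model.
* The conservation factor `C = ||sum_j L[, j]|| / sum_j ||L[, j]||` measures
  cancellation of simultaneously active sources; it contains no noise model,
  so sensor proximity barely moves it even when SNR improves.

## Information capacity

Rows of `L` are whitened by per-channel noise standard deviations derived
from spectral densities at a common bandwidth (default 1 Hz; only relative
levels matter for array comparisons). Defaults: 3 fT/√Hz for SQUID
magnetometers and gradiometers, 15 fT/√Hz for OPMs with 10 fT/√Hz as the
optimistic level. The whitened gain is orthogonalized by eigendecomposition
of `W W^T` (a Gram–Schmidt channel sweep gives the same `Itot` by
invariance; the tests assert this under random orthogonal mixing). Source
variance is `q^2 x identity` with `q^2` calibrated once so the mean
per-source SNR `q^2 ||w_j||^2` equals 1 on a designated reference — the
largest swept SQUID array over the whole brain — and the same `q^2` is then
used for every array, sensor type and region. The per-source SNR definition
is isolated in `calibrate_source_variance()` so the convention can be
swapped. Zero eigenvalues beyond the numerical rank contribute zero bits but
stay in the spectrum, keeping one entry per channel. Whole-brain capacity is
computed on the concatenated source space and is subadditive: it is *not*
the sum of the regional capacities.

## Numerical choices and problem sizes

Shells are icospheres (subdivision 4 = 2562 vertices reproduces the
conventional compartment-surface resolution; the fixture default of
subdivision 3 keeps distance queries fast). Sparse eigenproblems use ARPACK
shift-invert through a sparse Cholesky factor, falling back to dense
symmetric eigendecomposition for small meshes. Cosines and eigenvalue SNRs
are clipped at zero to absorb round-off. Degenerate inputs error early:
collinear candidate seeds, dipoles at the conductor center, field points
inside the conductor, zero matrices in subspace comparisons.

The shipped tests and the acceptance script run the full pipeline at
deliberately modest sizes — 1118 fixture dipoles, 102-sensor arrays,
1200–2000-vertex candidate meshes, 40–100 basis functions, sweeps to 100
sensors — chosen so a complete run takes about a minute on one core while
still exercising every code path; all sizes are configuration values and
scale up unchanged.

## Limitations

Single-geometry analysis (no subject population, no statistics across
heads); spherical conductor only, with anatomical accuracy delegated to
imported gains; no colored or brain-noise covariance, no interference
rejection modeling, no mechanical collision modeling beyond the overlap
flag; no inverse modeling — separability is assessed purely on forward
subspaces.
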