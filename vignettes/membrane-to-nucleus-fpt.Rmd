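---
title: "Membrane-to-nucleus first-passage times in voxelized cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-to-nucleus first-passage times in voxelized cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

fptcell studies the simplest spatial signal a cell can send itself: a
protein activated at the inner face of the cell membrane diffuses through
the cytosol until it first touches the nuclear membrane.  The cytosol of a
real cell is crowded with organelles — ER, mitochondria, Golgi — which the
model treats as reflecting obstacles, while the nuclear surface is a
perfect absorber.  Cell geometries enter as segmented 3D label volumes on
cubic voxels of edge $h$ (for soft X-ray tomography reconstructions,
$h \approx 0.035\,\mu m$), with each voxel classified as exterior, cytosol,
a nucleus component (e.g. heterochromatin, euchromatin), or an organelle
class.

On such a grid the probability density $p_h(x_i, t)$ ($\mu m^{-3}$) over
cytosol voxels obeys the semi-discrete diffusion equation
$\frac{dp_h}{dt} = D\,\Delta_h p_h$, where $\Delta_h$ is the 6-point
finite-volume Laplacian: face-adjacent cytosol voxels couple at rate
$D/h^2$, reflecting boundaries are simply absent couplings, and each face
shared with a nucleus voxel contributes a sink $-(D/h^2)\,p_i$.  This is
exactly a continuous-time random walk on the cytosol voxel graph with
absorption on nucleus contact.  Everything downstream derives from the
survival probability $S_h(t) = \sum_i p_h(x_i,t)\,h^3$ and the
first-passage-time density $f_h(t) = -S_h'(t) = D\,h \sum_i n_i\,
p_h(x_i,t)$, with $n_i$ the number of nucleus face-neighbors of voxel $i$.
(A per-voxel-mass reading of the flux formula would carry a $D/h^2$
prefactor; the $D\,h$ scaling is the unique one for which $f_h = -dS_h/dt$
holds with $p_h$ a density, and the package verifies
$\int_0^\infty f_h\,dt = 1$ on connected geometries as an invariant.)

First-order inactivation at rate $\lambda$ ($s^{-1}$) multiplies the
density by $e^{-\lambda t}$, so the probability of reaching the nucleus
before inactivation is the Laplace transform
$Z_{\lambda,h} = \int_0^\infty e^{-\lambda t} f_h(t)\,dt$, and conditional
statistics of the arrival time follow by weighting $f_h$ with
$e^{-\lambda t}$.  Two classical monotonicity facts organize the results:
$Z_\lambda$ and the conditional mean/median all decrease strictly in
$\lambda$, and the conditional CDF increases pointwise — inactivation
filters out the long searches.  For strong inactivation the surviving
arrivals are those taking the shortest lattice paths, giving
$Z_{\lambda,h} \sim -h^3 D^{d_g} \lambda^{-d_g} \sum_i (\Delta_h^{d_g}
g_h)(x_i)$ and $\langle T_{\lambda,h} \rangle \sim d_g/\lambda$, where
$d_g$ is the 6-neighbor graph distance from the release support to the
nucleus.  The conditional-mean ratio between a barrier-filled geometry and
its barrier-free variant therefore approaches the ratio of graph
distances: geometry's slowdown can be buffered out, at the price of a
small $Z$.

## Parameters that matter

* `D` — diffusivity, $\mu m^2 s^{-1}$; default 10, a typical cytosolic
  protein.  Time is in seconds, length in $\mu m$ throughout.
* `h` — voxel edge, $\mu m$.  Synthetic geometries default to
  0.05 $\mu m$, coarser than tomographic reconstructions but fine enough
  to resolve organelle-scale structure at desk scale; `h` is always a
  parameter.
* `lambda` — inactivation rate grid, $s^{-1}$.  Inactivation competes
  with search on timescales $1/\lambda$; the asymptotic $d_g/\lambda$
  regime requires $\lambda \gg D/h^2$, which for $D = 10$, $h = 0.1$ means
  $\lambda \gtrsim 10^5\,s^{-1}$ — far beyond physiological rates, which
  is precisely why the asymptotic limit is read as an explanation of the
  moderate-$\lambda$ buffering rather than a quantitative prediction.
* Initial condition — uniform over the membrane shell $\partial C_h$ (the
  cytosol voxels bordering the exterior) by default; patch and single-
  voxel releases are available.  Densities always normalize to
  $\sum_i g_i h^3 = 1$ (checked to $10^{-12}$).
* Eigen-tail retention — modes of $D\Delta_h$ with $|\mu| <$ `cutoff`
  (default $1\,s^{-1}$, capped at `max_modes = 200`).  Note that on
  desk-scale fixtures every eigenvalue exceeds $1\,s^{-1}$ in magnitude,
  so meaningful tails need a cutoff chosen for the fixture's timescale;
  tests pass it explicitly.

## Numerical scheme

The stiff linear system is integrated by `deSolve::lsodes` (sparse
analytic Jacobian pattern, absolute and relative tolerances $10^{-8}$),
sampled on a log-spaced output grid spanning nine decades below `t_end`
(default 1000 points) so that cumulative-trapezoid quadratures of
$e^{-\lambda t} f_h(t)$ stay accurate across widely separated timescales.
For long times the hybrid trajectory switches to a truncated eigenvector
expansion: the switch time is the first point in a scan window (default
$1 < t < 10\,s$) where integrator and expansion survival probabilities
agree to absolute error $10^{-5}$ and relative error $0.01$; beyond it all
Laplace-domain integrals are evaluated in closed form.  If the retained
tail is empty or never agrees, the package falls back to the
integrator-only trajectory with a warning.  Small operators are
diagonalized densely; larger ones use ARPACK shift-invert iterations on a
sparse Cholesky factor.

Conditional statistics have two independent routes.  The *time-domain*
route applies hybrid quadrature to the sampled density and also yields the
conditional CDF and median (bisection bracketed geometrically from the
conditional mean, $10^{-8}$ relative tolerance).  The *resolvent* route
solves $(\lambda I - D\Delta_h)z = (D/h^2)\,n$ and two further solves for
the conditional mean and second moment; it involves no quadrature, and it
is the recommended route for $\lambda \gtrsim 10^3\,s^{-1}$, where
$e^{-\lambda t} f_h(t)$ underflows any practical time grid.  The two
routes cross-validate each other to $10^{-4}$ relative in the tests.  MFPT
fields solve $D\,\Delta_h u = -1$ on the nucleus-connected component
(sparse Cholesky up to 60k unknowns, Jacobi-preconditioned conjugate
gradient beyond — no installed sparse iterative solver exists, so CG is
implemented in-package and validated against the Cholesky route);
unreachable voxels are flagged infinite rather than erroring, so
conditional statistics remain well defined on geometries with isolated
pockets.

Theorem-style properties are asserted numerically: the power sums
$\sum_i (\Delta_h^k g)(x_i)$ are computed by repeated sparse application
of the bare Laplacian using extended-precision accumulation; because
cancellation is the entire content of the zero-sum property, tolerances
are expressed relative to the first nonzero sum and the running maximum
voxel magnitude is reported alongside.  The asymptotic-$Z$ formula is
derived under $d_g > 1$ but agrees with the exact corridor closed form at
$d_g = 1$, so the package applies it for all $d_g \ge 1$.

## The synthetic generator

`random_cell()` emulates the gross structure of tomographic
reconstructions: an ellipsoidal cell (default semi-axes
$0.75 \times 0.65 \times 0.60\,\mu m$ — a deliberately compact test-scale
cell), an off-center ellipsoidal nucleus split into heterochromatin core
and euchromatin rim, and random ellipsoidal organelle blobs placed by
rejection sampling until a target organelle volume fraction (default
0.25) is reached.  A blob is accepted only if the remaining cytosol stays
6-connected to the nucleus, and blobs never occupy the membrane shell or
the nucleus-adjacent layer, so the release surface and absorbing
interface always survive.  Generation is bit-reproducible given the seed.

What it does *not* emulate: realistic organelle morphology (the source
reconstructions give no quantitative blob statistics, so shapes and sizes
are stated defaults, not fits), membrane curvature statistics, LAC
intensity, or cell-to-cell variability in nuclear position.  Passing
tests on these fixtures therefore demonstrates the correctness of the
numerics and the qualitative phenomenology (barriers slow every release
site; inactivation sharpens and buffers), not quantitative agreement with
any particular imaged cell.  Real reconstructions can be supplied as
NIfTI or raw+JSON label volumes and flow through the identical pipeline.

## Problem sizes and fixture choices

Tests and the acceptance script run at desk scale by design: corridors of
1–6 voxels with exact closed forms; a coarse sphere shell
($a = 0.5$, $R = 1$, $h = 0.2$, ~500 cytosol voxels) where dense
matrix-exponential and eigendecomposition oracles are affordable; a
$29\,000$-voxel sphere ($h = 0.1$) for the strong-inactivation scaling
fits; a $235\,000$-voxel sphere ($h = 0.05$) for continuum comparison;
and a seeded synthetic cell of ~9000 cytosol voxels.  The full suite runs
in about two minutes.

## Known limitations

* The absorbing nucleus is resolved only to the voxel scale: the
  effective absorbing surface of the lattice model sits roughly
  $0.3\,h$ inside the nominal nuclear radius (a lattice extrapolation
  length).  Against the concentric-spheres continuum closed form this
  produces a first-order-in-$h$ offset in MFPTs — about 4% at
  $h = (R-a)/20$, halving as $h$ halves.  Comparisons with continuum
  values should use $h \lesssim (R-a)/40$ or treat the offset explicitly.
* The conditional median exists only on the time-domain route; the
  resolvent route reports it as `NA`.
* The continuum conditional mean scales as $\lambda^{-1/2}$ at strong
  inactivation where the lattice model scales as $\lambda^{-1}$; the two
  agree only until the lattice regime takes over, which is an inherent
  property of the semi-discrete model, not a solver artifact.
* Linear (first-order) inactivation only: no phosphatase saturation,
  crowding, active transport, or reaction cascades.
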