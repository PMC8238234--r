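---
title: "Methods: image-based microvascular flow simulation with angioflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based microvascular flow simulation with angioflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`angioflow` turns a 2D binary vessel mask of a growing vascular plexus
into a steady 3D flow field and a quantitative statement about
perfusion of the angiogenic front. This vignette documents the model,
its assumptions, the numerical choices and the known limitations. It
states no empirical result that the package's test suite does not
itself compute.

## 1. Physical model and assumptions

Blood in the neonatal retinal microvasculature is treated as an
incompressible Newtonian fluid in steady flow. Both idealizations are
deliberate and follow standard practice for this regime:

* **Quasi-steady.** The Womersley number `alpha = d * sqrt(omega/nu)`
  compares the viscous wall-to-bulk momentum propagation time with the
  pulsation period. With murine values `d ~ 1e-5 m`, `omega ~ 1/s`,
  `nu ~ 1e-6 m^2/s`, `womersley()` gives `alpha ~ 1e-2`, deep in the
  viscous-dominated regime: velocity profiles develop essentially
  instantaneously within each cardiac cycle and the flow can be solved
  as steady.
* **Newtonian.** Shear rates in retinal arterioles/venules are high
  enough (hundreds per second) that rouleaux-driven shear thinning is
  negligible, and murine erythrocyte aggregation is weak.
* **Neglected**: the Fåhræus–Lindqvist effect, plasma skimming at
  bifurcations, wall elasticity, and oxygen transport itself. The
  package quantifies convective transport capacity (`Q_theta`, Peclet
  arguments), not oxygen fields.

The nondimensional governing equations (velocity scaled by the inlet
bulk speed `U_in*`, lengths by the inlet artery diameter `D_in*`) are

```
u_j du_i/dx_j = (1/Re) d2u_i/dx_j2 - dp/dx_i - eta * chi * u_i
du_i/dx_i = 0
```

with `Re = U_in* D_in* / nu* = 0.1` by default. The last term is the
volume-penalization (immersed-boundary) body force: `chi` is 1 in
tissue and 0 in the lumen, and a large `eta` drives the velocity to
zero in the solid, so arbitrary geometries can be embedded in a uniform
Cartesian grid without body-fitted meshing. The price is a smeared
fluid-solid boundary whose effect is controlled by grid refinement (see
the refinement test) rather than by boundary-layer meshing.

## 2. Geometry pipeline

**Local radius.** For every lumen pixel the local vessel radius is the
exact Euclidean distance to the nearest tissue pixel center, computed
with a two-pass lower-envelope (parabola) distance transform. This is
exact, not an approximation to it; the test suite checks equality with
an all-pairs search.

**Union of spheres.** A sphere of that radius is placed at each lumen
pixel on the mid-plane `z = 0`; the 3D lumen is the envelope. A voxel
at `(x, y, z)` is lumen iff `z^2 < max_p [ r(p)^2 - ||xy - p||^2 ]`,
so the whole construction is one generalized 2D distance transform with
per-pixel offsets `-r(p)^2` plus a per-plane test — `O(N log-ish)`
instead of a triple loop. The brute-force rasterization is retained as
the test oracle. The source text for this construction mentions both
the "radius" and the "diameter" of the local measurement; the package
follows the radius reading, which is the one consistent with the
occupancy rule `||x|| < r` and with reconstructed vessels whose
thickness matches their in-plane width.

**Level set and indicator.** The signed distance `phi` (negative in the
lumen) is the exact voxel-center distance across the interface. The
penalization mask is `chi = 1(phi > 0)` for `smoothing_width = 0`, or a
linear ramp over `phi in [-w dx, +w dx]` (default `w = 1`), which
represents the wall at sub-voxel accuracy and was measurably more
accurate on the Poiseuille benchmark than the hard indicator.

Grid spacing is isotropic and equals the mask pixel size (default
1.51 um, matching the published domain tables; `resample_mask()`
bridges other resolutions). The z extent is the thickest vessel plus
one tissue voxel per side, with `z = 0` on a cell-center plane.

## 3. Flow solver

Staggered layout (velocities on faces, pressure in cells), uniform
isotropic spacing.

* **Convection**: divergence-form second-order central differences,
  which conserve kinetic energy discretely in combination with the
  discrete continuity constraint (verified by a streamfunction-based
  global energy test). At `Re = 0.1` convection is nearly negligible;
  it is retained for fidelity.
* **Diffusion**: Crank-Nicolson, applied in delta form through an
  approximately factored operator (three tridiagonal sweeps per
  component). In delta form the factorization error multiplies the
  *update*, so the converged steady state is that of the unsplit
  scheme.
* **Penalization**: implicit Euler on `-eta * chi * u`, folded into the
  factored operator's diagonal as
  `(D - b Dxx) D^-1 (D - b Dyy) D^-1 (D - b Dzz)`, `D = I + dt_eff *
  eta * chi_face`. This is a deliberate deviation from treating the
  penalization with Crank-Nicolson: for `eta * dt >> 1` CN's
  amplification factor tends to -1 (marginally stable ringing in the
  solid), whereas implicit Euler damps the stiff mode in one step.
  Steady states are identical; the transient inside the penalized band
  becomes first-order accurate in pseudo-time (the test suite measures
  second order without penalization, first order with it), which is
  irrelevant for a steady solve.
* **Time marching**: low-storage three-stage Runge-Kutta
  (gamma = 8/15, 5/12, 3/4; zeta = 0, -17/60, -5/12) for the explicit
  terms, one SMAC pressure projection per full step. Default `eta =
  1e4` (nondimensional): penetration depth `sqrt(nu/eta) ~ 3%` of the
  inlet diameter, well below a cell at production resolution.
* **Pseudo-time step**: `dt = min(cfl * h / u_max, 1.3 * h^2 * Re)`.
  The second cap is an implementation-driven choice: the factored
  implicit operator's splitting terms scale like `(dt nu / h^2)^2` and
  throttle the per-step error contraction when that ratio is large;
  around `a_k dt nu / h^2 ~ 0.35` the march converges fastest in wall
  clock (measured on the tube benchmark). With the cap, the
  200 x 64 x 64 Poiseuille benchmark converges in about 220 steps.
* **Pressure Poisson**: pure Neumann (consistent with uniform-inflow /
  balanced-outflow boundaries), solved by a geometric multigrid V-cycle
  (Gauss-Seidel smoothing, per-axis semi-coarsening with per-axis
  spacings, trilinear prolongation), warm-started from the previous
  correction; a conjugate-gradient fallback guards the rare
  non-converging cycle. Relative tolerance 1e-8, zero-mean pinning.
* **Boundary conditions**: uniform unit inward speed on the open
  (lumen-adjacent) inlet faces; uniform outward outlet speed equal to
  the open-area ratio, so the volumetric flux balances to round-off by
  construction; all other box-face velocities are zero; pressure is
  Neumann everywhere. An inlet-to-outlet lumen connectivity check runs
  before each solve.
* **Convergence**: residual `max |u^{n+1} - u^n| / dt <= 1e-6`
  (nondimensional) sustained for 10 consecutive steps. The source work
  states no criterion; this one is ours, and the conservation
  invariants (flux imbalance at round-off, per-cell divergence at the
  Poisson tolerance) are asserted at convergence.

## 4. Morphometry conventions

* 8-connectivity throughout (thinning, branch points), matching the
  common Fiji convention.
* Thinning is Zhang-Suen with a connectivity-preserving cleanup of
  residual 2x2 blocks, so skeletons are one pixel wide and preserve the
  component count.
* A branch point is a skeleton pixel with >= 3 skeleton neighbours.
  Note that an X-crossing of two one-pixel lines yields a five-pixel
  junction cluster under this per-pixel definition (the center plus
  four diagonally-adjacent arm pixels); junction-merging analyzers
  count one junction there. Absolute branching indices are therefore
  higher than Fiji's, orderings between networks are unaffected.
* Centerline length sums unique 8-adjacency steps (orthogonal
  `= pixel`, diagonal `= sqrt(2) pixel`); densities use raw pixel-count
  areas, matching "percentage of area occupied".
* Density denominators use the ROI when one is attached to the mask,
  else the full image; both are supported because the original
  denominators are not documented.

## 5. Cylindrical perfusion analysis

The frame origin is the first branching point near the inlet
(user-supplied; `suggest_origin()` proposes the skeleton branch point
closest to the inlet face). `R_max` is the distance of the farthest
lumen voxel from the origin; the angiogenic front is
`0.7 R_max < r < R_max` (an S5-style three-region split `0.3/0.7` is a
parameter away). The azimuthal unit vector is oriented so artery-to-
vein transport is positive.

`Q_theta(region) = sum over lumen cells of u_theta * dV` is reported
raw, per unit fluid volume, and normalized by the inlet volumetric flux
times `D_in` (all nondimensional). The original figure's normalization
is unstated, so all three variants are reported; the package's
headline claims only use orderings, which all variants preserve (the
acceptance test checks two of them explicitly).

## 6. The synthetic A-V wedge generator

`generate_wedge()` emulates the minimum flow unit of the P5 retina: an
artery ray and a vein ray from a common origin just outside the inlet
edge (so the stubs cross the domain edge well apart), concentric
capillary arcs between them, and jittered radial connectors. Diameters
taper from the inlet caliber (default 12.08 um, the published median
domain's inlet) to capillary caliber (default 7 um); default domain
600 x 600 um at 1.51 um/px; the same seed reproduces the mask bitwise.

What the hyper/hypo presets encode, and why: the hyper-branching
phenotype adds vessels mainly in the inner and mid plexus, where
endothelial proliferation is concentrated behind the angiogenic front.
The presets therefore differ in ring count (9 vs 5), connectors per
ring (16 vs 7) *and* ring placement (`ring_compression = 1.7` vs 1,
which biases the extra rings inward while both presets share the front
rim). The inward weighting is not cosmetic: in the continuum limit a
*uniform* densification scales the sheet conductance everywhere and
leaves the flux split between inner plexus and front unchanged, so a
preset pair differing only by a uniform density factor would not
reproduce (and should not be expected to reproduce) the front-starving
effect. What produces it is the low-resistance inner shunt that denser
inner plexus creates between artery and vein. Connector counts are
capped so neighbouring connectors stay ~1.3 capillary diameters apart:
without the cap, dense presets merge into solid sheets near the wedge
apex, which is neither reticular biology nor a well-posed thin-sheet
reconstruction (the union-of-spheres rule would inflate a merged 2D
region into a thick 3D slab).

What a green end-to-end test establishes, and what it does not: it
shows the implemented physics produces the claimed *direction* (denser
inner plexus -> lower normalized front `Q_theta`, with all three
morphometric indices higher) on matched synthetic geometries with
identical inlet conditions and `R_max`. It does not reproduce the
published magnitudes, which come from real retinas and an unstated
normalization, and it cannot validate the generator as a model of real
plexus topology (no loops beyond the arc-spoke lattice, no diameter
heterogeneity within a class, no sprouting tips).

## 7. Numerical edge cases and conventions

* Pixel/voxel centers at `(i - 0.5) * spacing`; masks are `[x, y]`
  with y up; raster files are flipped on read/write accordingly.
* Binarization threshold: fraction of the dynamic range, strictly
  above; Otsu (256-bin between-class variance) behind
  `auto_threshold = TRUE`. The original binarization rule is not
  documented; 0.5 is the default.
* `r = 0` everywhere (no lumen) yields an empty occupancy rather than
  an error; a single-phase occupancy is rejected by the level-set
  stage.
* Cells at exactly `r = 0` in the cylindrical frame get
  `u_r = u_theta = 0` and belong to the innermost region.
* Pure-Neumann Poisson compatibility is enforced by subtracting the
  right-hand-side mean (the boundary fluxes already cancel to
  round-off); the solution is pinned to zero mean.
* Ties and smearing: the occupancy rule uses strict `<`, the hard
  indicator puts `phi = 0` in the tissue, and the ramp puts `chi = 0.5`
  there.

## 8. Known limitations

* Raster input is PGM/PPM/PBM/CSV; TIFF and PNG require external
  conversion (no raster package is available in the target
  environment).
* The outlet imposes a uniform profile on the domain face; fields
  within a few cells of the outlet are not meaningful (the same is true
  of the original setup).
* Penalization smears walls over ~1 cell: narrow vessels (< ~5 cells
  across) carry a resolution-dependent bias, which is why the
  grid-refinement check on the wedge is part of acceptance.
* Branch-point counts at X-crossings are junction-cluster counts (see
  section 4).
* The pseudo-time transient is not a physical transient (single
  projection per RK3 step, first-order penalization); only the steady
  state is meaningful.
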