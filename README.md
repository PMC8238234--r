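# angioflow

Image-based simulation of blood flow in the growing retinal
microvasculature, with morphometric and perfusion analysis of the
angiogenic front.

## The problem

During development (e.g. the postnatal mouse retina at P5), new vessels
sprout at the *angiogenic front*, the outer rim of the expanding
vascular plexus. Whether a denser (hyper-branching) or sparser
(hypo-branching) network perfuses that front better is not obvious from
morphology alone: it is a question about flow. `angioflow` answers it
computationally for the *A–V wedge* — the minimum flow unit consisting
of one feeding artery, one draining vein and the capillary bed between
them:

1. **Morphometry** of a 2D binary vessel mask: vascular density (% area
   occupied by lumen), vessel length density (% area occupied by the
   skeletonized centerline) and branching index (branch points per mm
   of centerline, 8-connectivity).
2. **3D reconstruction**: each lumen pixel gets its local radius
   `r(p)` (exact Euclidean distance to the nearest tissue pixel); the
   lumen is the envelope of spheres of radius `r(p)` centred on the
   image plane — voxel `v` is lumen iff `‖center(v) − (p, 0)‖ < r(p)`
   for some `p`. A signed-distance (level-set) field `φ` embeds the
   geometry in a uniform Cartesian grid.
3. **Flow solve**: steady incompressible Newtonian flow at `Re = 0.1`
   (quasi-steady is justified by the Womersley number
   `α = d √(ω/ν) ≈ 10⁻²`), governed by

   `u_j ∂u_i/∂x_j = (1/Re) ∂²u_i/∂x_j∂x_j − ∂p/∂x_i − η χ u_i`,
   `∂u_i/∂x_i = 0`,

   where `−η χ u` is the volume-penalization body force that enforces
   no-slip inside the tissue (`χ = 1`) without a body-fitted mesh.
   Discretization: staggered grid, energy-conservative second-order
   central differences, low-storage RK3 with Crank–Nicolson diffusion,
   SMAC pressure projection (pure-Neumann Poisson problem, geometric
   multigrid). Uniform inlet velocity; the outlet speed is scaled so
   volume is conserved exactly.
4. **Perfusion analysis**: velocities are decomposed in a cylindrical
   frame `(r, θ)` about the first branching point near the inlet; the
   angiogenic front is `0.7·R_max < r < R_max`. The azimuthal
   (artery→vein) flow rate `Q_θ = ∫ u_θ dV` per region quantifies how
   much flow each region transports; `Q_θ` at the front is the headline
   perfusion metric.

A synthetic generator (`generate_wedge()`, `wedge_preset()`) produces
A–V wedge masks with tunable branch density (hyper vs hypo presets), so
the whole pipeline is testable without imaging data.

## Worked example

```r
library(angioflow)

spec <- wedge_preset("hypo", domain_size = c(240, 240), pixel_size = 2,
                     inlet_diameter = 12, capillary_diameter = 7, seed = 7)
mask <- generate_wedge(spec)
morphometry(mask)
#> morphometry: vascular density 24.43 %, length density 6.94 %,
#>   branching index 138.8 /mm (397 branch points over 2.861 mm)

geom <- reconstruct_geometry(mask, smoothing_width = 1)
grid <- make_grid(geom$occupancy, D_in = spec$inlet_diameter)
pat  <- wedge_boundary_patches(mask, geom$occupancy)
flow <- run_to_steady_state(geom$solid$chi, grid,
                            flow_config(inlet = pat$inlet,
                                        outlet = pat$outlet))
flow
#> steady_flow: 120 x 120 x 11 cells, 456 steps, residual 7.83e-07 (converged)
#>   flux in 1.028, out 1.028, max |div| 4.20e-15

frame <- cylindrical_frame(attr(mask, "origin"),
                           attr(mask, "theta_artery"),
                           attr(mask, "theta_vein"))
part  <- partition_regions(geom$occupancy, frame, fractions = 0.7)
cyl   <- to_cylindrical(flow, frame)
azimuthal_flow_rate(cyl$u_theta, part, flow)
#> azimuthal flow report (regions inside-out):
#>  region fluid_volume Q_theta_raw Q_theta_per_volume Q_theta_normalized
#>       1     37.81481    7.626608         0.20168306           7.420483
#>       2     24.47685    1.332551         0.05444126           1.296536
#> total Q_theta: 8.959 (R_max 196.6 um)
```

Region 1 is the inner plexus, region 2 the angiogenic front. The
normalized column divides by the nondimensional inlet volumetric flux.
Running the same code with `wedge_preset("hyper", ...)` gives a denser
network whose *front* `Q_θ` is smaller (0.69 vs 1.30 normalized at
these settings) — hyper-branching starves the angiogenic front, the
central directional result the simulation reproduces.

(Numbers above were printed by this code with the given seed; residual
step counts vary by a few steps across BLAS builds.)

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "angioflow.R", package="angioflow"))')
Rscript "$CLI" synth --preset hypo --domain 240x240 --pixel-size 2 \
               --seed 7 --out mask.pgm
Rscript "$CLI" morphometry --mask mask.pgm --pixel-size 2 --out report.csv
Rscript "$CLI" simulate --mask mask.pgm --pixel-size 2 --out run/
```

Subcommands: `synth`, `morphometry`, `reconstruct`, `simulate`,
`analyze`, `pipeline`. Masks are PGM/PPM/CSV rasters; fields are
written as legacy-ASCII VTK structured points plus CSV reports.

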