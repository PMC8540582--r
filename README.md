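# orthosim

Quasistatic finite-element simulation of facial soft tissue for
computational planning of orthognathic (jaw) surgery.

In orthognathic surgery the maxilla and/or mandible are cut (Lefort
osteotomies, sagittal splits, genioplasty) and the fragments rigidly
repositioned. Planning software must predict how the facial soft tissue
follows the repositioned bone — accurately enough to be clinically useful
(errors below 3 mm over most of the face) and fast enough to iterate plans
interactively. `orthosim` implements a simulation methodology built around
that goal: careful, compact modeling of the tissue–bone boundary conditions
so that coarse tetrahedral meshes and a simple direct solver suffice.

## The model

**Soft tissue.** One homogeneous hyperelastic continuum discretized with
linear tetrahedra (one quadrature point per element, rest volume as weight).
The Neo-Hookean energy density is

    Psi(F) = mu/2 (tr(F'F) - 3) - mu log det F + lambda/2 (log det F)^2

with Lame constants from Young modulus E = 100 kPa and Poisson ratio
nu = 0.47 (defaults; all lengths mm, pressures kPa). The total energy is
`V_soft = sum_i w_i Psi(F_i) - f_ext' x`; gravity is deliberately omitted
because the pre-operative tissue is already gravity-loaded. Bones are rigid
bodies (center of mass `x_b`, rotation `R_b`) parameterized incrementally in
the rotation tangent space; they carry no elastic energy.

**Boundary conditions as constraints.** A selection matrix `S` picks the
constrained tissue DoFs; these are an affine function `A z + c` of the free
vector `z`. Fixed tissue has `A = 0`. Tissue bonded to a prescribed fragment
follows the fragment's rigid map through `c`. At a bone cut, coupling
weights blend the adjacent fragments by linear blend skinning: 0.5/0.5 on
the cut, ramping linearly to 1.0/0.0 over 1 cm. Sliding contact is a
quadratic penalty `V_contact = k/2 |U'(Bx + d)|^2` on signed-distance
penetrations, one-sided and refreshed per Newton iterate.

**Solver.** Each quasistatic solve is a sequence of Newton steps: the energy
is modeled quadratically with an SPD-projected Hessian, the constraints are
*eliminated* — `(S~ + A'S) H (S~' + S'A) z = -(S~ + A'S)(g + H S'c)` — so
that the constrained optimization collapses to one sparse symmetric linear
solve per iteration, with constraints satisfied exactly at every iterate. A
backtracking Armijo line search guarantees energy descent; planned
transforms are decomposed into substeps (10 by default) for robustness.

**Validation toolkit.** Point-to-point ICP (SVD Procrustes with reflection
guard) recovers the transform applied to a bone fragment; signed
closest-point distances (winding-number inside test; negative = inside the
reference) produce per-vertex error maps, area-weighted cumulative
error-threshold curves, and the percentage of surface within the 3 mm
clinical limit.

No patient data ships with the package: a fixture generator builds
slab-and-block scenes whose tissue void walls and bone-fragment surfaces
share vertices exactly, emulating the matched tissue–bone interface meshing
of a prepared surgical scene.

## Worked example

A 40 x 20 x 12 mm tissue slab with an embedded bone block, cut at its
mid-plane; the right fragment is advanced 4 mm:

```r
library(orthosim)

spec <- slab_spec(dims = c(40, 20, 12), resolution = c(10, 5, 3),
                  blocks = list(list(min = c(4, 8, 4), max = c(36, 12, 8))),
                  cuts = list(list(block = 1, point = c(20, 10, 6),
                                   normal = c(1, 0, 0))))
scene <- make_slab_scene(spec)
scene
#> sim_scene: 710 tets, 2 fragments (block1_a, block1_b), 66 fixed nodes, 36 coupled nodes
scene$weight_field
#> weight_field: 36 coupled nodes (20 blended), ramp 10 mm

plan <- make_advance_plan(scene, "block1_b", advance_mm = c(4, 0, 0),
                          substeps = 10)
res <- run_plan(scene, plan)
res$converged
#> [1] TRUE
```

The solve converges in 70 Newton iterations over the 10 substeps. Comparing
the deformed boundary against the pre-operative surface quantifies how much
tissue moved:

```r
sim_surface <- surface_mesh(res$positions, scene$mesh$boundary_surface$faces,
                            validate = FALSE)
map <- compute_error_map(sim_surface, scene$mesh$boundary_surface,
                         thresholds = 1:8)
error_report(map)
#> error_report: 97.06 % of ROI surface within 3 mm
#>   signed error min -4 / mean 0.117 / max 3.87 mm
```

About 92 % of the surface moves less than 1 mm (the slab far from the cut),
while the tissue bonded to the advanced fragment carries the full 4 mm —
positive signed error, i.e. outside the pre-operative surface. The
`weight_field` nodes at the cut itself blend both fragments 0.5/0.5 and move
by half the advancement, which is exactly the smoothing that keeps local
strain bounded near osteotomies.

A command-line wrapper over the same functions ships in `inst/cli/orthosim`
(`fixtures make-slab`, `simulate`, `register`, `validate`, `report`).

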