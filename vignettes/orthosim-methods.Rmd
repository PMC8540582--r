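---
title: "Soft-tissue simulation for orthognathic planning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-tissue simulation for orthognathic planning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthosim)
```

# The problem

Orthognathic surgery corrects jaw deformities by cutting the maxilla and/or
mandible and rigidly repositioning the fragments. A planning simulator takes
the planned fragment transforms as input and predicts the resulting facial
soft-tissue shape. Two properties matter in practice: clinical accuracy
(most of the face within 3 mm of the true post-operative surface) and speed
(seconds, so surgeons can iterate). `orthosim` implements a methodology
whose central idea is that *modeling the tissue–bone boundary conditions
carefully is what lets coarse meshes and a simple solver suffice*.

# Soft-tissue model

All soft anatomy (skin, lips, gums, internal muscle) is one homogeneous
elastic continuum on a tetrahedral mesh with linear shape functions and a
single quadrature point per element (weight = rest volume). The
constitutive law is compressible Neo-Hookean,

$$\Psi(F) = \tfrac{\mu}{2}(\operatorname{tr} F^TF - 3) - \mu \log\det F
  + \tfrac{\lambda}{2}(\log\det F)^2,$$

with $\mu,\lambda$ from Young modulus and Poisson ratio. Energy, its
gradient (via the first Piola–Kirchhoff stress $P = \mu(F - F^{-T}) +
\lambda \log\!\det\!F\, F^{-T}$) and per-element $12\times12$ Hessian blocks
are assembled in compiled code.

Key parameter defaults, with units and rationale:

| parameter | default | unit | why |
|---|---|---|---|
| Young modulus | 100 | kPa | facial soft tissue bulk stiffness; literature values span roughly 3 kPa–1 MPa and the prediction is driven by prescribed displacements, so results are insensitive to the absolute scale |
| Poisson ratio | 0.47 | — | near-incompressible tissue while keeping $\lambda$ finite |
| coupling ramp | 10 | mm | 1 cm linear blend at bone cuts (see below) |
| substeps | 10 | — | robustness of the quasistatic continuation |
| penalty stiffness $k$ | $10^4$ | kPa/mm | fixture penetrations below 0.1 mm at tissue stiffness 100 kPa |
| SDF resolution | 1 | mm | well below the coarse-mesh feature size |

Everything is millimetres and kilopascals, so energies are kPa·mm³ (µJ).
Gravity is omitted on purpose: the pre-operative scan is already
gravity-loaded, and adding gravity to the rest shape would deform it
wrongly; estimating an unloaded rest configuration is out of scope.
Heterogeneous tissue maps, muscle fibers and viscoelasticity are likewise
out of scope — the homogeneity approximation is adequate for bone-driven
repositioning, less so for detailed lip interventions.

# Bones and couplings

Bones are rigid bodies: center of mass $x_b$ (computed from the closed
surface by divergence-theorem integrals, assuming uniform density — any
fixed reference point would do, the centroid merely conditions the rotation
block best) and rotation $R_b$, reparameterized each iteration by an
incremental tangent-space axis-angle $\theta_b$, so the world map
linearizes as $x = R_bX - (R_bX)\times\theta_b + x_b$.

Boundary conditions are *constraints*, not penalties. A selection matrix
$S$ extracts the constrained tissue DoFs; these equal $Az + c$ in the free
vector $z$ (free tissue DoFs, plus 6 DoFs per non-prescribed fragment).
Fixed tissue: $A = 0$, $c$ = pinned positions. Tissue bonded to prescribed
fragments: $A$ rows zero and $c$ refreshed from the fragment pose each
substep. Free fragments contribute the linearized rigid map to $A$ and are
Tikhonov-regularized ($10^{-8}\times$ the mean Hessian diagonal) because a
gravity-free unloaded fragment is otherwise indeterminate. All the
package's planning runs prescribe fragments; free fragments exist for
completeness and are exercised against a dense KKT oracle in the tests.

**Smooth coupling at cuts.** When a cut splits a bone, adjacent tissue
would be torn between the two fragments' transforms, and in reality plates
and implants sit in the gap. Instead of modeling these, coupled nodes near
a cut blend the two fragments' rigid maps (linear blend skinning): weight
0.5/0.5 on the cut-interface curve, interpolating linearly to 1.0/0.0 at
1 cm. Distance is Euclidean to the nearest cut-interface vertex — cuts are
near-planar at this scale, so the difference from geodesic distance is
second order; this choice is deliberate and documented rather than derived.
Weights are computed once in the rest pose (consistent with a constant
$A$). Nodes influenced by three or more fragments would keep the two
nearest weights renormalized; the fixtures only produce two-fragment cuts.
Positions are blended (standard LBS), not rotations.

Face groups are assigned by nearest fragment surface from each interface
face centroid, with ties broken to the lexicographically smallest fragment
id for determinism. This relies on the tissue-side interface and the bone
surfaces being meshed identically, which the fixture generator guarantees
by construction (shared vertices, bitwise).

# Contact

Sliding contact (lips over teeth, tissue over advancing fragments) uses a
quadratic penalty on signed-distance violations: each penetrating soft
surface vertex contributes $\tfrac{k}{2}\,(u^T(x_p - x_q))^2$ with witness
point $x_q$ and normal $u$ from a voxelized signed distance field
(trilinear interpolation, 1 mm default spacing, rebuilt per substep).
Activation is one-sided — only penetrating vertices, so surfaces separate
freely, which is what distinguishes sliding contact from bonding. The
contact set is refreshed at each Newton iterate and frozen within it, so
the contact energy is a true quadratic with constant PSD Hessian there.
Penalty contact is approximate by nature: residual penetration decays as
$O(1/k)$, which the tests verify as a log–log slope of $-1$ over
$k \in \{10^2,\dots,10^5\}$ on a block-into-slab fixture. That fixture uses
a 1 kPa slab so the entire prescribed stiffness range lies in the
penalty-dominated regime where the asymptote is observable. Soft–soft
contact pairs (e.g. upper against lower lip) are not implemented; the scene
schema accepts only tissue-against-fragment pairs. Friction and
continuous-time collision detection are out of scope.

# The reduced Newton solver

Each substep solves
$$x = \arg\min V_{\text{soft}}(x) + V_{\text{contact}}(x)
  \quad \text{s.t.} \quad Sx - Az - c = 0.$$
The energy is approximated quadratically (Hessian $H$, gradient $g$);
substituting the reconstruction $x = \tilde S^Tz + S^T(Az + c)$ turns the
constrained quadratic program into one linear system,
$$(\tilde S + A^TS)\,H\,(\tilde S^T + S^TA)\,z
  = -(\tilde S + A^TS)(g + HS^Tc),$$
solved by sparse symmetric factorization (systems at the package's coarse
scale are a few thousand DoFs; a direct solve is simplest and
deterministic). Constraints therefore hold *exactly* at every iterate —
there is no constraint drift to tune away, which is the efficiency argument
for this formulation. Element Hessians are eigen-projected to positive
semidefinite before assembly (toggleable; the finite-difference tests
disable it) so the quadratic model is always solvable.

Numerical choices the formulation leaves open, and what this package does:

* **Line search**: backtracking Armijo, shrink 0.5, constant $10^{-4}$.
  Steps landing on $\det F \le 0$ (where the log barrier is undefined) are
  treated as infinite energy and halved.
* **Convergence**: $\|g_{\text{red}}\|_\infty \le
  \text{tol}\,(1 + |V|/s)$ with tol $10^{-6}$ kPa·mm² and
  $s = E\,\bar w^{2/3}$ ($\bar w$ = mean element volume), making the
  criterion roughly mesh-size independent. Iteration cap 50 per substep.
* **Substepping**: planned transforms are decomposed geodesically
  (axis-angle scaled $k/n$, translation linear) into 10 substeps, each
  solved to convergence warm-started from the last. This is the robustness
  mechanism: applying a multi-millimetre jump in one step can invert
  elements in the first iterate.
* **Determinism**: the solver contains no randomness; repeated runs produce
  byte-identical outputs.

# Synthetic scenes: what they emulate and what they do not

`make_slab_scene()` builds a rectangular tissue slab (structured hex grid,
each cell split into five tetrahedra with alternating parity so neighboring
cells share diagonals conformally) with embedded bone blocks. Block cells
are removed from the tissue mesh and re-meshed as closed fragment surfaces
using the *same grid vertices*, so the tissue void wall and the fragment
surface coincide bitwise — the fixture-level analogue of deriving both from
one Boolean difference during scene preparation. Cut planes split blocks
into `block<i>_a`/`block<i>_b` by centroid side; seeded uniform jitter (at
most 20 % of the cell size, interior nodes only, checked against element
inversion) provides irregular-mesh variants.

These fixtures exercise every code path — meshing invariants, face-group
assignment, the weight ramp, the reduced solver, contact, registration and
error mapping — but they are *not* faces: no lips, no sliding anatomy, no
segmentation noise, no scan-to-scan posture mismatch. Passing tests on them
validates the numerics and the boundary-condition machinery, not clinical
accuracy; clinical-scale claims require patient meshes that are not
distributed.

Test problem sizes were chosen as the smallest that resolve each property:
finite-difference checks on ~40-element meshes, solver behavior on a
~2 800-element slab (a coarse planning-scale mesh), ten substeps for a 4 mm
advancement.

# Validation pipeline

To replicate an executed surgery one registers each pre-operative fragment
to its post-operative counterpart and feeds the recovered transforms to the
solver. `icp_register()` is plain point-to-point ICP: closest-point
correspondences, best-fit rigid transform by SVD Procrustes with a
reflection guard, RMS monotonically non-increasing, stop at $10^{-8}$ mm
change or 100 iterations. No outlier trimming and no point-to-plane metric
— adequate for the near-overlapping fragment pairs this workflow produces.

`compute_error_map()` measures per-vertex signed closest-point distance of
the simulated surface against a reference; the sign convention is negative
inside the reference volume (a simulation sitting inside the post-operative
scan reads negative). Inside/outside uses the generalized winding number at
threshold 0.5, robust to nearly-closed scans; open references require an
explicit flag and take the sign from the nearest face normal. "Percentage
of the surface" is area-weighted (one third of incident face areas per
vertex) because a surface fraction is the clinically meaningful quantity;
vertex counting is available for comparison. Cumulative curves default to
1–8 mm thresholds spaced 1 mm, and reports quote the fraction within the
3 mm clinically acceptable limit; exported overlays record a −4 to 4 mm
color range as metadata. Regions outside the clinical region of interest
(neck, occiput in real data) are excluded via a caller-supplied vertex
mask; the package does not attempt to detect them.

# Known limitations

* Homogeneous isotropic material; no muscle fibers, pretension or
  viscoelasticity. Everted-lip behavior is expected to be under-predicted.
* Penalty contact admits $O(1/k)$ penetration; no friction; no soft–soft
  pairs.
* LBS distance is Euclidean, not geodesic — adequate for near-planar cuts.
* Fragment trajectories interpolate geodesically between rest and target;
  the true intra-operative path is unknown and irrelevant at equilibrium,
  but strongly non-convex intermediate states could in principle differ.
* Quasistatic only: no inertia, damping or time-dependent response.
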