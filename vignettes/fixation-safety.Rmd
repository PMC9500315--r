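---
title: "Methods: a synthetic-spine pipeline for cervical fixation safety"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a synthetic-spine pipeline for cervical fixation safety}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the numerical choices, and what the
synthetic phantom can and cannot tell you about real patient anatomy.

## 1. The question the pipeline answers

A multi-level anterior cervical discectomy and fusion (ACDF) replaces the
resected discs with interbody spacers and locks the treated block with an
anterior plate and screws. The construct is judged safe when, under the
loads of daily head motion, no bone region that the construct relies on is
strained beyond its failure limits. The pipeline operationalizes this as:
build a spine+instrument finite-element model, solve the four motion load
cases (flexion, extension, lateral flexion, axial rotation), and check the
principal-strain damage index

$$D_i = \max\!\left(\frac{\varepsilon_{1,i}}{\varepsilon_{t,t}},
                    \frac{\varepsilon_{3,i}}{\varepsilon_{c,t}}\right),
\qquad \varepsilon_{t,t} = +1.5\%,\quad \varepsilon_{c,t} = -2.0\%,$$

over the central vertebral bodies, the screw trajectories and the
spacer-contacting endplates. Each ratio is counted only when the strain has
the threshold's sign (a tensile $\varepsilon_3$ contributes nothing), so
$D_i \ge 0$ always and $D_i \ge 1$ marks an element as broken. The limits
are tissue-level principal-strain limits for vertebral bone; they are
configurable (`damage_thresholds()`), and the verdict is monotone in them:
widening the limits can never turn a PASS into a FAIL.

## 2. The synthetic phantom and what it emulates

Patient CT geometry is deliberately out of scope: the phantom is a
stylized, fully parametric C2–T2 stack whose purpose is to carry the same
*named structure* a patient-specific model would have — two trabecular
density regions per vertebra, a thin cortical shell, nucleus/annulus
discs, six ligament groups, articular facet contact, and the instrument
construct — so that every downstream stage runs unchanged.

* **Vertebral body**: an elliptic cylinder (default 16 mm wide, 18 mm
  deep, 10 mm tall cervical / 12 mm thoracic), meshed by mapping a
  structured grid onto the ellipse and splitting each hexahedron into six
  tetrahedra with a fixed, face-conforming pattern. The central region
  (elliptical radius ≤ 0.6) and the exterior region carry separately
  measured BMD. A posterior block (the stylized arch) carries the
  spinous-process and articular-facet landmarks and is tied to the body by
  nearest-node DOF merging.
* **Cortical shell**: one layer of quadratic wedge elements offset from
  the trabecular surface — radially on the side wall, axially on the
  endplates — with exact thickness 0.28 mm (cervical) or 0.24 mm
  (thoracic) along the analytic surface normal at every node. The side and
  endplate sub-layers share their inner rim nodes but keep separate outer
  rim nodes, leaving a hairline geometric seam at the rim; mechanically
  both sub-layers remain anchored to the same trabecular rim.
* **Discs**: concentric nucleus pulposus (NP) and anulus fibrosus (AF).
  The NP boundary is scaled so that its endplate-area share equals the
  requested fraction (default 0.35, admissible 0.25–0.50) while a
  sinusoidal mid-height bulge raises its volume share to the requested
  fraction (default 0.45, admissible 0.40–0.50). Membership is decided at
  element centroids; the endplate-area measurement samples the boundary at
  the plate plane where the bulge factor is one.
* **Ligaments**: ALL, PLL, ISL, SSL, ITL and LF as 2-node tension-only
  trusses, one unit per junction except the paired ITL and LF (left/right
  units). The ALL is omitted across the instrumented span (it is resected
  when the plate is applied). The unit counts are configurable because the
  anatomy fixes only the groups, not a truss census.
* **Instrumentation**: PEEK spacers filling the three spanned disc spaces
  (heights 8, 8, 7 mm), a 55 mm titanium plate on the anterior faces, and
  eight 4.0 × 15.0 mm titanium screws, two per spanned vertebra, with a
  10° medial convergence so that shaft and tip purchase in the denser
  central body — the anatomical intent of variable-angle screw systems.
  Trabecular elements inside each screw volume are carved into a titanium
  core set (the surgical drilling step), and the screw solids are
  *embedded*: every screw node follows the linear interpolation of its
  host tetrahedron, which distributes the bone–implant load transfer
  consistently along the whole shaft instead of through a handful of point
  ties.

Interfaces between parts that share the same in-plane grid (discs,
spacers, cortical endplates) stitch by exact node coincidence — the
textbook ideal of "node equivalence". Everything else (posterior
blocks) uses nearest-node DOF merging with a capture radius of twice the
mesh size.

What the phantom does **not** emulate: real vertebral shapes, lordotic or
kyphotic curvature, facet orientation, uncinate processes, cartilage
layers, muscles, and the patient's actual dimensions. Passing tests on the
phantom therefore validates the *method* — the load construction, solver,
and safety evaluation — not any clinical prediction for a specific
patient. Quantities tied to patient geometry (segmental ROMs, trajectory
strain extrema) are checked as properties (recovery of imposed rotations,
linearity, antisymmetry, argmax contracts) rather than against clinical
values.

## 3. Materials

Trabecular regions map BMD (mg/cc) to modulus via
$E = 10200\,( \mathrm{BMD}/1000)^{2.01}$ MPa with the sentinel
$E = 0.001$ at zero density. This `as_used` law reproduces all sixteen
tabulated per-region moduli of the shipped reference case to the printed
two decimals. The `as_printed` mode keeps the full piecewise form — a
$33900\,x^{2.2}$ branch below 0.27 g/cc and $5407\,x + 469$ between 0.27
and 0.60 g/cc — whose low-density branches disagree with the tabulated
values; both modes are exposed so the discrepancy is inspectable rather
than silently resolved. The branch thresholds are interpreted in g/cc
applied to BMD/1000; read literally in mg/cc every sample would fall into
the top branch and the branches would be dead text.

Constant cards: cortical bone (1000 MPa, ν 0.30), NP (1.0, 0.49), AF
(3.4, 0.40), PEEK (4000, 0.35), titanium (110 000, 0.30); ligaments carry
their tabulated moduli (20–70 MPa) and cross-sections (10–60 mm²) with
ν = 0.3 stored for completeness (irrelevant to axial truss stiffness).
The posterior block takes its level's exterior-trabecular modulus — a
stylization; real posterior elements are more cortical.

## 4. Loading

The head weight is `body_mass · head_mass_fraction · g` with defaults
0.0783 and 9.81 m/s². Body mass is an input; the shipped 39.97 kg is the
mass that yields the reference 30.7 N head weight. Gravity is split 50/50
over the two C2 odontoid-adjacent facet patches (equal nodal forces within
each side), so the total applied force is exactly (0, 0, −HW). Motion
torques are strength × head mass with strengths 418 / 683 / 542 / 208
N·mm/kg, rounded to integer N·mm for reporting (1308 / 2138 / 1696 / 651).

Axes are the phantom's global anatomical frame (x lateral, y anterior, z
vertical): flexion/extension about x with opposite signs, lateral flexion
about y, axial rotation about z. The torque acts at a reference point
kinematically coupled to the C2 spinous-process node set
(u = u_ref + θ × r), which transmits a clean moment without local
distortion. The base — the inferior surface of T2 by default, or T1 via
`set_fix_level()`, since fixation level is ambiguous when the model
extends one level below the support — is fixed in all translations.

## 5. Solver numerics

* **Elements**: isoparametric small-strain stiffness; tet4 with 1-point,
  tet10 with 4-point quadrature; wedge6 with 3×2 points; wedge15 with
  3×3 points. The 9-point rule for wedge15 is deliberate: a 45-DOF
  quadratic prism needs at least 39 independent strain samples, and a
  6-point rule (36 samples) leaves spurious zero-energy modes. All element
  kinds are verified to have exactly six rigid-body modes.
* **Constraints**: ties are resolved by union-find DOF merging; kinematic
  couplings and embedded nodes are linear maps folded into a sparse
  reduction operator T, so the solved system is `TᵀKT` on the free reduced
  DOFs. Prescribed non-zero displacements are supported (used by the patch
  tests).
* **Tension-only trusses**: active-set iteration; a truss in compression
  is removed and re-activated when it returns to tension. No smooth
  regularization — the active set either stabilizes or the solver reports
  non-convergence.
* **Contact**: small-sliding node-to-triangle penalty. Pairing, normal and
  reference gap are fixed at the initial projection. Penalty stiffness is
  50 × (master element modulus × face length scale); residual penetration
  beyond 10⁻³ mm at convergence is an error. Friction is Coulomb with
  μ = 0.07: full-stiffness stick springs, and for slipping nodes a secant
  tangential stiffness μN/|u_t| so the tangential force settles on the
  Coulomb cap. Stick/slip transitions are only evaluated once the active
  set has stabilized (decisions taken while activation still moves would
  use meaningless normal forces), a 5% hysteresis band prevents
  chattering, and the slip fixed point has its own displacement tolerance
  (10⁻⁵ relative) because nodes with vanishing normal force make the
  force-cap error ill-scaled. The sanity gate `contact_slip_check()`
  verifies every slip distance stays below one element length — the
  plausibility condition for small sliding.
* **Linear solves**: sparse Cholesky (Matrix), with a generic sparse solve
  as fallback; fixed DOF ordering, no randomized pivoting, so runs are
  bit-reproducible. Convergence of the outer loop: active sets unchanged
  and the displacement increment below `rtol` (default 10⁻⁸ relative);
  since each inner solve is exact for its active sets, unchanged sets
  without slipping nodes imply convergence immediately.
* **Energy check**: at convergence `uᵀKu = fᵀu` to 10⁻⁶ relative is
  asserted in the test suite.

## 6. Post-processing

Strain tensors are volume-averaged per element for the damage index and
optionally nodal-averaged (`nodal_principal_strains()`) for surface maps.
Segmental ROM is the rotation angle of the least-squares rigid fit
(Kabsch) of each vertebra's landmark cloud, relative between neighbours
and projected on the motion axis; the flexion and extension magnitudes are
summed when a combined flexion–extension ROM is requested. The fit is
exact for imposed rigid rotations and linear in the load for small angles
(the finite-rotation extraction deviates quadratically, which is why the
linearity tests drive the fixture at fractions of a degree). Axis
decomposition uses the fixed global frame — the phantom is built
axis-aligned and defines no per-vertebra anatomical frames.

The trajectory report lists, per screw, the extreme tensile and
compressive principal strains, the maximum damage index, and the position
of the worst element relative to the screw axis (anterior/posterior along
the shaft, medial/lateral, superior/inferior) — the localization needed to
discuss screw plowing. The verdict aggregates the damage reports of all
four motions.

## 7. Design decisions that were genuinely open

* **Which density–modulus form is authoritative**: the tabulated moduli
  all satisfy the 2.01 power law, while the printed piecewise branches do
  not reproduce them at low density. The table is treated as ground truth
  (`as_used` default); the piecewise form remains available.
* **Ligament units**: one truss per group per junction, two for the
  paired ITL/LF; the supraspinal ligament is carried at every junction by
  default (it is only partially separable from the interspinal
  attachment), configurable via `ssl_junctions`.
* **Spacer-contacting endplate sets**: defined as the first trabecular
  element layer within the actual spacer footprint (elliptical radius ≤
  0.7). The first cut also swept in elements just *outside* the footprint,
  which sit on the punch-edge stress concentration at the spacer margin
  and do not contact the spacer at all.
* **Screw connection**: evolved from nearest-node merging to carving plus
  embedded-element coupling with medial convergence (Section 2) — each
  step removes a discretization artifact or an anatomically wrong
  trajectory, none touches thresholds or loads.
* **Facet clearance**: 0.5 mm initial gap between articular surfaces. In
  the stiff, linear, tied-disc phantom the facet gap rarely closes under
  the applied torques; the contact machinery is therefore exercised by
  dedicated two-block fixtures in the test suite.

## 8. Problem sizes and determinism

The shipped example configuration meshes the phantom at 3.5 mm (about
19 000 quadratic elements, 10⁵ DOFs), which resolves every named region
while keeping a four-motion run in the minutes range; the finer 1.5 mm
default of `phantom_spec()` is appropriate for single-part studies.
Geometry is deterministic for a fixed seed (the optional interior-node
jitter is off by default), all randomness flows from the single
configuration seed, and re-running a configuration reproduces every output
file bit-for-bit.

## 9. Known limitations

Linear kinematics and materials throughout (no finite sliding, large
deformation or plasticity); ROM magnitudes of the phantom are much smaller
than in vivo values because the tied, linear-elastic, full-footprint discs
are far stiffer in bending than real cervical discs; facet cartilage and
muscles are absent; the damage criterion is a threshold on elastic strain,
not a fatigue model; and strain concentrations at bone–implant interfaces
remain mesh-sensitive — refine before reading absolute extremes as more
than comparative indicators.
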