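# cervifem

Finite-element safety assessment of anterior cervical fixation constructs
with patient-specific bone quality.

After a multi-level anterior cervical discectomy and fusion (ACDF), the
construct — an anterior plate, fixation screws and interbody spacers —
must hold while the fused segments heal. Screw loosening is one of the most
feared failure modes, and it begins as localized overstraining of the bone
along the screw trajectories. `cervifem` is a desk-scale pipeline for the
engineer or biomechanics researcher who wants to evaluate such a construct
quantitatively: it builds a parametric synthetic C2–T2 spine with the
instrumentation in place, maps per-region bone mineral density (BMD) to
elastic moduli, applies head-weight and isometric-strength-derived motion
torques, solves linear elastostatics, and judges fixation safety with a
principal-strain damage criterion and segmental range-of-motion (ROM)
measures.

## The model in brief

**Density–modulus law.** Trabecular bone regions (a central and an exterior
region per vertebra) receive a Young's modulus from their measured BMD
(mg/cc):

    E = 10200 · (BMD/1000)^2.01   [MPa],    E = 0.001 at BMD = 0

A piecewise variant with a 2.2-power branch below 0.27 g/cc and a linear
branch up to 0.60 g/cc is available as `density_modulus_law("as_printed")`;
the default `"as_used"` single power law reproduces every value of the
reference material table to the printed two decimals.

**Loading.** The head weight is `m · 0.0783 · g` (30.7 N for the shipped
39.97 kg case), applied on the two odontoid-adjacent facet patches of C2.
Each motion's torque is the isometric cervical strength (N·mm per kg of
head mass) times the head mass: 1308 (flexion), 2138 (extension), 1696
(lateral flexion) and 651 N·mm (axial rotation), applied through a
kinematic coupling on the C2 spinous process.

**Damage index.** For every bone element with principal strains ε₁ ≥ ε₃,

    Di = max( ε₁⁺ / ε_t,t , ε₃⁻ / ε_c,t ),   ε_t,t = +1.5%,  ε_c,t = −2.0%

(each ratio counted only when the strain has the threshold's sign). An
element with Di ≥ 1 is regarded as broken; the construct verdict is PASS
iff Di stays below one over the central vertebral bodies, the screw
trajectories and the spacer-contacting endplates in all four motions.

**Mechanics.** Quadratic tetrahedra for the solid parts, quadratic wedge
layers (0.28 mm cervical / 0.24 mm thoracic) for the cortical shell,
tension-only trusses for six ligament groups, small-sliding penalty contact
with Coulomb friction (μ = 0.07) at the articular facets of the
non-instrumented junctions, DOF-merging ties ("node equivalence") at part
interfaces, and embedded-element coupling for the screws.

## Worked example

```r
library(cervifem)

# density-modulus mapping for the C2 central body (BMD 200.4 mg/cc)
bmd_to_modulus(200.4, density_modulus_law("as_used"))
#> [1] 403.1018

# motion torques from the shipped body parameters
motion_torque_table()
#>         flexion       extension lateral_flexion        rotation
#>            1308            2138            1696             651

# the damage index of the worst C2 element under extension
damage_index(c(0.0147, -0.0167), damage_thresholds())
#> [1] 0.98     # below 1: not broken

# full pipeline on the shipped example configuration
cfg <- read_run_config(system.file("extdata", "example_run.yaml",
                                   package = "cervifem"))
out <- run_pipeline(cfg, out_dir = "run1")
out
#> <run_manifest> verdict: PASS (max Di = 0.760), outputs in run1
```

The run writes `report.json` (verdict, per-set damage maxima, torques,
contact-slip summary), `rom.csv` (per-junction ROM in degrees for each
motion plus the combined flexion–extension column) and `trajectory.csv`
(per-screw strain extrema with the arc position of the worst element).
In the shipped example the largest damage index, 0.76, occurs in the C2
central body under extension — C2 carries the largest deformation of the
construct, and extension is its worst motion.

A thin command-line front end is available at `inst/cli/cervifem.R`
(`Rscript cervifem.R run --config run.yaml --out out_dir`; exit code 0 =
PASS, 2 = FAIL, 1 = error).

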