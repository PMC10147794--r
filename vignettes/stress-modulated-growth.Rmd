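---
title: "Stress-modulated vertebral growth: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-modulated vertebral growth: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinegrowth)
```

## The problem

Adolescent idiopathic scoliosis (AIS) is a three-dimensional spinal
deformity: a lateral curvature of the spine with axial rotation that can
progress rapidly during the adolescent growth spurt. Progression is
believed to be driven by a mechanical feedback loop described by the
Hueter-Volkmann law: vertebral growth plates grow slower under relative
compression and faster under relative tension. In a laterally curved
spine, gravity compresses the concave side of each vertebra more than
the convex side, so the concave side grows less, the vertebra wedges,
and the curve deepens — a vicious cycle.

`spinegrowth` implements a desk-scale, patient-specific finite-element
(FE) framework for simulating this loop over multi-year follow-up
periods: reconstruct a spine from biplanar radiographic landmarks, morph
a normative template mesh to the patient, assign maturity- and
flexibility-scaled materials, compute the standing stress state with a
two-pass anti-gravity protocol, modulate regional vertebral growth by
intervertebral disc (IVD) stress, and step growth forward in six-month
intervals while extracting the standard clinical indices (Cobb angles,
kyphosis, lordosis, axial rotation, vertebral wedging).

## Model components and assumptions

### Landmarks and reconstruction

Each patient is described by 153 landmarks: 9 per vertebra (4 frontal
body corners, 4 sagittal body corners, the centroid) over the 17 levels
T1–L5. Biplanar views are combined by orthographic triangulation — x
from the lateral view, y from the frontal view, z averaged between the
views. True stereo-radiographic calibration (cone-beam geometry) is out
of scope; the orthographic assumption makes projection/triangulation an
exact round trip, which the tests exploit.

The global frame is +x anterior, +y patient-left, +z superior (mm).

### Template and mesh

The template is a parametric, straight (normative) stack of hexahedral
vertebral-body blocks (default 4 × 4 × 2 hexes per body) with IVD blocks
ruled between adjacent endplates. IVD and endplate share nodes, which
realizes the tied disc-endplate contact exactly and keeps the interface
free of penetration logic. Posterior bony elements are not meshed;
their load path is represented by a posterior spring chain (a stiff
isotropic arm from each body's posterior face to a chain node, plus
axial chain springs) whose default stiffness (140 N/mm) produces a
posterior load share of roughly 15%, inside the 3–25% range reported
for posterior load transmission. Seven tension-only ligament springs
connect each adjacent level pair. The caudal base is fully fixed and T1
is restricted to vertical translation, standing in for pelvis and trunk
stabilization. Facet sliding contact, ribcage and pelvis meshes are
deliberately omitted (see Limitations).

Mesh quality uses the standard hexahedral acceptance metrics (scaled
Jacobian ≥ 0.5, aspect ≤ 5, skewness ≤ 60°, warpage ≤ 40°, quad angles
in [30°, 150°]) with a configurable 0.97 pass-fraction floor.

### Morphing

Patient-specific geometry is produced by dual kriging with kernel
K(h) = h and full linear drift, fitted on the 153 template-to-patient
landmark pairs. The transform interpolates every control exactly and
reproduces affine maps with zero dual coefficients, so an isotropically
scaled patient yields an isotropically scaled mesh. The kernel is
configurable (h or h³) and an optional ridge handles ill-conditioned
control sets; by default interpolation is exact.

### Materials

All solids are linear elastic. Adult moduli (vertebra 350 MPa, IVD
20 MPa) are scaled by chronological-age factors; the default age
schedules are linear in age and anchored to the published example of a
16-year-old (0.95 bone/disc, 0.97 ligament, 0.94 costo-vertebral),
saturating at 1 in adulthood. Poisson ratios are not reported in the
source literature at this granularity; the package defaults to 0.3 for
bone and 0.45 (near-incompressible) for the disc, both overridable.

Patient spine flexibility enters through the spine flexibility ratio

$$\mathrm{SFR} = \frac{\mathrm{CAS} - \mathrm{CALB}}{\mathrm{CAS}}$$

(standing Cobb at the final timepoint vs. Cobb while bending into the
convexity), and the IVD modulus is scaled as

$$E_\mathrm{scaled} = E_\mathrm{baseline}\,(1 - C \times \mathrm{SFR}),
\qquad C = 0.3 .$$

Order of application is age scaling first, then flexibility scaling;
the combined value is never rounded internally (display rounding is 1
decimal for moduli, 2 for SFR).

### FE solver

Fully integrated trilinear hexahedra (2 × 2 × 2 Gauss), assembled into
a sparse symmetric system solved by CHOLMOD Cholesky; a failed
factorization is reported as unconstrained rigid-body modes. Springs
enter as rank-one axial terms (or 3-dof isotropic links for the
posterior arms); tension-only ligaments are resolved by fixed-point
iteration on the active set (≤ 20 iterations, oscillation detected).
Growth loads are per-element diagonal eigenstrains in the element's
local frame, converted to equivalent nodal forces — the thermal-
expansion analogy. Stresses are recovered at element centers.

One caveat of fully integrated trilinear bricks is parasitic shear
stiffness in bending: the cantilever verification uses 40 elements
along the length to sit within a stated 20% of the Euler-Bernoulli
closed form. At the template's element sizes and load levels this
stiffness bias is secondary to the modeling idealizations above.

### Gravity

Per-level bodyweight fractions act at the vertebral centroids. The
default table grows the cumulative carried weight linearly from 0.14 of
bodyweight above T1 to 0.55 at L5 (literature-typical; the exact
published per-level percentages are not reproduced in the source and
the table is config-overridable). The standing stress state is
established by the two-pass anti-gravity protocol: apply the forces
upward from the imaged geometry to find the unloaded shape, reset
stresses, then apply them downward so that the imaged geometry carries
a physiological stress profile. With stiffness frozen at the imaged
geometry the protocol restores the imaged shape exactly; re-resolving
the tension-only ligaments in each pass can leave sub-millimetre
deviations, warned above 2 mm RMS.

### Growth law and stepping

Each vertebra carries 13 regions (4 body quadrants + 9 posterior
regions) with growth coefficients in 3 directions: 17 × 13 × 3 = 663
coefficients. Only the 4 body quadrants' *vertical* coefficients are
stress-modulated:

$$G = G_m\,[\,1 + \beta\,(\sigma - \sigma_m)\,]$$

with tension-positive stress inside the law, growth floored at zero (no
resorption), and the stress sensitivity decaying with skeletal maturity
as β = max(0, 0.4 − 0.08 × Risser) MPa⁻¹, vanishing at Risser 5. Each
body quadrant is driven by the axial stress of the *matching quadrant*
of the disc below it (the disc above for L5). The baseline stress σ_m
is defined per level as the mean of that disc's four quadrant stresses
— a choice the source leaves open; it guarantees that symmetric loading
produces no modulation, which is the property the tests pin down. A
normative-baseline alternative can be substituted by passing explicit
quadrant baselines.

Baseline growth defaults to a vertical body strain of 4%/year at
Risser 0 declining linearly to zero at Risser 5, uniform over levels,
with transverse growth at 0.3 of the vertical rate; published normative
growth tables can be supplied through the same interface. Documented
Risser values are interpolated linearly across timepoints (held
constant if only one is documented) and both β and G_m are refreshed
every interval.

Each interval is a staggered step: (1) two-pass gravity at the current
geometry; (2) quadrant modulation of the coefficients; (3) one
eigenstrain solve applying α·dt; (4) commit the displaced nodes as the
new reference and reset stresses. Geometry thus updates incrementally
in small-strain steps rather than through a finite-strain formulation;
eigenstrain magnitudes above 0.2 per step are rejected with advice to
shorten dt (the default 0.5-year step stays near 2%).

### Clinical indices

Cobb angles use endplate lines through the frontal corner pairs with
end vertebrae selected by exhaustive maximization of the inter-endplate
angle (the clinical "most tilted" rule, verified in tests against a
brute-force oracle); the apex is the level with maximal lateral
deviation from the end-vertebra chord. Kyphosis (default T1–T12) and
lordosis (default L1–L5; the model has no sacrum) are Cobb-style
sagittal angles. Wedging is the superior-inferior endplate angle,
signed positive toward the convexity. Axial rotation is the transverse
angle of the left-right axis through the frontal corner midpoints — one
defensible choice among several in use clinically. All indices are
invariant to rigid translation and uniform scaling, and reported to
0.1°. Model-vs-reference comparison flags absolute errors against the
8° threshold used for manual radiographic measurement error.

## The synthetic-patient generator

No clinical radiographs ship with the package; the generator is the
test substrate. It builds per-level endplate orientations from
piecewise-linear tilt profiles: ±half the requested Cobb angle at the
curve end vertebrae (thoracic convex-left, lumbar compensatory
convex-right), a kyphosis profile over T1–T12 and a lordosis profile
over L1–L5 in the sagittal plane. Centroids are chained bottom-up along
the local tangent with spacing from a pediatric-plausible dimension
table (widths 26→42 mm, heights 13→23 mm, discs 4→8 mm, T1→L5). Two
numerical details make the measured angles exact on noise-free output:

* the frontal tilt is pre-compensated for projection coupling with the
  sagittal tilt (φ′ = atan(tan φ / cos ψ)), so the *projected* frontal
  endplate angle equals the request;
* the profile is continuous — a 3-level ramp-in above the thoracic
  curve and a halving decay below the lumbar one — because a profile
  that drops to zero outside the curve ranges concentrates a ~20° tilt
  step across one 4–5 mm disc and inverts its hexahedra after morphing.
  The ramp levels never exceed the end-vertebra tilts inside either
  measurement window, so Cobb maximization is unaffected.

Landmark noise is Gaussian, i.i.d. per coordinate, with a mandatory
seed. The default profile emulates a skeletally immature (Risser 0)
11-year-old, 37 kg, with a flexible 40° main thoracic curve — the
highest-progression-risk corner of the AIS demographic.

What the generator does *not* emulate: realistic vertebral shape beyond
boxes (no posterior element geometry in the landmarks), axial rotation
coupling, inter-patient shape variability, or measurement bias that is
not zero-mean. A green round-trip test therefore establishes the
internal consistency of generator + metrics + morphing, not clinical
reconstruction accuracy.

## Numerical choices

* Quadrant assignment splits each body block at its mid-sagittal and
  mid-coronal planes; refinements must be even so no element straddles
  a split and the landmark-bearing mid-plane nodes exist.
* Tension-only deactivation uses a −1e−12 elongation tolerance; ties
  (exactly zero elongation) stay active.
* The kriging system is solved by QR with a rank check; coplanar or
  duplicate controls are errors, condition numbers above 1e12 warn.
* Equilibrium is verified to 1e−8 relative on free dofs after every
  solve; element stresses come from the center point of each hex.
* Determinism: the only stochastic component is generator noise, seeded
  explicitly; repeated simulations are bit-identical.

## Scale and the acceptance suite

The published framework this package re-implements ran a 307,564-element
template inside a commercial explicit solver; its exact template,
13-region partition and the five patients' radiographs are not public.
The package therefore runs a reduced parametric template (~800 hexes at
the default 4 × 4 × 2 refinement) and its acceptance suite runs the
3-year growth criteria at 2 × 2 × 2 (~200 hexes) to stay inside a
desk-scale time budget — the identical pipeline, scaled down. The
acceptance criteria that *are* checked exactly are the closed-form
clinical quantities (flexibility ratios, the β schedule, age-scaled
moduli, the 663/153 cardinalities), FE patch tests to 1e−8, kriging
interpolation/affine reproduction, round-trip angle recovery within 1°,
symmetry preservation, the β-ordering of progression, wedging direction,
and physiological plausibility bands (IVD quadrant stress < 1.5 MPa,
apical wedging rate 0.1–2.0°/year).

## Known limitations

* No muscles, ribcage, pelvis, lungs or bracing; the constraint set and
  posterior springs stand in for their mechanical role.
* Linear elastic IVD without nonlinearity or osmotic swelling; single
  bone modulus without cortico-cancellous distinction.
* The axial-rotation estimator's noise floor is ~1° at 0.5 mm landmark
  noise (midpoint-axis definition); sub-degree recovery would need an
  all-corner fit.
* Lumbar Cobb requests much smaller than the thoracic request re-create
  a sharp tilt step at the thoracolumbar junction in the generator.
* Growth of the discs themselves is not simulated; column lengthening
  comes from the vertebrae alone.
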