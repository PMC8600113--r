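---
title: "Methods: cyclic plaque structural stress from cross-sectional imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cyclic plaque structural stress from cross-sectional imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`plaquestress` estimates how much the structural stress in a coronary vessel
wall changes over one cardiac cycle, frame by frame, from two inputs that
intravascular imaging workflows already produce: (i) segmented cross-section
geometry — lumen contour, internal elastic lamina (IEL) contour, labeled
lipid/calcium regions, media and adventitia thicknesses — and (ii) a resting
intracoronary pressure recording (simultaneous aortic and distal channels)
together with a pressure-ratio pullback curve that locates each frame between
the two pressure measurements.

Per frame the pipeline reports:

* **ΔPSS** (kPa): the maximal von Mises stress within the superficial band of
  the wall (reference-configuration depth ≤ 50 µm from the lumen) at the
  moment of maximal pressure load;
* **LDC** (mm) and **LDC%**: the change in lumen diameter over the cycle,
  absolute and relative to the minimal diameter, with "diameter" realized as
  the area-equivalent effective diameter `2*sqrt(A/pi)` (rotation invariant
  and insensitive to contour noise, unlike a caliper diameter);
* plaque burden (%) and minimal fibrous cap thickness (µm; undefined for
  frames without a lipid pool).

## Mechanical model

Each cross-section is treated as a 2D plane-strain solid in finite
deformation. The imaged (diastolic) geometry is the stress-free reference
configuration and the load is the *relative* pressure — the cyclic pressure
minus its own diastolic minimum — applied as a follower load on the lumen
boundary. This deliberately sidesteps zero-pressure-state reconstruction:
the quantity of interest is the stress *change* over the cycle, not the
absolute stress, so initial-stress estimation (pre-shrinking, backward
incremental methods) is out of scope.

Tissue behavior is hyperelastic and nearly incompressible:

* lipid pool and calcification: isotropic exponential Mooney–Rivlin,
  `W = c1(I1-3) + c2(I2-3) + d1(exp(d2(I1-3)) - 1)`;
* intimal fibrous tissue, media, adventitia: a two-term fiber-reinforced
  (Holzapfel-type) energy
  `W = mu(I1-3) + k1/k2 (exp{k2[(1-rho)(I1-3)^2 + rho(I4-1)^2]} - 1)`
  with a single in-plane circumferential fiber family. The two-term form is
  implemented literally as written above (it is not the
  Gasser–Ogden–Holzapfel kappa-dispersion variant); `rho` weights the fiber
  term against the isotropic exponential. The fiber contribution is active
  only in fiber tension (I4 ≥ 1), the standard collagen convention; the
  switch is configurable off.

Invariants are evaluated on the isochoric split (`J^{-2/3}`-scaled, with the
plane-strain out-of-plane stretch fixed at 1), and near-incompressibility is
enforced by a volumetric penalty `kappa/2 (J-1)^2` with `kappa` defaulting to
1000× the material's small-strain shear modulus (configurable;
values ≥ 100× behave as effectively incompressible).

### Material constants

No standard constants exist for these models, so the package ships a
default table transcribed from the vascular-biomechanics literature
(`inst/extdata/materials.yaml`, kPa): lipid `c1=2, d1=2, d2=1.5` and calcium
`c1=368, d1=144, d2=2` in the Mooney–Rivlin form (Tang et al. plaque
models), and layer-specific Holzapfel constants adapted from the human
coronary data of Holzapfel et al. (intima `mu=13.95, k1=263.66, k2=170.88`;
media `mu=0.64, k1=21.60, k2=8.21`; adventitia `mu=3.78, k1=38.57,
k2=85.59`; `rho=0.85` throughout, placing most of the exponential stiffening
in the circumferential fiber direction). `mu` is half the cited `c` because
this energy carries no 1/2 on the isotropic term. These are defaults, not
fitted values: any YAML file with the same layout can be passed through the
run configuration, and every run echoes the exact table it used into its
manifest. Note that these layer fits are stiff at small strain — simulated
LDC% values (≈1–2%) are accordingly smaller than typical clinical lumen
pulsation; comparisons between groups and along a lesion are the intended
use, not absolute deformation magnitudes.

## Position-specific load

The two pressure channels are anchored at the two ends of the pullback: the
proximal end feels the aortic pressure `Pa(t)`, the distal sensor position
the distal pressure `Pd(t)`. For a frame at pullback position `x` the
package linearly normalizes the pullback ratio curve between those anchors:

`P(x,t) = Pd(t) + (Pa(t) - Pd(t)) * (OFR(x) - OFR_w) / (OFR_p - OFR_w)`

with `OFR_p` the proximal-end value and `OFR_w` the value at the distal
sensor. This linear map is the minimal relation consistent with the two
anchors and is an explicit modeling assumption of the package. A flat pullback (no gradient)
falls back to `Pa(t)` with a warning.

One representative beat is used per analysis: the aortic channel is
segmented at its diastolic feet and the beat with the largest pulse pressure
is selected — deterministic, in contrast to ensemble averaging. The
diastolic reference subtracted from the cyclic pressure is the beat minimum
of the *frame's own* position-specific pressure, so the load vanishes
exactly at the frame's diastole and the imaged geometry is the stress-free
state. Conversion uses 1 mmHg = 0.133322 kPa. For the quasi-static elastic
solve the beat is discretized into monotone load levels up to the peak
(default 10); intermediate unloading is redundant because the response is
path independent.

## Geometry and meshing

All geometric bookkeeping exploits the fact that vessel cross-sections are
star-shaped about the lumen centroid (the coordinate origin after
normalization): contours are stored as closed counterclockwise polygons in
mm, and regions are decomposed into radial intervals along rays. Media and
adventitia are built by offsetting the IEL contour uniformly along its
outward vertex normals (contours are resampled to uniform arc length first,
for stable normals); lipid/calcium regions are clipped to the intima, with
calcium winning any overlap (calcium delineation is the higher-confidence
OCT reading). The layer/region areas must tile the wall annulus — the
package validates the partition to 0.1%. A partially visible IEL can be
completed by a direct least-squares ellipse fit when at least 180° of arc is
visible; otherwise the adjacent frame's IEL is the documented fallback, and
frames with invisible outer layers take their media/adventitia thicknesses
from an adjacent frame as substitute input.

The mesh is a conforming constant-strain triangulation built on radial node
columns: each column carries a node exactly on every interface its ray
crosses (lumen, region boundaries, IEL, media, outer boundary) with graded
filler nodes between, and adjacent columns are stitched by a monotone
two-pointer strip triangulation — conformity holds by construction. Element
size grades from `h_superficial` (default 0.045 mm) at the lumen to `h_bulk`
(default 0.15 mm) at the outer boundary; near the lumen the node spacing is
`h_superficial/sqrt(2)` with a tightened angular chord so that every element
of the 50 µm superficial band keeps its longest edge below 50 µm — the
resolution requirement that defines the superficial layer. The media and
adventitia layers share a single radial subdivision count across all columns
so that neighbouring columns cannot flip across a rounding threshold; inside
the intima, where region interfaces come and go, a few locally skewed
triangles (interior angles down to ≈15°) can appear at crescent tips —
away from the superficial band, and reported by `mesh_quality()`.

## Solver

Equilibrium is solved by an implicit quasi-static incremental Newton method;
an explicit dynamic solver would add mass scaling and damping parameters
without changing the quasi-static answer, so determinism and desk-scale
speed won the trade. Key numerical choices:

* **Incompressibility.** A local penalty on constant-strain triangles locks
  and produces a boundary pressure checkerboard, so the volumetric energy is
  assembled with the *average nodal pressure* treatment (node-patch-averaged
  Jacobians), the established cure for linear triangles; it plays the role
  of a mixed ("hybrid") displacement–pressure element.
* **Tangent.** The isochoric tangent is assembled by element-local *central*
  differences of the element forces (step 1e-7 mm). Central differencing
  matters: at the reference state every fiber sits exactly at the
  tension-switch kink I4 = 1, and one-sided differences there produce an
  inconsistent mixture of one-sided stiffnesses that can send Newton into
  overflow, while the central difference yields the symmetric generalized
  Jacobian (the semismooth-Newton object). The volumetric tangent is
  analytic (rank-one nodal term plus determinant Hessian); the follower-load
  stiffness is analytic.
* **Globalization.** Backtracking line search on the residual norm, which
  also guards against inverted elements and material-exponential overflow;
  on Newton failure the load step is bisected automatically (≤ 5 levels).
* **Constraints.** The three in-plane rigid-body modes are removed by
  Lagrange multipliers (zero mean translation, zero net rotation about the
  origin), restraining rotation — the model cannot roll — while leaving
  radial deformation free.
* **Convergence.** Relative residual ≤ 1e-8 (or absolute ≤ 1e-10) at every
  accepted level.

Stresses are reported per element (constant-strain centroids); ΔPSS is the
maximum over superficial-band centroids at peak load, without nodal
extrapolation. One detail of stress recovery: the penalty pressure
`kappa(Jbar - 1)` inherits mesh-scale Jacobian noise amplified by `kappa`,
so the *reported* hydrostatic component is passed once more through the
area-weighted node-patch average before being added to the deviatoric
stress (an output-smoothing step only — the equilibrium iteration uses the
unsmoothed field). Von Mises values are purely deviatoric and are unaffected
by this choice. Because the model is elastic and quasi-static, the minimal
lumen diameter occurs at zero load and the maximal at peak load; both are
always present as steps.

## Synthetic data: what it emulates and what it does not

The generator produces idealized cross-sections (smoothly perturbed circular
lumen and IEL, eccentric wall, a lipid crescent whose inner boundary is the
lumen offset by exactly the requested cap thickness, optional deeper calcium
arc), two-harmonic pressure waveforms (systolic peak plus dicrotic bump,
exact systolic/diastolic bounds), and sigmoidal pullback ratio curves.
Cohort defaults echo clinical scales: reference lumen radii 1.1–1.5 mm at
≈30% plaque burden, diseased lumen radii ≈0.8–1.05 mm with thick eccentric
intima (≈55–70% burden), caps 50–300 µm, ~1 Hz beats between ~80 and
~120 mmHg. Everything is deterministic per seed.

What the synthetic data does *not* contain: irregular (non-star-shaped)
lumina, napkin-ring or multi-pool plaque architectures, OCT segmentation
noise and attenuation artifacts, vessel curvature and axial stress, residual
stress. Passing the package's tests therefore demonstrates correctness of
the mechanics and plumbing on idealized morphology, not clinical validity on
patient images.

A consequence worth stating explicitly: with the literature material table
and these morphology scales, the *mean* superficial stress of plaque-free
reference sections is comparable to — and can exceed — that of diseased
sections, because reference sections combine a larger lumen radius (higher
wall tension at equal pressure) with a thin, very stiff intima, while small
diseased lumina are protected by the Laplace scaling unless the cap is thin.
The per-frame mechanistic direction is unambiguous (ΔPSS rises steeply and
strictly monotonically as cap thickness falls from 250 to 50 µm, ≈3× over
that family), but the *group-mean* contrast between diseased and normal
sections is sensitive to the cap-thickness distribution and to how stiff the
healthy intima is assumed to be. The package reports the group comparison as
computed and leaves the material table user-replaceable rather than shipping
constants chosen to force the clinical direction.

## Open choices resolved here

* Shoulder frames are midpoints in *frame index* (at fixed pullback speed
  this coincides with mm positions), with floor tie-breaking toward the
  proximal side, deterministic and logged.
* Cap thickness is the per-frame minimum lumen–lipid distance, not a
  fixed-sector measurement.
* The superficial band is fixed in the reference configuration, so band
  membership cannot change between load steps.
* The `<50 µm` mesh requirement is enforced in the superficial band with
  graded coarsening outward; meshing the whole wall at that size would cost
  ~10× the elements for no change in the reported metrics (the refinement
  acceptance check bounds the residual discretization effect).
* Quartiles in cohort summaries are type-7 (linear interpolation).
* Problem sizes used in the shipped tests and acceptance script: annulus
  benchmarks at the default mesh (~10k triangles), synthetic lesions with
  lumen radii 0.8–1.5 mm (~4–10k triangles per frame), two monotone load
  steps for metric extraction (path independence makes more steps
  redundant), chosen so a complete run stays at desk scale.

## Known limitations

2D plane strain ignores axial and shear loading and vessel curvature; no
wall shear stress, no fluid–structure interaction, no viscoelasticity,
damage or residual stress; material constants are population literature
values, not patient-specific; the OFR→pressure normalization is a documented
linear assumption; geometry must be star-shaped about the lumen centroid.
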