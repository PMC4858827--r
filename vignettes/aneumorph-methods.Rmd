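---
title: "Methods: phantoms, reconstruction, morphometry and WSS statistics in aneumorph"
author: "aneumorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantoms, reconstruction, morphometry and WSS statistics in aneumorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

Patient-specific hemodynamic analysis of intracranial aneurysms starts from
an angiographic scan. The three clinical modalities — rotational angiography
(3DRA), CT angiography and MR angiography — resolve the lumen with
decreasing spatial fidelity, and every downstream quantity (morphometrics,
wall shear stress statistics, rupture-risk indices) inherits that
difference. `aneumorph` reproduces this comparison at desk scale: a
synthetic "patient" with exactly known geometry is imaged under three
modality profiles, each image is segmented and reconstructed into a surface
model, and the modality-specific models are compared morphologically,
hemodynamically and by surface distance against the 3DRA-like reference
model (DM), exactly as a clinical three-modality cohort would be analysed.

The package deliberately replaces two stages that are outside its scope
with controlled stand-ins:

* **No CFD solve.** Wall-shear-stress fields are produced by a synthetic
  generator (`synthesize_wss`) rather than a Navier–Stokes solver. The
  generator is constructed to exhibit the canonical spatial pattern of
  saccular aneurysm hemodynamics — low cycle-averaged WSS over the sac,
  elevated oscillatory shear over the sac body, and a steep WSS gradient
  across the neck — so that the *post-processing* (AWSS, OSI, AWSSG and
  their regional statistics) is exercised on realistic inputs. Boundary
  condition helpers (mean inlet velocity from the flow waveform, peak
  Reynolds number, fluid constants rho = 1056 kg/m^3 and
  mu = 0.0035 Pa s, a 0.65:0.35 MCA:ACA outflow split) are provided for
  completeness but no flow is solved.
* **No observer-based flow classification.** Categorical flow
  characteristics can be supplied as labels and are compared with Cohen's
  kappa; nothing in the package generates them.

## The phantom and its closed-form ground truth

The phantom is the union of three implicit solids, meshed by marching
tetrahedra at level 0 of the signed distance:

* a parent vessel: a capped tube of radius `parent_radius` whose
  centerline is straight or an arc of curvature `parent_curvature` in the
  xy-plane;
* a neck column: a vertical cylinder of radius `neck_radius` (r_n)
  reaching from inside the tube up to the aperture plane, which sits
  `neck_standoff` above the tube top;
* the sac: a sphere of radius `sac_radius` (R) centred
  `sqrt(R^2 - r_n^2)` above the aperture centre.

Because the aperture plane intersects both column and sphere in the exact
circle of radius r_n, the morphological ground truth is closed-form:
size (maximum perpendicular height) `R + sqrt(R^2 - r_n^2)`, neck area
`pi r_n^2` (and the column makes this the *minimal* section, since the
sphere widens above the aperture and the column is constant below it),
aspect ratio size / (2 r_n), parent diameter 2 `parent_radius`, maximum
height from the neck centroid equal to the size (sphere geometry), hence
SR = size / PVD and an aneurysm angle of 90 degrees.

The `neck_standoff` (default 0.4 mm) exists for a geometric reason: if the
sac sat directly on the tube, the aperture plane would be tangent to the
parent surface, and any cross-section near the neck would graze the vessel
over its whole length — a degenerate configuration that no measuring
procedure handles gracefully (nor occurs anatomically, where the neck is a
distinct waist). With the standoff, all neck sections are transversal.

A tilted sac (`sac_offset_angle` > 0) adds an apex lobe — a sphere of
radius r_n centred on the tilted axis through the neck centre, protruding
past the main sphere. The lobe is what makes the tilt *measurable*: for a
pure sphere the farthest boundary point from any interior point lies on
the line through the centre, so the measured aneurysm axis would read 90
degrees regardless of construction. With the lobe, the constructed angle
is exactly `90 - sac_offset_angle` degrees.

Default study conditions: parent radius 2 mm, length 16 mm, sac radius
3 mm, neck radius 1.5 mm, meshed at 0.2 mm; per-patient jitter of sac
radius (±0.4 mm), neck radius (±0.25 mm) and curvature (0–0.02 /mm).
These are plausible mid-range values for middle-cerebral and carotid
segment aneurysms and small enough to run a five-patient, three-modality
study on one CPU in minutes.

## Modality profiles and image formation

A modality profile is three numbers: voxel spacing, Gaussian point-spread
sigma, and additive noise as a fraction of the lumen–background contrast.
Defaults:

| profile | spacing (mm) | PSF sigma (mm) | noise |
|---|---|---|---|
| DRA_like | 0.15 | 0.10 | 1% |
| CTA_like | 0.40 | 0.30 | 3% |
| MRA_like | 0.50 | 0.45 | 5% |

The ordering (rotational angiography best, MRA worst) is the empirically
established ranking of the three modalities for lumen imaging; the exact
numbers are package choices, exposed in the configuration, chosen to sit
in the range of clinical scanner protocols. Image formation renders the
lumen with linear partial-volume weighting (intensity ramps from
background to lumen across one voxel of signed distance), applies the
separable Gaussian PSF, then adds seeded white noise. Partial-volume
rendering matters: it is what lets a mid-intensity isosurface land on the
true surface with sub-voxel accuracy, and what produces the
characteristic overestimation of the neck area at coarse voxels (see
below).

## Reconstruction

The reconstruction stage mirrors a standard angiographic segmentation
workflow: global threshold ("auto" = midpoint of the two largest
histogram modes, falling back to the midpoint of 2-means intensity
centres), 26-connected region growing from a seed to remove unconnected
structures, grey-level isosurface extraction (marching tetrahedra on the
Kuhn 6-tetrahedron cube decomposition, which is consistent across cube
faces and therefore watertight), and Taubin lambda/mu smoothing
(lambda = 0.5, mu = -0.53, 10 passes by default) as the discrete
counterpart of recursive Gaussian surface filtering. Smoothing preserves
vertex count and topology; volume shrinkage is monitored and warned above
5%. Voxel coordinates are cell-centred (world = origin + index ×
spacing) and meshes always live in world millimetres.

Region partition takes the neck curve as given (for phantoms, the exact
aperture circle; the study applies the same ground-truth curve to every
reconstruction of a patient, isolating geometry-induced differences). The
plane fitted to the curve splits the surface; a band of total width
0.1 × D1 around the curve is `neck_band`; the parent ROI extends to
arclength station 1.5 × D1 from the neck along the parent principal axis,
and everything beyond is `extension` (excluded from all statistics, like
flow extensions in a CFD model). Two robustness choices deserve note:

* the aneurysm label is the largest connected component of sac-side faces
  after cutting along the neck band (with a cut radius adapted to facet
  size); otherwise facets of the parent wall that graze the neck plane —
  routine at 0.4–0.5 mm voxels — would leak the sac label down the vessel;
* the parent extent uses the axial station rather than a surface
  geodesic, so that a D1 = 4 mm vessel has its ROI end exactly 6 mm up-
  and downstream of the neck instead of varying around the circumference.

D1 itself is measured from the first closed parent cross-section proximal
to the neck aperture, because at the aperture station the parent section
is open where sac and vessel communicate.

## Morphometry

The seven morphological parameters follow the standard clinical
definitions. The neck plane is the least-squares plane of the neck curve;
neck diameters are directional widths of the projected curve over a dense
direction sweep, and the "average neck diameter" is (max + min)/2 — the
combination is a documented choice, configurable, since only the two
extreme diameters are well defined. Size is the maximum perpendicular
height of aneurysm vertices over the plane; AR = size / average neck
diameter holds exactly by construction. The neck area is the smallest
closed cross-section over candidate planes through the neck centroid with
normals perturbed up to ±10 degrees and small axial offsets up to ±10% of
the neck radius; the offsets let the minimiser avoid the isosurface
chamfer at the sac–column crease. PVD averages the sectional diameters D1
(proximal neck) and D2 (1.5 × D1 upstream). The maximum aneurysm height
H_max is the largest Euclidean distance from the neck centroid to the sac
(distinct from the perpendicular size), SR = H_max / PVD, and the
aneurysm angle is measured between the neck plane and the aneurysm axis,
with 90 degrees for a perpendicular sac. The axis direction averages the
farthest 1% of sac reach instead of taking the single farthest vertex,
which makes the angle robust to facet-level jitter (a single-vertex argmax
can wander several degrees on a hemispherical dome where many vertices are
nearly equidistant).

All parameters are rigid-motion invariant; size, sqrt(NA), PVD and H_max
scale linearly under uniform scaling; AR, SR and AA are scale-free. On
the default phantom meshed at 0.2 mm every parameter lands within 2% of
its closed form.

**A note on the neck area.** NA is the one parameter that remains
voxel-size sensitive even with noise and blur switched off: linear
interpolation across the concave sac–vessel junction chamfers the crease
outward, widening the measured neck by a fraction of a voxel. At 0.4–0.5
mm voxels this produces several-percent to tens-of-percent NA
overestimation relative to the 0.15 mm reference — the same partial-volume
behaviour reported for clinical CTA/MRA neck measurements. The pipeline
consistency test therefore holds size, AR, PVD and SR to 3% across
degradation-free modality grids but documents NA (and the angle, at 5%) as
genuinely grid-limited.

## Hemodynamic statistics

With the WSS vector sampled at n + 1 uniform times covering one full
cycle (both endpoints present, so trapezoidal quadrature spans exactly one
period):

* **AWSS** is the magnitude of the component-wise trapezoidal time
  average of the vector.
* **OSI** = 0.5 (1 − |∫ WSS dt| / ∫ |WSS| dt), clamped to [0, 0.5]
  against round-off; identically zero WSS gives OSI 0, flagged. A
  fixed-direction course gives exactly 0 and an equal-magnitude reversal
  exactly 0.5.
* **WSSG** uses the per-triangle linear-shape-function gradient of each
  Cartesian WSS component, area-averaged to vertices; **AWSSG** is the
  trapezoidal time average of the instantaneous root-sum-square gradient
  magnitude. The time average is taken of the gradient magnitude (the
  integrand under the root is instantaneous); averaging before the root
  is not meaningful dimensionally and is not what the standard WSSG
  definition does.

The nine regional parameters use area weighting throughout (vertex area =
one third of incident triangle areas): mean AWSS over the sac and parent
ROI, sac area fraction below 0.4 Pa at end diastole (LWSS), maximum and
area-weighted 90th-percentile WSS at peak systole (MWSS, 90WSS), mean,
maximum and above-0.2 area fraction of OSI (OSI, MOSI, HOSI), and mean
AWSSG. Area fractions rather than vertex fractions make the statistics
robust to non-uniform meshing; the percentile interpolates linearly
between order statistics with midpoint weighting. Peak systole defaults
to the time of maximum inlet flow and end diastole to the last sample of
the cycle; both can be overridden. OSI-derived statistics are computed on
the cycle-integrated OSI map: although summaries are reported "at peak
systole" in parts of the clinical literature, OSI is by definition a
whole-cycle quantity, so a per-instant OSI has no meaning; this reading
is fixed and documented.

The synthetic generator's defaults (base magnitude 3 Pa, dome attenuation
0.15, neck gradient scale 2 Pa/mm, body oscillation fraction 0.8, 32
timesteps, 5% spatial jitter) were chosen once so that the parent vessel
sits at a physiological arterial WSS scale, the sac mean falls below it
by roughly an order of magnitude at the dome, end-diastolic sac WSS
produces a nonzero LWSS fraction against the 0.4 Pa threshold, and peak
body OSI (≈0.3) comfortably exceeds the 0.2 high-OSI threshold. The
field is exactly periodic by construction (the closing sample is set
equal to the first).

What the generator does *not* emulate: impingement jets, secondary
vortices, inter-cycle turbulence, or any coupling between geometry and
flow beyond the region labels. Passing tests therefore demonstrate that
the measurement pipeline — not a flow solution — is correct, and that
geometric degradation propagates into the *measured* statistics; they say
nothing about how a real flow field would differ between modalities.

## Surface distance

Model pairs are compared by sampling each surface (all vertices plus
deterministic area-stratified face samples at ≥10 per mm^2 by default,
using a fixed low-discrepancy barycentric lattice — no RNG), measuring
each sample's exact point-to-triangle distance to the other surface
through a uniform-grid spatial index, and pooling both directions. The
report carries the mean, SD and maximum (the symmetric Hausdorff distance
of the sample sets); the mean is the headline scalar. Rigid alignment,
when requested, is ICP from a centroid + principal-axes initialisation
(all four proper axis-sign combinations scored), iterating exact
closest-point correspondences and Kabsch updates; it is deterministic and
refuses to return an improper rotation. In the synthetic study the models
share one world frame, so alignment defaults to off there.

## Statistical comparison

Each parameter is compared per patient as |test − DM| / DM × 100%;
cohort tables report mean ± SE (SD/√n) with a paired two-sided Wilcoxon
signed-rank test on the raw paired values (not on the percent
differences, which have no natural pairing against the reference). The
Wilcoxon implementation drops zero differences, mid-ranks ties, and uses
the exact null distribution up to n = 25 — computed by convolution over
sign assignments of the doubled midranks, which stays exact in the
presence of ties, where the classical tabulated distribution does not
apply — switching to a tie-corrected normal approximation with continuity
correction above. Cohen's kappa on categorical flow labels uses the
standard unweighted estimator with agreement categories poor (< 0.4),
moderate, good (> 0.75); boundary values fall to the lower category, a
documented resolution of the open boundary in the conventional strict
inequalities.

## Numerical choices and degenerate inputs

* Marching tetrahedra interpolation clamps edge parameters to
  [1e-6, 1 − 1e-6] and nudges exact zero node values, so no degenerate
  zero-area triangles arise from vertices landing on grid nodes; any
  remaining zero-area triangles are excluded from gradient assembly with
  a warning.
* Region growing refuses a seed outside the mask and suggests the
  nearest in-mask voxel; extraction refuses a mask touching the volume
  border (advising padding) rather than producing an open surface.
* An empty sac (sac_radius = 0) flags all sac metrics as undefined
  instead of erroring, so plain-vessel fixtures flow through the
  pipeline.
* Percent differences against a zero reference are flagged NA and
  excluded from cohort summaries with a logged note.
* All randomness is seeded through explicit `rng_seed` fields; the study
  fans per-patient seeds deterministically from one master seed, and seed
  state is restored after use, so identical configurations produce
  byte-identical report files.

## Problem sizes

The shipped configuration runs a five-patient, three-modality study —
fifteen reconstructions at up to 0.15 mm voxels with full morphometric,
hemodynamic and distance analysis — in a few minutes on one CPU; the
test-suite fixtures use 0.2–0.3 mm phantom meshes and 8–64 timestep
fields. These sizes were chosen as the smallest at which every
discretisation-sensitive tolerance in the test suite is met with margin;
all of them scale up by changing the configuration objects only.

## Known limitations

* The WSS generator is a pattern emulator, not physics; absolute
  hemodynamic differences between modalities reflect geometric error
  propagation only.
* Neck-curve delineation is taken as input (analytic for phantoms);
  there is no automatic minimal-girth neck detector.
* Branch vessels, bone, contrast dynamics and DICOM semantics are not
  modelled; fusiform aneurysms are out of scope of the morphometric
  definitions.
* The parent "centerline" is a principal axis, adequate for the gentle
  curvatures generated here but not for tortuous vessels.
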