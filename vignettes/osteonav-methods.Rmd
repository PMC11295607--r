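---
title: "Registration and cutting-plane accuracy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration and cutting-plane accuracy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteonav)
```

osteonav models the computational core of an image-guided workflow for high
tibial osteotomy (HTO): aligning ("overlaying") a virtual bone model onto the
physical bone, and measuring how faithfully a planned osteotomy cut is
executed under different guidance modalities. This vignette describes the
models, the parameters that matter, what the synthetic data emulate, and the
numerical choices, so that a reader can judge what the package's tests do and
do not demonstrate.

## The registration model

Everything rests on rigid-body registration. Let $p_i$ be points measured on
the real object (the physical bone) and $p_i'$ the corresponding points of
the virtual model. The overlay seeks the rotation $R$ and translation $t$
minimising

$$J = \tfrac{1}{2}\sum_{i=1}^n \left| p_i - (R\,p_i' + t) \right|^2 ,$$

with per-pair residuals $e_i = p_i - (R\,p_i' + t)$. The convention is fixed
throughout: *fixed* = real-object points $p$, *moving* = model points $p'$,
and the estimated transform maps model coordinates onto physical
coordinates. All lengths are millimetres; angles are reported in degrees.

`paired_point_register()` solves this minimisation in closed form by SVD of
the centred cross-covariance (the Kabsch solution), with the standard sign
correction of the smallest singular vector so a proper rotation
($\det R = +1$) is returned even for planar point sets. Collinear
configurations leave a rotation unobservable and raise a degeneracy error
rather than returning an arbitrary answer. The tests cross-check this solver
against an independently implemented quaternion (Horn) absolute-orientation
solver.

`icp_register()` implements point-to-point iterative closest point: under
the current transform each moving point is paired with its Euclidean-nearest
fixed point, the closed-form solver is re-run on those pairs, and the loop
repeats until the RMS correspondence distance changes by less than `tol_mm`
(default $10^{-4}$ mm) or `max_iter` (default 100) is reached. With this
cost definition the recorded `cost_history` is mathematically
non-increasing, which the tests verify on randomised trials. A `trim`
option can drop the worst fraction of correspondences each iteration; it is
off by default because the monotonicity guarantee holds only for the
untrimmed cost, and because the default error models keep outlier fractions
moderate. No random restarts are performed: a poor initialisation is the
caller's responsibility, which is precisely what the coarse stage is for.

`two_stage_register()` chains the two: *point matching* — 3 to 7 labelled
landmark pairs solved in closed form ("the coarse transformation matrix") —
followed by *surface matching* — ICP between dense surface clouds seeded by
the coarse result. More than 7 landmark pairs is rejected as outside the
procedure's definition; fewer than 3 shared labels is a degeneracy, with the
unmatched labels listed. The conventional-navigation workflow's "five-point
matching and surface matching" is this same code path with exactly five
landmarks.

Registration quality is reported as FRE (fiducial registration error, the
RMS landmark residual, equal to $\sqrt{2J/n}$) and TRE (target registration
error, the mean Euclidean deviation of clinically relevant target points
under estimated versus true transforms). TRE is the figure of merit:
a registration can fit its own fiducials well and still displace the
osteotomy site.

## Featured points

Commercial trackers extract proprietary image features; osteonav substitutes
a defined, reproducible operator with the same role. Vertices are scored by
angle-defect discrete curvature ($2\pi$ minus the sum of incident triangle
angles — high at sharp, contour-rich geometry), the top quartile by score
(extended through ties, and never fewer than the requested $n$) forms a
candidate pool, and greedy farthest-point selection spreads $n$ points
across that pool. Scores and distances are rounded at $10^{-9}$ before
ranking with ties broken by vertex index, which makes the selection exactly
equivariant under rigid motion of the mesh — a property the tests check —
and fully deterministic. The `seed` argument is retained in the signature
for API stability but the default ranking never consults the RNG.

The default feature count in the trial harness is $n = 200$, matching the
marker capacity of the tracking hardware the workflow is built around; it is
an interpretive default, not a measured property. A practical note
uncovered by the greedy construction: on a sphere, greedy farthest-point
selection of 4 points yields two antipodal plus two orthogonal points
(minimum pairwise distance $\sqrt{2}r$), not the inscribed regular
tetrahedron ($1.633r$); no selection of 4 vertices of a coarse uniform
sphere mesh can reach 90% of the tetrahedron spacing either, because any
four icosahedron vertices contain an adjacent pair. The spread test is
therefore phrased against the brute-force optimal vertex subset, which the
greedy selection matches on the meshes tested.

## Cutting planes and the accuracy metric

The coordinate convention is fixed: $Z$ = proximal shaft axis, $X$ =
medial–lateral, $Y$ = anterior–posterior. The planned *main* (vertical) cut
has its normal tilted `main_tilt_deg` (default 15°) from the shaft axis
about the hinge direction (default $+Y$); the *side* (horizontal) cut is
tilted a further `side_angle_deg` (default 70°) about the same hinge, so the
two planes meet at exactly that angle along a hinge line. Plane origins snap
to the mesh surface point nearest their nominal medial-cortex location. The
main cut sits at 80% of the bone's height (`main_height_frac`), with the
side cut 12 mm distal — proximal-tibia geometry at sawbone scale.

Accuracy is the angle between planned and achieved cutting planes after
projecting both normals into the XZ or YZ coordinate plane — the two tilt
components of the cut (sagittal/coronal under the convention above). Angles
are folded to $[0, 90]°$ with the absolute dot product, since a cutting
plane has no preferred normal sign, and are computed as
$\operatorname{atan2}(|u \times v|, |u \cdot v|)$ rather than
$\arccos$: the arccos form loses half the significant digits near 0°,
and the zero-noise tests require angle errors at the $10^{-9}$ degree
level. A normal perpendicular to the projection plane has no meaningful
projected direction; that case raises an explicit degeneracy error, never a
silent 0. Summaries use linear-interpolation quartiles (R `quantile`
type 7), stated here because box-plot reproducibility depends on the
convention.

## The simulated sawbone trial

`simulate_trial()` models one bench trial. A ground-truth pose $T_{true}$ is
drawn (rotations up to 30°, translations up to 50 mm per axis — tabletop
scale); the modality's measurements are synthesised from it; registration
produces $T_{est}$; and the achieved plane is the planned plane mapped
through $T_{est}^{-1} \circ T_{true}$, plus a direct execution-tilt noise.
This models a surgeon cutting exactly on the displayed virtual plane, so the
angle metric isolates navigation error plus hand/jig execution error; it is
a modelling assumption, not a claim about how achieved cuts are measured on
physical sawbones. TRE is evaluated at the two plane origins. In the
zero-noise limit every modality reproduces the plan exactly (to solver
tolerance), which the tests assert.

The three modality models:

* **metal** — a jig physically seated on the bone involves no registration:
  $T_{est} = T_{true}$, and only seating/execution tilt noise applies.
* **conventional** — five-point matching plus surface matching on a scanned
  surface cloud with modest noise.
* **ar** (tracker-less) — paired-feature coarse registration (200 featured
  points matched with feature-localisation noise) refined by ICP on a
  noisier, partial, outlier-contaminated view.

The scanned cloud in each trial is the transformed image of the same
underlying surface sample, then perturbed (Gaussian noise, a half-space
partial-view cut, uniform outliers in the doubled bounding box). Using the
same underlying sample makes the zero-noise limit exact and keeps the
perturbation parameters the only source of task difficulty; with noise
present, correspondences still have to be estimated and the usual ICP biases
appear.

**The default noise magnitudes are illustrative.** The bench trial this
harness mirrors reports outcomes per modality, not error-source magnitudes,
so any numeric calibration would present invented numbers as ground truth.
The defaults (`default_modality_models()`: metal — tilt 0.5° only;
conventional — landmark σ 2 mm, surface σ 1 mm, 2% outliers, 90% overlap;
ar — feature σ 4 mm, surface σ 2.5 mm, 15% outliers, 65% overlap; tilt 0.5°
for all) were chosen once to reproduce the qualitative accuracy ordering
(metal most accurate, tracker-less AR least) with clear separation, and the
tests check exactly that ordering property — not any particular degree
value. Because the execution-tilt noise is common to all arms and the
registration errors add on top, the ordering is structural rather than
finely tuned.

`run_experiment()` assembles the cohort: by default 10 synthetic patients ×
3 modalities × 1 replicate = 30 simulated sawbones, with every trial seeded
from the experiment seed and a provenance block (seed, config hash, package
version) embedded in the result.

## The synthetic tibia

`make_synthetic_tibia()` produces a closed triangulated surface: a tube
along $+Z$ (default radius 15 mm, length 120 mm) whose radius ramps by a
smoothstep over the proximal 20% to `flare` times the shaft radius (default
1.8 — the condylar widening), modulated by a low-order harmonic bump field
(3 circumferential × 2 axial modes, seeded coefficients, rescaled so its
peak equals `bump_amplitude_mm`, default 1.2 mm) that individualises each
"patient". Parameters that would collapse the radial field are rejected as
self-intersecting. The default grid (40 axial × 32 circumferential, 1282
vertices) keeps a full 20-experiment Monte-Carlo run in the low minutes on
one CPU; these problem sizes (250-point surface clouds, 500-point fixed
clouds, 200 features) are the package's defaults and the sizes at which the
reported test properties were established.

What the generator does *not* emulate: real cortical geometry (tuberosity,
plateau asymmetry), scanner-specific noise structure (correlated error,
holes), soft-tissue occlusion, and any biomechanics. Passing tests
demonstrate the correctness and internal consistency of the algorithms and
the claimed qualitative behaviours under this controlled generative model —
not clinical accuracy on real bones.

## Numerical choices

* Rotation validity: $R^\top R = I$ and $\det R = +1$ to $10^{-9}$
  ($10^{-8}$ after composition chains); reflections are rejected, not
  repaired.
* Geodesic rotation angles use
  $\theta = 2\arcsin(\lVert R_a^\top R_b - I\rVert_F / 2\sqrt{2})$, exact
  for rotations and accurate near 0° where arccos-of-trace is not.
* Nearest-neighbour search is vectorised brute force, chunked to bound
  memory; at the package's problem sizes (hundreds to a few thousand
  points) this is faster in practice than building spatial indices per ICP
  iteration.
* STL vertex welding merges bitwise-identical coordinates only — exact
  duplicates from the facet-soup format — never nearby-but-distinct
  vertices. Mesh writers emit ASCII with 10 significant digits, so
  round-trips hold to well under $10^{-6}$ mm at anatomical scales.
* Degenerate inputs (collinear registrations, zero-area meshes, zero-norm
  projections, near-parallel plane pairs under 5°) raise typed errors; the
  CLI maps usage errors to exit 1 and degeneracies to exit 2.

## Known limitations

Point-to-point ICP converges locally; initialisation beyond the coarse
stage's basin is not detected. No scale estimation, robust kernels or
globally optimal search is provided. Registration is single-shot: streaming
or continuously re-estimated tracking is out of scope. Landmark noise
affects the coarse stage but barely moves the final two-stage result (the
surface stage re-estimates the pose from hundreds of points), so the final
accuracy is governed by surface noise — visible in the monotonicity tests,
and itself a clean statement of why the two-stage procedure helps.
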