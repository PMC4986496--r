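---
title: "Reconstructing delivered dose from daily MV CT: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing delivered dose from daily MV CT: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxcalc)
```

## The problem

Helically delivered prostate radiotherapy is planned once, on a kilovoltage
(kV) CT, but delivered in 20--37 daily fractions.  Before each fraction a
megavoltage (MV) CT is acquired on the treatment unit and matched to the
planning scan; the couch shifts (x, y, z) and the roll applied at that
matching are recorded.  Because the anatomy -- above all the rectum --
differs every day, the dose actually delivered differs from the plan.
`voxcalc` reconstructs the per-fraction dose on the daily MV anatomy,
auto-segments the rectum on each MV scan, and accumulates rectal
dose-surface maps (DSMs) and generalized equivalent uniform dose (gEUD)
across the course, entirely non-interactively so that hundreds of patients
can be processed in batch.

## Composite kV/MV ray tracing

The MV scan circle is 38.6 cm across -- frequently smaller than the
patient.  Anatomy outside the circle still attenuates the beam, so the
water-equivalent path length (WEPL) to a point is computed as the sum of
two Siddon-style traces: one through the MV image, and one through the kV
image after it has been (i) resampled onto the MV frame using the recorded
shifts and roll and (ii) masked to $-1000$ HU (zero density) strictly
inside the scan circle.  No composite image is ever built; the composite
is only used as a test oracle.  Voxel values are treated as piecewise
constant and the traversal accumulates exact voxel-boundary segment
lengths, so WEPL is additive over ray subdivision and invariant under
direction reversal to machine precision.

Conventions fixed here (the inputs do not dictate them):

* Patient coordinates are DICOM LPS-like: x toward patient left, y
  posterior, z superior.  Voxel values sit at voxel centres.
* Positive roll moves the patient's left side anteriorly.  The kV volume
  is compensated by rotating it by $-\mathrm{roll}$ about the isocentre
  axis (bilinear in-plane interpolation, $-1000$ HU fill); the dose engine
  mirrors the treatment machine by adding the roll to every control
  point's gantry angle.
* Circle membership is strict (`<`); boundary voxels stay unmasked.
* kV slices map to MV planes by nearest-slice lookup after the SI shift;
  with kV slices at 3 mm or finer against the 6-mm MV spacing,
  interpolation along z would change WEPL by well under the in-plane
  discretisation error.

## HU calibration

Relative electron density is modelled as linear in HU,
$\mathrm{HU} = \mathrm{offset} + \mathrm{slope}\,(\rho_e - 1)$,
clamped at $\rho_e \ge 0$.  The offset is the HU of water; the standard kV
relation is offset 0, slope 1000.  MV calibrations drift over the life of
the machine, so calibration lines carry a machine id and a validity date
and are selected by the image date (piecewise constant, right-continuous);
the bundled table covers two machines across three calibration eras.
Calibration lines are fitted to density-insert phantom measurements by
ordinary least squares with HU as the response, because the measurement
noise lives in HU; the monthly QA check fails when the water insert
deviates from the calibrated value by 30 HU or more.  The tabulated
uncertainty columns are stored but deliberately not propagated into dose.

## The dose engine

A helical plan is a sinogram: one row of leaf-open fractions per
projection, 51 projections per rotation, with couch travel `pitch` per
rotation.  Each projection is expanded into seven control points uniformly
spanning its gantry arc and couch travel (the couch is interpolated along
with the angle -- an interpretation, documented here, since the
subprojection rule does not pin it down), each carrying 1/7 of the open
time.

The per-beamlet dose model is a documented simplification that is
interface-compatible with a full engine but makes no claim of clinical
accuracy:

$$D = \mathrm{OF} \cdot t \cdot e^{-\mu_\mathrm{eff}\, d_w} \cdot
      \left(\frac{\mathrm{SAD}}{r}\right)^2 \cdot
      e^{-\ell^2 / 2\sigma^2},$$

with open fraction $t$, water-equivalent depth $d_w$ from the dual trace,
source distance $r$, lateral offset $\ell$ at the isocentre plane, and
$\sigma$ set so the lateral FWHM equals one 6.25-mm leaf width.  Defaults
($\mu_\mathrm{eff} = 0.05\,\mathrm{cm}^{-1}$, SAD 850 mm, 64 leaves) are
standard helical-tomotherapy geometry; `fan_extent` is read as the SI jaw
width at the isocentre (default 25 mm) and gates which control points
reach a grid point.  There is no scatter kernel, no leaf latency, no
couch attenuation.  Dose is linear in the sinogram by construction, and
roll-offset delivery on a cylindrically symmetric phantom reproduces the
rotated roll-free dose to better than 2% of the maximum (the residual is
bilinear-interpolation error of the comparison, not engine asymmetry --
evaluating the rolled delivery directly at rotated points agrees to
better than 0.1%).

The dose grid derives from the MV image: in-plane spacing is the MV pixel
size times a power-of-two factor (factor 2 of a 0.76-mm pixel gives the
~1.5-mm production resolution), and the SI spacing is the 6-mm MV slice
interval.  Agreement between dose cubes is scored with a 3%/3-mm box
index (a point passes when some reference voxel within the 3-mm box is
within 3% of the global reference maximum), excluding points shallower
than 5 mm inside the body.

## Rectum segmentation

Each MV slice is segmented with a two-phase piecewise-constant Chan--Vese
level set seeded from the planning contour mapped through the fraction's
registration.  Numerical design, in the order the pixels see it:

1. gas below $-300$ HU is remapped to the rectal-material HU (+20), then
   intensities are windowed to $[-250, 250]$ HU and rescaled to $[0, 1]$;
2. the working region is cropped to the planning contour's bounding box
   plus an 18-mm margin (keeps the two-phase model local: rectum against
   mesorectal fat, not the whole pelvis);
3. two binomial smoothing passes condition the noisy MV data;
4. the level set runs as a semi-implicit Gauss--Seidel descent with a
   global delta (every pixel feels the region forces, so weakly
   contrasted connected tissue can change phase), curvature coefficients
   regularised with $\eta = 1$ so they stay bounded on plateaus, phi
   bounded in $[-1, 1]$, step 4, at most 300 sweeps, converged when the
   zero-level mask is static and the update has settled;
5. the mask returns to a polygon via marching squares at the 0.5 level,
   keeping the ring that contains the seed centroid.

The boundary-length weight is small ($\mu = 0.05$) because at 2.4-mm MV
resolution a rectum is only ~5 pixels in radius and curvature flow at
conventional weights visibly erodes it.  The outside region weight is
$\lambda_2 = 2$: the background of the crop is a mixture of fat and
muscle, which biases the implicit threshold inward at this resolution,
and the asymmetric weight compensates.  Both were tuned on the synthetic
phantom (the original tool was tuned on clinical training data that is
not available here) and are configurable.

Two corrections follow, mirroring clinical failure modes:

* **Inferior replacement.**  At the inferior rectum the muscle complex is
  indistinguishable from rectal content and the level set overcontours.
  A slice is "unexpectedly large" when its area exceeds 1.5x the matching
  planning slice (the planning contour is the only per-slice reference
  available); all slices from the inferior end up to the most superior
  flagged slice revert to the planning contours.
* **Smoothed-surface replacement.**  Contours are resampled to 36 radial
  rays about their own centroids; per-ray radii and the centroid track
  are smoothed across slices by a leave-one-out moving linear fit over 5
  slices (linear, not quadratic: one-sided extrapolation at the stack
  ends amplifies radius noise severalfold under higher degrees; at the
  ends the fit degrades to a window mean).  A slice whose mean radial
  deviation plus centroid displacement exceeds 3 mm is replaced by the
  smoothed contour.  Radii are measured about each slice's own centroid
  so centroid drift cannot masquerade as shape error.  The operation is
  idempotent at its tolerance.

The conformity index is Jaccard, $|A \cap B| / |A \cup B|$ -- stated
prominently because a Dice-based definition would report systematically
higher numbers.

## Dose-surface maps and gEUD

Each rectal contour is treated as a cylinder cross-section, cut where the
vertical line through the centroid crosses the posterior edge, and
unfolded into `n_theta` (default 21; the sampling count is a convention
of this toolkit) dose samples equally spaced by arc length, proceeding
patient-left first.  Cutting posterior of the centroid, rather than at
the most posterior boundary point, keeps the central column on the middle
of the anterior wall and avoids large slice-to-slice jumps.  `cut_point`
defaults to "posterior = $-y$" (the y-up display convention of its
examples); the DSM builder passes "posterior = $+y$" since it works in
LPS coordinates.

Fraction rows are reported at the slice position minus the fraction's SI
shift, so all fractions share the planning SI axis.  Accumulation lives
on a fixed 6-mm lattice spanning the rectum: where a fraction's short MV
scan has no coverage, the per-fraction planning DSM row is added instead
(a caller holding a full-course planning DSM divides it by the planned
fraction count first).  Fixing `n_theta` normalises away day-to-day
circumference changes; the map stores physical dose at the normalised
angular coordinate, and the per-row circumference is kept as metadata.

gEUD is the Niemierko power mean $(\mathrm{mean}\, d^a)^{1/a}$.  The
volume-effect parameter $a$ is a required choice; the command-line tools
default to $a = 8$ for rectum as a convention, not a measured value.
For $a < 0$ a zero dose anywhere drives the power mean to its limit 0,
which is returned with a warning.

## The synthetic phantoms

The generators exist so the whole pipeline runs and is tested without any
clinical data; their defaults are the study conditions of every test.

The **density-insert phantom** is a 300-mm water cylinder with two rings
of removable plugs (8 + 12, 12.5-mm radius).  HU are synthesised through
the forward calibration model, so image and ground-truth density map are
consistent by construction; the plug-removal experiment empties the inner
ring, then all holes.

The **pelvis phantom** is a 400 x 300 mm soft-tissue ellipse -- wider
than the 38.6-cm scan circle, so the composite kV/MV path is always
exercised -- containing femoral heads, a prostate sphere, and a rectum
tube (nominal radius 12 mm, smoothly varying along z) surrounded by
22 mm of mesorectal fat.  Per fraction: setup shifts are drawn at 3 mm
(SI 2 mm) 1-sd, roll at 0.5 degrees, and the rectum radius is jittered at
1.5 mm -- magnitudes typical of daily image-guided prostate treatment;
MV noise is 30 HU (MV images are genuinely this noisy), kV noise 5 HU.
Three daily degradations emulate exactly the failure modes the
segmentation corrections exist for: gas pockets (25% of fractions),
dark reconstruction streaks across the rectum (12% of slices), and an
inferior zone where the rectal wall is invisible because the surrounding
muscle has the same HU and the only visible edge is the displaced fat
boundary.  The ground truth is the generator's rectum tube; the streaks
are image-only and the invisible inferior wall is still the true wall,
which is what makes the corrections measurably useful.

What the phantom does **not** emulate: MV scatter and ring artifacts,
beam hardening, genuine deformable anatomy (only radius jitter), and
observer variability in the "ground truth".  Passing tests therefore
demonstrate the pipeline's correctness and its corrections' value under
controlled conditions, not clinical segmentation accuracy.

## Batch orchestration

Datasets live in a fixed hierarchy
(`patients/<id>/planning/{ct,struct}`, `patients/<id>/fractions/<NNN>/mv`)
with the plan and calibration table at the root.  One job is planned per
usable fraction per stage (dose, segment, dsm); fractions whose MV
headers carry the skip tag are marked skipped, jobs with existing outputs
are marked done and not re-queued.  Jobs are independent, failures are
isolated per job, outputs are written atomically (temp file + rename),
and merged results are identical for any worker count.  Merging
accumulates the per-fraction DSMs with planning padding and writes the
accumulated DSM plus a per-patient planned/delivered gEUD summary.  The
cluster/grid scale of the original deployment is out of scope; the
orchestration contract (splitting, skipping, merging, determinism) is
what is reimplemented and tested.

## Problem sizes used by the test-suite

The shipped tests run the pelvis phantom at 160 x 160 x 10 MV voxels
(2.4-mm pixels) for segmentation studies -- 20 scans for the headline
conformity figure -- and a compact 64--96 pixel geometry for the
end-to-end batch runs; dose cubes for the roll-rotation and plug-removal
studies use the cylindrical phantom at 128 x 128 with 2--3 rotations of
the geometric plan.  These sizes were chosen so the full suite completes
in minutes while every claim is still exercised at full pipeline depth;
all of them scale up by changing the spec objects, none of the algorithms
care.

## Known limitations

* The beamlet model is deliberately simple; absolute dose agreement with
  a clinical engine is out of scope, and only relative/structural claims
  (linearity, rotation equivariance, plug-removal direction) are tested.
* The Chan--Vese defaults are tuned to the phantom's contrast structure;
  clinical MV data would need retuning on real training contours.
* DSM accumulation assumes the rectum near the prostate does not rotate
  day to day; voxel-level deformable accumulation is explicitly not
  attempted.
* DICOM support covers the toolkit's own objects (explicit VR little
  endian, the CT/RTSTRUCT/RTDOSE attributes listed in the I/O module),
  not the full standard.
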