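---
title: "3D fluence-calculation QA: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D fluence-calculation QA: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluqa)
```

## The problem

A VMAT delivery modulates MLC leaves, dose rate and gantry speed
continuously while the gantry rotates.  Patient-specific QA must answer:
*was the plan delivered as intended?*  Comparing logged machine parameters
value-by-value misses the dosimetric consequence of combined small errors;
full dose recalculation is heavy and entangles QA with the dose engine; 2D
composite fluence maps collapse the gantry angle and are therefore blind to
gantry errors.  This package implements the middle road: reconstruct the
**primary fluence in air** as a 3D volume from both the DICOM-RT plan and
the trajectory log, and compare the two volumes voxel by voxel.

## The model and its assumptions

Every delivery is reduced to a sequence of *segments*, each carrying a mean
machine state (couch/gantry/collimator angles, jaw and leaf positions), an
MU increment, and an effective source position.  A segment contributes to a
voxel at $\mathbf r$

$$\Delta I(\mathbf r) = F(u, w)\, M(u, w)\, \Delta MU \,
  \frac{SAD^2}{|\mathbf r - \mathbf s|^2}$$

with $(u, w)$ the divergent projection of $\mathbf r$ onto the portal plane
after the inverse couch/gantry rotation and the in-plane collimator
rotation, $M$ the binary jaw + MLC aperture mask, and $F$ a pluggable in-air
profile (flat by default — no profile measurement is assumed).

Assumptions, deliberate and load-bearing:

* **No attenuation, no scatter, no secondary source.**  The volume is "dose
  in air" from a point source.  This keeps the computation exactly
  reproducible from machine parameters and fast, at the cost of not being a
  dose.
* **Binary mask.**  Physically the penumbra makes the mask a function of
  aperture size; the binary approximation under-penalises very small
  apertures.  The mask is sampled at voxel centres with half-open intervals
  `[lower, upper)` on every edge so boundary ties resolve deterministically.
* **Point-sampled voxels, no anti-aliasing.**  First-order ray tracing; the
  angular and spatial sampling below are chosen so residual aliasing stays
  far below the 3% decision threshold.
* **Isocentric geometry.**  Couch translations and non-isocentric setups are
  out of scope; leaf/jaw positions are interpreted at the isocenter plane
  (DICOM semantics).

Coordinate conventions (the file formats do not fix a room frame, so the
package does): origin at the isocenter; at all angles zero, +y is the beam
direction, +x the X-jaw/MLC travel direction, +w and +z the Y-jaw direction;
the gantry rotates about z, the couch about y, the collimator in the portal
plane.  The source sits at $(0, -SAD, 0)$ at gantry 0 and at $(0, SAD, 0)$
at gantry 180.  Angles are stored in the DICOM `[0, 360)` convention and
interpolated on the signed `(-180, 180]` representation with shortest-arc
differences, because VMAT arcs routinely cross the 0/360 seam.

## Resampling: plans up, logs down

Plans specify sparse control points (typically 4° of gantry travel apart)
between which the machine interpolates every axis linearly.  Sampling a full
arc at 4° aliases badly, so control-point intervals are subdivided until
consecutive segment centres differ by at most **1°** (the package default;
the alias-reduction ordering is asserted in the test suite by comparing 1°
and 4° volumes against a 0.5° reference).  Each sub-segment carries the
arithmetic mean of its end-point states and an MU share proportional to its
span, and its source is the mean of the end-point source positions — the
mean of two points on the SAD sphere, slightly inside it, which is the
correct first-order average of the moving source.

Trajectory logs go the other way: 20 ms records (≈ 0.048–0.06° of gantry
travel each) are far denser than needed to catch gross errors, so
consecutive groups of **16** records merge into one segment — circular-mean
angles, mean jaw/leaf positions, summed MU.  A trailing partial group is
merged the same way so that total MU is conserved for any factor.  The MU
increment of a group is the cumulative-MU difference across it; the MU
delivered before the very first record is unknowable from the log and is
not invented.

At these settings the plan-path and log-path volumes of the same delivery
agree to well under 1% of the maximum (the two paths converge to ≈ 0.1–0.35%
of max when both are refined), comfortably below the 3% decision threshold.

## The QA decision

Both tests normalise to the **maximum of the reference (plan) volume** and
evaluate only voxels whose reference value reaches 10% of that maximum —
excluded voxels appear in neither numerator nor denominator, which is the
only reading that keeps "excluded from analysis" meaningful.

* **Intensity difference:** a voxel fails when |delivered − planned| ≥ 3% of
  the reference maximum.
* **3D gamma (3%/3 mm):** global gamma with the evaluated volume sampled by
  trilinear interpolation on a ⅓-voxel lattice within a search radius of
  3 × DTA.  Restricting the search radius can only affect gamma values that
  are already above 3, never the pass/fail decision at γ = 1; γ = 1 exactly
  counts as a pass.  An exhaustive whole-grid oracle in the test suite
  agrees with the production search voxel-by-voxel.
* **Action level:** gamma failing rate > 5% ⇒ verdict "investigate".

The defaults (3%, 3 mm, 10% cutoff, 5% action level) are the clinically
conventional operating point for this kind of comparison and are all
adjustable through `test_criteria()`.

The 2D baseline (`composite_2d_fluence()`) accumulates ΔMU × aperture on the
portal plane with gantry and couch forced to zero and no divergence scaling.
Its plan segmentation is one segment per control-point interval —
deliberately *not* gantry-driven — so that the map is bit-identical under
any pure gantry perturbation.  That blindness is the point of comparison:
the 3D method sees those errors, the 2D method cannot.

## Error injection and sensitivity

Five error families with TG-142-style tolerances: gantry 1°, MU 1 MU, jaw
1 mm, collimator 1° (all uniform), MLC 2 mm (gaussian).  "Within tolerance"
draws magnitudes uniformly in `[0, tol]`; "outside" in `[tol, 2 tol]` (MLC
2–3 mm).  Signs are random — the tolerances bound magnitudes, not
directions.  The gaussian family uses σ = high/2 with redraws outside the
magnitude window (the distribution family is conventional; the σ is a
package choice).  MLC shifts touch only leaves that can contribute —
open pairs overlapping the Y-jaw window — since parked or closed leaves
outside the field cannot change the fluence; a shift that would cross the
banks collapses the pair to closed.  MU errors perturb per-interval MU and
rebuild the cumulative weights, keeping them monotone.  Errors are injected
into *plans* (not logs), so one unmodified reference delivery serves every
error scenario.  Injection is bit-reproducible given spec + seed.

`sensitivity_sweep()` normalises error magnitudes to the family tolerance
(100% = at tolerance), injects `n_reps` realisations per level, and records
mean failing rates for the 3D and 2D methods against the unmodified plan's
fluences.  Two structural facts the suite asserts: mean F_I is
non-decreasing in the level, and F_gamma ≤ F_I at matched criteria (a voxel
that passes the difference test passes gamma at zero search distance).

## What the synthetic generator does and does not emulate

`generate_synthetic_plan()` produces multi-arc plans with evenly spaced
meterset weights, static jaws, alternating arc directions chained
end-to-start, and four leaf patterns: `open`, `sliding-window` (a gap of
configurable width sweeping the field — narrow gaps give highly modulated
deliveries), `random-leaf` (seeded bounded random walk), and
`closed-junction` (closed leaf pairs left inside the jaw field, the classic
planning-system export defect).  `generate_matched_log()` traces the plan's
linear inter-control-point trajectories at 20 ms with constant dose rate per
beam, optional zero-mean per-axis tracking noise, and optional truncation
(`keep_fraction`) to emulate interrupted deliveries.

What it does **not** emulate: optimizer-derived clinical modulation,
variable dose rate and gantry speed profiles, jaw tracking, beam holds, or
anatomy-conformal apertures.  Passing tests on these fixtures therefore
demonstrate the *mechanics* of the method — geometry, resampling, masks,
statistics — not clinical failure-rate magnitudes; published clinical
failing rates come from real multi-target plans whose modulation is far
richer than any fixture here.  In particular, on desk-scale fixtures a
within-tolerance gantry error moves fluence by at most ~0.07 cm at 4 cm
radius, so the 3%/3 mm gamma (which forgives sub-DTA shifts) stays at zero
even while the intensity-difference test already fires; with clinical
targets both rise.

## Numerical choices

* The inverse-square factor uses the squared distance $|\mathbf r -
  \mathbf s|^2$; fluence in air must fall off as the inverse square, and the
  test suite checks R² ≥ 0.999 against $SAD^2/(SAD+y)^2$ along the axis.
* Accumulation is double precision in deterministic time/control-point
  order: volumes are bit-reproducible, MU linearity and beam superposition
  hold to machine precision.
* "Behind source" guard at y ≤ −SAD + 10⁻⁶ cm; degenerate voxel-at-source
  geometry errors out rather than returning infinities.
* Leaf-pair lookup uses the closed-form Millennium-120 index (half-cm bins
  folded onto 60 pairs); a boundary-table lookup serves as the test oracle
  and as the path for custom layouts.
* Reconstruction grids are cubes centred on the isocenter: maximal jaw
  half-opening + 1 cm margin, snapped up to whole 3 mm voxels (minimum 3
  per axis for degenerate jaw settings).
* The test suite and the acceptance script run at reduced problem sizes
  chosen for coverage per unit time: 20³–40³ grids, 19–91 control points,
  1–2 arcs, 10 repetitions per sweep level.  These sizes are stated here as
  the package's own verification conditions.

## File formats

DICOM RT Plans are read and written with a minimal explicit-VR
little-endian implementation covering the RT Plan module (beams, MLC
boundaries, control points, fraction-group metersets), including the sparse
control-point rule — unchanged parameters are inherited from the last
control point that specified them.  Delivery logs use a small documented
binary layout (header + fixed 130-double records; see `R/log_io.R`)
designed to mirror trajectory-log content without the proprietary vendor
format; `read_log()` accepts an adapter function for plugging in a vendor
reader.  Volumes export to NRRD (raw little-endian doubles) with spacing
and isocenter-relative origin in the header.

## Known limitations

* No attenuation/scatter/transmission/tongue-and-groove modelling — by
  design; the output is not a dose and must not be read as one.
* Binary mask under-represents small-aperture penumbra effects.
* Jaw tracking during arcs and couch motion mid-beam are unsupported.
* Log-derived QA inherits the log's honesty: a machine that logs positions
  it did not achieve will pass.  Independent machine QA remains necessary.
* Only the bundled log format and explicit-VR-LE DICOM are parsed natively.
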