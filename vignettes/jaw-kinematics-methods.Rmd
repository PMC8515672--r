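---
title: "Methods: six-degree-of-freedom jaw kinematics, dynamic occlusion and EMG synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: six-degree-of-freedom jaw kinematics, dynamic occlusion and EMG synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawtrack)
```

## Overview

`jawtrack` reconstructs mandibular motion relative to the maxilla from two
measurements that live in different coordinate systems: per-frame 3D marker
positions from a stereo motion-capture system, and micro-CT derived surface
anatomy carrying the same markers plus named landmarks. This vignette
documents the model, the parameters that matter, the synthetic data used for
validation, the numerical choices, and the known limits.

## The rigid model and its assumptions

The mandible is treated as a rigid body; the four markers are assumed
rigidly fixed to it, and the head (hence the maxilla) is assumed rigidly
restrained for the duration of a recording. Under these assumptions the
whole kinematic problem reduces to two instances of one primitive,
point-set rigid registration:

1. **Per-frame tracking.** For each capture frame, `fit_rigid()` finds the
   rotation $R \in SO(3)$ and translation $t$ minimizing
   $\sum_i \lVert R a_i + t - b_i\rVert^2$ between the marker reference
   configuration $a_i$ (CT frame) and the observed markers $b_i$. The
   solution is the classical Kabsch / orthogonal-Procrustes construction:
   centroid alignment followed by an SVD of the $3\times 3$ cross-covariance,
   with the smallest singular direction's sign flipped whenever the raw
   polar factor would be a reflection. A reflection is never a physical jaw
   pose, so the determinant correction is unconditional.
2. **Static maxilla registration.** One acquisition is taken with the jaw
   closed into the intercuspal position and consolidated with the cranium so
   mandible, markers and maxilla momentarily form a single rigid unit. The
   same fit then yields the single CT-to-capture pose that places the
   maxilla (and with it the whole cranium) in capture coordinates.

Composing a frame's mandible pose with the inverse static pose expresses the
motion in a maxilla-fixed frame. Because both registrations share the CT
frame, the output is axis-aligned to anatomical axes — +X anterior, +Y
animal-left, +Z superior (a right-handed convention chosen to make the
sagittal/frontal/occlusal plane projections orthographic coordinate drops) —
and is provably invariant to how the capture system was oriented: applying
an arbitrary rigid change of capture coordinates to both the dynamic frames
and the static frame cancels exactly. The test suite asserts this to
$10^{-9}$ mm.

Three or more non-collinear markers are mathematically sufficient; four are
the configured default because the redundancy conditions the fit and allows
one marker to drop out (occlusion from a camera) without losing the frame.
Frames with fewer than three usable markers become explicit gaps; they are
never silently interpolated (an optional fill uses linear interpolation on
translations and spherical-linear interpolation on quaternions).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| frame rate | 200 | Hz | capture rate of the reference system; 5 ms per frame |
| marker count | 4 | — | redundancy over the 3-marker minimum |
| degeneracy threshold | 1e-6 | mm | smallest singular value of the centred reference below which the marker set is declared collinear |
| orthonormality tolerance | 1e-9 | — | validity bound on $R^\top R - I$ and $\det R - 1$ |
| contact threshold | 0.05 | mm | occlusal contact distance; mesh-resolution scale of the toy dentition |
| phase prominence | 10% of gape | — | minimum prominence for a vertical maximum to delimit a cycle |
| EMG high-pass | 100 | Hz | conventional cutoff; zero-phase 4th-order Butterworth |
| EMG envelope window | 10 | ms | moving-RMS length |
| burst threshold | mean + 3 SD | — | primary threshold on the baseline envelope |
| burst peak validation | mean + 6 SD | — | secondary threshold a burst's peak must reach |
| burst persistence | 10 | ms | minimum duration; also the merge gap |

## What the synthetic generator emulates

`simulate_jaw_motion()` produces the ground truth every stage is tested
against. The motion model is a C1-periodic composition of:

* a **pitch** rotation about the intercondylar axis carrying 75% of the
  vertical opening (the rest is condylar translation), with the opening
  depth following piecewise half-cosine segments — opening to maximum gape,
  closing to the contact depth, then a shallow occlusal ramp back to the
  intercuspal position;
* two **condylar advance** curves (beta-shaped bumps, zero slope at the
  cycle boundaries so there is no jerk at maximum closing): the working-side
  condyle peaks a third of the way through the pre-contact cycle and
  reverses mid-opening, the balancing-side condyle peaks at maximum opening
  — their half-difference becomes yaw, their mean a translation;
* a posterior dip peaking exactly at contact onset (making the most
  posterior position coincide with the start of the occlusal phase) followed
  by anterior drift through occlusion; and
* a lateral deviation bump toward the working side.

Defaults: 10 cycles of 150 ms (30 frames per cycle at 200 Hz), 2 mm gape,
1.5 mm antero-posterior excursion scale, 0.3 mm added lateral deviation,
occlusal fraction 0.1. Gape and excursion magnitudes are not constrained by
any measurement; they are plausible murine values and are configurable.

`synth_dentition()` builds watertight toy meshes: the maxilla carries an
antero-posteriorly elongated fossa (a central groove, 0.1 mm deep, flat
ceiling) and the mandible a conical molar cusp (0.15 mm tall, 0.3 mm base
radius) whose tip touches the groove ceiling exactly at the intercuspal
pose. The geometry is engineered so that, throughout the contact regime, the
analytic vertical gap of the motion model *is* the mesh clearance (the cusp
tip is a mesh vertex under a flat triangulated ceiling), which is what makes
contact-onset recovery testable to the exact frame. The cusp radius is kept
well inside the groove half-width (0.45 mm) so lateral and yaw excursions
never graze the fossa walls. An incisor ridge pair with generous static
clearance completes the dentition; condylar landmarks are points in the CT
frame, not on the mesh.

`synth_emg()` gates 100-Hz-high-passed Gaussian activity with the truth
windows: digastric across the opening phase; working-side masseter from one
tenth of a cycle before contact onset; balancing-side masseter from contact
onset; both masseters off at maximum closing. A 250-ms silent lead-in
precedes the capture (providing the quiet baseline burst detection needs)
and a 50-ms run-out follows it, so the synchronization offset is genuinely
non-zero and bursts ending at the last frame are recorded whole.

**What the generator does not emulate:** soft-tissue marker wobble,
non-rigid mandibular strain, head-fixation slip, camera calibration error
and lens distortion, marker mislabeling/swaps, EMG cross-talk between
muscles, movement artefacts, and amplitude non-stationarity across cycles.
Passing tests therefore demonstrate the correctness of the reconstruction
machinery under the rigid-body and synchronization assumptions — not
robustness to every failure mode of a live recording.

## Numerical choices

* **Clearance** is the symmetric minimum vertex-to-surface distance (posed
  mandible vertices against maxilla triangles and vice versa), computed
  exactly; a uniform grid over triangle bounding boxes only prunes
  candidates. This metric is oracle-checkable by exhaustive scan (asserted
  to $10^{-9}$ mm on random mesh pairs) and symmetric. Surfaces that cross
  report clearance 0; signed penetration depth is out of scope. It slightly
  underestimates true surface-to-surface distance between coarse meshes
  (edge-edge minima), which is immaterial at the 0.05-mm resolutions used.
* **Cycle delimitation** uses vertical-position maxima with a minimum
  prominence of 10% of the vertical range, re-evaluated after removing
  sub-prominent candidates so a jitter bump cannot shield a genuine maximum.
  Ties break to the earliest frame; a trajectory with no antero-posterior
  range is segmented but flagged degenerate.
* **Contact release tail.** A smooth periodic motion necessarily keeps the
  teeth within the contact threshold for a frame or two *after* maximum
  closing, as the jaw begins to open. Truth and detector agree on this tail;
  the scientifically meaningful boundary — the occlusal-phase onset, defined
  as the first contact at or after maximum opening — is recovered exactly,
  and a consistency flag records its agreement with the most posterior
  position.
* **EMG burst boundaries.** The primary rule (envelope above baseline mean
  + 3 SD, 10-ms persistence, sub-gap merging) sits, by construction, in the
  tail of the baseline envelope's own fluctuations: on pure noise the
  envelope crosses it regularly, and runs contiguous with a genuine burst
  drag its boundary outward. The detector therefore validates and delimits
  each burst at a secondary threshold (mean + 6 SD by default), uses
  primary-threshold runs only for grouping and interior bridging, corrects
  the reported crossings by half the envelope window (a step edge enters a
  centred RMS window half a window early), and judges persistence on the
  primary span minus the window smear. Under the default synthetic
  conditions this recovers all burst boundaries within ±5 ms in 100
  seeded runs with a 0.5% false-positive rate over 200 pure-noise records.
* **Calibration percent error** divides by the commanded per-axis
  displacement; zero commanded components are excluded rather than divided
  by. The displacement-resolution criterion declares a step resolved when
  the measured change exceeds the peak-to-peak fluctuation of the dwell
  segments; reusing one noise realization across candidate steps makes the
  criterion monotone in step size, so the minimal resolvable step can be
  bisected and cross-checked against a sweep.

## Problem sizes in the test suite

Unit and property tests run on 1-3 cycle records with 0.1-0.25 mm meshes;
the full-resolution (0.05 mm, ~18k triangles) dentition and the 10-cycle
default record are exercised in the whole-system checks; Monte-Carlo
comparisons use 300 observed against 1000 reference replicates; the EMG
statistics use 100 seeded runs for ordering and 200 for false positives.
These sizes were chosen to make every distributional claim testable while
keeping a full run of the suite around a minute.

## Known limitations

* The maxilla pose is a single constant; per-frame cranial markers (for
  imperfect head fixation) are out of scope.
* Contact is a distance threshold, not a contact-area or pressure model;
  whether a visual judgement of "contact" corresponds to any particular
  threshold cannot be established without physical reference data.
* Chewing side (working vs balancing) is an input, not inferred from
  kinematics.
* Accuracy figures quoted for physical camera systems (sub-5-µm resolution,
  per-axis percent errors) characterize hardware; the package reproduces the
  *protocols* and reports the errors implied by a user-specified noise model
  instead.
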