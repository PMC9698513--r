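---
title: "arusim: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{arusim: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arusim)
```

arusim is a headless, fully testable engine for monitor-based
augmented-reality ultrasound training. The setting it models is deliberately
low-cost: a student sits in front of a webcam, holds a pen or phone as a
simulated ultrasound probe, and sticks a printed square fiducial marker on
it. The computer tracks the marker, tracks the student's arm through a
body-pose keypoint provider, and — after a short calibration — displays the
pre-recorded ultrasound frame that corresponds to where (and at what tilt)
the probe touches the forearm. This vignette records the models, the tunable
parameters, and the design decisions, in the order the data flows.

## 1. Marker dictionary

A marker is a `grid_size × grid_size` binary payload inside a one-cell black
border; bit polarity is black = 1 because thresholded ink is the signal. The
dictionary must make identity *and spin* recoverable, so
`build_dictionary()` enforces two constraints by construction:

* every pair of codewords differs in at least `min_hamming` cells under all
  four relative quarter-turn rotations;
* no codeword maps to itself under a quarter, half or three-quarter turn.

The second constraint is slightly stronger than merely excluding four-fold
symmetry: a half-turn-symmetric codeword would leave the decoded spin
ambiguous between `r` and `r + 2`, which breaks the round-trip property that
matching a rotated render returns the exact rotation applied. Matching
accepts a candidate within Hamming distance `floor((min_hamming − 1)/2)`, so
flipping up to that many payload cells can never change the matched
identity; both properties are verified by exhaustive enumeration in the test
suite.

Defaults: `grid_size = 4` (16 payload bits), 50 ids achievable, and
`min_hamming = 3`, generated greedily from a seeded RNG with a bounded
search budget (an explicit capacity error is raised when the requested
dictionary cannot be placed). These sizes keep exhaustive pairwise testing
trivial while leaving one bit of error correction. The tests and examples
use a 16-id dictionary for speed; nothing in the pipeline depends on the
dictionary size.

## 2. Detection pipeline

`detect_markers()` follows the classical four-stage square-fiducial recipe:

1. **Local adaptive thresholding.** A pixel is foreground iff its intensity
   is below the local window mean minus an offset. Defaults: window 23 px,
   offset 7/255. The window must be wider than the marker's border ring so
   that every ink pixel sees some paper; the offset suppresses sensor-level
   texture. Because the rule is mean-relative, detection survives global
   affine intensity changes `a·I + b` over the range a practitioner would
   encounter (verified for several `(a, b)` in the tests); the fixed offset
   makes extreme contrast reductions the known failure mode.
2. **Quad extraction.** Outer boundaries of connected components are traced
   (interior child contours are ignored) and simplified with a closed
   Douglas–Peucker pass at tolerance `0.05 × perimeter`. Only strictly
   convex 4-vertex polygons above `min_area = 100 px²` with corner
   separation above 5 px survive. Corner order is normalised to the
   top-left → top-right → bottom-right → bottom-left sense.
3. **Sub-pixel corner refinement.** Contour corners sit on foreground pixel
   centres and are therefore biased ~0.5–1 px inward. For each quad edge we
   sample perpendicular intensity profiles, locate the mid-intensity
   crossing by linear interpolation, fit a total-least-squares line, and
   intersect adjacent edge lines. This is what brings corner accuracy from
   pixel level to the ≲0.05 px regime the pose stage benefits from; a
   refined corner moving more than 3 px is rejected as unreliable.
4. **Rectification and decoding.** The homography mapping the quad to a
   canonical square is sampled as a `(grid_size + 2)²` cell grid with 5 × 5
   points per cell; samples are thresholded by Otsu's rule on the sampled
   values (the adaptive-threshold image is *not* reused here, because its
   mean-relative rule hollows out solid dark regions larger than the
   window). The border must be ≥ 90 % foreground; payload cells are
   assigned by majority vote and matched against the dictionary under all
   four rotations. Duplicate candidates for one id collapse to the lowest
   decode distance, ties to the larger quad.

All parameters live in `detect_params()` and are config-exposed; none are
stated by the training-system protocol itself, so the defaults were chosen
once to be robust on the synthetic corpus and left alone.

## 3. Pose estimation

`estimate_pose()` minimises the sum of squared corner reprojection
residuals over a 6-parameter pose (axis-angle rotation + translation) with
Levenberg–Marquardt (λ initialised at 1e-3, cost-decrease tolerance 1e-10,
100-iteration cap), initialised from the homography decomposition of the
marker plane. Axis-angle avoids the normalisation drift a quaternion
parameterisation would need to police inside the optimizer. The camera is an
undistorted pinhole: the synthetic frames are distortion-free by
construction, which keeps the renderer–estimator loop an exact oracle;
intrinsics are required config input.

Planar pose has a well-known two-fold ambiguity at near-frontal views. We
refine from both the homography pose and its reflected-normal counterpart
and keep the candidate with the lower residual, breaking exact ties toward
the marker normal facing the camera. With noise-free corners the estimator
recovers rotations to ~1e-6 degrees; through rendered pixels, the residual
corner noise (~0.03 px RMS) maps to a rotation uncertainty that grows as
tilt decreases — around 0.2–0.5° at 20–25° tilt and worse below 10°. This
matters downstream: the sweep selector bins tilt in 1.5° steps, so
selection is stable at working tilts but can flicker between adjacent sweep
bins when the probe is held nearly frontal. That behaviour is inherent to
single-marker planar tracking, not a defect of the optimizer.

## 4. Frame calibration

Body keypoints live in the body-tracking basis; marker poses live in the
camera (marker-tracking) basis. Registering four joints — left shoulder,
left elbow, left hand, right hand — in both bases determines the linear map
`R` and translation `T` with `X_A = R·X_BT + T`. With difference matrices
`D_BT = [X2−X1 | X3−X1 | X4−X1]` and `D_A` likewise, the closed form is

```
R = D_A · D_BT⁻¹,    T = X1_A − R·X1_BT
```

an exact interpolant of the four correspondences whenever the body-tracking
points are non-coplanar. Three deliberate choices:

* `R` is kept as a **general invertible matrix**, exactly as the closed form
  yields — no orthonormalisation is imposed, so the calibration can absorb
  scale and shear differences between the two tracking systems. Users who
  want a rigid map can set `rigid = TRUE`, which polar-projects `R` onto the
  nearest rotation.
* Degeneracy is **refused, not amplified**: the solve rejects registrations
  whose difference matrix has condition number above `cond_max = 1e6`
  (configurable) with an error naming the problem, since a near-coplanar
  tetrahedron multiplies registration noise into the transform.
* The joint labels are user-experience only: any permutation of the four
  correspondences yields the same transform (property-tested), because the
  construction is symmetric in the choice of base point.

The noise behaviour is quantified rather than assumed: held-out transfer
error grows monotonically both with Gaussian noise on the registered
coordinates and with the flatness of the registration tetrahedron. This is
the quantitative form of the observation that calibration precision depends
on how carefully the user positions the marker on each joint.

## 5. The atlas and frame selection

The pre-recorded data is modelled as a grid: 35 longitudinal positions from
the inner elbow to the wrist, 10 lateral positions from right to left, and
a 40-frame angular sweep over `(−β, +β)` at each point, recorded in B-mode
and Doppler conditions, plus two 10-second Doppler clips at fixed positions
(Doppler images change over time even for a static probe). β is not part of
the recorded protocol description; the default is 30°, config-exposed.

All three selectors share one normative binning rule. For a fraction
`f ∈ [0, 1]` of the recorded range and `n` frames, the displayed index is
`floor(f·n) + 1`, with the final bin closed and out-of-range values clamped.
The rule is chosen so that the elbow (`l = 0`) shows the first image, the
wrist (`l = L`) the last, and the index is total and non-decreasing along
the arm. The longitudinal fraction is `l/L` where `l` is the along-axis
distance from the elbow to the probe marker and `L` is the user-specific
elbow-to-wrist distance measured during registration. Two conventions the
implementation documents explicitly:

* the registered *left hand* point serves as the wrist anchor — the hand is
  the nearest registered joint to the wrist, and `L` is computed from it;
* lateral selection is an extension by analogy: the recording protocol
  defines the 10 lateral positions but no selection formula, so the same
  binning rule is applied to the across-arm coordinate over
  `[−half_width, +half_width]` (default half-width 5 cm).

The sweep angle is the signed tilt of the probe axis relative to the arm
surface normal, measured in the plane spanned by the arm axis and the
normal; positive tilts lean toward the wrist. Doppler clips attach to
configurable frame keys; when the probe holds within a clip's key the clip
plays at `floor(elapsed × fps)`, looping — the trigger rule is the
package's own, since the original protocol does not state one.

## 6. Synthetic generators: what they emulate, and what they do not

The synthetic module replaces every hardware input so the full pipeline runs
offline:

* **Scenes** (`render_scene()`): markers are warped into the frame by the
  exact pinhole homography of their scripted 6-DoF poses, composited over
  flat, noise, or value-noise textured backgrounds, with scripted
  rectangular occluders. Rendering supersamples 4× and box-downsamples, so
  the sub-pixel corner ground truth that detector accuracy is measured
  against is meaningful. Flat backgrounds are the no-noise condition used
  for geometry accuracy; texture stresses the adaptive threshold.
* **Keypoints** (`generate_keypoints()`): the arm is articulated by smooth
  seeded joint-angle curves, so segment lengths are rigid before noise;
  i.i.d. per-frame Gaussian noise models body-tracking jitter. Any external
  keypoint provider can be wrapped with `keypoint_stream()` — the deep
  body-pose network of a live system is out of scope by design and enters
  only through this contract.
* **Atlas** (`generate_atlas()`): each frame deterministically encodes its
  key both visually (a vessel whose position tracks the key through a
  speckle background) and machine-readably (a 16-block binary strip across
  the top rows), so selection correctness is assertable from pixels alone.
  Frames default to 48 × 36 px and clips to 10 fps — small, deterministic
  stand-ins chosen by this package; the grid counts and the 10 s clip
  durations are the recording protocol's.

What passing tests on these generators shows — and what it does not: the
synthetic corpus establishes that the geometry chain (threshold → quad →
corner → pose → calibration → selection) is internally consistent and
numerically tight. It does not establish robustness to real webcam imagery:
lens distortion, motion blur, rolling shutter, specular paper, compression
artefacts and real body-pose-network error statistics are all absent, and a
live deployment would need the intrinsics (and ideally distortion) of the
actual camera.

## 7. Session orchestration

`run_registration()` detects four dwell intervals — windows of at least 15
consecutive frames whose marker-translation standard deviation stays below
3 mm — and takes the time-median marker position over each, paired with the
time-median keypoint of the corresponding joint, in the fixed joint order.
Dwell-based confirmation (rather than an explicit button press) suits a
headless pipeline; the scripted study conditions hold each joint for about
two seconds, which is also what an on-screen instruction would elicit. The
probe can be tracked from camera frames or supplied as a precomputed pose
stream; the second path exists because exactness claims about the
calibration (recovery to 1e-6 and better) are only meaningful upstream of
pixel quantisation, while the rendered path is exercised end-to-end by the
session tests.

`run_session()` emits exactly one log row per frame. Arm anchors follow the
live transformed elbow/hand keypoints rather than the frozen registration
points, so the virtual arm tracks the learner. Detection gaps follow the
tracking policy: the last key is re-emitted (`held`) for up to
`hold_frames` frames (default 10, ~0.3 s at 30 fps — enough to bridge
single-frame decode misses without masking true occlusion, which is the
known failure mode when the probe marker covers the arm), then the log
reports `lost` until redetection. Mode switching is a function argument /
CLI flag, not an interactive control.

## 8. Numerical choices and degenerate inputs

* Binning: `floor(f·n) + 1` with a closed final bin is the single rule
  everywhere; bin-edge inputs therefore belong to the upper bin, and test
  fixtures deliberately avoid scripting geometry that sits exactly on a bin
  edge, where any tracking noise makes the selected index flicker by one.
* Homographies come from the normalised DLT with an SVD rank guard;
  degenerate quads are rejected as candidates rather than raised.
* The optimizer accepts only cost-decreasing steps, so the residual trace
  is non-increasing by construction (property-tested).
* Collinear pose corners, coplanar registrations, zero-length arms, unknown
  ids, out-of-range frame keys and missing atlas files all raise
  descriptive errors naming the offending input.
* Every stochastic component (dictionary search, backgrounds, keypoints,
  atlas speckle) is seeded and bit-reproducible; derived seeds stay below
  2³¹.

## 9. Problem sizes used by the checks

The test suite and the acceptance script regenerate everything they
measure: a 200-frame detection corpus (tilt ≤ 45°, marker ≥ ~85 px, flat
background), 200 seeded affine calibrations cross-checked against a stacked
linear-system solve, the full default atlas (2 × 14 000 frames plus two
100-frame clips), a 200-frame scripted elbow-to-wrist sweep replayed both
from ground-truth geometry and through rendered pixels, and 50-seed
Monte-Carlo noise curves. These sizes are the package's chosen study
conditions; they run comfortably on a single CPU.

## 10. Known limitations

* Single marker, single person; no tracking across frames beyond the
  hold/lost policy, and no multi-marker fusion.
* No lens distortion model — intrinsics are trusted as given.
* Sweep-bin stability degrades at near-frontal probe tilts (Section 3).
* The lateral selector is an extension; recorded protocols that define
  their own lateral rule should override it.
* Ultrasound appearance is procedural: the atlas generator encodes
  geometry, not tissue physics, so it validates selection logic rather than
  image realism.
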