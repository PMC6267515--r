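---
title: "Model-based stereoscopic gaze reconstruction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based stereoscopic gaze reconstruction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereogaze)
```

## The measurement problem

A stereoscopic video eye tracker films each eye with two calibrated
cameras while two infrared illuminators produce corneal reflections
(glints). From the per-frame pixel coordinates of the pupil image and the
two glints in both cameras, the 3-D position of the eye and the
orientation of its optical axis can be reconstructed without a
conventional multi-point gaze calibration: only the angular offset
between the optical axis and the visual axis, and one participant-specific
length, must be estimated, and a single fixation of a known target
suffices for that. This makes the approach attractive when calibration
time is scarce or compliance is limited (young children, clinical
populations), and it tolerates moderate head translations because the eye
is localized in 3-D on every frame.

`stereogaze` implements the full offline pipeline, a forward ray-tracing
simulator of the eye and rig that generates feature streams with known
ground truth, mirror-based localization of the hidden rig components, the
raster-segmentation computations that produce the pixel features in the
first place, and the analytics used to validate such systems (fixation
accuracy and precision, saccade kinematics, agreement statistics).

## Coordinate frames and the eye model

Two right-handed frames are used. The *tracker frame* has its origin at
the camera-1 nodal point, x/y parallel to that camera's image plane and
+z toward the participant. The *stimulus frame* has its origin at the
screen center, x horizontal, y vertical, +z out of the screen toward the
participant; the physical screen surface is the plane $Z = 0$. The rigid
transform between them ($P = R\,p + T$) comes from the system
calibration. All lengths are millimeters and all angles degrees at the
API surface.

The eye is modeled with a spherical anterior cornea of radius $R$
(default 7.8 mm) centered on the center of corneal curvature $c$. The
pupil center lies on the optical axis at distance $K$ (default 4.2 mm)
from $c$. The visual axis (line of sight) is rotated from the optical
axis by a horizontal angle $\alpha$ (default 5 deg, nasal) and a vertical
angle $\beta$ (default 1.5 deg). These are standard schematic-eye values;
$K$, $\alpha$ and $\beta$ are re-estimated per participant by the
one-point calibration.

Gaze directions are parameterized Fick-style by a pan angle $\theta$ and
a tilt angle $\phi$ through

$$\hat g(\theta, \phi) =
  \begin{bmatrix} \cos\phi \sin\theta \\ \sin\phi \\
                  -\cos\phi \cos\theta \end{bmatrix},$$

so $(\theta, \phi) = (0, 0)$ looks straight into the screen.

## The reconstruction pipeline

`reconstruct_gaze()` chains the following stages per eye.

1. **Synchronization.** The two cameras free-run at independent rates, so
   each camera's features are linearly interpolated at the other camera's
   timestamps; the synchronized stream has one record per input timestamp
   of either camera inside the temporal overlap. Interpolation never
   bridges more than two consecutive invalid frames; longer gaps
   propagate as invalid samples (blink handling belongs downstream).
2. **Virtual pupil.** The pupil image seen through the refracting cornea
   is a *virtual* pupil. Its center $p_v$ is triangulated from the two
   image points and the camera nodal points, as the midpoint of the
   shortest segment between the two back-projected lines (closed-form
   least squares on the two line parameters). No refraction correction is
   applied in the inverse model: the virtual pupil center is known to
   remain within a fraction of a degree of the optical axis, and treating
   it as a point on the axis keeps the inverse problem linear in the
   geometry.
3. **Corneal-curvature center.** The cornea acts as a convex mirror
   during glint formation. For each illuminator the virtual image behind
   the cornea is triangulated from the two glint back-projections; $c$ is
   then the least-squares intersection of the two lines joining each
   illuminator to its virtual image.
4. **K constraint.** Image noise corrupts the triangulated depth (tracker
   z) far more than x/y, because it slides the reconstruction along the
   nearly parallel viewing rays. The virtual pupil's x/y are therefore
   kept and its z replaced by
   $z'_{pv} = z_c - \sqrt{K^2 - (x_c - x_{pv})^2 - (y_c - y_{pv})^2}$,
   restoring the calibrated distance $K$ exactly. The negative root is
   hard-coded: the pupil is always nearer the cameras than $c$ in tracker
   coordinates. Samples whose planar distance already exceeds $K$ are
   flagged invalid rather than clamped.
5. **Stimulus frame and filtering.** $c$ and the constrained pupil are
   mapped into the stimulus frame; their components and the measured
   length $K_{actual} = \lVert c - p_v \rVert$ are median-filtered
   (width 20 samples). The median preserves saccade edges while removing
   impulsive noise.
6. **Angles and gaze point.** The optical-axis angles come from the unit
   vector from $C$ to $P'_v$; adding $(\alpha, \beta)$ gives the gaze
   direction $\hat g$, and the point of gaze is the screen intersection
   $POG = C + \lambda_g\, \hat g$ with
   $\lambda_g = Z_c / (\cos(\phi+\beta)\cos(\theta+\alpha)) > 0$.
7. **K-gain correction.** A real cornea is not spherical, so the measured
   $K_{actual}$ varies systematically with gaze angle and eye position,
   and with it the reconstructed gaze angles are systematically over- or
   under-estimated. The correction rescales the full gaze-point vector by
   the dimensionless gain $K / K_{actual}$ (an empirical correction, kept
   exactly as formulated): $POG_{corr} = (K / K_{actual})(C + \lambda_g \hat g)$,
   with corrected angles recomputed from $POG_{corr}$ and the *unscaled*
   $C$. When $K_{actual} = K$ the correction is the identity. The
   correction is deliberately applied in stimulus coordinates: the gain
   is anchored to the one-point calibration, whose reference point is the
   screen center.

### One-point calibration

During a steady fixation (1.2 s by default, matching the central-fixation
timing of a saccade trial) of a known target, $K$ is the median of the
per-sample measured $\lVert c - p_v\rVert$, and $\alpha, \beta$ are the
medians of the per-sample differences between the line-of-sight angles
(from $C$ to the target, same Fick parameterization) and the optical-axis
angles. The same parameterization on both sides makes the offsets exactly
additive. Medians are used throughout for robustness. The angle
differences are computed from the same median-filtered $C$/$P'_v$ signals
the runtime pipeline uses, so calibration and reconstruction see
identically processed data; $K$ is always the median of the raw lengths.

## The forward simulator

The simulator is the package's oracle: it renders the exact pixel
features a rig would record from a known eye, so every inverse stage can
be tested by round-trip parameter recovery.

* **Glints** are found by a 1-D root-find on the in-plane corneal surface
  angle (the specular point lies in the plane of illuminator, nodal point
  and sphere center); the stationarity condition of Fermat's path length
  is solved to a tolerance of 1e-15 rad, giving reflection-law residuals
  below 1e-9 rad. A 2-D spherical search is unnecessary because the
  in-plane reduction is exact for a sphere.
* **Pupil imaging** has two modes. `no_refraction` projects the true
  pupil center, which makes the inverse model's pupil step exact and is
  the basis of the round-trip tests. `snell` traces the chief ray: the
  corneal entry point for which the ray from the nodal point, refracted
  at the spherical surface (n = 1.3375 inside), passes through the true
  pupil center. This reproduces the depth displacement of the virtual
  pupil and, with it, the systematic variation of the measured
  $K_{actual}$ that the K-gain correction targets.
* **Trials** follow the validation-study design: a central fixation, then
  a saccade to one of 54 targets (eccentricities 3, 6, 9, 12 deg in
  twelve directions plus 15 deg in six directions, converted to screen
  millimeters through an imaginary eye at 650 mm). Saccades use a
  raised-cosine velocity profile whose peak velocity follows the
  saturating main sequence $v_{peak} = v_0(1 - e^{-Amp/Amp_0})$ (defaults
  $v_0 = 500$ deg/s, $Amp_0 = 5$ deg), so duration is $2\,Amp/v_{peak}$.
  The two cameras sample at independent, jittered rates (defaults 330 and
  300 Hz, ±10% uniform interval jitter); head translations displace the
  eye by up to ±50 mm horizontally and ±30 mm vertically, the bite-board
  range of the validation design. Isotropic Gaussian pixel noise is added
  per feature; all randomness flows from one integer seed per script.

The reference rig (`default_rig()`) places the two cameras 120 mm apart
on a rail below the screen, aimed at a nominal eye position 600 mm away,
with the illuminators flanking them and a 1920 × 1200 screen (0.27-mm
pixel pitch) whose center is 650 mm from the nominal eye.

**What the simulator does not emulate.** The cornea is exactly spherical;
real corneas are aspheric, which makes the measured $K_{actual}$ vary
more strongly and less regularly than the Snell-mode sphere produces, so
the correction's benefit here is qualitative, not a quantitative
prediction for real eyes. There is no eyelid occlusion, no torsion, no
pupil-size change, no photometric model of the iris, and pixel noise is
white and isotropic whereas real feature noise is neither. Passing
round-trip tests therefore demonstrates internal consistency of the
geometry and processing chain, not field accuracy.

### Noise levels

Two pixel-noise settings recur. The stress fixture uses 0.1 px, which on
this rig produces a tracker noticeably noisier than a good desk system;
it is used for the noise-reduction and robustness checks. For the
saccade-analysis experiment the default is 0.025 px, chosen so the
simulated tracker reproduces the fixation precision reported for desk
stereo trackers of this class (sample-to-sample RMS of a few hundredths
of a degree, window SD around 0.1 deg).

## Validation analytics

* `pog_mm_to_deg()` converts screen millimeters to degrees per component
  as $\arctan(\text{offset}/650)$ — the orientation of an imaginary eye
  on the screen axis. The per-component decomposition matches the way
  horizontal and vertical accuracies are reported; no 2-D angular metric
  is implied.
* `filter_and_velocity()` resamples to a uniform 500-Hz grid (2-ms
  interval), applies a zero-phase 8th-order 40-Hz Butterworth, and
  differentiates with central differences; vectorial speed is the
  Pythagorean sum. The zero-phase pass is implemented in the package
  (odd-reflection padding plus step-matched initial conditions in
  transposed direct-form II) because `signal::filtfilt` performs neither
  and leaves edge transients large enough to masquerade as saccades; the
  implementation matches `scipy.signal.filtfilt` to four decimals on
  saccade profiles, and the coefficient design still comes from
  `signal::butter`.
* `detect_saccades()` marks maximal runs of speed above 45 deg/s;
  amplitude is the vectorial position difference between offset and
  onset, peak velocity the in-run maximum. A saccade starting within
  250 ms of the previous offset with less than half its amplitude is
  flagged corrective; the fixation window (80 ms, starting 20 ms after
  the relevant offset) then anchors on the corrective saccade. The
  corrective-saccade criterion is this package's own convention — the
  windowing rule requires one, and none is standard.
* `fixation_metrics()` reports accuracy as the per-component mean
  absolute error of window means against targets, and precision both as
  RMS of successive sample displacements (RMS-s2s) and as the window SD,
  averaged over trials.
* `fit_main_sequence()` fits $v_0, Amp_0$ by Levenberg–Marquardt
  (`minpack.lm::nlsLM`); `bland_altman()` reports the mean difference and
  1.96-SD limits of agreement. `expected_amplitude_diff_sd()` is the
  closed-form error-propagation companion: with independent
  horizontal/vertical accuracies for two systems, the expected SD of
  their amplitude difference is the root sum of squares of the four
  accuracies (its conventional 95% companion is twice that).

## Numerical choices and degenerate inputs

* Two-line "intersection" is solved in closed form (2 × 2 normal
  equations); rays with $|\cos\angle| \ge 1 - 10^{-9}$ raise a
  degenerate-geometry error — such geometry never occurs in a sane rig
  and signals corrupt input rather than a recoverable measurement.
* The mirror plane is fit by total least squares (SVD of the centered
  triangulated markers); screen pose by orthogonal Procrustes (Kabsch).
  Both error out on collinear configurations. Calibration residuals are
  always reported rather than silently accepted.
* The median filter uses windows extending $w/2$ samples back and
  $w/2 - 1$ forward for even widths, truncated at the series edges, with
  even-cardinality windows averaging the two middle order statistics —
  length-preserving without inventing padding data.
* Samples violating the K constraint, glints without a specular path, and
  features off the sensor all become validity flags, never exceptions, in
  stream processing; hard errors are reserved for configuration problems.
* Segmentation uses 8-connected components (EBImage's 4-connected
  labeling plus a diagonal union-find merge), boundary pixels as the
  contour, and a direct least-squares conic fit with the ellipse
  constraint for the pupil; glint centroids weight pixels by their
  above-threshold excess, which removes the pedestal bias of a cropped
  spot. Default thresholds are fixture-tuned for the built-in renderer.

## Known limitations

* **A noiseless accuracy floor of ~0.06 deg.** With exact specular
  glints, the virtual image of an illuminator in a convex mirror is
  weakly camera-dependent (spherical aberration): each camera's glint
  back-projection crosses the illuminator-to-$c$ axis exactly, but at
  axial positions differing by ~0.03 mm across a 120-mm camera baseline.
  The triangulated virtual image therefore sits slightly off-axis,
  biasing $c$ by ~0.016 mm and the measured $K$ by ~0.015 mm on the
  reference rig. The one-point calibration absorbs the constant part;
  the gaze-dependent remainder leaves up to ~0.06 deg of angle error
  across the ±15-deg grid even with noiseless pixels. This is a property
  of the virtual-image intersection method itself, not of its
  implementation; it vanishes in camera-symmetric configurations.
* **Peak-velocity attenuation for brief saccades.** The prescribed
  velocity chain (zero-phase 8th-order 40-Hz Butterworth, 2-ms central
  differences) attenuates the peak velocity of a 27-ms raised-cosine
  saccade (3 deg at the default main sequence) by about 17%, 6-deg
  saccades by 7%, and 9 deg and larger by under 2%. Main-sequence fits
  through the full chain consequently overestimate $Amp_0$ by roughly a
  third and $v_0$ by just under a tenth relative to the generating
  values; fits restricted to the saturating branch recover $v_0$ well.
  Any comparison of fitted parameters between systems processed with the
  same chain remains fair, which is how such fits are used in practice.
* **Vertical offset variance.** Depth noise projects into the vertical
  angle through the cameras' upward viewing obliquity, so the one-point
  calibration's $\beta$ has a standard error around 0.15 deg at 0.1-px
  noise for a 1.2-s fixation — several times the horizontal $\alpha$'s.
  Longer calibration fixations reduce it in proportion to the square
  root of duration.

## Problem sizes used by tests and the acceptance script

The bundled checks run the full 54-target grid at all 9 head positions
for the noiseless round trip, 54 Snell-mode fixation trials for the
correction-efficacy comparison, 54 saccade trials for the main-sequence
experiment, 0.1-to-0.3-s fixations elsewhere, and 1000 random ray pairs
plus dense sphere sampling for the oracle equivalences — sizes chosen so
the entire suite completes in a few minutes on one core while every
stage is exercised end to end.
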