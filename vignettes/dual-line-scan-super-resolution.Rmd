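---
title: "Dual line-array scanning super-resolution: models and methods"
author: "duolineSR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual line-array scanning super-resolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duolineSR)
```

## The imaging problem

A lensless optofluidic microscope records cells flowing through a
microfluidic channel with a bare CMOS sensor placed directly beneath it.
With no optics, the sampling pitch of the image equals the physical pixel
pitch — 2.2 um here — which is the same order as the cells themselves, so
the directly acquired image is severely undersampled. Reading the sensor
as a *line* (one row per frame) and tilting that line by an acute angle
$\theta$ to the flow direction reduces the effective lateral sampling
pitch to

$$d_x = d\,\sin\theta,$$

because neighbouring pixels along the tilted line are only $d\sin\theta$
apart *across* the channel. Stacking the line reads over time yields a
scan image whose columns sample the object at this finer pitch: at
$d = 2.2\,\mu m$ and $\theta = 21^\circ$ the equivalent pixel size is
$0.79\,\mu m$, a $2.8\times$ improvement; at $15^\circ$ and $10^\circ$ it
is $0.569$ and $0.382\,\mu m$. The reconstruction grid uses square pixels,
$d_y = d_x$.

The price of scanning is that the image's second axis is *time*: a row is
wherever the object happened to be when that line was read. Cells in a
microfluidic channel do not move at constant velocity, so resampling the
scan image back into object coordinates requires knowing the motion. The
method solves this with a **second, parallel line sensor** a small
perpendicular distance $d_{gap}$ downstream: each feature of the cell
crosses the two lines with a time lag $\Delta t$, giving its instantaneous
velocity, and differences between consecutive features give accelerations.

## Coordinate frames and kinematics

Two frames are used throughout. The *object frame* C1 has $x$
perpendicular to the channel and $y$ along the flow; the *scan frame* C2
has $x'$ along the sensor line and $y'$ along the perpendicular approach
direction. They are related by the fixed rotation

$$V_{x'} = V_y\cos\theta + V_x\sin\theta,\qquad
  V_{y'} = V_y\sin\theta - V_x\cos\theta,$$

implemented by `velocityToScanFrame()` / `velocityToObjectFrame()` (and
the same matrix for accelerations). $\theta$ is always the *mounting*
angle from the `SensorConfig`; the instantaneous flow-deviation angle
$\arctan(V_x/V_y)$ is available as a diagnostic (`flowDeviationAngle()`)
but never substituted into the transforms, since the rotation between the
frames is a property of the rig, not of the motion.

## Scan-time inversion

An object point at object-frame pixel coordinates $(x, y)$ crosses the
first sensor line at the frame $y'$ solving

$$\frac{a_{y'}}{2f}\,y'^2 + V_{y'}\,y' - d f \sin\theta\,
  (y\sin\theta + x\cos\theta) = 0,$$

with $f$ the line rate. The scan-frame components $V_{y'}, a_{y'}$ absorb
lateral drift exactly — substituting the rotation above reproduces the
full crossing condition including the $S_{V_x}/\tan\theta$ term — so the
same quadratic applies to drifting objects. The crossing pixel is
$x' = x + S_{V_x}/(d\sin\theta)$ with $S_{V_x}$ the lateral displacement
accumulated by time $y'/f$. `solveCrossingFrame()` takes the smallest
non-negative real root (the first crossing); a negative discriminant
(decelerating object that never reaches the line) marks the pixel
invalid, and invalid pixels render as background with the validity mask
exported.

For piecewise-constant acceleration, the cumulative scan distance
$S'(y')$ is integrated gap by gap from the measured velocities
(`computeSegmentBoundaries()`), each boundary mapping to the object-frame
intercept $b_y = S'/(d\sin^2\theta)$ of the sensor line
$y = -x/\tan\theta + b_y$. `mapObjectToScan()` assigns each object pixel
to its acceleration segment (closed upper boundary: a point exactly on an
intercept belongs to the earlier segment), solves that segment's
quadratic on the residual distance, and accumulates the earlier segments'
frame spans and lateral drift. The analytic map agrees with a dense
time-stepping oracle to $\sim10^{-6}$ frames; the test suite asserts
0.5 frame / 0.5 pixel over $10^4$ random point/motion instances.

Three motion models are exposed by `reconstructImage()`:
`uniform_velocity` (mean measured velocity), `uniform_acceleration`
(single least-squares $(V', a')$ fit to the velocity series) and
`variable_acceleration` (the full piecewise model). With a degenerate,
constant velocity series all three coincide. Interpolation into the scan
image is bilinear by default, nearest-neighbour behind a flag.

**Extrapolation outside the feature span.** Velocities are only
observable while ring features cross the sensors. Before the first and
after the last feature the nearest measured velocity is held constant:
extrapolating a measured *acceleration* backwards across the long
unobserved pre-transit span amplifies its measurement error quadratically
in time, which we found degrades the reconstruction rather than improving
it. A consequence is that the absolute object position is known only up
to a global offset — quantitative comparisons against a reference
therefore register by correlation peak first (`registerToReference()`).

## Foreground extraction

A line sensor's fixed-pattern ("stripe") noise — per-column gain and
offset from pixel non-uniformity and uneven illumination — is stable
over an acquisition, so a per-column running mean models the background.
For each new row $P_i$ the signed difference $EP_i = P_i - \bar P_i$ is
thresholded into a background mask ($M=1$ when $T_1 \le EP \le T_2$,
thresholds $\pm 15$ DN by default, boundary values counting as
background), and the model is updated with the leaky mean

$$\bar P' = \frac{\bar P (N-1) + M P}{N - 1 + M},$$

so foreground columns leave the model untouched and background columns
follow an exponential moving average with factor $(N-1)/N$ ($N = 20$
rows by default). The emitted foreground $EP' = P - \bar P'$ uses the
post-update mean. The first $N$ rows initialise the model and are assumed
cell-free; if their spread exceeds the threshold window a warning flags a
likely contaminated preamble. Because every step is per-column, column
permutation commutes with the whole pipeline, and stripe noise cancels
identically while a global-mean subtraction would leave it in.

## Feature velocimetry

Cells far from the sensor plane image as concentric bright/dark
diffraction rings of uniform grey level, which are exactly the stable
connected regions an MSER (maximally stable extremal regions) detector
finds. The detector here sweeps intensity thresholds in steps of
$\Delta$ (default 2) for both polarities, scores each connected
component within the area limits by its relative area variation across
one step, keeps components below the stability limit (default 20%,
interpretable alternatively as a region-count cap) and de-duplicates
overlapping candidates. Compressing the dynamic range to 190 beforehand
(a rank-preserving linear rescale) limits the number of levels swept.

Each region yields two corner features — the mean abscissa at the
region's extreme ordinates — screened by non-maximum suppression on the
ordinate using the kernel score $|{\sum M_{data} \odot M_{corner}}|$
(9×9 antisymmetric band kernel by default, user-configurable since the
printed layout of the original is ambiguous). Corners are matched on the
second sensor by minimising the sum of squared differences of a
$(H{+}1)\times(W{+}1)$ template ($H = W = 20$) over a search box centred
at the expected lag and the geometric column offset
$d_{gap}\cos\theta/(d\sin\theta)$. Three deliberate choices here:

* **Minimise, not maximise.** SSD is a squared-difference sum; its
  minimum marks the best match.
* **Sub-frame refinement.** A parabola through the three SSD scores
  around the minimum refines the lag to sub-frame precision (never
  moving it more than half a step). Integer lags would quantise
  velocities at $\sim$2% at typical lags of 40–50 frames, and the
  integrated quantisation error misplaces rings by about two equivalent
  pixels in the reconstruction.
* **Two matching passes.** The first pass uses a wide box
  ($\pm$half the expected lag); a robust linear fit of its lags against
  the ordinate then re-centres a narrow ($\pm$10%) box per corner.
  Diffraction rings are self-similar, and the wide box occasionally
  locks onto a neighbouring ring; the second pass suppresses this.

The matched pair gives the scan-frame velocity

$$V_{y'} = \frac{d_{gap} f}{y'_2 - y'_1},\qquad
  V_{x'} = \frac{d\,f\,(x'_2 - x'_1)}{y'_2 - y'_1},$$

where the apparent column shift $x'_2 - x'_1$ of column-aligned sensors
contains the fixed geometric offset which, divided by the lag, yields
exactly the lateral component of the frame rotation — so the recovered
$(V_{x'}, V_{y'})$ transforms back to the object frame consistently.
Each velocity is attributed to the **mid-transit frame**
$(y'_1+y'_2)/2$: under constant acceleration the lag-average velocity
equals the instantaneous velocity there exactly, whereas attributing it
to the first crossing biases it by several percent under deceleration.
Finite differences between consecutive features give the $K-1$
accelerations for $K$ features.

## The synthetic acquisition model

`acquireDualLineScan()` is the forward model the validation rests on. A
rendered phantom — a disk darker than background carrying `nRings`
concentric sinusoidal intensity oscillations with a smooth edge taper, a
geometric stand-in for a microsphere's diffraction pattern — flows past
both tilted lines under a piecewise-constant-acceleration
`MotionProfile`. Each sensor pixel point-samples the phantom bilinearly
at the object point it sees at that frame (an optional box-sampling mode
averages over the pixel footprint); row $i$ is sampled at $t = i/f$
exactly, with no exposure smear. Noise follows the stable-stripe model:
per-column gain $g_j \sim 1+\mathcal N(0, 0.02)$ and offset
$o_j \sim \mathcal N(0, 2\,\mathrm{DN})$ drawn once per capture, plus
per-pixel read noise $\mathcal N(0, 1\,\mathrm{DN})$, with optional
quantisation to integer DN. Identical seeds give bit-identical streams.

The default study conditions emulate the experimental rig: 2.2 um pitch,
$21^\circ$ tilt, 1230 lines/s, 88-pixel lines, a gap of six pixel
pitches (13.2 um; the physical gap of the original rig is not public,
and six pitches keeps the transit lag near 45 frames — long enough for
$\sim$1% velocity resolution, short enough that a transit rarely spans
more than one acceleration change). The phantom is 32 um across with
five rings — the diffraction pattern of a $\sim$20 um microsphere
extends well beyond the sphere — and the default motion enters at
700 um/s through three acceleration periods $(+3000, -5000, +3000)$
um/s² lasting 160/55/120 frames. The durations are chosen from the
transit geometry: ring corners are only observable during the
$\sim$100-frame window in which the disk crosses the line, so the three
periods are placed to partition that window (the first also covers the
cell-free preamble needed by the background model). Speeds and
acceleration magnitudes match the scale reported for microspheres in
this kind of channel.

What the simulator does **not** model: physical Fresnel diffraction (the
rings are geometric), multi-cell occlusion, Brownian motion, exposure
smear, and sensor saturation beyond simple clamping. Passing round-trip
tests therefore demonstrates the correctness of the geometry, the
velocimetry and the inversion — not robustness to optical effects absent
from the model.

## Evaluation metrics

`imageEntropy()` is the Shannon entropy of the 256-bin grey-level
histogram (float images are rescaled to 0–255 first). `psnr()` and
`ssim()` use the standard definitions; SSIM uses a uniform 7×7 window
with sample-covariance normalisation and matches the conventional
reference implementation to machine precision (asserted in the tests
against an independent implementation). `estimateDiameter()` thresholds
at the midpoint between the median background and the robust object
level (mean of the strongest 5% of deviations), keeps the largest
connected component and reports the equivalent-area diameter
$2\sqrt{A/\pi}$; a calliper (maximum-chord) alternative sits behind a
flag. The measurement procedure for the original size numbers is not
public, so this choice is documented rather than calibrated.

## Numerical choices and degenerate inputs

* Angles are degrees at every interface and radians internally.
* Frames are 0-based at $t = i/f$; R matrix row $r$ holds frame
  `frameOffset + r - 1`.
* Root selection in the crossing quadratic: smallest non-negative real
  root; linear fallback at zero acceleration; complex roots mark the
  pixel invalid.
* Boundary conventions: mask thresholds are strict inequalities (values
  exactly at $T_1$/$T_2$ are background); segment upper boundaries are
  closed; SSD ties break to the smallest ordinate then abscissa; corner
  screening ties break to smaller ordinate then abscissa.
* A small epsilon absorbs floating-point dust at image borders and in
  grid extents (e.g. $\cos(90^\circ) \approx 6\times10^{-17}$ would
  otherwise invalidate the first reconstruction column).
* Constant images: dynamic-range compression and MSER return their
  inputs/empty sets rather than dividing by zero.

## Worked example

```{r example, eval = FALSE}
cfg <- SensorConfig()                  # 2.2 um, 21 deg, 1230 lines/s
ph  <- renderRingPhantom(diameter = 32, nRings = 5)
sim <- acquireDualLineScan(ph, defaultMotionProfile(), cfg,
                           noiseSpec(), seed = 1)
fg1 <- extractForeground(sim$stream1)
fg2 <- extractForeground(sim$stream2)
kin <- estimateKinematics(fg1, fg2, cfg)
rec <- reconstructImage(fg1, kin, cfg, model = "variable_acceleration")
ref <- downsamplePhantom(ph, equivalentPixelSize(cfg))
reg <- registerToReference(reconImage(rec), ref)
ssim(reg$aligned, ref)
```

## Known limitations

* Velocity resolution is bounded by the lag and the sub-frame
  refinement; very short gaps quantise velocities coarsely, very long
  gaps average over acceleration changes. Transits that straddle a
  boundary between acceleration periods estimate the transit-average
  velocity, which is the method's actual estimand but differs from the
  instantaneous velocity at any single frame.
* Lateral (cross-channel) drift makes reconstruction columns fall
  between scan columns, adding bilinear resampling blur that an
  axis-aligned flow does not incur.
* The absolute position of the object along the flow is unobservable
  before its transit; reconstructions are defined up to a global offset.
* One object per capture is assumed: the kinematics table describes a
  single timeline, and the diameter estimator expects one dominant
  component.
* The reconstruction samples the first sensor's stream only; the second
  sensor serves velocimetry.
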