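# duolineSR

Super-resolution scanning reconstruction for lensless microfluidic
imaging with a dual line-array sensor.

## The problem

A lensless optofluidic microscope images cells flowing through a
microfluidic channel with a bare CMOS sensor under the channel — no
lens, so the resolution is set by the physical pixel pitch (2.2 µm
here), the same order of magnitude as the cells. Reading the sensor as a
single tilted line and stacking the reads over time turns the flow
itself into a scanner: with the line at an acute angle θ to the flow,
the effective lateral sampling pitch drops to

    d_x = d · sin(θ)

(0.79 µm at 2.2 µm pitch and 21°, a 2.8× improvement; 0.569 µm at 15°;
0.382 µm at 10°). The catch is that the scan image's second axis is
time, and cells do not flow at constant speed, so the image is distorted
by the unknown motion. A second parallel line a small perpendicular
distance d_gap downstream resolves this: each diffraction-ring feature
of the cell arrives at the second line with a lag Δt, giving its
instantaneous velocity

    V_y' = d_gap · f / Δy',    V_x' = d · f · Δx' / Δy'

(f = line rate, Δy' = lag in frames, Δx' = apparent column shift), and
differences between consecutive features give piecewise accelerations.
The scan image is then resampled into object coordinates by inverting,
segment by segment, the crossing quadratic

    (a_y'/2f) y'² + V_y' y' − d f sin(θ)(y sinθ + x cosθ) = 0,

which maps every object pixel to the frame and sensor pixel at which the
line swept over it.

The package is aimed at researchers building or evaluating line-scan /
optofluidic imaging systems: it implements the full chain — geometry,
streaming background subtraction, MSER ring detection, SSD feature
matching across the two sensors, velocimetry, and reconstruction under
uniform-velocity, uniform-acceleration and piecewise
variable-acceleration motion models — plus a forward acquisition
simulator with ground truth, and the evaluation metrics (entropy, PSNR,
SSIM, equivalent-area diameter) used to judge the reconstructions.

## Worked example

Simulate a ring phantom (the diffraction pattern of a ~20 µm
microsphere) flowing through three acceleration periods, extract the
foreground from both streams, estimate its kinematics, and reconstruct:

```r
library(duolineSR)

cfg <- SensorConfig()            # 2.2 um pitch, 21 deg, 1230 lines/s
equivalentPixelSize(cfg)
#> [1] 0.7884095

ph  <- renderRingPhantom(diameter = 32, nRings = 5)
sim <- acquireDualLineScan(ph, defaultMotionProfile(), cfg,
                           noiseSpec(), seed = 1)
fg1 <- extractForeground(sim$stream1)   # N = 20, thresholds +-15
fg2 <- extractForeground(sim$stream2)
kin <- estimateKinematics(fg1, fg2, cfg)
kin
#> KinematicsTable: 7 features, 6 accelerations
#>   Vy' range 319.8..376.9 um/s

rec <- reconstructImage(fg1, kin, cfg, model = "variable_acceleration")
rec
#> ReconstructionGrid (variable_acceleration): 337x88 px at 0.7884 um/px,
#> 65.6% valid
```

The feature table shows the deceleration the profile imposes mid-transit
(scan-frame V_y' falls from ~370 to ~320 µm/s, i.e. object-frame ~1050
to ~900 µm/s). Comparing the reconstruction against the phantom
downsampled to the equivalent pixel size — after correlation-peak
registration, since the object's absolute position before its transit is
unobservable — shows why the variable-acceleration model matters:

```r
ref <- downsamplePhantom(ph, equivalentPixelSize(cfg))
ssim(registerToReference(reconImage(rec), ref)$aligned, ref)
#> [1] 0.889
recU <- reconstructImage(fg1, kin, cfg, model = "uniform_velocity")
ssim(registerToReference(reconImage(recU), ref)$aligned, ref)
#> [1] 0.567
```

(0.903 vs 0.575 for a noise-free capture.) A thin command-line wrapper
over the same functions is installed at `inst/scripts/duoline-sr.R` with
subcommands `simulate`, `extract`, `velocity`, `reconstruct`,
`evaluate` and `run`.

The methods vignette
(`vignettes/dual-line-scan-super-resolution.Rmd`) documents the models,
the parameter choices and their defaults, the synthetic study
conditions, and the package's numerical conventions.

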