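# Shared fixtures: the study conditions (rig + phantom + motion profile)
# and independent oracles used across the suite.

studyCfg <- function(...) SensorConfig(...)

studyPhantom <- function() renderRingPhantom(diameter = 32, nRings = 5)

studySim <- function(seed = 1, noise = noiseSpec(),
                     profile = defaultMotionProfile(),
                     cfg = studyCfg()) {
  acquireDualLineScan(studyPhantom(), profile, cfg, noise, seed = seed)
}

studyAccels <- function() c(3000, -5000, 3000)

# --- brute-force crossing oracle -------------------------------------
# Dense time stepping of the trajectory; independent of the analytic
# quadratic path. A(t) = sflow(t) - svx(t)/tan(theta) is strictly
# increasing for any valid profile, so the first crossing of object point
# (Sx, Sy) [um] is where A(t) reaches Sy + Sx/tan(theta).
oracleTable <- function(profile, cfg, tMaxFrames, stepsPerFrame = 10) {
  f <- lineRate(cfg)
  th <- tiltAngle(cfg) * pi / 180
  dt <- 1 / (stepsPerFrame * f)
  tt <- seq(0, tMaxFrames / f, by = dt)
  disp <- trajectoryPosition(profile, tt, f)
  list(tt = tt, A = disp[, "y"] - disp[, "x"] / tan(th),
       svx = disp[, "x"], f = f, th = th,
       d = pixelPitch(cfg))
}

# vectorised: returns frames (y'') and pixels (x'') or NA outside range
oracleCrossing <- function(tab, Sx, Sy) {
  c0 <- Sy + Sx / tan(tab$th)
  n <- length(c0)
  yp <- rep(NA_real_, n); xp <- rep(NA_real_, n)
  idx <- findInterval(c0, tab$A)
  ok <- idx >= 1L & idx < length(tab$A) & c0 >= tab$A[1]
  i <- idx[ok]
  frac <- (c0[ok] - tab$A[i]) / (tab$A[i + 1L] - tab$A[i])
  tStar <- tab$tt[i] + frac * (tab$tt[i + 1L] - tab$tt[i])
  svx <- tab$svx[i] + frac * (tab$svx[i + 1L] - tab$svx[i])
  yp[ok] <- tStar * tab$f
  xp[ok] <- (Sx[ok] + svx) / (tab$d * sin(tab$th))
  data.frame(ypp = yp, xpp = xp, valid = ok)
}

# scan-frame piecewise profile wrapped as SegmentBoundaries, from exact
# object-frame velocities (for reconstruct-module tests)
exactBoundaries <- function(profile, cfg, frames) {
  f <- lineRate(cfg); th <- tiltAngle(cfg) * pi / 180
  d <- pixelPitch(cfg)
  st <- trajectoryVelocity(profile, frames / f, f)
  seg <- profile@segments
  bord <- c(0, cumsum(seg$duration))
  aIdx <- pmin(findInterval(frames, bord, left.open = FALSE),
               nrow(seg))
  pr <- data.frame(startFrame = frames,
                   v = st[, "vy"] * sin(th) - st[, "vx"] * cos(th),
                   a = seg$ay[aIdx] * sin(th) - seg$ax[aIdx] * cos(th),
                   vxObj = st[, "vx"], axObj = seg$ax[aIdx])
  n <- nrow(pr)
  dtt <- diff(pr$startFrame) / f
  pr$cumS <- c(0, cumsum(pr$v[-n] * dtt + 0.5 * pr$a[-n] * dtt^2))
  pr$cumLat <- c(0, cumsum(pr$vxObj[-n] * dtt +
                             0.5 * pr$axObj[-n] * dtt^2))
  new("SegmentBoundaries", featureFrames = pr$startFrame,
      scanDistance = pr$cumS + seq_len(n) * 1e-9,
      intercepts = (pr$cumS + seq_len(n) * 1e-9) / (d * sin(th)^2),
      profile = pr)
}

# --- stripe-noise stream with an inserted rectangular blob -----------
# per-column fixed offsets (stripes), optional read noise, and a block of
# `amplitude` DN below background over the given frame/column window
stripeBlobStream <- function(frames = 140, cols = 48, background = 120,
                             stripeSd = 8, readSd = 1, amplitude = 40,
                             blobFrames = 81:100, blobCols = 15:30,
                             seed = 42) {
  set.seed(seed)
  stripes <- rnorm(cols, 0, stripeSd)
  m <- matrix(background, frames, cols)
  m <- sweep(m, 2, stripes, "+")
  if (readSd > 0) m <- m + matrix(rnorm(frames * cols, 0, readSd), frames)
  m[blobFrames, blobCols] <- m[blobFrames, blobCols] - amplitude
  footprint <- matrix(FALSE, frames, cols)
  footprint[blobFrames, blobCols] <- TRUE
  list(stream = LineScanStream(m), footprint = footprint,
       readSd = readSd, stripeSd = stripeSd)
}

# scikit-image SSIM (independent implementation) via the system python
pythonSSIM <- function(a, b, dataRange) {
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write.table(a, fa, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(b, fb, sep = ",", row.names = FALSE, col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy as np; from skimage.metrics import ",
    "structural_similarity as s; ",
    "a=np.loadtxt('%s',delimiter=','); b=np.loadtxt('%s',delimiter=','); ",
    "print('%%.17g' %% float(s(a,b,data_range=%.17g,win_size=7)))"),
    fa, fb, dataRange)
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  as.numeric(out[length(out)])
}

# registered SSIM of a reconstruction against the downsampled phantom
roundTripSSIM <- function(sim, cfg, model, fg1 = NULL, kin = NULL) {
  if (is.null(fg1)) fg1 <- extractForeground(sim$stream1)
  if (is.null(kin)) {
    fg2 <- extractForeground(sim$stream2)
    kin <- suppressMessages(estimateKinematics(fg1, fg2, cfg))
  }
  rec <- reconstructImage(fg1, kin, cfg, model = model)
  ref <- downsamplePhantom(sim$truth$phantom, equivalentPixelSize(cfg))
  reg <- registerToReference(reconImage(rec), ref)
  ssim(reg$aligned, ref)
}
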