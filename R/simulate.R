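# Forward acquisition model: ring phantom, piecewise-quadratic trajectory,
# and the dual tilted line-scan sampling with fixed-pattern stripe noise.

#' Render a concentric-ring disk phantom
#'
#' Geometric stand-in for the diffraction pattern of a flowing microsphere:
#' a disk darker than the background carrying `nRings` concentric
#' bright/dark intensity oscillations (the alternating diffraction rings),
#' with a smooth edge taper. Deterministic for any `seed`.
#'
#' @param diameter disk diameter (um)
#' @param nRings number of radial intensity oscillations (>= 1)
#' @param contrast ring modulation amplitude as a fraction of the
#'   background level (0 gives a uniform disk)
#' @param pixelSize phantom sampling pitch (um); must oversample the ring
#'   period (`diameter / (2 nRings) >= 2 * pixelSize`)
#' @param seed accepted for interface uniformity; rendering is
#'   deterministic
#' @param background background intensity (DN)
#' @param depth how much darker the disk base is than the background (DN)
#' @param margin clear border around the disk (um)
#' @return a [Phantom-class]
#' @examples
#' ph <- renderRingPhantom(diameter = 20, nRings = 3, pixelSize = 0.25)
#' @export
renderRingPhantom <- function(diameter = 20, nRings = 3, contrast = 0.4,
                              pixelSize = 0.25, seed = 1L,
                              background = 120, depth = 40,
                              margin = diameter / 4) {
  if (diameter < 4 * pixelSize)
    stop("diameter must be at least 4 pixel sizes")
  R <- diameter / 2
  if (nRings < 1) stop("nRings must be >= 1")
  if (R / nRings < 2 * pixelSize)
    stop("diameter too small for the requested number of rings at this ",
         "pixel size")
  half <- R + margin
  n <- 2L * ceiling(half / pixelSize) + 1L
  ctr <- (n + 1) / 2
  ax <- (seq_len(n) - ctr) * pixelSize
  r <- sqrt(outer(ax^2, ax^2, "+"))
  # smooth edge: full coverage inside R - w, none beyond R
  w <- max(2 * pixelSize, 0.05 * R)
  cov <- pmin(pmax((R - r) / w, 0), 1)
  alpha <- cov * cov * (3 - 2 * cov)  # smoothstep
  rings <- cos(2 * pi * nRings * r / R)
  img <- background + alpha * (-depth + contrast * background * rings)
  img <- pmin(pmax(img, 0), 255)
  new("Phantom", image = img, pixelSize = pixelSize,
      backgroundLevel = background)
}

# cumulative state (position, velocity) at the start of every segment,
# durations converted to seconds through the line rate
.profileStates <- function(profile, lineRate) {
  seg <- profile@segments
  tB <- c(0, cumsum(seg$duration)) / lineRate
  vx <- profile@initialVelocity@vx
  vy <- profile@initialVelocity@vy
  n <- nrow(seg)
  st <- data.frame(t0 = tB[seq_len(n)], x0 = NA_real_, y0 = NA_real_,
                   vx0 = NA_real_, vy0 = NA_real_, ax = seg$ax, ay = seg$ay,
                   dt = diff(tB))
  x <- 0; y <- 0
  for (i in seq_len(n)) {
    st$x0[i] <- x; st$y0[i] <- y; st$vx0[i] <- vx; st$vy0[i] <- vy
    d <- st$dt[i]
    x <- x + vx * d + 0.5 * seg$ax[i] * d^2
    y <- y + vy * d + 0.5 * seg$ay[i] * d^2
    vx <- vx + seg$ax[i] * d
    vy <- vy + seg$ay[i] * d
  }
  attr(st, "final") <- c(t = tB[n + 1L], x = x, y = y, vx = vx, vy = vy)
  if (min(st$vy0) <= 0 || attr(st, "final")["vy"] <= 0)
    stop("flow velocity must stay positive throughout the profile")
  st
}

#' Object displacement along a piecewise-constant-acceleration profile
#'
#' Exact piecewise-quadratic integration: within each segment
#' \eqn{s = s_0 + v\tau + a\tau^2/2}, with velocity continuous across
#' segment boundaries. Beyond the profile's total duration the final
#' velocity is held constant.
#'
#' @param profile a [MotionProfile()]
#' @param t time(s) in seconds, `t >= 0`
#' @param lineRate line rate (lines/s) used to convert segment durations
#'   from frames to seconds
#' @return matrix with columns `x`, `y`: displacement (um) since t = 0
#' @export
trajectoryPosition <- function(profile, t, lineRate) {
  if (any(t < 0)) stop("t must be non-negative")
  st <- .profileStates(profile, lineRate)
  fin <- attr(st, "final")
  idx <- findInterval(t, st$t0)        # >= 1 since t >= 0 = st$t0[1]
  tau <- t - st$t0[idx]
  x <- st$x0[idx] + st$vx0[idx] * tau + 0.5 * st$ax[idx] * tau^2
  y <- st$y0[idx] + st$vy0[idx] * tau + 0.5 * st$ay[idx] * tau^2
  over <- t > fin["t"]
  if (any(over)) {
    tau2 <- t[over] - fin["t"]
    x[over] <- fin["x"] + fin["vx"] * tau2
    y[over] <- fin["y"] + fin["vy"] * tau2
  }
  cbind(x = x, y = y)
}

#' @rdname trajectoryPosition
#' @return for `trajectoryVelocity`, matrix with columns `vx`, `vy` (um/s)
#' @export
trajectoryVelocity <- function(profile, t, lineRate) {
  if (any(t < 0)) stop("t must be non-negative")
  st <- .profileStates(profile, lineRate)
  fin <- attr(st, "final")
  idx <- findInterval(t, st$t0)
  tau <- pmin(t - st$t0[idx], st$dt[idx])
  cbind(vx = st$vx0[idx] + st$ax[idx] * tau,
        vy = st$vy0[idx] + st$ay[idx] * tau)
}

#' Sensor noise model parameters
#'
#' Fixed-pattern stripe noise of a line sensor (a per-column gain and
#' offset, stable over the acquisition) plus per-pixel additive Gaussian
#' read noise, with optional quantisation to integer DN.
#'
#' @param gainSd s.d. of the per-column multiplicative gain around 1
#' @param offsetSd s.d. of the per-column additive offset (DN)
#' @param readSd s.d. of the per-pixel read noise (DN)
#' @param quantize round the output to integer DN
#' @return a list understood by [acquireDualLineScan()]
#' @export
noiseSpec <- function(gainSd = 0.02, offsetSd = 2, readSd = 1,
                      quantize = TRUE) {
  stopifnot(gainSd >= 0, offsetSd >= 0, readSd >= 0)
  list(gainSd = gainSd, offsetSd = offsetSd, readSd = readSd,
       quantize = quantize)
}

#' @rdname noiseSpec
#' @export
zeroNoise <- function() noiseSpec(0, 0, 0, quantize = FALSE)

#' Default three-segment motion profile
#'
#' The study condition used throughout the package's validation: flow
#' along the channel at about 1.1 mm/s through three periods of
#' alternating-sign acceleration, all three spanning the object's transit
#' across the sensors. The speed scale (1.1-1.5 mm/s) and scan-frame
#' acceleration magnitudes match those observed for 20 um microspheres in
#' a microfluidic channel scanned at 1230 lines/s; the first period is
#' longer because it also covers the cell-free preamble before the object
#' reaches the first line.
#'
#' @param vy0 initial flow speed (um/s)
#' @param accels the three flow-direction accelerations (um/s^2)
#' @param durations frames per segment
#' @return a [MotionProfile()]
#' @export
defaultMotionProfile <- function(vy0 = 700,
                                 accels = c(3000, -5000, 3000),
                                 durations = c(160L, 55L, 120L)) {
  MotionProfile(Velocity2(0, vy0, "C1"),
                data.frame(duration = as.integer(durations),
                           ax = 0, ay = accels))
}

# first time the object point (Sx, Sy) [um, object coords] crosses the
# sensor line of `sensor`, by dense sampling of the trajectory + linear
# interpolation; returns time in seconds (NA if never within tMax)
.crossingTimeNumeric <- function(Sx, Sy, profile, cfg, sensor = 1L,
                                 tMax = NULL, dt = NULL) {
  f <- lineRate(cfg)
  th <- .deg2rad(tiltAngle(cfg))
  if (is.null(dt)) dt <- 1 / (20 * f)
  if (is.null(tMax)) {
    need <- Sy + Sx / tan(th) + (sensor == 2L) * sensorGap(cfg) / sin(th)
    vy0 <- profile@initialVelocity@vy
    tMax <- max(4 * abs(need) / vy0, sum(profile@segments$duration) / f) * 2
  }
  tt <- seq(0, tMax, by = dt)
  disp <- trajectoryPosition(profile, tt, f)
  need <- Sy + (Sx + disp[, "x"]) / tan(th) +
    (sensor == 2L) * sensorGap(cfg) / sin(th)
  h <- disp[, "y"] - need
  k <- which(h >= 0)[1]
  if (is.na(k)) return(NA_real_)
  if (k == 1L) return(tt[1])
  # linear interpolation of the sign change
  tt[k - 1L] + dt * (0 - h[k - 1L]) / (h[k] - h[k - 1L])
}

#' Simulate a dual line-scan acquisition
#'
#' Flows a phantom past the two tilted line sensors under a
#' piecewise-constant-acceleration motion profile and returns both
#' row-stacked streams plus the ground truth needed for validation. Each
#' sensor pixel point-samples the phantom (bilinear interpolation in the
#' phantom grid) at the object-frame location the pixel sees at that frame;
#' the second sensor line is the first displaced by the sensor gap along
#' the perpendicular approach direction, with column-aligned pixels.
#' Fixed-pattern stripe noise and read noise are applied per
#' [noiseSpec()].
#'
#' Frame r (0-based) is sampled at t = r / lineRate exactly. The object
#' coordinate origin is the point of the moving medium that crosses sensor
#' pixel 0 of the first line at frame 0; the phantom centre is reported in
#' these coordinates in the ground truth.
#'
#' @param phantom a [Phantom()]; its pixel size must not exceed the
#'   equivalent pixel size of `cfg`
#' @param profile a [MotionProfile()]
#' @param cfg a [SensorConfig()]
#' @param noise a [noiseSpec()]
#' @param seed integer seed for the noise draws
#' @param preambleFrames cell-free frames before the phantom reaches the
#'   first sensor (for background-model initialisation)
#' @param tailFrames extra frames after the phantom clears the second
#'   sensor
#' @param phantomCenterX lateral position of the phantom centre (um);
#'   default centres it on the overlap of the two sensors' lateral
#'   coverage
#' @param boxSample average over a pixel-footprint box (4-point
#'   supersampling) instead of point sampling
#' @return list with elements `stream1`, `stream2` ([LineScanStream-class])
#'   and `truth`: phantomCenter (um, object coords), crossingFrame1/2 of
#'   the centre, segmentBoundaryFrames, velocityByFrame (object frame),
#'   preambleFrames, truncated flag, and the inputs (cfg, profile, noise,
#'   seed)
#' @export
acquireDualLineScan <- function(phantom, profile, cfg,
                                noise = noiseSpec(), seed = 1L,
                                preambleFrames = 30L, tailFrames = 20L,
                                phantomCenterX = NULL,
                                boxSample = FALSE) {
  stopifnot(is(phantom, "Phantom"), is(profile, "MotionProfile"),
            is(cfg, "SensorConfig"))
  if (phantom@pixelSize > equivalentPixelSize(cfg))
    stop("phantom pixel size must not exceed the equivalent pixel size ",
         "(phantom must oversample the scan)")
  th <- .deg2rad(tiltAngle(cfg))
  d <- pixelPitch(cfg); gap <- sensorGap(cfg)
  f <- lineRate(cfg); L <- lineLength(cfg)
  p <- seq_len(L) - 1L
  img <- phantom@image
  psz <- phantom@pixelSize
  bg <- phantom@backgroundLevel
  halfExtent <- (ncol(img) - 1) / 2 * psz

  # lateral coverage: sensor 1 spans [0, (L-1) d sin], sensor 2 is shifted
  # by -gap cos(theta); centre the phantom on the overlap unless told not to
  lat1 <- c(0, (L - 1) * d * sin(th))
  lat2 <- lat1 - gap * cos(th)
  if (is.null(phantomCenterX))
    phantomCenterX <- (max(lat1[1], lat2[1]) + min(lat1[2], lat2[2])) / 2
  cx <- phantomCenterX

  # place the phantom far enough upstream for a cell-free preamble
  tPre <- preambleFrames / f
  sPre <- unname(trajectoryPosition(profile, tPre, f)[, "y"])
  cy <- halfExtent + sPre + 2 * equivalentPixelSize(cfg)

  truncated <- (cx - halfExtent) < max(lat1[1], lat2[1]) ||
    (cx + halfExtent) > min(lat1[2], lat2[2])
  if (truncated)
    warning("phantom extends laterally beyond the dual-sensor coverage; ",
            "streams are truncated")

  # frames until the farthest phantom corner has crossed sensor 2
  needMax <- (cy + halfExtent) + (cx + halfExtent) / tan(th) + gap / sin(th)
  tEnd <- .crossingTimeNumeric(cx + halfExtent, cy + halfExtent, profile,
                               cfg, sensor = 2L)
  if (is.na(tEnd))
    stop("profile too short/slow: phantom never clears the second sensor")
  total <- ceiling(tEnd * f) + as.integer(tailFrames)

  tt <- (seq_len(total) - 1L) / f
  disp <- trajectoryPosition(profile, tt, f)
  svx <- disp[, "x"]; sflow <- disp[, "y"]

  sampleSensor <- function(sensor) {
    off <- if (sensor == 2L) gap else 0
    # lab position of pixel p: p d (sin, cos) + off * (-cos, sin)
    labx <- p * d * sin(th) - off * cos(th)
    laby <- p * d * cos(th) + off * sin(th)
    # object coords seen by (frame i, pixel p)
    SX <- outer(-svx, labx, "+")        # total x L
    SY <- outer(sflow, -laby, "+")
    colc <- (SX - cx) / psz + (ncol(img) + 1) / 2
    rowc <- (SY - cy) / psz + (nrow(img) + 1) / 2
    if (boxSample) {
      h <- d / 4 / psz
      vals <- (bilinearSample(img, rowc - h, colc - h, bg) +
               bilinearSample(img, rowc - h, colc + h, bg) +
               bilinearSample(img, rowc + h, colc - h, bg) +
               bilinearSample(img, rowc + h, colc + h, bg)) / 4
    } else {
      vals <- bilinearSample(img, rowc, colc, bg)
    }
    matrix(vals, nrow = total, ncol = L)
  }

  clean1 <- sampleSensor(1L)
  clean2 <- sampleSensor(2L)

  set.seed(as.integer(seed))
  applyNoise <- function(m) {
    gains <- 1 + rnorm(L, 0, noise$gainSd)
    offs <- rnorm(L, 0, noise$offsetSd)
    m <- sweep(sweep(m, 2, gains, "*"), 2, offs, "+")
    if (noise$readSd > 0)
      m <- m + matrix(rnorm(length(m), 0, noise$readSd), nrow = nrow(m))
    if (isTRUE(noise$quantize)) m <- round(m)
    pmin(pmax(m, 0), 65535)
  }
  s1 <- applyNoise(clean1)
  s2 <- applyNoise(clean2)

  t1 <- .crossingTimeNumeric(cx, cy, profile, cfg, sensor = 1L)
  t2 <- .crossingTimeNumeric(cx, cy, profile, cfg, sensor = 2L)
  vel <- trajectoryVelocity(profile, tt, f)

  list(stream1 = LineScanStream(s1, "first", 0L),
       stream2 = LineScanStream(s2, "second", 0L),
       truth = list(
         phantomCenter = c(x = unname(cx), y = unname(cy)),
         crossingFrame1 = t1 * f, crossingFrame2 = t2 * f,
         segmentBoundaryFrames = cumsum(profile@segments$duration),
         velocityByFrame = data.frame(frame = seq_len(total) - 1L,
                                      vx = vel[, "vx"], vy = vel[, "vy"]),
         preambleFrames = preambleFrames, truncated = truncated,
         cfg = cfg, profile = profile, noise = noise, seed = seed,
         phantom = phantom))
}
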