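# Inverting the scan-time mapping: object coordinates -> (x'', y'') in the
# stacked line-scan image, under uniform-velocity, uniform-acceleration or
# piecewise variable-acceleration motion, followed by resampling.
#
# The crossing condition for object point (x, y) (object pixels) is the
# quadratic A y'^2 + B y' + C = 0 with A = a_y'/(2f), B = V_y' and
# C = -d f sin(theta) (y sin(theta) + x cos(theta)); the scan-frame
# components absorb lateral motion exactly, so the same quadratic holds
# for drifting objects.

#' Analytic crossing frame of an object point
#'
#' Smallest non-negative real root of the crossing quadratic for a single
#' constant-acceleration motion; with zero acceleration it degrades to the
#' linear solution y' = -C/B.
#'
#' @param x,y object-frame pixel coordinates (vectors allowed)
#' @param v scan-frame [Velocity2()] ("C2")
#' @param a scan-frame [Accel2()] ("C2")
#' @param cfg a [SensorConfig()]
#' @return data.frame: `yPrime` (frames) and `valid` (FALSE when the
#'   discriminant is negative or both roots are negative: the point never
#'   crosses)
#' @export
solveCrossingFrame <- function(x, y, v, a, cfg) {
  .frameCheck(v, "C2"); .frameCheck(a, "C2")
  th <- .deg2rad(tiltAngle(cfg))
  f <- lineRate(cfg); d <- pixelPitch(cfg)
  A <- a@ay / (2 * f)
  B <- v@vy
  C <- -d * f * sin(th) * (y * sin(th) + x * cos(th))
  n <- max(length(x), length(y))
  C <- rep_len(C, n)
  yp <- rep(NA_real_, n); ok <- rep(FALSE, n)
  if (A == 0) {
    if (B <= 0) stop("need V_y' > 0 or a_y' > 0 for a crossing")
    yp <- -C / B
    ok <- yp >= 0
  } else {
    disc <- B^2 - 4 * A * C
    real <- disc >= 0
    r1 <- (-B + sqrt(pmax(disc, 0))) / (2 * A)
    r2 <- (-B - sqrt(pmax(disc, 0))) / (2 * A)
    lo <- pmin(r1, r2); hi <- pmax(r1, r2)
    first <- ifelse(lo >= 0, lo, hi)      # smallest non-negative root
    ok <- real & first >= 0
    yp[ok] <- first[ok]
  }
  yp[!ok] <- NA_real_
  data.frame(yPrime = yp, valid = ok)
}

#' Lateral scan coordinate of an object point
#'
#' \deqn{x' = x + y'(V_x + a_x y'/(2f)) / (d f \sin\theta)} with
#' \eqn{(V_x, a_x)} the object-frame lateral components: an object
#' drifting sideways while approaching the line lands on a shifted pixel.
#'
#' @param x object-frame abscissa (pixels)
#' @param yPrime crossing frame(s)
#' @param v object-frame [Velocity2()] ("C1")
#' @param a object-frame [Accel2()] ("C1")
#' @param cfg a [SensorConfig()]
#' @return scan abscissa x' (pixels)
#' @export
lateralScanCoordinate <- function(x, yPrime, v, a, cfg) {
  .frameCheck(v, "C1"); .frameCheck(a, "C1")
  if (any(yPrime < 0, na.rm = TRUE)) stop("yPrime must be non-negative")
  th <- .deg2rad(tiltAngle(cfg))
  f <- lineRate(cfg); d <- pixelPitch(cfg)
  x + yPrime * (v@vx + a@ax * yPrime / (2 * f)) / (d * f * sin(th))
}

# Per-segment scan-frame motion profile for reconstruction.
# Rows cover [startFrame_i, startFrame_{i+1}): scan-frame speed v and
# acceleration a, object-frame lateral vxObj/axObj, and the cumulative
# scan distance (um) and lateral displacement (um) at the row's start.
# Before the first feature the first measured velocity is held constant;
# after the last, the last one.
.buildScanProfile <- function(kin, cfg, model, frameOffset = 0L) {
  feats <- featureTable(kin)
  if (nrow(feats) == 0L)
    stop("empty kinematics table: supply a velocity explicitly")
  f <- lineRate(cfg)
  # velocities are attributed at mid-transit (their exact estimand under
  # constant acceleration); fall back to the first-sensor frame
  yRef <- if (!is.null(feats$yMid)) feats$yMid else feats$y1
  yF <- yRef - 1 + frameOffset              # 0-based absolute frames
  model <- match.arg(model, c("variable_acceleration", "uniform_velocity",
                              "uniform_acceleration"))
  if (model == "uniform_velocity" || nrow(feats) == 1L) {
    pr <- data.frame(startFrame = 0, v = mean(feats$vyp), a = 0,
                     vxObj = mean(feats$vx), axObj = 0)
  } else if (model == "uniform_acceleration") {
    tSec <- yF / f
    fit <- lm(feats$vyp ~ tSec)
    fitX <- lm(feats$vx ~ tSec)   # lateral fitted on the object frame
    pr <- data.frame(startFrame = 0, v = unname(coef(fit)[1]),
                     a = unname(coef(fit)[2]),
                     vxObj = unname(coef(fitX)[1]),
                     axObj = unname(coef(fitX)[2]))
  } else {
    acc <- accelerationTable(kin)
    k <- nrow(feats)
    aS <- ifelse(is.finite(acc$ayp), acc$ayp, 0)
    aL <- ifelse(is.finite(acc$ax), acc$ax, 0)
    # before the first and after the last feature the nearest measured
    # velocity is held constant: extrapolating a (noisy) edge
    # acceleration over the long unobserved pre-span amplifies its error
    # quadratically in time
    pr <- data.frame(
      startFrame = c(0, yF),
      v = c(feats$vyp[1], feats$vyp),
      a = c(0, aS, 0),
      vxObj = c(feats$vx[1], feats$vx),
      axObj = c(0, aL, 0))
    pr <- pr[!duplicated(pr$startFrame), , drop = FALSE]
  }
  if (any(pr$v <= 0))
    stop("non-positive scan-frame speed: flow reversal is not supported")
  # accumulate distance/lateral displacement at segment starts
  n <- nrow(pr)
  pr$cumS <- 0; pr$cumLat <- 0
  if (n > 1L) {
    dt <- diff(pr$startFrame) / f
    dS <- pr$v[-n] * dt + 0.5 * pr$a[-n] * dt^2
    dL <- pr$vxObj[-n] * dt + 0.5 * pr$axObj[-n] * dt^2
    pr$cumS <- c(0, cumsum(dS))
    pr$cumLat <- c(0, cumsum(dL))
  }
  pr
}

# cumulative scan distance (um) at an absolute frame
.scanDistanceAtFrame <- function(profile, frame, lineRate) {
  idx <- pmax(findInterval(frame, profile$startFrame), 1L)
  tau <- (frame - profile$startFrame[idx]) / lineRate
  profile$cumS[idx] + profile$v[idx] * tau + 0.5 * profile$a[idx] * tau^2
}

#' Segment boundaries of the piecewise motion in object coordinates
#'
#' Integrates the measured piecewise velocity to the cumulative scan-frame
#' distance S' at every feature frame and converts it to the object-frame
#' boundary intercept b_y = S' / (d sin^2 theta): the sensor line at
#' feature i satisfies y = -x/tan(theta) + b_yi.
#'
#' @param kin a [KinematicsTable-class] with at least 2 features
#' @param cfg a [SensorConfig()]
#' @param frameOffset 0-based frame of foreground row 1 (aligns feature
#'   ordinates, which are foreground-row indices, with the acquisition
#'   timeline)
#' @return a [SegmentBoundaries-class]
#' @export
computeSegmentBoundaries <- function(kin, cfg, frameOffset = 0L) {
  feats <- featureTable(kin)
  if (nrow(feats) < 2L) stop("need at least 2 features")
  th <- .deg2rad(tiltAngle(cfg))
  pr <- .buildScanProfile(kin, cfg, "variable_acceleration", frameOffset)
  yRef <- if (!is.null(feats$yMid)) feats$yMid else feats$y1
  yF <- yRef - 1 + frameOffset
  S <- .scanDistanceAtFrame(pr, yF, lineRate(cfg))
  if (is.unsorted(S, strictly = TRUE))
    stop("cumulative scan distance is not strictly increasing ",
         "(implied flow reversal)")
  new("SegmentBoundaries", featureFrames = as.numeric(yF),
      scanDistance = S,
      intercepts = S / (pixelPitch(cfg) * sin(th)^2),
      profile = pr)
}

#' Acceleration-segment index of an object point
#'
#' Returns i such that b_yi < x/tan(theta) + y <= b_y(i+1), with segment 0
#' the region before the first boundary and points beyond the last
#' boundary assigned to the last segment. A point exactly on a boundary
#' belongs to the earlier segment (closed upper bound).
#'
#' @param x,y object-frame pixel coordinates
#' @param boundaries a [SegmentBoundaries-class]
#' @param cfg a [SensorConfig()]
#' @return integer segment index, 0-based (0 = before the first feature)
#' @export
assignAcceleration <- function(x, y, boundaries, cfg) {
  th <- .deg2rad(tiltAngle(cfg))
  u <- y + x * cos(th) / sin(th)
  idx <- findInterval(u, boundaries@intercepts, left.open = TRUE)
  pmin(idx, length(boundaries@intercepts) - 1L)
}

#' Map object coordinates to absolute scan coordinates
#'
#' Solves, per point, the crossing quadratic of its acceleration segment
#' using the residual scan distance after subtracting the distance covered
#' by all earlier segments; the absolute scan ordinate y'' accumulates the
#' earlier segments' frame spans, and x'' adds the cumulative lateral
#' drift.
#'
#' @param x,y object-frame pixel coordinates (vectors)
#' @param boundaries a [SegmentBoundaries-class]
#' @param cfg a [SensorConfig()]
#' @return data.frame: `xpp`, `ypp` (scan pixels / frames, 0-based),
#'   `valid`
#' @export
mapObjectToScan <- function(x, y, boundaries, cfg) {
  pr <- boundaries@profile
  th <- .deg2rad(tiltAngle(cfg))
  f <- lineRate(cfg); d <- pixelPitch(cfg)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  u <- y + x * cos(th) / sin(th)
  Sreq <- u * d * sin(th)^2
  seg <- pmax(findInterval(Sreq, pr$cumS, left.open = TRUE), 1L)
  R <- Sreq - pr$cumS[seg]
  v <- pr$v[seg]; a <- pr$a[seg]
  tau <- rep(NA_real_, n)
  lin <- a == 0
  tau[lin] <- R[lin] / v[lin]
  if (any(!lin)) {
    disc <- v[!lin]^2 + 2 * a[!lin] * R[!lin]
    tq <- ifelse(disc >= 0,
                 (-v[!lin] + sqrt(pmax(disc, 0))) / a[!lin], NA_real_)
    tau[!lin] <- tq
  }
  valid <- is.finite(tau) & tau >= -1e-12 & u >= 0
  tau[!valid] <- NA_real_
  ypp <- pr$startFrame[seg] + tau * f
  lat <- pr$cumLat[seg] + pr$vxObj[seg] * tau +
    0.5 * pr$axObj[seg] * tau^2
  xpp <- x + lat / (d * sin(th))
  data.frame(xpp = xpp, ypp = ypp, valid = valid)
}

#' Reconstruct the object-frame image from a foreground stream
#'
#' Allocates an object grid at the equivalent pixel size d sin(theta),
#' maps every grid pixel into the stacked scan image under the chosen
#' motion model, and interpolates the foreground intensities there.
#' `uniform_velocity` uses the mean measured scan-frame velocity,
#' `uniform_acceleration` a single least-squares (V', a') fit to the
#' velocity series, and `variable_acceleration` the full piecewise model.
#'
#' @param fg a [ForegroundStream-class] from the first sensor (or a signed
#'   matrix, in which case `frameOffset` should be given)
#' @param kin a [KinematicsTable-class] from the same capture; may be
#'   empty only for `uniform_velocity` with `velocity` supplied
#' @param cfg a [SensorConfig()]
#' @param model motion model
#' @param velocity optional scan-frame [Velocity2()] overriding the
#'   kinematics (required when `kin` is empty)
#' @param interpolation "bilinear" or "nearest"
#' @param background fill value for invalid pixels
#' @param yMax object-grid extent along the flow (pixels); default spans
#'   the full foreground stream
#' @param frameOffset frame of row 1 when `fg` is a plain matrix
#' @return a [ReconstructionGrid-class]
#' @export
reconstructImage <- function(fg, kin, cfg,
                             model = c("variable_acceleration",
                                       "uniform_velocity",
                                       "uniform_acceleration"),
                             velocity = NULL,
                             interpolation = c("bilinear", "nearest"),
                             background = 0, yMax = NULL,
                             frameOffset = NULL) {
  model <- match.arg(model)
  interpolation <- match.arg(interpolation)
  img <- if (is(fg, "ForegroundStream")) differenceImage(fg) else
    as.matrix(fg)
  off <- if (is(fg, "ForegroundStream")) frameOffset(fg) else
    if (is.null(frameOffset)) 0L else as.integer(frameOffset)
  th <- .deg2rad(tiltAngle(cfg))
  f <- lineRate(cfg); d <- pixelPitch(cfg)

  empty <- is.null(kin) || nrow(featureTable(kin)) == 0L
  if (empty) {
    if (model != "uniform_velocity" || is.null(velocity))
      stop("empty kinematics: only uniform_velocity with an explicit ",
           "velocity is possible")
  }
  if (!is.null(velocity)) {
    .frameCheck(velocity, "C2")
    vObj <- velocityToObjectFrame(velocity, cfg)
    pr <- data.frame(startFrame = 0, v = velocity@vy, a = 0,
                     vxObj = vObj@vx, axObj = 0, cumS = 0, cumLat = 0)
  } else {
    pr <- .buildScanProfile(kin, cfg, model, off)
  }
  bnd <- new("SegmentBoundaries",
             featureFrames = pr$startFrame,
             scanDistance = pr$cumS,
             intercepts = pr$cumS / (d * sin(th)^2),
             profile = pr)

  lastFrame <- off + nrow(img) - 1L
  Send <- .scanDistanceAtFrame(pr, lastFrame, f)
  uEnd <- Send / (d * sin(th)^2)
  if (is.null(yMax)) yMax <- floor(uEnd + 1e-9)
  nx <- lineLength(cfg)
  gx <- rep(seq_len(nx) - 1L, each = yMax + 1L)
  gy <- rep(0:yMax, times = nx)
  mp <- mapObjectToScan(gx, gy, bnd, cfg)

  rows <- mp$ypp - off + 1
  cols <- mp$xpp + 1
  # tolerate floating-point dust at the image boundary
  eps <- 1e-6
  inRange <- !is.na(rows) & !is.na(cols) &
    rows >= 1 - eps & rows <= nrow(img) + eps &
    cols >= 1 - eps & cols <= ncol(img) + eps
  rows <- pmin(pmax(rows, 1), nrow(img))
  cols <- pmin(pmax(cols, 1), ncol(img))
  vals <- if (interpolation == "bilinear")
    bilinearSample(img, rows, cols, background)
  else nearestSample(img, rows, cols, background)
  ok <- mp$valid & inRange
  vals[!ok] <- background
  new("ReconstructionGrid",
      image = matrix(vals, nrow = yMax + 1L, ncol = nx),
      valid = matrix(ok, nrow = yMax + 1L, ncol = nx),
      pixelSize = equivalentPixelSize(cfg), model = model)
}
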