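#' Dual line-array sensor configuration
#'
#' Geometry and timing of the tilted dual line-array: the pixel pitch along
#' each line, the perpendicular spacing between the two parallel lines, the
#' acute tilt angle between the lines and the flow direction, the line rate
#' and the number of pixels per line. All lengths are in micrometres, angles
#' in degrees, rates in lines per second.
#'
#' @slot pixelPitch pixel spacing along the line sensor (um)
#' @slot sensorGap perpendicular spacing between the two lines (um)
#' @slot tiltAngle acute angle between sensor line and flow direction (deg)
#' @slot lineRate acquisition rate (lines/s)
#' @slot lineLength pixels per line
#' @aliases SensorConfig-class
#' @exportClass SensorConfig
setClass("SensorConfig",
  slots = c(pixelPitch = "numeric", sensorGap = "numeric",
            tiltAngle = "numeric", lineRate = "numeric",
            lineLength = "integer"))

setValidity("SensorConfig", function(object) {
  msg <- character()
  if (length(object@pixelPitch) != 1 || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a single positive number")
  if (length(object@sensorGap) != 1 || !is.finite(object@sensorGap) ||
      object@sensorGap <= 0)
    msg <- c(msg, "sensorGap must be a single positive number")
  if (length(object@tiltAngle) != 1 || !is.finite(object@tiltAngle) ||
      object@tiltAngle <= 0 || object@tiltAngle > 90)
    msg <- c(msg, "tiltAngle must be in (0, 90] degrees")
  if (length(object@lineRate) != 1 || !is.finite(object@lineRate) ||
      object@lineRate <= 0)
    msg <- c(msg, "lineRate must be a single positive number")
  if (length(object@lineLength) != 1 || is.na(object@lineLength) ||
      object@lineLength < 2L)
    msg <- c(msg, "lineLength must be at least 2")
  if (length(msg)) msg else TRUE
})

#' Create a sensor configuration
#'
#' Defaults mirror a 2.2 um pitch area sensor read out as two line windows at
#' 1230 lines/s with a 21 degree tilt; the gap defaults to six pixel pitches.
#'
#' @param pixelPitch pixel pitch along the line (um)
#' @param sensorGap perpendicular line spacing (um)
#' @param tiltAngle tilt angle (degrees, in (0, 90])
#' @param lineRate line rate (lines/s)
#' @param lineLength pixels per line
#' @return a [SensorConfig-class] object
#' @examples
#' cfg <- SensorConfig()
#' equivalentPixelSize(cfg)
#' @export
SensorConfig <- function(pixelPitch = 2.2, sensorGap = 6 * pixelPitch,
                         tiltAngle = 21, lineRate = 1230,
                         lineLength = 88L) {
  new("SensorConfig", pixelPitch = as.numeric(pixelPitch),
      sensorGap = as.numeric(sensorGap), tiltAngle = as.numeric(tiltAngle),
      lineRate = as.numeric(lineRate), lineLength = as.integer(lineLength))
}

#' Two-component velocity with a coordinate-frame tag
#'
#' Frame "C1" is the object frame (x perpendicular to the channel, y along
#' the flow); frame "C2" is the scan frame (x' along the sensor line, y'
#' along the perpendicular approach direction). Units um/s.
#'
#' @slot vx,vy velocity components (um/s)
#' @slot frame "C1" or "C2"
#' @aliases Velocity2-class
#' @exportClass Velocity2
setClass("Velocity2",
  slots = c(vx = "numeric", vy = "numeric", frame = "character"))

setValidity("Velocity2", function(object) {
  if (!identical(length(object@frame), 1L) ||
      !object@frame %in% c("C1", "C2"))
    return("frame must be exactly one of 'C1', 'C2'")
  if (!is.finite(object@vx) || !is.finite(object@vy))
    return("velocity components must be finite")
  TRUE
})

#' @rdname Velocity2-class
#' @param vx,vy components (um/s)
#' @param frame "C1" (object frame) or "C2" (scan frame)
#' @export
Velocity2 <- function(vx, vy, frame = c("C1", "C2")) {
  new("Velocity2", vx = as.numeric(vx), vy = as.numeric(vy),
      frame = match.arg(frame))
}

#' Two-component acceleration with a coordinate-frame tag
#'
#' Same frame convention as [Velocity2()]; units um/s^2.
#'
#' @slot ax,ay acceleration components (um/s^2)
#' @slot frame "C1" or "C2"
#' @aliases Accel2-class
#' @exportClass Accel2
setClass("Accel2",
  slots = c(ax = "numeric", ay = "numeric", frame = "character"))

setValidity("Accel2", function(object) {
  if (!identical(length(object@frame), 1L) ||
      !object@frame %in% c("C1", "C2"))
    return("frame must be exactly one of 'C1', 'C2'")
  if (!is.finite(object@ax) || !is.finite(object@ay))
    return("acceleration components must be finite")
  TRUE
})

#' @rdname Accel2-class
#' @param ax,ay components (um/s^2)
#' @param frame "C1" or "C2"
#' @export
Accel2 <- function(ax, ay, frame = c("C1", "C2")) {
  new("Accel2", ax = as.numeric(ax), ay = as.numeric(ay),
      frame = match.arg(frame))
}

#' Ordered line-scan rows from one sensor
#'
#' Row r of `rows` is the line read at frame `frameOffset + r - 1` (frames
#' are 0-based); columns are sensor pixels, column 1 nearest the intersection
#' of the sensor line with the flow axis.
#'
#' @slot rows frames x pixels intensity matrix
#' @slot sensorId "first" or "second"
#' @slot frameOffset 0-based frame index of the first row
#' @aliases LineScanStream-class
#' @exportClass LineScanStream
setClass("LineScanStream",
  slots = c(rows = "matrix", sensorId = "character",
            frameOffset = "integer"))

setValidity("LineScanStream", function(object) {
  msg <- character()
  if (!object@sensorId %in% c("first", "second"))
    msg <- c(msg, "sensorId must be 'first' or 'second'")
  if (nrow(object@rows) < 1L)
    msg <- c(msg, "stream must contain at least one row")
  if (length(msg)) msg else TRUE
})

#' @rdname LineScanStream-class
#' @param rows frames x pixels matrix
#' @param sensorId "first" or "second"
#' @param frameOffset 0-based index of the first frame
#' @export
LineScanStream <- function(rows, sensorId = "first", frameOffset = 0L) {
  new("LineScanStream", rows = as.matrix(rows), sensorId = sensorId,
      frameOffset = as.integer(frameOffset))
}

#' Piecewise-constant-acceleration motion profile
#'
#' The object enters with `initialVelocity` (object frame) and then runs
#' through the listed segments, each holding a constant acceleration for an
#' integer number of frames. Beyond the last segment the final velocity is
#' held constant.
#'
#' @slot initialVelocity a [Velocity2-class] tagged "C1"
#' @slot segments data.frame with columns `duration` (frames), `ax`, `ay`
#'   (um/s^2, object frame)
#' @aliases MotionProfile-class
#' @exportClass MotionProfile
setClass("MotionProfile",
  slots = c(initialVelocity = "Velocity2", segments = "data.frame"))

setValidity("MotionProfile", function(object) {
  msg <- character()
  if (object@initialVelocity@frame != "C1")
    msg <- c(msg, "initialVelocity must be tagged C1")
  s <- object@segments
  if (nrow(s) < 1L)
    msg <- c(msg, "at least one segment is required")
  if (!all(c("duration", "ax", "ay") %in% names(s)))
    msg <- c(msg, "segments needs columns duration, ax, ay")
  else if (any(s$duration <= 0) || any(s$duration != round(s$duration)))
    msg <- c(msg, "segment durations must be positive integers (frames)")
  if (length(msg)) msg else TRUE
})

#' @rdname MotionProfile-class
#' @param initialVelocity object-frame [Velocity2()]
#' @param segments data.frame(duration, ax, ay)
#' @export
MotionProfile <- function(initialVelocity, segments) {
  new("MotionProfile", initialVelocity = initialVelocity,
      segments = as.data.frame(segments))
}

#' Rendered phantom object
#'
#' A 2-D intensity grid standing in for the diffraction pattern of a
#' flowing microsphere, together with its own sampling pitch and the
#' surrounding background level.
#'
#' @slot image intensity matrix (rows = y, cols = x)
#' @slot pixelSize phantom sampling pitch (um)
#' @slot backgroundLevel intensity outside the object
#' @aliases Phantom-class
#' @exportClass Phantom
setClass("Phantom",
  slots = c(image = "matrix", pixelSize = "numeric",
            backgroundLevel = "numeric"))

setValidity("Phantom", function(object) {
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  if (any(!is.finite(object@image))) return("image must be finite")
  TRUE
})

#' Foreground stream extracted from a line-scan stream
#'
#' Signed per-column differences against the running background model, plus
#' the binary background mask (1 = background) used to gate the model
#' update. Row r corresponds to frame `frameOffset + r - 1`.
#'
#' @slot difference frames x pixels signed difference matrix (EP')
#' @slot mask frames x pixels 0/1 matrix (1 = background)
#' @slot frameOffset 0-based frame of the first emitted row
#' @slot params list(N, T1, T2) used for extraction
#' @aliases ForegroundStream-class
#' @exportClass ForegroundStream
setClass("ForegroundStream",
  slots = c(difference = "matrix", mask = "matrix",
            frameOffset = "integer", params = "list"))

setValidity("ForegroundStream", function(object) {
  if (!identical(dim(object@difference), dim(object@mask)))
    return("difference and mask must have identical dimensions")
  if (!all(object@mask %in% c(0, 1)))
    return("mask entries must be 0 or 1")
  TRUE
})

#' Matched-feature kinematics
#'
#' Per-feature matched coordinates on the two sensors with scan-frame and
#' object-frame velocities, plus the K-1 finite-difference accelerations
#' between consecutive features.
#'
#' @slot features data.frame: featureId, x1, y1, x2, y2, ssd, vxp, vyp,
#'   vx, vy (p = scan frame; plain = object frame)
#' @slot accelerations data.frame: yStart, yEnd, axp, ayp, ax, ay
#' @slot config the [SensorConfig-class] used
#' @aliases KinematicsTable-class
#' @exportClass KinematicsTable
setClass("KinematicsTable",
  slots = c(features = "data.frame", accelerations = "data.frame",
            config = "SensorConfig"))

setValidity("KinematicsTable", function(object) {
  k <- nrow(object@features)
  if (k >= 1L && nrow(object@accelerations) != k - 1L)
    return("a table of K features must carry exactly K-1 accelerations")
  TRUE
})

#' Piecewise-motion segment boundaries for reconstruction
#'
#' Cumulative scan-frame distances at the feature frames and the
#' object-frame boundary intercepts b_y = S'/(d sin^2 theta), together with
#' the full per-segment profile used by [mapObjectToScan()].
#'
#' @slot featureFrames frames (sensor 1) of the K features
#' @slot scanDistance cumulative scan-frame distance S' at those frames (um)
#' @slot intercepts boundary intercepts b_y (object pixels)
#' @slot profile data.frame: startFrame, v, a (scan frame, um/s, um/s^2),
#'   vxObj, axObj (object-frame lateral), cumS (um), cumLat (um)
#' @aliases SegmentBoundaries-class
#' @exportClass SegmentBoundaries
setClass("SegmentBoundaries",
  slots = c(featureFrames = "numeric", scanDistance = "numeric",
            intercepts = "numeric", profile = "data.frame"))

setValidity("SegmentBoundaries", function(object) {
  if (is.unsorted(object@intercepts, strictly = TRUE))
    return("boundary intercepts must be strictly increasing")
  if (is.unsorted(object@scanDistance, strictly = TRUE))
    return("cumulative scan distances must be strictly increasing")
  TRUE
})

#' Reconstructed object-frame image
#'
#' @slot image object-frame intensity grid (rows = y, cols = x)
#' @slot valid logical matrix marking pixels with a real, in-range crossing
#' @slot pixelSize equivalent pixel size d sin(theta) (um)
#' @slot model motion model used ("uniform_velocity",
#'   "uniform_acceleration" or "variable_acceleration")
#' @aliases ReconstructionGrid-class
#' @exportClass ReconstructionGrid
setClass("ReconstructionGrid",
  slots = c(image = "matrix", valid = "matrix", pixelSize = "numeric",
            model = "character"))

setValidity("ReconstructionGrid", function(object) {
  if (!identical(dim(object@image), dim(object@valid)))
    return("image and valid must have identical dimensions")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})
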