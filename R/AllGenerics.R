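# Accessor generics and show methods for the core classes.

#' @describeIn SensorConfig-class pixel pitch (um)
#' @param object,x a class instance
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
setMethod("pixelPitch", "SensorConfig", function(object) object@pixelPitch)

#' @describeIn SensorConfig-class perpendicular sensor gap (um)
#' @export
setGeneric("sensorGap", function(object) standardGeneric("sensorGap"))
setMethod("sensorGap", "SensorConfig", function(object) object@sensorGap)

#' @describeIn SensorConfig-class tilt angle (degrees)
#' @export
setGeneric("tiltAngle", function(object) standardGeneric("tiltAngle"))
setMethod("tiltAngle", "SensorConfig", function(object) object@tiltAngle)

#' @describeIn SensorConfig-class line rate (lines/s)
#' @export
setGeneric("lineRate", function(object) standardGeneric("lineRate"))
setMethod("lineRate", "SensorConfig", function(object) object@lineRate)

#' @describeIn SensorConfig-class pixels per line
#' @export
setGeneric("lineLength", function(object) standardGeneric("lineLength"))
setMethod("lineLength", "SensorConfig", function(object) object@lineLength)

setMethod("show", "SensorConfig", function(object) {
  cat("SensorConfig: pitch", object@pixelPitch, "um, gap",
      object@sensorGap, "um, tilt", object@tiltAngle, "deg,",
      object@lineRate, "lines/s,", object@lineLength, "px/line\n")
  cat("  equivalent pixel size:",
      signif(object@pixelPitch * sin(.deg2rad(object@tiltAngle)), 4),
      "um\n")
  invisible(object)
})

setMethod("show", "Velocity2", function(object) {
  cat(sprintf("Velocity2[%s] (%.4g, %.4g) um/s\n",
              object@frame, object@vx, object@vy))
  invisible(object)
})

setMethod("show", "Accel2", function(object) {
  cat(sprintf("Accel2[%s] (%.4g, %.4g) um/s^2\n",
              object@frame, object@ax, object@ay))
  invisible(object)
})

#' @describeIn LineScanStream-class intensity rows (frames x pixels)
#' @export
setGeneric("streamRows", function(object) standardGeneric("streamRows"))
setMethod("streamRows", "LineScanStream", function(object) object@rows)

#' @describeIn LineScanStream-class number of frames
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
setMethod("nFrames", "LineScanStream", function(object) nrow(object@rows))

#' @describeIn LineScanStream-class 0-based frame index of the first row
#' @export
setGeneric("frameOffset", function(object) standardGeneric("frameOffset"))
setMethod("frameOffset", "LineScanStream",
          function(object) object@frameOffset)
setMethod("frameOffset", "ForegroundStream",
          function(object) object@frameOffset)

setMethod("show", "LineScanStream", function(object) {
  cat("LineScanStream (", object@sensorId, "): ", nrow(object@rows),
      " frames x ", ncol(object@rows), " px, first frame ",
      object@frameOffset, "\n", sep = "")
  invisible(object)
})

#' @describeIn ForegroundStream-class signed difference image (EP')
#' @export
setGeneric("differenceImage",
           function(object) standardGeneric("differenceImage"))
setMethod("differenceImage", "ForegroundStream",
          function(object) object@difference)

#' @describeIn ForegroundStream-class background mask (1 = background)
#' @export
setGeneric("maskImage", function(object) standardGeneric("maskImage"))
setMethod("maskImage", "ForegroundStream", function(object) object@mask)

setMethod("show", "ForegroundStream", function(object) {
  cat("ForegroundStream: ", nrow(object@difference), " frames x ",
      ncol(object@difference), " px (N=", object@params$N, ", T=[",
      object@params$T1, ",", object@params$T2, "]), ",
      round(100 * mean(object@mask == 0), 1), "% foreground\n", sep = "")
  invisible(object)
})

#' @describeIn KinematicsTable-class per-feature table
#' @export
setGeneric("featureTable", function(object) standardGeneric("featureTable"))
setMethod("featureTable", "KinematicsTable", function(object) object@features)

#' @describeIn KinematicsTable-class per-gap acceleration table
#' @export
setGeneric("accelerationTable",
           function(object) standardGeneric("accelerationTable"))
setMethod("accelerationTable", "KinematicsTable",
          function(object) object@accelerations)

setMethod("show", "KinematicsTable", function(object) {
  k <- nrow(object@features)
  cat("KinematicsTable:", k, "features,", nrow(object@accelerations),
      "accelerations\n")
  if (k > 0) {
    cat(sprintf("  Vy' range %.1f..%.1f um/s\n",
                min(object@features$vyp), max(object@features$vyp)))
  }
  invisible(object)
})

#' @describeIn ReconstructionGrid-class reconstructed image
#' @export
setGeneric("reconImage", function(object) standardGeneric("reconImage"))
setMethod("reconImage", "ReconstructionGrid", function(object) object@image)

#' @describeIn ReconstructionGrid-class validity mask
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
setMethod("validMask", "ReconstructionGrid", function(object) object@valid)

#' @describeIn ReconstructionGrid-class equivalent pixel size (um)
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
setMethod("pixelSize", "ReconstructionGrid", function(object) object@pixelSize)
setMethod("pixelSize", "Phantom", function(object) object@pixelSize)

#' @describeIn Phantom-class phantom intensity image
#' @export
setGeneric("phantomImage", function(object) standardGeneric("phantomImage"))
setMethod("phantomImage", "Phantom", function(object) object@image)

setMethod("show", "Phantom", function(object) {
  cat("Phantom: ", nrow(object@image), "x", ncol(object@image), " px at ",
      object@pixelSize, " um/px, background ", object@backgroundLevel,
      "\n", sep = "")
  invisible(object)
})

setMethod("show", "ReconstructionGrid", function(object) {
  cat("ReconstructionGrid (", object@model, "): ", nrow(object@image), "x",
      ncol(object@image), " px at ", signif(object@pixelSize, 4),
      " um/px, ", round(100 * mean(object@valid), 1), "% valid\n",
      sep = "")
  invisible(object)
})

setMethod("show", "SegmentBoundaries", function(object) {
  cat("SegmentBoundaries:", length(object@intercepts),
      "boundaries, intercept range",
      paste(signif(range(object@intercepts), 4), collapse = ".."), "\n")
  invisible(object)
})

setMethod("show", "MotionProfile", function(object) {
  cat("MotionProfile: V0 = (", object@initialVelocity@vx, ",",
      object@initialVelocity@vy, ") um/s,", nrow(object@segments),
      "segments,", sum(object@segments$duration), "frames\n")
  invisible(object)
})
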