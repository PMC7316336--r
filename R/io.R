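# Readers/writers for line-scan streams and run configuration.
#
# Streams travel as row-stacked grayscale TIFF (16-bit by default) or PNG,
# or as raw binary with a JSON sidecar declaring shape and dtype.

#' Write a line-scan stream to disk
#'
#' TIFF output is 16-bit grayscale (lossless for integer DN up to 65535);
#' a `<path>.json` sidecar records sensor id and frame offset. Signed
#' float matrices (e.g. foreground differences) can be written as 32-bit
#' float TIFF with `bits = 32`.
#'
#' @param stream a [LineScanStream()] or numeric matrix
#' @param path output path ending in .tif/.tiff or .png
#' @param bits 8, 16 (integer) or 32 (float TIFF)
#' @return the path, invisibly
#' @export
writeLineScan <- function(stream, path, bits = 16) {
  m <- if (is(stream, "LineScanStream")) streamRows(stream) else
    as.matrix(stream)
  ext <- tolower(tools::file_ext(path))
  offset <- 0; scaleF <- 1
  if (ext %in% c("tif", "tiff")) {
    if (bits == 32) {
      # float TIFF is only defined on [0,1]: store normalised, record the
      # affine restore coefficients in the sidecar
      rng <- range(m)
      offset <- rng[1]
      scaleF <- if (diff(rng) > 0) diff(rng) else 1
      tiff::writeTIFF((m - offset) / scaleF, path, bits.per.sample = 32L)
    } else {
      scale <- 2^bits - 1
      if (min(m) < 0 || max(m) > scale)
        stop("integer TIFF requires values in [0, ", scale, "]")
      tiff::writeTIFF(m / scale, path, bits.per.sample = as.integer(bits))
    }
  } else if (ext == "png") {
    scale <- 2^bits - 1
    if (bits > 16) stop("PNG supports 8 or 16 bits")
    png::writePNG(m / scale, path)
  } else {
    stop("unsupported image format: ", ext)
  }
  meta <- list(bits = bits)
  if (bits == 32) meta <- c(meta, list(offset = offset, scale = scaleF))
  if (is(stream, "LineScanStream"))
    meta <- c(meta, list(sensor_id = stream@sensorId,
                         frame_offset = stream@frameOffset))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a line-scan stream
#'
#' Accepts TIFF/PNG written by [writeLineScan()] (the sidecar restores
#' sensor id and frame offset) or a raw binary file with a `<path>.json`
#' sidecar declaring `shape` (frames, pixels), `dtype` ("uint8"/"uint16")
#' and optionally `sensor_id`/`frame_offset`.
#'
#' @param path image or raw file
#' @param sensorId,frameOffset used when no sidecar is present
#' @return a [LineScanStream-class]
#' @export
readLineScan <- function(path, sensorId = "first", frameOffset = 0L) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) {
    m <- tryCatch(jsonlite::read_json(side, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupted sidecar ", side, ": ",
                         conditionMessage(e)))
    if (!is.list(m)) stop("corrupted sidecar ", side, ": not an object")
    m
  } else list()
  if (!is.null(meta$sensor_id)) sensorId <- meta$sensor_id
  if (!is.null(meta$frame_offset)) frameOffset <- meta$frame_offset
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    bits <- if (!is.null(meta$bits)) meta$bits else 16
    m <- tiff::readTIFF(path)
    if (bits == 32) {
      if (!is.null(meta$scale)) m <- m * meta$scale + meta$offset
    } else m <- round(m * (2^bits - 1))
  } else if (ext == "png") {
    bits <- if (!is.null(meta$bits)) meta$bits else 8
    m <- round(png::readPNG(path) * (2^bits - 1))
  } else {
    if (is.null(meta$shape) || is.null(meta$dtype))
      stop("raw input needs a sidecar declaring shape and dtype")
    shape <- as.integer(meta$shape)
    if (length(shape) != 2L || any(is.na(shape)) || any(shape < 1L))
      stop("corrupted sidecar: shape must be two positive integers")
    size <- switch(meta$dtype, uint8 = 1L, uint16 = 2L,
                   stop("unsupported dtype: ", meta$dtype))
    n <- prod(shape)
    v <- readBin(path, "integer", n = n, size = size, signed = FALSE,
                 endian = "little")
    if (length(v) != n)
      stop("raw file length does not match the sidecar shape")
    m <- matrix(v, nrow = shape[1], byrow = TRUE)
  }
  if (is.array(m) && length(dim(m)) > 2) m <- m[, , 1]
  LineScanStream(m, sensorId = sensorId,
                 frameOffset = as.integer(frameOffset))
}

# ---- run configuration ----

.runConfigDefaults <- function() {
  list(
    sensor = list(pixel_pitch_um = 2.2, sensor_gap_um = 13.2,
                  tilt_angle_deg = 21, line_rate_hz = 1230,
                  line_length = 88L),
    foreground = list(n = 20L, t1 = -15, t2 = 15),
    features = list(delta = 2, max_stable = 20,
                    interpretation = "variation",
                    dynamic_range_cap = 190, min_area = 30,
                    max_area = 5000, h = 20L, w = 20L,
                    search_half_x = 5L, search_half_lag_frac = 0.5),
    reconstruct = list(model = "variable_acceleration",
                       interpolation = "bilinear"),
    simulate = list(diameter_um = 32, n_rings = 5, contrast = 0.4,
                    phantom_pixel_um = 0.25, background = 120,
                    depth = 40, vy0 = 700,
                    accels = c(3000, -5000, 3000),
                    segment_frames = c(160L, 55L, 120L), gain_sd = 0.02,
                    offset_sd = 2, read_sd = 1, seed = 1L))
}

.validateRunConfig <- function(cfg) {
  def <- .runConfigDefaults()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad)) stop("unknown config block(s): ",
                        paste(bad, collapse = ", "))
  for (blk in names(cfg)) {
    extra <- setdiff(names(cfg[[blk]]), names(def[[blk]]))
    if (length(extra))
      stop("unknown key(s) in '", blk, "': ",
           paste(extra, collapse = ", "))
  }
  merged <- def
  for (blk in names(cfg))
    merged[[blk]] <- modifyList(def[[blk]], cfg[[blk]])
  s <- merged$sensor
  # SensorConfig's validity gives keyed messages for the geometry block
  tryCatch(
    SensorConfig(s$pixel_pitch_um, s$sensor_gap_um, s$tilt_angle_deg,
                 s$line_rate_hz, s$line_length),
    error = function(e) stop("sensor: ", conditionMessage(e),
                             call. = FALSE))
  if (!(merged$foreground$t1 < merged$foreground$t2))
    stop("foreground: t1 must be less than t2")
  if (merged$foreground$n < 2) stop("foreground: n must be >= 2")
  if (!merged$reconstruct$model %in%
      c("variable_acceleration", "uniform_velocity",
        "uniform_acceleration"))
    stop("reconstruct: unknown model '", merged$reconstruct$model, "'")
  merged
}

#' Load (or default) a run configuration
#'
#' YAML or JSON with blocks `sensor`, `foreground`, `features`,
#' `reconstruct`, `simulate`; missing keys take the package defaults
#' (2.2 um pitch, 21 degree tilt, 1230 lines/s, N = 20, thresholds +-15,
#' delta = 2, dynamic-range cap 190, H = W = 20). Unknown keys are
#' rejected with their key path.
#'
#' @param path YAML/JSON file, or NULL for all defaults
#' @return validated nested configuration list
#' @export
loadRunConfig <- function(path = NULL) {
  if (is.null(path)) return(.validateRunConfig(list()))
  raw <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  .validateRunConfig(raw)
}

#' Write a run configuration
#'
#' @param cfg nested configuration list from [loadRunConfig()]
#' @param path output .yaml or .json path
#' @export
writeRunConfig <- function(cfg, path) {
  if (tolower(tools::file_ext(path)) == "json")
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Sensor block of a run configuration as a SensorConfig
#'
#' @param cfg nested configuration list
#' @return a [SensorConfig-class]
#' @export
sensorFromConfig <- function(cfg) {
  s <- cfg$sensor
  SensorConfig(s$pixel_pitch_um, s$sensor_gap_um, s$tilt_angle_deg,
               s$line_rate_hz, s$line_length)
}
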