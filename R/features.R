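# Corner features on diffraction rings, SSD matching across the two
# sensors, and per-feature velocity / per-gap acceleration estimation.
#
# Image convention throughout: rows are frames (the ordinate y), columns
# are sensor pixels (the abscissa x).

#' Extract the two corner features of each MSER region
#'
#' On a diffraction ring the corner features sit at the upper and lower
#' vertices of the region: the ordinate is the extremum of the region's
#' ordinate, and the abscissa is the mean abscissa over the pixels at that
#' extremum. Each region yields two corners.
#'
#' @param regions region list from [detectMSER()]
#' @return data.frame: `x` (abscissa, possibly fractional), `y` (ordinate),
#'   `regionId`, `end` ("top"/"bottom")
#' @export
extractCorners <- function(regions) {
  out <- lapply(regions, function(r) {
    px <- r$pixels
    if (is.null(px) || nrow(px) == 0L) return(NULL)
    yTop <- min(px[, 1L]); yBot <- max(px[, 1L])
    data.frame(
      x = c(mean(px[px[, 1L] == yTop, 2L]),
            mean(px[px[, 1L] == yBot, 2L])),
      y = c(yTop, yBot),
      regionId = if (is.null(r$id)) NA_integer_ else r$id,
      end = c("top", "bottom"))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(x = numeric(), y = numeric(),
                      regionId = integer(), end = character())
  out
}

#' Default corner-feature kernel
#'
#' A 9 x 9 matrix with a +1 band in the top rows mirrored by a -1 band in
#' the bottom rows: it responds to the bright-above/dark-below transition
#' a ring vertex presents in the scan image, and is antisymmetric so a
#' uniform window scores zero.
#'
#' @return 9 x 9 numeric matrix
#' @export
defaultCornerKernel <- function() {
  k <- matrix(0, 9, 9)
  k[1, 6:8] <- 1; k[2, 5:7] <- 1; k[3, 5:6] <- 1
  k[7, 1:2] <- -1; k[8, 1:3] <- -1; k[9, 1:3] <- -1
  k
}

#' Corner strength score
#'
#' Absolute value of the element-wise product sum of an intensity window
#' with the corner kernel: the larger the score, the more pronounced the
#' corner.
#'
#' @param window intensity patch, same shape as `kernel`
#' @param kernel corner kernel (see [defaultCornerKernel()])
#' @return non-negative strength
#' @export
scoreCorner <- function(window, kernel = defaultCornerKernel()) {
  if (!identical(dim(as.matrix(window)), dim(as.matrix(kernel))))
    stop("window and kernel must have the same shape")
  abs(sum(window * kernel))
}

# score every corner by placing the kernel window at its (rounded)
# location; corners whose window leaves the image get strength 0
.scoreCornersOnImage <- function(corners, image, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  strength <- numeric(nrow(corners))
  for (i in seq_len(nrow(corners))) {
    cy <- round(corners$y[i]); cx <- round(corners$x[i])
    if (cy - r < 1 || cy + r > nrow(image) ||
        cx - r < 1 || cx + r > ncol(image)) next
    strength[i] <- scoreCorner(
      image[(cy - r):(cy + r), (cx - r):(cx + r)], kernel)
  }
  corners$strength <- strength
  corners
}

#' Screen corners by non-maximum suppression on the ordinate
#'
#' Greedy: corners are visited in decreasing strength (ties broken by
#' smaller ordinate, then smaller abscissa) and kept only when at least
#' `minSeparation` frames from every corner already kept.
#'
#' @param corners data.frame with columns `x`, `y`, `strength`
#' @param minSeparation minimum ordinate distance (frames); default
#'   max(3, 10% of the ordinate spread)
#' @return the retained subset, sorted by `y`
#' @export
screenCorners <- function(corners, minSeparation = NULL) {
  if (nrow(corners) <= 1L) return(corners)
  if (is.null(minSeparation))
    minSeparation <- max(3, 0.1 * diff(range(corners$y)))
  ord <- order(-corners$strength, corners$y, corners$x)
  keptY <- numeric(0)
  keep <- logical(nrow(corners))
  for (i in ord) {
    if (!length(keptY) || min(abs(corners$y[i] - keptY)) >= minSeparation) {
      keep[i] <- TRUE
      keptY <- c(keptY, corners$y[i])
    }
  }
  out <- corners[keep, , drop = FALSE]
  out[order(out$y), , drop = FALSE]
}

#' Match a feature on the second sensor by sum of squared differences
#'
#' An (H+1) x (W+1) template centred on the feature in `img1` is compared
#' against every centre position inside the search box of `img2`; the
#' position with the smallest SSD wins (ties: smallest ordinate, then
#' smallest abscissa).
#'
#' @param x,y feature centre in `img1` (abscissa = column, ordinate = row)
#' @param img1,img2 the two scan images (common intensity scale)
#' @param H,W template extent: the patch is (H+1) x (W+1)
#' @param searchRows,searchCols candidate centre ranges in `img2`
#' @param subpixel refine the integer minimum to sub-frame precision by
#'   fitting a parabola through the SSD scores of the two neighbouring
#'   candidates along each axis (the refinement never moves the match by
#'   more than half a step); without it the lag is quantised to whole
#'   frames, i.e. a ~2\% velocity granularity at typical lags
#' @return list(x2, y2, ssd), or NULL if the template or the whole search
#'   box falls outside the images (the feature is dropped with a message)
#' @export
ssdMatch <- function(x, y, img1, img2, H = 20, W = 20,
                     searchRows, searchCols, subpixel = TRUE) {
  hh <- H %/% 2; hw <- W %/% 2
  cy <- round(y); cx <- round(x)
  if (cy - hh < 1 || cy + hh > nrow(img1) ||
      cx - hw < 1 || cx + hw > ncol(img1)) {
    message("ssdMatch: template at (", cx, ",", cy, ") crosses the image ",
            "border; feature dropped")
    return(NULL)
  }
  tmpl <- img1[(cy - hh):(cy + hh), (cx - hw):(cx + hw)]
  searchRows <- searchRows[searchRows - hh >= 1 &
                           searchRows + hh <= nrow(img2)]
  searchCols <- searchCols[searchCols - hw >= 1 &
                           searchCols + hw <= ncol(img2)]
  if (!length(searchRows) || !length(searchCols)) {
    message("ssdMatch: search box outside the second image; feature dropped")
    return(NULL)
  }
  S <- matrix(NA_real_, length(searchRows), length(searchCols))
  for (j in seq_along(searchCols)) for (i in seq_along(searchRows)) {
    ii <- searchRows[i]; jj <- searchCols[j]
    S[i, j] <- sum((img2[(ii - hh):(ii + hh), (jj - hw):(jj + hw)] -
                      tmpl)^2)
  }
  k <- which(S == min(S), arr.ind = TRUE)[1, ]  # ties: smallest i, then j
  y2 <- as.numeric(searchRows[k[1]])
  x2 <- as.numeric(searchCols[k[2]])
  refine1d <- function(sm, s0, sp) {
    # an exact minimum (zero SSD) is already sub-pixel perfect
    if (s0 == 0) return(0)
    den <- sm - 2 * s0 + sp
    if (!is.finite(den) || den <= 0) return(0)
    max(min((sm - sp) / (2 * den), 0.5), -0.5)
  }
  if (subpixel) {
    if (k[1] > 1L && k[1] < nrow(S))
      y2 <- y2 + refine1d(S[k[1] - 1L, k[2]], S[k[1], k[2]],
                          S[k[1] + 1L, k[2]])
    if (k[2] > 1L && k[2] < ncol(S))
      x2 <- x2 + refine1d(S[k[1], k[2] - 1L], S[k[1], k[2]],
                          S[k[1], k[2] + 1L])
  }
  list(x2 = x2, y2 = y2, ssd = unname(S[k[1], k[2]]))
}

#' Scan-frame velocity of one matched feature pair
#'
#' The arrival-time lag of the feature between the two lines gives the
#' perpendicular approach speed, and the apparent column shift the
#' along-line speed:
#' \deqn{V_{y'} = d_{gap} f / (y' - y),\quad
#'       V_{x'} = d_{pitch} f (x' - x)/(y' - y).}
#' With column-aligned sensors the geometric column offset
#' \eqn{d_{gap}\cos\theta/(d_{pitch}\sin\theta)} contained in \eqn{x'-x}
#' combines with the lag to yield exactly the scan-frame lateral component
#' of the rotation transform.
#'
#' @param pair list or one-row data.frame with `x1`, `y1`, `x2`, `y2`
#' @param cfg a [SensorConfig()]
#' @return a [Velocity2()] tagged "C2"
#' @export
estimateVelocity <- function(pair, cfg) {
  lag <- pair$y2 - pair$y1
  if (!is.finite(lag) || lag <= 0)
    stop("matched pair must arrive later on the second sensor (y2 > y1)")
  f <- lineRate(cfg)
  Velocity2(pixelPitch(cfg) * f * (pair$x2 - pair$x1) / lag,
            sensorGap(cfg) * f / lag, frame = "C2")
}

#' Finite-difference accelerations between consecutive features
#'
#' For features sorted by first-sensor ordinate, the acceleration over gap
#' i is f (V_{i+1} - V_i) / (y_{i+1} - y_i). Gaps with duplicated
#' ordinates are skipped with a warning.
#'
#' @param features data.frame with `y1`, `vxp`, `vyp` sorted by `y1`
#' @param cfg a [SensorConfig()]
#' @param ordinate which ordinate carries each velocity: the feature's
#'   first-sensor frame (`"y1"`) or the mid-transit frame (`"yMid"`,
#'   requires a `yMid` column); the lag-average velocity of a matched
#'   pair equals the instantaneous velocity at mid-transit exactly under
#'   constant acceleration
#' @return data.frame: `yStart`, `yEnd`, `axp`, `ayp` (scan frame)
#' @export
estimateAccelerations <- function(features, cfg,
                                  ordinate = c("y1", "yMid")) {
  ordinate <- match.arg(ordinate)
  k <- nrow(features)
  if (k < 2L) stop("need at least two features")
  yy <- features[[ordinate]]
  if (is.null(yy)) stop("features lack the '", ordinate, "' column")
  if (is.unsorted(yy)) stop("features must be sorted by ", ordinate)
  f <- lineRate(cfg)
  dy <- diff(yy)
  if (any(dy == 0))
    warning("duplicate feature ordinates; those gaps are skipped")
  data.frame(yStart = yy[-k], yEnd = yy[-1L],
             axp = ifelse(dy == 0, NA_real_,
                          f * diff(features$vxp) / dy),
             ayp = ifelse(dy == 0, NA_real_,
                          f * diff(features$vyp) / dy))
}

# inter-sensor lag estimate from the row-energy profiles of the two
# foreground images (peak of the positive-lag cross-correlation)
.lagFromRowEnergy <- function(d1, d2) {
  e1 <- rowSums(abs(d1)); e2 <- rowSums(abs(d2))
  n <- length(e1)
  maxLag <- max(2L, floor(0.6 * n))
  sc <- vapply(seq_len(maxLag), function(l)
    sum(e1[seq_len(n - l)] * e2[seq_len(n - l) + l]), numeric(1))
  which.max(sc)
}

#' Full feature velocimetry between the two sensors
#'
#' Detects MSER regions on the first sensor's foreground image, extracts
#' and screens ring-vertex corners, matches each on the second sensor by
#' SSD inside a search box centred at the expected lag and geometric
#' column offset, and derives per-feature velocities from the dual-line
#' lag relations plus the K-1 inter-feature accelerations, in both
#' frames.
#'
#' @param fg1,fg2 [ForegroundStream-class] objects (or signed matrices)
#'   from the first and second sensor
#' @param cfg a [SensorConfig()]
#' @param mser an [mserParams()] list
#' @param kernel corner kernel for strength scoring
#' @param H,W SSD template extent (patch is (H+1) x (W+1))
#' @param minSeparation corner screening distance; see [screenCorners()]
#' @param expectedLag expected inter-sensor lag in frames; default
#'   estimated by cross-correlating the two row-energy profiles
#' @param searchHalfX lateral search half-width (pixels)
#' @param searchHalfLagFrac search half-height as a fraction of the
#'   expected lag
#' @param refine run a second matching pass with the search box centred
#'   on a locally predicted lag (robust linear fit of the first-pass lags
#'   against the ordinate); the narrowed box suppresses mismatches onto
#'   neighbouring rings
#' @return a [KinematicsTable-class]
#' @export
estimateKinematics <- function(fg1, fg2, cfg, mser = mserParams(),
                               kernel = defaultCornerKernel(),
                               H = 20, W = 20, minSeparation = NULL,
                               expectedLag = NULL, searchHalfX = 5,
                               searchHalfLagFrac = 0.5, refine = TRUE) {
  d1 <- if (is(fg1, "ForegroundStream")) differenceImage(fg1) else
    as.matrix(fg1)
  d2 <- if (is(fg2, "ForegroundStream")) differenceImage(fg2) else
    as.matrix(fg2)
  # joint intensity scale so SSD values are comparable across sensors
  rng <- range(c(d1, d2))
  toCommon <- function(m)
    if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng) * 255
  img1 <- toCommon(d1); img2 <- toCommon(d2)

  regions <- detectMSER(img1, mser)
  corners <- extractCorners(regions)
  if (nrow(corners) == 0L)
    return(new("KinematicsTable",
               features = .emptyFeatureFrame(),
               accelerations = .emptyAccelFrame(), config = cfg))
  corners <- .scoreCornersOnImage(corners, img1, kernel)
  corners <- screenCorners(corners, minSeparation)

  if (is.null(expectedLag)) expectedLag <- .lagFromRowEnergy(d1, d2)
  th <- .deg2rad(tiltAngle(cfg))
  colOffset <- sensorGap(cfg) * cos(th) /
    (pixelPitch(cfg) * sin(th))

  matchAll <- function(lagAt, halfLag) {
    feats <- list()
    for (i in seq_len(nrow(corners))) {
      x1 <- corners$x[i]; y1 <- corners$y[i]
      ctrY <- round(y1 + lagAt[i])
      ctrX <- round(x1 + colOffset)
      m <- ssdMatch(x1, y1, img1, img2, H, W,
                    searchRows = (ctrY - halfLag):(ctrY + halfLag),
                    searchCols = (ctrX - searchHalfX):(ctrX + searchHalfX))
      if (is.null(m) || !is.finite(m$y2) || m$y2 <= y1) next
      feats[[length(feats) + 1L]] <-
        data.frame(x1 = x1, y1 = y1, x2 = m$x2, y2 = m$y2, ssd = m$ssd)
    }
    if (length(feats)) do.call(rbind, feats) else NULL
  }

  halfLag <- max(3L, ceiling(searchHalfLagFrac * expectedLag))
  feats <- matchAll(rep(expectedLag, nrow(corners)), halfLag)
  if (refine && !is.null(feats) && nrow(feats) >= 3L) {
    # robust local lag model: least squares with one outlier-trim round
    lag <- feats$y2 - feats$y1
    fit <- lm(lag ~ feats$y1)
    res <- lag - fitted(fit)
    keep <- abs(res - median(res)) <= 3 * mad(res) + 1e-9
    if (sum(keep) >= 2L) fit <- lm(lag[keep] ~ feats$y1[keep])
    lagAt <- coef(fit)[1] + coef(fit)[2] * corners$y
    feats2 <- matchAll(lagAt, max(3L, ceiling(0.1 * expectedLag)))
    if (!is.null(feats2)) feats <- feats2
  }
  if (is.null(feats))
    return(new("KinematicsTable",
               features = .emptyFeatureFrame(),
               accelerations = .emptyAccelFrame(), config = cfg))
  feats <- feats[order(feats$y1, feats$x1), , drop = FALSE]
  # one feature per ordinate: keep the best (smallest SSD) match per y1
  feats <- do.call(rbind, lapply(split(feats, feats$y1),
                                 function(g) g[which.min(g$ssd), ]))
  feats <- feats[order(feats$y1), , drop = FALSE]
  # the lag-average velocity is the instantaneous velocity at mid-transit
  feats$yMid <- (feats$y1 + feats$y2) / 2

  vel <- lapply(seq_len(nrow(feats)),
                function(i) estimateVelocity(feats[i, ], cfg))
  feats$vxp <- vapply(vel, function(v) v@vx, numeric(1))
  feats$vyp <- vapply(vel, function(v) v@vy, numeric(1))
  velObj <- lapply(vel, velocityToObjectFrame, cfg = cfg)
  feats$vx <- vapply(velObj, function(v) v@vx, numeric(1))
  feats$vy <- vapply(velObj, function(v) v@vy, numeric(1))
  feats$featureId <- seq_len(nrow(feats))
  rownames(feats) <- NULL
  feats <- feats[, c("featureId", "x1", "y1", "x2", "y2", "yMid", "ssd",
                     "vxp", "vyp", "vx", "vy")]

  acc <- if (nrow(feats) >= 2L) {
    a <- estimateAccelerations(feats, cfg, ordinate = "yMid")
    aObj <- lapply(seq_len(nrow(a)), function(i) {
      if (!is.finite(a$ayp[i])) return(c(NA_real_, NA_real_))
      o <- accelToObjectFrame(Accel2(a$axp[i], a$ayp[i], "C2"), cfg)
      c(o@ax, o@ay)
    })
    a$ax <- vapply(aObj, `[`, numeric(1), 1L)
    a$ay <- vapply(aObj, `[`, numeric(1), 2L)
    a
  } else .emptyAccelFrame()
  new("KinematicsTable", features = feats, accelerations = acc,
      config = cfg)
}

.emptyFeatureFrame <- function() {
  data.frame(featureId = integer(), x1 = numeric(), y1 = numeric(),
             x2 = numeric(), y2 = numeric(), yMid = numeric(),
             ssd = numeric(), vxp = numeric(), vyp = numeric(),
             vx = numeric(), vy = numeric())
}

.emptyAccelFrame <- function() {
  data.frame(yStart = numeric(), yEnd = numeric(), axp = numeric(),
             ayp = numeric(), ax = numeric(), ay = numeric())
}

#' Write a kinematics table to CSV
#'
#' @param kin a [KinematicsTable-class]
#' @param path output file
#' @export
writeKinematics <- function(kin, path) {
  f <- featureTable(kin)
  a <- accelerationTable(kin)
  f$axp <- c(a$axp, NA)[seq_len(max(nrow(f), 0))]
  f$ayp <- c(a$ayp, NA)[seq_len(max(nrow(f), 0))]
  f$ax <- c(a$ax, NA)[seq_len(max(nrow(f), 0))]
  f$ay <- c(a$ay, NA)[seq_len(max(nrow(f), 0))]
  write.csv(f, path, row.names = FALSE)
  invisible(path)
}

#' Read a kinematics table written by [writeKinematics()]
#'
#' @param path CSV file
#' @param cfg the [SensorConfig()] the table belongs to
#' @return a [KinematicsTable-class]
#' @export
readKinematics <- function(path, cfg) {
  f <- read.csv(path)
  if (is.null(f$yMid)) f$yMid <- f$y1
  yy <- f$yMid
  acc <- if (nrow(f) >= 2L)
    data.frame(yStart = yy[-nrow(f)], yEnd = yy[-1L],
               axp = f$axp[-nrow(f)], ayp = f$ayp[-nrow(f)],
               ax = f$ax[-nrow(f)], ay = f$ay[-nrow(f)])
  else .emptyAccelFrame()
  new("KinematicsTable",
      features = f[, c("featureId", "x1", "y1", "x2", "y2", "yMid",
                       "ssd", "vxp", "vyp", "vx", "vy")],
      accelerations = acc, config = cfg)
}
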