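# Image-quality evaluation: Shannon entropy of the gray-level histogram,
# PSNR/SSIM against a reference, and equivalent-area object diameter.

#' Shannon entropy of an image
#'
#' Entropy of the 256-bin gray-level histogram, -sum p log2 p with
#' 0 log 0 = 0. Float images are linearly rescaled to 0..255 and binned at
#' integer levels; images already in 0..255 integers are binned as they
#' are. Higher values mean more information.
#'
#' @param image numeric matrix
#' @return entropy in bits/pixel
#' @examples
#' imageEntropy(matrix(rep(c(0, 255), 50), 10))  # 1 bit/pixel
#' @export
imageEntropy <- function(image) {
  x <- as.numeric(image)
  if (!length(x)) stop("empty image")
  isByte <- all(x == round(x)) && min(x) >= 0 && max(x) <= 255
  if (!isByte) x <- as.numeric(rescaleRange(matrix(x, 1), 0, 255))
  counts <- tabulate(as.integer(round(x)) + 1L, nbins = 256L)
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

#' Peak signal-to-noise ratio
#'
#' 10 log10(max^2 / MSE) in dB; identical images return Inf.
#'
#' @param image,reference same-shape numeric matrices
#' @param maxValue peak of the intensity scale (default: reference range)
#' @return PSNR in dB
#' @export
psnr <- function(image, reference, maxValue = NULL) {
  image <- as.matrix(image); reference <- as.matrix(reference)
  if (!identical(dim(image), dim(reference)))
    stop("image and reference must have the same shape")
  if (is.null(maxValue)) maxValue <- max(reference) - min(reference)
  mse <- mean((image - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(maxValue^2 / mse)
}

#' Structural similarity index
#'
#' Conventional windowed SSIM with a uniform window (default 7 x 7),
#' sample-covariance normalisation and constants C1 = (0.01 L)^2,
#' C2 = (0.03 L)^2 for dynamic range L; the SSIM map is averaged over the
#' positions where the window fits entirely.
#'
#' @param image,reference same-shape numeric matrices
#' @param windowSize odd window edge length
#' @param dataRange dynamic range L (default: reference range)
#' @return mean SSIM in [-1, 1]
#' @export
ssim <- function(image, reference, windowSize = 7, dataRange = NULL) {
  x <- as.matrix(image); y <- as.matrix(reference)
  if (!identical(dim(x), dim(y)))
    stop("image and reference must have the same shape")
  w <- as.integer(windowSize)
  if (w < 2 || nrow(x) < w || ncol(x) < w)
    stop("window does not fit inside the images")
  if (is.null(dataRange)) dataRange <- max(y) - min(y)
  if (dataRange <= 0) dataRange <- 1
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  np <- w * w
  covNorm <- np / (np - 1)
  ux <- boxMeanValid(x, w); uy <- boxMeanValid(y, w)
  uxx <- boxMeanValid(x * x, w); uyy <- boxMeanValid(y * y, w)
  uxy <- boxMeanValid(x * y, w)
  vx <- covNorm * (uxx - ux * ux)
  vy <- covNorm * (uyy - uy * uy)
  vxy <- covNorm * (uxy - ux * uy)
  m <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux * ux + uy * uy + C1) * (vx + vy + C2))
  mean(m)
}

#' Equivalent-area diameter of the dominant object
#'
#' Thresholds at the midpoint between the robust background level (the
#' median) and the robust object level (mean of the strongest 5% of
#' deviations, in the polarity of the largest deviation), keeps the
#' largest connected component and returns 2 sqrt(area/pi) * pixelSize.
#' Invariant to linear intensity rescaling.
#'
#' @param image numeric matrix containing one dominant object
#' @param pixelSize physical pixel size (um)
#' @param method "area" (equivalent-area diameter) or "caliper" (largest
#'   chord through the component)
#' @return diameter in um
#' @export
estimateDiameter <- function(image, pixelSize,
                             method = c("area", "caliper")) {
  method <- match.arg(method)
  img <- as.matrix(image)
  if (!length(img)) stop("empty image")
  bg <- median(img)
  dev <- img - bg
  polarity <- sign(dev[which.max(abs(dev))])
  s <- polarity * dev
  top <- s[s >= quantile(s, 0.95)]
  objLevel <- mean(top)
  if (objLevel <= 0) stop("no object found above the background")
  binary <- s > objLevel / 2
  if (!any(binary)) stop("no object found above the threshold")
  lab <- EBImage::bwlabel(matrix(as.numeric(binary), nrow(img)))
  areas <- tabulate(lab)
  big <- which.max(areas)
  if (method == "area")
    return(2 * sqrt(areas[big] / pi) * pixelSize)
  px <- which(lab == big, arr.ind = TRUE)
  hull <- px[grDevices::chull(px), , drop = FALSE]
  dmat <- as.matrix(dist(hull))
  max(dmat) * pixelSize
}

#' Register an image to a reference by correlation peak
#'
#' A reconstruction built from measured kinematics carries an arbitrary
#' global offset (the object's absolute position before it reaches the
#' sensors is unobservable), so quantitative comparison against a
#' reference requires registration first. The image is aligned by
#' searching integer translations for the Pearson-correlation peak,
#' refining to sub-pixel precision with a parabolic fit, and bilinearly
#' resampling the image at the refined offset.
#'
#' @param image numeric matrix, at least as large as the reference
#' @param reference numeric matrix
#' @param maxShift integer search radius around the centroid-based
#'   initial offset (pixels)
#' @return list: `aligned` (matrix of the reference's shape), `shift`
#'   (row/col offset applied), `correlation` at the peak
#' @export
registerToReference <- function(image, reference, maxShift = 10) {
  img <- as.matrix(image); ref <- as.matrix(reference)
  mr <- nrow(ref); mc <- ncol(ref)
  refv <- as.numeric(ref)
  cen <- function(M) {
    W <- abs(M); s <- sum(W)
    if (s == 0) return(c((nrow(M) + 1) / 2, (ncol(M) + 1) / 2))
    c(sum(row(M) * W) / s, sum(col(M) * W) / s)
  }
  r0 <- cen(img)[1] - (mr - 1) / 2 + (cen(ref)[1] - (mr + 1) / 2)
  c0 <- cen(img)[2] - (mc - 1) / 2 + (cen(ref)[2] - (mc + 1) / 2)
  r0 <- round(r0); c0 <- round(c0)
  sampleAt <- function(dr, dc) {
    rows <- rep(r0 + dr + seq_len(mr) - 1, times = mc)
    cols <- rep(c0 + dc + seq_len(mc) - 1, each = mr)
    matrix(bilinearSample(img, rows, cols, 0), mr, mc)
  }
  corAt <- function(dr, dc) {
    v <- as.numeric(sampleAt(dr, dc))
    if (sd(v) == 0) return(-1)
    cor(v, refv)
  }
  grid <- expand.grid(dr = -maxShift:maxShift, dc = -maxShift:maxShift)
  cc <- mapply(corAt, grid$dr, grid$dc)
  best <- which.max(cc)
  dr <- grid$dr[best]; dc <- grid$dc[best]
  refine <- function(cm, c0v, cp) {
    den <- cm - 2 * c0v + cp
    if (!is.finite(den) || den >= 0) return(0)
    max(min((cm - cp) / (2 * den), 0.5), -0.5)
  }
  fr <- refine(corAt(dr - 1, dc), cc[best], corAt(dr + 1, dc))
  fc <- refine(corAt(dr, dc - 1), cc[best], corAt(dr, dc + 1))
  aligned <- sampleAt(dr + fr, dc + fc)
  list(aligned = aligned,
       shift = c(row = r0 + dr + fr - 1, col = c0 + dc + fc - 1),
       correlation = cor(as.numeric(aligned), refv))
}

#' Downsample a phantom to a reconstruction's pixel grid
#'
#' Bilinear resampling of the background-subtracted phantom to the
#' equivalent pixel size, for round-trip comparison against a
#' [ReconstructionGrid-class].
#'
#' @param phantom a [Phantom-class]
#' @param pixelSize target pixel size (um)
#' @return numeric matrix (rows = y, cols = x), background at zero
#' @export
downsamplePhantom <- function(phantom, pixelSize) {
  img <- phantomImage(phantom) - phantom@backgroundLevel
  pz <- phantom@pixelSize
  m <- floor((nrow(img) - 1) * pz / pixelSize) + 1
  ax <- ((seq_len(m) - 1) * pixelSize) / pz + 1
  matrix(bilinearSample(img, rep(ax, times = m), rep(ax, each = m), 0),
         m, m)
}

#' Evaluate a reconstruction against a reference
#'
#' @param image reconstructed image (matrix or [ReconstructionGrid-class])
#' @param reference reference image, same shape (optional)
#' @param pixelSize physical pixel size for the diameter estimate (um);
#'   taken from the grid when `image` is a [ReconstructionGrid-class]
#' @param trueDiameter known object diameter (um) for the error field
#' @return list: entropy, psnr, ssim, diameter, diameterErrorPercent
#'   (NA where not computable)
#' @export
evaluateReconstruction <- function(image, reference = NULL,
                                   pixelSize = NULL,
                                   trueDiameter = NULL) {
  if (is(image, "ReconstructionGrid")) {
    if (is.null(pixelSize)) pixelSize <- pixelSize(image)
    image <- reconImage(image)
  }
  out <- list(entropy = imageEntropy(image), psnr = NA_real_,
              ssim = NA_real_, diameter = NA_real_,
              diameterErrorPercent = NA_real_)
  if (!is.null(reference)) {
    out$psnr <- psnr(image, reference)
    out$ssim <- ssim(image, reference)
  }
  if (!is.null(pixelSize)) {
    dia <- tryCatch(estimateDiameter(image, pixelSize),
                    error = function(e) NA_real_)
    out$diameter <- dia
    if (!is.null(trueDiameter) && is.finite(dia))
      out$diameterErrorPercent <- 100 * abs(dia - trueDiameter) /
        trueDiameter
  }
  out
}
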