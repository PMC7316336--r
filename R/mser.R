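# Maximally stable extremal regions, both polarities, by a threshold sweep
# with component tracking. Regions here are the alternating bright/dark
# diffraction rings of a cell far from the sensor plane; stability is the
# relative area growth across +/- delta threshold steps.

#' MSER detector parameters
#'
#' `maxStable` is the stability limit: a region is kept when its relative
#' area variation across a +/- delta threshold step is at most `maxStable`
#' percent (interpretation "variation", the default). Under interpretation
#' "count" the same value caps the number of regions returned (most stable
#' first) and the variation limit is dropped.
#'
#' @param delta intensity step between threshold levels
#' @param maxStable stability limit (percent variation) or region-count
#'   cap, per `interpretation`
#' @param interpretation how to read `maxStable`
#' @param dynamicRangeCap ceiling used by [compressDynamicRange()] before
#'   detection
#' @param minArea,maxArea region size limits (pixels)
#' @return parameter list for [detectMSER()]
#' @export
mserParams <- function(delta = 2, maxStable = 20,
                       interpretation = c("variation", "count"),
                       dynamicRangeCap = 190, minArea = 30,
                       maxArea = 5000) {
  stopifnot(delta > 0, dynamicRangeCap > 0, minArea >= 1,
            maxArea > minArea)
  list(delta = delta, maxStable = maxStable,
       interpretation = match.arg(interpretation),
       dynamicRangeCap = dynamicRangeCap,
       minArea = minArea, maxArea = maxArea)
}

#' Compress the dynamic range of an image
#'
#' Linear rescale so the image maximum maps to `cap` (images whose maximum
#' is already at or below `cap`, and constant images, are returned
#' unchanged). Pixel rank order is preserved; compressing before MSER
#' detection limits the number of threshold levels swept.
#'
#' @param image numeric matrix (non-negative)
#' @param cap intensity ceiling
#' @return rescaled matrix
#' @export
compressDynamicRange <- function(image, cap = 190) {
  stopifnot(cap > 0)
  mx <- max(image)
  if (!is.finite(mx) || mx <= cap || diff(range(image)) == 0) return(image)
  image * (cap / mx)
}

# one polarity sweep: extremal regions are connected components of
# {g <= t}; `g` must already be oriented so regions of interest are dark
.mserSweep <- function(g, params, polarity) {
  lv <- seq(min(g), max(g), by = params$delta)
  if (length(lv) < 3L) return(list())
  labs <- lapply(lv, function(t) EBImage::bwlabel(g <= t))
  out <- list()
  for (k in seq(2L, length(lv) - 1L)) {
    Lk <- labs[[k]]; Ldn <- labs[[k - 1L]]; Lup <- labs[[k + 1L]]
    areas <- tabulate(Lk)
    keep <- which(areas >= params$minArea & areas <= params$maxArea)
    if (!length(keep)) next
    areasUp <- tabulate(Lup)
    areasDn <- tabulate(Ldn)
    for (id in keep) {
      idx <- which(Lk == id)
      aUp <- areasUp[Lup[idx[1L]]]          # parent contains the region
      kids <- Ldn[idx]
      kids <- kids[kids > 0L]
      aDn <- if (length(kids)) max(areasDn[unique(kids)]) else 0
      v <- 100 * (aUp - aDn) / areas[id]
      out[[length(out) + 1L]] <- list(
        pixels = arrayInd(idx, dim(g)), area = areas[id],
        level = lv[k], polarity = polarity, variation = v)
    }
  }
  out
}

# greedy de-duplication of the stability-sorted candidates: a candidate is
# dropped when it overlaps a kept region by more than half (Jaccard)
.mserDedupe <- function(regs, dims) {
  if (!length(regs)) return(regs)
  ord <- order(vapply(regs, `[[`, numeric(1), "variation"))
  kept <- list()
  keptIdx <- list()
  for (i in ord) {
    idx <- (regs[[i]]$pixels[, 2L] - 1L) * dims[1L] + regs[[i]]$pixels[, 1L]
    dup <- FALSE
    for (j in seq_along(kept)) {
      inter <- sum(idx %in% keptIdx[[j]])
      if (inter / (length(idx) + length(keptIdx[[j]]) - inter) > 0.5) {
        dup <- TRUE; break
      }
    }
    if (!dup) {
      kept[[length(kept) + 1L]] <- regs[[i]]
      keptIdx[[length(keptIdx) + 1L]] <- idx
    }
  }
  kept
}

#' Detect maximally stable extremal regions
#'
#' Sweeps intensity thresholds in steps of `delta` for both polarities
#' (dark regions on a bright background and the reverse), scores every
#' connected component within the area limits by its relative area
#' variation across one threshold step, and returns the de-duplicated
#' stable regions.
#'
#' @param image grayscale matrix
#' @param params an [mserParams()] list
#' @return list of regions, each a list with `pixels` (n x 2 matrix of
#'   row/col), `area`, `level`, `polarity` ("dark"/"bright"),
#'   `variation` (percent) and `id`
#' @export
detectMSER <- function(image, params = mserParams()) {
  g <- as.matrix(image)
  if (diff(range(g)) == 0) return(list())
  g <- rescaleRange(g, 0, 255)
  g <- compressDynamicRange(g, params$dynamicRangeCap)
  cand <- c(.mserSweep(g, params, "dark"),
            .mserSweep(max(g) - g, params, "bright"))
  if (params$interpretation == "variation")
    cand <- Filter(function(r) r$variation <= params$maxStable, cand)
  regs <- .mserDedupe(cand, dim(g))
  if (params$interpretation == "count" && length(regs) > params$maxStable)
    regs <- regs[seq_len(params$maxStable)]
  for (i in seq_along(regs)) regs[[i]]$id <- i
  regs
}
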