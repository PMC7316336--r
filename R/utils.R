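# internal numeric helpers shared across modules

.deg2rad <- function(deg) deg * pi / 180

# Bilinear interpolation on a matrix. `row`/`col` are 1-based continuous
# coordinates; locations outside [1, nrow] x [1, ncol] return `fill`.
bilinearSample <- function(img, row, col, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  valid <- is.finite(row) & is.finite(col) &
    row >= 1 & row <= nr & col >= 1 & col <= nc
  out <- rep(fill, length(row))
  if (!any(valid)) return(out)
  r <- row[valid]; c <- col[valid]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(r0 + 1L, c0)]
  i01 <- img[cbind(r0, c0 + 1L)]
  i11 <- img[cbind(r0 + 1L, c0 + 1L)]
  out[valid] <- i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
  out
}

# Nearest-neighbour lookup with the same contract as bilinearSample().
nearestSample <- function(img, row, col, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  valid <- is.finite(row) & is.finite(col) &
    row >= 1 & row <= nr & col >= 1 & col <= nc
  out <- rep(fill, length(row))
  if (!any(valid)) return(out)
  out[valid] <- img[cbind(pmin(pmax(round(row[valid]), 1L), nr),
                          pmin(pmax(round(col[valid]), 1L), nc))]
  out
}

# Linear rescale of a matrix to [lo, hi]; constant input maps to lo.
rescaleRange <- function(x, lo = 0, hi = 255) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(array(lo, dim = dim(x)))
  (x - rng[1]) / diff(rng) * (hi - lo) + lo
}

# Box-filter local means with "valid" semantics via a summed-area table.
# Returns an (nr-w+1) x (nc-w+1) matrix of exact window means.
boxMeanValid <- function(x, w) {
  nr <- nrow(x); nc <- ncol(x)
  stopifnot(w >= 1, nr >= w, nc >= w)
  sat <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed cumulative sums
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  i1 <- seq_len(nr - w + 1L); i2 <- i1 + w
  j1 <- seq_len(nc - w + 1L); j2 <- j1 + w
  (sat[i2, j2, drop = FALSE] - sat[i2, j1, drop = FALSE] -
     sat[i1, j2, drop = FALSE] + sat[i1, j1, drop = FALSE]) / (w * w)
}
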