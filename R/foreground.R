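# Streaming mean-background model with multi-threshold foreground gating.
#
# The stripe noise of a line sensor (per-column gain/offset) is stable over
# time, so a per-column running mean captures it; pixels whose difference
# from the model leaves [T1, T2] are foreground and are excluded from the
# model update so the object does not bleed into the background estimate.

#' Initialise the per-column background model
#'
#' The model mean is the column-wise arithmetic mean of the first N
#' (assumed cell-free) rows.
#'
#' @param rows an N x lineLength matrix of cell-free rows
#' @param T1,T2 lower/upper foreground thresholds on the signed
#'   difference (T1 < T2)
#' @return a background model list: `meanRow`, `windowSize`, `T1`, `T2`
#' @export
initBackground <- function(rows, T1 = -15, T2 = 15) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2L) stop("need at least 2 rows to initialise")
  if (!(T1 < T2)) stop("T1 must be less than T2")
  list(meanRow = colMeans(rows), windowSize = nrow(rows), T1 = T1, T2 = T2)
}

#' Signed difference of a row against the background model
#'
#' @param row an intensity row
#' @param model a background model from [initBackground()]
#' @return signed per-column difference (EP)
#' @export
foregroundDifference <- function(row, model) {
  if (length(row) != length(model$meanRow))
    stop("row length does not match the background model")
  as.numeric(row) - model$meanRow
}

#' Background mask from a difference row
#'
#' mask = 0 (foreground present) where the difference is strictly below T1
#' or strictly above T2; otherwise 1 (background). Values exactly at a
#' threshold count as background.
#'
#' @param diff signed difference row
#' @param model a background model
#' @return 0/1 mask row (1 = background)
#' @export
backgroundMask <- function(diff, model) {
  as.numeric(!(diff < model$T1 | diff > model$T2))
}

#' Leaky running-mean update gated by the background mask
#'
#' Per column j: mean' = (mean (N-1) + mask_j row_j) / (N - 1 + mask_j).
#' Columns flagged as foreground (mask 0) leave the model untouched;
#' background columns follow an exponential moving average with factor
#' (N-1)/N.
#'
#' @param model a background model
#' @param row the current intensity row
#' @param mask the row's background mask
#' @return the updated model
#' @export
updateBackground <- function(model, row, mask) {
  N <- model$windowSize
  model$meanRow <- (model$meanRow * (N - 1) + mask * as.numeric(row)) /
    (N - 1 + mask)
  model
}

#' Extract the foreground stream
#'
#' Single streaming pass: the first N rows initialise the model and are not
#' emitted; every later row is differenced against the current model,
#' masked, the model updated, and the refined difference EP' (row minus the
#' post-update mean) emitted together with the mask.
#'
#' @param stream a [LineScanStream()] (or a frames x pixels matrix)
#' @param N background window size (rows)
#' @param T1,T2 foreground thresholds (T1 < T2)
#' @return a [ForegroundStream-class]
#' @examples
#' s <- matrix(100, 40, 8); s[30, 3:5] <- 60
#' fg <- extractForeground(LineScanStream(s), N = 20)
#' @export
extractForeground <- function(stream, N = 20, T1 = -15, T2 = 15) {
  rows <- if (is(stream, "LineScanStream")) streamRows(stream)
          else as.matrix(stream)
  off <- if (is(stream, "LineScanStream")) frameOffset(stream) else 0L
  total <- nrow(rows)
  if (total <= N) stop("stream must be longer than the window size N")
  model <- initBackground(rows[seq_len(N), , drop = FALSE], T1, T2)
  # the model assumes a cell-free start; flag a likely violation
  spread <- max(abs(sweep(rows[seq_len(N), , drop = FALSE], 2,
                          model$meanRow)))
  if (spread > (T2 - T1))
    warning("initialisation window spans a large intensity range; ",
            "the first N rows may not be cell-free")
  nOut <- total - N
  dif <- matrix(0, nOut, ncol(rows))
  msk <- matrix(1, nOut, ncol(rows))
  for (i in seq_len(nOut)) {
    row <- rows[N + i, ]
    ep <- foregroundDifference(row, model)
    m <- backgroundMask(ep, model)
    model <- updateBackground(model, row, m)
    dif[i, ] <- as.numeric(row) - model$meanRow   # EP': post-update mean
    msk[i, ] <- m
  }
  new("ForegroundStream", difference = dif, mask = msk,
      frameOffset = as.integer(off + N),
      params = list(N = N, T1 = T1, T2 = T2))
}

#' Rescale a signed foreground image to 8-bit for visualisation
#'
#' @param fg a [ForegroundStream-class] or signed matrix
#' @return integer matrix in 0..255
#' @export
foregroundTo8bit <- function(fg) {
  m <- if (is(fg, "ForegroundStream")) differenceImage(fg) else as.matrix(fg)
  round(rescaleRange(m, 0, 255))
}
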