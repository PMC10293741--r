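# Smoothing, ratio computation and pseudo-colouring: the steps that turn
# an aligned two-channel stack into a masked FRET-ratio movie.

# Offsets of the discrete disk dx^2 + dy^2 <= r^2 (13 pixels at r = 2).
diskOffsets <- function(radiusPx) {
  r <- as.integer(radiusPx)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= radiusPx^2, , drop = FALSE]
}

# NA-aware neighborhood mean of one matrix: each pixel becomes the mean
# of the defined in-frame pixels of its disk neighborhood.
diskMean <- function(m, offsets) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  ok <- is.finite(m)
  mz <- ifelse(ok, m, 0)
  for (i in seq_len(nrow(offsets))) {
    dy <- offsets$dy[i]; dx <- offsets$dx[i]
    rs <- max(1, 1 - dy):min(nr, nr - dy)
    cs <- max(1, 1 - dx):min(nc, nc - dx)
    acc[rs, cs] <- acc[rs, cs] + mz[rs + dy, cs + dx]
    cnt[rs, cs] <- cnt[rs, cs] + ok[rs + dy, cs + dx]
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Mean-filter both channels of a movie
#'
#' Replaces each pixel by the mean of its circular neighborhood of
#' radius \code{radiusPx} (13-pixel support at the default radius 2,
#' following the convention that the "two pixels" of the mean filter is
#' a radius). At image borders the mean runs over the in-frame part of
#' the disk, so constant images are exactly preserved. Radius 0 is the
#' identity. Undefined acceptor samples (from registration) are excluded
#' from neighborhood means.
#'
#' @param movie a \linkS4class{TwoChannelMovie}.
#' @param radiusPx neighborhood radius in pixels (>= 0).
#' @return a smoothed \linkS4class{TwoChannelMovie}.
#' @export
smoothMovie <- function(movie, radiusPx = 2) {
  if (radiusPx < 0) stop("radiusPx must be >= 0")
  if (radiusPx == 0) return(movie)
  off <- diskOffsets(radiusPx)
  d <- dim(movie@donor)
  don <- movie@donor; acc <- movie@acceptor
  accNA <- acc
  accNA[!movie@acceptorValid] <- NA_real_
  for (f in seq_len(d[3])) {
    don[, , f] <- diskMean(movie@donor[, , f], off)
    acc[, , f] <- diskMean(accNA[, , f], off)
  }
  val <- is.finite(acc)
  acc[!val] <- 0
  new("TwoChannelMovie", donor = don, acceptor = acc,
      acceptorValid = val, acq = movie@acq)
}

#' Compute the masked FRET-ratio movie
#'
#' Pixel-wise acceptor/donor ratio wherever the donor is at or above the
#' floor, the acceptor sample is defined and positive; all other pixels
#' are invalid (NA), never infinite. The default floor is the background
#' plus three read-noise SDs when the acquisition metadata carries a
#' noise model, else 1 percent of the donor dynamic range -- a guard
#' against division noise that avoids biasing low-signal ratios the way
#' an added epsilon would.
#'
#' @param movie an aligned, smoothed \linkS4class{TwoChannelMovie}.
#' @param donorFloor minimum donor intensity for a defined ratio
#'   (>= 0); NULL for the default above.
#' @return a \linkS4class{RatioMovie}.
#' @export
computeRatio <- function(movie, donorFloor = NULL) {
  if (is.null(donorFloor)) {
    acq <- movie@acq
    donorFloor <- if (acq@readNoiseSD > 0 || acq@background > 0)
      acq@background + 3 * acq@readNoiseSD
    else 0.01 * (max(movie@donor) - min(movie@donor))
  }
  if (donorFloor < 0) stop("donorFloor must be >= 0")
  don <- movie@donor; acc <- movie@acceptor
  valid <- movie@acceptorValid & is.finite(don) & is.finite(acc) &
    don >= donorFloor & don > 0 & acc > 0
  ratio <- array(NA_real_, dim(don))
  ratio[valid] <- acc[valid] / don[valid]
  new("RatioMovie", ratio = ratio, valid = valid,
      pixelSize = pixelSize(movie), frameInterval = frameInterval(movie))
}

# 16-level blue-to-red lookup table in the style of the ImageJ
# "16 colors" table: low ratio blue, high ratio red/white.
sixteenColorLUT <- function() {
  rbind(
    c(0.00, 0.00, 0.65), c(0.00, 0.00, 1.00), c(0.00, 0.35, 1.00),
    c(0.00, 0.65, 1.00), c(0.00, 0.90, 0.90), c(0.00, 1.00, 0.60),
    c(0.20, 1.00, 0.20), c(0.60, 1.00, 0.00), c(0.85, 1.00, 0.00),
    c(1.00, 1.00, 0.00), c(1.00, 0.80, 0.00), c(1.00, 0.60, 0.00),
    c(1.00, 0.40, 0.00), c(1.00, 0.15, 0.00), c(1.00, 0.00, 0.00),
    c(1.00, 0.85, 0.85))
}

#' Pseudo-colour a ratio movie
#'
#' Maps defined ratio pixels onto a discrete 16-level blue-to-red lookup
#' table over \code{lutRange} (values at or below the low end take the
#' bottom level, at or above the high end the top level; the mapping is
#' monotone in the ratio). Invalid pixels are rendered in the background
#' colour.
#'
#' @param ratio a \linkS4class{RatioMovie}.
#' @param lutRange c(low, high) ratio range, low < high.
#' @param backgroundColor RGB triple for invalid pixels.
#' @return rows x cols x 3 x frames RGB array in [0, 1], with the
#'   integer LUT level per pixel attached as attribute "levels".
#' @export
pseudocolor <- function(ratio, lutRange,
                        backgroundColor = c(0, 0, 0)) {
  if (lutRange[1] >= lutRange[2]) stop("lutRange must satisfy low < high")
  lut <- sixteenColorLUT()
  d <- dim(ratio@ratio)
  lev <- array(NA_integer_, d)
  frac <- (ratio@ratio - lutRange[1]) / diff(lutRange)
  lev[] <- pmin(16L, pmax(1L, 1L + as.integer(floor(frac * 16))))
  lev[!ratio@valid] <- NA_integer_
  out <- array(NA_real_, c(d[1], d[2], 3, d[3]))
  for (ch in 1:3) {
    v <- lut[, ch][lev]
    v[is.na(v)] <- backgroundColor[ch]
    out[, , ch, ] <- array(v, c(d[1], d[2], d[3]))
  }
  attr(out, "levels") <- lev
  out
}
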