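# Mask-based scalar metrics: segmentation, adherent-cell counting with
# the small-particle exclusion, whole-cell mean FRET time series, and
# AUC summaries over stated windows.

newCellMask <- function(mask, frame, pixelSize) {
  area <- sum(mask) * pixelSize^2
  per <- chainPerimeter(mask) * pixelSize
  circ <- min(4 * pi * area / per^2, 1.05)
  new("CellMask", mask = mask, frame = as.integer(frame), area = area,
      perimeter = per, circularity = circ,
      centroid = maskCentroid(mask, pixelSize), pixelSize = pixelSize)
}

#' Segment cells in one frame
#'
#' Otsu threshold on the (ideally smoothed) donor frame, hole filling,
#' connected-component labelling and optional watershed splitting of
#' touching cells. Shape descriptors use a bias-corrected chain-code
#' perimeter so circularity is close to 1 for rasterized disks.
#'
#' @param frame numeric matrix (donor channel).
#' @param pixelSize um per pixel (> 0).
#' @param threshold "otsu" or a numeric intensity cutoff.
#' @param split logical; watershed-split touching cells.
#' @param minPixels discard specks smaller than this many pixels.
#' @return list of \linkS4class{CellMask} (empty for a blank frame).
#' @export
segmentFrame <- function(frame, pixelSize, threshold = "otsu",
                         split = FALSE, minPixels = 9L) {
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  rng <- range(frame)
  if (diff(rng) <= 0) return(list())
  norm <- (frame - rng[1]) / diff(rng)
  th <- if (identical(threshold, "otsu"))
    EBImage::otsu(EBImage::Image(norm))
  else (threshold - rng[1]) / diff(rng)
  mask <- norm > th
  if (!any(mask)) return(list())
  mask <- EBImage::fillHull(mask * 1) > 0
  lab <- if (split) {
    EBImage::watershed(EBImage::distmap(mask * 1))
  } else EBImage::bwlabel(mask * 1)
  out <- list()
  for (i in seq_len(max(lab))) {
    m <- lab == i
    if (sum(m) < minPixels) next
    out[[length(out) + 1L]] <- newCellMask(m, 1L, pixelSize)
  }
  out
}

#' Count adherent cells with the small-particle exclusion
#'
#' Counts masks whose area is at least \code{minArea}; objects smaller
#' than the cutoff (default 40 um^2) are excluded, objects of exactly
#' the cutoff retained.
#'
#' @param masks list of \linkS4class{CellMask} from one field of view.
#' @param minArea exclusion cutoff, um^2 (>= 0).
#' @return integer count.
#' @export
countAdherent <- function(masks, minArea = 40) {
  if (minArea < 0) stop("minArea must be >= 0")
  if (!length(masks)) return(0L)
  sum(vapply(masks, function(m) m@area, 0) >= minArea)
}

#' Whole-cell mean FRET ratio over time
#'
#' One value per frame: the mean ratio over defined pixels inside the
#' cell mask. Frames whose mask holds no defined pixel are NA.
#'
#' @param ratio a \linkS4class{RatioMovie}.
#' @param track a \linkS4class{CellTrack} (masks must match the ratio
#'   frames).
#' @return data.frame(time_s, value) with one row per frame.
#' @export
wholeCellMeanFret <- function(ratio, track) {
  n <- nFrames(ratio)
  if (!identical(dim(track@masks), dim(ratio@ratio)))
    stop("track masks and ratio movie dimensions differ")
  vals <- vapply(seq_len(n), function(f) {
    sel <- track@masks[, , f] & ratio@valid[, , f]
    if (!any(sel)) return(NA_real_)
    mean(ratio@ratio[, , f][sel])
  }, 0)
  if (all(is.na(vals)))
    stop("no defined in-mask pixels in any frame")
  data.frame(time_s = (seq_len(n) - 1) * ratio@frameInterval,
             value = vals)
}

#' Trapezoidal area under a time series over a window
#'
#' Integrates value-versus-time over [t0, t1] by the trapezoid rule,
#' interpolating the window endpoints. Missing samples are bridged
#' linearly with a warning, keeping AUC windows comparable across cells.
#'
#' @param series data.frame(time_s, value) with strictly increasing
#'   times.
#' @param window c(t0, t1) within the series' time span.
#' @return AUC in value-units times seconds.
#' @export
aucWindow <- function(series, window) {
  t <- series$time_s; v <- series$value
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (window[1] < min(t) - 1e-9 || window[2] > max(t) + 1e-9)
    stop("AUC window lies outside the data's time span")
  if (sum(t >= window[1] & t <= window[2]) < 2)
    stop("need at least 2 samples inside the AUC window")
  if (anyNA(v)) {
    warning("missing samples bridged linearly for AUC")
    ok <- !is.na(v)
    v <- approx(t[ok], v[ok], xout = t, rule = 2)$y
  }
  tt <- sort(unique(c(window, t[t > window[1] & t < window[2]])))
  vv <- approx(t, v, xout = tt)$y
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
}
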