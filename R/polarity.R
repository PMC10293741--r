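# Where activity sits in the cell: longitudinal-axis line scans and
# their 20-bin reduction, kymographs, peripheral edge-band sampling,
# polar (eccentric-circle) maps, and peak-activity statistics (pole
# dwell, switch events, wave durations).
#
# Angles are measured about the centroid with atan2(dy, dx) in image
# coordinates (y down rows), so "up" on screen is 270 degrees and due
# west is 180 degrees.

#' Longitudinal-axis ratio profile for one frame
#'
#' Samples the ratio image along the leading-edge-to-uropod chord at
#' <= 0.5 px spacing (midpoint positions), averaging across a 3-px-wide
#' band normal to the axis, and reduces the profile to \code{nBins}
#' equal-length bin means (bin 1 at the leading edge). The sample count
#' is a multiple of \code{nBins}, so the mean of the bin means equals
#' the profile mean exactly.
#'
#' @param ratioFrame numeric matrix (NA where invalid).
#' @param front,rear leading-edge and uropod anchor points c(x, y), um.
#' @param pixelSize um per pixel.
#' @param nBins number of bins (default 20, i.e. 5 percent bins).
#' @param spacingPx maximum sample spacing along the axis, px.
#' @param bandPx width of the averaging band normal to the axis, px.
#' @return list(pos = axial positions um from the leading edge,
#'   value = ratio samples, bins = bin means, axisLength = um).
#' @export
axisProfile <- function(ratioFrame, front, rear, pixelSize, nBins = 20,
                        spacingPx = 0.5, bandPx = 3) {
  axis <- rear - front
  L <- vecNorm(axis)
  if (L < nBins * pixelSize)
    stop(sprintf("axis (%.2f um) shorter than %d pixels", L, nBins))
  u <- axis / L
  nrm <- c(-u[2], u[1])
  perBin <- max(1L, ceiling(L / (spacingPx * pixelSize) / nBins))
  nS <- perBin * nBins
  pos <- (seq_len(nS) - 0.5) / nS * L
  offs <- (seq_len(bandPx) - (bandPx + 1) / 2) * pixelSize
  acc <- matrix(NA_real_, nS, length(offs))
  for (k in seq_along(offs)) {
    px <- front[1] + pos * u[1] + offs[k] * nrm[1]
    py <- front[2] + pos * u[2] + offs[k] * nrm[2]
    acc[, k] <- bilinearSample(ratioFrame, px, py, pixelSize)
  }
  val <- rowMeans(acc, na.rm = TRUE)
  val[is.nan(val)] <- NA_real_
  list(pos = pos, value = val, bins = binMeans(val, nBins),
       axisLength = L)
}

#' Equal-length bin means of a profile
#'
#' Reduces an equally spaced profile to \code{nBins} bin means; the
#' sample count must be a multiple of \code{nBins} (as produced by
#' \code{\link{axisProfile}}), so the mean of the bin means equals the
#' profile mean.
#'
#' @param values numeric profile samples.
#' @param nBins number of bins.
#' @return numeric vector of \code{nBins} bin means.
#' @export
binMeans <- function(values, nBins) {
  stopifnot(length(values) %% nBins == 0)
  perBin <- length(values) / nBins
  vapply(seq_len(nBins), function(b) {
    v <- values[((b - 1) * perBin + 1):(b * perBin)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
}

#' Axis profiles for every frame of a tracked cell
#'
#' @param ratio a \linkS4class{RatioMovie}.
#' @param track a \linkS4class{CellTrack}.
#' @param nBins number of bins per frame.
#' @return an \linkS4class{AxisProfileSeries}.
#' @export
axisProfileSeries <- function(ratio, track, nBins = 20) {
  n <- nFrames(ratio)
  profs <- vector("list", n)
  bins <- matrix(NA_real_, n, nBins)
  axl <- rep(NA_real_, n)
  for (f in seq_len(n)) {
    fr <- track@frontAnchor[f, ]
    re <- track@rearAnchor[f, ]
    if (anyNA(fr) || anyNA(re)) next
    p <- tryCatch(
      axisProfile(ratio@ratio[, , f], fr, re, ratio@pixelSize, nBins),
      error = function(e) NULL)
    if (is.null(p) || all(is.na(p$value))) next
    profs[[f]] <- p[c("pos", "value")]
    bins[f, ] <- p$bins
    axl[f] <- p$axisLength
  }
  new("AxisProfileSeries", profiles = profs, bins = bins,
      axisLength = axl, frameInterval = ratio@frameInterval)
}

#' Kymograph matrix of binned axis profiles
#'
#' Row t is the binned profile at frame t, leading edge in column 1.
#'
#' @param profiles an \linkS4class{AxisProfileSeries} with >= 2 frames.
#' @return frames x bins numeric matrix.
#' @export
kymograph <- function(profiles) {
  if (nFrames(profiles) < 2) stop("need at least 2 frames")
  profiles@bins
}

#' Reverse the axis orientation of a profile series
#'
#' Swaps the leading-edge/uropod assignment: bin k becomes bin
#' nBins + 1 - k and profile positions are measured from the other pole.
#'
#' @param profiles an \linkS4class{AxisProfileSeries}.
#' @return an \linkS4class{AxisProfileSeries}.
#' @export
reverseAxis <- function(profiles) {
  nb <- ncol(profiles@bins)
  pr <- lapply(seq_along(profiles@profiles), function(f) {
    p <- profiles@profiles[[f]]
    if (is.null(p)) return(NULL)
    L <- profiles@axisLength[f]
    list(pos = rev(L - p$pos), value = rev(p$value))
  })
  new("AxisProfileSeries", profiles = pr,
      bins = profiles@bins[, nb:1, drop = FALSE],
      axisLength = profiles@axisLength,
      frameInterval = profiles@frameInterval)
}

#' Peripheral edge-band ratio by angular position
#'
#' Mean ratio of in-mask pixels whose centre lies within
#' \code{bandWidth} of the cell contour, grouped by angular position
#' about the centroid (default 360 one-degree bins). Pixels farther from
#' the contour contribute nothing.
#'
#' @param ratioFrame numeric matrix (NA invalid).
#' @param contour closed polyline (n x 2, um).
#' @param pixelSize um per pixel.
#' @param bandWidth band width, um (default 0.4). If narrower than one
#'   pixel it is widened to one pixel with a warning.
#' @param nAngularBins number of angular bins covering 360 degrees.
#' @param mask optional logical matrix of in-cell pixels; derived from
#'   the contour when absent.
#' @param centroid optional c(x, y) um; contour vertex mean when absent.
#' @return numeric vector of length \code{nAngularBins} (NA where the
#'   band has no pixels), bin b centred near (b - 0.5) * 360 / n deg.
#' @export
edgeBandValues <- function(ratioFrame, contour, pixelSize,
                           bandWidth = 0.4, nAngularBins = 360,
                           mask = NULL, centroid = NULL) {
  if (bandWidth <= 0) stop("bandWidth must be > 0")
  if (bandWidth < pixelSize) {
    warning("band narrower than one pixel; widened to 1 px")
    bandWidth <- pixelSize
  }
  g <- pixelGrid(dim(ratioFrame), pixelSize, expand = TRUE)
  pts <- cbind(as.vector(g$X), as.vector(g$Y))
  if (is.null(mask)) {
    inside <- pointInPolygon(pts, contour)
  } else inside <- as.vector(mask)
  if (is.null(centroid)) centroid <- colMeans(contour)
  # restrict the distance computation to pixels near the contour
  bb <- apply(contour, 2, range)
  cand <- inside &
    pts[, 1] >= bb[1, 1] - bandWidth & pts[, 1] <= bb[2, 1] + bandWidth &
    pts[, 2] >= bb[1, 2] - bandWidth & pts[, 2] <= bb[2, 2] + bandWidth
  idx <- which(cand)
  if (!length(idx)) return(rep(NA_real_, nAngularBins))
  dd <- distanceToPolyline(pts[idx, , drop = FALSE], contour)
  sel <- idx[dd <= bandWidth]
  vals <- as.vector(ratioFrame)[sel]
  keep <- is.finite(vals)
  sel <- sel[keep]; vals <- vals[keep]
  out <- rep(NA_real_, nAngularBins)
  if (!length(sel)) return(out)
  ang <- atan2(pts[sel, 2] - centroid[2],
               pts[sel, 1] - centroid[1]) * 180 / pi
  ang <- (ang + 360) %% 360
  bin <- pmin(nAngularBins, floor(ang / (360 / nAngularBins)) + 1L)
  agg <- tapply(vals, bin, mean)
  out[as.integer(names(agg))] <- as.vector(agg)
  out
}

#' Polar map of edge-band activity
#'
#' Rotates per-frame angular edge profiles so the chemoattractant
#' needle direction maps to a fixed compass point (due west, 180
#' degrees, by default) and stacks frames radially (first frame
#' innermost when rendered).
#'
#' @param edgeProfiles frames x nAngular matrix (rows from
#'   \code{\link{edgeBandValues}}).
#' @param needleDirectionDeg needle direction per frame, degrees in
#'   image coordinates (NA allowed: those frames stay unrotated, with
#'   one warning).
#' @param referenceDeg compass angle the needle is rotated to.
#' @return a \linkS4class{PolarMap}.
#' @export
polarMap <- function(edgeProfiles, needleDirectionDeg,
                     referenceDeg = 180) {
  edgeProfiles <- rbind(edgeProfiles)
  nb <- ncol(edgeProfiles)
  if (length(needleDirectionDeg) == 1)
    needleDirectionDeg <- rep(needleDirectionDeg, nrow(edgeProfiles))
  if (anyNA(needleDirectionDeg))
    warning("missing needle annotation; affected frames left unrotated")
  binW <- 360 / nb
  out <- edgeProfiles
  for (f in seq_len(nrow(edgeProfiles))) {
    nd <- needleDirectionDeg[f]
    if (is.na(nd)) next
    shift <- round((referenceDeg - nd) / binW) %% nb
    if (shift == 0) next
    out[f, ] <- edgeProfiles[f, ((seq_len(nb) - 1 - shift) %% nb) + 1]
  }
  new("PolarMap", values = out,
      anglesDeg = (seq_len(nb) - 0.5) * binW, referenceDeg = referenceDeg)
}

#' Combine polar maps across cells
#'
#' Angular-bin-wise mean of maps with identical geometry.
#'
#' @param maps list of \linkS4class{PolarMap}.
#' @return a \linkS4class{PolarMap}.
#' @export
combinePolarMaps <- function(maps) {
  stopifnot(length(maps) >= 1)
  vals <- lapply(maps, function(m) m@values)
  d <- dim(vals[[1]])
  arr <- array(unlist(vals), c(d, length(vals)))
  new("PolarMap", values = apply(arr, c(1, 2), mean, na.rm = TRUE),
      anglesDeg = maps[[1]]@anglesDeg,
      referenceDeg = maps[[1]]@referenceDeg)
}

#' Trace the peak-activity position and its pole oscillations
#'
#' Finds the maximum-ratio sample of the un-binned axis profile per
#' frame, labels it by pole zone (within \code{poleZone} um of the
#' leading edge or uropod along the axis), and derives switch events
#' (the peak entering one pole zone after last having been in the
#' opposite zone), wave durations (intervals between successive
#' switches) and per-pole dwell times. Ties are broken toward the
#' previous frame's peak, then toward the leading edge; frames with no
#' defined profile are skipped and no switch is inferred across a gap.
#'
#' @param profiles an \linkS4class{AxisProfileSeries}.
#' @param poleZone pole-zone half-width, um (default 0.8).
#' @return a \linkS4class{PeakTrace}.
#' @export
peakTrace <- function(profiles, poleZone = 0.8) {
  n <- nFrames(profiles)
  if (n < 1) stop("empty profile series")
  dt <- profiles@frameInterval
  peakUm <- rep(NA_real_, n)
  zone <- rep(NA_character_, n)
  switchFlag <- rep(FALSE, n)
  switchTimes <- numeric()
  lastPole <- NA_character_
  gapSince <- FALSE
  prevPeak <- NA_real_
  for (f in seq_len(n)) {
    p <- profiles@profiles[[f]]
    if (is.null(p) || all(is.na(p$value))) { gapSince <- TRUE; next }
    v <- p$value
    mx <- max(v, na.rm = TRUE)
    cand <- which(v == mx)
    if (length(cand) > 1) {
      if (is.finite(prevPeak)) {
        cand <- cand[order(abs(p$pos[cand] - prevPeak), p$pos[cand])]
      } else cand <- cand[order(p$pos[cand])]
    }
    pk <- p$pos[cand[1]]
    peakUm[f] <- pk
    prevPeak <- pk
    L <- profiles@axisLength[f]
    z <- if (pk <= poleZone) "front"
         else if (pk >= L - poleZone) "rear" else "interior"
    zone[f] <- z
    if (z %in% c("front", "rear")) {
      if (gapSince || is.na(lastPole)) {
        lastPole <- z
      } else if (z != lastPole) {
        switchFlag[f] <- TRUE
        switchTimes <- c(switchTimes, (f - 1) * dt)
        lastPole <- z
      }
      gapSince <- FALSE
    }
  }
  tab <- data.frame(
    frame = seq_len(n), time_s = (seq_len(n) - 1) * dt,
    peak_um_from_front = peakUm,
    peak_fraction = peakUm / profiles@axisLength,
    zone = zone, switch_flag = switchFlag)
  new("PeakTrace", table = tab, switchTimes = switchTimes,
      waveDurations = if (length(switchTimes) >= 2) diff(switchTimes)
                      else numeric(),
      dwellFront = sum(zone == "front", na.rm = TRUE) * dt,
      dwellRear = sum(zone == "rear", na.rm = TRUE) * dt,
      poleZone = poleZone, frameInterval = dt,
      convention = "oscillations counted as pole-switch events")
}

#' Leading-edge, uropod and whole-cell activity AUC
#'
#' Time-integrals (trapezoid) of the mean of bins 2-3 (leading edge),
#' bins 18-19 (uropod) and bins 1-20 (whole cell), 1-indexed from the
#' leading edge, over the observation period.
#'
#' @param profiles an \linkS4class{AxisProfileSeries} with >= 2 frames
#'   and at least 20 bins.
#' @param frontBins,rearBins bin indices summarized as leading edge and
#'   uropod.
#' @return list(leadingEdge, uropod, wholeCell, window) of AUC values
#'   (ratio x s) and the time window used.
#' @export
frontBackSummary <- function(profiles, frontBins = 2:3,
                             rearBins = 18:19) {
  if (nFrames(profiles) < 2) stop("need at least 2 frames")
  b <- profiles@bins
  t <- (seq_len(nrow(b)) - 1) * profiles@frameInterval
  mk <- function(cols) data.frame(
    time_s = t, value = rowMeans(b[, cols, drop = FALSE]))
  w <- range(t)
  list(leadingEdge = aucWindow(mk(frontBins), w),
       uropod = aucWindow(mk(rearBins), w),
       wholeCell = aucWindow(mk(seq_len(ncol(b))), w),
       window = w)
}
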