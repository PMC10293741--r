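# Cell tracking: per-frame contour, centroid, smoothed heading, and the
# leading-edge / uropod anchors (extremal contour points along the
# heading). Input is one segmented mask stack per cell; where several
# objects are present per frame the largest is taken.

#' Build a cell track from per-frame masks
#'
#' Computes per-frame sub-pixel contours and centroids, a unit heading
#' smoothed over a 5 s window (falling back to the mask's long-axis
#' orientation, with sign continuity, when the cell barely moves), and
#' the leading-edge/uropod anchors as the contour points extremal along
#' +/- heading.
#'
#' @param masks logical/binary array rows x cols x frames (one cell; the
#'   largest object is used when a frame holds several).
#' @param pixelSize um per pixel.
#' @param frameInterval seconds per frame.
#' @param headingWindow smoothing window for the heading, s.
#' @param minSpeed displacement rate (um/s) below which the long-axis
#'   fallback orientation is used.
#' @param onGap behavior when the cell is lost for more than 2
#'   consecutive frames: keep the "longest" contiguous segment (with a
#'   warning) or "error".
#' @return a \linkS4class{CellTrack}.
#' @export
buildTrack <- function(masks, pixelSize, frameInterval,
                       headingWindow = 5, minSpeed = 0.02,
                       onGap = c("longest", "error")) {
  onGap <- match.arg(onGap)
  d <- dim(masks)
  n <- d[3]
  if (n < 2) stop("need at least 2 frames to build a track")
  present <- vapply(seq_len(n), function(f) any(masks[, , f] > 0), TRUE)
  if (!all(present)) {
    r <- rle(present)
    if (any(!r$values & r$lengths > 2)) {
      if (onGap == "error") stop("cell lost for > 2 consecutive frames")
      warning("cell lost for > 2 consecutive frames; ",
              "keeping the longest contiguous segment")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      seg <- which(r$values)[which.max(r$lengths[r$values])]
      keep <- rep(FALSE, n)
      keep[starts[seg]:ends[seg]] <- TRUE
      return(buildTrack(masks[, , keep, drop = FALSE], pixelSize,
                        frameInterval, headingWindow, minSpeed))
    }
  }
  if (sum(present) < 2) stop("need at least 2 frames with a cell mask")

  keepLargest <- function(m) {
    lab <- EBImage::bwlabel(m * 1)
    if (max(lab) <= 1) return(m > 0)
    sizes <- tabulate(lab[lab > 0])
    lab == which.max(sizes)
  }

  cmask <- array(FALSE, d)
  ctr <- matrix(NA_real_, n, 2)
  cont <- vector("list", n)
  for (f in seq_len(n)) {
    if (!present[f]) next
    m <- keepLargest(masks[, , f])
    cmask[, , f] <- m
    ctr[f, ] <- maskCentroid(m, pixelSize)
    cont[[f]] <- maskContour(m, pixelSize)
  }
  # bridge <=2-frame gaps in the centroid for heading computation
  for (k in 1:2) ctr[, k] <- approx(which(present),
                                    ctr[present, k],
                                    xout = seq_len(n), rule = 2)$y

  w <- max(1L, round(headingWindow / frameInterval))
  if (w %% 2 == 0) w <- w + 1L
  vx <- rollMean(c(diff(ctr[, 1]), NA), w)
  vy <- rollMean(c(diff(ctr[, 2]), NA), w)
  vx[n] <- vx[n - 1]; vy[n] <- vy[n - 1]
  speed <- sqrt(vx^2 + vy^2) / frameInterval

  head <- matrix(NA_real_, n, 2)
  lastH <- NULL
  for (f in seq_len(n)) {
    if (is.finite(speed[f]) && speed[f] >= minSpeed) {
      h <- c(vx[f], vy[f]) / sqrt(vx[f]^2 + vy[f]^2)
    } else {
      h <- maskPrincipalAxis(cmask[, , f])
      if (!is.null(lastH)) {
        if (sum(h * lastH) < 0) h <- -h
      } else if (!is.null(cont[[f]])) {
        # orient toward the pole with greater extent from the centroid
        # (the protrusive front of a polarized outline)
        proj <- (cont[[f]][, 1] - ctr[f, 1]) * h[1] +
                (cont[[f]][, 2] - ctr[f, 2]) * h[2]
        if (max(proj) < -min(proj)) h <- -h
      }
    }
    head[f, ] <- h
    lastH <- h
  }

  # anchors: extremal contour points along the heading; among points
  # within half a pixel of the extreme (flat rasterized tips), take the
  # one nearest the central axis
  front <- rear <- matrix(NA_real_, n, 2)
  for (f in seq_len(n)) {
    p <- cont[[f]]
    if (is.null(p)) next
    dx <- p[, 1] - ctr[f, 1]; dy <- p[, 2] - ctr[f, 2]
    proj <- dx * head[f, 1] + dy * head[f, 2]
    off <- abs(dx * head[f, 2] - dy * head[f, 1])
    tip <- which(proj >= max(proj) - 0.5 * pixelSize)
    front[f, ] <- p[tip[which.min(off[tip])], ]
    tail <- which(proj <= min(proj) + 0.5 * pixelSize)
    rear[f, ] <- p[tail[which.min(off[tail])], ]
  }
  new("CellTrack", masks = cmask, contours = cont, centroid = ctr,
      heading = head, frontAnchor = front, rearAnchor = rear,
      pixelSize = pixelSize, frameInterval = frameInterval)
}

#' Build a track directly from ground truth
#'
#' Convenience for recovery tests and noiseless pipelines: uses the
#' simulator's true masks.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param pixelSize um per pixel.
#' @param frameInterval seconds per frame.
#' @return a \linkS4class{CellTrack}.
#' @export
trackFromTruth <- function(truth, pixelSize, frameInterval) {
  buildTrack(truth@mask, pixelSize, frameInterval)
}
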