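# Phagocytosis quantification: particle detection/tracking in
# brightfield, phagosomal FRET traces with contact and engulfment
# timing, and particle-uptake counts on labeled fixed-cell scenes.

#' Detect and track particles in a brightfield stack
#'
#' Detects circular objects of the expected diameter (within +/- 30
#' percent) as dark blobs against the brightfield background and links
#' detections across frames by nearest neighbor within one diameter per
#' frame. Detections whose area suggests two merged particles are
#' flagged ambiguous.
#'
#' @param brightfield rows x cols x frames numeric array.
#' @param pixelSize um per pixel.
#' @param frameInterval seconds per frame.
#' @param particleDiameter expected particle diameter, um (> 0).
#' @param diameterTol relative tolerance on the equivalent diameter.
#' @return list of tracks, each a data.frame(frame, time_s, x_um, y_um,
#'   ambiguous); empty list when nothing is detected.
#' @export
detectParticles <- function(brightfield, pixelSize, frameInterval,
                            particleDiameter = 2, diameterTol = 0.3) {
  if (particleDiameter <= 0) stop("particleDiameter must be > 0")
  d <- dim(brightfield)
  detections <- vector("list", d[3])
  for (f in seq_len(d[3])) {
    fr <- brightfield[, , f]
    bg <- median(fr)
    dark <- bg - fr
    spread <- max(dark)
    if (spread <= 0) next
    mask <- dark > 0.5 * spread
    lab <- EBImage::bwlabel(mask * 1)
    if (max(lab) == 0) next
    rows <- list()
    for (i in seq_len(max(lab))) {
      npx <- sum(lab == i)
      eqd <- 2 * sqrt(npx / pi) * pixelSize
      if (eqd < particleDiameter * (1 - diameterTol)) next
      if (eqd > particleDiameter * (1 + diameterTol)) {
        # possibly merged particles: keep, flagged
        if (eqd > particleDiameter * 2.5) next
        amb <- TRUE
      } else amb <- FALSE
      idx <- which(lab == i, arr.ind = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, time_s = (f - 1) * frameInterval,
        x_um = (mean(idx[, 2]) - 0.5) * pixelSize,
        y_um = (mean(idx[, 1]) - 0.5) * pixelSize,
        ambiguous = amb)
    }
    if (length(rows)) detections[[f]] <- do.call(rbind, rows)
  }
  # nearest-neighbor linking within one diameter per frame step
  tracks <- list()
  active <- list()
  for (f in seq_len(d[3])) {
    det <- detections[[f]]
    used <- logical(if (is.null(det)) 0 else nrow(det))
    for (j in seq_along(active)) {
      tr <- tracks[[active[[j]]]]
      lastRow <- tr[nrow(tr), ]
      if (!is.null(det) && f - lastRow$frame <= 1) {
        dd <- sqrt((det$x_um - lastRow$x_um)^2 +
                   (det$y_um - lastRow$y_um)^2)
        k <- which.min(dd)
        if (length(k) && dd[k] <= particleDiameter && !used[k]) {
          tracks[[active[[j]]]] <- rbind(tr, det[k, ])
          used[k] <- TRUE
          next
        }
      }
      active[[j]] <- NA  # track ends
    }
    active <- Filter(function(a) !is.na(a[1]), active)
    if (!is.null(det)) for (k in which(!used)) {
      tracks[[length(tracks) + 1]] <- det[k, , drop = FALSE]
      active[[length(active) + 1]] <- length(tracks)
    }
  }
  lapply(tracks, function(t) { rownames(t) <- NULL; t })
}

#' Phagosomal FRET trace from contact to full engulfment
#'
#' Contact is the first frame at which the particle boundary comes
#' within one pixel of the cell mask; full engulfment the first frame
#' at which the whole particle disk lies inside the mask eroded by one
#' pixel (the erosion guards against boundary-pixel flicker). The
#' per-frame readout is the mean ratio over the in-mask annulus of
#' \code{annulusWidth} around the particle -- the forming phagosome
#' cup, where the sensor signal lives -- from contact until full
#' engulfment is reached (or the movie ends).
#'
#' @param ratio a \linkS4class{RatioMovie}.
#' @param track a \linkS4class{CellTrack}.
#' @param particleTrack data.frame(frame, x_um, y_um) from
#'   \code{\link{detectParticles}}, or the simulator's true particle
#'   positions.
#' @param particleDiameter particle diameter, um.
#' @param annulusWidth annulus width, um.
#' @return a \linkS4class{PhagosomeTrace} (empty table with
#'   complete = FALSE when the particle never contacts the cell).
#' @export
phagosomeTrace <- function(ratio, track, particleTrack,
                           particleDiameter = 2, annulusWidth = 0.5) {
  ps <- ratio@pixelSize
  dt <- ratio@frameInterval
  r <- particleDiameter / 2
  g <- pixelGrid(dim(ratio@ratio)[1:2], ps, expand = TRUE)
  contactF <- engulfF <- NA_integer_
  rows <- list()
  theta <- seq(0, 2 * pi, length.out = 33L)[-33L]
  for (i in seq_len(nrow(particleTrack))) {
    f <- particleTrack$frame[i]
    if (f > nFrames(ratio)) break
    mask <- track@masks[, , f]
    if (!any(mask)) next
    cx <- particleTrack$x_um[i]; cy <- particleTrack$y_um[i]
    # distance of the particle boundary to the cell mask
    distOut <- EBImage::distmap((!mask) * 1) * ps
    bd <- bilinearSample(distOut, cx + r * cos(theta),
                         cy + r * sin(theta), ps)
    if (is.na(contactF) && any(bd <= 1 * ps + 1e-9, na.rm = TRUE))
      contactF <- f
    if (!is.na(contactF) && is.na(engulfF)) {
      er <- EBImage::erode(mask * 1,
                           EBImage::makeBrush(3L, "box")) > 0
      pd <- sqrt((g$X - cx)^2 + (g$Y - cy)^2)
      diskPix <- pd <= r
      if (any(diskPix) && all(er[diskPix])) engulfF <- f
    }
    if (!is.na(contactF) && f >= contactF) {
      pd <- sqrt((g$X - cx)^2 + (g$Y - cy)^2)
      ann <- mask & ratio@valid[, , f] & pd > r & pd <= r + annulusWidth
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, time_s = (f - 1) * dt,
        mean_ratio = if (any(ann)) mean(ratio@ratio[, , f][ann])
                     else NA_real_,
        engulfing = is.na(engulfF) || f <= engulfF)
    }
  }
  complete <- !is.na(engulfF)
  if (is.na(contactF)) {
    return(new("PhagosomeTrace",
               table = data.frame(frame = integer(), time_s = numeric(),
                                  mean_ratio = numeric(),
                                  engulfing = logical()),
               contactTime = NA_real_, engulfedTime = NA_real_,
               engulfmentTime = NA_real_, complete = FALSE))
  }
  new("PhagosomeTrace", table = do.call(rbind, rows),
      contactTime = (contactF - 1) * dt,
      engulfedTime = if (complete) (engulfF - 1) * dt else NA_real_,
      engulfmentTime = if (complete) (engulfF - contactF) * dt
                       else NA_real_,
      complete = complete)
}

#' Count particle uptake in a labeled fixed-cell scene
#'
#' A particle counts as taken up iff it lies inside a cell mask and its
#' phagosomal-membrane flag is positive (distinguishing internalized
#' particles from ones attached to the outside). Particles inside two
#' overlapping masks are assigned to the nearer cell centroid with a
#' warning.
#'
#' @param cellMasks list of logical matrices (one per cell, common
#'   geometry).
#' @param particles data.frame(x_um, y_um, membrane_flag).
#' @param pixelSize um per pixel.
#' @return list(perCell = integer counts, meanPerCell,
#'   fractionWithUptake).
#' @export
countUptake <- function(cellMasks, particles, pixelSize) {
  if (!length(cellMasks)) stop("no cell masks supplied")
  nC <- length(cellMasks)
  counts <- integer(nC)
  cents <- t(vapply(cellMasks, maskCentroid, numeric(2),
                    pixelSize = pixelSize))
  for (i in seq_len(nrow(particles) %||% 0)) {
    px <- particles$x_um[i]; py <- particles$y_um[i]
    r <- pmax(1L, pmin(round(py / pixelSize + 0.5),
                       nrow(cellMasks[[1]])))
    c_ <- pmax(1L, pmin(round(px / pixelSize + 0.5),
                        ncol(cellMasks[[1]])))
    inC <- which(vapply(cellMasks, function(m) m[r, c_], TRUE))
    if (!length(inC)) next
    if (length(inC) > 1) {
      warning("particle inside overlapping masks; assigned to nearer centroid")
      dd <- sqrt((cents[inC, 1] - px)^2 + (cents[inC, 2] - py)^2)
      inC <- inC[which.min(dd)]
    }
    if (isTRUE(particles$membrane_flag[i]))
      counts[inC] <- counts[inC] + 1L
  }
  list(perCell = counts, meanPerCell = mean(counts),
       fractionWithUptake = mean(counts >= 1))
}
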