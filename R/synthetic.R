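# Synthetic two-channel biosensor movies with known ground truth.
#
# The renderer is phenomenological: a smooth star-shaped cell contour
# (harmonically perturbed ellipse aligned with the heading, plus optional
# protrusion bumps), a strictly positive FRET-ratio field (baseline +
# front-high gradient + travelling axial peak + peripheral enrichment),
# donor intensity set by a uniform cell brightness, and acceptor = ratio
# x donor before noise. Noise is Poisson photon noise followed by
# additive Gaussian read noise, per channel.

#' Construct an acquisition configuration
#'
#' @param pixelSize um per pixel. The default 0.27 um/px is nominal for a
#'   60x objective on a 16-um-pixel EM-CCD.
#' @param frameInterval seconds between frames (the assays use 1 or 5 s).
#' @param frameCount number of frames.
#' @param imageShape c(rows, cols) in pixels.
#' @param photonScale expected donor photons at unit scene intensity.
#' @param readNoiseSD Gaussian read noise SD, photons.
#' @param background background level, photons.
#' @param misalignment 2x3 affine (um, donor frame -> acceptor frame);
#'   see \code{\link{affineTransform}}.
#' @param seed integer seed for the renderer (NA = leave RNG alone).
#' @return an \linkS4class{AcquisitionConfig}.
#' @export
acquisitionConfig <- function(pixelSize = 0.27, frameInterval = 1,
                              frameCount = 120L,
                              imageShape = c(128L, 128L),
                              photonScale = 200, readNoiseSD = 2,
                              background = 5,
                              misalignment = identityAffine(),
                              seed = NA_integer_) {
  new("AcquisitionConfig", pixelSize = pixelSize,
      frameInterval = frameInterval, frameCount = as.integer(frameCount),
      imageShape = as.integer(imageShape), photonScale = photonScale,
      readNoiseSD = readNoiseSD, background = background,
      misalignment = misalignment, seed = as.integer(seed))
}

#' Construct a cell shape model
#'
#' @param centroid frames x 2 matrix of centroid positions (um), or a
#'   single c(x, y) replicated over \code{frames}.
#' @param heading frames x 2 unit headings, or a single direction.
#' @param bodyLength,bodyWidth cell dimensions, um. The 15.6 um default
#'   length is twice the 7.8 um half body length of a polarized
#'   neutrophil.
#' @param harmonics relative amplitudes of contour harmonics 2, 3, ...
#' @param protrusions data.frame(onset_s, angle_deg, growth_um_s,
#'   width_deg) of programmed protrusion bumps (angles in the lab frame).
#' @param frames frame count when centroid/heading are single points.
#' @param frameInterval seconds per frame.
#' @return a \linkS4class{CellModel}.
#' @export
cellModel <- function(centroid, heading = c(1, 0), bodyLength = 15.6,
                      bodyWidth = 9, harmonics = c(0.06, 0.03),
                      protrusions = NULL, frames = NULL,
                      frameInterval = 1) {
  if (is.null(dim(centroid)))
    centroid <- matrix(centroid, nrow = frames %||% 1L, ncol = 2,
                       byrow = TRUE)
  if (is.null(dim(heading)))
    heading <- matrix(heading, nrow = nrow(centroid), ncol = 2,
                      byrow = TRUE)
  heading <- heading / sqrt(rowSums(heading^2))
  if (is.null(protrusions))
    protrusions <- data.frame(onset_s = numeric(), angle_deg = numeric(),
                              growth_um_s = numeric(),
                              width_deg = numeric())
  new("CellModel", bodyLength = bodyLength, bodyWidth = bodyWidth,
      harmonics = harmonics, centroid = centroid, heading = heading,
      protrusions = protrusions, frameInterval = frameInterval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an activity field
#'
#' @param baselineRatio baseline FRET ratio (> 0).
#' @param gradientAmplitude front-minus-back ratio difference (front
#'   high when positive).
#' @param peakAmplitude height of the travelling axial peak.
#' @param peakPosition per-frame axial peak position as a fraction of
#'   axis length (0 = leading edge); see
#'   \code{\link{oscillatingPeakPosition}}.
#' @param peakWidth Gaussian sigma of the peak, um.
#' @param oscillationCycle full pole-to-pole-and-back period, s.
#' @param edgeEnrichment multiplicative ratio factor within the edge band.
#' @param edgeBandWidth width of the peripheral band, um.
#' @return an \linkS4class{ActivityField}.
#' @export
activityField <- function(baselineRatio = 1.2, gradientAmplitude = 0,
                          peakAmplitude = 0, peakPosition = numeric(),
                          peakWidth = 1.2, oscillationCycle = NA_real_,
                          edgeEnrichment = 1, edgeBandWidth = 0.8) {
  new("ActivityField", baselineRatio = baselineRatio,
      gradientAmplitude = gradientAmplitude,
      peakAmplitude = peakAmplitude, peakPosition = peakPosition,
      peakWidth = peakWidth, oscillationCycle = oscillationCycle,
      edgeEnrichment = edgeEnrichment, edgeBandWidth = edgeBandWidth)
}

#' Pole-to-pole triangle-wave peak trajectory
#'
#' Axial peak position oscillating between the leading edge (0) and the
#' uropod (1) as a triangle wave with full cycle \code{cycle} seconds,
#' starting at the leading edge.
#'
#' @param times frame times, s.
#' @param cycle full pole-to-pole-and-back period, s.
#' @return fractions in [0, 1], one per time.
#' @export
oscillatingPeakPosition <- function(times, cycle) {
  2 * abs(times / cycle - floor(times / cycle + 0.5))
}

# Contour radius (um) at angles theta relative to the heading, for one
# frame. Star-shaped by construction; protrusion bumps grow linearly
# from their onset.
contourRadius <- function(cell, frame, theta, headingAngle) {
  a <- cell@bodyLength / 2
  b <- cell@bodyWidth / 2
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (length(cell@harmonics)) {
    pert <- 0
    for (k in seq_along(cell@harmonics))
      pert <- pert + cell@harmonics[k] * cos((k + 1) * theta)
    r <- r * (1 + pert)
  }
  pr <- cell@protrusions
  if (nrow(pr)) {
    t <- (frame - 1) * cell@frameInterval
    for (i in seq_len(nrow(pr))) {
      amp <- pr$growth_um_s[i] * (t - pr$onset_s[i])
      if (amp <= 0) next
      dth <- (theta + headingAngle - pr$angle_deg[i] * pi / 180)
      dth <- atan2(sin(dth), cos(dth))
      sg <- pr$width_deg[i] * pi / 180
      r <- r + amp * exp(-dth^2 / (2 * sg^2))
    }
  }
  r
}

#' Evaluate a cell scene at arbitrary points
#'
#' Analytic evaluation of the true scene for one frame: inside/outside,
#' axial fraction and true FRET ratio at each query point. Used by the
#' renderer and available to tests as an oracle.
#'
#' @param cell a \linkS4class{CellModel}.
#' @param field an \linkS4class{ActivityField}.
#' @param frame frame index (1-based).
#' @param pts n x 2 matrix of query points (um).
#' @return list(inside = logical, ratio = numeric with NA outside,
#'   axialFraction = numeric).
#' @export
sceneEval <- function(cell, field, frame, pts) {
  ctr <- cell@centroid[frame, ]
  h <- cell@heading[frame, ]
  ha <- atan2(h[2], h[1])
  dx <- pts[, 1] - ctr[1]; dy <- pts[, 2] - ctr[2]
  rho <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) - ha
  th <- atan2(sin(th), cos(th))
  rc <- contourRadius(cell, frame, th, ha)
  inside <- rho <= rc
  rFront <- contourRadius(cell, frame, 0, ha)
  rRear <- contourRadius(cell, frame, pi, ha)
  axisLen <- rFront + rRear
  s <- dx * h[1] + dy * h[2]
  u <- clamp((rFront - s) / axisLen, 0, 1)
  ratio <- field@baselineRatio + field@gradientAmplitude * (1 - u)
  if (field@peakAmplitude != 0 && length(field@peakPosition) >= frame) {
    pk <- field@peakPosition[frame]
    ratio <- ratio + field@peakAmplitude *
      exp(-((u - pk) * axisLen)^2 / (2 * field@peakWidth^2))
  }
  if (field@edgeEnrichment != 1) {
    band <- inside & (rc - rho) <= field@edgeBandWidth
    ratio[band] <- ratio[band] * field@edgeEnrichment
  }
  ratio[!inside] <- NA_real_
  list(inside = inside, ratio = ratio, axialFraction = u)
}

withSeed <- function(seed, expr) {
  if (!is.na(seed)) {
    had <- exists(".Random.seed", envir = globalenv())
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()))
  }
  force(expr)
}

applyNoise <- function(expected, acq) {
  v <- expected
  if (acq@photonScale > 0)
    v <- array(rpois(length(v), lambda = pmax(0, v)), dim = dim(v))
  if (acq@readNoiseSD > 0)
    v <- v + array(rnorm(length(v), sd = acq@readNoiseSD), dim = dim(v))
  v
}

# Per-frame motility phase labels from a centroid trajectory: runs of
# per-step speed above/below displacement/minDuration, with runs shorter
# than minDuration left unlabeled.
phaseLabelsFromTrajectory <- function(centroid, dt, displacement = 2,
                                      minDuration = 20) {
  n <- nrow(centroid)
  if (n < 2) return(rep(NA_character_, n))
  step <- sqrt(rowSums((centroid[-1, , drop = FALSE] -
                        centroid[-n, , drop = FALSE])^2))
  moving <- step / dt >= displacement / minDuration
  r <- rle(moving)
  stepLab <- rep(NA_character_, n - 1)
  pos <- 1
  for (i in seq_along(r$lengths)) {
    len <- r$lengths[i]
    if (len * dt >= minDuration)
      stepLab[pos:(pos + len - 1)] <-
        if (r$values[i]) "migrating" else "stalling"
    pos <- pos + len
  }
  c(stepLab, stepLab[n - 1])
}

#' Render a synthetic two-channel biosensor movie
#'
#' Renders donor and acceptor stacks from a cell model and activity
#' field. The donor channel is a uniform cell brightness; the acceptor
#' channel equals the true ratio times the donor signal, so with noise
#' disabled, zero background and identity misalignment the per-pixel
#' acceptor/donor quotient reproduces the true field exactly. The
#' acceptor channel is rendered in the misaligned camera frame given by
#' \code{acq@misalignment} (evaluated analytically, not resampled).
#'
#' @param cell a \linkS4class{CellModel} (frame count must match
#'   \code{acq}).
#' @param field an \linkS4class{ActivityField}.
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @param brightness uniform cell brightness (donor scene intensity).
#' @param noise logical; apply the Poisson + Gaussian noise model.
#' @return list(movie = \linkS4class{TwoChannelMovie},
#'   truth = \linkS4class{GroundTruth}).
#' @export
renderMovie <- function(cell, field, acq, brightness = 1, noise = TRUE) {
  nF <- acq@frameCount
  if (nrow(cell@centroid) != nF)
    stop("cell model and acquisition config disagree on frame count")
  shp <- acq@imageShape
  ps <- acq@pixelSize
  fov <- c(shp[2], shp[1]) * ps  # x, y extent
  g <- pixelGrid(shp, ps, expand = TRUE)
  pts <- cbind(as.vector(g$X), as.vector(g$Y))
  Minv <- affineInvert(acq@misalignment)
  misaligned <- max(abs(acq@misalignment - identityAffine())) > 0
  ptsA <- if (misaligned) affineApply(Minv, pts) else pts

  don <- acc <- trueR <- array(NA_real_, c(shp[1], shp[2], nF))
  msk <- array(FALSE, c(shp[1], shp[2], nF))
  front <- rear <- matrix(NA_real_, nF, 2)
  pk <- rep(NA_real_, nF)

  for (f in seq_len(nF)) {
    h <- cell@heading[f, ]
    ha <- atan2(h[2], h[1])
    thc <- seq(0, 2 * pi, length.out = 361L)[-361L]
    rc <- contourRadius(cell, f, thc, ha)
    cx <- cell@centroid[f, 1] + rc * cos(thc + ha)
    cy <- cell@centroid[f, 2] + rc * sin(thc + ha)
    if (any(cx < 0 | cx > fov[1] | cy < 0 | cy > fov[2]))
      stop(sprintf("cell contour exits the field of view at frame %d", f))
    ev <- sceneEval(cell, field, f, pts)
    don[, , f] <- acq@background +
      acq@photonScale * brightness * ev$inside
    rA <- if (misaligned) sceneEval(cell, field, f, ptsA) else ev
    accSig <- ifelse(rA$inside, rA$ratio, 0)
    acc[, , f] <- acq@background +
      acq@photonScale * brightness * ifelse(is.na(accSig), 0, accSig)
    trueR[, , f] <- ev$ratio
    msk[, , f] <- ev$inside
    front[f, ] <- cell@centroid[f, ] + contourRadius(cell, f, 0, ha) * h
    rear[f, ] <- cell@centroid[f, ] - contourRadius(cell, f, pi, ha) * h
    if (field@peakAmplitude != 0 && length(field@peakPosition) >= f)
      pk[f] <- field@peakPosition[f]
  }

  if (noise) {
    withSeed(acq@seed, {
      don <- applyNoise(don, acq)
      acc <- applyNoise(acc, acq)
    })
  }

  movie <- new("TwoChannelMovie", donor = don, acceptor = acc,
               acceptorValid = array(TRUE, dim(don)), acq = acq)
  truth <- new("GroundTruth", ratio = trueR, mask = msk,
               centroid = cell@centroid, frontPoint = front,
               rearPoint = rear, peakAxialFraction = pk,
               phase = phaseLabelsFromTrajectory(cell@centroid,
                                                 acq@frameInterval),
               events = list())
  list(movie = movie, truth = truth)
}

#' Render a calibration bead field
#'
#' Sub-resolution fluorescent beads visible in both channels, with the
#' acceptor-channel bead positions displaced by \code{acq@misalignment}
#' -- the input for channel registration.
#'
#' @param nBeads number of beads (>= 3, enough to fit an affine).
#' @param acq an \linkS4class{AcquisitionConfig}; \code{seed} fixes the
#'   layout.
#' @param sigmaPx Gaussian spot sigma, px.
#' @param noise logical; apply the noise model.
#' @param returnTruth also return the true spot centres per channel.
#' @return a \linkS4class{TwoChannelMovie}, or (with
#'   \code{returnTruth = TRUE}) list(movie, donorCenters,
#'   acceptorCenters) with centres in um.
#' @export
renderBeadField <- function(nBeads, acq, sigmaPx = 1.3, noise = TRUE,
                            returnTruth = FALSE) {
  if (nBeads < 3)
    stop("at least 3 beads are required to constrain an affine transform")
  ps <- acq@pixelSize
  shp <- acq@imageShape
  margin <- (8 * sigmaPx + 6) * ps
  minSep <- 12 * ps  # beads must be resolvable as separate landmarks
  pos <- withSeed(acq@seed, {
    p <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(p) < nBeads && tries < 2000) {
      cand <- c(runif(1, margin, shp[2] * ps - margin),
                runif(1, margin, shp[1] * ps - margin))
      if (!nrow(p) ||
          min(sqrt((p[, 1] - cand[1])^2 + (p[, 2] - cand[2])^2)) >=
            minSep)
        p <- rbind(p, cand)
      tries <- tries + 1
    }
    if (nrow(p) < nBeads)
      stop("could not place ", nBeads, " beads at the required spacing")
    unname(p)
  })
  posA <- affineApply(acq@misalignment, pos)
  g <- pixelGrid(shp, ps, expand = TRUE)
  spot <- function(centers) {
    img <- matrix(acq@background, shp[1], shp[2])
    s2 <- 2 * (sigmaPx * ps)^2
    for (i in seq_len(nrow(centers)))
      img <- img + acq@photonScale *
        exp(-((g$X - centers[i, 1])^2 + (g$Y - centers[i, 2])^2) / s2)
    img
  }
  dframe <- spot(pos)
  aframe <- spot(posA)
  don <- array(rep(dframe, acq@frameCount),
               c(shp[1], shp[2], acq@frameCount))
  acc <- array(rep(aframe, acq@frameCount),
               c(shp[1], shp[2], acq@frameCount))
  if (noise) {
    withSeed(if (is.na(acq@seed)) NA_integer_ else acq@seed + 1L, {
      don <- applyNoise(don, acq)
      acc <- applyNoise(acc, acq)
    })
  }
  movie <- new("TwoChannelMovie", donor = don, acceptor = acc,
               acceptorValid = array(TRUE, dim(don)), acq = acq)
  if (returnTruth)
    list(movie = movie, donorCenters = pos, acceptorCenters = posA)
  else movie
}

#' Render a phagocytosis scene
#'
#' A round cell engulfing a particle: the particle approaches, makes
#' contact at \code{contactTime}, and sinks into the cell over
#' \code{engulfmentDuration}; between contact and full engulfment the
#' true ratio is elevated in an annulus around the particle (the forming
#' phagosome cup). A parallel brightfield stack shows the particle as a
#' dark disk.
#'
#' @param cell a \linkS4class{CellModel}; a round stationary cell is
#'   typical (see \code{\link{scenePhagocytosis}}).
#' @param particleDiameter particle diameter, um (default 2 um
#'   microspheres).
#' @param contactTime time of first particle-cell contact, s.
#' @param engulfmentDuration time from contact to full engulfment, s.
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @param annulusRatio true ratio inside the phagosome annulus during
#'   engulfment.
#' @param annulusWidth annulus width, um.
#' @param noise logical; apply the noise model.
#' @return list(movie, brightfield = rows x cols x frames array,
#'   truth = \linkS4class{GroundTruth} with events contact_s,
#'   engulfed_s, contact_frame, engulfed_frame and the particle track in
#'   \code{events$particle} (frames x 2, um)).
#' @export
renderPhagocytosisScene <- function(cell, particleDiameter = 2,
                                    contactTime, engulfmentDuration,
                                    acq, annulusRatio = 2,
                                    annulusWidth = 0.5, noise = TRUE) {
  if (particleDiameter <= 0) stop("particleDiameter must be > 0")
  nF <- acq@frameCount
  dt <- acq@frameInterval
  duration <- (nF - 1) * dt
  if (contactTime + engulfmentDuration > duration)
    stop("contact + engulfment must fit within the movie duration")
  ps <- acq@pixelSize
  r <- particleDiameter / 2
  ctr <- cell@centroid[1, ]
  R <- cell@bodyLength / 2  # round cell assumed for the engulfment path
  # The centre-to-centre distance d is programmed so the analysis
  # predicates flip decisively at the stated frames: clearly apart
  # (> 1 px boundary gap) before contact, overlapping the mask edge
  # from the contact frame, sinking but never fully inside during the
  # cup phase, and well inside the 1-px-eroded mask from the full-
  # engulfment frame on. The margins exceed the pixel quantization of
  # the rasterized masks, so detected frames match programmed frames.
  dTouch <- R + r - 0.5 * ps
  dAlmost <- R - r + 1.5 * ps
  dInside <- R - r - 2.5 * ps
  engulfTime <- contactTime + engulfmentDuration
  approachSpeed <- 0.1
  times <- (seq_len(nF) - 1) * dt
  d <- ifelse(times < contactTime,
              R + r + 2.5 * ps +
                approachSpeed * (contactTime - times),
              ifelse(times < engulfTime,
                     dTouch + (dAlmost - dTouch) *
                       (times - contactTime) /
                       max(engulfmentDuration, dt),
                     dInside))
  particle <- cbind(ctr[1] + d, rep(ctr[2], nF))

  shp <- acq@imageShape
  g <- pixelGrid(shp, ps, expand = TRUE)
  pts <- cbind(as.vector(g$X), as.vector(g$Y))
  field <- activityField(baselineRatio = 1)
  don <- acc <- trueR <- array(NA_real_, c(shp[1], shp[2], nF))
  bf <- array(NA_real_, c(shp[1], shp[2], nF))
  msk <- array(FALSE, c(shp[1], shp[2], nF))
  front <- rear <- matrix(NA_real_, nF, 2)
  engulfing <- times >= contactTime &
    times <= contactTime + engulfmentDuration
  for (f in seq_len(nF)) {
    ev <- sceneEval(cell, field, f, pts)
    ratio <- ev$ratio
    pd <- sqrt((pts[, 1] - particle[f, 1])^2 +
               (pts[, 2] - particle[f, 2])^2)
    if (engulfing[f]) {
      ann <- ev$inside & pd > r & pd <= r + annulusWidth
      ratio[ann] <- annulusRatio
    }
    don[, , f] <- acq@background + acq@photonScale * ev$inside
    acc[, , f] <- acq@background + acq@photonScale *
      ifelse(ev$inside, ratio, 0)
    trueR[, , f] <- ratio
    msk[, , f] <- ev$inside
    h <- cell@heading[f, ]
    front[f, ] <- ctr + R * h
    rear[f, ] <- ctr - R * h
    bff <- matrix(0.7, shp[1], shp[2])
    bff[matrix(ev$inside, shp[1], shp[2])] <- 0.6
    bff[matrix(pd <= r, shp[1], shp[2])] <- 0.15
    bf[, , f] <- bff
  }
  if (noise) {
    withSeed(acq@seed, {
      don <- applyNoise(don, acq)
      acc <- applyNoise(acc, acq)
      bf <- bf + array(rnorm(length(bf), sd = 0.01), dim(bf))
    })
  }
  movie <- new("TwoChannelMovie", donor = don, acceptor = acc,
               acceptorValid = array(TRUE, dim(don)), acq = acq)
  truth <- new("GroundTruth", ratio = trueR, mask = msk,
               centroid = cell@centroid, frontPoint = front,
               rearPoint = rear,
               peakAxialFraction = rep(NA_real_, nF),
               phase = rep(NA_character_, nF),
               events = list(
                 contact_s = contactTime,
                 engulfed_s = contactTime + engulfmentDuration,
                 contact_frame = floor(contactTime / dt) + 1L,
                 engulfed_frame =
                   floor((contactTime + engulfmentDuration) / dt) + 1L,
                 particle = particle,
                 annulus_ratio = annulusRatio,
                 annulus_width = annulusWidth,
                 particle_diameter = particleDiameter))
  list(movie = movie, brightfield = bf, truth = truth)
}
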