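# Preset synthetic scenes emulating each imaging assay: random migration,
# chemokinesis (move/stall/move), micropipette chemotaxis with an
# oscillating activity peak and a needle move, bead calibration pairs,
# and particle engulfment. These are the study conditions the recovery
# tests and the acceptance checks run on.

#' Build a centroid trajectory from piecewise-constant phases
#'
#' @param phases data.frame(duration_s, speed_um_s, direction_deg).
#' @param frameInterval seconds per frame.
#' @param start starting position c(x, y), um.
#' @return frames x 2 matrix of centroid positions covering the summed
#'   phase durations (first frame at the start position).
#' @export
trajectoryFromPhases <- function(phases, frameInterval, start) {
  nF <- as.integer(round(sum(phases$duration_s) / frameInterval)) + 1L
  pos <- matrix(NA_real_, nF, 2)
  pos[1, ] <- start
  times <- (seq_len(nF) - 1) * frameInterval
  bounds <- cumsum(phases$duration_s)
  for (f in 2:nF) {
    ph <- which(times[f] <= bounds + 1e-9)[1]
    a <- phases$direction_deg[ph] * pi / 180
    v <- phases$speed_um_s[ph]
    pos[f, ] <- pos[f - 1, ] +
      v * frameInterval * c(cos(a), sin(a))
  }
  pos
}

# Grow a (square) image shape until a trajectory of the given span plus
# a polarized cell body fits with margin.
growShape <- function(imageShape, span_um, pixelSize,
                      bodyLength = 15.6) {
  need <- ceiling((span_um + 1.3 * bodyLength + 3) / pixelSize)
  as.integer(pmax(imageShape, need))
}

headingFromTrajectory <- function(centroid, fallback = c(1, 0)) {
  n <- nrow(centroid)
  h <- matrix(NA_real_, n, 2)
  last <- fallback / vecNorm(fallback)
  for (f in seq_len(n)) {
    d <- if (f < n) centroid[f + 1, ] - centroid[f, ]
         else centroid[f, ] - centroid[f - 1, ]
    if (vecNorm(d) > 1e-9) last <- d / vecNorm(d)
    h[f, ] <- last
  }
  h
}

#' Steadily migrating cell scene
#'
#' A polarized cell migrating at constant speed with a front-high
#' activity gradient.
#'
#' @param speed migration speed, um/s.
#' @param directionDeg migration direction, degrees (lab frame).
#' @param frames,frameInterval movie length and sampling.
#' @param gradientAmplitude front-minus-back ratio difference.
#' @param noise logical.
#' @param seed integer seed.
#' @param imageShape,pixelSize image geometry.
#' @param ... further arguments to \code{\link{acquisitionConfig}}.
#' @return list(movie, truth) as from \code{\link{renderMovie}}.
#' @export
sceneMigration <- function(speed = 0.15, directionDeg = 0, frames = 120L,
                           frameInterval = 1, gradientAmplitude = 0.4,
                           noise = TRUE, seed = NA_integer_,
                           imageShape = c(128L, 128L), pixelSize = 0.27,
                           ...) {
  span <- speed * (frames - 1) * frameInterval
  imageShape <- growShape(imageShape, span, pixelSize)
  acq <- acquisitionConfig(pixelSize = pixelSize,
                           frameInterval = frameInterval,
                           frameCount = frames, imageShape = imageShape,
                           seed = seed, ...)
  fov <- rev(imageShape) * pixelSize
  a <- directionDeg * pi / 180
  start <- fov / 2 - span / 2 * c(cos(a), sin(a))
  phases <- data.frame(duration_s = (frames - 1) * frameInterval,
                       speed_um_s = speed, direction_deg = directionDeg)
  ctr <- trajectoryFromPhases(phases, frameInterval, start)
  cell <- cellModel(centroid = ctr,
                    heading = headingFromTrajectory(ctr),
                    frameInterval = frameInterval)
  fld <- activityField(baselineRatio = 1.2,
                       gradientAmplitude = gradientAmplitude)
  renderMovie(cell, fld, acq, noise = noise)
}

#' Chemokinesis scene with migrating and stalling phases
#'
#' @param phases data.frame(duration_s, speed_um_s, direction_deg);
#'   default 40 s move / 30 s stall / 40 s move at 0.15 um/s.
#' @param frameInterval seconds per frame.
#' @param noise,seed,imageShape,pixelSize,... as in
#'   \code{\link{sceneMigration}}.
#' @return list(movie, truth).
#' @export
sceneChemokinesis <- function(phases = NULL, frameInterval = 1,
                              noise = TRUE, seed = NA_integer_,
                              imageShape = c(128L, 128L),
                              pixelSize = 0.27, ...) {
  if (is.null(phases))
    phases <- data.frame(duration_s = c(40, 30, 40),
                         speed_um_s = c(0.15, 0, 0.15),
                         direction_deg = c(0, 0, 0))
  frames <- as.integer(round(sum(phases$duration_s) / frameInterval)) + 1L
  imageShape <- growShape(imageShape,
                          sum(phases$duration_s * phases$speed_um_s),
                          pixelSize)
  acq <- acquisitionConfig(pixelSize = pixelSize,
                           frameInterval = frameInterval,
                           frameCount = frames, imageShape = imageShape,
                           seed = seed, ...)
  fov <- rev(imageShape) * pixelSize
  travel <- sum(phases$duration_s * phases$speed_um_s)
  start <- c(fov[1] / 2 - travel / 2, fov[2] / 2)
  ctr <- trajectoryFromPhases(phases, frameInterval, start)
  cell <- cellModel(centroid = ctr,
                    heading = headingFromTrajectory(ctr),
                    frameInterval = frameInterval)
  fld <- activityField(baselineRatio = 1.2, gradientAmplitude = 0.4)
  renderMovie(cell, fld, acq, noise = noise)
}

#' Oscillating-peak chemotaxis scene
#'
#' A cell whose peak activity travels pole-to-pole as a triangle wave
#' with full cycle \code{cycle} seconds -- the scene used to validate
#' wave-duration recovery (a full cycle contains two waves, so a 16 s
#' cycle gives 8 s waves).
#'
#' @param cycle full pole-to-pole-and-back period, s.
#' @param frames,frameInterval movie length and sampling (default 2 min
#'   at 1 s).
#' @param speed migration speed, um/s (0 = stationary).
#' @param peakAmplitude,peakWidth travelling peak shape.
#' @param noise,seed,imageShape,pixelSize,... as in
#'   \code{\link{sceneMigration}}.
#' @return list(movie, truth).
#' @export
sceneOscillation <- function(cycle = 16, frames = 120L,
                             frameInterval = 1, speed = 0,
                             peakAmplitude = 0.8, peakWidth = 1.2,
                             noise = FALSE, seed = NA_integer_,
                             imageShape = c(128L, 128L),
                             pixelSize = 0.27, ...) {
  span <- speed * (frames - 1) * frameInterval
  imageShape <- growShape(imageShape, span, pixelSize)
  acq <- acquisitionConfig(pixelSize = pixelSize,
                           frameInterval = frameInterval,
                           frameCount = frames, imageShape = imageShape,
                           seed = seed, ...)
  fov <- rev(imageShape) * pixelSize
  start <- c(fov[1] / 2 - span / 2, fov[2] / 2)
  phases <- data.frame(duration_s = (frames - 1) * frameInterval,
                       speed_um_s = speed, direction_deg = 0)
  ctr <- trajectoryFromPhases(phases, frameInterval, start)
  cell <- cellModel(centroid = ctr,
                    heading = headingFromTrajectory(ctr),
                    frameInterval = frameInterval)
  times <- (seq_len(frames) - 1) * frameInterval
  fld <- activityField(baselineRatio = 1.2, gradientAmplitude = 0.1,
                       peakAmplitude = peakAmplitude,
                       peakPosition = oscillatingPeakPosition(times, cycle),
                       peakWidth = peakWidth, oscillationCycle = cycle)
  renderMovie(cell, fld, acq, noise = noise)
}

#' Chemotaxis turning scene (micropipette moved mid-run)
#'
#' A stationary polarized cell that forms a programmed protrusion toward
#' a new needle direction a fixed latency after the needle moves.
#'
#' @param needleMoveTime time of the needle move, s.
#' @param latency programmed time from needle move to protrusion onset, s.
#' @param newDirectionDeg direction of the new needle position from the
#'   cell, degrees.
#' @param growth protrusion bump growth rate, um/s.
#' @param frames,frameInterval movie length and sampling.
#' @param noise,seed,imageShape,pixelSize,... as in
#'   \code{\link{sceneMigration}}.
#' @return list(movie, truth); truth events carry needle_move_s and the
#'   per-frame needle direction in events$needle_direction_deg.
#' @export
sceneChemotaxisTurn <- function(needleMoveTime = 60, latency = 30,
                                newDirectionDeg = 270, growth = 0.25,
                                frames = 120L, frameInterval = 1,
                                noise = FALSE, seed = NA_integer_,
                                imageShape = c(128L, 128L),
                                pixelSize = 0.27, ...) {
  acq <- acquisitionConfig(pixelSize = pixelSize,
                           frameInterval = frameInterval,
                           frameCount = frames, imageShape = imageShape,
                           seed = seed, ...)
  fov <- rev(imageShape) * pixelSize
  pr <- data.frame(onset_s = needleMoveTime + latency,
                   angle_deg = newDirectionDeg,
                   growth_um_s = growth, width_deg = 25)
  cell <- cellModel(centroid = fov / 2, heading = c(-1, 0),
                    protrusions = pr, frames = frames,
                    frameInterval = frameInterval)
  fld <- activityField(baselineRatio = 1.2, gradientAmplitude = 0.4)
  out <- renderMovie(cell, fld, acq, noise = noise)
  times <- (seq_len(frames) - 1) * frameInterval
  out$truth@events <- list(
    needle_move_s = needleMoveTime,
    protrusion_onset_s = needleMoveTime + latency,
    new_direction_deg = newDirectionDeg,
    needle_direction_deg = ifelse(times < needleMoveTime, 180,
                                  newDirectionDeg))
  out
}

#' Bead calibration scene
#'
#' @param nBeads number of beads.
#' @param misalignment 2x3 affine applied to the acceptor channel (um).
#' @param noise,seed,imageShape,pixelSize image settings.
#' @param ... further arguments to \code{\link{acquisitionConfig}}.
#' @return list(movie, donorCenters, acceptorCenters).
#' @export
sceneBeads <- function(nBeads = 10L, misalignment = identityAffine(),
                       noise = FALSE, seed = 1L,
                       imageShape = c(128L, 128L), pixelSize = 0.27,
                       ...) {
  acq <- acquisitionConfig(pixelSize = pixelSize, frameInterval = 1,
                           frameCount = 1L, imageShape = imageShape,
                           misalignment = misalignment, seed = seed, ...)
  renderBeadField(nBeads, acq, noise = noise, returnTruth = TRUE)
}

#' Phagocytosis scene preset
#'
#' A round stationary cell engulfing a 2 um particle, imaged every 5 s
#' (the live phagocytosis protocol: up to 15 min observation).
#'
#' @param contactTime first contact, s.
#' @param engulfmentDuration contact-to-full-engulfment time, s.
#' @param frames,frameInterval movie length and sampling.
#' @param particleDiameter particle diameter, um.
#' @param noise,seed,imageShape,pixelSize,... image settings.
#' @return list(movie, brightfield, truth) as from
#'   \code{\link{renderPhagocytosisScene}}.
#' @export
scenePhagocytosis <- function(contactTime = 20, engulfmentDuration = 60,
                              frames = 40L, frameInterval = 5,
                              particleDiameter = 2, noise = FALSE,
                              seed = NA_integer_,
                              imageShape = c(96L, 96L),
                              pixelSize = 0.27, ...) {
  acq <- acquisitionConfig(pixelSize = pixelSize,
                           frameInterval = frameInterval,
                           frameCount = frames, imageShape = imageShape,
                           seed = seed, ...)
  fov <- rev(imageShape) * pixelSize
  cell <- cellModel(centroid = c(fov[1] * 0.38, fov[2] / 2),
                    heading = c(1, 0), bodyLength = 12, bodyWidth = 12,
                    harmonics = numeric(), frames = frames,
                    frameInterval = frameInterval)
  renderPhagocytosisScene(cell, particleDiameter = particleDiameter,
                          contactTime = contactTime,
                          engulfmentDuration = engulfmentDuration,
                          acq = acq, noise = noise)
}
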