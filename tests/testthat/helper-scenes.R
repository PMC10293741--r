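# Shared fixture builders: every fixture is generated in code.

PS <- 0.27  # default pixel size used across tests, um/px

# Noise settings approximating SNR ~10 on the donor channel.
snr10 <- list(photonScale = 100, readNoiseSD = 2, background = 5)

# Segmentation-based track for a rendered movie (the realistic path:
# smooth -> threshold -> largest object -> track).
segTrack <- function(movie, ps = PS, dt = frameInterval(movie)) {
  dm <- smoothMovie(movie)@donor
  d <- dim(dm)
  mk <- array(FALSE, d)
  for (f in seq_len(d[3])) {
    cm <- segmentFrame(dm[, , f], ps)
    if (length(cm)) {
      areas <- vapply(cm, function(m) m@area, 0)
      mk[, , f] <- cm[[which.max(areas)]]@mask
    }
  }
  buildTrack(mk, ps, dt)
}

# Minimal CellTrack carrying a programmed centroid/anchor trajectory
# (for boundary tests that need exact geometry, not rendered images).
makeTrack <- function(centroid, dt = 1, ps = PS, anchor = NULL,
                      maskSide = 4L) {
  n <- nrow(centroid)
  masks <- array(FALSE, c(maskSide, maskSide, n))
  masks[2, 2, ] <- TRUE
  if (is.null(anchor)) anchor <- centroid
  new("CellTrack", masks = masks, contours = vector("list", n),
      centroid = centroid, heading = matrix(c(1, 0), n, 2, byrow = TRUE),
      frontAnchor = anchor, rearAnchor = anchor,
      pixelSize = ps, frameInterval = dt)
}

# Straight-line trajectory with given net displacement over (n-1)*dt.
straightTrack <- function(displacement, n = 121L, dt = 1, ps = PS) {
  x <- seq(0, displacement, length.out = n)
  makeTrack(cbind(10 + x, rep(10, n)), dt = dt, ps = ps)
}

# AxisProfileSeries built directly from positions/values per frame.
makeProfiles <- function(posList, valueList, axisLength, dt = 1,
                         nBins = 20) {
  n <- length(posList)
  bins <- matrix(NA_real_, n, nBins)
  profs <- vector("list", n)
  for (f in seq_len(n)) {
    if (is.null(posList[[f]])) next
    profs[[f]] <- list(pos = posList[[f]], value = valueList[[f]])
    if (length(valueList[[f]]) %% nBins == 0)
      bins[f, ] <- binMeans(valueList[[f]], nBins)
  }
  new("AxisProfileSeries", profiles = profs, bins = bins,
      axisLength = rep(axisLength, n), frameInterval = dt)
}

# Profile series whose peak sits at a fixed axial offset from the
# leading edge (value 2 on a baseline of 1), axis length L.
peakAtProfiles <- function(peakPos, L = 15, nFrames = 3, dt = 1) {
  pos <- sort(unique(c(seq(0, L, by = 0.25), peakPos)))
  makeProfiles(
    replicate(nFrames, pos, simplify = FALSE),
    replicate(nFrames, ifelse(pos == peakPos, 2, 1), simplify = FALSE),
    axisLength = L, dt = dt)
}

# RatioMovie wrapper around a plain array.
makeRatioMovie <- function(arr, ps = PS, dt = 1) {
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  new("RatioMovie", ratio = arr, valid = is.finite(arr) & arr > 0,
      pixelSize = ps, frameInterval = dt)
}

# Track whose masks exactly match a ground truth (noiseless oracle).
truthTrack <- function(truth, ps = PS, dt = 1) {
  trackFromTruth(truth, ps, dt)
}

# Gaussian bead frame rendered outside the package (independent of the
# package's own renderer) for degenerate-landmark tests.
gaussianBeadFrame <- function(centersUm, shape = c(64L, 64L), ps = PS,
                              sigmaPx = 1.3, amp = 200, bg = 0) {
  y <- (seq_len(shape[1]) - 0.5) * ps
  x <- (seq_len(shape[2]) - 0.5) * ps
  X <- matrix(x, shape[1], shape[2], byrow = TRUE)
  Y <- matrix(y, shape[1], shape[2])
  img <- matrix(bg, shape[1], shape[2])
  s2 <- 2 * (sigmaPx * ps)^2
  for (i in seq_len(nrow(centersUm)))
    img <- img + amp * exp(-((X - centersUm[i, 1])^2 +
                             (Y - centersUm[i, 2])^2) / s2)
  img
}

twoChannelFromFrames <- function(donorFrame, acceptorFrame, ps = PS,
                                 dt = 1) {
  d <- c(dim(donorFrame), 1)
  new("TwoChannelMovie",
      donor = array(donorFrame, d),
      acceptor = array(acceptorFrame, d),
      acceptorValid = array(TRUE, d),
      acq = acquisitionConfig(pixelSize = ps, frameInterval = dt,
                              frameCount = 1L,
                              imageShape = dim(donorFrame),
                              photonScale = 0, readNoiseSD = 0,
                              background = 0))
}
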