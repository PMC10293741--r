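# Tracking, axis profiles and bins, kymographs, edge bands, polar maps
# and peak-oscillation statistics.

test_that("tracking recovers heading and pole anchors", {
  sc <- sceneMigration(speed = 0.15, frames = 40L, noise = FALSE,
                       background = 0, readNoiseSD = 0)
  trk <- truthTrack(sc$truth)
  h <- headings(trk)
  late <- 6:35  # clear of the smoothing window edges
  expect_true(all(abs(h[late, 1] - 1) < 1e-6))
  expect_true(all(abs(h[late, 2]) < 1e-6))
  # anchors near the true poles in at least 90% of frames, and never
  # more than two pixels away
  dfront <- sqrt(rowSums((frontAnchors(trk) - sc$truth@frontPoint)^2))
  drear <- sqrt(rowSums((rearAnchors(trk) - sc$truth@rearPoint)^2))
  expect_gte(mean(dfront <= 1.1 * PS), 0.9)
  expect_gte(mean(drear <= 1.1 * PS), 0.9)
  expect_lt(max(c(dfront, drear)), 2 * PS)
})

test_that("a stationary cell falls back to its long-axis orientation", {
  sc <- sceneMigration(speed = 0, frames = 10L, noise = FALSE,
                       background = 0, readNoiseSD = 0)
  trk <- truthTrack(sc$truth)
  h <- headings(trk)
  expect_true(all(abs(abs(h[, 1]) - 1) < 0.02))  # x elongated cell
  expect_true(all(h[, 1] * h[1, 1] > 0))          # sign continuity
})

test_that("a lost cell splits the track with a warning", {
  masks <- array(FALSE, c(16, 16, 10))
  masks[6:10, 6:10, c(1:3, 8:10)] <- TRUE  # 4-frame gap
  expect_warning(trk <- buildTrack(masks, 1, 1), "lost")
  expect_equal(nFrames(trk), 3)
})

test_that("axis profiles bin correctly and conserve the mean", {
  expect_equal(binMeans(c(1, 1, 2, 2, 3, 3, 4, 4), 4), c(1, 2, 3, 4))

  sc <- sceneMigration(speed = 0, frames = 3L, noise = FALSE,
                       background = 0, readNoiseSD = 0,
                       gradientAmplitude = 0)
  rat <- computeRatio(sc$movie, donorFloor = 1)
  trk <- truthTrack(sc$truth)
  profs <- axisProfileSeries(rat, trk)
  b <- binMatrix(profs)[1, ]
  expect_equal(b, rep(1.2, 20), tolerance = 1e-9)

  scg <- sceneMigration(speed = 0.1, frames = 30L, noise = FALSE,
                        background = 0, readNoiseSD = 0,
                        gradientAmplitude = 1)  # front 2.0 -> back 1.0
  scg$truth@ratio  # field baseline 1.2; rescale expectation below
  ratg <- computeRatio(scg$movie, donorFloor = 1)
  trkg <- truthTrack(scg$truth)
  pg <- axisProfileSeries(ratg, trkg)
  bg <- binMatrix(pg)[15, ]
  expect_true(all(diff(bg) < 0))
  expect_lt(abs(bg[1] - 2.2) / 2.2, 0.05)
  expect_lt(abs(bg[20] - 1.2) / 1.2, 0.05)
  # bin-mean conservation
  for (f in c(5, 15, 25)) {
    pm <- mean(pg@profiles[[f]]$value, na.rm = TRUE)
    expect_lt(abs(mean(binMatrix(pg)[f, ]) - pm), 1e-6)
  }
  # axis shorter than nBins pixels is an error
  tiny <- matrix(1.5, 30, 30)
  expect_error(axisProfile(tiny, front = c(1, 1), rear = c(2, 1),
                           pixelSize = 1), "shorter")
})

test_that("kymograph rows equal the binned profiles", {
  sc <- sceneOscillation(cycle = 16, frames = 40L, noise = FALSE,
                         background = 0, readNoiseSD = 0)
  rat <- computeRatio(sc$movie, donorFloor = 1)
  profs <- axisProfileSeries(rat, truthTrack(sc$truth))
  km <- kymograph(profs)
  expect_identical(km, binMatrix(profs))
  # ridge alternates between pole bin regions at the programmed period
  ridge <- apply(km, 1, which.max)
  expect_true(all(ridge[c(1, 17, 33)] <= 3))   # front extremes
  expect_true(all(ridge[c(9, 25)] >= 18))      # rear extremes
  one <- makeProfiles(list(NULL), list(NULL), 10)
  expect_error(kymograph(one), "2 frames")
})

test_that("axis reversal maps bin k to 21-k and swaps pole summaries", {
  sc <- sceneMigration(speed = 0.1, frames = 20L, noise = FALSE,
                       background = 0, readNoiseSD = 0)
  profs <- axisProfileSeries(computeRatio(sc$movie, donorFloor = 1),
                             truthTrack(sc$truth))
  rev <- reverseAxis(profs)
  expect_equal(binMatrix(rev), binMatrix(profs)[, 20:1])
  fb <- frontBackSummary(profs)
  fbr <- frontBackSummary(rev)
  expect_equal(fbr$leadingEdge, fb$uropod)
  expect_equal(fbr$uropod, fb$leadingEdge)
  expect_equal(fbr$wholeCell, fb$wholeCell)
  expect_gt(fb$leadingEdge, fb$uropod)  # front-high gradient scene
})

test_that("edge band sampling respects the band width", {
  # square cell with an analytically known band
  ps <- 0.1
  n <- 60L
  mask <- matrix(FALSE, n, n)
  mask[11:50, 11:50] <- TRUE
  sq <- 0.1 * cbind(c(10, 50, 50, 10), c(10, 10, 50, 50))
  g <- fretPolarity:::pixelGrid(c(n, n), ps, expand = TRUE)
  edgeDist <- pmin(pmin(g$X - 1.0, 5.0 - g$X),
                   pmin(g$Y - 1.0, 5.0 - g$Y))  # distance to square edge
  ratio <- matrix(1, n, n)
  ratio[mask & edgeDist <= 0.4] <- 2
  ratio[!mask] <- NA
  prof <- edgeBandValues(ratio, sq, ps, bandWidth = 0.4, mask = mask)
  expect_true(all(abs(prof[!is.na(prof)] - 2) < 1e-9))

  # uniform scene gives a flat profile
  u <- matrix(1.4, n, n); u[!mask] <- NA
  pu <- edgeBandValues(u, sq, ps, bandWidth = 0.4, mask = mask)
  expect_true(all(abs(pu[!is.na(pu)] - 1.4) < 1e-12))

  # a bright pixel 1 um inside contributes nothing at 0.4 um band
  br <- matrix(1, n, n); br[!mask] <- NA
  br[30, 21] <- 100  # x = 2.05, 1.05 um from the nearest edge
  pb <- edgeBandValues(br, sq, ps, bandWidth = 0.4, mask = mask)
  expect_lt(max(pb, na.rm = TRUE), 2)

  expect_warning(
    edgeBandValues(u, sq, ps, bandWidth = 0.05, mask = mask),
    "widened")
})

test_that("polar maps rotate the needle to the reference compass point", {
  set.seed(2)
  ep <- matrix(runif(360), 1, 360)
  expect_equal(polarMap(ep, 180)@values, ep)  # needle already west
  # needle due north (270 deg in image coords): hotspot at 0 -> 270
  hot <- matrix(1, 1, 360); hot[1, 1] <- 5
  pm <- polarMap(hot, 270)
  expect_equal(which.max(pm@values[1, ]), 271)
  # rotation equivariance: rotating profiles and annotation together
  for (th in c(30, 90, 215)) {
    shifted <- ep[, ((seq_len(360) - 1 - th) %% 360) + 1, drop = FALSE]
    expect_equal(polarMap(shifted, (th + 180) %% 360)@values,
                 polarMap(ep, 180)@values)
  }
  expect_warning(polarMap(ep, NA_real_), "needle")
  comb <- combinePolarMaps(list(polarMap(ep, 180), polarMap(ep, 180)))
  expect_equal(comb@values, polarMap(ep, 180)@values)
})

test_that("peak tracing counts pole switches and dwell times", {
  # peak pinned at the leading edge: full dwell, no switches
  fixed <- peakAtProfiles(0.3, L = 15, nFrames = 120)
  pk <- peakTrace(fixed)
  expect_equal(pk@dwellFront, 120)
  expect_equal(length(switchTimes(pk)), 0)

  # uniform profile: tie broken toward the leading edge
  flat <- makeProfiles(list(seq(0, 15, 0.5)),
                       list(rep(1, 31)), axisLength = 15)
  pkf <- peakTrace(flat)
  expect_equal(pkf@table$peak_um_from_front[1], 0)
  expect_equal(pkf@table$zone[1], "front")

  # square-wave alternation with full cycle 16 s: waves of 8 s
  n <- 120
  posn <- rep(list(seq(0, 15, 0.5)), n)
  half <- ((seq_len(n) - 1) %/% 8) %% 2  # 0 = front, 1 = rear
  valn <- lapply(seq_len(n), function(f) {
    v <- rep(1, 31); v[if (half[f] == 0) 1 else 31] <- 2; v
  })
  sq <- makeProfiles(posn, valn, axisLength = 15)
  pks <- peakTrace(sq)
  expect_equal(length(switchTimes(pks)), 14)
  expect_equal(mean(waveDurations(pks)), 8)

  # dwell additivity: front + rear + interior frames = all frames
  tab <- pks@table
  expect_equal(sum(tab$zone == "front") + sum(tab$zone == "rear") +
               sum(tab$zone == "interior"), n)

  # no switch inferred across a gap
  posg <- posn[1:20]; valg <- valn[1:20]
  posg[[9]] <- NULL; valg[[9]] <- NULL  # NULL profile = gap
  posg <- c(posn[1:8], list(NULL), posn[10:20])
  valg <- c(valn[1:8], list(NULL), valn[10:20])
  pkg <- peakTrace(makeProfiles(posg, valg, axisLength = 15))
  expect_equal(length(switchTimes(pkg)),
               length(switchTimes(peakTrace(
                 makeProfiles(posn[1:20], valn[1:20], 15)))) - 1)
})

test_that("wave periods are recovered across cycle lengths", {
  for (Tc in c(8, 12, 16, 20)) {
    sc <- sceneOscillation(cycle = Tc, frames = 120L, noise = FALSE,
                           background = 0, readNoiseSD = 0)
    rat <- computeRatio(sc$movie, donorFloor = 1)
    pk <- peakTrace(axisProfileSeries(rat, truthTrack(sc$truth)))
    expect_lte(abs(mean(waveDurations(pk)) - Tc / 2), 1)
  }
  # at SNR ~10 the period survives within two frame intervals
  scn <- sceneOscillation(cycle = 16, frames = 120L, noise = TRUE,
                          seed = 5L, photonScale = snr10$photonScale,
                          readNoiseSD = snr10$readNoiseSD,
                          background = snr10$background)
  ratn <- computeRatio(smoothMovie(scn$movie))
  pkn <- peakTrace(axisProfileSeries(ratn, segTrack(scn$movie)))
  expect_lte(abs(mean(waveDurations(pkn)) - 8), 2)
})
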