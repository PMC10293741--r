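# Velocity, phase classification, migration criteria, protrusion
# detection, turning latency and movement plots.

test_that("front-pixel velocity is windowed anchor displacement", {
  anchor <- cbind(seq(0, 12, length.out = 61), rep(5, 61))  # 0.2 um/s
  trk <- makeTrack(anchor, dt = 1)
  v <- frontPixelVelocity(trk, 20)
  expect_equal(v$perWindow$velocity_um_s, rep(0.2, 3), tolerance = 1e-9)
  expect_equal(v$mean, 0.2, tolerance = 1e-9)

  still <- makeTrack(matrix(5, 61, 2), dt = 1)
  expect_equal(frontPixelVelocity(still, 20)$mean, 0)
  expect_error(frontPixelVelocity(trk, 1.5), "2 frame intervals")
})

test_that("programmed speeds are recovered from rendered scenes", {
  for (v in c(0.05, 0.15, 0.3)) {
    sc <- sceneMigration(speed = v, frames = 121L, noise = FALSE,
                         background = 0, readNoiseSD = 0)
    rec <- frontPixelVelocity(truthTrack(sc$truth))$mean
    expect_lt(abs(rec - v) / v, 0.05)
    scn <- sceneMigration(speed = v, frames = 121L, noise = TRUE,
                          seed = 3L, photonScale = snr10$photonScale,
                          readNoiseSD = snr10$readNoiseSD,
                          background = snr10$background)
    recn <- frontPixelVelocity(segTrack(scn$movie))$mean
    expect_lt(abs(recn - v) / v, 0.15)
  }
})

test_that("phases are classified by the windowed displacement rule", {
  steady <- straightTrack(6, n = 61, dt = 1)  # 0.1 um/s for 60 s
  ph <- classifyPhases(steady)
  expect_equal(nrow(ph), 1)
  expect_equal(ph$label, "migrating")

  still <- makeTrack(matrix(7, 61, 2), dt = 1)
  ps <- classifyPhases(still)
  expect_equal(ps$label, "stalling")
  expect_error(classifyPhases(still, minDuration = 0), "minDuration")

  sc <- sceneChemokinesis(noise = FALSE, background = 0,
                          readNoiseSD = 0)
  segs <- classifyPhases(truthTrack(sc$truth))
  expect_equal(segs$label, c("migrating", "stalling", "migrating"))
  # frame-level agreement with ground truth of at least 95%
  n <- nFrames(truthTrack(sc$truth))
  lab <- rep(NA_character_, n)
  for (i in seq_len(nrow(segs))) {
    f0 <- round(segs$start_s[i]) + 1; f1 <- round(segs$end_s[i]) + 1
    lab[f0:f1] <- segs$label[i]
  }
  tru <- sc$truth@phase
  both <- !is.na(lab) & !is.na(tru)
  expect_gte(mean(lab[both] == tru[both]), 0.95)
})

test_that("migration flags use inclusive displacement thresholds", {
  expect_true(classifyMigrating(straightTrack(7.8), "half-body"))
  expect_false(classifyMigrating(straightTrack(7.79), "half-body"))
  expect_true(classifyMigrating(straightTrack(12), "half-body"))
  expect_error(classifyMigrating(straightTrack(10, n = 61), "half-body"),
               "requires")
  # monotonicity: increasing displacement never unsets the flag
  flags <- vapply(seq(5, 12, by = 0.5), function(d)
    as.logical(classifyMigrating(straightTrack(d), "half-body")), TRUE)
  expect_true(all(diff(flags) >= 0))

  # diameter criterion: mean area 113.1 um^2 -> 12.0 um threshold
  n <- 601L
  side <- 34L  # 34 x 34 px square... area set via pixel size below
  px <- sqrt(113.1 / (side * side))
  masks <- array(FALSE, c(48, 48, n))
  masks[8 + seq_len(side), 8 + seq_len(side), ] <- TRUE
  x <- seq(0, 12.01, length.out = n)
  trk <- new("CellTrack", masks = masks, contours = vector("list", n),
             centroid = cbind(20 + x, rep(20, n)),
             heading = matrix(c(1, 0), n, 2, byrow = TRUE),
             frontAnchor = cbind(20 + x, rep(20, n)),
             rearAnchor = cbind(20 + x, rep(20, n)),
             pixelSize = px, frameInterval = 1)
  flag <- classifyMigrating(trk, "diameter")
  expect_equal(attr(flag, "threshold_um"), 2 * sqrt(113.1 / pi),
               tolerance = 1e-9)
  expect_equal(attr(flag, "threshold_um"), 12.0, tolerance = 1e-3)
  expect_true(flag)
})

test_that("protrusion events are detected with onset timing", {
  # static contour: no events
  sc0 <- sceneMigration(speed = 0, frames = 30L, noise = FALSE,
                        background = 0, readNoiseSD = 0)
  expect_equal(nrow(detectProtrusions(truthTrack(sc0$truth))), 0)

  # single programmed protrusion at 90 s
  tn <- sceneChemotaxisTurn(needleMoveTime = 60, latency = 30,
                            noise = FALSE, background = 0,
                            readNoiseSD = 0)
  ev <- detectProtrusions(truthTrack(tn$truth))
  expect_gte(nrow(ev), 1)
  expect_lte(abs(ev$onset_s[1] - 90), 1)

  # two disjoint programmed protrusions
  acq <- acquisitionConfig(frameCount = 60L, imageShape = c(128L, 128L),
                           photonScale = 200, readNoiseSD = 0,
                           background = 0)
  fov <- rev(acq@imageShape) * acq@pixelSize
  pr <- data.frame(onset_s = c(15, 30), angle_deg = c(90, 270),
                   growth_um_s = 0.25, width_deg = 20)
  cell <- cellModel(centroid = fov / 2, heading = c(1, 0),
                    protrusions = pr, frames = 60L)
  out <- renderMovie(cell, activityField(), acq, noise = FALSE)
  ev2 <- detectProtrusions(trackFromTruth(out$truth, PS, 1))
  expect_equal(nrow(ev2), 2)
  expect_equal(sort(round(ev2$angle_deg / 10) * 10), c(90, 270))
})

test_that("turning latency measures needle-to-protrusion time", {
  tn <- sceneChemotaxisTurn(needleMoveTime = 60, latency = 30,
                            noise = FALSE, background = 0,
                            readNoiseSD = 0)
  trk <- truthTrack(tn$truth)
  ev <- detectProtrusions(trk)
  lat <- turningLatency(trk, ev, 60, c(0, -1))  # 270 deg = new needle
  expect_lte(abs(lat - 30), 1)
  # protrusion opposite the new direction only -> missing
  opp <- turningLatency(trk, ev, 60, c(0, 1))
  expect_true(is.na(opp))
  expect_true(attr(opp, "missing"))
  expect_error(turningLatency(trk, ev, 60, c(0, 0)), "non-zero")
  expect_warning(late <- turningLatency(trk, ev, 500, c(0, -1)),
                 "end of the track")
  expect_true(is.na(late))
})

test_that("movement plots anchor at the origin", {
  straight <- movementPlot(straightTrack(10, n = 21))
  expect_equal(straight$netDisplacement_um, 10)
  expect_equal(straight$pathLength_um, 10)
  expect_equal(unlist(straight$path[1, c("x_um", "y_um")]),
               c(x_um = 0, y_um = 0))

  th <- seq(0, 2 * pi, length.out = 41)
  loop <- makeTrack(cbind(10 + cos(th), 10 + sin(th)))
  mpl <- movementPlot(loop)
  expect_lt(mpl$netDisplacement_um, 1e-9)
  expect_gt(mpl$pathLength_um, 6)

  set.seed(31)
  for (i in 1:100) {
    steps <- matrix(rnorm(40, sd = 0.3), 20, 2)
    walk <- makeTrack(apply(rbind(c(10, 10), steps), 2, cumsum))
    mp <- movementPlot(walk)
    expect_lte(mp$netDisplacement_um, mp$pathLength_um + 1e-12)
  }
})
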