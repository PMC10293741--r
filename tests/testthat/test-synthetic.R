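# The synthetic renderer: ratio identity, determinism, analytic field
# reproduction, bead displacement, phagocytosis event plumbing, and the
# noise model.

noiselessAcq <- function(frames = 2L, shape = c(96L, 96L), ...) {
  acquisitionConfig(frameCount = frames, imageShape = shape,
                    photonScale = 200, readNoiseSD = 0, background = 0,
                    ...)
}

centeredCell <- function(acq, frames = acq@frameCount, ...) {
  fov <- rev(acq@imageShape) * acq@pixelSize
  cellModel(centroid = fov / 2, frames = frames, ...)
}

test_that("a ratio-1 field renders identical channels inside the cell", {
  acq <- noiselessAcq()
  cell <- centeredCell(acq)
  out <- renderMovie(cell, activityField(baselineRatio = 1), acq,
                     noise = FALSE)
  m <- out$truth@mask
  expect_identical(donor(out$movie)[m], acceptor(out$movie)[m])
})

test_that("seeded renders are bit-reproducible", {
  mk <- function() {
    acq <- acquisitionConfig(frameCount = 2L, imageShape = c(64L, 64L),
                             seed = 7L)
    fov <- rev(acq@imageShape) * acq@pixelSize
    renderMovie(cellModel(centroid = fov / 2, frames = 2L,
                          bodyLength = 12, bodyWidth = 7),
                activityField(), acq)
  }
  a <- mk(); b <- mk()
  expect_identical(donor(a$movie), donor(b$movie))
  expect_identical(acceptor(a$movie), acceptor(b$movie))
  b1 <- renderBeadField(10, acquisitionConfig(frameCount = 1L, seed = 7L),
                        returnTruth = TRUE)
  b2 <- renderBeadField(10, acquisitionConfig(frameCount = 1L, seed = 7L),
                        returnTruth = TRUE)
  expect_identical(b1$donorCenters, b2$donorCenters)
  expect_identical(donor(b1$movie), donor(b2$movie))
})

test_that("noiseless renders reproduce the analytic field to 1e-9", {
  # gradient case from the scene family plus randomized positive fields
  set.seed(42)
  acq <- noiselessAcq()
  cell <- centeredCell(acq)
  fields <- c(
    list(activityField(baselineRatio = 1.2, gradientAmplitude = 0.4)),
    lapply(1:3, function(i)
      activityField(baselineRatio = runif(1, 0.5, 2),
                    gradientAmplitude = runif(1, -0.5, 0.5),
                    peakAmplitude = runif(1, 0, 1),
                    peakPosition = runif(2),
                    peakWidth = runif(1, 0.8, 2),
                    edgeEnrichment = runif(1, 1, 1.4))))
  for (fld in fields) {
    out <- renderMovie(cell, fld, acq, noise = FALSE)
    rat <- computeRatio(out$movie, donorFloor = 1)
    m <- out$truth@mask & rat@valid
    expect_lt(max(abs(rat@ratio[m] - out$truth@ratio[m])), 1e-9)
  }
})

test_that("bead fields displace acceptor spots by the misalignment", {
  ps <- PS
  ident <- sceneBeads(8, noise = FALSE, seed = 2)
  offs <- ident$acceptorCenters - ident$donorCenters
  expect_lt(max(abs(offs)), 1e-12)
  mis <- affineTransform(dx = 1.5 * ps, dy = -0.5 * ps)
  b <- sceneBeads(10, misalignment = mis, noise = FALSE, seed = 2)
  # measured spot centroids, not the programmed centres
  don <- fretPolarity:::detectBeadCentroids(donor(b$movie)[, , 1], ps)
  acc <- fretPolarity:::detectBeadCentroids(acceptor(b$movie)[, , 1], ps)
  don <- don[order(don[, 1], don[, 2]), ]
  acc <- acc[order(acc[, 1], acc[, 2]), ]
  off <- (acc - don) / ps
  expect_equal(unname(colMeans(off)), c(1.5, -0.5), tolerance = 0.02)
  expect_error(renderBeadField(2, noiselessAcq()), "3 beads")
})

test_that("phagocytosis ground truth matches its stated inputs", {
  pg <- scenePhagocytosis(contactTime = 20, engulfmentDuration = 60,
                          frames = 40L, frameInterval = 5,
                          noise = FALSE, background = 0,
                          readNoiseSD = 0)
  ev <- pg$truth@events
  expect_equal(ev$contact_s, 20)
  expect_equal(ev$engulfed_s, 80)
  # 1-based frames with frame f at time (f-1)*dt
  expect_equal(ev$contact_frame, 5L)
  expect_equal(ev$engulfed_frame, 17L)
  expect_error(
    scenePhagocytosis(contactTime = 300, engulfmentDuration = 60,
                      frames = 40L, frameInterval = 5),
    "within the movie duration")
  expect_error(
    scenePhagocytosis(particleDiameter = 0),
    "particleDiameter")
  # noiseless annulus: rendered ratio equals the configured annulus
  # value exactly where the truth says the cup is
  rat <- computeRatio(pg$movie, donorFloor = 1)
  f <- 10L  # mid-engulfment
  g <- fretPolarity:::pixelGrid(dim(rat@ratio)[1:2], PS, expand = TRUE)
  pd <- sqrt((g$X - ev$particle[f, 1])^2 + (g$Y - ev$particle[f, 2])^2)
  ann <- pg$truth@mask[, , f] & pd > 1 & pd <= 1.5 & rat@valid[, , f]
  expect_gt(sum(ann), 0)
  expect_lt(max(abs(rat@ratio[, , f][ann] - 2)), 1e-9)
})

test_that("per-pixel noise variance follows shot plus read noise", {
  acq <- acquisitionConfig(frameCount = 500L, imageShape = c(24L, 24L),
                           photonScale = 150, readNoiseSD = 3,
                           background = 0, seed = 11L)
  fov <- rev(acq@imageShape) * acq@pixelSize
  cell <- cellModel(centroid = fov / 2, bodyLength = 5, bodyWidth = 5,
                    harmonics = numeric(), frames = 500L)
  out <- renderMovie(cell, activityField(baselineRatio = 1), acq)
  inside <- out$truth@mask[, , 1]
  v <- apply(donor(out$movie), c(1, 2), var)[inside]
  expect_lt(abs(mean(v) - (150 + 9)) / (150 + 9), 0.1)
})

test_that("ground-truth phase labels respect the displacement criterion", {
  sc <- sceneChemokinesis(noise = FALSE, background = 0,
                          readNoiseSD = 0)
  ph <- sc$truth@phase
  ctr <- centroids(sc$truth)
  wf <- 20L  # 20 s at 1 s frames
  # within any stalling run, every 20 s window displaces < 2 um
  r <- rle(ph == "stalling")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (i in which(r$values)) {
    for (a in starts[i]:(ends[i] - wf)) {
      if (a < 1 || a + wf > ends[i]) next
      expect_lt(sqrt(sum((ctr[a + wf, ] - ctr[a, ])^2)), 2)
    }
  }
  expect_setequal(unique(ph[!is.na(ph)]), c("migrating", "stalling"))
})

test_that("a contour leaving the field of view names the frame", {
  acq <- noiselessAcq(frames = 3L, shape = c(48L, 48L))
  ctr <- rbind(c(6, 6), c(6, 6), c(1, 6))  # frame 3 walks off the edge
  cell <- cellModel(centroid = ctr, bodyLength = 8, bodyWidth = 5,
                    frameInterval = 1)
  expect_error(renderMovie(cell, activityField(), acq, noise = FALSE),
               "frame 3")
})
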