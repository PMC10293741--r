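# Segmentation shape metrics, adherent-cell counting, whole-cell mean
# FRET and AUC summaries.

rasterDisk <- function(r, cx, cy, shape = c(96L, 96L)) {
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]))
  m <- matrix(0, shape[1], shape[2])
  m[(g$i - cy)^2 + (g$j - cx)^2 <= r^2] <- 1
  m
}

test_that("a rasterized disk segments as one near-circular mask", {
  img <- rasterDisk(20, 50.3, 48.2)
  cm <- segmentFrame(img, pixelSize = 1)
  expect_length(cm, 1)
  expect_gte(cm[[1]]@circularity, 0.95)
  expect_lte(cm[[1]]@circularity, 1.05)
  expect_lt(abs(cm[[1]]@area - pi * 400) / (pi * 400), 0.02)
  expect_length(segmentFrame(matrix(0, 32, 32), 1), 0)
})

test_that("rectangle circularity matches the analytic value", {
  img <- matrix(0, 120, 60)
  img[21:100, 21:40] <- 1  # 80 x 20 px, 4:1
  cm <- segmentFrame(img, pixelSize = 1)
  analytic <- 4 * pi * (80 * 20) / (2 * (80 + 20))^2
  expect_lt(abs(cm[[1]]@circularity - analytic), 0.05)
})

test_that("adherent counting excludes objects below the area cutoff", {
  mk <- function(npx) {
    m <- matrix(FALSE, 32, 32)
    m[cbind(5 + (seq_len(npx) - 1) %/% 20, 5 + (seq_len(npx) - 1) %% 20)] <- TRUE
    new("CellMask", mask = m, frame = 1L, area = npx, perimeter = 10,
        circularity = 0.5, centroid = c(5, 5), pixelSize = 1)
  }
  expect_equal(countAdherent(list(mk(30), mk(60)), 40), 1)
  expect_equal(countAdherent(list(mk(40)), 40), 1)  # boundary retained
  expect_equal(countAdherent(list(mk(39)), 40), 0)
  expect_equal(countAdherent(list(), 40), 0L)
  expect_error(countAdherent(list(mk(40)), -1), "minArea")
  # monotone non-increasing in the cutoff
  masks <- lapply(c(10, 25, 40, 41, 80), mk)
  counts <- vapply(seq(0, 100, by = 5),
                   function(a) countAdherent(masks, a), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("whole-cell mean FRET averages defined in-mask pixels", {
  arr <- array(1.3, c(8, 8, 3))
  rm <- makeRatioMovie(arr)
  masks <- array(TRUE, c(8, 8, 3))
  trk <- new("CellTrack", masks = masks, contours = vector("list", 3),
             centroid = matrix(1, 3, 2),
             heading = matrix(c(1, 0), 3, 2, byrow = TRUE),
             frontAnchor = matrix(1, 3, 2), rearAnchor = matrix(1, 3, 2),
             pixelSize = PS, frameInterval = 1)
  s <- wholeCellMeanFret(rm, trk)
  expect_equal(s$value, rep(1.3, 3))

  half <- array(1, c(8, 8, 1)); half[1:4, , 1] <- 2
  trk1 <- new("CellTrack", masks = array(TRUE, c(8, 8, 1)),
              contours = vector("list", 1), centroid = matrix(1, 1, 2),
              heading = matrix(c(1, 0), 1, 2),
              frontAnchor = matrix(1, 1, 2),
              rearAnchor = matrix(1, 1, 2),
              pixelSize = PS, frameInterval = 1)
  expect_equal(wholeCellMeanFret(makeRatioMovie(half), trk1)$value, 1.5)

  # simulator scene: per-frame means match the analytic in-mask mean
  sc <- sceneMigration(speed = 0.05, frames = 5L, noise = FALSE,
                       background = 0, readNoiseSD = 0)
  rat <- computeRatio(sc$movie, donorFloor = 1)
  trk2 <- truthTrack(sc$truth)
  got <- wholeCellMeanFret(rat, trk2)$value
  want <- vapply(1:5, function(f)
    mean(sc$truth@ratio[, , f][sc$truth@mask[, , f]]), 0)
  expect_equal(got, want, tolerance = 0.02)
})

test_that("AUC is a trapezoidal integral with endpoint interpolation", {
  const <- data.frame(time_s = seq(0, 130, by = 5), value = 1)
  expect_equal(aucWindow(const, c(0, 125)), 125)
  ramp <- data.frame(time_s = seq(0, 100, by = 1),
                     value = seq(0, 1, by = 0.01))
  expect_equal(aucWindow(ramp, c(0, 100)), 50)
  expect_error(aucWindow(ramp, c(-5, 50)), "outside")

  # refined-grid numerical oracle on a random series
  set.seed(5)
  t <- sort(runif(40, 0, 100)); v <- runif(40)
  ser <- data.frame(time_s = t, value = v)
  fine <- seq(min(t), max(t), length.out = 40001)
  vf <- approx(t, v, xout = fine)$y
  oracle <- sum(diff(fine) * (head(vf, -1) + tail(vf, -1)) / 2)
  got <- aucWindow(ser, range(t))
  expect_lt(abs(got - oracle) / oracle, 1e-6)

  gap <- data.frame(time_s = 0:10, value = c(1, 1, NA, 1, 1, 1, 1, 1,
                                             NA, 1, 1))
  expect_warning(a <- aucWindow(gap, c(0, 10)), "bridged")
  expect_equal(a, 10)
})
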