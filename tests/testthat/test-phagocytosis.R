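# Particle detection/tracking, phagosomal traces with engulfment
# timing, and fixed-scene uptake counting.

test_that("particles are detected and tracked in brightfield", {
  pg <- scenePhagocytosis(noise = FALSE, background = 0, readNoiseSD = 0)
  pts <- detectParticles(pg$brightfield, PS, 5)
  expect_length(pts, 1)
  tr <- pts[[1]]
  expect_equal(nrow(tr), dim(pg$brightfield)[3])
  tru <- pg$truth@events$particle
  err <- sqrt((tr$x_um - tru[tr$frame, 1])^2 +
              (tr$y_um - tru[tr$frame, 2])^2) / PS
  expect_lt(max(err), 0.5)
  expect_false(any(tr$ambiguous))

  empty <- array(0.7, c(32, 32, 3))
  expect_length(detectParticles(empty, PS, 5), 0)

  # two particles closer than one radius merge into a flagged blob
  bf <- array(0.7, c(64, 64, 1))
  g <- expand.grid(i = 1:64, j = 1:64)
  for (cx in c(28, 35)) {
    sel <- (g$i - 32)^2 + (g$j - cx)^2 <= (1 / PS)^2
    bf[, , 1][sel] <- 0.15
  }
  two <- detectParticles(bf, PS, 1)
  expect_true(any(vapply(two, function(t) any(t$ambiguous), TRUE)))
})

test_that("engulfment timing is recovered across durations", {
  for (dur in c(30, 60, 120)) {
    pg <- scenePhagocytosis(contactTime = 20, engulfmentDuration = dur,
                            frames = 40L, noise = FALSE,
                            background = 0, readNoiseSD = 0)
    rat <- computeRatio(pg$movie, donorFloor = 1)
    trk <- truthTrack(pg$truth, dt = 5)
    pt <- detectParticles(pg$brightfield, PS, 5)[[1]]
    tr <- phagosomeTrace(rat, trk, pt)
    expect_true(tr@complete)
    expect_lte(abs(tr@contactTime - 20), 5)
    expect_lte(abs(tr@engulfmentTime - dur), 5)
    expect_lte(tr@contactTime, tr@engulfedTime)
  }
})

test_that("the phagosomal annulus reads the cup ratio then relaxes", {
  pg <- scenePhagocytosis(contactTime = 20, engulfmentDuration = 60,
                          frames = 40L, noise = FALSE, background = 0,
                          readNoiseSD = 0)
  rat <- computeRatio(pg$movie, donorFloor = 1)
  trk <- truthTrack(pg$truth, dt = 5)
  tru <- pg$truth@events$particle
  pt <- data.frame(frame = seq_len(nrow(tru)), x_um = tru[, 1],
                   y_um = tru[, 2])
  tr <- phagosomeTrace(rat, trk, pt)
  tab <- tr@table
  during <- tab$time_s >= 25 & tab$time_s <= 75
  after <- tab$time_s > 85
  expect_gt(min(tab$mean_ratio[during], na.rm = TRUE), 1.8)
  expect_lt(max(tab$mean_ratio[after], na.rm = TRUE), 1.1)
})

test_that("a particle that never meets the cell yields no trace", {
  pg <- scenePhagocytosis(noise = FALSE, background = 0, readNoiseSD = 0)
  rat <- computeRatio(pg$movie, donorFloor = 1)
  trk <- truthTrack(pg$truth, dt = 5)
  far <- data.frame(frame = 1:10, x_um = 24, y_um = 2)
  tr <- phagosomeTrace(rat, trk, far)
  expect_false(tr@complete)
  expect_equal(nrow(tr@table), 0)
  expect_true(is.na(tr@engulfmentTime))
})

test_that("uptake counting applies the membrane-flag rule", {
  mk <- function(rows, cols) {
    m <- matrix(FALSE, 40, 40); m[rows, cols] <- TRUE; m
  }
  cells <- list(mk(2:12, 2:12), mk(2:12, 20:30), mk(20:30, 2:12))
  particles <- data.frame(
    x_um = c(25, 5, 7, 5),
    y_um = c(5, 25, 25, 5),
    membrane_flag = c(TRUE, TRUE, TRUE, FALSE))
  res <- countUptake(cells, particles, pixelSize = 1)
  expect_equal(res$perCell, c(0L, 1L, 2L))
  expect_equal(res$meanPerCell, 1)
  expect_equal(res$fractionWithUptake, 2 / 3)
  # order invariance
  res2 <- countUptake(cells, particles[c(3, 1, 4, 2), ], pixelSize = 1)
  expect_equal(res2$perCell, res$perCell)
  expect_error(countUptake(list(), particles, 1), "no cell masks")
  # overlapping masks: assigned to the nearer centroid with a warning
  overl <- list(mk(2:20, 2:20), mk(10:30, 10:30))
  p1 <- data.frame(x_um = 12, y_um = 12, membrane_flag = TRUE)
  expect_warning(ro <- countUptake(overl, p1, 1), "overlapping")
  expect_equal(sum(ro$perCell), 1L)
})
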