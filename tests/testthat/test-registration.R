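# Bead-based affine registration: recovery of injected misalignments,
# degenerate inputs, and resampling behavior.

test_that("identity misalignment is recovered as identity", {
  b <- sceneBeads(8, noise = FALSE, seed = 4)
  m <- estimateRegistration(b$movie)
  ident <- cbind(diag(2), c(0, 0))
  expect_lt(max(abs(m@coef[, 1:2] - diag(2))), 0.05)
  expect_lt(max(abs(m@coef[, 3])) / PS, 0.05)
  expect_lt(m@residual, 0.05)
})

test_that("a pure translation is recovered within 0.02 px", {
  mis <- affineTransform(dx = 1.5 * PS, dy = -0.5 * PS)
  b <- sceneBeads(10, misalignment = mis, noise = FALSE, seed = 3)
  m <- estimateRegistration(b$movie)
  tru <- fretPolarity:::affineInvert(mis)
  expect_lt(max(abs(m@coef[, 3] - tru[, 3])) / PS, 0.02)
  expect_lt(max(abs(m@coef[, 1:2] - tru[, 1:2])), 0.002)
})

test_that("too few or collinear landmarks are errors", {
  expect_error(sceneBeads(2, noise = FALSE, seed = 1), "3 beads")
  centers <- cbind(c(4, 8, 12), c(4, 8, 12))  # collinear in um
  don <- gaussianBeadFrame(centers)
  mov <- twoChannelFromFrames(don, don)
  expect_error(estimateRegistration(mov), "collinear")
})

test_that("random affine misalignments are recovered to spec accuracy", {
  set.seed(19)
  ctrUm <- c(64, 64) * PS  # camera rotations pivot on the image centre
  for (i in 1:4) {
    mis <- affineTransform(dx = runif(1, -5, 5) * PS,
                           dy = runif(1, -5, 5) * PS,
                           rotationDeg = runif(1, -3, 3),
                           center = ctrUm)
    b <- sceneBeads(12, misalignment = mis, noise = FALSE, seed = 20 + i)
    m <- estimateRegistration(b$movie)
    pred <- t(m@coef[, 1:2] %*% t(b$acceptorCenters) + m@coef[, 3])
    rms <- sqrt(mean(rowSums((pred - b$donorCenters)^2))) / PS
    expect_lt(rms, 0.1)
    bn <- sceneBeads(12, misalignment = mis, noise = TRUE,
                     seed = 40 + i, photonScale = snr10$photonScale,
                     readNoiseSD = snr10$readNoiseSD,
                     background = snr10$background)
    mn <- estimateRegistration(bn$movie)
    predn <- t(mn@coef[, 1:2] %*% t(bn$acceptorCenters) + mn@coef[, 3])
    rmsn <- sqrt(mean(rowSums((predn - bn$donorCenters)^2))) / PS
    expect_lt(rmsn, 0.3)
  }
})

test_that("applying registration resamples only the acceptor channel", {
  sc <- sceneMigration(speed = 0.05, frames = 4L, noise = FALSE,
                       background = 0, readNoiseSD = 0)
  ident <- new("RegistrationModel", coef = cbind(diag(2), c(0, 0)),
               residual = 0, nLandmarks = 3L)
  out <- applyRegistration(sc$movie, ident)
  expect_identical(donor(out), donor(sc$movie))
  expect_equal(max(abs(acceptor(out) - acceptor(sc$movie))), 0)

  shift <- new("RegistrationModel",
               coef = cbind(diag(2), c(2 * PS, 0)),
               residual = 0, nLandmarks = 3L)
  fwd <- applyRegistration(sc$movie, shift)
  back <- applyRegistration(
    fwd, new("RegistrationModel",
             coef = fretPolarity:::affineInvert(shift@coef),
             residual = 0, nLandmarks = 3L))
  d <- dim(donor(sc$movie))
  interior <- 4:(d[2] - 3)
  orig <- acceptor(sc$movie)[, interior, ]
  rec <- acceptor(back)[, interior, ]
  ok <- back@acceptorValid[, interior, ]
  expect_lt(max(abs(orig[ok] - rec[ok])), 1e-6)
  # applying a non-identity model twice is not the same as once
  twice <- applyRegistration(fwd, shift)
  expect_gt(max(abs(acceptor(twice) - acceptor(fwd)), na.rm = TRUE), 0.1)
})
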