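# Bead-based channel registration: detect beads in both channels, match
# them, and fit a planar affine transform (acceptor -> donor) by least
# squares. The physical misalignment of a two-camera emission splitter
# is well modelled by an affine map, which is exactly invertible; this
# is a deliberate simplification relative to elastic registration.

# Intensity-weighted bead centroids (um). Spots are segmented by a
# threshold above the background, grown to capture the Gaussian tails.
detectBeadCentroids <- function(frame, pixelSize, growPx = 4L) {
  bg <- median(frame)
  peak <- max(frame)
  if (peak - bg <= 0) return(matrix(numeric(), 0, 2))
  mask <- frame > bg + 0.2 * (peak - bg)
  mask <- EBImage::dilate(mask * 1, EBImage::makeBrush(2L * growPx + 1L,
                                                      "disc")) > 0
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0) return(matrix(numeric(), 0, 2))
  w <- pmax(frame - bg, 0)
  out <- matrix(NA_real_, nlab, 2)
  for (i in seq_len(nlab)) {
    idx <- which(lab == i, arr.ind = TRUE)
    wi <- w[idx]
    if (sum(wi) <= 0) next
    out[i, ] <- c(sum((idx[, 2] - 0.5) * wi),
                  sum((idx[, 1] - 0.5) * wi)) / sum(wi) * pixelSize
  }
  out[is.finite(out[, 1]), , drop = FALSE]
}

#' Estimate the channel registration from a bead image pair
#'
#' Detects beads in the donor and acceptor channels of a calibration
#' movie (first frame), matches them by proximity, and fits the affine
#' transform mapping acceptor coordinates onto donor coordinates by
#' least squares.
#'
#' @param beadPair a \linkS4class{TwoChannelMovie} of a bead field.
#' @param maxMatchDistPx maximum centroid distance (px) for a cross-
#'   channel bead match.
#' @return a \linkS4class{RegistrationModel} (residual in px).
#' @export
estimateRegistration <- function(beadPair, maxMatchDistPx = 12) {
  ps <- pixelSize(beadPair)
  don <- detectBeadCentroids(donor(beadPair)[, , 1], ps)
  acc <- detectBeadCentroids(acceptor(beadPair)[, , 1], ps)
  if (nrow(don) < 3 || nrow(acc) < 3)
    stop("fewer than 3 beads detected; cannot fit an affine transform")
  # match each acceptor bead to the nearest donor bead
  pairs <- matrix(NA_real_, 0, 4)
  for (i in seq_len(nrow(acc))) {
    d <- sqrt((don[, 1] - acc[i, 1])^2 + (don[, 2] - acc[i, 2])^2)
    j <- which.min(d)
    if (d[j] <= maxMatchDistPx * ps)
      pairs <- rbind(pairs, c(acc[i, ], don[j, ]))
  }
  if (nrow(pairs) < 3)
    stop("fewer than 3 matched bead landmarks across channels")
  A <- pairs[, 1:2, drop = FALSE]  # acceptor
  D <- pairs[, 3:4, drop = FALSE]  # donor
  sv <- svd(scale(A, scale = FALSE))$d
  if (sv[2] < 1e-6 * max(sv[1], 1e-12))
    stop("bead landmarks are collinear; affine transform is degenerate")
  fit <- function(A, D) t(qr.solve(cbind(A, 1), D))
  coef <- fit(A, D)
  # refine: large misalignments can seed a few wrong nearest-neighbor
  # matches; re-match against the model prediction with a tight gate,
  # trimming gross residuals, until the match set stabilizes
  for (iter in 1:3) {
    predAll <- affineApply(coef, acc)
    A2 <- matrix(NA_real_, 0, 2); D2 <- matrix(NA_real_, 0, 2)
    for (i in seq_len(nrow(acc))) {
      d <- sqrt((don[, 1] - predAll[i, 1])^2 +
                (don[, 2] - predAll[i, 2])^2)
      j <- which.min(d)
      if (d[j] <= 3 * ps) {
        A2 <- rbind(A2, acc[i, ]); D2 <- rbind(D2, don[j, ])
      }
    }
    if (nrow(A2) < 3) break
    A <- A2; D <- D2
    coef <- fit(A, D)
  }
  pred <- affineApply(coef, A)
  res <- mean(sqrt(rowSums((pred - D)^2))) / ps
  new("RegistrationModel", coef = coef, residual = res,
      nLandmarks = nrow(A))
}

#' Apply a registration model to a movie
#'
#' Leaves the donor stack untouched and resamples every acceptor frame
#' into the donor coordinate frame with bilinear interpolation. Samples
#' falling outside the acceptor frame are flagged invalid (NA).
#'
#' @param movie a \linkS4class{TwoChannelMovie}.
#' @param model a \linkS4class{RegistrationModel}.
#' @return a \linkS4class{TwoChannelMovie} with aligned acceptor and an
#'   updated validity stack.
#' @export
applyRegistration <- function(movie, model) {
  ps <- pixelSize(movie)
  d <- dim(donor(movie))
  Rinv <- affineInvert(model@coef)
  g <- pixelGrid(d[1:2], ps, expand = TRUE)
  src <- affineApply(Rinv, cbind(as.vector(g$X), as.vector(g$Y)))
  acc <- movie@acceptor
  val <- movie@acceptorValid
  outA <- array(NA_real_, d)
  outV <- array(FALSE, d)
  for (f in seq_len(d[3])) {
    s <- bilinearSample(acc[, , f], src[, 1], src[, 2], ps)
    outA[, , f] <- matrix(s, d[1], d[2])
    outV[, , f] <- matrix(is.finite(s), d[1], d[2]) & val[, , f]
  }
  new("TwoChannelMovie", donor = movie@donor, acceptor = outA,
      acceptorValid = outV, acq = movie@acq)
}
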