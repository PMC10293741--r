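# Low-level geometry shared across modules.
#
# Coordinate convention: images are rows x cols matrices; pixel (r, c) has
# its centre at x = (c - 0.5) * pixelSize, y = (r - 0.5) * pixelSize, so
# physical points are c(x, y) in micrometres with y increasing down rows.

identityAffine <- function() cbind(diag(2), c(0, 0))

#' Build a planar affine transform
#'
#' Convenience constructor for the 2x3 matrices used as channel
#' misalignments and registration models: rotation (degrees, CCW about
#' the origin) followed by scaling, then translation.
#'
#' @param dx,dy translation (units of the space the transform acts on).
#' @param rotationDeg rotation angle in degrees.
#' @param scale isotropic scale factor.
#' @param center c(x, y) the rotation/scaling centre (for a camera
#'   misalignment this is the image centre, not the origin).
#' @return a 2x3 numeric matrix \code{cbind(L, t)}.
#' @export
affineTransform <- function(dx = 0, dy = 0, rotationDeg = 0, scale = 1,
                            center = c(0, 0)) {
  th <- rotationDeg * pi / 180
  L <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cbind(L, c(dx, dy) + center - L %*% center)
}

affineApply <- function(A, pts) {
  pts <- rbind(pts)  # accept single point
  t(A[, 1:2] %*% t(pts) + A[, 3])
}

affineInvert <- function(A) {
  Li <- solve(A[, 1:2])
  cbind(Li, -Li %*% A[, 3])
}

# Pixel-centre coordinate grid in micrometres: list(x = cols vector,
# y = rows vector) and full matrices when expand = TRUE.
pixelGrid <- function(shape, pixelSize, expand = FALSE) {
  y <- (seq_len(shape[1]) - 0.5) * pixelSize
  x <- (seq_len(shape[2]) - 0.5) * pixelSize
  if (!expand) return(list(x = x, y = y))
  list(X = matrix(x, shape[1], shape[2], byrow = TRUE),
       Y = matrix(y, shape[1], shape[2]))
}

# Bilinear sample of a matrix at physical points (um). Returns NA outside
# the frame. img is rows x cols.
bilinearSample <- function(img, x, y, pixelSize) {
  pracma::interp2(x = (seq_len(ncol(img)) - 0.5) * pixelSize,
                  y = (seq_len(nrow(img)) - 0.5) * pixelSize,
                  Z = img, xp = x, yp = y, method = "linear")
}

# Distance from points (n x 2) to a closed polyline (m x 2): minimum
# point-to-segment distance over edges. Vectorized over points per edge.
distanceToPolyline <- function(pts, poly) {
  pts <- rbind(pts)
  m <- nrow(poly)
  nxt <- c(2:m, 1)
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(m)) {
    a <- poly[i, ]; b <- poly[nxt[i], ]
    ab <- b - a
    L2 <- sum(ab^2)
    if (L2 < 1e-24) {
      dd <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / L2
      t <- pmin(1, pmax(0, t))
      dd <- (pts[, 1] - (a[1] + t * ab[1]))^2 +
            (pts[, 2] - (a[2] + t * ab[2]))^2
    }
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

# Even-odd point-in-polygon test, vectorized over points.
pointInPolygon <- function(pts, poly) {
  pts <- rbind(pts)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & is.finite(cross))
    j <- i
  }
  inside
}

# Bias-corrected perimeter of a binary mask (pixels): length of the
# corner-cut (moving-average smoothed) boundary-pixel-centre polygon,
# plus the half-pixel Minkowski offset (pi for one closed boundary) that
# accounts for the chain running half a pixel inside the true outline.
# Near-exact for rasterized disks and rectangles.
chainPerimeter <- function(mask, smoothW = 5L) {
  lab <- EBImage::bwlabel(mask * 1)
  oc <- EBImage::ocontour(lab)
  if (length(oc) == 0) return(0)
  total <- 0
  for (b in oc) {
    n <- nrow(b)
    if (n < 3) { total <- total + 2 + pi; next }
    w <- min(smoothW, n)
    if (w > 1) {
      half <- floor(w / 2)
      for (k in 1:2) {
        ext <- c(b[(n - half + 1):n, k], b[, k], b[1:half, k])
        b[, k] <- as.vector(stats::filter(ext, rep(1 / w, w)))[
          (half + 1):(half + n)]
      }
    }
    d <- diff(rbind(b, b[1, ]))
    total <- total + sum(sqrt(rowSums(d^2))) + pi
  }
  total
}

# Ordered sub-pixel contour of the largest object in a mask, in um
# (closed polyline, pixel centres of the 8-connected boundary).
maskContour <- function(mask, pixelSize) {
  lab <- EBImage::bwlabel(mask * 1)
  oc <- EBImage::ocontour(lab)
  if (length(oc) == 0) return(NULL)
  sizes <- vapply(oc, nrow, 1L)
  b <- oc[[which.max(sizes)]]
  # EBImage indexes dim1 (rows here) as x, 0-based: b[,1] = row-1, b[,2] = col-1
  cbind(x = (b[, 2] + 0.5) * pixelSize, y = (b[, 1] + 0.5) * pixelSize)
}

maskCentroid <- function(mask, pixelSize) {
  idx <- which(mask, arr.ind = TRUE)
  c(x = (mean(idx[, 2]) - 0.5) * pixelSize,
    y = (mean(idx[, 1]) - 0.5) * pixelSize)
}

# Principal axis (unit vector) of a mask from the covariance of pixel
# centre coordinates; sign is arbitrary.
maskPrincipalAxis <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) return(c(1, 0))
  xy <- cbind(idx[, 2], idx[, 1])
  ev <- eigen(stats::cov(xy), symmetric = TRUE)
  v <- ev$vectors[, 1]
  v / sqrt(sum(v^2))
}

# Rolling mean with centred window (odd w); near the ends the window
# shrinks symmetrically, which keeps the estimate unbiased for linear
# trends everywhere.
rollMean <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- floor(w / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    out[i] <- mean(x[(i - h):(i + h)], na.rm = TRUE)
  }
  out
}

# Rolling median with centred window; preserves run boundaries exactly
# (unlike a rolling mean) while suppressing single-frame spikes.
rollMedian <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- floor(w / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1, i - half); b <- min(n, i + half)
    out[i] <- median(x[a:b], na.rm = TRUE)
  }
  out
}

vecNorm <- function(v) sqrt(sum(v^2))

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
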