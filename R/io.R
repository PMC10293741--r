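# File interfaces: per-channel multi-page TIFF with a JSON sidecar for
# acquisition metadata, ground-truth CSV tables, registration models as
# JSON, and CSV writers with a unit-naming header comment.
#
# TIFF values are scaled into [0, 1] on write (32-bit float pages) with
# the scale recorded in the sidecar, so arbitrary photon counts round-
# trip losslessly.

#' Write a two-channel movie to TIFF + JSON sidecar
#'
#' @param movie a \linkS4class{TwoChannelMovie}.
#' @param prefix output path prefix; writes <prefix>_donor.tif,
#'   <prefix>_acceptor.tif and <prefix>_meta.json.
#' @return the sidecar path, invisibly.
#' @export
writeMovieTIFF <- function(movie, prefix) {
  writeStack <- function(arr, path) {
    lo <- min(arr)
    hi <- max(arr, lo + 1e-12)
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(f) (arr[, , f] - lo) / (hi - lo))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    c(lo, hi)
  }
  sd <- writeStack(movie@donor, paste0(prefix, "_donor.tif"))
  sa <- writeStack(movie@acceptor, paste0(prefix, "_acceptor.tif"))
  acq <- movie@acq
  meta <- list(
    pixel_size_um = acq@pixelSize, frame_interval_s = acq@frameInterval,
    frame_count = acq@frameCount, image_shape = acq@imageShape,
    photon_scale = acq@photonScale, read_noise_sd = acq@readNoiseSD,
    background = acq@background,
    misalignment = as.vector(acq@misalignment),
    seed = if (is.na(acq@seed)) NULL else acq@seed,
    donor_range = sd, acceptor_range = sa)
  path <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a two-channel movie written by \code{writeMovieTIFF}
#'
#' @param prefix path prefix used at write time.
#' @return a \linkS4class{TwoChannelMovie}.
#' @export
readMovieTIFF <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  readStack <- function(path, rng) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(NA_real_, c(dim(pages[[1]]), length(pages)))
    for (f in seq_along(pages))
      arr[, , f] <- pages[[f]] * (rng[2] - rng[1]) + rng[1]
    arr
  }
  don <- readStack(paste0(prefix, "_donor.tif"), meta$donor_range)
  acc <- readStack(paste0(prefix, "_acceptor.tif"), meta$acceptor_range)
  acq <- acquisitionConfig(
    pixelSize = meta$pixel_size_um, frameInterval = meta$frame_interval_s,
    frameCount = meta$frame_count, imageShape = meta$image_shape,
    photonScale = meta$photon_scale, readNoiseSD = meta$read_noise_sd,
    background = meta$background,
    misalignment = matrix(meta$misalignment, 2, 3),
    seed = meta$seed %||% NA_integer_)
  new("TwoChannelMovie", donor = don, acceptor = acc,
      acceptorValid = array(TRUE, dim(don)), acq = acq)
}

#' Write a ratio movie as float TIFF plus validity mask TIFF
#'
#' @param ratio a \linkS4class{RatioMovie}.
#' @param prefix output path prefix.
#' @return invisibly, the ratio TIFF path.
#' @export
writeRatioTIFF <- function(ratio, prefix) {
  hi <- max(ratio@ratio, na.rm = TRUE)
  pages <- lapply(seq_len(nFrames(ratio)), function(f) {
    m <- ratio@ratio[, , f] / hi
    m[is.na(m)] <- 0
    m
  })
  tiff::writeTIFF(pages, paste0(prefix, "_ratio.tif"),
                  bits.per.sample = 32L)
  vm <- lapply(seq_len(nFrames(ratio)),
               function(f) ratio@valid[, , f] * 1)
  tiff::writeTIFF(vm, paste0(prefix, "_valid.tif"),
                  bits.per.sample = 8L)
  jsonlite::write_json(list(ratio_scale = hi,
                            pixel_size_um = ratio@pixelSize,
                            frame_interval_s = ratio@frameInterval),
                       paste0(prefix, "_ratio.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, "_ratio.tif"))
}

#' Write / read a registration model as JSON
#'
#' @param model a \linkS4class{RegistrationModel}.
#' @param path JSON file path.
#' @return \code{writeRegistrationJSON}: the path, invisibly;
#'   \code{readRegistrationJSON}: the model.
#' @export
writeRegistrationJSON <- function(model, path) {
  jsonlite::write_json(list(coef = as.vector(model@coef),
                            residual_px = model@residual,
                            n_landmarks = model@nLandmarks),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRegistrationJSON
#' @export
readRegistrationJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("RegistrationModel", coef = matrix(j$coef, 2, 3),
      residual = j$residual_px, nLandmarks = as.integer(j$n_landmarks))
}

#' Write the ground-truth table of a synthetic scene as CSV
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path CSV path.
#' @param frameInterval seconds per frame.
#' @return the path, invisibly.
#' @export
writeGroundTruthCSV <- function(truth, path, frameInterval = 1) {
  n <- nFrames(truth)
  df <- data.frame(
    frame = seq_len(n), time_s = (seq_len(n) - 1) * frameInterval,
    centroid_x_um = truth@centroid[, 1],
    centroid_y_um = truth@centroid[, 2],
    front_x_um = truth@frontPoint[, 1],
    front_y_um = truth@frontPoint[, 2],
    peak_axial_fraction = truth@peakAxialFraction,
    phase = truth@phase)
  writeCSVWithUnits(df, path,
                    "frame [1], time [s], positions [um], fraction [0-1]")
  invisible(path)
}

# CSV with a leading '# units: ...' comment line.
writeCSVWithUnits <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  write.csv(df, con, row.names = FALSE)
  path
}

readCSVWithUnits <- function(path) {
  read.csv(path, comment.char = "#")
}
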