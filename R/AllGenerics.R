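#' Accessor generics
#'
#' Small accessor family shared by the movie, track and profile classes:
#' \code{donor()}, \code{acceptor()} raw channel stacks;
#' \code{ratioValues()}, \code{validMask()} the ratio stack and its
#' validity; \code{pixelSize()}, \code{frameInterval()}, \code{nFrames()}
#' acquisition metadata; \code{centroids()}, \code{contours()},
#' \code{headings()}, \code{frontAnchors()}, \code{rearAnchors()} track
#' geometry; \code{binMatrix()} the frames x bins profile reduction;
#' \code{waveDurations()}, \code{switchTimes()}, \code{dwellTimes()}
#' oscillation statistics.
#'
#' @param x an object of one of the package's classes.
#' @return the corresponding slot content (see each class's documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("donor", function(x) standardGeneric("donor"))
#' @rdname accessors
#' @export
setGeneric("acceptor", function(x) standardGeneric("acceptor"))
#' @rdname accessors
#' @export
setGeneric("ratioValues", function(x) standardGeneric("ratioValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("contours", function(x) standardGeneric("contours"))
#' @rdname accessors
#' @export
setGeneric("headings", function(x) standardGeneric("headings"))
#' @rdname accessors
#' @export
setGeneric("frontAnchors", function(x) standardGeneric("frontAnchors"))
#' @rdname accessors
#' @export
setGeneric("rearAnchors", function(x) standardGeneric("rearAnchors"))
#' @rdname accessors
#' @export
setGeneric("binMatrix", function(x) standardGeneric("binMatrix"))
#' @rdname accessors
#' @export
setGeneric("waveDurations", function(x) standardGeneric("waveDurations"))
#' @rdname accessors
#' @export
setGeneric("switchTimes", function(x) standardGeneric("switchTimes"))
#' @rdname accessors
#' @export
setGeneric("dwellTimes", function(x) standardGeneric("dwellTimes"))

# --- methods -----------------------------------------------------------

#' @rdname accessors
setMethod("donor", "TwoChannelMovie", function(x) x@donor)
#' @rdname accessors
setMethod("acceptor", "TwoChannelMovie", function(x) x@acceptor)
#' @rdname accessors
setMethod("pixelSize", "TwoChannelMovie", function(x) x@acq@pixelSize)
#' @rdname accessors
setMethod("frameInterval", "TwoChannelMovie", function(x) x@acq@frameInterval)
#' @rdname accessors
setMethod("nFrames", "TwoChannelMovie", function(x) dim(x@donor)[3])

#' @rdname accessors
setMethod("ratioValues", "RatioMovie", function(x) x@ratio)
#' @rdname accessors
setMethod("validMask", "RatioMovie", function(x) x@valid)
#' @rdname accessors
setMethod("pixelSize", "RatioMovie", function(x) x@pixelSize)
#' @rdname accessors
setMethod("frameInterval", "RatioMovie", function(x) x@frameInterval)
#' @rdname accessors
setMethod("nFrames", "RatioMovie", function(x) dim(x@ratio)[3])

#' @rdname accessors
setMethod("centroids", "CellTrack", function(x) x@centroid)
#' @rdname accessors
setMethod("contours", "CellTrack", function(x) x@contours)
#' @rdname accessors
setMethod("headings", "CellTrack", function(x) x@heading)
#' @rdname accessors
setMethod("frontAnchors", "CellTrack", function(x) x@frontAnchor)
#' @rdname accessors
setMethod("rearAnchors", "CellTrack", function(x) x@rearAnchor)
#' @rdname accessors
setMethod("pixelSize", "CellTrack", function(x) x@pixelSize)
#' @rdname accessors
setMethod("frameInterval", "CellTrack", function(x) x@frameInterval)
#' @rdname accessors
setMethod("nFrames", "CellTrack", function(x) dim(x@masks)[3])

#' @rdname accessors
setMethod("centroids", "GroundTruth", function(x) x@centroid)
#' @rdname accessors
setMethod("nFrames", "GroundTruth", function(x) dim(x@mask)[3])

#' @rdname accessors
setMethod("binMatrix", "AxisProfileSeries", function(x) x@bins)
#' @rdname accessors
setMethod("nFrames", "AxisProfileSeries", function(x) length(x@profiles))
#' @rdname accessors
setMethod("frameInterval", "AxisProfileSeries", function(x) x@frameInterval)

#' @rdname accessors
setMethod("waveDurations", "PeakTrace", function(x) x@waveDurations)
#' @rdname accessors
setMethod("switchTimes", "PeakTrace", function(x) x@switchTimes)
#' @rdname accessors
setMethod("dwellTimes", "PeakTrace", function(x)
  c(front = x@dwellFront, rear = x@dwellRear))

# --- show methods ------------------------------------------------------

setMethod("show", "TwoChannelMovie", function(object) {
  d <- dim(object@donor)
  cat(sprintf(
    "TwoChannelMovie: %d x %d px, %d frames, %.3g um/px, dt = %g s\n",
    d[1], d[2], d[3], object@acq@pixelSize, object@acq@frameInterval))
})

setMethod("show", "RatioMovie", function(object) {
  d <- dim(object@ratio)
  cat(sprintf(
    "RatioMovie: %d x %d px, %d frames, %.1f%% pixels defined\n",
    d[1], d[2], d[3], 100 * mean(object@valid)))
})

setMethod("show", "RegistrationModel", function(object) {
  cat("RegistrationModel (acceptor -> donor affine)\n")
  print(round(object@coef, 4))
  cat(sprintf("residual: %.4g px over %d landmarks\n",
              object@residual, object@nLandmarks))
})

setMethod("show", "CellTrack", function(object) {
  cat(sprintf(
    "CellTrack: %d frames, dt = %g s, net displacement %.2f um\n",
    nFrames(object), object@frameInterval,
    sqrt(sum((object@centroid[nrow(object@centroid), ] -
              object@centroid[1, ])^2))))
})

setMethod("show", "PeakTrace", function(object) {
  cat(sprintf(
    paste0("PeakTrace: %d frames, %d switches, mean wave %.2f s, ",
           "dwell front/rear %.1f/%.1f s\n"),
    nrow(object@table), length(object@switchTimes),
    if (length(object@waveDurations)) mean(object@waveDurations) else NA,
    object@dwellFront, object@dwellRear))
})

setMethod("show", "PhagosomeTrace", function(object) {
  cat(sprintf(
    "PhagosomeTrace: contact %.1f s, engulfed %s, engulfment time %s\n",
    object@contactTime,
    if (object@complete) sprintf("%.1f s", object@engulfedTime) else "never",
    if (object@complete) sprintf("%.1f s", object@engulfmentTime) else "NA"))
})
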