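#' @import methods
#' @importFrom stats rnorm rpois runif sd median approx setNames
#' @importFrom utils write.csv read.csv head tail
NULL

#' Acquisition configuration for synthetic or real movies
#'
#' Bundles the physical acquisition metadata that every downstream stage
#' needs: pixel size, frame interval, image geometry, and (for the
#' synthetic renderer) the photon-noise model and the planar affine
#' misalignment applied to the acceptor channel, emulating a two-camera
#' emission splitter.
#'
#' @slot pixelSize pixel size in micrometres per pixel (> 0).
#' @slot frameInterval time between frames in seconds (> 0).
#' @slot frameCount number of frames.
#' @slot imageShape integer vector c(rows, cols) in pixels.
#' @slot photonScale expected donor photons at unit scene intensity (>= 0);
#'   0 disables Poisson noise.
#' @slot readNoiseSD Gaussian read noise SD in photons (>= 0).
#' @slot background background level in photons (>= 0).
#' @slot misalignment 2x3 affine matrix mapping donor-frame coordinates
#'   (micrometres) to the acceptor camera frame; identity when aligned.
#' @slot seed integer seed for the renderer's random streams (NA for none).
#' @export
setClass("AcquisitionConfig",
  representation(
    pixelSize = "numeric", frameInterval = "numeric",
    frameCount = "integer", imageShape = "integer",
    photonScale = "numeric", readNoiseSD = "numeric",
    background = "numeric", misalignment = "matrix", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
    if (object@frameCount < 1) msg <- c(msg, "frameCount must be >= 1")
    if (length(object@imageShape) != 2 || any(object@imageShape < 4))
      msg <- c(msg, "imageShape must be two pixel counts >= 4")
    if (object@photonScale < 0) msg <- c(msg, "photonScale must be >= 0")
    if (object@readNoiseSD < 0) msg <- c(msg, "readNoiseSD must be >= 0")
    if (object@background < 0) msg <- c(msg, "background must be >= 0")
    if (!all(dim(object@misalignment) == c(2L, 3L)))
      msg <- c(msg, "misalignment must be a 2x3 affine matrix")
    if (length(msg)) msg else TRUE
  })

#' Two-channel biosensor movie
#'
#' Paired donor and acceptor frame stacks with acquisition metadata.
#' Arrays are rows x cols x frames; the optional acceptor validity stack
#' flags pixels lost during registration resampling.
#'
#' @slot donor numeric array rows x cols x frames.
#' @slot acceptor numeric array, same dimensions.
#' @slot acceptorValid logical array, same dimensions (TRUE where the
#'   acceptor sample is defined).
#' @slot acq an \linkS4class{AcquisitionConfig}.
#' @export
setClass("TwoChannelMovie",
  representation(donor = "array", acceptor = "array",
                 acceptorValid = "array", acq = "AcquisitionConfig"),
  validity = function(object) {
    d <- dim(object@donor)
    if (length(d) != 3) return("donor must be a rows x cols x frames array")
    if (!identical(d, dim(object@acceptor)))
      return("donor and acceptor dimensions differ")
    if (!identical(d, dim(object@acceptorValid)))
      return("acceptorValid dimensions differ from channels")
    TRUE
  })

#' Masked FRET-ratio movie
#'
#' Per-frame acceptor/donor ratio images with a validity mask. Ratios are
#' defined (finite, positive) only where the mask is TRUE; undefined
#' pixels hold NA.
#'
#' @slot ratio numeric array rows x cols x frames (NA where invalid).
#' @slot valid logical array, same dimensions.
#' @slot pixelSize micrometres per pixel.
#' @slot frameInterval seconds per frame.
#' @export
setClass("RatioMovie",
  representation(ratio = "array", valid = "array",
                 pixelSize = "numeric", frameInterval = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@ratio), dim(object@valid)))
      return("ratio and valid dimensions differ")
    ok <- object@ratio[object@valid]
    if (any(!is.finite(ok)) || any(ok <= 0))
      return("defined ratio pixels must be finite and > 0")
    if (any(!is.na(object@ratio[!object@valid])))
      return("invalid pixels must be NA")
    TRUE
  })

#' Channel registration model
#'
#' Planar affine transform (2x3 coefficients) mapping acceptor-channel
#' coordinates onto donor-channel coordinates, with the mean landmark
#' residual of the fit.
#'
#' @slot coef 2x3 affine matrix (linear part in columns 1:2, offset in 3).
#' @slot residual mean landmark error after alignment, in pixels (>= 0).
#' @slot nLandmarks number of matched bead landmarks used in the fit.
#' @export
setClass("RegistrationModel",
  representation(coef = "matrix", residual = "numeric",
                 nLandmarks = "integer"),
  validity = function(object) {
    if (!all(dim(object@coef) == c(2L, 3L)))
      return("coef must be a 2x3 affine matrix")
    if (abs(det(object@coef[, 1:2])) < 1e-12)
      return("transform is not invertible (singular linear part)")
    if (object@residual < 0) return("residual must be >= 0")
    TRUE
  })

#' Phenomenological polarized-cell shape model
#'
#' A smooth closed contour: a low-order harmonic perturbation of an
#' ellipse, in a frame aligned with the per-frame heading, optionally
#' carrying time-varying protrusion bumps. Default body length is 15.6
#' micrometres (twice the 7.8 um half-length of a polarized neutrophil).
#'
#' @slot bodyLength cell length along the heading, micrometres.
#' @slot bodyWidth cell width normal to the heading, micrometres.
#' @slot harmonics numeric vector of relative harmonic amplitudes
#'   (harmonic k >= 2); small values keep the contour simple.
#' @slot centroid frames x 2 matrix of centroid positions (um, x/y).
#' @slot heading frames x 2 matrix of unit heading vectors.
#' @slot protrusions data.frame with columns onset_s, angle_deg,
#'   growth_um_s, width_deg (possibly zero rows): bump amplitude grows
#'   linearly from onset.
#' @slot frameInterval seconds per frame.
#' @export
setClass("CellModel",
  representation(bodyLength = "numeric", bodyWidth = "numeric",
                 harmonics = "numeric", centroid = "matrix",
                 heading = "matrix", protrusions = "data.frame",
                 frameInterval = "numeric"),
  validity = function(object) {
    if (object@bodyLength <= 0 || object@bodyWidth <= 0)
      return("body dimensions must be > 0")
    if (nrow(object@centroid) != nrow(object@heading))
      return("centroid and heading frame counts differ")
    n <- sqrt(rowSums(object@heading^2))
    if (any(abs(n - 1) > 1e-6)) return("heading rows must be unit vectors")
    if (sum(abs(object@harmonics)) > 0.45)
      return("harmonic amplitudes too large: contour may self-intersect")
    TRUE
  })

#' True biosensor activity field for synthetic movies
#'
#' A strictly positive phenomenological FRET-ratio field inside the cell:
#' a baseline plus a front-high longitudinal gradient, a travelling
#' Gaussian activity peak whose axial position oscillates pole-to-pole,
#' and an optional multiplicative enrichment within a peripheral band
#' (activity concentrated around the cell edge).
#'
#' @slot baselineRatio dimensionless baseline ratio (> 0).
#' @slot gradientAmplitude front-minus-back ratio difference.
#' @slot peakAmplitude height of the travelling peak above baseline.
#' @slot peakPosition numeric vector, per-frame axial position of the
#'   peak as a fraction of axis length (0 = leading edge, 1 = uropod).
#' @slot peakWidth Gaussian sigma of the peak along the axis, um.
#' @slot oscillationCycle full pole-to-pole-and-back period, seconds
#'   (metadata; peakPosition holds the realized trajectory).
#' @slot edgeEnrichment multiplicative factor within the edge band (1 =
#'   none).
#' @slot edgeBandWidth width of the peripheral enrichment band, um.
#' @export
setClass("ActivityField",
  representation(baselineRatio = "numeric", gradientAmplitude = "numeric",
                 peakAmplitude = "numeric", peakPosition = "numeric",
                 peakWidth = "numeric", oscillationCycle = "numeric",
                 edgeEnrichment = "numeric", edgeBandWidth = "numeric"),
  validity = function(object) {
    if (object@baselineRatio <= 0) return("baselineRatio must be > 0")
    if (object@baselineRatio + min(0, object@gradientAmplitude) +
        min(0, object@peakAmplitude) <= 0)
      return("field must stay strictly positive")
    if (object@edgeEnrichment <= 0) return("edgeEnrichment must be > 0")
    if (object@peakWidth <= 0) return("peakWidth must be > 0")
    TRUE
  })

#' Ground truth accompanying a rendered synthetic movie
#'
#' Everything a recovery test needs: the true ratio images and masks, the
#' true centroid/front/rear trajectories, the true axial peak position,
#' per-frame motility phase labels, and event times (needle move,
#' particle contact, full engulfment).
#'
#' @slot ratio numeric array of true ratio images (NA outside the cell).
#' @slot mask logical array of true cell masks.
#' @slot centroid frames x 2 true centroid (um).
#' @slot frontPoint frames x 2 true leading-edge pole (um).
#' @slot rearPoint frames x 2 true uropod pole (um).
#' @slot peakAxialFraction per-frame true axial peak position (fraction
#'   of axis length from the leading edge), NA when no peak is rendered.
#' @slot phase character per frame: "migrating", "stalling" or NA.
#' @slot events named list of event times in seconds (e.g. needle_move_s,
#'   contact_s, engulfed_s) and derived frame indices.
#' @export
setClass("GroundTruth",
  representation(ratio = "array", mask = "array", centroid = "matrix",
                 frontPoint = "matrix", rearPoint = "matrix",
                 peakAxialFraction = "numeric", phase = "character",
                 events = "list"),
  validity = function(object) {
    n <- dim(object@mask)[3]
    if (dim(object@ratio)[3] != n || nrow(object@centroid) != n ||
        length(object@phase) != n)
      return("ground-truth components disagree on frame count")
    TRUE
  })

#' Per-frame segmented cell with shape descriptors
#'
#' @slot mask logical matrix.
#' @slot frame frame index (1-based).
#' @slot area mask area, um^2.
#' @slot perimeter bias-corrected boundary length, um.
#' @slot circularity 4*pi*A/P^2 (1 for a circle; tolerance +0.05 for
#'   rasterization).
#' @slot centroid c(x, y) in um.
#' @slot pixelSize um per pixel.
#' @export
setClass("CellMask",
  representation(mask = "matrix", frame = "integer", area = "numeric",
                 perimeter = "numeric", circularity = "numeric",
                 centroid = "numeric", pixelSize = "numeric"),
  validity = function(object) {
    if (object@area <= 0) return("area must be > 0")
    if (object@circularity <= 0 || object@circularity > 1.05)
      return("circularity outside (0, 1.05]")
    TRUE
  })

#' Tracked cell across frames
#'
#' Per-frame mask, sub-pixel contour, centroid, smoothed unit heading,
#' and the leading-edge / uropod anchors (extremal contour points along
#' +heading / -heading).
#'
#' @slot masks logical array rows x cols x frames.
#' @slot contours list of n x 2 matrices (um), one per frame (closed
#'   polylines; NULL entries for missing frames).
#' @slot centroid frames x 2 matrix (um).
#' @slot heading frames x 2 unit-vector matrix.
#' @slot frontAnchor frames x 2 matrix (um), leading-edge anchor.
#' @slot rearAnchor frames x 2 matrix (um), uropod anchor.
#' @slot pixelSize um per pixel.
#' @slot frameInterval seconds per frame.
#' @export
setClass("CellTrack",
  representation(masks = "array", contours = "list", centroid = "matrix",
                 heading = "matrix", frontAnchor = "matrix",
                 rearAnchor = "matrix", pixelSize = "numeric",
                 frameInterval = "numeric"),
  validity = function(object) {
    n <- dim(object@masks)[3]
    if (nrow(object@centroid) != n || length(object@contours) != n)
      return("track components disagree on frame count")
    h <- object@heading
    nz <- rowSums(h^2) > 0
    if (any(abs(sqrt(rowSums(h[nz, , drop = FALSE]^2)) - 1) > 1e-6))
      return("non-missing heading rows must be unit vectors")
    TRUE
  })

#' Longitudinal-axis activity profiles over time
#'
#' Per-frame FRET-ratio line scans along the leading-edge-to-uropod axis,
#' and their reduction to a fixed number of equal-length bins (bin 1 at
#' the leading edge).
#'
#' @slot profiles list, one per frame: list(pos = axial positions um from
#'   the leading edge, value = ratio samples); NULL for skipped frames.
#' @slot bins frames x nBins matrix of bin means.
#' @slot axisLength per-frame axis length, um.
#' @slot frameInterval seconds per frame.
#' @export
setClass("AxisProfileSeries",
  representation(profiles = "list", bins = "matrix",
                 axisLength = "numeric", frameInterval = "numeric"),
  validity = function(object) {
    if (length(object@profiles) != nrow(object@bins))
      return("profiles and bins disagree on frame count")
    TRUE
  })

#' Peak-activity trace and oscillation statistics
#'
#' Axial position of the maximum-ratio pixel per frame, pole-zone labels
#' (within \code{poleZone} um of the leading edge or uropod along the
#' axis), switch events, wave durations and dwell times.
#'
#' @slot table data.frame: frame, time_s, peak_um_from_front,
#'   peak_fraction, zone ("front"/"rear"/"interior"/NA), switch_flag.
#' @slot switchTimes times (s) at which the peak entered one pole zone
#'   after last having been in the opposite zone.
#' @slot waveDurations intervals between successive switch events, s.
#' @slot dwellFront total time with the peak in the leading-edge zone, s.
#' @slot dwellRear total time with the peak in the uropod zone, s.
#' @slot poleZone pole-zone half-width used, um.
#' @slot frameInterval seconds per frame.
#' @slot convention character note on how oscillations are counted.
#' @export
setClass("PeakTrace",
  representation(table = "data.frame", switchTimes = "numeric",
                 waveDurations = "numeric", dwellFront = "numeric",
                 dwellRear = "numeric", poleZone = "numeric",
                 frameInterval = "numeric", convention = "character"),
  validity = function(object) {
    if (any(object@waveDurations <= 0))
      return("wave durations must be positive")
    tot <- nrow(object@table) * object@frameInterval
    if (object@dwellFront + object@dwellRear > tot + 1e-9)
      return("pole dwell exceeds observation time")
    TRUE
  })

#' Polar map of edge-band activity (eccentric-circle plot)
#'
#' Frames x angular-bin matrix of peripheral FRET ratio, rotated so a
#' reference direction (the chemoattractant micropipette) sits at a fixed
#' compass point; rendered with the first frame at the centre and the
#' last at the plot edge.
#'
#' @slot values frames x nAngular matrix (NA where the band had no
#'   pixels at that angle).
#' @slot anglesDeg angular bin centres, degrees (0 = east, CCW).
#' @slot referenceDeg compass angle the reference direction was rotated
#'   to (180 = west).
#' @export
setClass("PolarMap",
  representation(values = "matrix", anglesDeg = "numeric",
                 referenceDeg = "numeric"),
  validity = function(object) {
    if (ncol(object@values) != length(object@anglesDeg))
      return("anglesDeg length must match value columns")
    TRUE
  })

#' Phagosomal FRET trace
#'
#' Mean FRET ratio in an annulus around a tracked particle, from cell
#' contact to full engulfment, with the engulfment time.
#'
#' @slot table data.frame: frame, time_s, mean_ratio, engulfing (logical).
#' @slot contactTime first particle-cell contact, s (NA if never).
#' @slot engulfedTime time of full engulfment, s (NA if incomplete).
#' @slot engulfmentTime engulfedTime - contactTime, s (NA if incomplete).
#' @slot complete logical: was the particle fully engulfed.
#' @export
setClass("PhagosomeTrace",
  representation(table = "data.frame", contactTime = "numeric",
                 engulfedTime = "numeric", engulfmentTime = "numeric",
                 complete = "logical"),
  validity = function(object) {
    if (isTRUE(object@complete)) {
      if (!is.finite(object@engulfmentTime) || object@engulfmentTime <= 0)
        return("complete engulfment requires a positive engulfment time")
      if (object@contactTime > object@engulfedTime)
        return("contact must precede full engulfment")
    }
    TRUE
  })
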