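# Migration behavior: front-pixel velocity, migrating/stalling phase
# classification (centre-of-mass displacement criterion), migration
# flags under the half-body-length and one-cell-diameter criteria,
# protrusion detection, turning latency, and movement plots.

#' Front-pixel velocity over fixed windows
#'
#' Displacement of the leading-edge anchor over consecutive
#' non-overlapping windows (default 20 s) divided by the window length.
#' The front pixel is the extremal contour point along the heading --
#' deterministic and robust to intensity noise.
#'
#' @param track a \linkS4class{CellTrack}.
#' @param window window length, s (>= 2 frame intervals).
#' @param anchorSmooth centred rolling-mean window (s) applied to the
#'   anchor trajectory before differencing; damps the upward bias that
#'   pixel-level anchor jitter adds to slow speeds. Has no effect on
#'   noiseless linear motion.
#' @return list(perWindow = data.frame(start_s, end_s, velocity_um_s),
#'   mean = mean velocity um/s).
#' @export
frontPixelVelocity <- function(track, window = 20, anchorSmooth = 5) {
  dt <- track@frameInterval
  if (window < 2 * dt) stop("window must span at least 2 frame intervals")
  n <- nFrames(track)
  span <- (n - 1) * dt
  if (span < window) stop("track shorter than one velocity window")
  sw <- max(1L, round(anchorSmooth / dt))
  if (sw %% 2 == 0) sw <- sw + 1L
  anchor <- cbind(rollMean(track@frontAnchor[, 1], sw),
                  rollMean(track@frontAnchor[, 2], sw))
  wf <- round(window / dt)
  starts <- seq(1L, n - wf, by = wf)
  per <- data.frame(
    start_s = (starts - 1) * dt,
    end_s = (starts - 1 + wf) * dt,
    velocity_um_s = vapply(starts, function(s) {
      d <- anchor[s + wf, ] - anchor[s, ]
      vecNorm(d) / (wf * dt)
    }, 0))
  list(perWindow = per, mean = mean(per$velocity_um_s, na.rm = TRUE))
}

#' Classify migrating and stalling phases
#'
#' Segments the track into maximal phases of at least
#' \code{minDuration} (default 20 s) labeled migrating where the cell
#' displaces its centre of mass by at least
#' \code{displacementThreshold} (default 2 um) per \code{minDuration}
#' window, stalling where it does not; sub-threshold-duration remainders
#' are left unlabeled. Segment boundaries come from the per-step
#' centre-of-mass speed crossing the equivalent rate
#' (threshold / duration).
#'
#' @param track a \linkS4class{CellTrack}.
#' @param minDuration minimum phase duration, s (> 0).
#' @param displacementThreshold COM displacement criterion, um.
#' @param smoothFrames odd rolling-median window (frames) applied to the
#'   per-step speed before thresholding (suppresses single-frame
#'   segmentation jitter without eroding run boundaries).
#' @return data.frame(start_s, end_s, label, window_displacement_um)
#'   with non-overlapping, time-ordered segments.
#' @export
classifyPhases <- function(track, minDuration = 20,
                           displacementThreshold = 2,
                           smoothFrames = 3) {
  if (minDuration <= 0) stop("minDuration must be > 0")
  dt <- track@frameInterval
  ctr <- track@centroid
  n <- nrow(ctr)
  if ((n - 1) * dt < minDuration)
    stop("track shorter than the minimum phase duration")
  step <- sqrt(rowSums((ctr[-1, , drop = FALSE] -
                        ctr[-n, , drop = FALSE])^2)) / dt
  step <- rollMedian(step, smoothFrames)
  moving <- step >= displacementThreshold / minDuration
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- data.frame(start_s = numeric(), end_s = numeric(),
                     label = character(),
                     window_displacement_um = numeric())
  wf <- round(minDuration / dt)
  for (i in seq_along(r$lengths)) {
    dur <- r$lengths[i] * dt
    if (dur < minDuration) next
    a <- starts[i]; b <- ends[i] + 1L  # frames spanned by these steps
    wd <- vapply(a:(b - wf), function(s)
      vecNorm(ctr[s + wf, ] - ctr[s, ]), 0)
    mwd <- mean(wd)
    segs <- rbind(segs, data.frame(
      start_s = (a - 1) * dt, end_s = (b - 1) * dt,
      label = if (mwd >= displacementThreshold) "migrating"
              else "stalling",
      window_displacement_um = mwd))
  }
  attr(segs, "criterion") <- sprintf(
    "COM displacement >= %g um per %g s (operational reading of the phase definition)",
    displacementThreshold, minDuration)
  segs
}

#' Classify a cell as migrating under a stated criterion
#'
#' Either the half-body-length rule (net displacement of at least
#' 7.8 um over a 2 min observation) or the one-cell-diameter rule (net
#' displacement of at least one equivalent-circle diameter of the
#' cell's mean area over 10 min). Both boundaries are inclusive
#' ("at least").
#'
#' @param track a \linkS4class{CellTrack} spanning the observation
#'   period.
#' @param criterion "half-body" or "diameter".
#' @param halfBodyLength threshold for the half-body criterion, um.
#' @param observation observation period, s (120 for half-body, 600 for
#'   diameter by default).
#' @return logical flag, with attributes threshold_um and
#'   net_displacement_um.
#' @export
classifyMigrating <- function(track,
                              criterion = c("half-body", "diameter"),
                              halfBodyLength = 7.8,
                              observation = NULL) {
  criterion <- match.arg(criterion)
  dt <- track@frameInterval
  if (is.null(observation))
    observation <- if (criterion == "half-body") 120 else 600
  n <- nFrames(track)
  if ((n - 1) * dt < observation - 1e-9)
    stop(sprintf("track spans %.0f s; criterion requires %.0f s",
                 (n - 1) * dt, observation))
  last <- round(observation / dt) + 1L
  net <- vecNorm(track@centroid[last, ] - track@centroid[1, ])
  thr <- if (criterion == "half-body") halfBodyLength else {
    areas <- vapply(seq_len(n), function(f)
      sum(track@masks[, , f]) * track@pixelSize^2, 0)
    2 * sqrt(mean(areas) / pi)
  }
  structure(net >= thr, threshold_um = thr, net_displacement_um = net)
}

#' Detect leading-edge protrusion events
#'
#' A protrusion event is a contiguous contour arc of at least
#' \code{arcMin} whose outward advance rate is at least
#' \code{advanceRateMin}, sustained for at least \code{sustainMin}.
#' Advance is measured as the distance of current contour points beyond
#' the mask several frames back (a lag long enough that a
#' threshold-rate protrusion moves about two pixels), which keeps
#' rasterized contour motion from flickering below the rate threshold;
#' the event onset is back-extrapolated from the first detection using
#' the event's steady advance rate. An automated proxy for what the
#' original assay scored by eye; defaults are calibrated on synthetic
#' scenes. Best suited to stationary/polarising cells -- whole-cell
#' translation also advances the front and is not discounted.
#'
#' @param track a \linkS4class{CellTrack}.
#' @param advanceRateMin minimum outward advance rate, um/s.
#' @param arcMin minimum arc length, um.
#' @param sustainMin minimum duration, s.
#' @return data.frame(onset_s, angle_deg, arc_um, duration_s), one row
#'   per event (zero rows when the contour is static).
#' @export
detectProtrusions <- function(track, advanceRateMin = 0.05, arcMin = 2,
                              sustainMin = 5) {
  dt <- track@frameInterval
  n <- nFrames(track)
  ps <- track@pixelSize
  lag <- min(max(1L, ceiling(2 * ps / (advanceRateMin * dt))), 15L,
             n - 1L)
  # per-frame candidate arcs: angular intervals (deg) of advancing contour
  cands <- vector("list", n)
  for (f in (lag + 1):n) {
    p <- track@contours[[f]]
    prev <- track@masks[, , f - lag]
    if (is.null(p) || !any(prev)) next
    outside <- EBImage::distmap((!prev) * 1) * ps  # dist to lagged mask
    adv <- bilinearSample(outside, p[, 1], p[, 2], ps)
    adv[is.na(adv)] <- 0
    fast <- adv / (lag * dt) >= advanceRateMin
    if (!any(fast)) next
    # contiguous runs along the (closed) contour
    m <- length(fast)
    runs <- list()
    if (all(fast)) {
      runs[[1]] <- seq_len(m)
    } else {
      brk <- which(!fast)[1]  # start the walk at a gap to respect wraparound
      cur <- integer()
      for (i in (brk:(brk + m - 1)) %% m + 1) {
        if (fast[i]) cur <- c(cur, i)
        else if (length(cur)) { runs[[length(runs) + 1]] <- cur
                                cur <- integer() }
      }
      if (length(cur)) runs[[length(runs) + 1]] <- cur
    }
    ctr <- track@centroid[f, ]
    seg <- sqrt(rowSums((p[c(2:m, 1), ] - p)^2))
    arcs <- list()
    for (rr in runs) {
      alen <- sum(seg[rr])
      if (alen < arcMin) next
      ang <- atan2(p[rr, 2] - ctr[2], p[rr, 1] - ctr[1])
      mang <- atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi
      arcs[[length(arcs) + 1]] <- c(angle = (mang + 360) %% 360,
                                    arc = alen, adv = max(adv[rr]))
    }
    if (length(arcs)) cands[[f]] <- do.call(rbind, arcs)
  }
  # link candidate arcs across frames by angular proximity
  events <- data.frame(onset_s = numeric(), angle_deg = numeric(),
                       arc_um = numeric(), duration_s = numeric())
  angDiff <- function(a, b) abs(atan2(sin((a - b) * pi / 180),
                                      cos((a - b) * pi / 180))) * 180 / pi
  finish <- function(ev) {
    dur <- (ev$lastFrame - ev$onsetFrame + 1) * dt
    if (dur < sustainMin) return(NULL)
    # back-extrapolate the onset: the first detection already carries
    # advFirst um of advance, accrued at roughly the steady event rate
    rateHat <- max(ev$advs) / (lag * dt)
    backoff <- min(ev$advs[1] / rateHat, lag * dt)
    data.frame(onset_s = max(0, (ev$onsetFrame - 1) * dt - backoff),
               angle_deg = (atan2(mean(sin(ev$angles * pi / 180)),
                                  mean(cos(ev$angles * pi / 180))) *
                 180 / pi + 360) %% 360,
               arc_um = max(ev$arcs), duration_s = dur)
  }
  open <- list()  # each: list(onsetFrame, lastFrame, angles, arcs, advs)
  for (f in seq_len(n)) {
    cc <- cands[[f]]
    used <- logical(if (is.null(cc)) 0 else nrow(cc))
    for (j in seq_along(open)) {
      if (is.null(open[[j]])) next
      if (!is.null(cc)) {
        dd <- angDiff(cc[, "angle"], mean(open[[j]]$angles))
        k <- which.min(dd)
        if (length(k) && dd[k] < 45 && !used[k]) {
          open[[j]]$lastFrame <- f
          open[[j]]$angles <- c(open[[j]]$angles, cc[k, "angle"])
          open[[j]]$arcs <- c(open[[j]]$arcs, cc[k, "arc"])
          open[[j]]$advs <- c(open[[j]]$advs, cc[k, "adv"])
          used[k] <- TRUE
          next
        }
      }
      if (f - open[[j]]$lastFrame > 1) {  # closed
        events <- rbind(events, finish(open[[j]]))
        open[[j]] <- NULL
      }
    }
    open <- Filter(Negate(is.null), open)
    if (!is.null(cc)) for (k in which(!used)) {
      open[[length(open) + 1]] <- list(
        onsetFrame = f, lastFrame = f,
        angles = cc[k, "angle"], arcs = cc[k, "arc"],
        advs = cc[k, "adv"])
    }
  }
  for (ev in open) events <- rbind(events, finish(ev))
  events[order(events$onset_s), , drop = FALSE]
}

#' Latency to the first protrusion toward a new needle direction
#'
#' Time from the needle move to the onset of the first protrusion event
#' whose arc direction (from the cell centroid) lies within
#' \code{coneHalfangle} of the new needle direction. NA (flagged
#' missing) when no such protrusion occurs.
#'
#' @param track a \linkS4class{CellTrack}.
#' @param events protrusion events from
#'   \code{\link{detectProtrusions}}.
#' @param needleMoveTime needle move time, s (within the track span).
#' @param newDirection unit vector (or any non-zero vector) toward the
#'   new needle position, image coordinates.
#' @param coneHalfangle acceptance cone half-angle, degrees.
#' @return latency in seconds, or NA with attribute missing = TRUE.
#' @export
turningLatency <- function(track, events, needleMoveTime, newDirection,
                           coneHalfangle = 45) {
  if (vecNorm(newDirection) == 0) stop("newDirection must be non-zero")
  dt <- track@frameInterval
  span <- (nFrames(track) - 1) * dt
  if (needleMoveTime >= span) {
    warning("needle moved at or after the end of the track")
    return(structure(NA_real_, missing = TRUE))
  }
  target <- atan2(newDirection[2], newDirection[1]) * 180 / pi
  after <- events[events$onset_s > needleMoveTime, , drop = FALSE]
  if (nrow(after)) {
    dd <- abs(atan2(sin((after$angle_deg - target) * pi / 180),
                    cos((after$angle_deg - target) * pi / 180))) *
      180 / pi
    hit <- which(dd <= coneHalfangle)
    if (length(hit))
      return(after$onset_s[hit[1]] - needleMoveTime)
  }
  structure(NA_real_, missing = TRUE)
}

#' Origin-anchored movement plot
#'
#' @param track a \linkS4class{CellTrack} with >= 2 frames.
#' @return list(path = data.frame(time_s, x_um, y_um) translated so the
#'   first centroid is the origin, netDisplacement_um, pathLength_um).
#' @export
movementPlot <- function(track) {
  ctr <- track@centroid
  n <- nrow(ctr)
  if (n < 2) stop("need at least 2 frames")
  rel <- sweep(ctr, 2, ctr[1, ])
  steps <- sqrt(rowSums((rel[-1, , drop = FALSE] -
                         rel[-n, , drop = FALSE])^2))
  list(path = data.frame(time_s = (seq_len(n) - 1) * track@frameInterval,
                         x_um = rel[, 1], y_um = rel[, 2]),
       netDisplacement_um = vecNorm(rel[n, ]),
       pathLength_um = sum(steps))
}
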