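# End-to-end runs: a flat, serializable run configuration carrying every
# assay threshold, a pipeline driver (register -> ratio -> segment ->
# track -> analyses) with a plain-text run log, and per-group
# descriptive summaries (mean, SD, SEM, n).

#' Default run configuration
#'
#' Flat named list of every stage parameter, with defaults equal to the
#' assay's stated values: 2 px smoothing radius, 40 um^2 adhesion
#' exclusion, 125 s AUC window, 20 s / 2 um phase criteria, 7.8 um
#' half-body migration threshold over 120 s, 600 s diameter-criterion
#' observation, 0.8 um pole zones, 0.4 um edge band, 20 axial bins,
#' 2 um particles.
#'
#' @param ... overrides of individual keys.
#' @return named list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    pixel_size_um = 0.27,
    frame_interval_s = 1,
    smooth_radius_px = 2L,
    donor_floor = -1,           # -1: derive from acquisition metadata
    min_area_um2 = 40,
    auc_window_s = 125,
    phase_min_duration_s = 20,
    phase_displacement_um = 2,
    migrating_half_body_um = 7.8,
    migrating_observation_s = 120,
    diameter_observation_s = 600,
    pole_zone_um = 0.8,
    edge_band_um = 0.4,
    axis_bins = 20L,
    particle_diameter_um = 2,
    annulus_width_um = 0.5,
    velocity_window_s = 20,
    seed = 1L,
    out_dir = "fretpolarity-run")
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  cfg
}

#' Write / read a run configuration (flat YAML)
#'
#' The round trip serialize -> parse -> serialize is byte-identical.
#'
#' @param config named list (see \code{\link{defaultRunConfig}}).
#' @param path file path.
#' @return \code{writeRunConfig}: the path invisibly;
#'   \code{readRunConfig}: the config list.
#' @export
writeRunConfig <- function(config, path) {
  config <- config[order(names(config))]
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}

logLine <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

#' Run the analysis pipeline on a movie
#'
#' Executes register -> smooth -> ratio -> segment -> track and the
#' selected analyses, writing per-cell CSVs (with unit headers),
#' rendered PNG figures and a run log containing the fully resolved
#' configuration. When the acquisition declares a non-identity channel
#' misalignment but no bead calibration movie is supplied, identity
#' registration is used with a warning.
#'
#' @param movie a \linkS4class{TwoChannelMovie}.
#' @param config named list from \code{\link{defaultRunConfig}}.
#' @param beads optional bead-pair \linkS4class{TwoChannelMovie} for
#'   registration.
#' @param analyses character subset of c("morphometry", "polarity",
#'   "motility").
#' @param brightfield optional brightfield stack (enables
#'   "phagocytosis").
#' @param writeOutputs logical; write CSVs/figures/log under
#'   \code{config$out_dir}.
#' @return list of results: ratio movie, track, per-analysis tables and
#'   summary rows.
#' @export
runPipeline <- function(movie, config = defaultRunConfig(),
                        beads = NULL,
                        analyses = c("morphometry", "polarity",
                                     "motility"),
                        brightfield = NULL, writeOutputs = TRUE) {
  outDir <- config$out_dir
  log <- NULL
  if (writeOutputs) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    log <- file(file.path(outDir, "run.log"), "w")
    on.exit(close(log))
    logLine(log, "pipeline start, seed=", config$seed)
    for (k in sort(names(config)))
      logLine(log, "config ", k, " = ", paste(config[[k]], collapse = ","))
  }
  step <- function(name, expr) {
    if (!is.null(log)) logLine(log, "stage ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  model <- step("register", {
    if (!is.null(beads)) {
      estimateRegistration(beads)
    } else {
      if (max(abs(movie@acq@misalignment - identityAffine())) > 0)
        warning("misalignment declared but no bead calibration; ",
                "using identity registration")
      new("RegistrationModel", coef = identityAffine(), residual = 0,
          nLandmarks = 0L)
    }
  })
  aligned <- step("align", {
    if (max(abs(model@coef - identityAffine())) > 0)
      applyRegistration(movie, model)
    else movie
  })
  sm <- step("smooth", smoothMovie(aligned, config$smooth_radius_px))
  ratio <- step("ratio", computeRatio(
    sm, if (config$donor_floor >= 0) config$donor_floor else NULL))
  track <- step("track", {
    d <- dim(sm@donor)
    masks <- array(FALSE, d)
    for (f in seq_len(d[3])) {
      cm <- segmentFrame(sm@donor[, , f], pixelSize(movie))
      if (length(cm)) {
        areas <- vapply(cm, function(m) m@area, 0)
        masks[, , f] <- cm[[which.max(areas)]]@mask
      }
    }
    buildTrack(masks, pixelSize(movie), frameInterval(movie))
  })

  res <- list(config = config, registration = model, ratio = ratio,
              track = track, summary = list())

  if ("morphometry" %in% analyses) {
    res$morphometry <- step("morphometry", {
      n <- nFrames(ratio)
      per <- data.frame(
        frame = seq_len(n),
        time_s = (seq_len(n) - 1) * frameInterval(movie),
        area_um2 = vapply(seq_len(n), function(f)
          sum(track@masks[, , f]) * pixelSize(movie)^2, 0))
      fret <- wholeCellMeanFret(ratio, track)
      per$mean_fret <- fret$value
      w <- c(0, min(config$auc_window_s,
                    max(fret$time_s)))
      list(perFrame = per,
           aucMeanFret = aucWindow(fret, w),
           aucArea = aucWindow(data.frame(time_s = per$time_s,
                                          value = per$area_um2), w),
           window = w)
    })
    res$summary$auc_mean_fret <- res$morphometry$aucMeanFret
  }
  if ("polarity" %in% analyses) {
    res$polarity <- step("polarity", {
      profs <- axisProfileSeries(ratio, track, config$axis_bins)
      pk <- peakTrace(profs, config$pole_zone_um)
      fb <- frontBackSummary(profs)
      list(profiles = profs, kymograph = kymograph(profs),
           peakTrace = pk, frontBack = fb)
    })
    pk <- res$polarity$peakTrace
    res$summary$n_switches <- length(switchTimes(pk))
    res$summary$mean_wave_s <-
      if (length(waveDurations(pk))) mean(waveDurations(pk)) else NA
    res$summary$dwell_front_s <- pk@dwellFront
    res$summary$dwell_rear_s <- pk@dwellRear
  }
  if ("motility" %in% analyses) {
    res$motility <- step("motility", {
      mv <- movementPlot(track)
      vel <- tryCatch(frontPixelVelocity(track,
                                         config$velocity_window_s),
                      error = function(e) NULL)
      ph <- tryCatch(classifyPhases(track,
                                    config$phase_min_duration_s,
                                    config$phase_displacement_um),
                     error = function(e) NULL)
      mig <- tryCatch(classifyMigrating(
        track, "half-body", config$migrating_half_body_um,
        config$migrating_observation_s), error = function(e) NA)
      list(movement = mv, velocity = vel, phases = ph,
           migrating = mig)
    })
    res$summary$net_displacement_um <-
      res$motility$movement$netDisplacement_um
    if (!is.null(res$motility$velocity))
      res$summary$mean_velocity_um_s <- res$motility$velocity$mean
  }
  if ("phagocytosis" %in% analyses && !is.null(brightfield)) {
    res$phagocytosis <- step("phagocytosis", {
      pts <- detectParticles(brightfield, pixelSize(movie),
                             frameInterval(movie),
                             config$particle_diameter_um)
      traces <- lapply(pts, function(pt)
        phagosomeTrace(ratio, track, pt,
                       config$particle_diameter_um,
                       config$annulus_width_um))
      list(particles = pts, traces = traces)
    })
  }

  if (writeOutputs) {
    step("write", {
      if (!is.null(res$morphometry))
        writeCSVWithUnits(res$morphometry$perFrame,
                          file.path(outDir, "morphometry.csv"),
                          "time [s], area [um^2], mean_fret [ratio]")
      if (!is.null(res$polarity)) {
        write.csv(res$polarity$kymograph,
                  file.path(outDir, "kymograph.csv"),
                  row.names = FALSE)
        writeCSVWithUnits(res$polarity$peakTrace@table,
                          file.path(outDir, "peak_trace.csv"),
                          "time [s], peak position [um], zone [label]")
        pngSafe(file.path(outDir, "kymograph.png"), function()
          plotKymograph(res$polarity$kymograph,
                        frameInterval(movie)))
      }
      if (!is.null(res$motility)) {
        writeCSVWithUnits(res$motility$movement$path,
                          file.path(outDir, "path.csv"),
                          "time [s], x [um], y [um]")
        if (!is.null(res$motility$phases))
          writeCSVWithUnits(res$motility$phases,
                            file.path(outDir, "phases.csv"),
                            "start/end [s], displacement [um]")
      }
      sumdf <- data.frame(metric = names(res$summary),
                          value = unlist(res$summary))
      writeCSVWithUnits(sumdf, file.path(outDir, "summary.csv"),
                        "metric-specific (s, um, counts)")
      logLine(log, "pipeline done")
    })
  }
  res
}

pngSafe <- function(path, fn) {
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  fn()
}

#' Plot a kymograph matrix
#'
#' @param km frames x bins matrix.
#' @param frameInterval seconds per frame.
#' @return invisibly, NULL.
#' @export
plotKymograph <- function(km, frameInterval = 1) {
  graphics::image(
    x = (seq_len(nrow(km)) - 1) * frameInterval,
    y = seq_len(ncol(km)), z = km,
    col = grDevices::rgb(sixteenColorLUT()),
    xlab = "time (s)", ylab = "axial bin (1 = leading edge)",
    main = "activity kymograph", useRaster = TRUE)
  invisible(NULL)
}

#' Plot a polar (eccentric-circle) map
#'
#' First frame at the centre, last frame at the plot edge, the
#' reference direction (needle) at the configured compass point.
#'
#' @param map a \linkS4class{PolarMap}.
#' @return invisibly, NULL.
#' @export
plotPolarMap <- function(map) {
  v <- map@values
  nf <- nrow(v); nb <- ncol(v)
  rng <- range(v, na.rm = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  lut <- sixteenColorLUT()
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "edge-band activity (first frame centre)")
  th <- map@anglesDeg * pi / 180
  for (f in seq_len(nf)) {
    r0 <- (f - 1) / nf; r1 <- f / nf
    lev <- pmin(16L, pmax(1L, 1L + floor(
      (v[f, ] - rng[1]) / diff(rng) * 16)))
    for (b in seq_len(nb)) {
      if (is.na(v[f, b])) next
      a0 <- th[b] - pi / nb; a1 <- th[b] + pi / nb
      aa <- seq(a0, a1, length.out = 5)
      graphics::polygon(c(r0 * cos(aa), r1 * cos(rev(aa))),
                        -c(r0 * sin(aa), r1 * sin(rev(aa))),
                        col = grDevices::rgb(lut[lev[b], 1],
                                             lut[lev[b], 2],
                                             lut[lev[b], 3]),
                        border = NA)
    }
  }
  invisible(NULL)
}

#' Per-group descriptive summaries (mean, SD, SEM, n)
#'
#' Summarizes per-cell metric tables by group, optionally nested by
#' experiment (mean of experiment means). Groups with a single value
#' report SEM as NA; empty groups are omitted with a warning.
#'
#' @param data data.frame of per-cell rows.
#' @param metrics character vector of metric column names.
#' @param group name of the grouping column.
#' @param experiment optional name of the experiment column for nested
#'   summaries.
#' @return data.frame(group, metric, mean, sd, sem, n).
#' @export
summarizeGroups <- function(data, metrics, group,
                            experiment = NULL) {
  out <- list()
  for (g in unique(data[[group]])) {
    sub <- data[data[[group]] == g, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      if (!is.null(experiment)) {
        v <- tapply(v, sub[[experiment]], mean, na.rm = TRUE)
        v <- as.vector(v)
      }
      v <- v[!is.na(v)]
      if (!length(v)) {
        warning(sprintf("empty group '%s' for metric '%s'; omitted",
                        g, m))
        next
      }
      out[[length(out) + 1]] <- data.frame(
        group = g, metric = m, mean = mean(v),
        sd = if (length(v) > 1) sd(v) else NA_real_,
        sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
        n = length(v))
    }
  }
  do.call(rbind, out)
}
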