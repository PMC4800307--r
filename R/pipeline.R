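# End-to-end orchestration: phantom/stack -> (optics) -> restoration ->
# cell segmentation -> contours -> linking -> classification -> marker
# stats -> inventory, as reproducible, configured, logged runs.

#' Pipeline run configuration
#'
#' All tunables of the negative-contrast pipeline with their defaults.
#' Unknown names are an error, so typos do not silently fall back.
#'
#' @param ... name = value overrides of: \code{contourFraction} (0.925,
#'   must lie in [0.90, 0.95]), \code{psfLateralFWHM} (0.25 um),
#'   \code{psfAxialFWHM} (0.6 um), \code{deconvolve} (TRUE),
#'   \code{rlIterations} (30), \code{linkOverlap} (0.5),
#'   \code{minContrast} (0.6), \code{minDiameter} (0.3 um),
#'   \code{binarizeContours} (TRUE: ImageJ-style black-and-white
#'   conversion before contour tracing; see \code{\link{extractContours}}),
#'   \code{sgDiameterRange} (c(0.3, 1.5) um), \code{tubeDiameter} (0.4 um),
#'   \code{tubeElongation} (2), \code{excludeTruncated} (TRUE: truncated
#'   objects are flagged and left out of size statistics),
#'   \code{markerChannel} ("marker"), \code{gfpChannel} (1),
#'   \code{voxelSizeOverride} (NULL), \code{simulateOptics} (TRUE for
#'   phantom scenes), \code{seed} (1).
#' @return list of class "nciConfig".
#' @export
nciConfig <- function(...) {
  cfg <- list(contourFraction = 0.925, psfLateralFWHM = 0.25,
              psfAxialFWHM = 0.6, deconvolve = TRUE, rlIterations = 30L,
              linkOverlap = 0.5, minContrast = 0.6, minDiameter = 0.3,
              binarizeContours = TRUE,
              sgDiameterRange = c(0.3, 1.5), tubeDiameter = 0.4,
              tubeElongation = 2, excludeTruncated = TRUE,
              markerChannel = "marker", gfpChannel = 1L,
              voxelSizeOverride = NULL, simulateOptics = TRUE, seed = 1L)
  ov <- list(...)
  if (length(ov) == 1L && is.list(ov[[1]]) && is.null(names(ov)))
    ov <- ov[[1]]
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  if (cfg$contourFraction < 0.90 || cfg$contourFraction > 0.95)
    stop("contour fraction must lie in [0.90, 0.95]")
  class(cfg) <- "nciConfig"
  cfg
}

#' Run the full negative-contrast pipeline on one stack
#'
#' Stages: optional acquisition simulation (for phantom scenes), optional
#' Richardson-Lucy restoration of the GFP channel, cell-body/nucleus
#' segmentation, cytoplasm-level estimation, per-slice seed detection and
#' contour extraction, contour linking, compartment classification, and
#' marker colocalization when a marker channel carries signal. Outputs are
#' deterministic given (input, config, seed); every stage is logged with
#' counts and every discarded contour leaves a reason line.
#'
#' @param x a \linkS4class{VoxelStack}, a phantom scene list (as returned
#'   by \code{\link{makeBeadPhantom}} / \code{\link{makeCellPhantom}}), or
#'   a TIFF path.
#' @param config an \code{\link{nciConfig}}.
#' @return a \linkS4class{CellReconstruction}.
#' @export
runPipeline <- function(x, config = nciConfig()) {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  scene <- NULL
  if (is.character(x)) {
    x <- readStack(x, voxelSize = config$voxelSizeOverride)
    say("io: read stack (%s)", paste(dim(getChannel(x, 1)), collapse = "x"))
  }
  if (is.list(x) && !is.null(x$stack)) {
    scene <- x
    x <- scene$stack
    if (isTRUE(config$simulateOptics)) {
      psf <- gaussianPSF(config$psfLateralFWHM, config$psfAxialFWHM)
      x <- applyOptics(x, psf, scene$spec, occupancy = scene$occupancy)
      say("optics: PSF FWHM %.3g/%.3g um, seed %d", config$psfLateralFWHM,
          config$psfAxialFWHM, scene$spec$seed)
    }
  }
  vs <- voxelSize(x)
  if (config$deconvolve) {
    psf <- gaussianPSF(config$psfLateralFWHM, config$psfAxialFWHM)
    for (ch in seq_len(nChannels(x))) {
      if (max(getChannel(x, ch)) <= 0) next  # empty channel
      x <- deconvolveRL(x, psf, iterations = config$rlIterations,
                        channel = ch)
      say("restoration: Richardson-Lucy, %d iterations (channel %s)",
          config$rlIterations, channelNames(x)[ch])
    }
  } else say("restoration: skipped (--no-deconv)")
  cellMask <- segmentCellBody(x, channel = config$gfpChannel)
  say("segment: cell volume %.1f um^3 (%d component(s), largest kept)",
      cellVolume(cellMask), attr(cellMask, "nComponents"))
  cyt <- estimateCytoplasmLevel(x, cellMask, channel = config$gfpChannel)
  say("cytoplasm level: median %.1f (robust sd %.1f)", cyt$median, cyt$sd)
  gfp <- getChannel(x, config$gfpChannel)
  d <- dim(gfp)
  # seeds are confined to the eroded cell interior: the blurred rim and
  # top/bottom cap slices of the cell are not organelle territory
  interior <- erodeMask3d(cellMask@mask, vs, margin = 0.4)
  # 3D negatively stained regions: each void's 0% reference is the darkest
  # core of its 3D dark component, shared by all its slices (incl. caps)
  smArr <- array(0, d)
  for (z in seq_len(d[1]))
    smArr[z, , ] <- EBImage::gblur(sliceMatrix(gfp, z), sigma = 0.75)
  dark3 <- smArr < config$minContrast * cyt$median & cellMask@mask
  lab3 <- label3d(dark3)
  compMin <- if (any(dark3))
    tapply(smArr[dark3], lab3[dark3], min) else numeric(0)
  contoursBySlice <- vector("list", d[1])
  nSeeds <- 0L
  for (z in seq_len(d[1])) {
    sl <- sliceMatrix(gfp, z)
    cms <- matrix(cellMask@mask[z, , ], d[2], d[3])
    ims <- matrix(interior[z, , ], d[2], d[3])
    seeds <- detectVoidSeeds(sl, ims, cyt$median, vs,
                             minContrast = config$minContrast)
    nSeeds <- nSeeds + nrow(seeds)
    refs <- NULL
    if (nrow(seeds)) {
      labSlice <- matrix(lab3[z, , ], d[2], d[3])
      comp <- labSlice[cbind(seeds[, 1], seeds[, 2])]
      refs <- ifelse(comp > 0L, compMin[as.character(comp)], NA_real_)
    }
    cts <- suppressWarnings(
      extractContours(sl, z, seeds, cms, cyt$median, vs,
                      fraction = config$contourFraction,
                      minContrast = config$minContrast,
                      minDiameter = config$minDiameter,
                      binarize = config$binarizeContours,
                      centerRefs = refs))  # discards are in the log
    log <- c(log, attr(cts, "log"))
    contoursBySlice[[z]] <- cts
  }
  nCts <- sum(vapply(contoursBySlice, length, integer(1)))
  say("contours: %d seeds -> %d contours kept", nSeeds, nCts)
  orgs <- linkContours(contoursBySlice, vs["dz"],
                       overlapThreshold = config$linkOverlap, nz = d[1])
  say("link: %d organelle(s)", length(orgs))
  for (i in seq_along(orgs)) {
    orgs[[i]]@label <- classifyCompartment(
      orgs[[i]], cellMask, sgDiameterRange = config$sgDiameterRange,
      tubeDiameter = config$tubeDiameter,
      tubeElongation = config$tubeElongation)
  }
  hasMarker <- (is.character(config$markerChannel) &&
                config$markerChannel %in% channelNames(x))
  if (hasMarker && max(getChannel(x, config$markerChannel)) > 0) {
    mc <- markerColocalization(orgs, x, config$markerChannel, cellMask)
    orgs <- mc$organelles
    say("marker: positive fraction %.3f (bg %.1f +/- %.1f)",
        mc$positiveFraction, mc$background$mean, mc$background$sd)
  }
  tab <- objectTable(orgs)
  counts <- table(factor(tab$class, levels = c("SG", "mitochondrion-like",
                                               "nuclear", "unclassified")))
  say("classify: %s", paste(names(counts), as.integer(counts),
                            sep = "=", collapse = ", "))
  say("truncated objects: %d (excludeTruncated=%s)", sum(tab$truncated),
      config$excludeTruncated)
  new("CellReconstruction", cellMask = cellMask, organelles = orgs,
      table = tab, log = log, config = unclass(config))
}

#' Bead diameter-recovery benchmark
#'
#' For each bead size, simulates a field of n isolated, fully excluding
#' beads, runs the full pipeline (optics, deconvolution, contour rule,
#' linking), matches recovered organelles to the planted beads by nearest
#' centroid, and reports per-size recovered-diameter statistics as a
#' percentage of the true diameter. Sizes outside the validated 0.5-1.0 um
#' window can be included to quantify the degradation; undetected beads
#' enter the mean absolute error as 100% error.
#'
#' @param sizes bead diameters in um (default c(0.5, 0.75, 1.0)).
#' @param n beads per size (>= 3, default 12).
#' @param seed integer seed; each size uses seed + its index.
#' @param config an \code{\link{nciConfig}}.
#' @param voxelSize acquisition grid (default 0.1-um z, 40-nm pixels).
#' @return data.frame: diameter, n, nDetected, meanRecoveryPct,
#'   sdRecoveryPct, meanAbsErrorPct.
#' @export
runBenchmark <- function(sizes = c(0.5, 0.75, 1.0), n = 12L, seed = 1L,
                         config = nciConfig(),
                         voxelSize = c(0.1, 0.04, 0.04)) {
  if (n < 3L) stop("need n >= 3 beads per size")
  rows <- lapply(seq_along(sizes), function(k) {
    dtrue <- sizes[k]
    spec <- beadFieldSpec(n, dtrue, voxelSize = voxelSize,
                          seed = seed + k)
    scene <- makeBeadPhantom(spec)
    rec <- runPipeline(scene, config)
    tab <- rec@table
    tab <- tab[tab$class != "nuclear", , drop = FALSE]
    recov <- rep(NA_real_, n)
    if (nrow(tab)) {
      for (i in seq_len(n)) {
        tr <- scene$truth[i, ]
        dd <- sqrt((tab$centroidX - tr$cx)^2 + (tab$centroidY - tr$cy)^2 +
                   (tab$centroidZ - tr$cz)^2)
        j <- which.min(dd)
        if (dd[j] <= 0.75 * dtrue + 0.3)
          recov[i] <- 100 * tab$equivDiameter[j] / dtrue
      }
    }
    det <- !is.na(recov)
    absErr <- ifelse(det, abs(recov - 100), 100)
    data.frame(diameter = dtrue, n = n, nDetected = sum(det),
               meanRecoveryPct = if (any(det)) mean(recov[det]) else NA_real_,
               sdRecoveryPct = if (sum(det) > 1) stats::sd(recov[det])
                               else NA_real_,
               meanAbsErrorPct = mean(absErr))
  })
  do.call(rbind, rows)
}
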