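# Population statistics, marker colocalization, tracking and fusion
# detection.

organellePixelArea <- function(organelles) {
  for (o in organelles) for (ct in o@contours)
    if (!is.null(ct$pixelArea)) return(sqrt(ct$pixelArea) * 1)
  NA_real_
}

# erode a per-slice pixel index set (linear indices into an ny x nx slice)
erodePixelSet <- function(pix, ny, nx, erPx) {
  ys <- ((pix - 1L) %% ny) + 1L
  xs <- ((pix - 1L) %/% ny) + 1L
  y0 <- max(1L, min(ys) - 1L); x0 <- max(1L, min(xs) - 1L)
  m <- matrix(0, max(ys) - y0 + 2L, max(xs) - x0 + 2L)
  m[cbind(ys - y0 + 1L, xs - x0 + 1L)] <- 1
  brush <- EBImage::makeBrush(2L * erPx + 1L, shape = "disc")
  er <- EBImage::erode(m, brush) > 0
  idx <- which(er, arr.ind = TRUE)
  if (!nrow(idx)) return(integer(0))
  (idx[, 2] + x0 - 2L) * ny + (idx[, 1] + y0 - 1L)
}

#' Histogram of granule sizes with cell-size stratification
#'
#' Histogram of lamination volumes of SG-class objects. When per-object
#' cell volumes are supplied, the distribution is additionally stratified
#' into small (< \code{smallCutoff}) and large (> \code{largeCutoff})
#' cells, the conventional 1,500 / 2,500 um^3 cutoffs.
#'
#' @param objects an \code{\link{objectTable}} data.frame (or a numeric
#'   vector of volumes).
#' @param breaks histogram bin edges in um^3, or a bin count.
#' @param cellVolumes optional per-object cell volume (um^3) for
#'   stratification.
#' @param smallCutoff,largeCutoff stratification cutoffs in um^3.
#' @return list(breaks, counts, n, median, iqr[, strata]) of class
#'   "SizeDistribution"; counts always sum to n.
#' @export
sizeDistribution <- function(objects, breaks = 20,
                             cellVolumes = NULL,
                             smallCutoff = 1500, largeCutoff = 2500) {
  vols <- if (is.data.frame(objects)) {
    sel <- objects$class == "SG"
    objects$volumeLamination[sel]
  } else as.numeric(objects)
  if (!length(vols)) stop("no SG-class objects")
  h <- graphics::hist(vols, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  out <- list(breaks = h$breaks, counts = h$counts, n = length(vols),
              median = stats::median(vols),
              iqr = stats::quantile(vols, c(0.25, 0.75), names = FALSE))
  if (!is.null(cellVolumes)) {
    cv <- if (is.data.frame(objects)) cellVolumes[objects$class == "SG"]
          else cellVolumes
    out$strata <- list(
      small = vols[cv < smallCutoff],
      large = vols[cv > largeCutoff])
  }
  class(out) <- "SizeDistribution"
  out
}

#' @export
print.SizeDistribution <- function(x, ...) {
  cat("SizeDistribution: n =", x$n, ", median =", signif(x$median, 3),
      "um^3, IQR = [", signif(x$iqr[1], 3), ",", signif(x$iqr[2], 3), "]\n")
  invisible(x)
}

#' Correlation between cell volume and granule count
#'
#' Pearson correlation (with Spearman alongside) of (cell volume, SG
#' count) pairs across cells, a least-squares slope/intercept, and a
#' seeded bootstrap 95% CI (percentile, 1,000 resamples) for both r and
#' the slope.
#'
#' @param cellVolumes numeric vector of cell volumes (um^3), or a list of
#'   \linkS4class{CellReconstruction} objects.
#' @param sgCounts SG counts per cell (ignored when reconstructions are
#'   given).
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return list(r, spearman, slope, intercept, n, ciR, ciSlope).
#' @export
cellSgCorrelation <- function(cellVolumes, sgCounts = NULL, nBoot = 1000L,
                              seed = 1L) {
  if (is.list(cellVolumes) && !is.numeric(cellVolumes)) {
    recs <- cellVolumes
    cellVolumes <- vapply(recs, cellVolume, numeric(1))
    sgCounts <- vapply(recs, function(r) sum(r@table$class == "SG"),
                       numeric(1))
  }
  n <- length(cellVolumes)
  if (n < 3L) stop("need at least 3 cells")
  r <- stats::cor(cellVolumes, sgCounts)
  rho <- stats::cor(cellVolumes, sgCounts, method = "spearman")
  fit <- stats::lm(sgCounts ~ cellVolumes)
  bootStats <- withSeed(seed, {
    t(vapply(seq_len(nBoot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::sd(cellVolumes[i]) == 0 || stats::sd(sgCounts[i]) == 0)
        return(c(NA_real_, NA_real_))
      c(stats::cor(cellVolumes[i], sgCounts[i]),
        stats::coef(stats::lm(sgCounts[i] ~ cellVolumes[i]))[2])
    }, numeric(2)))
  })
  list(r = r, spearman = rho,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = n,
       ciR = stats::quantile(bootStats[, 1], c(0.025, 0.975), na.rm = TRUE,
                             names = FALSE),
       ciSlope = stats::quantile(bootStats[, 2], c(0.025, 0.975),
                                 na.rm = TRUE, names = FALSE))
}

#' Marker colocalization of segmented voids
#'
#' An object is marker-positive iff its mean interior marker intensity
#' exceeds the background mean by more than 3 background SDs. The
#' background is estimated over the cell mask excluding all object
#' interiors (or can be supplied). Interior means are taken over a core
#' eroded by \code{coreErosion} um from each contour, reducing
#' partial-volume dilution at the void boundary; the full interior is
#' used when the eroded core is empty.
#'
#' @param organelles list of \linkS4class{Organelle3D}.
#' @param stack a \linkS4class{VoxelStack} with a marker channel.
#' @param markerChannel channel name or index of the marker.
#' @param cellMask optional \linkS4class{CellMask} restricting the
#'   background region.
#' @param background optional list(mean, sd) override.
#' @param classes object classes entering the positive fraction
#'   (default "SG").
#' @param coreErosion lateral erosion of the interior before averaging,
#'   in um (default 0.15).
#' @return list(organelles = annotated list, positiveFraction, background,
#'   table = per-object data.frame).
#' @export
markerColocalization <- function(organelles, stack, markerChannel = "marker",
                                 cellMask = NULL, background = NULL,
                                 classes = "SG", coreErosion = 0.15) {
  if (is.character(markerChannel) &&
      !markerChannel %in% channelNames(stack))
    stop("missing marker channel '", markerChannel, "'")
  mk <- getChannel(stack, markerChannel)
  d <- dim(mk)
  if (is.null(background)) {
    bgMask <- if (is.null(cellMask)) array(TRUE, d) else cellMask@mask
    for (o in organelles) for (ct in o@contours) {
      if (ct$npix) bgMask[(ct$z - 1L) + (ct$pixels - 1L) * d[1] + 1L] <- FALSE
    }
    # linear index in (z,y,x): z + (pix-1)*nz where pix indexes (y,x)
    v <- mk[bgMask]
    background <- list(mean = mean(v), sd = stats::sd(v))
  }
  thr <- background$mean + 3 * background$sd
  vsLat <- sqrt(organellePixelArea(organelles))
  erPx <- if (is.finite(vsLat) && vsLat > 0)
    max(0L, round(coreErosion / vsLat)) else 0L
  means <- vapply(organelles, function(o) {
    vals <- unlist(lapply(o@contours, function(ct) {
      if (!ct$npix) return(numeric(0))
      pix <- ct$pixels
      if (erPx > 0L && ct$npix > 8L) {
        core <- erodePixelSet(pix, d[2], d[3], erPx)
        if (length(core)) pix <- core
      }
      mk[(ct$z - 1L) + (pix - 1L) * d[1] + 1L]
    }))
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1))
  ann <- organelles
  for (i in seq_along(ann)) {
    ann[[i]]@markerMean <- means[i]
    ann[[i]]@markerPositive <- isTRUE(means[i] > thr)
  }
  labels <- vapply(ann, function(o) o@label, character(1))
  sel <- labels %in% classes
  frac <- if (any(sel))
    mean(vapply(ann[sel], function(o) o@markerPositive, logical(1)))
  else NA_real_
  list(organelles = ann, positiveFraction = frac, background = background,
       table = data.frame(
         id = vapply(ann, function(o) o@id, integer(1)),
         markerMean = means,
         markerPositive = vapply(ann, function(o) o@markerPositive,
                                 logical(1))))
}

#' Track organelles across time-lapse frames
#'
#' Greedy nearest-centroid matching between consecutive frames with a gate
#' radius; unmatched objects open or close tracks.
#'
#' @param frameTables list of \code{\link{objectTable}} data.frames, one
#'   per frame in time order (>= 2 frames, same calibration).
#' @param gate maximum centroid displacement per frame in um (default 1.0).
#' @return data.frame with columns track, frame, id, centroidX/Y/Z,
#'   volume, equivDiameter, markerMean.
#' @export
trackObjects <- function(frameTables, gate = 1.0) {
  if (length(frameTables) < 2L) stop("need at least 2 frames")
  nF <- length(frameTables)
  rows <- list()
  nextTrack <- 0L
  prevTracks <- NULL
  for (f in seq_len(nF)) {
    tab <- frameTables[[f]]
    assigned <- rep(NA_integer_, nrow(tab))
    if (f > 1L && nrow(tab) && !is.null(prevTracks) && nrow(prevTracks)) {
      cand <- NULL
      for (i in seq_len(nrow(prevTracks))) for (j in seq_len(nrow(tab))) {
        dd <- sqrt((prevTracks$centroidX[i] - tab$centroidX[j])^2 +
                   (prevTracks$centroidY[i] - tab$centroidY[j])^2 +
                   (prevTracks$centroidZ[i] - tab$centroidZ[j])^2)
        if (dd <= gate) cand <- rbind(cand, c(i, j, dd))
      }
      if (!is.null(cand)) {
        cand <- cand[order(cand[, 3]), , drop = FALSE]
        usedP <- usedC <- integer(0)
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (i %in% usedP || j %in% usedC) next
          usedP <- c(usedP, i); usedC <- c(usedC, j)
          assigned[j] <- prevTracks$track[i]
        }
      }
    }
    for (j in seq_len(nrow(tab))) {
      if (is.na(assigned[j])) {
        nextTrack <- nextTrack + 1L
        assigned[j] <- nextTrack
      }
    }
    if (nrow(tab)) {
      rows[[f]] <- data.frame(track = assigned, frame = f, id = tab$id,
                              centroidX = tab$centroidX,
                              centroidY = tab$centroidY,
                              centroidZ = tab$centroidZ,
                              volume = tab$volumeLamination,
                              equivDiameter = tab$equivDiameter,
                              markerMean = tab$markerMean,
                              markerPositive = if ("markerPositive" %in%
                                                   names(tab))
                                tab$markerPositive else tab$markerMean > 0)
      prevTracks <- rows[[f]]
    } else prevTracks <- NULL
  }
  do.call(rbind, rows)
}

#' Detect granule-granule fusion events from tracks
#'
#' An event is declared when two tracks coexist at frame t, at least one
#' terminates there, and at frame t+1 a track (new, or the continuation of
#' one parent) lies within the union of the parents' extents with a volume
#' conservation ratio V_child / (V_p1 + V_p2) inside
#' \code{conservationWindow}. When exactly one parent carries marker, the
#' marker dilution ratio (child per-volume marker / marked-parent
#' per-volume marker) is reported; the approach axis is the unit vector
#' between the parent centroids at frame t.
#'
#' @param tracks data.frame from \code{\link{trackObjects}}.
#' @param conservationWindow acceptable volume conservation ratio range
#'   (default c(0.6, 1.4)).
#' @param markerPositiveLevel optional marker mean above which a parent
#'   counts as marked; by default the tracks' \code{markerPositive} flag
#'   (3 sigma above background, see
#'   \code{\link{markerColocalization}}) decides.
#' @return data.frame, one row per event: frame, parent track ids, child
#'   track id, conservationRatio, dilutionRatio, axis components and the
#'   angle to the z axis in degrees.
#' @export
detectFusionEvents <- function(tracks, conservationWindow = c(0.6, 1.4),
                               markerPositiveLevel = NULL) {
  ev <- list()
  frames <- sort(unique(tracks$frame))
  for (t in frames[-length(frames)]) {
    cur <- tracks[tracks$frame == t, ]
    nxt <- tracks[tracks$frame == t + 1L, ]
    if (nrow(cur) < 2L || !nrow(nxt)) next
    ended <- cur$track[!cur$track %in% nxt$track]
    if (!length(ended)) next
    for (p1 in ended) {
      others <- cur$track[cur$track != p1]
      for (p2 in others) {
        if (p2 %in% ended && p2 < p1) next  # each unordered pair once
        r1 <- cur[cur$track == p1, ]; r2 <- cur[cur$track == p2, ]
        vSum <- r1$volume + r2$volume
        # child candidates at t+1 within the union of parent extents
        reach1 <- r1$equivDiameter / 2 + 0.35
        reach2 <- r2$equivDiameter / 2 + 0.35
        for (j in seq_len(nrow(nxt))) {
          ch <- nxt[j, ]
          if (ch$track %in% c(p1, p2) && ch$track %in% ended) next
          d1 <- sqrt((ch$centroidX - r1$centroidX)^2 +
                     (ch$centroidY - r1$centroidY)^2 +
                     (ch$centroidZ - r1$centroidZ)^2)
          d2 <- sqrt((ch$centroidX - r2$centroidX)^2 +
                     (ch$centroidY - r2$centroidY)^2 +
                     (ch$centroidZ - r2$centroidZ)^2)
          if (d1 > reach1 + reach2 && d2 > reach1 + reach2) next
          cons <- ch$volume / vSum
          if (cons < conservationWindow[1] || cons > conservationWindow[2])
            next
          # if the "child" is one parent's continuation, the other must
          # have ended (it did: p1 ended; or both)
          axis <- c(r2$centroidZ - r1$centroidZ,
                    r2$centroidY - r1$centroidY,
                    r2$centroidX - r1$centroidX)
          nrm <- sqrt(sum(axis^2))
          axis <- if (nrm > 0) axis / nrm else c(NA, NA, NA)
          m1 <- r1$markerMean; m2 <- r2$markerMean
          marked <- if (!is.null(markerPositiveLevel))
            c(isTRUE(m1 > markerPositiveLevel),
              isTRUE(m2 > markerPositiveLevel))
          else c(isTRUE(r1$markerPositive), isTRUE(r2$markerPositive))
          dil <- if (sum(marked) == 1L)
            ch$markerMean / c(m1, m2)[marked] else NA_real_
          ev[[length(ev) + 1L]] <- data.frame(
            frame = t, parent1 = p1, parent2 = p2, child = ch$track,
            conservationRatio = cons, dilutionRatio = dil,
            axisZ = axis[1], axisY = axis[2], axisX = axis[3],
            angleToZ = acos(pmin(1, abs(axis[1]))) * 180 / pi)
          break
        }
        if (length(ev) && ev[[length(ev)]]$frame == t &&
            ev[[length(ev)]]$parent1 == p1) break
      }
    }
  }
  if (!length(ev)) {
    return(data.frame(frame = integer(0), parent1 = integer(0),
                      parent2 = integer(0), child = integer(0),
                      conservationRatio = numeric(0),
                      dilutionRatio = numeric(0), axisZ = numeric(0),
                      axisY = numeric(0), axisX = numeric(0),
                      angleToZ = numeric(0)))
  }
  unique(do.call(rbind, ev))
}
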