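# Slice-wise detection of negatively stained voids and contour extraction
# by the relative-intensity rule: the void boundary is the iso-intensity
# curve at a chosen fraction (90-95%, default 92.5%) of the way from the
# void centre (0% reference) to the surrounding cytoplasm (100% reference,
# measured locally in an annulus outside the void).

sliceMatrix <- function(arr, z) {
  d <- dim(arr)
  matrix(arr[z, , ], d[2], d[3])
}

robustFieldLevel <- function(x) {
  ref <- stats::quantile(x, 0.99, names = FALSE)
  if (ref <= 0) return(0)
  stats::median(x[x > 0.3 * ref])
}

#' Erode a 3D mask by a physical margin
#'
#' Lateral disc erosion per slice plus axial erosion by whole slices,
#' shrinking the mask by about \code{margin} um in every direction. Used
#' to restrict void detection to the cell interior, away from the blurred
#' cell boundary.
#'
#' @param mask logical 3D array (z, y, x).
#' @param voxelSize numeric(3) (dz, dy, dx) um.
#' @param margin erosion depth in um (default 0.4).
#' @return logical 3D array.
#' @rdname erodeMask3d
#' @export
erodeMask3d <- function(mask, voxelSize, margin = 0.4) {
  d <- dim(mask)
  out <- mask
  erodePx <- max(1L, round(margin / voxelSize[3]))
  brush <- EBImage::makeBrush(2L * erodePx + 1L, shape = "disc")
  for (z in seq_len(d[1])) {
    m <- matrix(as.numeric(out[z, , ]), d[2], d[3])
    out[z, , ] <- EBImage::erode(m, brush) > 0
  }
  nzEr <- min(max(1L, round(margin / voxelSize[1])), max(0L, d[1] %/% 3L))
  if (nzEr > 0L) {
    shrunk <- out
    for (k in seq_len(nzEr)) {
      shrunk[seq_len(d[1] - k), , ] <-
        shrunk[seq_len(d[1] - k), , ] & out[seq_len(d[1] - k) + k, , ]
      shrunk[seq_len(d[1] - k) + k, , ] <-
        shrunk[seq_len(d[1] - k) + k, , ] & out[seq_len(d[1] - k), , ]
    }
    out <- shrunk
  }
  out
}

#' @rdname erodeMask3d
#' @export
dilateMask3d <- function(mask, voxelSize, margin = 0.4) {
  d <- dim(mask)
  out <- mask
  px <- max(1L, round(margin / voxelSize[3]))
  brush <- EBImage::makeBrush(2L * px + 1L, shape = "disc")
  for (z in seq_len(d[1])) {
    m <- matrix(as.numeric(out[z, , ]), d[2], d[3])
    out[z, , ] <- EBImage::dilate(m, brush) > 0
  }
  nzDil <- min(max(1L, round(margin / voxelSize[1])), max(0L, d[1] %/% 3L))
  if (nzDil > 0L) {
    grown <- out
    for (k in seq_len(nzDil)) {
      grown[seq_len(d[1] - k), , ] <-
        grown[seq_len(d[1] - k), , ] | out[seq_len(d[1] - k) + k, , ]
      grown[seq_len(d[1] - k) + k, , ] <-
        grown[seq_len(d[1] - k) + k, , ] | out[seq_len(d[1] - k), , ]
    }
    out <- grown
  }
  out
}

#' Segment the cell body and nucleus from the GFP channel
#'
#' The cell body is the largest connected component above background
#' (threshold at \code{threshFraction} of the cytoplasmic level, i.e. the
#' half-maximum edge criterion relaxed to be robust to voids), with holes
#' filled per slice so that excluded organelles stay inside the mask. The
#' nucleus is recovered as the largest connected dim region (below
#' \code{nucleusLevel} of the cytoplasm) of at least
#' \code{nucleusMinVolume} um^3 in the eroded cell interior.
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param channel GFP channel name or index.
#' @param threshFraction cell-body threshold as a fraction of the
#'   cytoplasmic level (default 0.4).
#' @param nucleusLevel dim-region threshold fraction (default 0.75).
#' @param nucleusMinVolume minimum nucleus volume in um^3 (default 30);
#'   the effective floor is \code{min(nucleusMinVolume, max(8, 4\%} of the
#'   cell volume\code{))}, since nuclei of small cells are smaller but no
#'   granule approaches 8 um^3.
#' @return a \linkS4class{CellMask}; attribute "nComponents" records how
#'   many above-background components were found (the largest is kept).
#' @export
segmentCellBody <- function(stack, channel = 1L, threshFraction = 0.4,
                            nucleusLevel = 0.75, nucleusMinVolume = 30) {
  x <- getChannel(stack, channel)
  vs <- voxelSize(stack)
  d <- dim(x)
  cyt <- robustFieldLevel(x)
  if (!is.finite(cyt) || cyt <= 0) stop("no foreground found")
  mask <- x > threshFraction * cyt
  if (!any(mask)) stop("no foreground found")
  for (z in seq_len(d[1])) {
    m <- matrix(as.numeric(mask[z, , ]), d[2], d[3])
    mask[z, , ] <- EBImage::fillHull(m) > 0
  }
  lab <- label3d(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  nComp <- sum(sizes > 0.01 * max(sizes))
  mask <- lab == keep
  # nucleus: dim region in the eroded interior (avoid the blurred edge shell)
  interior <- erodeMask3d(mask, vs, margin = 0.4)
  if (d[1] > 4L) interior[c(1L, d[1]), , ] <- FALSE
  dimReg <- interior & x < nucleusLevel * cyt
  nucleus <- array(FALSE, d)
  if (any(dimReg)) {
    nl <- label3d(dimReg)
    nsz <- tabulate(nl[nl > 0L]) * prod(vs)
    minVol <- min(nucleusMinVolume, max(8, 0.04 * sum(mask) * prod(vs)))
    big <- which(nsz >= minVol)
    if (length(big)) {
      nucleus <- array(nl == big[which.max(nsz[big])], d)
      # morphological opening sheds granule-sized voids whose dark regions
      # touch the nucleus, keeping the smooth nuclear body itself
      nucleus <- dilateMask3d(erodeMask3d(nucleus, vs, 0.45), vs, 0.5) &
        mask
    }
  }
  cm <- new("CellMask", mask = mask, nucleus = nucleus,
            voxelSize = as.numeric(vs))
  attr(cm, "nComponents") <- nComp
  cm
}

#' Detect void seed points in one slice
#'
#' Regional intensity minima of the (lightly smoothed) slice inside the
#' cell whose depth passes the minimum-contrast criterion (centre below
#' \code{minContrast} of the cytoplasmic level); minima closer than
#' \code{mergeRadius} um are merged, keeping the darkest.
#'
#' @param slice numeric matrix (y, x), one z-slice of the GFP channel.
#' @param cellMaskSlice logical matrix or NULL (whole slice).
#' @param cytoplasmLevel reference cytoplasm intensity (see
#'   \code{\link{estimateCytoplasmLevel}}).
#' @param voxelSize numeric(3) (dz, dy, dx) um.
#' @param minContrast seed acceptance: centre intensity must be below this
#'   fraction of the cytoplasm (default 0.6).
#' @param mergeRadius minima closer than this (um) are merged (default 0.25).
#' @param smoothSigma Gaussian presmoothing sigma in pixels (default 0.75).
#' @return integer matrix with columns y, x (pixel indices) and a column
#'   \code{intensity}; zero rows when no seed qualifies.
#' @export
detectVoidSeeds <- function(slice, cellMaskSlice = NULL, cytoplasmLevel,
                            voxelSize, minContrast = 0.6,
                            mergeRadius = 0.25, smoothSigma = 0.75) {
  d <- dim(slice)
  sm <- if (smoothSigma > 0) EBImage::gblur(slice, sigma = smoothSigma)
        else slice
  sm <- matrix(sm, d[1], d[2])
  cm <- if (is.null(cellMaskSlice)) matrix(TRUE, d[1], d[2]) else cellMaskSlice
  dark <- sm < minContrast * cytoplasmLevel & cm
  none <- cbind(y = integer(0), x = integer(0), intensity = numeric(0))
  if (!any(dark)) return(none)
  # strict-ish local minima over the 8-neighbourhood
  pad <- matrix(Inf, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- sm
  isMin <- matrix(TRUE, d[1], d[2])
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- pad[(2:(d[1] + 1L)) + dy, (2:(d[2] + 1L)) + dx]
    isMin <- isMin & sm <= nb
  }
  # reject plateau interiors (all eight neighbours equal): they are not
  # regional minima, just flat regions
  nbMax <- matrix(-Inf, d[1], d[2])
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    pd <- matrix(-Inf, d[1] + 2L, d[2] + 2L)
    pd[2:(d[1] + 1L), 2:(d[2] + 1L)] <- sm
    nbMax <- pmax(nbMax, pd[(2:(d[1] + 1L)) + dy, (2:(d[2] + 1L)) + dx])
  }
  isMin <- isMin & nbMax > sm
  cand <- which(dark & isMin, arr.ind = TRUE)
  if (!nrow(cand)) return(none)
  vals <- sm[cand]
  o <- order(vals)
  cand <- cand[o, , drop = FALSE]
  vals <- vals[o]
  physY <- (cand[, 1] - 0.5) * voxelSize[2]
  physX <- (cand[, 2] - 0.5) * voxelSize[3]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    sel <- which(keep)
    dmin <- min(sqrt((physY[sel] - physY[i])^2 + (physX[sel] - physX[i])^2))
    if (dmin > mergeRadius) keep[i] <- TRUE
  }
  cbind(y = cand[keep, 1], x = cand[keep, 2], intensity = vals[keep])
}

# close a contourLines polyline if its ends meet; NULL when genuinely open
closedPolygon <- function(cl, tol) {
  xy <- cbind(x = cl$y, y = cl$x)  # contourLines: $x along rows (=y phys)
  if (nrow(xy) < 4L) return(NULL)
  gap <- sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2))
  if (gap > tol) return(NULL)
  if (gap > 0) xy <- rbind(xy, xy[1, ])
  xy
}

# rasterize polygon to full-slice linear pixel indices
polygonPixels <- function(xy, d, vs) {
  ry <- range(xy[, 2]); rx <- range(xy[, 1])
  yi <- max(1L, floor(ry[1] / vs[2])):min(d[1], ceiling(ry[2] / vs[2] + 1))
  xi <- max(1L, floor(rx[1] / vs[3])):min(d[2], ceiling(rx[2] / vs[3] + 1))
  if (!length(yi) || !length(xi)) return(integer(0))
  gy <- (yi - 0.5) * vs[2]
  gx <- (xi - 0.5) * vs[3]
  pts <- expand.grid(y = gy, x = gx)
  inside <- pointsInPolygon(pts$x, pts$y, xy)
  idx <- expand.grid(y = yi, x = xi)
  (idx$x[inside] - 1L) * d[1] + idx$y[inside]
}

makeContourRecord <- function(xy, z, d, vs, Ic, Ip, fraction, level,
                              split = FALSE, seed = NULL) {
  area <- polygonArea(xy)
  pix <- polygonPixels(xy, d, vs)
  py <- ((pix - 1L) %% d[1]) + 1L
  px <- ((pix - 1L) %/% d[1]) + 1L
  atBorder <- length(pix) > 0L &&
    (any(py <= 1L) || any(py >= d[1]) || any(px <= 1L) || any(px >= d[2]))
  list(z = as.integer(z), xy = xy, area = area,
       centroid = polygonCentroid(xy),
       centerIntensity = Ic, peripheryIntensity = Ip,
       fraction = fraction, level = level,
       pixels = pix, npix = length(pix), pixelArea = vs[2] * vs[3],
       atBorder = atBorder, split = split, seed = seed)
}

#' Extract void contours in one slice
#'
#' For every seed, determines the preliminary void support (the connected
#' dark region containing the seed), measures the local periphery
#' reference as the median intensity in an annulus 0.2-0.4 um outside the
#' support (global cytoplasm median as fallback when the annulus is
#' unusable), sets the iso-level L = Ic + fraction * (Ip - Ic), and traces
#' the closed sub-pixel iso-curve around the seed by linear interpolation
#' (marching squares). When several seeds share one dark region, the region
#' is split along the intensity ridge by seeded region growing and each
#' seed's contour is the boundary of its share.
#'
#' Discards (with a reason in the "log" attribute): open curves at the
#' image border, contours escaping the cell mask, and contours below the
#' minimum size (equivalent circle diameter < \code{minDiameter}).
#'
#' @param slice numeric matrix (y, x).
#' @param z integer z index the slice came from.
#' @param seeds seed matrix from \code{\link{detectVoidSeeds}}.
#' @param cellMaskSlice logical matrix or NULL.
#' @param cytoplasmLevel global cytoplasm reference.
#' @param voxelSize numeric(3) (dz, dy, dx) um.
#' @param fraction relative iso-level in [0.90, 0.95] (default 0.925,
#'   the midpoint of the 90-95% band).
#' @param minContrast dark-support threshold fraction (default 0.6).
#' @param minDiameter minimum contour equivalent-circle diameter in um
#'   (default 0.3, below the validated size window).
#' @param binarize apply the rule to the binarized slice: the void support
#'   is first thresholded at the midpoint between the centre (0%) and
#'   periphery (100%) references, as an ImageJ-style black-and-white
#'   conversion, and the contour is then traced on the binary image at the
#'   \code{fraction} level. On a binary slice every fraction in the 90-95%
#'   band yields the same interface, so the extractor is idempotent under
#'   re-running on its own binarization. FALSE traces the grey-level
#'   iso-curve at L directly.
#' @param peripheryMode "annulus" (default): the 100% reference is the
#'   median intensity in an annulus 0.2-0.4 um outside the preliminary
#'   void support, falling back to the global cytoplasm median when the
#'   annulus is unusable (too small or overlapping another void);
#'   "global": use \code{cytoplasmLevel} directly.
#' @param centerRefs optional numeric vector, one value per seed row: the
#'   0% centre reference of the 3D negatively stained region the seed
#'   belongs to (its darkest core across slices). NA falls back to the
#'   per-slice centre (3x3 mean around the seed). Supplying the 3D core
#'   keeps cap slices of one void on the same reference as its equator.
#' @return list of contour records (fields z, xy, area, centroid,
#'   centerIntensity, peripheryIntensity, fraction, level, pixels, npix,
#'   pixelArea, atBorder, split, seed), with attribute "log".
#' @export
extractContours <- function(slice, z, seeds, cellMaskSlice = NULL,
                            cytoplasmLevel, voxelSize, fraction = 0.925,
                            minContrast = 0.6, minDiameter = 0.3,
                            binarize = FALSE, centerRefs = NULL,
                            peripheryMode = c("annulus", "global")) {
  peripheryMode <- match.arg(peripheryMode)
  if (fraction < 0.90 || fraction > 0.95)
    stop("contour fraction must lie in [0.90, 0.95]")
  d <- dim(slice)
  vs <- voxelSize
  log <- character(0)
  out <- list()
  if (is.null(seeds) || nrow(seeds) == 0L) {
    attr(out, "log") <- log
    return(out)
  }
  cm <- if (is.null(cellMaskSlice)) matrix(TRUE, d[1], d[2]) else cellMaskSlice
  dark <- slice < minContrast * cytoplasmLevel & cm
  lab <- EBImage::bwlabel(matrix(as.numeric(dark), d[1], d[2]))
  lab <- matrix(as.integer(lab), d[1], d[2])
  seedLab <- lab[cbind(seeds[, 1], seeds[, 2])]
  marginPx <- ceiling(0.65 / vs[3]) + 1L
  tol <- 1.5 * max(vs[2], vs[3])
  for (rid in unique(seedLab)) {
    sIdx <- which(seedLab == rid)
    if (rid == 0L) {
      # seed sits in a shallow minimum whose support vanished; skip
      log <- c(log, sprintf("z=%d: %d seed(s) without dark support", z,
                            length(sIdx)))
      next
    }
    regPix <- which(lab == rid, arr.ind = TRUE)
    yR <- range(regPix[, 1]); xR <- range(regPix[, 2])
    yi <- max(1L, yR[1] - marginPx):min(d[1], yR[2] + marginPx)
    xi <- max(1L, xR[1] - marginPx):min(d[2], xR[2] + marginPx)
    crop <- slice[yi, xi, drop = FALSE]
    support <- lab[yi, xi, drop = FALSE] == rid
    # periphery reference: annulus 0.2-0.4 um outside the support
    dmap <- EBImage::distmap(matrix(as.numeric(!support), nrow(crop)))
    dum <- matrix(dmap, nrow(crop)) * vs[3]
    annulus <- dum > 0.2 & dum <= 0.4 & !(lab[yi, xi] > 0L) & cm[yi, xi]
    Ip <- if (peripheryMode == "annulus" && sum(annulus) >= 8L)
      stats::median(crop[annulus]) else cytoplasmLevel
    gy <- (yi - 0.5) * vs[2]
    gx <- (xi - 0.5) * vs[3]
    nSeed <- length(sIdx)
    if (nSeed > 1L) {
      seedImg <- matrix(0L, nrow(crop), ncol(crop))
      for (k in seq_len(nSeed)) {
        seedImg[seeds[sIdx[k], 1] - yi[1] + 1L,
                seeds[sIdx[k], 2] - xi[1] + 1L] <- k
      }
      prop <- EBImage::propagate(crop, seedImg, mask = support)
      prop <- matrix(as.integer(prop), nrow(crop))
    }
    for (k in seq_len(nSeed)) {
      sy <- seeds[sIdx[k], 1]; sx <- seeds[sIdx[k], 2]
      y0 <- max(1L, sy - 1L):min(d[1], sy + 1L)
      x0 <- max(1L, sx - 1L):min(d[2], sx + 1L)
      Ic <- mean(slice[y0, x0])
      if (!is.null(centerRefs) && is.finite(centerRefs[sIdx[k]]))
        Ic <- min(Ic, centerRefs[sIdx[k]])
      if (Ip <= Ic) {
        log <- c(log, sprintf("z=%d seed(%d,%d): periphery not above center",
                              z, sy, sx))
        next
      }
      level <- Ic + fraction * (Ip - Ic)
      if (nSeed > 1L) {
        msub <- prop == k
        cls <- grDevices::contourLines(x = gy, y = gx,
                                       z = msub + 0, levels = 0.5)
      } else if (binarize) {
        # black-and-white conversion at the midpoint between the region's
        # core (0%) and the local periphery (100%): caps and shadows that
        # never reach half depth relative to the core are not voids and
        # drop out here
        lvlBin <- Ic + 0.5 * (Ip - Ic)
        bw <- (crop < lvlBin) + 0
        cls <- grDevices::contourLines(x = gy, y = gx, z = bw,
                                       levels = fraction)
        level <- lvlBin
      } else {
        cls <- grDevices::contourLines(x = gy, y = gx, z = crop,
                                       levels = level)
      }
      seedPhys <- c((sx - 0.5) * vs[3], (sy - 0.5) * vs[2])  # (x, y)
      best <- NULL
      sawOpen <- FALSE
      for (cl in cls) {
        xy <- closedPolygon(cl, tol)
        if (is.null(xy)) { sawOpen <- TRUE; next }
        if (!pointsInPolygon(seedPhys[1], seedPhys[2], xy)) next
        if (is.null(best) || polygonArea(xy) < polygonArea(best)) best <- xy
      }
      if (is.null(best)) {
        reason <- if (sawOpen) "open iso-curve at image border"
                  else "no enclosing iso-curve"
        log <- c(log, sprintf("z=%d seed(%d,%d): discarded (%s)",
                              z, sy, sx, reason))
        if (sawOpen)
          warning("open iso-curve at image border discarded (z=", z, ")")
        next
      }
      rec <- makeContourRecord(best, z, d, vs, Ic, Ip, fraction,
                               level, split = nSeed > 1L,
                               seed = c(sy, sx))
      if (2 * sqrt(rec$area / pi) < minDiameter) {
        log <- c(log, sprintf(
          "z=%d seed(%d,%d): discarded (below minimum diameter)", z, sy, sx))
        next
      }
      if (rec$npix > 0L && any(!cm[rec$pixels])) {
        log <- c(log, sprintf(
          "z=%d seed(%d,%d): discarded (escapes cell mask)", z, sy, sx))
        next
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  attr(out, "log") <- log
  out
}

#' Extract the contour around a single seed
#'
#' Thin wrapper over \code{\link{extractContours}} for one seed point.
#' Here the supplied \code{cytoplasmLevel} is the 100% periphery
#' reference, so that on an analytic radial profile
#' I(r) = C (1 - exp(-(r/r0)^2)) the extracted radius matches the closed
#' form r = r0 sqrt(-log(1 - fraction)).
#'
#' @inheritParams extractContours
#' @param seed integer(2): (y, x) pixel indices of a detected minimum.
#' @return a contour record, or NULL when no valid contour exists.
#' @export
extractContour <- function(slice, seed, cytoplasmLevel, fraction = 0.925,
                           voxelSize, cellMaskSlice = NULL, z = 1L, ...) {
  seeds <- cbind(y = seed[1], x = seed[2], intensity = slice[seed[1], seed[2]])
  res <- extractContours(slice, z, seeds, cellMaskSlice, cytoplasmLevel,
                         voxelSize, fraction = fraction,
                         peripheryMode = "global", ...)
  if (length(res)) res[[1]] else NULL
}
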