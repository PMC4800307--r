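# Link per-slice contours into 3D organelles (serial-section style: a
# contour joins the organelle whose contour in the neighbouring slice it
# overlaps) and compute lamination volumes and shape metrics.

#' Link contours across slices into 3D organelles
#'
#' Two contours in adjacent slices belong to one organelle iff their
#' overlap area is at least \code{overlapThreshold} times the smaller of
#' the two areas ("at the same position in the neighbouring image").
#' Each contour joins at most one organelle; competing overlaps are
#' resolved by largest overlap, then smallest centroid distance. Unmatched
#' contours start or end objects. Linking is symmetric: reversing the
#' slice order yields the same partition.
#'
#' @param contoursBySlice list of contour-record lists, one element per z
#'   index in order (empty elements allowed), as produced by
#'   \code{\link{extractContours}}.
#' @param dz z spacing in um.
#' @param overlapThreshold overlap ratio threshold (default 0.5).
#' @param nz total number of slices in the stack (for truncation
#'   flagging); defaults to the length of \code{contoursBySlice}.
#' @return list of \linkS4class{Organelle3D}, ids in deterministic order
#'   (ascending first slice, then centroid).
#' @export
linkContours <- function(contoursBySlice, dz, overlapThreshold = 0.5,
                         nz = length(contoursBySlice)) {
  flat <- list()
  for (ct in contoursBySlice) for (c1 in ct) flat[[length(flat) + 1L]] <- c1
  n <- length(flat)
  if (!n) return(list())
  zs <- vapply(flat, function(ct) ct$z, integer(1))
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (z in sort(unique(zs))) {
    a <- which(zs == z); b <- which(zs == z + 1L)
    if (!length(a) || !length(b)) next
    cand <- NULL
    for (i in a) for (j in b) {
      inter <- length(intersect(flat[[i]]$pixels, flat[[j]]$pixels))
      if (inter == 0L) next
      if (inter >= overlapThreshold * min(flat[[i]]$npix, flat[[j]]$npix)) {
        cd <- sqrt(sum((flat[[i]]$centroid - flat[[j]]$centroid)^2))
        cand <- rbind(cand, c(i, j, inter, cd))
      }
    }
    if (is.null(cand)) next
    cand <- cand[order(-cand[, 3], cand[, 4]), , drop = FALSE]
    usedA <- usedB <- integer(0)
    for (r in seq_len(nrow(cand))) {
      i <- as.integer(cand[r, 1]); j <- as.integer(cand[r, 2])
      if (i %in% usedA || j %in% usedB) next
      usedA <- c(usedA, i); usedB <- c(usedB, j)
      ra <- findRoot(i); rb <- findRoot(j)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  groups <- split(seq_len(n), roots)
  # deterministic ordering: by first z, then centroid y/x
  keyOf <- function(g) {
    zmin <- min(zs[g])
    first <- flat[[g[which.min(zs[g])]]]
    c(zmin, first$centroid[2], first$centroid[1])
  }
  keys <- t(vapply(groups, keyOf, numeric(3)))
  ord <- order(keys[, 1], keys[, 2], keys[, 3])
  orgs <- vector("list", length(groups))
  for (k in seq_along(ord)) {
    g <- groups[[ord[k]]]
    cts <- flat[g][order(zs[g])]
    zAll <- vapply(cts, function(ct) ct$z, integer(1))
    trunc <- any(zAll == 1L) || any(zAll == nz) ||
      any(vapply(cts, function(ct) isTRUE(ct$atBorder), logical(1)))
    orgs[[k]] <- new("Organelle3D", id = k, contours = cts,
                     dz = unname(dz), truncated = trunc)
  }
  orgs
}

#' Lamination volume of an organelle
#'
#' Serial-section slab model: volume = dz x sum of contour areas, i.e. the
#' organelle reconstructed by lamination at the acquisition interval. This
#' is the primary reported volume; \code{\link{voxelVolume}} is recorded
#' alongside for QC.
#'
#' @param x an \linkS4class{Organelle3D}.
#' @param dz optional z spacing override in um.
#' @return volume in um^3.
#' @export
setGeneric("laminationVolume", function(x, dz = NULL)
  standardGeneric("laminationVolume"))
#' @rdname laminationVolume
#' @export
setMethod("laminationVolume", "Organelle3D", function(x, dz = NULL) {
  if (is.null(dz)) dz <- x@dz
  dz * sum(vapply(x@contours, function(ct) ct$area, numeric(1)))
})

#' Voxel-count volume of an organelle
#' @param x an \linkS4class{Organelle3D}.
#' @return volume in um^3 from rasterized contour interiors.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "Organelle3D", function(x) {
  x@dz * sum(vapply(x@contours, function(ct) ct$npix * ct$pixelArea,
                    numeric(1)))
})

#' Equivalent spherical diameter, (6 V / pi)^(1/3)
#' @param x an \linkS4class{Organelle3D}.
#' @export
setGeneric("equivalentDiameter", function(x)
  standardGeneric("equivalentDiameter"))
#' @rdname equivalentDiameter
#' @export
setMethod("equivalentDiameter", "Organelle3D", function(x) {
  (6 * laminationVolume(x) / pi)^(1 / 3)
})

#' Shape metrics of an organelle
#'
#' z-extent (number of contours x dz), maximum lateral extent (largest
#' vertex-to-vertex distance of any contour), mean lateral equivalent
#' diameter (mean over contours of 2 sqrt(A/pi)), elongation =
#' z-extent / mean lateral diameter, and the area-weighted centroid.
#' Single-contour objects are flagged \code{thin} (z-extent equals the
#' slice spacing floor).
#'
#' @param x an \linkS4class{Organelle3D}.
#' @return list(zExtent, maxLateralExtent, meanLateralDiameter, elongation,
#'   centroid = c(x, y, z) um, nContours, thin).
#' @export
setGeneric("shapeMetrics", function(x) standardGeneric("shapeMetrics"))
#' @rdname shapeMetrics
#' @export
setMethod("shapeMetrics", "Organelle3D", function(x) {
  areas <- vapply(x@contours, function(ct) ct$area, numeric(1))
  zExtent <- length(x@contours) * x@dz
  latD <- 2 * sqrt(areas / pi)
  feret <- max(vapply(x@contours, function(ct) maxFeret(ct$xy), numeric(1)))
  cents <- t(vapply(x@contours, function(ct) ct$centroid, numeric(2)))
  zPhys <- (vapply(x@contours, function(ct) ct$z, integer(1)) - 0.5) * x@dz
  w <- areas / sum(areas)
  list(zExtent = zExtent, maxLateralExtent = feret,
       meanLateralDiameter = stats::weighted.mean(latD, w),
       elongation = zExtent / stats::weighted.mean(latD, w),
       centroid = c(sum(w * cents[, 1]), sum(w * cents[, 2]),
                    sum(w * zPhys)),
       nContours = length(x@contours), thin = length(x@contours) == 1L)
})

#' Classify an organelle into a compartment class
#'
#' Centroid inside the nucleus mask: "nuclear". Thin tubular objects
#' (lateral diameter below \code{tubeDiameter}, elongation above
#' \code{tubeElongation} along z or in-plane): "mitochondrion-like".
#' Equivalent diameter within \code{sgDiameterRange}: "SG" (secretory
#' granule, including strung/elongated granules). Otherwise
#' "unclassified".
#'
#' @param x an \linkS4class{Organelle3D}.
#' @param cellMask a \linkS4class{CellMask} (or NULL: no nuclear test).
#' @param sgDiameterRange equivalent-diameter window in um (default
#'   c(0.3, 1.5)).
#' @param tubeDiameter lateral diameter bound for tubes in um (default 0.4).
#' @param tubeElongation elongation bound for tubes (default 2).
#' @return character class label.
#' @export
setGeneric("classifyCompartment",
           function(x, cellMask = NULL, sgDiameterRange = c(0.3, 1.5),
                    tubeDiameter = 0.4, tubeElongation = 2)
             standardGeneric("classifyCompartment"))
#' @rdname classifyCompartment
#' @export
setMethod("classifyCompartment", "Organelle3D",
  function(x, cellMask = NULL, sgDiameterRange = c(0.3, 1.5),
           tubeDiameter = 0.4, tubeElongation = 2) {
  sm <- shapeMetrics(x)
  if (!is.null(cellMask)) {
    vs <- cellMask@voxelSize
    d <- dim(cellMask@nucleus)
    zi <- min(max(1L, round(sm$centroid[3] / vs[1] + 0.5)), d[1])
    yi <- min(max(1L, round(sm$centroid[2] / vs[2] + 0.5)), d[2])
    xi <- min(max(1L, round(sm$centroid[1] / vs[3] + 0.5)), d[3])
    if (cellMask@nucleus[zi, yi, xi]) return("nuclear")
  }
  # tubular along z, or tubular in-plane (ellipse width approx 4A/(pi F))
  widths <- vapply(x@contours, function(ct)
    if (maxFeret(ct$xy) > 0) 4 * ct$area / (pi * maxFeret(ct$xy)) else 0,
    numeric(1))
  inPlaneAspect <- max(vapply(x@contours, function(ct) {
    f <- maxFeret(ct$xy)
    w <- if (f > 0) 4 * ct$area / (pi * f) else f
    if (w > 0) f / w else 1
  }, numeric(1)))
  if ((sm$meanLateralDiameter < tubeDiameter &&
       sm$elongation > tubeElongation) ||
      (stats::median(widths) < tubeDiameter &&
       inPlaneAspect > tubeElongation))
    return("mitochondrion-like")
  dEq <- equivalentDiameter(x)
  if (dEq >= sgDiameterRange[1] && dEq <= sgDiameterRange[2]) return("SG")
  "unclassified"
})

#' Assemble the organelle inventory table
#'
#' One row per organelle, ordered by id: class label, lamination and voxel
#' volumes, equivalent diameter, centroid, extents, elongation, marker
#' statistics and the truncation flag.
#'
#' @param organelles list of \linkS4class{Organelle3D}.
#' @return data.frame.
#' @export
objectTable <- function(organelles) {
  if (!length(organelles)) {
    return(data.frame(id = integer(0), class = character(0),
                      volumeLamination = numeric(0), volumeVoxel = numeric(0),
                      equivDiameter = numeric(0), centroidX = numeric(0),
                      centroidY = numeric(0), centroidZ = numeric(0),
                      zExtent = numeric(0), lateralExtent = numeric(0),
                      elongation = numeric(0), nContours = integer(0),
                      markerMean = numeric(0), markerPositive = logical(0),
                      truncated = logical(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(organelles, function(o) {
    sm <- shapeMetrics(o)
    data.frame(id = o@id, class = o@label,
               volumeLamination = laminationVolume(o),
               volumeVoxel = voxelVolume(o),
               equivDiameter = equivalentDiameter(o),
               centroidX = sm$centroid[1], centroidY = sm$centroid[2],
               centroidZ = sm$centroid[3], zExtent = sm$zExtent,
               lateralExtent = sm$maxLateralExtent,
               elongation = sm$elongation, nContours = sm$nContours,
               markerMean = o@markerMean, markerPositive = o@markerPositive,
               truncated = o@truncated, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
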