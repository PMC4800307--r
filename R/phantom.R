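# Synthetic negative-contrast phantoms with analytic ground truth: a bright,
# roughly uniform cytoplasmic GFP field in which organelles appear as dark
# voids because they exclude the fluorophore. Object voxelization uses 8x
# per-axis supersampling of boundary voxels so that planted volumes are
# unbiased and the diameter-recovery benchmark has a trustworthy truth.

#' Describe one planted object
#'
#' @param id integer id, unique within a phantom.
#' @param shape "sphere", "cylinder" (axis along z), "string"
#'   (a string of touching spheres along z) or "ellipsoid" (axis-aligned).
#' @param center numeric(3) physical centre (z, y, x) in um.
#' @param diameter sphere/cylinder/bead diameter in um (> 0); for an
#'   ellipsoid, its equivalent spherical diameter (derived from semiaxes
#'   when those are given).
#' @param length cylinder length in um (cylinder only).
#' @param nBeads number of beads in a string (string only).
#' @param semiaxes numeric(3) (z, y, x) semiaxes in um (ellipsoid only).
#' @param markerLevel mean marker-channel intensity of the object interior
#'   (a.u.); 0 means marker-negative.
#' @param exclusion fraction of the cytoplasmic level remaining inside the
#'   object, in [0, 1): 0 is a fully excluding void.
#' @return one-row data.frame.
#' @export
plantedObject <- function(id, shape = c("sphere", "cylinder", "string",
                                        "ellipsoid"),
                          center, diameter = NA_real_, length = NA_real_,
                          nBeads = NA_integer_, semiaxes = NULL,
                          markerLevel = 0, exclusion = 0) {
  shape <- match.arg(shape)
  if (exclusion < 0 || exclusion >= 1)
    stop("exclusion must lie in [0, 1)")
  if (shape == "ellipsoid") {
    if (is.null(semiaxes) || length(semiaxes) != 3L || any(semiaxes <= 0))
      stop("ellipsoid needs three positive semiaxes")
    diameter <- 2 * prod(semiaxes)^(1 / 3)
  } else {
    if (is.na(diameter) || diameter <= 0) stop("diameter must be > 0")
  }
  if (shape == "cylinder" && (is.na(length) || length <= 0))
    stop("cylinder needs length > 0")
  if (shape == "string" && (is.na(nBeads) || nBeads < 2L))
    stop("string needs nBeads >= 2")
  if (is.null(semiaxes)) semiaxes <- rep(NA_real_, 3)
  data.frame(id = as.integer(id), shape = shape,
             cz = center[1], cy = center[2], cx = center[3],
             diameter = diameter, length = length,
             nBeads = as.integer(nBeads),
             saz = semiaxes[1], say = semiaxes[2], sax = semiaxes[3],
             markerLevel = markerLevel,
             exclusion = exclusion, stringsAsFactors = FALSE)
}

#' Specify a synthetic negative-contrast phantom
#'
#' Holds the acquisition geometry (default: 40 x 40 nm pixels; z spacing
#' 0.1 um for bead fields, set 0.2 um for cells), the cytoplasmic intensity,
#' the planted objects, optional cell/nucleus geometry, and the noise and
#' attenuation model used by \code{\link{applyOptics}}.
#'
#' @param fieldShape integer(3) voxel counts (nz, ny, nx).
#' @param voxelSize numeric(3) (dz, dy, dx) um, all > 0.
#' @param cytoplasmLevel mean cytoplasmic photon count (a.u.).
#' @param objects data.frame of \code{\link{plantedObject}} rows.
#' @param cell optional list(center, semiaxes) in um: ellipsoidal cell body.
#'   When NULL the fluorescent field fills the whole stack (bead slurry).
#' @param nucleus optional list(center, semiaxes, level, substructures,
#'   penetration): ellipsoidal nucleus at \code{level} x cytoplasm (default
#'   0.5) containing \code{substructures} dark spheres whose interior
#'   intensity is \code{penetration} x the nuclear level, penetration in
#'   [0, 1].
#' @param noise list(poissonGain, gaussianSD): photon (shot) noise applied
#'   as Poisson counts at \code{poissonGain} counts per a.u., then additive
#'   Gaussian read noise.
#' @param depthAttenuation fractional intensity loss per um of z depth in
#'   the medium (default 0: good penetration).
#' @param objectAttenuation fractional excitation loss per um of excluding
#'   object material traversed along z (default 0.3: scattering by
#'   polystyrene-like objects casts a shadow above large objects).
#' @param seed integer RNG seed for all stochastic steps.
#' @return list of class "PhantomSpec".
#' @export
phantomSpec <- function(fieldShape, voxelSize = c(0.1, 0.04, 0.04),
                        cytoplasmLevel = 1000, objects,
                        cell = NULL, nucleus = NULL,
                        noise = list(poissonGain = 1, gaussianSD = 2),
                        depthAttenuation = 0, objectAttenuation = 0.3,
                        seed = 1L) {
  if (any(voxelSize <= 0)) stop("voxel sizes must be strictly positive")
  if (any(objects$exclusion < 0 | objects$exclusion >= 1))
    stop("exclusion must lie in [0, 1)")
  if (!is.null(nucleus)) {
    pen <- if (is.null(nucleus$penetration)) 0.3 else nucleus$penetration
    if (pen < 0 || pen > 1) stop("penetration fraction must lie in [0, 1]")
  }
  ext <- fieldShape * voxelSize
  inField <- objects$cz > 0 & objects$cz < ext[1] &
    objects$cy > 0 & objects$cy < ext[2] &
    objects$cx > 0 & objects$cx < ext[3]
  if (!all(inField)) stop("all object centers must lie inside the field")
  structure(list(fieldShape = as.integer(fieldShape),
                 voxelSize = as.numeric(voxelSize),
                 cytoplasmLevel = cytoplasmLevel, objects = objects,
                 cell = cell, nucleus = nucleus, noise = noise,
                 depthAttenuation = depthAttenuation,
                 objectAttenuation = objectAttenuation,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

## ---- voxelization ----

axisCenters <- function(n, d) (seq_len(n) - 0.5) * d

# fraction of each listed voxel inside the indicator, by ss^3 supersampling
superSampleFraction <- function(coords, vs, insideFun, ss = 8L) {
  offs <- (seq_len(ss) - 0.5) / ss - 0.5
  frac <- numeric(nrow(coords))
  for (oz in offs) for (oy in offs) for (ox in offs) {
    frac <- frac + insideFun(coords[, 1] + oz * vs[1],
                             coords[, 2] + oy * vs[2],
                             coords[, 3] + ox * vs[3])
  }
  frac / ss^3
}

# coverage of an axis-aligned ellipsoid over its bounding box; returns
# list(zi, yi, xi, cover) or NULL when the box misses the field
ellipsoidCoverage <- function(dims, vs, center, semiaxes, ss = 8L) {
  zc <- axisCenters(dims[1], vs[1])
  yc <- axisCenters(dims[2], vs[2])
  xc <- axisCenters(dims[3], vs[3])
  hd <- sqrt(sum((vs / 2)^2))
  zi <- which(abs(zc - center[1]) <= semiaxes[1] + hd)
  yi <- which(abs(yc - center[2]) <= semiaxes[2] + hd)
  xi <- which(abs(xc - center[3]) <= semiaxes[3] + hd)
  if (!length(zi) || !length(yi) || !length(xi)) return(NULL)
  # normalized radius minus 1, scaled back to um by the smallest semiaxis:
  # a conservative signed-distance proxy for boundary detection
  u2 <- outer(((yc[yi] - center[2]) / semiaxes[2])^2,
              ((xc[xi] - center[3]) / semiaxes[3])^2, "+")
  arr <- aperm(outer(u2, ((zc[zi] - center[1]) / semiaxes[1])^2, "+"),
               c(3, 1, 2))
  rn <- sqrt(arr)
  sdfUM <- (rn - 1) * min(semiaxes)
  cover <- array(0, dim(arr))
  cover[sdfUM <= -hd] <- 1
  bnd <- which(abs(sdfUM) < hd)
  if (length(bnd)) {
    aidx <- arrayInd(bnd, dim(arr))
    coords <- cbind(zc[zi][aidx[, 1]], yc[yi][aidx[, 2]], xc[xi][aidx[, 3]])
    insideFun <- function(z, y, x) {
      ((z - center[1]) / semiaxes[1])^2 + ((y - center[2]) / semiaxes[2])^2 +
        ((x - center[3]) / semiaxes[3])^2 <= 1
    }
    cover[bnd] <- superSampleFraction(coords, vs, insideFun, ss)
  }
  list(zi = zi, yi = yi, xi = xi, cover = cover)
}

sphereCoverage <- function(dims, vs, center, diameter, ss = 8L) {
  r <- diameter / 2
  ellipsoidCoverage(dims, vs, center, c(r, r, r), ss)
}

cylinderCoverage <- function(dims, vs, center, diameter, length, ss = 8L) {
  r <- diameter / 2
  zc <- axisCenters(dims[1], vs[1])
  yc <- axisCenters(dims[2], vs[2])
  xc <- axisCenters(dims[3], vs[3])
  hd <- sqrt(sum((vs / 2)^2))
  zi <- which(abs(zc - center[1]) <= length / 2 + hd)
  yi <- which(abs(yc - center[2]) <= r + hd)
  xi <- which(abs(xc - center[3]) <= r + hd)
  if (!length(zi) || !length(yi) || !length(xi)) return(NULL)
  latd <- sqrt(outer((yc[yi] - center[2])^2, (xc[xi] - center[3])^2, "+")) - r
  zd <- abs(zc[zi] - center[1]) - length / 2
  arr <- aperm(outer(latd, zd, FUN = pmax), c(3, 1, 2))
  cover <- array(0, dim(arr))
  cover[arr <= -hd] <- 1
  bnd <- which(abs(arr) < hd)
  if (length(bnd)) {
    aidx <- arrayInd(bnd, dim(arr))
    coords <- cbind(zc[zi][aidx[, 1]], yc[yi][aidx[, 2]], xc[xi][aidx[, 3]])
    insideFun <- function(z, y, x) {
      (y - center[2])^2 + (x - center[3])^2 <= r^2 &
        abs(z - center[1]) <= length / 2
    }
    cover[bnd] <- superSampleFraction(coords, vs, insideFun, ss)
  }
  list(zi = zi, yi = yi, xi = xi, cover = cover)
}

# accumulate an object's coverage into a field-sized array (max-combine)
addCoverage <- function(field, cov) {
  if (is.null(cov)) return(field)
  sub <- field[cov$zi, cov$yi, cov$xi, drop = FALSE]
  field[cov$zi, cov$yi, cov$xi] <- pmax(sub, cov$cover)
  field
}

objectCoverage <- function(spec, obj, ss = 8L) {
  dims <- spec$fieldShape; vs <- spec$voxelSize
  ctr <- c(obj$cz, obj$cy, obj$cx)
  if (obj$shape == "sphere") {
    sphereCoverage(dims, vs, ctr, obj$diameter, ss)
  } else if (obj$shape == "ellipsoid") {
    ellipsoidCoverage(dims, vs, ctr, c(obj$saz, obj$say, obj$sax), ss)
  } else if (obj$shape == "cylinder") {
    cylinderCoverage(dims, vs, ctr, obj$diameter, obj$length, ss)
  } else { # string of touching spheres stacked along z
    field <- NULL
    k <- obj$nBeads
    z0 <- obj$cz - (k - 1) / 2 * obj$diameter
    covs <- lapply(seq_len(k) - 1L, function(i)
      sphereCoverage(dims, vs, c(z0 + i * obj$diameter, obj$cy, obj$cx),
                     obj$diameter, ss))
    zi <- sort(unique(unlist(lapply(covs, `[[`, "zi"))))
    yi <- sort(unique(unlist(lapply(covs, `[[`, "yi"))))
    xi <- sort(unique(unlist(lapply(covs, `[[`, "xi"))))
    cover <- array(0, c(length(zi), length(yi), length(xi)))
    for (cv in covs) {
      if (is.null(cv)) next
      iz <- match(cv$zi, zi); iy <- match(cv$yi, yi); ix <- match(cv$xi, xi)
      cover[iz, iy, ix] <- pmax(cover[iz, iy, ix], cv$cover)
    }
    list(zi = zi, yi = yi, xi = xi, cover = cover)
  }
}

analyticVolume <- function(obj) {
  switch(obj$shape,
         sphere = pi / 6 * obj$diameter^3,
         cylinder = pi / 4 * obj$diameter^2 * obj$length,
         string = obj$nBeads * pi / 6 * obj$diameter^3,
         ellipsoid = 4 / 3 * pi * obj$saz * obj$say * obj$sax)
}

groundTruthTable <- function(objects) {
  vol <- vapply(seq_len(nrow(objects)), function(i)
    analyticVolume(objects[i, ]), numeric(1))
  data.frame(id = objects$id, shape = objects$shape,
             cz = objects$cz, cy = objects$cy, cx = objects$cx,
             diameter = objects$diameter, volume = vol,
             equivDiameter = (6 * vol / pi)^(1 / 3),
             markerLevel = objects$markerLevel,
             markerPositive = objects$markerLevel > 0,
             stringsAsFactors = FALSE)
}

# render the noiseless, pre-optics phantom; returns stack + occupancy
renderPhantom <- function(spec, ss = 8L) {
  dims <- spec$fieldShape
  cyt <- spec$cytoplasmLevel
  if (is.null(spec$cell)) {
    gfp <- array(cyt, dims)
  } else {
    cv <- ellipsoidCoverage(dims, spec$voxelSize, spec$cell$center,
                            spec$cell$semiaxes, ss)
    gfp <- array(0, dims)
    if (!is.null(cv)) gfp[cv$zi, cv$yi, cv$xi] <- cyt * cv$cover
  }
  if (!is.null(spec$nucleus)) {
    nuc <- spec$nucleus
    lev <- if (is.null(nuc$level)) 0.5 else nuc$level
    cv <- ellipsoidCoverage(dims, spec$voxelSize, nuc$center, nuc$semiaxes, ss)
    if (!is.null(cv)) {
      sub <- gfp[cv$zi, cv$yi, cv$xi]
      gfp[cv$zi, cv$yi, cv$xi] <- sub * (1 - (1 - lev) * cv$cover)
    }
    if (!is.null(nuc$substructures) && length(nuc$substructures)) {
      pen <- if (is.null(nuc$penetration)) 0.3 else nuc$penetration
      for (sb in nuc$substructures) {
        cv <- sphereCoverage(dims, spec$voxelSize, sb$center, sb$diameter, ss)
        if (is.null(cv)) next
        sub <- gfp[cv$zi, cv$yi, cv$xi]
        gfp[cv$zi, cv$yi, cv$xi] <- sub * (1 - (1 - pen) * cv$cover)
      }
    }
  }
  occupancy <- array(0, dims)
  marker <- array(0, dims)
  for (i in seq_len(nrow(spec$objects))) {
    obj <- spec$objects[i, ]
    cv <- objectCoverage(spec, obj, ss)
    if (is.null(cv)) next
    sub <- gfp[cv$zi, cv$yi, cv$xi]
    gfp[cv$zi, cv$yi, cv$xi] <- sub * (1 - (1 - obj$exclusion) * cv$cover)
    occupancy <- addCoverage(occupancy, cv)
    if (obj$markerLevel > 0) {
      sub <- marker[cv$zi, cv$yi, cv$xi]
      marker[cv$zi, cv$yi, cv$xi] <- sub + obj$markerLevel * cv$cover
    }
  }
  stack <- VoxelStack(GFP = gfp, marker = marker,
                      voxelSize = spec$voxelSize)
  list(stack = stack, occupancy = occupancy)
}

## ---- phantom constructors ----

#' Generate a bead phantom: fully excluding spheres in a uniform GFP field
#'
#' Emulates uniformly sized polystyrene beads suspended in a GFP solution
#' and co-labelled with a red dye: the GFP channel carries dark spheres in a
#' bright field, the marker channel bright spheres. Bead fields default to
#' 0.1-um z spacing. Beads must be isolated: any pair closer than one bead
#' diameter (surface to surface) is rejected, since the accuracy benchmark
#' assumes isolated beads.
#'
#' @param spec a \code{\link{phantomSpec}} whose objects are all spheres.
#' @param ss supersampling factor per axis for boundary voxels.
#' @return list(stack = \linkS4class{VoxelStack} (pre-optics), truth =
#'   ground-truth data.frame, occupancy = object coverage array, spec).
#' @examples
#' sp <- phantomSpec(fieldShape = c(24, 50, 50),
#'                   objects = plantedObject(1, "sphere", c(1.2, 1, 1), 1.0))
#' ph <- makeBeadPhantom(sp)
#' ph$truth$volume    # pi/6 * 1^3
#' @export
makeBeadPhantom <- function(spec, ss = 8L) {
  obj <- spec$objects
  if (!all(obj$shape == "sphere"))
    stop("bead phantoms take sphere objects only")
  if (nrow(obj) > 1L) {
    ctr <- as.matrix(obj[, c("cz", "cy", "cx")])
    dd <- as.matrix(stats::dist(ctr))
    for (i in seq_len(nrow(obj) - 1L)) for (j in seq(i + 1L, nrow(obj))) {
      gap <- dd[i, j] - (obj$diameter[i] + obj$diameter[j]) / 2
      if (gap < max(obj$diameter[i], obj$diameter[j]))
        stop("beads ", obj$id[i], " and ", obj$id[j],
             " overlap or are closer than one bead diameter")
    }
  }
  rp <- renderPhantom(spec, ss)
  list(stack = rp$stack, truth = groundTruthTable(obj),
       occupancy = rp$occupancy, spec = spec)
}

#' Convenience spec for a field of identical beads on a jittered grid
#'
#' @param n number of beads.
#' @param diameter bead diameter in um.
#' @param voxelSize (dz, dy, dx) um; default 0.1-um z spacing, 40-nm pixels.
#' @param cytoplasmLevel mean field photon count.
#' @param markerLevel marker-channel intensity of the beads.
#' @param seed RNG seed (placement jitter).
#' @param ... further arguments to \code{\link{phantomSpec}}.
#' @return a \code{\link{phantomSpec}}.
#' @export
beadFieldSpec <- function(n, diameter, voxelSize = c(0.1, 0.04, 0.04),
                          cytoplasmLevel = 1000, markerLevel = 500,
                          seed = 1L, ...) {
  spacing <- max(2.2 * diameter, diameter + 1.0)
  ncol <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol)
  margin <- spacing / 2 + 0.5
  zmid <- diameter / 2 + 0.9
  withSeed(seed, {
    jit <- matrix(stats::runif(3 * n, -0.03, 0.03) * diameter, ncol = 3)
    ij <- arrayInd(seq_len(n), c(nrow_, ncol))
    objs <- do.call(rbind, lapply(seq_len(n), function(k) {
      plantedObject(k, "sphere",
                    center = c(zmid + jit[k, 1],
                               margin + (ij[k, 1] - 1) * spacing + jit[k, 2],
                               margin + (ij[k, 2] - 1) * spacing + jit[k, 3]),
                    diameter = diameter, markerLevel = markerLevel)
    }))
  })
  extY <- 2 * margin + (nrow_ - 1) * spacing
  extX <- 2 * margin + (ncol - 1) * spacing
  extZ <- diameter + 2 * 0.9
  phantomSpec(fieldShape = ceiling(c(extZ, extY, extX) / voxelSize),
              voxelSize = voxelSize, cytoplasmLevel = cytoplasmLevel,
              objects = objs, seed = seed, ...)
}

#' Generate a cell phantom: an ellipsoidal cell with nucleus and granules
#'
#' The GFP channel equals the cytoplasmic level inside the cell body minus
#' exclusions (granules, nucleus and its substructures) and ~0 outside; the
#' marker channel fills the marker-positive subset of objects.
#'
#' @param spec a \code{\link{phantomSpec}} with a non-NULL \code{cell}.
#' @param ss boundary supersampling factor.
#' @return list(stack, truth, occupancy, spec, cellVolume) where
#'   \code{cellVolume} is the analytic ellipsoid volume in um^3.
#' @export
makeCellPhantom <- function(spec, ss = 8L) {
  if (is.null(spec$cell)) stop("cell phantom needs spec$cell geometry")
  sa <- spec$cell$semiaxes; ctr <- spec$cell$center
  obj <- spec$objects
  rn <- sqrt(((obj$cz - ctr[1]) / sa[1])^2 + ((obj$cy - ctr[2]) / sa[2])^2 +
               ((obj$cx - ctr[3]) / sa[3])^2)
  rmax <- obj$diameter / 2 / min(sa)
  if (any(rn + rmax > 1))
    stop("object(s) ", paste(obj$id[rn + rmax > 1], collapse = ", "),
         " lie outside the cell body")
  rp <- renderPhantom(spec, ss)
  list(stack = rp$stack, truth = groundTruthTable(obj),
       occupancy = rp$occupancy, spec = spec,
       cellVolume = 4 / 3 * pi * prod(sa))
}

#' Convenience spec for a randomized cell phantom
#'
#' Places \code{nSG} spherical granules uniformly in the cytoplasm (inside
#' the cell ellipsoid, outside the nucleus, pairwise separated), a nucleus
#' at 45% of the cell semiaxes with dark substructures, and marks a given
#' fraction of granules in the second channel.
#'
#' @param cellVolume target analytic cell volume in um^3.
#' @param nSG number of granules.
#' @param sgDiameter range (min, max) of granule diameters in um.
#' @param markerFraction fraction of granules that are marker-positive.
#' @param voxelSize (dz, dy, dx) um; cells default to 0.2-um z spacing.
#' @param cytoplasmLevel mean cytoplasmic photon count.
#' @param axialRatio cell z semiaxis relative to lateral (cells are
#'   flattened on the coverslip; default 0.55).
#' @param nucleus logical: include a nucleus.
#' @param objectAttenuation fractional excitation loss per um of granule
#'   material (default 0.1: organelles scatter far less than polystyrene).
#' @param seed RNG seed.
#' @param ... further arguments to \code{\link{phantomSpec}} (noise, ...).
#' @return a \code{\link{phantomSpec}}.
#' @export
cellPhantomSpec <- function(cellVolume = 2000, nSG = 50,
                            sgDiameter = c(0.5, 1.0), markerFraction = 1,
                            voxelSize = c(0.2, 0.1, 0.1),
                            cytoplasmLevel = 1000, axialRatio = 0.55,
                            nucleus = TRUE, objectAttenuation = 0.1,
                            seed = 1L, ...) {
  # semiaxes (a_z, a_lat, a_lat) with a_z = axialRatio * a_lat
  aLat <- (3 * cellVolume / (4 * pi * axialRatio))^(1 / 3)
  aZ <- axialRatio * aLat
  margin <- 0.8
  ext <- 2 * c(aZ, aLat, aLat) + 2 * margin
  ctr <- ext / 2
  sa <- c(aZ, aLat, aLat)
  nuc <- NULL
  nucSA <- c(0, 0, 0)
  if (nucleus) {
    nucSA <- 0.45 * sa
    withSeed(seed + 1L, {
      subs <- lapply(seq_len(3L), function(i) {
        u <- stats::runif(3, -0.4, 0.4)
        list(center = ctr + u * nucSA, diameter = 0.8)
      })
    })
    nuc <- list(center = ctr, semiaxes = nucSA, level = 0.5,
                substructures = subs, penetration = 0.3)
  }
  withSeed(seed, {
    diam <- stats::runif(nSG, sgDiameter[1], sgDiameter[2])
    marked <- seq_len(nSG) <= round(markerFraction * nSG)
    marked <- sample(marked)
    placed <- matrix(NA_real_, 0, 3)
    objs <- vector("list", nSG)
    for (k in seq_len(nSG)) {
      r <- diam[k] / 2
      ok <- FALSE
      for (try in seq_len(4000)) {
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) > 1) next
        p <- ctr + u * (sa - r - 0.25)
        # containment under the conservative (min-semiaxis) criterion
        if (sqrt(sum(((p - ctr) / sa)^2)) + r / min(sa) > 0.98) next
        # outside the nucleus (with clearance), inside the cell
        if (nucleus) {
          rnuc <- sqrt(sum(((p - ctr) / (nucSA + r + 0.2))^2))
          if (rnuc < 1) next
        }
        if (nrow(placed) > 0) {
          dmin <- min(sqrt(rowSums(sweep(placed, 2, p)^2)))
          if (dmin < (max(diam) + diam[k]) / 2 + 0.35) next
        }
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place ", nSG, " granules; cell too crowded")
      placed <- rbind(placed, p)
      objs[[k]] <- plantedObject(k, "sphere", p, diam[k],
                                 markerLevel = if (marked[k]) 600 else 0)
    }
  })
  phantomSpec(fieldShape = ceiling(ext / voxelSize), voxelSize = voxelSize,
              cytoplasmLevel = cytoplasmLevel, objects = do.call(rbind, objs),
              cell = list(center = ctr, semiaxes = sa), nucleus = nuc,
              objectAttenuation = objectAttenuation, seed = seed, ...)
}
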