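# Shared fixtures: small phantoms built in code.

# single fully-excluding sphere in a uniform field, pre-optics
oneSphereSpec <- function(diameter = 1.0, voxelSize = c(0.1, 0.04, 0.04),
                          margin = 0.9, seed = 1L, ...) {
  ext <- diameter + 2 * margin
  phantomSpec(fieldShape = ceiling(rep(ext, 3) / voxelSize),
              voxelSize = voxelSize,
              objects = plantedObject(1, "sphere", rep(ext / 2, 3), diameter),
              seed = seed, ...)
}

noNoise <- list(poissonGain = 0, gaussianSD = 0)

# analytic circle areas of a sphere of radius r sampled at slice offsets
circleAreas <- function(r, offsets) {
  a <- pmax(r^2 - offsets^2, 0)
  pi * a
}

# build a synthetic contour record (circle polygon) without segmentation
circleContour <- function(z, cx, cy, r, d = c(200L, 200L),
                          vs = c(0.2, 0.04, 0.04), n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  xy <- cbind(x = cx + r * cos(th), y = cy + r * sin(th))
  area <- pi * r^2
  yi <- pmax(1L, floor((cy - r) / vs[2])):pmin(d[1], ceiling((cy + r) / vs[2]))
  xi <- pmax(1L, floor((cx - r) / vs[3])):pmin(d[2], ceiling((cx + r) / vs[3]))
  gy <- (yi - 0.5) * vs[2]; gx <- (xi - 0.5) * vs[3]
  pts <- expand.grid(y = gy, x = gx)
  inside <- (pts$x - cx)^2 + (pts$y - cy)^2 <= r^2
  idx <- expand.grid(y = yi, x = xi)
  pix <- (idx$x[inside] - 1L) * d[1] + idx$y[inside]
  list(z = as.integer(z), xy = xy, area = area, centroid = c(cx, cy),
       centerIntensity = 0, peripheryIntensity = 1000, fraction = 0.925,
       level = 925, pixels = pix, npix = length(pix),
       pixelArea = vs[2] * vs[3], atBorder = FALSE, split = FALSE,
       seed = NULL)
}

# contours of a sphere sampled at z slices (dz spacing), centred at (cx, cy)
sphereContours <- function(r, centerZ, dz, nz, cx = 2, cy = 2,
                           d = c(200L, 200L), vs = NULL) {
  if (is.null(vs)) vs <- c(dz, 0.04, 0.04)
  cbs <- vector("list", nz)
  for (z in seq_len(nz)) {
    off <- (z - 0.5) * dz - centerZ
    if (abs(off) >= r) { cbs[[z]] <- list(); next }
    rr <- sqrt(r^2 - off^2)
    cbs[[z]] <- list(circleContour(z, cx, cy, rr, d, vs))
  }
  cbs
}
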