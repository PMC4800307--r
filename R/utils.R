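# Internal helpers: seeded evaluation, padded FFT convolution, 3D labelling,
# polygon geometry. Arrays are indexed (z, y, x); physical coordinates are in
# micrometres with the origin at the stack corner and voxel centres at
# (i - 0.5) * voxel_size.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's
#' RNG state afterwards.
#' @noRd
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Reflected (mirror) index mapping for padding: maps any integer position to
#' a valid index in 1..n by folding at the boundaries.
#' @noRd
reflectIndex <- function(p, n) {
  if (n == 1L) return(rep(1L, length(p)))
  period <- 2L * n
  q <- ((p - 1L) %% period + period) %% period  # 0 .. 2n-1
  ifelse(q < n, q + 1L, period - q)
}

#' Pad a 3D array by (lo, hi) voxels per axis with mirror extension.
#' @noRd
padReflect3d <- function(x, lo, hi) {
  d <- dim(x)
  iz <- reflectIndex(seq.int(1L - lo[1], d[1] + hi[1]), d[1])
  iy <- reflectIndex(seq.int(1L - lo[2], d[2] + hi[2]), d[2])
  ix <- reflectIndex(seq.int(1L - lo[3], d[3] + hi[3]), d[3])
  x[iz, iy, ix, drop = FALSE]
}

#' FFT-friendly size (products of 2, 3, 5) at least n.
#' @noRd
goodFFTSize <- function(n) {
  as.integer(stats::nextn(n, factors = c(2L, 3L, 5L)))
}

#' 3D convolution with a (small) kernel using FFTs and mirror padding.
#' Returns an array the same size as x. The kernel centre is taken at
#' ceiling(dim/2) per axis.
#' @noRd
convolve3d <- function(x, kernel, correlate = FALSE) {
  d <- dim(x)
  dk <- dim(kernel)
  if (any(dk > d)) stop("PSF kernel is larger than the image field")
  hk <- dk %/% 2L
  target <- vapply(d + 2L * hk, goodFFTSize, integer(1))
  lo <- hk
  hi <- target - d - lo
  xp <- padReflect3d(x, lo, hi)
  # embed kernel with its centre at index (1,1,1), wrapped
  kp <- array(0, dim = target)
  ctr <- (dk + 1L) %/% 2L
  iz <- ((seq_len(dk[1]) - ctr[1]) %% target[1]) + 1L
  iy <- ((seq_len(dk[2]) - ctr[2]) %% target[2]) + 1L
  ix <- ((seq_len(dk[3]) - ctr[3]) %% target[3]) + 1L
  kp[iz, iy, ix] <- kernel
  K <- stats::fft(kp)
  if (correlate) K <- Conj(K)
  out <- Re(stats::fft(stats::fft(xp) * K, inverse = TRUE)) / prod(target)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3]),
      drop = FALSE]
}

#' Label connected components of a 3D logical array (26-connectivity across
#' slices via overlap of per-slice 2D components).
#' @noRd
label3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  offset <- 0L
  nper <- integer(d[1])
  for (z in seq_len(d[1])) {
    sl <- EBImage::bwlabel(matrix(as.numeric(mask[z, , ]), d[2], d[3]))
    sl <- as.integer(sl)
    n <- max(sl)
    sl[sl > 0L] <- sl[sl > 0L] + offset
    lab[z, , ] <- sl
    nper[z] <- n
    offset <- offset + n
  }
  if (offset == 0L) return(lab)
  # union-find over z-adjacent overlapping labels
  parent <- seq_len(offset)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (z in seq_len(d[1] - 1L)) {
    a <- lab[z, , ]
    b <- lab[z + 1L, , ]
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    prs <- unique(cbind(a[sel], b[sel]))
    for (k in seq_len(nrow(prs))) {
      ra <- findRoot(prs[k, 1]); rb <- findRoot(prs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(offset), findRoot, integer(1))
  relab <- match(roots, sort(unique(roots)))
  nz <- lab > 0L
  lab[nz] <- relab[lab[nz]]
  lab
}

#' Signed area of a closed polygon (positive regardless of orientation).
#' @noRd
polygonArea <- function(xy) {
  abs(pracma::polyarea(xy[, 1], xy[, 2]))
}

#' Area centroid of a simple closed polygon.
#' @noRd
polygonCentroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

#' Maximum vertex-to-vertex distance (Feret diameter proxy).
#' @noRd
maxFeret <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  max(stats::dist(xy))
}

#' Test whether points lie inside a closed polygon.
#' @noRd
pointsInPolygon <- function(px, py, xy) {
  pracma::inpolygon(px, py, xy[, 1], xy[, 2], boundary = TRUE)
}
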