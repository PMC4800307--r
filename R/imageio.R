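# Stack and table I/O with explicit physical calibration. Stacks are
# multi-page TIFF (page order: z-major, channel-minor) with a JSON sidecar
# ("<stem>.json") carrying voxel size, channel names and the intensity
# scale; tables are plain CSV. 32-bit pages are the default: each
# write/read cycle reproduces intensities to within one step of the
# 32-bit TIFF sample grid (< 2^-31 of full scale). 16-bit export is
# available for viewer compatibility.

sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a VoxelStack to TIFF (+ JSON calibration sidecar)
#'
#' @param stack a \linkS4class{VoxelStack}.
#' @param path output TIFF path.
#' @param bits 32 (default; round-trips to < 2^-31 relative error) or 16.
#' @return invisibly, the sidecar path.
#' @export
writeStack <- function(stack, path, bits = 32L) {
  stopifnot(bits %in% c(16L, 32L))
  nz <- dim(getChannel(stack, 1L))[1]
  nc <- nChannels(stack)
  mx <- max(vapply(seq_len(nc), function(i) max(getChannel(stack, i)),
                   numeric(1)), 1e-12)
  scale <- 2^ceiling(log2(mx))  # power of two: scaling is exact
  # half-step offset compensates the TIFF writer's truncation to the
  # 2^bits - 1 sample grid, making write/read idempotent
  half <- 0.5 / (2^bits - 1)
  pages <- vector("list", nz * nc)
  k <- 0L
  for (z in seq_len(nz)) for (ch in seq_len(nc)) {
    k <- k + 1L
    p <- sliceMatrix(getChannel(stack, ch), z) / scale
    pages[[k]] <- pmin(p + half, 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  meta <- list(voxelSize = as.numeric(voxelSize(stack)),
               channelNames = channelNames(stack),
               nz = nz, nChannels = nc, scale = scale, bits = bits,
               timeIndex = stack@timeIndex)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(sidecarPath(path))
}

#' Read a VoxelStack from TIFF
#'
#' Calibration is taken from the JSON sidecar written by
#' \code{\link{writeStack}}; without a sidecar, \code{voxelSize} (and
#' \code{nChannels}) must be supplied as an override, otherwise reading
#' errors.
#'
#' @param path TIFF path.
#' @param voxelSize optional numeric(3) (dz, dy, dx) um override.
#' @param nChannels optional channel count when no sidecar exists
#'   (default 1).
#' @param channelNames optional channel names override.
#' @return a \linkS4class{VoxelStack}.
#' @export
readStack <- function(path, voxelSize = NULL, nChannels = NULL,
                      channelNames = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop("not a readable TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"),
                        ""))
  if (length(dims) != 1L) stop("z-slices of unequal shape")
  meta <- NULL
  if (file.exists(sidecarPath(path)))
    meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  if (is.null(meta) && is.null(voxelSize))
    stop("no calibration metadata for ", path,
         "; supply a voxelSize override")
  vs <- if (!is.null(voxelSize)) as.numeric(voxelSize)
        else as.numeric(meta$voxelSize)
  nc <- if (!is.null(meta)) meta$nChannels
        else if (!is.null(nChannels)) nChannels else 1L
  scale <- if (!is.null(meta)) meta$scale else 1
  cn <- if (!is.null(channelNames)) channelNames
        else if (!is.null(meta)) meta$channelNames
        else paste0("ch", seq_len(nc))
  if (length(pages) %% nc != 0L) stop("page count not divisible by channels")
  nz <- length(pages) %/% nc
  d2 <- dim(pages[[1]])[1:2]
  chans <- lapply(seq_len(nc), function(ch) {
    a <- array(0, c(nz, d2[1], d2[2]))
    for (z in seq_len(nz)) {
      p <- pages[[(z - 1L) * nc + ch]]
      if (length(dim(p)) == 3L) p <- p[, , 1]
      a[z, , ] <- p * scale
    }
    a
  })
  ti <- NA_integer_
  if (!is.null(meta) && !is.null(meta$timeIndex)) {
    tiv <- suppressWarnings(as.integer(meta$timeIndex))
    if (length(tiv) == 1L && !is.na(tiv)) ti <- tiv
  }
  VoxelStack(chans, voxelSize = vs, channelNames = cn, timeIndex = ti)
}

#' Write the organelle inventory as CSV
#'
#' One row per organelle with the fixed \code{\link{objectTable}} header,
#' in deterministic id order. Duplicate ids are an error.
#'
#' @param objects an \code{\link{objectTable}} data.frame or a list of
#'   \linkS4class{Organelle3D}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeObjectsTable <- function(objects, path) {
  tab <- if (is.data.frame(objects)) objects else objectTable(objects)
  if (anyDuplicated(tab$id)) stop("duplicate organelle ids")
  tab <- tab[order(tab$id), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read an organelle inventory CSV
#' @param path CSV path.
#' @return data.frame.
#' @export
readObjectsTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Dump per-slice contours as GeoJSON-like polygons
#'
#' One feature per contour: z index plus vertex coordinates in um, for
#' external inspection.
#'
#' @param contoursBySlice list of contour-record lists.
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
writeContoursJSON <- function(contoursBySlice, path) {
  feats <- list()
  for (ct in contoursBySlice) for (c1 in ct) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(z = c1$z, area = c1$area,
                        centerIntensity = c1$centerIntensity,
                        peripheryIntensity = c1$peripheryIntensity,
                        fraction = c1$fraction),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(apply(c1$xy, 1, as.list)))))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
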