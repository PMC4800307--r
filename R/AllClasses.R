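#' @import methods
NULL

#' VoxelStack: a calibrated multichannel confocal z-stack
#'
#' The universal image carrier of the package. Each channel is a 3D array of
#' nonnegative intensities indexed \code{(z, y, x)} with z = 1 the bottom
#' slice; \code{voxelSize} gives the physical voxel dimensions
#' \code{(dz, dy, dx)} in micrometres. Defaults elsewhere in the package
#' follow typical high-resolution confocal acquisition of negative-contrast
#' stacks: 40 x 40 nm pixels and 0.20 um z-steps for cells, 0.1 um z-steps
#' for bead fields.
#'
#' @slot data list of numeric 3D arrays, one per channel, identical dims.
#' @slot voxelSize numeric(3), (dz, dy, dx) in micrometres, all > 0.
#' @slot channelNames character, one name per channel.
#' @slot timeIndex integer(1), frame index for time-lapse series (NA when
#'   the stack is a single acquisition).
#' @export
setClass("VoxelStack",
  representation(data = "list", voxelSize = "numeric",
                 channelNames = "character", timeIndex = "integer"),
  prototype(timeIndex = NA_integer_))

setValidity("VoxelStack", function(object) {
  if (length(object@data) < 1L) return("at least one channel required")
  dims <- lapply(object@data, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("each channel must be a 3D array (z, y, x)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    return("all channels must share the same dimensions")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three strictly positive values (dz, dy, dx)")
  if (length(object@channelNames) != length(object@data))
    return("one channel name per channel required")
  mins <- vapply(object@data, min, numeric(1))
  if (any(!is.finite(mins)) || any(mins < -1e-9))
    return("intensities must be finite and nonnegative")
  TRUE
})

#' Construct a VoxelStack
#'
#' @param ... numeric 3D arrays (z, y, x), one per channel; names become
#'   channel names when \code{channelNames} is missing.
#' @param voxelSize numeric(3) voxel dimensions (dz, dy, dx) in um.
#' @param channelNames optional character vector of channel names.
#' @param timeIndex optional integer frame index.
#' @return A \linkS4class{VoxelStack}.
#' @examples
#' vs <- VoxelStack(GFP = array(1, c(4, 8, 8)), voxelSize = c(0.2, 0.04, 0.04))
#' voxelSize(vs)
#' @export
VoxelStack <- function(..., voxelSize, channelNames = NULL,
                       timeIndex = NA_integer_) {
  chans <- list(...)
  if (length(chans) == 1L && is.list(chans[[1]]) && !is.array(chans[[1]]))
    chans <- chans[[1]]
  if (is.null(channelNames)) {
    channelNames <- names(chans)
    if (is.null(channelNames) || any(!nzchar(channelNames)))
      channelNames <- paste0("ch", seq_along(chans))
  }
  chans <- lapply(chans, function(a) {
    a[a < 0] <- 0
    storage.mode(a) <- "double"
    a
  })
  new("VoxelStack", data = unname(chans), voxelSize = as.numeric(voxelSize),
      channelNames = as.character(channelNames),
      timeIndex = as.integer(timeIndex))
}

#' PSFModel: parametric or measured point spread function
#'
#' Either an anisotropic Gaussian described by lateral and axial full width
#' at half maximum (FWHM, um), or an explicit nonnegative 3D kernel that
#' sums to one. Confocal PSFs are axially elongated, which is what stretches
#' negatively stained organelles along z.
#'
#' @slot kind "gaussian" or "measured".
#' @slot fwhm numeric(2): lateral and axial FWHM in um (gaussian kind).
#' @slot kernel numeric 3D array (measured kind) or empty.
#' @export
setClass("PSFModel",
  representation(kind = "character", fwhm = "numeric", kernel = "array"),
  prototype(kernel = array(1, c(1, 1, 1))))

setValidity("PSFModel", function(object) {
  if (!object@kind %in% c("gaussian", "measured"))
    return("kind must be 'gaussian' or 'measured'")
  if (object@kind == "gaussian") {
    if (length(object@fwhm) != 2L || any(object@fwhm <= 0))
      return("gaussian PSF needs lateral and axial FWHM > 0")
  } else {
    k <- object@kernel
    if (length(dim(k)) != 3L) return("measured kernel must be 3D")
    if (any(k < 0)) return("kernel must be nonnegative")
    if (abs(sum(k) - 1) > 1e-6) return("kernel must sum to 1 (+/- 1e-6)")
  }
  TRUE
})

#' Gaussian PSF model
#'
#' @param fwhmLateral lateral FWHM in um (default 0.25, typical of a 1.4 NA
#'   oil objective at GFP wavelengths).
#' @param fwhmAxial axial FWHM in um (default 0.6).
#' @return A \linkS4class{PSFModel}.
#' @examples
#' psf <- gaussianPSF()
#' @export
gaussianPSF <- function(fwhmLateral = 0.25, fwhmAxial = 0.6) {
  new("PSFModel", kind = "gaussian",
      fwhm = c(lateral = fwhmLateral, axial = fwhmAxial))
}

#' Measured-kernel PSF model
#'
#' @param kernel nonnegative 3D array (z, y, x); normalized to sum 1.
#' @return A \linkS4class{PSFModel}.
#' @export
measuredPSF <- function(kernel) {
  s <- sum(kernel)
  if (s <= 0) stop("kernel must have positive mass")
  new("PSFModel", kind = "measured", fwhm = numeric(0), kernel = kernel / s)
}

#' CellMask: cell body and nucleus segmentation of one stack
#'
#' @slot mask logical 3D array (z, y, x): the cell body, holes filled.
#' @slot nucleus logical 3D array: nucleus subregion (all FALSE if absent).
#' @slot voxelSize numeric(3) (dz, dy, dx) um.
#' @export
setClass("CellMask",
  representation(mask = "array", nucleus = "array", voxelSize = "numeric"))

setValidity("CellMask", function(object) {
  if (!identical(dim(object@mask), dim(object@nucleus)))
    return("mask and nucleus must have identical dimensions")
  if (any(object@nucleus & !object@mask))
    return("nucleus must be contained in the cell body")
  if (any(object@voxelSize <= 0)) return("voxel sizes must be > 0")
  TRUE
})

#' Organelle3D: a z-contiguous stack of linked contours
#'
#' Built by \code{\link{linkContours}}; morphometry is provided by
#' \code{\link{laminationVolume}}, \code{\link{equivalentDiameter}} and
#' \code{\link{shapeMetrics}}.
#'
#' @slot id integer organelle id.
#' @slot contours list of per-slice contour records (see
#'   \code{\link{extractContour}}) with contiguous z indices.
#' @slot dz numeric z spacing in um.
#' @slot label character class label: "SG", "mitochondrion-like",
#'   "nuclear" or "unclassified".
#' @slot truncated logical: touches the first/last slice or the lateral
#'   image border, so its volume is an underestimate.
#' @slot markerMean numeric mean interior marker intensity (NA if no
#'   marker channel).
#' @slot markerPositive logical marker-positivity flag (NA if unset).
#' @export
setClass("Organelle3D",
  representation(id = "integer", contours = "list", dz = "numeric",
                 label = "character", truncated = "logical",
                 markerMean = "numeric", markerPositive = "logical"),
  prototype(label = "unclassified", truncated = FALSE,
            markerMean = NA_real_, markerPositive = NA))

setValidity("Organelle3D", function(object) {
  if (length(object@contours) < 1L) return("at least one contour required")
  zs <- vapply(object@contours, function(ct) ct$z, integer(1))
  if (any(diff(sort(zs)) != 1L)) return("contour z indices must be contiguous")
  if (object@dz <= 0) return("dz must be > 0")
  TRUE
})

#' CellReconstruction: the full inventory of one reconstructed cell
#'
#' @slot cellMask a \linkS4class{CellMask}.
#' @slot organelles list of \linkS4class{Organelle3D}.
#' @slot table data.frame, one row per organelle (see
#'   \code{\link{objectTable}}).
#' @slot log character vector of per-stage processing messages.
#' @slot config list: the configuration the run used (echoed for
#'   reproducibility).
#' @export
setClass("CellReconstruction",
  representation(cellMask = "CellMask", organelles = "list",
                 table = "data.frame", log = "character", config = "list"))

## ---- generics ----

#' @rdname VoxelStack-class
#' @param x,object a VoxelStack
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname VoxelStack-class
#' @export
setMethod("voxelSize", "VoxelStack", function(x) {
  stats::setNames(x@voxelSize, c("dz", "dy", "dx"))
})
#' @rdname VoxelStack-class
#' @export
setMethod("voxelSize", "CellMask", function(x) {
  stats::setNames(x@voxelSize, c("dz", "dy", "dx"))
})

#' @rdname VoxelStack-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname VoxelStack-class
#' @export
setMethod("channelNames", "VoxelStack", function(x) x@channelNames)

#' @rdname VoxelStack-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname VoxelStack-class
#' @export
setMethod("nChannels", "VoxelStack", function(x) length(x@data))

#' Extract one channel of a VoxelStack as a 3D array
#' @param x a VoxelStack
#' @param channel channel name or index
#' @return numeric 3D array (z, y, x)
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))
#' @rdname getChannel
#' @export
setMethod("getChannel", "VoxelStack", function(x, channel) {
  if (is.character(channel)) {
    i <- match(channel, x@channelNames)
    if (is.na(i)) stop("no channel named '", channel, "'")
  } else i <- as.integer(channel)
  x@data[[i]]
})

#' Replace one channel of a VoxelStack
#' @param x a VoxelStack
#' @param channel channel name or index
#' @param value 3D array with matching dimensions
#' @export
setGeneric("setChannel<-", function(x, channel, value)
  standardGeneric("setChannel<-"))
#' @rdname setChannel-set
#' @export
setMethod("setChannel<-", "VoxelStack", function(x, channel, value) {
  if (is.character(channel)) i <- match(channel, x@channelNames)
  else i <- as.integer(channel)
  value[value < 0] <- 0
  x@data[[i]] <- value
  validObject(x)
  x
})

#' Cell-body volume of a CellMask in cubic micrometres
#' @param x a CellMask or CellReconstruction
#' @export
setGeneric("cellVolume", function(x) standardGeneric("cellVolume"))
#' @rdname cellVolume
#' @export
setMethod("cellVolume", "CellMask", function(x) {
  sum(x@mask) * prod(x@voxelSize)
})
#' @rdname cellVolume
#' @export
setMethod("cellVolume", "CellReconstruction", function(x) {
  cellVolume(x@cellMask)
})

#' Organelle inventory of a CellReconstruction
#' @param x a CellReconstruction
#' @export
setGeneric("organelles", function(x) standardGeneric("organelles"))
#' @rdname organelles
#' @export
setMethod("organelles", "CellReconstruction", function(x) x@organelles)

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@data[[1]])
  cat("VoxelStack:", length(object@data), "channel(s) [",
      paste(object@channelNames, collapse = ", "), "]\n")
  cat("  dims (z,y,x):", paste(d, collapse = " x "),
      " voxel (dz,dy,dx):", paste(signif(object@voxelSize, 3), collapse = " x "),
      "um\n")
  if (!is.na(object@timeIndex)) cat("  time index:", object@timeIndex, "\n")
})

setMethod("show", "CellMask", function(object) {
  cat("CellMask: cell volume", round(cellVolume(object), 1), "um^3;",
      "nucleus voxels:", sum(object@nucleus), "\n")
})

setMethod("show", "Organelle3D", function(object) {
  cat(sprintf("Organelle3D #%d [%s]: %d contour(s), V_lam = %.3f um^3, d_eq = %.3f um\n",
              object@id, object@label, length(object@contours),
              laminationVolume(object), equivalentDiameter(object)))
})

setMethod("show", "CellReconstruction", function(object) {
  cat("CellReconstruction: cell volume", round(cellVolume(object), 1),
      "um^3;", length(object@organelles), "organelle(s) of which",
      sum(object@table$class == "SG"), "SG\n")
})
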