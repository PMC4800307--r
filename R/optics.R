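# Confocal acquisition emulation: depth/object attenuation of excitation,
# PSF blur, Poisson shot noise, Gaussian read noise. Deterministic given the
# spec seed.

#' Materialize a PSF kernel on a voxel grid
#'
#' Gaussian kernels are sampled at the voxel centres with sigma =
#' FWHM / (2 sqrt(2 ln 2)), truncated at 3 sigma per axis, and normalized
#' to sum 1.
#'
#' @param psf a \linkS4class{PSFModel}.
#' @param voxelSize numeric(3) (dz, dy, dx) um.
#' @return numeric 3D array summing to 1.
#' @export
psfKernel <- function(psf, voxelSize) {
  if (psf@kind == "measured") return(psf@kernel)
  sigma <- psf@fwhm / (2 * sqrt(2 * log(2)))   # lateral, axial
  sz <- c(sigma[2], sigma[1], sigma[1])        # (z, y, x)
  half <- pmax(1L, ceiling(3 * sz / voxelSize))
  gz <- stats::dnorm((-half[1]:half[1]) * voxelSize[1], sd = sz[1])
  gy <- stats::dnorm((-half[2]:half[2]) * voxelSize[2], sd = sz[2])
  gx <- stats::dnorm((-half[3]:half[3]) * voxelSize[3], sd = sz[3])
  k <- aperm(outer(outer(gy, gx), gz), c(3, 1, 2))
  k / sum(k)
}

#' Simulate confocal acquisition of a phantom stack
#'
#' Applies, in order: depth attenuation in the medium, excitation shadowing
#' by excluding-object material accumulated from the bottom slice upward
#' (illumination enters from the objective below), PSF convolution with a
#' unit-sum kernel under mirror padding, Poisson shot noise, and additive
#' Gaussian read noise. With attenuation and noise disabled the transform
#' conserves total intensity to within the padding approximation, and is
#' bit-reproducible for a fixed (spec, seed).
#'
#' @param stack a \linkS4class{VoxelStack} (pre-optics phantom).
#' @param psf a \linkS4class{PSFModel}.
#' @param spec the \code{\link{phantomSpec}} that produced the stack
#'   (supplies noise, attenuation and seed).
#' @param occupancy optional object-coverage array from the phantom
#'   generator, required when \code{spec$objectAttenuation > 0}.
#' @return a \linkS4class{VoxelStack} of noisy, blurred intensities.
#' @export
applyOptics <- function(stack, psf, spec, occupancy = NULL) {
  vs <- voxelSize(stack)
  kern <- psfKernel(psf, vs)
  d <- dim(getChannel(stack, 1L))
  if (any(dim(kern) > d)) stop("PSF kernel is larger than the image field")
  att <- NULL
  if (spec$objectAttenuation > 0 && !is.null(occupancy)) {
    # cumulative object thickness (um) traversed below each voxel
    thick <- apply(occupancy, c(2, 3), cumsum) # (z, y, x) after apply
    thick <- array(thick, dim = d) * vs[1]
    att <- (1 - spec$objectAttenuation)^thick
  }
  if (spec$depthAttenuation > 0) {
    zdepth <- (seq_len(d[1]) - 0.5) * vs[1]
    med <- (1 - spec$depthAttenuation)^zdepth
    medArr <- array(rep(med, times = d[2] * d[3]), dim = d)
    att <- if (is.null(att)) medArr else att * medArr
  }
  gain <- spec$noise$poissonGain
  gsd <- spec$noise$gaussianSD
  out <- withSeed(spec$seed, {
    lapply(seq_len(nChannels(stack)), function(i) {
      x <- getChannel(stack, i)
      if (!is.null(att)) x <- x * att
      x <- convolve3d(x, kern)
      x[x < 0] <- 0
      if (!is.null(gain) && gain > 0) {
        x <- array(stats::rpois(length(x), x * gain) / gain, dim = d)
      }
      if (!is.null(gsd) && gsd > 0) {
        x <- x + array(stats::rnorm(length(x), sd = gsd), dim = d)
      }
      x[x < 0] <- 0
      x
    })
  })
  VoxelStack(out, voxelSize = vs, channelNames = channelNames(stack),
             timeIndex = stack@timeIndex)
}
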