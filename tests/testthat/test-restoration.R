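test_that("PSF kernels are nonnegative and sum to one", {
  k <- psfKernel(gaussianPSF(), c(0.1, 0.04, 0.04))
  expect_true(all(k >= 0))
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_error(measuredPSF(array(-1, c(3, 3, 3))), "positive")
  km <- measuredPSF(array(1, c(3, 3, 3)))
  expect_equal(sum(km@kernel), 1, tolerance = 1e-12)
})

test_that("RL restores a blurred point source to its true location", {
  a <- array(100, c(16, 24, 24))
  a[8, 12, 12] <- 5000
  vs <- c(0.1, 0.05, 0.05)
  psf <- gaussianPSF(0.2, 0.4)
  st <- VoxelStack(GFP = nciquant:::convolve3d(a, psfKernel(psf, vs)),
                  voxelSize = vs)
  out <- deconvolveRL(st, psf, iterations = 50)
  g <- getChannel(out, 1)
  expect_equal(as.integer(which(g == max(g), arr.ind = TRUE)[1, ]),
               c(8L, 12L, 12L))
  # intensity conserved, output nonnegative
  expect_equal(sum(g), sum(getChannel(st, 1)), tolerance = 0.01)
  expect_true(all(g >= 0))
})

test_that("RL improves negative contrast of a dark sphere", {
  sp <- oneSphereSpec(1.0, noise = noNoise, objectAttenuation = 0)
  ph <- makeBeadPhantom(sp)
  blur <- applyOptics(ph$stack, gaussianPSF(), sp, occupancy = NULL)
  dec <- deconvolveRL(blur, gaussianPSF(), iterations = 20)
  ctr <- round(dim(getChannel(blur, 1)) / 2)
  cB <- getChannel(blur, 1)[ctr[1], ctr[2], ctr[3]]
  cD <- getChannel(dec, 1)[ctr[1], ctr[2], ctr[3]]
  cyt <- sp$cytoplasmLevel
  expect_gt(1 - cD / cyt, 1 - cB / cyt)  # contrast increases
})

test_that("RL residuals decrease monotonically on noiseless data", {
  sp <- oneSphereSpec(0.8, voxelSize = c(0.1, 0.06, 0.06),
                      noise = noNoise, objectAttenuation = 0)
  ph <- makeBeadPhantom(sp)
  blur <- applyOptics(ph$stack, gaussianPSF(), sp, occupancy = NULL)
  res <- rlResiduals(blur, gaussianPSF(), iterations = 8)
  expect_true(all(diff(res) < 0))
})

test_that("RL rejects invalid input", {
  a <- array(1, c(4, 8, 8))
  st <- VoxelStack(GFP = a, voxelSize = c(0.2, 0.1, 0.1))
  expect_error(deconvolveRL(st, gaussianPSF(), iterations = 0), ">= 1")
  b <- a; b[1] <- Inf
  st2 <- VoxelStack(GFP = b, voxelSize = c(0.2, 0.1, 0.1))
  expect_error(deconvolveRL(st2, gaussianPSF()), "non-finite")
})

test_that("cytoplasm level estimation excludes voids iteratively", {
  x <- array(1000, c(10, 20, 20))
  st <- VoxelStack(GFP = x, voxelSize = c(0.2, 0.1, 0.1))
  est <- estimateCytoplasmLevel(st)
  expect_equal(est$median, 1000)
  # 10% zero-intensity voids barely move the estimate
  withr::with_seed(3, {
    x2 <- x
    x2[sample(length(x2), 0.1 * length(x2))] <- 0
  })
  est2 <- estimateCytoplasmLevel(array(x2, dim(x)))
  expect_equal(est2$median, 1000, tolerance = 0.01)
  # empty and dead masks error
  expect_error(estimateCytoplasmLevel(st, array(FALSE, dim(x))), "empty")
  expect_error(estimateCytoplasmLevel(array(0, c(4, 4, 4))), "no signal")
})
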