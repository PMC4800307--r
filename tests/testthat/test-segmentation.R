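# The analytic radial profile I(r) = C (1 - exp(-(r/0.3)^2)) admits a
# closed-form contour radius: I = f C  =>  r = 0.3 sqrt(-log(1 - f)).

radialSlice <- function(C = 1000, n = 101L, dx = 0.02, r0 = 0.3) {
  ctr <- (n / 2) * dx
  xs <- (seq_len(n) - 0.5) * dx
  rr <- sqrt(outer((xs - ctr)^2, (xs - ctr)^2, "+"))
  list(slice = C * (1 - exp(-(rr / r0)^2)), ctr = ctr, dx = dx)
}

test_that("extracted contour radius matches the closed form", {
  for (f in c(0.90, 0.925, 0.95)) {
    rs <- radialSlice()
    vs <- c(0.1, rs$dx, rs$dx)
    seed <- matrix(c(51, 51), 1, dimnames = list(NULL, c("y", "x")))
    ct <- extractContour(rs$slice, c(51L, 51L), cytoplasmLevel = 1000,
                         fraction = f, voxelSize = vs)
    expect_false(is.null(ct))
    rTheory <- 0.3 * sqrt(-log(1 - f))
    rMeasured <- sqrt(ct$area / pi)
    expect_lt(abs(rMeasured - rTheory), rs$dx / 2)
  }
  # the worked constant: f = 0.925 -> r ~ 0.483 um
  expect_equal(0.3 * sqrt(-log(1 - 0.925)), 0.4828, tolerance = 1e-3)
})

test_that("contour areas are nested and monotone in the fraction", {
  rs <- radialSlice()
  vs <- c(0.1, rs$dx, rs$dx)
  areas <- vapply(c(0.90, 0.925, 0.95), function(f) {
    extractContour(rs$slice, c(51L, 51L), cytoplasmLevel = 1000,
                   fraction = f, voxelSize = vs)$area
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_error(extractContour(rs$slice, c(51L, 51L), cytoplasmLevel = 1000,
                              fraction = 0.85, voxelSize = vs),
               "0.90")
})

test_that("flat slices yield no seeds and no contours", {
  flat <- matrix(1000, 60, 60)
  vs <- c(0.1, 0.04, 0.04)
  seeds <- detectVoidSeeds(flat, NULL, 1000, vs)
  expect_identical(nrow(seeds), 0L)
  cts <- extractContours(flat, 1L, seeds, NULL, 1000, vs)
  expect_length(cts, 0L)
})

test_that("seed detection finds one seed per void and merges close minima", {
  sp <- oneSphereSpec(0.8, voxelSize = c(0.1, 0.04, 0.04),
                      noise = noNoise, objectAttenuation = 0)
  ph <- makeBeadPhantom(sp)
  blur <- applyOptics(ph$stack, gaussianPSF(), sp, occupancy = NULL)
  g <- getChannel(blur, 1)
  zc <- round(dim(g)[1] / 2)
  sl <- matrix(g[zc, , ], dim(g)[2], dim(g)[3])
  seeds <- detectVoidSeeds(sl, NULL, 1000, sp$voxelSize)
  expect_identical(nrow(seeds), 1L)
  truth <- ph$truth
  expect_lt(abs((seeds[1, "y"] - 0.5) * 0.04 - truth$cy), 0.15)
  # two spheres 2 um apart -> two seeds in the shared slice
  objs <- rbind(plantedObject(1, "sphere", c(1.2, 1.2, 1.4), 0.8),
                plantedObject(2, "sphere", c(1.2, 1.2, 3.4), 0.8))
  sp2 <- phantomSpec(fieldShape = c(24, 60, 120),
                     voxelSize = c(0.1, 0.04, 0.04), objects = objs,
                     noise = noNoise, objectAttenuation = 0)
  ph2 <- makeBeadPhantom(sp2)
  blur2 <- applyOptics(ph2$stack, gaussianPSF(), sp2, occupancy = NULL)
  sl2 <- matrix(getChannel(blur2, 1)[12, , ], 60, 120)
  seeds2 <- detectVoidSeeds(sl2, NULL, 1000, sp2$voxelSize)
  expect_identical(nrow(seeds2), 2L)
})

test_that("cell body segmentation recovers volume and flags extra blobs", {
  sp <- cellPhantomSpec(cellVolume = 400, nSG = 8, seed = 4,
                        voxelSize = c(0.2, 0.1, 0.1), noise = noNoise)
  ph <- makeCellPhantom(sp)
  st <- applyOptics(ph$stack, gaussianPSF(), sp, occupancy = ph$occupancy)
  cm <- segmentCellBody(st)
  expect_lt(abs(cellVolume(cm) - ph$cellVolume) / ph$cellVolume, 0.05)
  # nucleus found inside the cell
  expect_gt(sum(cm@nucleus), 0)
  expect_true(all(cm@mask[cm@nucleus]))
  # empty field errors
  dark <- VoxelStack(GFP = array(0, c(6, 10, 10)),
                     voxelSize = c(0.2, 0.1, 0.1))
  expect_error(segmentCellBody(dark), "no foreground")
})

test_that("largest of two cells is kept and the count is recorded", {
  # two well-separated bright ellipsoids
  dims <- c(30, 120, 200)
  vs <- c(0.2, 0.1, 0.1)
  g <- array(0, dims)
  mk1 <- nciquant:::ellipsoidCoverage(dims, vs, c(3, 6, 6), c(2.2, 4, 4))
  mk2 <- nciquant:::ellipsoidCoverage(dims, vs, c(3, 6, 14), c(1.4, 2.5, 2.5))
  g[mk1$zi, mk1$yi, mk1$xi] <- 1000 * mk1$cover
  g[mk2$zi, mk2$yi, mk2$xi] <- pmax(g[mk2$zi, mk2$yi, mk2$xi],
                                    1000 * mk2$cover)
  st <- VoxelStack(GFP = g, voxelSize = vs)
  cm <- segmentCellBody(st)
  expect_identical(attr(cm, "nComponents"), 2L)
  vol1 <- 4 / 3 * pi * 2.2 * 4 * 4
  expect_lt(abs(cellVolume(cm) - vol1) / vol1, 0.06)
})

test_that("contours stay inside the cell and open curves are discarded", {
  # void hugging the image border: its iso-curve cannot close
  sl <- matrix(1000, 50, 50)
  xs <- (seq_len(50) - 0.5) * 0.04
  rr <- sqrt(outer((xs - 0.02)^2, (xs - 1.0)^2, "+"))
  sl <- sl * (1 - pmax(1 - (rr / 0.4)^2, 0))
  seeds <- detectVoidSeeds(sl, NULL, 1000, c(0.1, 0.04, 0.04))
  expect_gt(nrow(seeds), 0L)
  expect_warning(
    cts <- extractContours(sl, 1L, seeds, NULL, 1000, c(0.1, 0.04, 0.04)),
    "border")
  expect_length(cts, 0L)
})
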