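test_that("analytic ground-truth volumes are exact", {
  sp <- oneSphereSpec(1.0)
  ph <- makeBeadPhantom(sp)
  expect_identical(nrow(ph$truth), 1L)
  expect_equal(ph$truth$volume, pi / 6, tolerance = 1e-12)
  expect_equal(ph$truth$equivDiameter, 1.0, tolerance = 1e-12)
  # cylinder and string
  sp2 <- phantomSpec(fieldShape = c(40, 40, 40), voxelSize = c(0.1, 0.1, 0.1),
                     objects = rbind(
                       plantedObject(1, "cylinder", c(2, 1, 1), 0.6,
                                     length = 2),
                       plantedObject(2, "string", c(2, 3, 3), 0.6,
                                     nBeads = 3)))
  rp <- nciquant:::groundTruthTable(sp2$objects)
  expect_equal(rp$volume[1], pi / 4 * 0.36 * 2, tolerance = 1e-12)
  expect_equal(rp$volume[2], 3 * pi / 6 * 0.6^3, tolerance = 1e-12)
})

test_that("voxelized coverage integrates to the analytic volume", {
  sp <- oneSphereSpec(1.0)
  ph <- makeBeadPhantom(sp)
  vox <- sum(ph$occupancy) * prod(sp$voxelSize)
  expect_equal(vox, pi / 6, tolerance = 2e-3)
})

test_that("bead phantom enforces isolation and validity invariants", {
  expect_error(plantedObject(1, "sphere", c(1, 1, 1), 1.0, exclusion = 1.0),
               "exclusion")
  expect_error(plantedObject(1, "sphere", c(1, 1, 1), -1), "diameter")
  # overlapping / too-close beads rejected
  objs <- rbind(plantedObject(1, "sphere", c(1.5, 1.5, 1.5), 1.0),
                plantedObject(2, "sphere", c(1.5, 1.5, 2.9), 1.0))
  sp <- phantomSpec(fieldShape = c(30, 120, 120),
                    voxelSize = c(0.1, 0.04, 0.04), objects = objs)
  expect_error(makeBeadPhantom(sp), "closer than one bead diameter")
  # centers outside field rejected
  expect_error(phantomSpec(fieldShape = c(10, 10, 10),
                           voxelSize = c(0.1, 0.1, 0.1),
                           objects = plantedObject(1, "sphere",
                                                   c(5, 1, 1), 0.5)),
               "inside the field")
})

test_that("a 12-bead field matches the planted inventory", {
  sp <- beadFieldSpec(12, 1.0, seed = 7)
  ph <- makeBeadPhantom(sp)
  expect_identical(nrow(ph$truth), 12L)
  expect_true(all(ph$truth$diameter == 1.0))
  expect_true(all(ph$truth$markerPositive))
})

test_that("cell phantom echoes geometry and rejects escapees", {
  sp <- cellPhantomSpec(cellVolume = 500, nSG = 12, seed = 2,
                        voxelSize = c(0.2, 0.1, 0.1))
  ph <- makeCellPhantom(sp)
  expect_identical(nrow(ph$truth), 12L)
  expect_equal(ph$cellVolume, 500, tolerance = 1e-9)
  # GFP ~ 0 outside the cell, ~cytoplasm inside
  g <- getChannel(ph$stack, "GFP")
  expect_equal(g[1, 1, 1], 0)
  ctr <- round(dim(g) / 2)
  # marker-negative subset is honoured
  sp2 <- cellPhantomSpec(cellVolume = 500, nSG = 20, markerFraction = 0.8,
                         seed = 3, voxelSize = c(0.2, 0.1, 0.1))
  ph2 <- makeCellPhantom(sp2)
  expect_identical(sum(!ph2$truth$markerPositive), 4L)
  # object outside the cell body errors
  bad <- sp
  bad$objects$cy[1] <- 0.2
  expect_error(makeCellPhantom(bad), "outside the cell body")
})

test_that("planted SG counts correlate with cell volume across a cohort", {
  vols <- seq(400, 1000, length.out = 7)
  counts <- vapply(seq_along(vols), function(i) {
    sp <- cellPhantomSpec(cellVolume = vols[i], nSG = round(vols[i] / 25),
                          seed = 10 + i, voxelSize = c(0.2, 0.1, 0.1))
    nrow(makeCellPhantom(sp)$truth)
  }, numeric(1))
  expect_gt(cor(vols, counts), 0.95)
})

test_that("acquisition simulation is conservative, deterministic and blurs", {
  sp <- oneSphereSpec(1.0, noise = noNoise)
  ph <- makeBeadPhantom(sp)
  # delta PSF + no noise = identity
  delta <- measuredPSF(array(1, c(1, 1, 1)))
  out <- applyOptics(ph$stack, delta, sp, occupancy = NULL)
  expect_equal(getChannel(out, 1), getChannel(ph$stack, 1), tolerance = 1e-12)
  # unit-sum kernel conserves total intensity within 1%
  spNoAtt <- oneSphereSpec(1.0, noise = noNoise, objectAttenuation = 0)
  phNA <- makeBeadPhantom(spNoAtt)
  blur <- applyOptics(phNA$stack, gaussianPSF(), spNoAtt, occupancy = NULL)
  expect_equal(sum(getChannel(blur, 1)), sum(getChannel(phNA$stack, 1)),
               tolerance = 0.01)
  # determinism: same (spec, seed) twice -> identical stacks
  spN <- oneSphereSpec(1.0, seed = 42)
  phN <- makeBeadPhantom(spN)
  a <- applyOptics(phN$stack, gaussianPSF(), spN, occupancy = phN$occupancy)
  b <- applyOptics(phN$stack, gaussianPSF(), spN, occupancy = phN$occupancy)
  expect_identical(getChannel(a, 1), getChannel(b, 1))
  # kernel larger than field errors
  small <- phantomSpec(fieldShape = c(4, 6, 6), voxelSize = c(0.1, 0.04, 0.04),
                       objects = plantedObject(1, "sphere",
                                               c(0.2, 0.12, 0.12), 0.1))
  phS <- makeBeadPhantom(small)
  expect_error(applyOptics(phS$stack, gaussianPSF(), small), "larger than")
})

test_that("blurred dark sphere keeps a deep but nonzero centre", {
  # independent oracle: direct kernel-weighted sum at the centre voxel
  sp <- oneSphereSpec(1.0, noise = noNoise, objectAttenuation = 0)
  ph <- makeBeadPhantom(sp)
  psf <- gaussianPSF(0.25, 0.6)
  blur <- applyOptics(ph$stack, psf, sp, occupancy = NULL)
  g <- getChannel(blur, 1)
  ctr <- round(dim(g) / 2)
  kern <- psfKernel(psf, sp$voxelSize)
  x <- getChannel(ph$stack, 1)
  hk <- dim(kern) %/% 2L
  sub <- x[ctr[1] + (-hk[1]:hk[1]), ctr[2] + (-hk[2]:hk[2]),
           ctr[3] + (-hk[3]:hk[3])]
  oracle <- sum(rev(kern) * sub)  # symmetric kernel: plain weighted sum
  expect_equal(g[ctr[1], ctr[2], ctr[3]], oracle, tolerance = 0.02 * 1000)
  expect_gt(g[ctr[1], ctr[2], ctr[3]], 0)
  expect_lt(g[ctr[1], ctr[2], ctr[3]], 0.5 * sp$cytoplasmLevel)
})
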