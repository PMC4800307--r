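test_that("lamination volume matches the hand-computed slab oracle", {
  # r = 0.5 um sphere sampled at slice offsets 0, +/-0.2, +/-0.4:
  # areas pi (0.25 - z^2) = 0.7854, 0.6597 x2, 0.2827 x2 -> V = 0.2 x 2.6702
  offsets <- c(-0.4, -0.2, 0, 0.2, 0.4)
  areas <- circleAreas(0.5, offsets)
  expect_equal(round(areas[3], 4), 0.7854)
  expect_equal(round(areas[2], 4), 0.6597)
  expect_equal(round(areas[1], 4), 0.2827)
  cbs <- sphereContours(0.5, centerZ = 0.5, dz = 0.2, nz = 5)
  orgs <- linkContours(cbs, 0.2)
  expect_length(orgs, 1L)
  # hand-computed: 0.2 x 2.6702 = 0.5340 (4-decimal intermediates)
  expect_lt(abs(laminationVolume(orgs[[1]]) - 0.5340), 1e-4)
  expect_equal(laminationVolume(orgs[[1]]), 0.2 * sum(areas),
               tolerance = 1e-3)
  # slab bias vanishes as dz -> 0: within 1% of (pi/6) at dz = 0.02
  cbs2 <- sphereContours(0.5, centerZ = 0.5, dz = 0.02, nz = 50)
  orgs2 <- linkContours(cbs2, 0.02)
  expect_lt(abs(laminationVolume(orgs2[[1]]) - pi / 6) / (pi / 6), 0.01)
})

test_that("lamination volume is linear in dz and in contour areas", {
  ct <- circleContour(1, 2, 2, 0.4)
  org <- linkContours(list(list(ct)), 0.2)[[1]]
  expect_equal(laminationVolume(org), 0.2 * pi * 0.4^2, tolerance = 1e-6)
  expect_equal(laminationVolume(org, dz = 0.4),
               2 * laminationVolume(org), tolerance = 1e-12)
  expect_equal(equivalentDiameter(org),
               (6 * laminationVolume(org) / pi)^(1 / 3), tolerance = 1e-12)
})

test_that("linking joins overlapping contours and separates distant ones", {
  # sphere d = 1.0 at dz = 0.2 centred on a slice -> 5 contours, 1 organelle
  cbs <- sphereContours(0.5, centerZ = 0.9, dz = 0.2, nz = 9)
  expect_identical(sum(vapply(cbs, length, integer(1))), 5L)
  orgs <- linkContours(cbs, 0.2)
  expect_length(orgs, 1L)
  expect_length(orgs[[1]]@contours, 5L)
  # two spheres 3 um apart laterally -> 2 organelles
  cbsA <- sphereContours(0.4, centerZ = 0.9, dz = 0.2, nz = 9, cx = 2, cy = 2)
  cbsB <- sphereContours(0.4, centerZ = 0.9, dz = 0.2, nz = 9, cx = 5, cy = 2)
  both <- lapply(seq_len(9), function(z) c(cbsA[[z]], cbsB[[z]]))
  expect_length(linkContours(both, 0.2), 2L)
  # string of 3 touching spheres along z -> 1 organelle (phantom route:
  # the blurred neck keeps slice-to-slice contours overlapping)
  sp <- phantomSpec(fieldShape = c(40, 50, 50),
                    voxelSize = c(0.1, 0.04, 0.04),
                    objects = plantedObject(1, "string", c(2, 1, 1), 0.8,
                                            nBeads = 3),
                    noise = noNoise, objectAttenuation = 0)
  ph <- nciquant:::renderPhantom(sp)
  blur <- applyOptics(ph$stack, gaussianPSF(), sp, occupancy = NULL)
  g <- getChannel(blur, 1)
  cbs3 <- lapply(seq_len(40), function(z) {
    sl <- matrix(g[z, , ], 50, 50)
    seeds <- detectVoidSeeds(sl, NULL, 1000, sp$voxelSize)
    extractContours(sl, z, seeds, NULL, 1000, sp$voxelSize, binarize = TRUE)
  })
  orgs3 <- linkContours(cbs3, 0.1, nz = 40)
  expect_length(orgs3, 1L)
  expect_gt(shapeMetrics(orgs3[[1]])$elongation, 1.5)
})

test_that("linking is symmetric under slice-order reversal", {
  cbs <- sphereContours(0.5, centerZ = 0.9, dz = 0.2, nz = 9)
  fwd <- linkContours(cbs, 0.2)
  rev_ <- lapply(rev(cbs), function(ct) {
    lapply(ct, function(c1) { c1$z <- 10L - c1$z; c1 })
  })
  bwd <- linkContours(rev_, 0.2)
  expect_identical(length(fwd), length(bwd))
  sig <- function(orgs) sort(vapply(orgs, function(o)
    round(laminationVolume(o), 9), numeric(1)))
  expect_identical(sig(fwd), sig(bwd))
})

test_that("shape metrics separate spheres from tubes", {
  cbs <- sphereContours(0.5, centerZ = 1.1, dz = 0.2, nz = 11)
  org <- linkContours(cbs, 0.2)[[1]]
  sm <- shapeMetrics(org)
  expect_lt(abs(sm$elongation - 1), 0.25)
  # z-cylinder, length 2 um, d 0.6 -> elongation ~ 2 / 0.6
  cyl <- lapply(seq_len(10), function(z) list(circleContour(z, 2, 2, 0.3)))
  co <- linkContours(cyl, 0.2)[[1]]
  smc <- shapeMetrics(co)
  expect_equal(smc$elongation, 2 / 0.6, tolerance = 0.05)
  expect_equal(smc$zExtent, 2, tolerance = 1e-9)
  # single-contour object: z extent is the slice floor, flagged thin
  one <- linkContours(list(list(circleContour(1, 2, 2, 0.3))), 0.2)[[1]]
  expect_true(shapeMetrics(one)$thin)
  expect_equal(shapeMetrics(one)$zExtent, 0.2)
})

test_that("compartment classification follows the rules", {
  d <- c(20L, 60L, 60L)
  vs <- c(0.2, 0.1, 0.1)
  nucleus <- array(FALSE, d)
  nucleus[5:15, 20:40, 20:40] <- TRUE
  mask <- array(TRUE, d)
  cm <- new("CellMask", mask = mask, nucleus = nucleus, voxelSize = vs)
  # 0.8-um cytoplasmic sphere -> SG
  sph <- linkContours(sphereContours(0.4, centerZ = 0.5, dz = 0.2, nz = 20,
                                     cx = 0.5, cy = 0.5, d = d[2:3],
                                     vs = vs), 0.2)[[1]]
  expect_identical(classifyCompartment(sph, cm), "SG")
  # same shape centred in the nucleus -> nuclear
  nucSph <- linkContours(sphereContours(0.4, centerZ = 2.0, dz = 0.2,
                                        nz = 20, cx = 3, cy = 3, d = d[2:3],
                                        vs = vs), 0.2)[[1]]
  expect_identical(classifyCompartment(nucSph, cm), "nuclear")
  # 0.3 x 2.0 um tube -> mitochondrion-like
  tube <- linkContours(lapply(seq_len(10), function(z)
    list(circleContour(z, 0.5, 0.5, 0.15, d = d[2:3], vs = vs))), 0.2)[[1]]
  expect_identical(classifyCompartment(tube, cm), "mitochondrion-like")
  # oversized void -> unclassified
  big <- linkContours(sphereContours(1.2, centerZ = 2.4, dz = 0.2, nz = 24,
                                     cx = 0.8, cy = 3, d = d[2:3],
                                     vs = vs), 0.2)[[1]]
  expect_identical(classifyCompartment(big, cm), "unclassified")
})

test_that("objectTable carries the inventory with unique ordered ids", {
  cbsA <- sphereContours(0.4, centerZ = 0.9, dz = 0.2, nz = 9, cx = 2)
  cbsB <- sphereContours(0.3, centerZ = 0.9, dz = 0.2, nz = 9, cx = 5)
  both <- lapply(seq_len(9), function(z) c(cbsA[[z]], cbsB[[z]]))
  tab <- objectTable(linkContours(both, 0.2))
  expect_identical(tab$id, seq_len(nrow(tab)))
  expect_true(all(tab$volumeLamination > 0))
  expect_true(all(abs(tab$volumeVoxel - tab$volumeLamination) /
                    tab$volumeLamination < 0.2))
})

test_that("contours touching the first or last slice flag truncation", {
  cbs <- sphereContours(0.5, centerZ = 0.3, dz = 0.2, nz = 6)
  org <- linkContours(cbs, 0.2, nz = 6)[[1]]
  expect_true(org@truncated)
  cbs2 <- sphereContours(0.4, centerZ = 0.7, dz = 0.2, nz = 8)
  expect_false(linkContours(cbs2, 0.2, nz = 8)[[1]]@truncated)
})
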