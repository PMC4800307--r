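mkFrame <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[1], centroidX = r[2], centroidY = r[3],
               centroidZ = r[4], volumeLamination = r[5],
               equivDiameter = (6 * r[5] / pi)^(1 / 3),
               markerMean = r[6])
  }))
}

test_that("size distribution bins volumes and stratifies by cell size", {
  sd1 <- sizeDistribution(c(0.41, 1.32), breaks = c(0, 1, 2))
  expect_identical(sd1$counts, c(1L, 1L))
  expect_identical(sd1$n, 2L)
  # all-equal volumes occupy a single bin
  sd2 <- sizeDistribution(rep(0.7, 25), breaks = seq(0, 2, 0.25))
  expect_identical(sum(sd2$counts > 0), 1L)
  expect_identical(sum(sd2$counts), sd2$n)
  # planted log-normal volumes: histogram median within 10% of truth
  withr::with_seed(11, vols <- rlnorm(1000, log(0.5), 0.4))
  sd3 <- sizeDistribution(vols, breaks = 40)
  expect_lt(abs(sd3$median - 0.5) / 0.5, 0.10)
  # small/large stratification by the 1,500 / 2,500 um^3 cutoffs
  cv <- rep(c(1000, 3000), each = 500)
  sd4 <- sizeDistribution(vols, breaks = 40, cellVolumes = cv)
  expect_length(sd4$strata$small, 500L)
  expect_length(sd4$strata$large, 500L)
  expect_error(sizeDistribution(numeric(0)), "no SG")
})

test_that("cell volume vs SG count correlation recovers planted slopes", {
  vols <- seq(1000, 4000, length.out = 7)
  res <- cellSgCorrelation(vols, 0.5 * vols, seed = 1)
  expect_equal(res$r, 1.0, tolerance = 1e-12)
  expect_equal(res$slope, 0.5, tolerance = 1e-9)
  expect_identical(res$n, 7L)
  # independent counts: |r| < 0.5 with high probability at n = 20
  withr::with_seed(5, {
    v <- runif(20, 1000, 4000)
    k <- rpois(20, 60)
  })
  res2 <- cellSgCorrelation(v, k, seed = 2)
  expect_lt(abs(res2$r), 0.5)
  # planted slope lies inside the bootstrap CI on a noisy linear cohort
  withr::with_seed(7, {
    v3 <- runif(15, 1000, 4000)
    k3 <- rpois(15, 0.3 * v3)
  })
  res3 <- cellSgCorrelation(v3, k3, seed = 3)
  expect_gt(res3$r, 0.9)
  expect_true(res3$ciSlope[1] <= 0.3 && 0.3 <= res3$ciSlope[2])
  expect_error(cellSgCorrelation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("marker colocalization recovers the planted marked fraction", {
  sp <- cellPhantomSpec(cellVolume = 350, nSG = 10, markerFraction = 0.8,
                        sgDiameter = c(0.6, 0.9), seed = 21,
                        nucleus = FALSE, voxelSize = c(0.2, 0.1, 0.1))
  ph <- makeCellPhantom(sp)
  cfg <- nciConfig(deconvolve = FALSE, seed = 21)
  rec <- runPipeline(ph, cfg)
  tab <- rec@table[rec@table$class == "SG", ]
  expect_identical(nrow(tab), 10L)
  expect_equal(mean(tab$markerPositive), 0.8, tolerance = 0.051)
  # all-zero marker channel -> fraction 0
  st <- ph$stack
  setChannel(st, "marker") <- array(0, dim(getChannel(st, 1)))
  mc <- markerColocalization(rec@organelles, st, "marker", rec@cellMask)
  expect_identical(mc$positiveFraction, 0)
  # missing marker channel errors
  solo <- VoxelStack(GFP = getChannel(st, 1), voxelSize = voxelSize(st))
  expect_error(markerColocalization(rec@organelles, solo, "marker"),
               "missing marker channel")
})

test_that("tracking follows objects within the gate and breaks beyond it", {
  f1 <- mkFrame(c(1, 2, 2, 1, 0.3, 0), c(2, 5, 5, 1, 0.2, 400))
  # static: every track spans all frames
  tr <- trackObjects(list(f1, f1, f1))
  expect_equal(as.integer(table(tr$track)), c(3L, 3L))
  # 0.3 um/frame drift: one continuous track
  f2 <- mkFrame(c(1, 2.3, 2, 1, 0.3, 0))
  f3 <- mkFrame(c(1, 2.6, 2, 1, 0.3, 0))
  tr2 <- trackObjects(list(mkFrame(c(1, 2, 2, 1, 0.3, 0)), f2, f3))
  expect_identical(length(unique(tr2$track)), 1L)
  # 5 um/frame exceeds the gate: the track breaks
  f4 <- mkFrame(c(1, 7, 2, 1, 0.3, 0))
  tr3 <- trackObjects(list(mkFrame(c(1, 2, 2, 1, 0.3, 0)), f4))
  expect_identical(length(unique(tr3$track)), 2L)
  expect_error(trackObjects(list(f1)), "at least 2")
})

test_that("fusion detection flags scheduled events with correct ratios", {
  # two equal granules stacked along z, one marked; they fuse at frame 3
  fA <- mkFrame(c(1, 2, 2, 1.5, 0.27, 600), c(2, 2, 2, 2.7, 0.27, 0))
  fB <- mkFrame(c(1, 2, 2, 1.7, 0.27, 600), c(2, 2, 2, 2.5, 0.27, 0))
  fC <- mkFrame(c(3, 2, 2, 2.1, 0.54, 300))
  fD <- fC
  tr <- trackObjects(list(fA, fB, fC, fD))
  ev <- detectFusionEvents(tr)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$conservationRatio, 1.0, tolerance = 1e-9)
  expect_equal(ev$dilutionRatio, 0.5, tolerance = 1e-9)
  expect_lt(ev$angleToZ, 30)
  # no fusion scheduled -> no events
  tr0 <- trackObjects(list(fA, fA, fA))
  expect_identical(nrow(detectFusionEvents(tr0)), 0L)
  # volume not conserved -> no event
  fBad <- mkFrame(c(3, 2, 2, 2.1, 1.2, 300))
  trB <- trackObjects(list(fA, fB, fBad))
  expect_identical(nrow(detectFusionEvents(trB)), 0L)
})

test_that("scheduled fusion phantoms conserve volume and dilute marker", {
  objs <- rbind(plantedObject(1, "sphere", c(1.5, 1.3, 1.3), 0.8,
                              markerLevel = 600),
                plantedObject(2, "sphere", c(2.9, 1.3, 1.3), 0.8))
  sp <- phantomSpec(fieldShape = c(44, 52, 52),
                    voxelSize = c(0.1, 0.05, 0.05), objects = objs,
                    noise = noNoise, objectAttenuation = 0, seed = 9)
  sched <- data.frame(frame = 3L, parent1 = 1L, parent2 = 2L, child = 3L)
  tl <- makeTimelapseFusion(sp, sched, nFrames = 4)
  expect_length(tl$frames, 4L)
  # parents present before, child after, volume conserved exactly in truth
  expect_identical(nrow(tl$frames[[2]]$truth), 2L)
  expect_identical(nrow(tl$frames[[3]]$truth), 1L)
  vParents <- sum(tl$frames[[1]]$truth$volume)
  expect_equal(tl$frames[[4]]$truth$volume, vParents, tolerance = 1e-9)
  # per-volume marker halves (1:1 marked/unmarked parents)
  expect_equal(tl$truth$schedule$dilutionRatio, 0.5, tolerance = 1e-12)
  # child is elongated along z
  expect_identical(which.max(tl$frames[[3]]$spec$objects[1,
                     c("saz", "say", "sax")][1, ] |> as.numeric()), 1L)
  # empty schedule -> static series
  tl0 <- makeTimelapseFusion(sp, sched[0, ], nFrames = 3)
  expect_identical(tl0$frames[[1]]$truth$cz, tl0$frames[[3]]$truth$cz)
  # distant parents cannot reach each other -> not adjacent -> error
  far <- rbind(plantedObject(1, "sphere", c(1.0, 0.8, 0.8), 0.6),
               plantedObject(2, "sphere", c(3.8, 1.8, 1.8), 0.6,
                             markerLevel = 500))
  spF <- phantomSpec(fieldShape = c(44, 52, 52),
                     voxelSize = c(0.1, 0.05, 0.05), objects = far,
                     noise = noNoise, seed = 2)
  expect_error(makeTimelapseFusion(spF, sched, nFrames = 3),
               "not adjacent")
})
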