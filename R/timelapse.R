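# Time-lapse phantoms with scheduled granule-granule fusion. Fusion
# conserves combined volume, pools the parents' marker content into the
# child (so per-unit-volume marker fluorescence is diluted), and elongates
# the child along the approach axis.

#' Generate a time-lapse fusion phantom
#'
#' Frames before a scheduled event contain both parent granules, moving
#' toward surface contact along the line between their centres while their
#' pooled (volume-weighted) centroid stays fixed; frames from the event on
#' contain a single child whose volume is the sum of the parents' volumes,
#' whose per-unit-volume marker intensity equals the pooled marker content
#' divided by the combined volume, and which is elongated (axis ratio 1.6)
#' along the approach axis.
#'
#' @param spec a \code{\link{phantomSpec}} whose objects are the frame-1
#'   granules (spheres).
#' @param schedule data.frame with columns \code{frame} (first frame showing
#'   the fused child), \code{parent1}, \code{parent2}, \code{child} (ids).
#'   An empty schedule yields a static series.
#' @param nFrames number of frames.
#' @param maxStep maximum allowed parent displacement per frame in um;
#'   parents whose approach would exceed it are rejected as not adjacent at
#'   the fusion frame.
#' @param preFusionGap surface-to-surface clearance (um) the parents keep
#'   at their closest pre-fusion approach (default 0.4, just above the
#'   axial resolution, so the two voids remain separable until they fuse).
#' @return list(frames = list of phantom scenes (stack, truth, occupancy,
#'   spec) with \code{timeIndex} set, truth = list(objects = per-frame
#'   ground-truth table, schedule = schedule with expected child marker
#'   level, dilution ratio and approach axis)).
#' @export
makeTimelapseFusion <- function(spec, schedule, nFrames = 4L,
                                maxStep = 1.0, preFusionGap = 0.4) {
  obj0 <- spec$objects
  if (!all(obj0$shape == "sphere"))
    stop("fusion phantoms take sphere objects")
  if (nrow(schedule)) {
    ids <- c(schedule$parent1, schedule$parent2)
    if (anyDuplicated(ids) || any(!ids %in% obj0$id))
      stop("schedule parents must be distinct existing object ids")
    if (any(schedule$frame < 2L) || any(schedule$frame > nFrames))
      stop("fusion frames must lie in 2..nFrames")
  }
  vols <- pi / 6 * obj0$diameter^3
  names(vols) <- obj0$id
  # per-event geometry
  events <- NULL
  if (nrow(schedule)) {
    events <- lapply(seq_len(nrow(schedule)), function(k) {
      ev <- schedule[k, ]
      p1 <- obj0[obj0$id == ev$parent1, ]
      p2 <- obj0[obj0$id == ev$parent2, ]
      v1 <- pi / 6 * p1$diameter^3; v2 <- pi / 6 * p2$diameter^3
      c1 <- c(p1$cz, p1$cy, p1$cx); c2 <- c(p2$cz, p2$cy, p2$cx)
      axis <- c2 - c1
      nrm <- sqrt(sum(axis^2))
      if (nrm < 1e-9) stop("parents coincide")
      axis <- axis / nrm
      centroid <- (v1 * c1 + v2 * c2) / (v1 + v2)
      touch <- (p1$diameter + p2$diameter) / 2 + preFusionGap
      # final parent positions: surface contact, pooled centroid fixed
      f1 <- centroid - axis * touch * v2 / (v1 + v2)
      f2 <- centroid + axis * touch * v1 / (v1 + v2)
      steps <- max(ev$frame - 2L, 1L)
      travel <- max(sqrt(sum((f1 - c1)^2)), sqrt(sum((f2 - c2)^2))) / steps
      if (travel > maxStep)
        stop("parents ", ev$parent1, "/", ev$parent2,
             " are not adjacent at the fusion frame (required step ",
             round(travel, 2), " um > ", maxStep, " um)")
      mPooled <- (p1$markerLevel * v1 + p2$markerLevel * v2) / (v1 + v2)
      vTot <- v1 + v2
      elong <- 1.6
      a <- (3 * vTot / (4 * pi * elong))^(1 / 3)
      semi <- rep(a, 3)
      semi[which.max(abs(axis))] <- a * elong
      parentPerVol <- c(p1$markerLevel, p2$markerLevel)
      dil <- if (sum(parentPerVol > 0) == 1L)
        mPooled / max(parentPerVol) else NA_real_
      list(row = ev, v1 = v1, v2 = v2, c1 = c1, c2 = c2, f1 = f1, f2 = f2,
           axis = axis, centroid = centroid, markerChild = mPooled,
           semiaxes = semi, dilution = dil)
    })
  }
  frames <- vector("list", nFrames)
  perFrame <- vector("list", nFrames)
  for (t in seq_len(nFrames)) {
    objs <- obj0
    for (evg in events) {
      ev <- evg$row
      pidx <- objs$id %in% c(ev$parent1, ev$parent2)
      if (t < ev$frame) {
        # linear approach over frames 1 .. frame-1
        steps <- max(ev$frame - 2L, 1L)
        s <- min((t - 1) / steps, 1)
        p1 <- evg$c1 + s * (evg$f1 - evg$c1)
        p2 <- evg$c2 + s * (evg$f2 - evg$c2)
        objs[objs$id == ev$parent1, c("cz", "cy", "cx")] <- as.list(p1)
        objs[objs$id == ev$parent2, c("cz", "cy", "cx")] <- as.list(p2)
      } else {
        objs <- objs[!pidx, ]
        child <- plantedObject(ev$child, "ellipsoid", evg$centroid,
                               semiaxes = evg$semiaxes,
                               markerLevel = evg$markerChild)
        objs <- rbind(objs, child)
      }
    }
    fspec <- spec
    fspec$objects <- objs
    fspec$seed <- spec$seed + t
    rp <- renderPhantom(fspec)
    st <- rp$stack
    st@timeIndex <- as.integer(t)
    tt <- groundTruthTable(objs)
    tt$frame <- t
    frames[[t]] <- list(stack = st, truth = tt, occupancy = rp$occupancy,
                        spec = fspec)
    perFrame[[t]] <- tt
  }
  sched <- schedule
  if (nrow(schedule)) {
    sched$childMarkerLevel <- vapply(events, `[[`, numeric(1), "markerChild")
    sched$dilutionRatio <- vapply(events, `[[`, numeric(1), "dilution")
    ax <- t(vapply(events, `[[`, numeric(3), "axis"))
    sched$axisZ <- ax[, 1]; sched$axisY <- ax[, 2]; sched$axisX <- ax[, 3]
  }
  list(frames = frames,
       truth = list(objects = do.call(rbind, perFrame), schedule = sched))
}
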