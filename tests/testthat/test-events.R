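test_that("cycle anchors locate peaks, nadirs and the suspended rise", {
  # triangular transient rising 0 -> 100 over frames 10 -> 20, then falling
  fa <- c(rep(0, 10), seq(0, 100, by = 10), seq(90, 0, by = -10), rep(0, 5))
  an <- cycleAnchors(fa, 50)
  expect_equal(an$peaks, 20)
  expect_equal(an$nadirs, 0)
  expect_equal(an$suspended, 15:20)        # the >= 50% half of the rise
  # boundary cutoffs
  expect_equal(cycleAnchors(fa, 100)$suspended, 20)
  expect_equal(cycleAnchors(fa, 0)$suspended, 0:20)
  expect_error(cycleAnchors(rep(5, 50), 50), "no transient peak")
})

test_that("two-cycle anchors alternate and bound each suspension at a peak", {
  fa <- rep(c(rep(2, 20), seq(2, 82, length.out = 5),
              seq(82, 2, length.out = 25)), 2)
  an <- cycleAnchors(fa, 20)
  expect_length(an$peaks, 2)
  expect_length(an$nadirs, 2)
  expect_true(all(an$nadirs < an$peaks))
  for (i in 1:2)
    expect_true(max(an$suspended[an$suspended <= an$peaks[i]]) ==
                  an$peaks[i])
})

simpleConfig <- function(...) runConfig(size_threshold = 4,
                                        intensity_threshold = 10, ...)

# drive trackEvents with hand-built clusters over a tiny grid
clusterOf <- function(px, fnt_frame, eligible = TRUE) {
  list(pixels = px, size = length(px), intensity = sum(fnt_frame[px]),
       birth_eligible = eligible)
}

test_that("an event dies by stochastic attrition when its signal decays", {
  H <- 8; W <- 8; T <- 6
  fnt <- array(0, dim = c(H, W, T))
  px <- as.integer(outer((2:4) * H, 2:4, "+"))   # 3x3 block
  for (t in 2:4) fnt[, , t][px] <- 10
  cl <- rep(list(list()), T)
  for (t in 2:4) cl[[t]] <- list(clusterOf(px, fnt[, , t]))
  ev <- trackEvents(cl, fnt, sigma_cell = 1, simpleConfig(), anchors = NULL)
  expect_length(ev, 1)
  e <- ev[[1]]
  expect_true(e$dead)
  expect_equal(e$mode, "stochastic_attrition")
  expect_equal(e$birth, 1L)
  expect_equal(e$death, 4L)   # elevation gone at frame 4
})

test_that("a surviving event at a suspended frame dies by transient", {
  H <- 8; W <- 8; T <- 6
  fnt <- array(0, dim = c(H, W, T))
  px <- as.integer(outer((2:4) * H, 2:4, "+"))
  for (t in 2:T) fnt[, , t][px] <- 10
  cl <- rep(list(list()), T)
  for (t in 2:T) cl[[t]] <- list(clusterOf(px, fnt[, , t]))
  anchors <- list(peaks = 5L, nadirs = 0L, suspended = 4L)
  ev <- trackEvents(cl, fnt, 1, simpleConfig(), anchors)
  e <- ev[[1]]
  expect_true(e$dead)
  expect_equal(e$mode, "transient")
  expect_equal(e$death, 4L)
})

test_that("an event alive at the last frame stays open with dead = FALSE", {
  H <- 8; W <- 8; T <- 4
  fnt <- array(0, dim = c(H, W, T))
  px <- as.integer(outer((2:4) * H, 2:4, "+"))
  for (t in 2:T) fnt[, , t][px] <- 10
  cl <- rep(list(list()), T)
  for (t in 2:T) cl[[t]] <- list(clusterOf(px, fnt[, , t]))
  ev <- trackEvents(cl, fnt, 1, simpleConfig(), NULL)
  fin <- finalizeEvents(ev, NULL, fnt, T)
  r <- fin$records
  expect_false(r$dead)
  expect_false(any(as.logical(r[, c("dead_by_collision", "dead_by_transient",
                                    "dead_by_stochastic_attrition")])))
  expect_equal(r$duration_frames, 3L)      # frames 1..3 inclusive
})

test_that("collision keeps the largest event; ties go to the lower id", {
  H <- 10; W <- 12; T <- 4
  fnt <- array(0, dim = c(H, W, T))
  pxA <- as.integer(outer((1:3) * H, 2:5, "+"))    # 12 px
  pxB <- pix(7:8, rep(6, 2), H)                    # 2 px, clearly smaller
  bridge <- sort(unique(c(pxA, pxB,
                          pix(4:6, rep(4, 3), H))))  # connects A and B
  for (t in 2:3) { fnt[, , t][pxA] <- 10; fnt[, , t][pxB] <- 10 }
  fnt[, , 4][bridge] <- 10
  cl <- rep(list(list()), T)
  cl[[2]] <- list(clusterOf(pxA, fnt[, , 2]), clusterOf(pxB, fnt[, , 2]))
  cl[[3]] <- cl[[2]]
  cl[[4]] <- list(clusterOf(bridge, fnt[, , 4]))
  ev <- trackEvents(cl, fnt, 1, simpleConfig(), NULL)
  expect_length(ev, 2)
  modes <- vapply(ev, `[[`, character(1), "mode")
  expect_identical(sort(modes), c("collision", "none"))
  dead <- ev[[which(modes == "collision")]]
  surv <- ev[[which(modes == "none")]]
  expect_equal(dead$death, 3L)
  expect_lt(length(dead$pixelsByFrame[["2"]]),
            length(surv$pixelsByFrame[["2"]]))
  # the survivor incorporates the bridged pixels
  expect_true(all(bridge %in% surv$pixelsByFrame[["3"]]))
})

test_that("a size tie in a collision is resolved toward the lower id", {
  H <- 10; W <- 14; T <- 3
  fnt <- array(10, dim = c(H, W, T))
  fnt[, , 1] <- 0                                  # pre-birth baseline
  pxA <- pix(rep(1:2, 2), rep(2:3, each = 2), H)   # 4 px born first
  pxB <- pix(rep(1:2, 2), rep(9:10, each = 2), H)  # 4 px born second
  bridge <- sort(unique(c(pxA, pxB, pix(rep(1, 5), 4:8, H))))
  cl <- list(list(),
             list(clusterOf(pxA, fnt[, , 1]), clusterOf(pxB, fnt[, , 1])),
             list(clusterOf(bridge, fnt[, , 2])))
  ev <- trackEvents(cl, fnt, 1, simpleConfig(), NULL)
  surv <- Filter(function(e) !identical(e$mode, "collision"), ev)[[1]]
  expect_equal(surv$id, 1L)
})

test_that("separation keeps a single identity covering both fragments", {
  H <- 10; W <- 12; T <- 4
  fnt <- array(0, dim = c(H, W, T))
  px0 <- pix(rep(4, 10), 1:10, H)                  # 10-px bar
  pxL <- pix(rep(4, 5), 1:5, H); pxR <- pix(rep(4, 5), 6:10, H)
  fnt[, , 2][px0] <- 10
  fnt[, , 3][c(pxL, pxR)] <- 10
  cl <- list(list(), list(clusterOf(px0, fnt[, , 2])),
             list(clusterOf(pxL, fnt[, , 3]), clusterOf(pxR, fnt[, , 3])),
             list())
  ev <- trackEvents(cl, fnt, 1, simpleConfig(), NULL)
  expect_length(ev, 1)
  expect_equal(length(ev[[1]]$pixelsByFrame[["2"]]), 10L)  # trace value 10
})

test_that("sub-threshold fragments continue events but cannot found them", {
  H <- 8; W <- 8; T <- 3
  fnt <- array(10, dim = c(H, W, T))
  fnt[, , 1] <- 0
  tiny <- pix(2:3, c(2, 2), H)
  cl <- list(list(), list(clusterOf(tiny, fnt[, , 1], eligible = FALSE)),
             list())
  ev <- trackEvents(cl, fnt, 1, simpleConfig(), NULL)
  expect_length(ev, 0)
})

test_that("finalize derives areas, timing and amplitude as specified", {
  H <- 20
  fnt <- array(0, dim = c(20, 30, 40))
  # stationary 9-px event alive frames 2..6 -> start = max = path = 9
  px <- as.integer(outer((5:7) * H, 5:7, "+"))
  for (t in 3:7) fnt[, , t][px] <- c(rep(8, 8), 20)  # max F_nt = 20
  evA <- makeEvent(1L, 2L, stats::setNames(lapply(1:5, function(i) px),
                                           as.character(2:6)),
                   dead = TRUE, mode = "stochastic_attrition", death = 6L)
  # event whose 3x3 block shifts right 3 px/frame for 4 frames
  shifted <- lapply(0:3, function(k)
    as.integer(outer(((10:12) + 3 * k) * H, 10:12, "+")))
  evB <- makeEvent(2L, 12L, stats::setNames(shifted, as.character(12:15)),
                   dead = TRUE, mode = "transient", death = 15L)
  anchors <- list(peaks = c(10L), nadirs = c(5L), suspended = integer())
  fin <- finalizeEvents(list(evA, evB), anchors, fnt, 40L)
  rA <- fin$records[1, ]; rB <- fin$records[2, ]
  expect_equal(rA$start_area_px, 9L)
  expect_equal(rA$max_area_px, 9L)
  expect_equal(rA$path_area_px, 9L)
  expect_equal(rA$duration_frames, 5L)
  expect_equal(rA$half_max_amplitude, 10)
  expect_equal(rA$birth_from_nadir_frames, -3L)   # born before its nadir
  expect_true(is.na(rA$lcr_cycle_frames))         # no preceding peak
  # union of four overlapping 3x3 boxes shifted by 3: 9 + 3*3*3 = 36
  expect_equal(rB$path_area_px, 36L)
  expect_equal(rB$max_area_px, 9L)
  expect_equal(rB$lcr_cycle_frames, 2L)           # birth 12 - peak 10
  expect_equal(rB$birth_from_nadir_frames, 7L)
  # bounding box covers the travelled path
  expect_equal(rB$max_x - rB$min_x, 11)
  # death bookkeeping: dead implies exactly one mode flag
  flags <- fin$records[, c("dead_by_collision", "dead_by_transient",
                           "dead_by_stochastic_attrition")]
  expect_true(all(rowSums(flags) == as.integer(fin$records$dead)))
  # ensemble equals the per-frame sum of individual traces
  agg <- stats::aggregate(area_px ~ frame, fin$traces, sum)
  expect_equal(fin$ensemble[agg$frame + 1], agg$area_px)
})

test_that("hotspot map counts overlapping event paths", {
  H <- 10
  e1 <- makeEvent(1L, 0L, list("0" = pix(2:4, rep(2, 3), H)))
  e2 <- makeEvent(2L, 3L, list("3" = pix(4:6, rep(2, 3), H)))
  hm <- hotspotMap(list(e1, e2), dims = c(10, 10))
  expect_equal(hm[pix(4, 2, H)], 2L)
  expect_equal(hm[pix(2, 2, H)], 1L)
  expect_equal(sum(hm), 6L)
  expect_true(all(hotspotMap(list(), dims = c(5, 5)) == 0L))
})
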