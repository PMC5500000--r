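test_that("max filter cuts at the mean of per-pixel maxima", {
  # 25% of pixels at max 200, 75% at max 10 -> cut 57.5, mask = bright block
  st <- blockStack(H = 20, W = 20, rows = 1:10, cols = 1:10)
  mf <- maxFilterMask(st)
  expect_equal(mf$area_px, 100L)
  expect_true(all(mf$mask[1:10, 1:10]))
  expect_false(any(mf$mask[11:20, ]))
  # an off-cell bright speckle is dropped by the largest-component rule
  arr <- frames(st); arr[18, 18, 1] <- 250
  mf2 <- maxFilterMask(imageStack(arr))
  expect_false(mf2$mask[18, 18])
  expect_equal(mf2$area_px, 100L)
  expect_error(maxFilterMask(imageStack(array(5, dim = c(8, 8, 2)))),
               "empty mask")
})

test_that("normalization anchors the masked extremes at exactly 0 and 255", {
  set.seed(2)
  arr <- array(runif(10 * 10 * 4, 50, 150), dim = c(10, 10, 4))
  arr[3, 3, 2] <- 50; arr[7, 7, 3] <- 150   # force exact extremes
  mask <- matrix(TRUE, 10, 10)
  fn <- normalizeStack(arr, mask)
  expect_equal(min(fn), 0)
  expect_equal(max(fn), 255)
  expect_equal(fn[3, 3, 2], 0)
  expect_equal(fn[7, 7, 3], 255)
  # midpoint linearity
  arr2 <- array(50, dim = c(8, 8, 2)); arr2[1, 1, 1] <- 150
  arr2[2, 2, 1] <- 100
  fn2 <- normalizeStack(arr2, matrix(TRUE, 8, 8))
  expect_equal(fn2[2, 2, 1], 127.5)
  expect_error(normalizeStack(array(5, dim = c(8, 8, 2)),
                              matrix(TRUE, 8, 8)), "constant")
  # frozen anchors clamp out-of-range values
  fn3 <- normalizeStack(arr2, matrix(TRUE, 8, 8), limits = c(60, 110))
  expect_equal(max(fn3), 255)
  expect_equal(min(fn3), 0)
})

test_that("transient removal subtracts the cell average and clips at 0", {
  mask <- matrix(TRUE, 8, 8)
  arr <- array(100, dim = c(8, 8, 3))
  arr[1, 1, 2] <- 110; arr[2, 2, 2] <- 95
  rt <- removeTransient(arr, mask, TRUE)
  fa2 <- mean(arr[, , 2])
  expect_equal(rt$f_a[2], fa2)
  expect_equal(rt$f_nt[1, 1, 2], 110 - fa2)
  expect_equal(rt$f_nt[2, 2, 2], 0)            # below the average: clipped
  expect_true(all(rt$f_nt[, , 1] == 0))        # uniform frame self-subtracts
  # with transients absent the stack passes through untouched
  rt2 <- removeTransient(arr, mask, FALSE)
  expect_identical(rt2$f_nt, arr)
})

test_that("despeckle removes lone spikes and preserves constants", {
  mask <- matrix(TRUE, 10, 10)
  arr <- array(5, dim = c(10, 10, 2))
  arr[5, 5, 1] <- 200
  out <- despeckle(arr, mask, median_filter = TRUE)
  expect_equal(out[5, 5, 1], 5)
  expect_true(all(out[, , 2] == 5))
  expect_identical(despeckle(arr, mask), arr)   # both flags off: identity
  outm <- despeckle(array(7, dim = c(10, 10, 2)), mask,
                    median_filter = TRUE, mean_filter = TRUE)
  expect_true(all(outm == 7))
})

test_that("differential filter matches its brute-force oracle", {
  wg <- windowGeometry(3, 0.2539)
  expect_identical(wg$side_px, 7L)
  set.seed(10)
  for (trial in 1:5) {
    arr <- array(runif(16 * 16 * 10, 0, 100), dim = c(16, 16, 10))
    mask <- matrix(runif(256) > 0.3, 16, 16)
    d <- sample(1:3, 1)
    got <- differentialFilter(arr, mask, d)
    ref <- bruteDifferential(arr, mask, d)
    expect_equal(got$S, ref$S, tolerance = 1e-9)
    expect_equal(got$D, ref$D, tolerance = 1e-9)
    expect_equal(got$sigma_cell, ref$sigma_cell, tolerance = 1e-9)
  }
})

test_that("differential filter rejects constant fluorescence and unit steps", {
  mask <- matrix(TRUE, 16, 16)
  arr <- array(rep(matrix(runif(256, 10, 90), 16, 16), 6),
               dim = c(16, 16, 6))
  got <- differentialFilter(arr, mask, 3)
  expect_true(all(got$D == 0))                  # static heterogeneity vanishes
  # a 0 -> 49 step in one pixel raises a full 7x7 window's mean by exactly 1
  arr2 <- array(0, dim = c(16, 16, 3))
  arr2[8, 8, 2:3] <- 49
  got2 <- differentialFilter(arr2, mask, 3)
  expect_equal(got2$D[5:11, 5:11, 2], matrix(1, 7, 7))
  expect_true(all(got2$D[, , 3] == 0))
})

test_that("candidacy thresholds D and fills 7-of-8 holes in one pass", {
  mask <- matrix(TRUE, 10, 10)
  D <- array(0, dim = c(10, 10, 2))
  D[4:6, 4:6, 2] <- 1.5            # 3x3 block above threshold ...
  D[5, 5, 2] <- 0                  # ... with a hole (8 hot neighbours)
  D[1, 1, 2] <- 1.5                # isolated corner pixel
  cand <- candidateMask(D, sigma_cell = 1, sd_detection = 1,
                        suspended_frames = integer(), mask = mask)
  expect_true(cand[5, 5, 2])       # filled (>= 7 of 8)
  expect_true(cand[1, 1, 2])
  expect_false(any(cand[, , 1]))
  # exactly 7 hot neighbours still fills; 6 does not
  D2 <- array(0, dim = c(10, 10, 2))
  D2[4:6, 4:6, 2] <- 1.5; D2[5, 5, 2] <- 0; D2[4, 4, 2] <- 0
  c2 <- candidateMask(D2, 1, 1, integer(), mask)
  expect_true(c2[5, 5, 2])         # 7 neighbours
  D2[6, 6, 2] <- 0
  c3 <- candidateMask(D2, 1, 1, integer(), mask)
  expect_false(c3[5, 5, 2])        # 6 neighbours
  # suspended frames yield no candidates at all
  c4 <- candidateMask(D, 1, 1, suspended_frames = 1L, mask = mask)
  expect_false(any(c4[, , 2]))
})

test_that("clusters are 4-connected and births require size AND intensity", {
  cand <- matrix(FALSE, 10, 10)
  cand[2:3, 2:3] <- TRUE           # 4 px cluster
  cand[5, 5] <- TRUE               # diagonal neighbour: separate cluster
  fnt <- matrix(10, 10, 10)
  cl <- findClusters(cand, fnt, size_threshold = 4, intensity_threshold = 100)
  expect_length(cl, 2)
  sizes <- vapply(cl, `[[`, integer(1), "size")
  expect_setequal(sizes, c(4L, 1L))
  # 4 px x 10 = 40 < 100: rejected despite size (Boolean AND)
  expect_false(any(vapply(cl, `[[`, logical(1), "birth_eligible")))
  cl2 <- findClusters(cand, matrix(30, 10, 10), 4, 100)
  eligible <- vapply(cl2, `[[`, logical(1), "birth_eligible")
  expect_identical(sum(eligible), 1L)          # only the 4-px cluster
  expect_identical(findClusters(matrix(FALSE, 5, 5), fnt, 4, 100), list())
})

test_that("cluster labelling agrees exactly with a brute-force flood fill", {
  set.seed(21)
  for (trial in 1:20) {
    m <- matrix(runif(16 * 16) > 0.6, 16, 16)
    a <- LCRtrack:::labelComponents(m)
    b <- bruteComponents(m)
    # same partition (labels may differ): compare canonical signatures
    sig <- function(lab) unname(split(which(lab > 0), lab[lab > 0]))
    canon <- function(s) s[order(vapply(s, min, integer(1)))]
    expect_identical(canon(sig(a)), canon(sig(b)))
  }
})
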