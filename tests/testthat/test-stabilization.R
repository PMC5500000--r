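flatPoints <- function(T, xs, y = 20) {
  pts <- array(NA_real_, dim = c(T, length(xs), 2))
  for (t in seq_len(T)) { pts[t, , 1] <- xs; pts[t, , 2] <- y }
  pts
}

test_that("mesh construction follows the isosceles-strip recipe", {
  m2 <- buildMesh(flatPoints(2, c(10, 30)), 20)
  expect_identical(nrow(m2@triangles), 2L)           # no intervening pair
  m3 <- buildMesh(flatPoints(2, c(10, 30, 50)), 20)
  expect_identical(nrow(m3@triangles), 6L)           # 4 primary + 2 intervening
  # apexes sit exactly +/- h from the base midpoints (y increases downward)
  v <- m3@vertices[1, , ]
  expect_equal(v[4, ], c(20, 0))                     # upper apex of pair 1
  expect_equal(v[6, ], c(20, 40))                    # lower apex of pair 1
  expect_error(buildMesh(flatPoints(2, 10), 20), "two spine points")
  expect_error(buildMesh(flatPoints(2, c(10, 30)), 0), "positive")
})

test_that("triangle affine maps vertices exactly and rejects degeneracy", {
  ref <- rbind(c(0, 0), c(10, 0), c(0, 10))
  expect_equal(triangleAffine(ref, ref), diag(3), tolerance = 1e-12)
  def <- ref + rep(c(3, -2), each = 3)
  A <- triangleAffine(ref, def)
  expect_equal(A[1:2, 3], c(3, -2))
  expect_equal(A[1:2, 1:2], diag(2), tolerance = 1e-12)
  for (i in 1:3)
    expect_equal(as.numeric(A %*% c(ref[i, ], 1))[1:2], def[i, ],
                 tolerance = 1e-12)
  expect_error(triangleAffine(rbind(c(0, 0), c(5, 5), c(10, 10)), def),
               "degenerate")
})

test_that("adjacent triangles agree on their shared edge to 1e-9", {
  set.seed(3)
  pts <- flatPoints(2, c(10, 25, 40), y = 20)
  pts[2, , 1] <- pts[2, , 1] + runif(3, -2, 2)   # deformed frame
  pts[2, , 2] <- pts[2, , 2] + runif(3, -2, 2)
  mesh <- buildMesh(pts, 15)
  refV <- mesh@vertices[1, , ]; defV <- mesh@vertices[2, , ]
  tris <- mesh@triangles
  for (i in seq_len(nrow(tris) - 1)) for (j in (i + 1):nrow(tris)) {
    shared <- intersect(tris[i, ], tris[j, ])
    if (length(shared) != 2) next
    Ai <- triangleAffine(refV[tris[i, ], ], defV[tris[i, ], ])
    Aj <- triangleAffine(refV[tris[j, ], ], defV[tris[j, ], ])
    for (w in c(0, 0.33, 0.71, 1)) {
      p <- c(w * refV[shared[1], ] + (1 - w) * refV[shared[2], ], 1)
      expect_equal(as.numeric(Ai %*% p), as.numeric(Aj %*% p),
                   tolerance = 1e-9)
    }
  }
})

test_that("a stationary mesh stabilizes to the identity inside the mesh", {
  set.seed(5)
  arr <- array(runif(40 * 60 * 3, 0, 200), dim = c(40, 60, 3))
  st <- imageStack(arr)
  mesh <- buildMesh(flatPoints(3, c(5, 25, 45, 55)), 15)
  out <- stabilize(st, mesh, ref_frame = 0, background = 7)
  inside <- assign <- LCRtrack:::assignTriangles(mesh@vertices[1, , ],
                                                 mesh@triangles, 40, 60)
  for (t in 1:3) {
    fr <- frames(out)[, , t]
    expect_equal(fr[inside > 0], arr[, , t][inside > 0], tolerance = 1e-9)
    expect_true(all(fr[inside == 0] == 7))
  }
})

test_that("forward warp then stabilize recovers smooth frames within 1 gray level", {
  # smooth test image: sum of broad sinusoids
  H <- 48; W <- 96; T <- 4
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  img <- 100 + 60 * sin(xs / 11) * cos(ys / 7) + 30 * sin((xs + ys) / 17)
  arr <- array(rep(img, T), dim = c(H, W, T))
  st <- imageStack(arr)
  pts <- flatPoints(T, c(6, 30, 60, 89), y = 24)
  set.seed(9)
  for (t in 2:T) {
    pts[t, , 1] <- pts[t, , 1] + runif(4, -2.5, 2.5)
    pts[t, , 2] <- pts[t, , 2] + runif(4, -2.5, 2.5)
  }
  mesh <- buildMesh(pts, 18)
  warped <- deformStack(st, mesh, ref_frame = 0, background = 0)
  back <- stabilize(warped, mesh, ref_frame = 0, background = 0)
  inside <- LCRtrack:::assignTriangles(mesh@vertices[1, , ],
                                       mesh@triangles, H, W) > 0
  # stay clear of the mesh border where the deformed mesh may not cover
  core <- inside & xs > 12 & xs < 83 & ys > 10 & ys < 38
  for (t in 2:T) {
    err <- abs(frames(back)[, , t][core] - arr[, , t][core])
    expect_lt(mean(err), 1)
  }
})

test_that("simulator contraction is recovered by its own truth mesh", {
  sim <- simulateMovie(seed = 6, contraction_amplitude = 0.05,
                       n_events_per_cycle = 0, noise_sd = 0,
                       width = 128, height = 48, n_frames = 30)
  base <- simulateMovie(seed = 6, contraction_amplitude = 0,
                        n_events_per_cycle = 0, noise_sd = 0,
                        width = 128, height = 48, n_frames = 30)
  stab <- suppressMessages(
    stabilize(sim$stack, sim$truth$mesh, 0, background = 10))
  err <- abs(frames(stab)[, 20:108, ] - frames(base$stack)[, 20:108, ])
  expect_lt(mean(err), 1)
})
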