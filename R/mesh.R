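#' Build the per-frame triangular mesh over tracked spine points
#'
#' Each adjacent pair of spine points is the base of two isosceles
#' triangles, one above and one below the spine, with apexes offset purely
#' vertically by the user-defined height from the base midpoint. Each pair
#' of neighbouring same-side apexes defines an intervening triangle of
#' opposite orientation, so the strip is tiled without gaps. The index
#' topology is identical in every frame; only vertex positions move.
#'
#' @param points numeric \code{T x n x 2} array of spine points from
#'   [spinePoints()] (x strictly increasing within each frame).
#' @param height apex height in pixels (> 0).
#' @return a [TriangleMesh-class] with \code{3n - 2} vertices and
#'   \code{2(n-1) + 2(n-2)} triangles per frame.
#' @export
buildMesh <- function(points, height) {
  if (height <= 0) stop("height must be positive", call. = FALSE)
  d <- dim(points)
  if (is.null(d) || length(d) != 3L)
    stop("points must be a T x n x 2 array", call. = FALSE)
  TT <- d[1]; n <- d[2]
  if (n < 2L) stop("need at least two spine points", call. = FALSE)
  nV <- 3L * n - 2L
  verts <- array(NA_real_, dim = c(TT, nV, 2L))
  for (t in seq_len(TT)) {
    px <- points[t, , 1L]; py <- points[t, , 2L]
    if (is.unsorted(px, strictly = TRUE))
      stop("spine points must have strictly increasing x", call. = FALSE)
    mx <- (px[-n] + px[-1L]) / 2
    my <- (py[-n] + py[-1L]) / 2
    verts[t, 1:n, 1L] <- px
    verts[t, 1:n, 2L] <- py
    verts[t, n + seq_len(n - 1L), 1L] <- mx            # upper apexes
    verts[t, n + seq_len(n - 1L), 2L] <- my - height   # y decreases upward
    verts[t, (2L * n - 1L) + seq_len(n - 1L), 1L] <- mx  # lower apexes
    verts[t, (2L * n - 1L) + seq_len(n - 1L), 2L] <- my + height
  }
  up <- function(i) n + i
  dn <- function(i) 2L * n - 1L + i
  tris <- list()
  for (i in seq_len(n - 1L)) {
    tris[[length(tris) + 1L]] <- c(i, i + 1L, up(i))
    tris[[length(tris) + 1L]] <- c(i, i + 1L, dn(i))
  }
  if (n >= 3L) for (i in seq_len(n - 2L)) {
    tris[[length(tris) + 1L]] <- c(up(i), up(i + 1L), i + 1L)
    tris[[length(tris) + 1L]] <- c(dn(i), dn(i + 1L), i + 1L)
  }
  new("TriangleMesh", vertices = verts,
      triangles = matrix(as.integer(unlist(tris)), ncol = 3L, byrow = TRUE),
      height = as.numeric(height))
}

#' Affine map between two triangles
#'
#' Returns the 3x3 homogeneous matrix \code{M_d \%*\% solve(M_r)} that maps
#' each vertex of the reference triangle exactly onto the corresponding
#' vertex of the deformed triangle (columns of \code{M} are the homogeneous
#' vertex coordinates).
#'
#' @param ref_tri,def_tri 3x2 matrices of \code{(x, y)} vertex coordinates.
#' @return 3x3 affine matrix acting on homogeneous column vectors
#'   \code{(x, y, 1)}.
#' @export
triangleAffine <- function(ref_tri, def_tri) {
  Mr <- rbind(t(ref_tri), 1)
  Md <- rbind(t(def_tri), 1)
  det <- det(Mr)
  if (abs(det) < 1e-12)
    stop("reference triangle is degenerate (collinear vertices)",
         call. = FALSE)
  Md %*% solve(Mr)
}

# Assign each pixel of an H x W grid to the first triangle containing it
# (edges inclusive, barycentric tolerance 1e-9); 0 where outside all.
assignTriangles <- function(verts, tris, H, W) {
  assign <- matrix(0L, H, W)
  xs <- matrix(rep(0:(W - 1L), each = H), H, W)
  ys <- matrix(rep(0:(H - 1L), times = W), H, W)
  for (j in seq_len(nrow(tris))) {
    v <- verts[tris[j, ], , drop = FALSE]
    xmin <- max(1L, floor(min(v[, 1])) + 1L)
    xmax <- min(W, ceiling(max(v[, 1])) + 1L)
    ymin <- max(1L, floor(min(v[, 2])) + 1L)
    ymax <- min(H, ceiling(max(v[, 2])) + 1L)
    if (xmin > xmax || ymin > ymax) next
    rows <- ymin:ymax; cols <- xmin:xmax
    px <- xs[rows, cols]; py <- ys[rows, cols]
    d <- (v[2, 2] - v[3, 2]) * (v[1, 1] - v[3, 1]) +
         (v[3, 1] - v[2, 1]) * (v[1, 2] - v[3, 2])
    if (abs(d) < 1e-12) next
    l1 <- ((v[2, 2] - v[3, 2]) * (px - v[3, 1]) +
           (v[3, 1] - v[2, 1]) * (py - v[3, 2])) / d
    l2 <- ((v[3, 2] - v[1, 2]) * (px - v[3, 1]) +
           (v[1, 1] - v[3, 1]) * (py - v[3, 2])) / d
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    sub <- assign[rows, cols]
    sub[inside & sub == 0L] <- j
    assign[rows, cols] <- sub
  }
  assign
}

# Warp one frame: every output pixel assigned to triangle j in `toVerts`
# geometry is sampled (bilinearly) from `img` at the location given by the
# affine map from the `to` triangle to the `from` triangle.
warpFrame <- function(img, fromVerts, toVerts, tris, assign, background) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(background, H, W)
  nClamped <- 0L
  for (j in seq_len(nrow(tris))) {
    idx <- which(assign == j)
    if (length(idx) == 0L) next
    A <- triangleAffine(toVerts[tris[j, ], , drop = FALSE],
                        fromVerts[tris[j, ], , drop = FALSE])
    xy <- indexToXY(idx, H)
    sx <- A[1, 1] * xy[, 1] + A[1, 2] * xy[, 2] + A[1, 3]
    sy <- A[2, 1] * xy[, 1] + A[2, 2] * xy[, 2] + A[2, 3]
    sm <- bilinearSample(img, sx, sy)
    out[idx] <- sm$values
    nClamped <- nClamped + sm$nClamped
  }
  attr(out, "nClamped") <- nClamped
  out
}

#' Stabilize a stack against its tracked mesh
#'
#' Warps every frame into the geometry of the reference frame so the cell
#' appears motionless: for each output pixel inside a reference triangle,
#' the value is a bilinear sample of the source frame at the position given
#' by the triangle's reference-to-deformed affine map (backward warping, so
#' the output has no holes). Pixels outside all reference triangles are set
#' to the constant background level. Mapped coordinates falling outside the
#' source frame are clamped to the border and counted in a message.
#'
#' @param stack an [ImageStack-class]; frames must align with the mesh.
#' @param mesh a [TriangleMesh-class] with one vertex set per frame.
#' @param ref_frame reference frame (0-based; default 0).
#' @param background constant used outside the mesh (typically the
#'   background mean \code{b} from [estimateBackground()]).
#' @return a stabilized [ImageStack-class] of identical dimensions.
#' @export
stabilize <- function(stack, mesh, ref_frame = 0L, background = 0) {
  stopifnot(is(stack, "ImageStack"), is(mesh, "TriangleMesh"))
  arr <- frames(stack)
  d <- dim(arr)
  if (dim(mesh@vertices)[1] != d[3])
    stop("mesh frames do not align with stack frames", call. = FALSE)
  r <- ref_frame + 1L
  if (r < 1L || r > d[3]) stop("ref_frame out of range", call. = FALSE)
  refV <- mesh@vertices[r, , , drop = TRUE]
  tris <- mesh@triangles
  # reference triangles must be non-degenerate
  for (j in seq_len(nrow(tris))) {
    v <- refV[tris[j, ], , drop = FALSE]
    if (abs(det(rbind(t(v), 1))) < 1e-12)
      stop("degenerate triangle in reference frame", call. = FALSE)
  }
  assign <- assignTriangles(refV, tris, d[1], d[2])
  out <- array(0, dim = d)
  totClamped <- 0L
  for (t in seq_len(d[3])) {
    defV <- mesh@vertices[t, , , drop = TRUE]
    w <- warpFrame(arr[, , t], defV, refV, tris, assign, background)
    totClamped <- totClamped + attr(w, "nClamped")
    out[, , t] <- w
  }
  if (totClamped > 0L)
    message(sprintf("stabilize: %d mapped coordinate(s) clamped to border",
                    totClamped))
  out[out < 0] <- 0
  imageStack(out, pixelSize(stack), frameInterval(stack))
}

#' Forward-deform a stack through a mesh (simulation helper)
#'
#' The inverse of [stabilize()]: renders each frame in the deformed
#' per-frame geometry by sampling the source frame (in reference geometry)
#' through the deformed-to-reference affine maps. Used by the simulator to
#' apply a known contraction, so that stabilizing with the same mesh
#' recovers the original frames up to interpolation error.
#'
#' @inheritParams stabilize
#' @return a deformed [ImageStack-class].
#' @export
deformStack <- function(stack, mesh, ref_frame = 0L, background = 0) {
  stopifnot(is(stack, "ImageStack"), is(mesh, "TriangleMesh"))
  arr <- frames(stack)
  d <- dim(arr)
  if (dim(mesh@vertices)[1] != d[3])
    stop("mesh frames do not align with stack frames", call. = FALSE)
  refV <- mesh@vertices[ref_frame + 1L, , , drop = TRUE]
  tris <- mesh@triangles
  out <- array(0, dim = d)
  for (t in seq_len(d[3])) {
    defV <- mesh@vertices[t, , , drop = TRUE]
    assign <- assignTriangles(defV, tris, d[1], d[2])
    w <- warpFrame(arr[, , t], refV, defV, tris, assign, background)
    out[, , t] <- w
  }
  out[out < 0] <- 0
  imageStack(out, pixelSize(stack), frameInterval(stack))
}

#' Export per-frame mesh vertices to CSV
#'
#' @param mesh a [TriangleMesh-class].
#' @param path destination CSV path.
#' @return invisibly, \code{path}.
#' @export
writeMeshVertices <- function(mesh, path) {
  d <- dim(mesh@vertices)
  df <- do.call(rbind, lapply(seq_len(d[1]), function(t) {
    data.frame(frame = t - 1L, vertex = seq_len(d[2]) - 1L,
               x = mesh@vertices[t, , 1L], y = mesh@vertices[t, , 2L])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
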