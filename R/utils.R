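# Internal numeric helpers shared across modules.

# Sliding-window box sum with window half-width d, truncated at the image
# border, via a padded summed-area table. Returns a matrix of the same size
# where entry (i, j) is the sum of M over rows i-d..i+d, cols j-d..j+d
# intersected with the image.
boxSum <- function(M, d) {
  H <- nrow(M); W <- ncol(M)
  # padded cumulative sums: C[i+1, j+1] = sum of M[1..i, 1..j]
  C <- matrix(0, H + 1L, W + 1L)
  C[-1L, -1L] <- t(apply(apply(M, 2L, cumsum), 1L, cumsum))
  r1 <- pmax(seq_len(H) - d, 1L); r2 <- pmin(seq_len(H) + d, H)
  c1 <- pmax(seq_len(W) - d, 1L); c2 <- pmin(seq_len(W) + d, W)
  C[r2 + 1L, c2 + 1L, drop = FALSE] - C[r1, c2 + 1L, drop = FALSE] -
    C[r2 + 1L, c1, drop = FALSE] + C[r1, c1, drop = FALSE]
}

# Bilinear sampling of matrix img at 0-based coordinates (x = column,
# y = row), clamped to the image border. Returns list(values, nClamped).
bilinearSample <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  clamped <- x < 0 | x > (W - 1L) | y < 0 | y > (H - 1L)
  x <- pmin(pmax(x, 0), W - 1L)
  y <- pmin(pmax(y, 0), H - 1L)
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(x0, W - 2L); y0 <- pmin(y0, H - 2L)
  fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1L; j0 <- x0 + 1L
  v00 <- img[cbind(i0,      j0)]
  v01 <- img[cbind(i0,      j0 + 1L)]
  v10 <- img[cbind(i0 + 1L, j0)]
  v11 <- img[cbind(i0 + 1L, j0 + 1L)]
  vals <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
          fy       * ((1 - fx) * v10 + fx * v11)
  list(values = vals, nClamped = sum(clamped))
}

# 4-connected component labelling of a logical matrix.
labelComponents <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

# Shift a matrix by (dy, dx), filling vacated entries with `fill`.
shiftMatrix <- function(M, dy, dx, fill = 0) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(fill, H, W)
  rs <- seq_len(H) - dy; cs <- seq_len(W) - dx
  rok <- rs >= 1L & rs <= H; cok <- cs >= 1L & cs <= W
  out[rok, cok] <- M[rs[rok], cs[cok]]
  out
}

# Parse/validate a 0-based "x,y,w,h" rectangle against frame dims; returns a
# list with 1-based row/col index ranges.
parseRegion <- function(region, H, W, what = "region") {
  if (is.character(region)) {
    region <- suppressWarnings(as.numeric(strsplit(region, ",")[[1]]))
  }
  if (length(region) != 4L || anyNA(region))
    stop(what, " must be x,y,w,h", call. = FALSE)
  x <- region[1]; y <- region[2]; w <- region[3]; h <- region[4]
  if (w < 1 || h < 1)
    stop(what, " has zero area", call. = FALSE)
  if (x < 0 || y < 0 || x + w > W || y + h > H)
    stop(what, " lies outside frame bounds", call. = FALSE)
  list(rows = seq.int(y + 1L, y + h), cols = seq.int(x + 1L, x + w))
}

# Population standard deviation (exact for fixture-sized tests).
popSD <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# Linear index (1-based, column-major H x W) -> 0-based (x, y).
indexToXY <- function(idx, H) {
  idx0 <- idx - 1L
  cbind(x = idx0 %/% H, y = idx0 %% H)
}
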