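#' Background statistics from an off-cell region
#'
#' Mean and population standard deviation of the fluorescence over a
#' user-chosen rectangle lying off the cell, pooled across all frames. These
#' define the threshold \code{b + 3*sigma} that separates cell from
#' background in the spine computation.
#'
#' @param stack an [ImageStack-class].
#' @param bg_region rectangle as \code{c(x, y, w, h)} (0-based) or an
#'   \code{"x,y,w,h"} string; must lie inside the frame.
#' @return list with elements \code{b} (mean) and \code{sigma}
#'   (population SD).
#' @export
estimateBackground <- function(stack, bg_region) {
  d <- dim(stack)
  reg <- parseRegion(bg_region, d[1], d[2], "bg_region")
  vals <- frames(stack)[reg$rows, reg$cols, , drop = FALSE]
  list(b = mean(vals), sigma = popSD(vals))
}

#' Background-threshold a frame
#'
#' Above-background intensity \code{a = i - b} where \code{i > b + 3*sigma}
#' (strict), and 0 elsewhere.
#'
#' @param frame numeric \code{H x W} matrix.
#' @param stats background statistics from [estimateBackground()].
#' @return non-negative matrix \code{a} of the same shape.
#' @export
thresholdFrame <- function(frame, stats) {
  cut <- stats$b + 3 * stats$sigma
  a <- frame - stats$b
  a[frame <= cut] <- 0
  a
}

#' Intensity-weighted centre-of-mass spine of one frame
#'
#' For each image column, the spine height is the centre of mass of the
#' thresholded intensities raised to the power 1.5 -- the power sharpens the
#' weighting toward the bright cell body so dim halo pixels barely move the
#' midline. Columns with no above-threshold pixel are \code{NA}.
#'
#' @param a_frame thresholded frame from [thresholdFrame()].
#' @return numeric vector of length \code{W}: 0-based y-coordinate
#'   \code{zeta(x)} per column, \code{NA} where undefined.
#' @export
computeSpine <- function(a_frame) {
  H <- nrow(a_frame)
  w <- a_frame^1.5
  den <- colSums(w)
  num <- colSums(w * (seq_len(H) - 1L))
  zeta <- num / den
  zeta[den <= 0] <- NA_real_
  zeta
}

#' Spine map over all frames
#'
#' Thresholds every frame against the background statistics and stacks the
#' per-frame spines into a \code{T x W} matrix.
#'
#' @param stack an [ImageStack-class].
#' @param stats background statistics from [estimateBackground()].
#' @return numeric \code{T x W} matrix \code{zeta(t, x)} (0-based y;
#'   \code{NA} where undefined).
#' @export
spineMap <- function(stack, stats) {
  arr <- frames(stack)
  d <- dim(arr)
  zeta <- matrix(NA_real_, d[3], d[2])
  for (t in seq_len(d[3]))
    zeta[t, ] <- computeSpine(thresholdFrame(arr[, , t], stats))
  zeta
}

# Central Savitzky-Golay derivative filter coefficients (window n, order p,
# derivative m), oriented for a dot product with the window in increasing-x
# order. signal::sgolay already applies the factorial/derivative scaling.
sgCentralCoef <- function(n, p, m) {
  sg <- signal::sgolay(p = p, n = n, m = m)
  as.numeric(sg[(n + 1L) %/% 2L, ])  # centre row (n odd)
}

#' Local-curvature map of the spine
#'
#' Differentiates the spine along x with Savitzky-Golay filters and forms
#' the signed curvature \code{k = zeta_xx / (1 + zeta_x^2)^(3/2)} per frame.
#' Bends in the cell appear as horizontal bands of constant curvature that
#' deflect when the cell contracts; those bands are the tracking landmarks.
#'
#' Interior NA gaps in the defined span of a frame's spine are filled by
#' linear interpolation before differentiation and flagged in the result;
#' output is interior-only (no polynomial extrapolation at the span ends).
#'
#' @param zeta \code{T x W} spine matrix from [spineMap()] (or a single
#'   spine as a 1-row matrix).
#' @param sg_window odd Savitzky-Golay window width (columns).
#' @param sg_order polynomial order, \code{< sg_window}.
#' @return a [CurvatureMap-class].
#' @export
curvatureMap <- function(zeta, sg_window = 11L, sg_order = 3L) {
  if (is.null(dim(zeta))) zeta <- matrix(zeta, nrow = 1L)
  n <- as.integer(sg_window); p <- as.integer(sg_order)
  if (n %% 2L == 0L || n < 3L) stop("sg_window must be odd and >= 3")
  if (p >= n) stop("sg_order must be < sg_window")
  h <- (n - 1L) %/% 2L
  c1 <- sgCentralCoef(n, p, 1L)
  c2 <- sgCentralCoef(n, p, 2L)
  TT <- nrow(zeta); W <- ncol(zeta)
  k <- matrix(NA_real_, TT, W)
  zfill <- zeta
  interp <- matrix(FALSE, TT, W)
  for (t in seq_len(TT)) {
    def <- which(!is.na(zeta[t, ]))
    if (length(def) == 0L) next
    lo <- min(def); hi <- max(def)
    if (hi - lo + 1L < n)
      stop(sprintf("frame %d: contiguous defined spine span (%d) shorter than sg_window (%d)",
                   t - 1L, hi - lo + 1L, n))
    span <- lo:hi
    gaps <- span[is.na(zeta[t, span])]
    if (length(gaps) > 0L) {
      zfill[t, span] <- stats::approx(def, zeta[t, def], xout = span)$y
      interp[t, gaps] <- TRUE
    }
    z <- zfill[t, span]
    m <- length(z)
    E <- stats::embed(z, n)               # row i: z[i+n-1] .. z[i]
    d1 <- as.numeric(E %*% rev(c1))
    d2 <- as.numeric(E %*% rev(c2))
    ctr <- span[(h + 1L):(m - h)]         # centres of full windows
    k[t, ctr] <- d2 / (1 + d1^2)^1.5
  }
  new("CurvatureMap", k = k, zeta = zfill, interpolated = interp,
      sgWindow = n, sgOrder = p)
}
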