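#' Segment the cell with the maximum-over-time filter
#'
#' Computes the per-pixel maximum over time; because the background is much
#' darker than the cell, the mean of all per-pixel maxima gives a cut point
#' separating cytoplasm from background. Pixels whose maximum exceeds the
#' cut are cell; only the largest 4-connected component is retained (to
#' drop stray bright speckles off the cell).
#'
#' @param stack an [ImageStack-class] (stabilized).
#' @return list with \code{mask} (logical \code{H x W}) and \code{area_px}.
#' @export
maxFilterMask <- function(stack) {
  arr <- frames(stack)
  mx <- apply(arr, c(1L, 2L), max)
  cut <- mean(mx)
  mask <- mx > cut
  if (!any(mask))
    stop("Max Filter produced an empty mask (uniform stack?)", call. = FALSE)
  lab <- labelComponents(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  mask <- lab == keep
  list(mask = mask, area_px = sum(mask))
}

#' Normalize masked intensities to the 0-255 gray scale
#'
#' Linear rescaling over the masked pixels across all frames: the masked
#' minimum maps to exactly 0 and the masked maximum to exactly 255. Pixels
#' outside the mask are set to 0.
#'
#' @param stack an [ImageStack-class] or a raw \code{H x W x T} array.
#' @param mask logical \code{H x W} cell mask.
#' @param limits optional fixed \code{c(f_min, f_max)} anchors (used by the
#'   false-positive control to condition an off-cell region on the cell
#'   run's scale); values outside the anchors are clamped.
#' @return \code{H x W x T} array \code{F_norm} in \code{[0, 255]}, with
#'   the anchors used attached as attribute \code{"limits"}.
#' @export
normalizeStack <- function(stack, mask, limits = NULL) {
  arr <- if (is(stack, "ImageStack")) frames(stack) else stack
  d <- dim(arr)
  if (is.null(limits)) {
    mvals <- arr[rep(mask, d[3])]
    limits <- c(min(mvals), max(mvals))
  }
  fmin <- limits[1]; fmax <- limits[2]
  if (fmax <= fmin)
    stop("masked signal is constant; cannot normalize", call. = FALSE)
  out <- 255 * (arr - fmin) / (fmax - fmin)
  out[out < 0] <- 0
  out[out > 255] <- 255
  out[rep(!mask, d[3])] <- 0
  attr(out, "limits") <- limits
  out
}

#' Remove the whole-cell transient from the normalized stack
#'
#' The AP-induced transient is taken as the cell-average signal
#' \code{F_a(t)}; subtracting it per frame and clipping negatives at 0
#' leaves only signal that is locally above the cell average -- the
#' substrate on which LCRs live. When \code{transients_present} is unset
#' the subtraction is skipped entirely and the normalized stack passes
#' through (the cell-average trace is still returned).
#'
#' @param f_norm array from [normalizeStack()].
#' @param mask logical cell mask.
#' @param transients_present logical flag.
#' @return list with \code{f_nt} (transient-subtracted array) and
#'   \code{f_a} (per-frame cell-average trace).
#' @export
removeTransient <- function(f_norm, mask, transients_present = TRUE) {
  d <- dim(f_norm)
  fa <- vapply(seq_len(d[3]), function(t) mean(f_norm[, , t][mask]),
               numeric(1))
  if (!transients_present)
    return(list(f_nt = f_norm, f_a = fa))
  fnt <- f_norm
  for (t in seq_len(d[3])) {
    fr <- f_norm[, , t] - fa[t]
    fr[fr < 0] <- 0
    fr[!mask] <- 0
    fnt[, , t] <- fr
  }
  list(f_nt = fnt, f_a = fa)
}

#' Optional 3x3 despeckling filters
#'
#' Mask-aware 3x3 median and/or mean filters applied per frame (median
#' first when both are enabled). A lone intensity spike is replaced by its
#' neighbourhood's median, suppressing salt-and-pepper noise while leaving
#' smooth structure (an LCR spans many pixels) essentially untouched.
#' Neighbours outside the mask contribute the centre pixel's own value, so
#' the kernel never mixes in background and constant regions are exact
#' fixed points.
#'
#' @param arr \code{H x W x T} array (typically \code{F_nt}).
#' @param mask logical cell mask.
#' @param median_filter,mean_filter logical flags; both off is the
#'   identity.
#' @return filtered array.
#' @export
despeckle <- function(arr, mask, median_filter = FALSE, mean_filter = FALSE) {
  if (!median_filter && !mean_filter) return(arr)
  d <- dim(arr)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  shifts <- function(fr) {
    out <- vector("list", nrow(offs))
    for (o in seq_len(nrow(offs))) {
      sv <- shiftMatrix(fr, offs$dy[o], offs$dx[o], fill = NA_real_)
      sm <- shiftMatrix(mask, offs$dy[o], offs$dx[o], fill = FALSE)
      sv[!sm] <- NA_real_
      bad <- is.na(sv)
      sv[bad] <- fr[bad]            # absent neighbour -> centre value
      out[[o]] <- sv
    }
    out
  }
  for (t in seq_len(d[3])) {
    fr <- arr[, , t]
    if (median_filter) {
      v <- shifts(fr)
      med <- median9(v)
      med[!mask] <- fr[!mask]
      fr <- med
    }
    if (mean_filter) {
      v <- shifts(fr)
      mn <- Reduce(`+`, v) / 9
      mn[!mask] <- fr[!mask]
      fr <- mn
    }
    arr[, , t] <- fr
  }
  arr
}

# exact median of nine equally shaped matrices via a full sorting network
# of vectorized pairwise min/max exchanges
median9 <- function(v) {
  for (i in 1:8) for (j in 1:(9 - i)) {
    lo <- pmin(v[[j]], v[[j + 1]]); hi <- pmax(v[[j]], v[[j + 1]])
    v[[j]] <- lo; v[[j + 1]] <- hi
  }
  v[[5]]
}

#' The composite spatiotemporal differential filter
#'
#' Averages the conditioned signal over a \code{(2d+1) x (2d+1)} window
#' around every cell pixel (truncated to in-mask pixels, so the cell edge
#' is not diluted by background) and then takes frame-to-frame differences:
#' \code{D(x,y,t) = S(x,y,t) - S(x,y,t-1)}, with \code{D = 0} at frame 0.
#' Locations with constant fluorescence (heterogeneous indicator loading,
#' nuclei) therefore vanish, while fast local rises stand out. The scalar
#' \code{sigma_cell} -- the population SD of \code{D} over all cell pixels
#' and frames >= 1, excluding any frames in \code{exclude_frames} -- is
#' the noise scale against which the detection, birth-mass and termination
#' thresholds are expressed. Excluding the transient-suspended frames keeps
#' the scale anchored to the noise of the frames detection actually
#' operates on, independent of cell geometry and transient residuals.
#'
#' @param f_nt conditioned array from [removeTransient()] (optionally
#'   despeckled).
#' @param mask logical cell mask.
#' @param search_distance window half-width \code{d >= 1}.
#' @param exclude_frames 0-based frames left out of the sigma estimate
#'   (typically the suspended frames from [cycleAnchors()]); \code{D}
#'   itself is computed for every frame.
#' @return list with \code{D} (\code{H x W x T}, zero outside the mask),
#'   \code{sigma_cell}, and \code{S} (the spatially averaged stack).
#' @export
differentialFilter <- function(f_nt, mask, search_distance = 3L,
                               exclude_frames = integer()) {
  d <- as.integer(search_distance)
  if (d < 1L) stop("search_distance must be >= 1", call. = FALSE)
  dm <- dim(f_nt)
  maskN <- boxSum(matrix(as.numeric(mask), dm[1], dm[2]), d)
  S <- array(0, dim = dm)
  for (t in seq_len(dm[3])) {
    fr <- f_nt[, , t]
    fr[!mask] <- 0
    s <- boxSum(fr, d) / maskN
    s[!mask] <- 0
    s[maskN == 0] <- 0
    S[, , t] <- s
  }
  D <- array(0, dim = dm)
  for (t in 2:dm[3])
    D[, , t] <- S[, , t] - S[, , t - 1L]
  for (t in seq_len(dm[3])) D[, , t][!mask] <- 0
  keep <- setdiff(2:dm[3], exclude_frames + 1L)
  dv <- as.numeric(D[, , keep, drop = FALSE])[rep(mask, length(keep))]
  list(D = D, sigma_cell = popSD(dv), S = S)
}

#' Per-frame LCR candidacy
#'
#' A cell pixel is an LCR candidate at frame t when its differential signal
#' exceeds \code{sd_detection * sigma_cell} and the frame is not suspended
#' by the transient cutoff. A single fill pass then grants candidacy to any
#' cell pixel with at least 7 of its 8 neighbours already candidates, to
#' absorb pixel anomalies inside an LCR.
#'
#' @param D differential array from [differentialFilter()].
#' @param sigma_cell scalar noise level from the same call.
#' @param sd_detection threshold multiplier.
#' @param suspended_frames integer vector of 0-based suspended frames (from
#'   [cycleAnchors()]), or empty.
#' @param mask logical cell mask.
#' @return logical \code{H x W x T} candidate array.
#' @export
candidateMask <- function(D, sigma_cell, sd_detection = 1,
                          suspended_frames = integer(), mask) {
  d <- dim(D)
  thr <- sd_detection * sigma_cell
  cand <- array(FALSE, dim = d)
  suspended <- rep(FALSE, d[3])
  if (length(suspended_frames) > 0)
    suspended[suspended_frames + 1L] <- TRUE
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  for (t in seq_len(d[3])) {
    if (suspended[t]) next
    c0 <- D[, , t] > thr & mask
    nb <- matrix(0L, d[1], d[2])
    for (o in seq_len(nrow(offs)))
      nb <- nb + shiftMatrix(c0, offs$dy[o], offs$dx[o], fill = FALSE)
    cand[, , t] <- c0 | (mask & nb >= 7L)
  }
  cand
}

#' Connected candidate clusters of one frame
#'
#' Groups candidate pixels into 4-connected clusters ("common borders")
#' and applies the two birth sensitivity tests: a cluster can found a new
#' LCR only if its pixel count reaches \code{size_threshold} AND its summed
#' intensity reaches \code{intensity_threshold} (a Boolean AND: a newborn
#' must be large and bright enough). In the default pipeline the intensity
#' summed is the differential signal \code{D} -- the total signal mass that
#' appeared in one frame -- which separates genuine fast local rises from
#' pure-noise clusters far better than the conditioned intensity, whose sum
#' grows with cluster area wherever the cytoplasm sits above the cell
#' average. Clusters failing either test are retained as continuation-only
#' fragments: they may still join an existing LCR but cannot found one.
#'
#' @param cand_frame logical \code{H x W} candidate mask for one frame.
#' @param intensity_frame matching frame of the array whose values are
#'   summed for the brightness test (the differential signal \code{D} in
#'   [detectLCRs()]).
#' @param size_threshold minimum newborn pixel count.
#' @param intensity_threshold minimum newborn summed intensity.
#' @return list of clusters, each a list with \code{pixels} (1-based linear
#'   indices), \code{size}, \code{intensity}, \code{birth_eligible}.
#' @export
findClusters <- function(cand_frame, intensity_frame, size_threshold = 8L,
                         intensity_threshold = 150) {
  if (!any(cand_frame)) return(list())
  lab <- labelComponents(cand_frame)
  n <- max(lab)
  out <- vector("list", n)
  idxAll <- which(lab > 0L)
  labs <- lab[idxAll]
  for (j in seq_len(n)) {
    px <- idxAll[labs == j]
    s <- length(px)
    inten <- sum(intensity_frame[px])
    out[[j]] <- list(pixels = px, size = s, intensity = inten,
                     birth_eligible = s >= size_threshold &&
                       inten >= intensity_threshold)
  }
  out
}

#' Geometry of the spatial averaging window
#'
#' The side (pixels) and physical area of the differential filter's
#' averaging window for a given search distance and pixel size; e.g. the
#' default search distance 3 gives a 7x7 window, which at 0.2539 um/pixel
#' covers 3.16 um^2.
#'
#' @param search_distance window half-width.
#' @param pixel_size_um pixel edge in micrometres.
#' @return list with \code{side_px}, \code{n_px} and \code{area_um2}.
#' @export
windowGeometry <- function(search_distance = 3L, pixel_size_um = 0.2539) {
  side <- 2L * as.integer(search_distance) + 1L
  list(side_px = side, n_px = side * side,
       area_um2 = as.numeric(side)^2 * pixel_size_um^2)
}
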