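#' Find all contractions matching a template window
#'
#' Contractions of a pacemaker cell are highly stereotyped, so one
#' user-identified contraction (a frame window and a column range on the
#' curvature map) serves as a template for a least-difference search over
#' all candidate time offsets. The dissimilarity of a candidate window is
#' the mean absolute difference between its curvature sub-matrix and the
#' template's; a candidate is accepted when it is a local minimum of the
#' dissimilarity profile and lies below \code{match_threshold} percent of
#' the profile's maximum, so raising the threshold admits more (noisier)
#' matches. Accepted windows are constrained non-overlapping (lowest
#' dissimilarity wins) and returned sorted by time; the template window
#' itself always matches.
#'
#' @param cmap a [CurvatureMap-class].
#' @param frame_window template frames \code{c(t_start, t_end)}, 0-based
#'   inclusive.
#' @param column_range template columns \code{c(x_lo, x_hi)}, 0-based
#'   inclusive, within the defined spine span.
#' @param match_threshold acceptance level in percent of the maximum
#'   dissimilarity (default 20).
#' @return data.frame with 0-based columns \code{start}, \code{end} and
#'   \code{dissimilarity}, sorted by \code{start}.
#' @export
matchContractions <- function(cmap, frame_window, column_range,
                              match_threshold = 20) {
  stopifnot(is(cmap, "CurvatureMap"))
  k <- cmap@k
  TT <- nrow(k); W <- ncol(k)
  t0 <- frame_window[1] + 1L; t1 <- frame_window[2] + 1L
  if (t1 <= t0)
    stop("template window must span more than one frame", call. = FALSE)
  if (t0 < 1L || t1 > TT)
    stop("template window outside stack", call. = FALSE)
  cols <- (column_range[1] + 1L):(column_range[2] + 1L)
  if (any(cols < 1L) || any(cols > W))
    stop("column_range outside curvature map", call. = FALSE)
  L <- t1 - t0 + 1L
  template <- k[t0:t1, cols, drop = FALSE]
  starts <- seq_len(TT - L + 1L)
  d <- vapply(starts, function(s) {
    mean(abs(k[s:(s + L - 1L), cols, drop = FALSE] - template), na.rm = TRUE)
  }, numeric(1))
  if (all(!is.finite(d)))
    stop("curvature map undefined over the template columns", call. = FALSE)
  dmax <- max(d, na.rm = TRUE)
  nS <- length(d)
  localMin <- vapply(seq_len(nS), function(i) {
    left  <- if (i > 1L) d[i] <= d[i - 1L] else TRUE
    right <- if (i < nS) d[i] <= d[i + 1L] else TRUE
    left && right
  }, logical(1))
  accept <- which(localMin & d <= (match_threshold / 100) * dmax)
  # non-overlap: greedily keep lowest-dissimilarity candidates
  accept <- accept[order(d[accept])]
  kept <- integer(0)
  for (s in accept) {
    if (!any(abs(kept - s) < L)) kept <- c(kept, s)
  }
  kept <- sort(kept)
  data.frame(start = kept - 1L, end = kept + L - 2L,
             dissimilarity = d[kept])
}

#' Track a constant-curvature guide line through all contractions
#'
#' A horizontal guide at column \code{guide_x} follows a band of constant
#' curvature. Within the template contraction the user supplies a bend -- a
#' polyline of \code{(frame, offset)} vertices describing how far the band
#' deflects from the guide -- and that same bend is replayed, aligned to the
#' window start, in every matched contraction window. Outside all windows
#' the line stays at \code{guide_x}.
#'
#' @param cmap a [CurvatureMap-class] (provides the frame count).
#' @param guide_x baseline column position (0-based, real-valued).
#' @param bend data.frame or 2-column matrix of \code{(frame, offset)}
#'   vertices; frames are 0-based relative to a window start and offsets are
#'   in columns. An empty bend means the line never moves.
#' @param windows matched windows from [matchContractions()].
#' @return a \code{TrackedLine}: list with \code{baseline_x},
#'   \code{offsets} (per frame) and \code{L} (per-frame column position).
#' @export
trackLine <- function(cmap, guide_x, bend, windows) {
  TT <- nrow(cmap@k)
  offsets <- numeric(TT)
  if (is.null(bend) || NROW(bend) == 0L) {
    bf <- numeric(0); bo <- numeric(0)
  } else {
    bend <- as.matrix(bend)
    bf <- bend[, 1]; bo <- bend[, 2]
    if (any(bf < 0))
      stop("bend vertices must lie within the template window", call. = FALSE)
  }
  if (NROW(windows) > 0 && length(bf) > 0) {
    wlen <- windows$end[1] - windows$start[1] + 1L
    if (any(bf > wlen - 1L))
      stop("bend vertices must lie within the template window", call. = FALSE)
    for (i in seq_len(nrow(windows))) {
      s <- windows$start[i]; e <- windows$end[i]
      dt <- seq.int(0L, e - s)
      off <- if (length(bf) == 1L) rep(bo, length(dt)) else
        stats::approx(bf, bo, xout = dt, rule = 2)$y
      offsets[(s:e) + 1L] <- off
    }
  }
  structure(list(baseline_x = guide_x, offsets = offsets,
                 L = guide_x + offsets),
            class = "TrackedLine")
}

#' Interpolate new guide lines between tracked neighbours
#'
#' Inserts \code{n_between} lines between each neighbouring pair of tracked
#' lines, linearly interpolating both the baseline column and the per-frame
#' offsets. Input lines must be sorted by baseline and must never cross.
#'
#' @param lines list of \code{TrackedLine} objects sorted by
#'   \code{baseline_x}.
#' @param n_between number of lines to insert per neighbouring pair.
#' @return list of \code{TrackedLine} objects (originals plus insertions,
#'   sorted by baseline).
#' @export
interpolateLines <- function(lines, n_between) {
  if (length(lines) < 2L)
    stop("need at least two lines", call. = FALSE)
  bl <- vapply(lines, `[[`, numeric(1), "baseline_x")
  if (is.unsorted(bl, strictly = TRUE))
    stop("lines must be sorted by baseline_x", call. = FALSE)
  for (i in seq_len(length(lines) - 1L)) {
    bad <- which(lines[[i]]$L >= lines[[i + 1L]]$L)
    if (length(bad) > 0)
      stop(sprintf("lines %d and %d cross at frame %d", i, i + 1L,
                   bad[1] - 1L), call. = FALSE)
  }
  if (n_between == 0L) return(lines)
  out <- list(lines[[1L]])
  for (i in seq_len(length(lines) - 1L)) {
    a <- lines[[i]]; b <- lines[[i + 1L]]
    for (j in seq_len(n_between)) {
      w <- j / (n_between + 1)
      off <- (1 - w) * a$offsets + w * b$offsets
      base <- (1 - w) * a$baseline_x + w * b$baseline_x
      out[[length(out) + 1L]] <- structure(
        list(baseline_x = base, offsets = off, L = base + off),
        class = "TrackedLine")
    }
    out[[length(out) + 1L]] <- b
  }
  out
}

#' Per-frame spine points under the tracked lines
#'
#' Evaluates the spine at each line's per-frame column position,
#' interpolating linearly between integer columns, and returns the ordered
#' point set \code{(L_i(t), zeta(L_i(t), t))} that seeds the stabilization
#' mesh.
#'
#' @param lines list of \code{TrackedLine} objects.
#' @param cmap a [CurvatureMap-class] (its gap-filled spine is used).
#' @return numeric array \code{T x n x 2} of 0-based \code{(x, y)} points,
#'   ordered by x within every frame.
#' @export
spinePoints <- function(lines, cmap) {
  zeta <- cmap@zeta
  TT <- nrow(zeta)
  n <- length(lines)
  pts <- array(NA_real_, dim = c(TT, n, 2L))
  for (t in seq_len(TT)) {
    def <- which(!is.na(zeta[t, ]))
    lo <- min(def); hi <- max(def)
    xs <- vapply(lines, function(l) l$L[t], numeric(1))
    if (any(xs < lo - 1L) || any(xs > hi - 1L))
      stop(sprintf("line position outside defined spine span at frame %d",
                   t - 1L), call. = FALSE)
    ys <- stats::approx(def - 1L, zeta[t, def], xout = xs)$y
    ord <- order(xs)
    pts[t, , 1L] <- xs[ord]
    pts[t, , 2L] <- ys[ord]
  }
  pts
}
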