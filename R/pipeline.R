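#' Run the full LCR detection pipeline on a (stabilized) stack
#'
#' Chains cell segmentation (max filter), 0-255 normalization, whole-cell
#' transient removal, optional despeckling, the spatiotemporal differential
#' filter, SD-thresholded candidacy with the 7-of-8 fill, cluster formation
#' under the size/intensity birth tests, and lifecycle tracking with the
#' three death modes, then finalizes the per-event parameter records.
#'
#' @param stack an [ImageStack-class], already stabilized (or from a
#'   non-contracting preparation).
#' @param config a [RunConfig-class].
#' @param mask optional logical \code{H x W} cell mask; when missing it is
#'   computed with [maxFilterMask()].
#' @param calibration optional list with \code{limits} (Eq-6 normalization
#'   anchors) and \code{sigma_cell}, freezing the intensity scale and noise
#'   level to those of another run; used by [falsePositiveRate()] so the
#'   control region is analysed by the identical instrument.
#' @return an [LCRAnalysis-class].
#' @examples
#' sim <- simulateMovie(seed = 1, n_frames = 60, width = 96, height = 32,
#'                      n_events_per_cycle = 2)
#' res <- detectLCRs(sim$stack, runConfig(intensity_threshold = 200))
#' eventRecords(res)
#' @export
detectLCRs <- function(stack, config = runConfig(), mask = NULL,
                       calibration = NULL) {
  stopifnot(is(stack, "ImageStack"), is(config, "RunConfig"))
  if (is.null(mask)) {
    mask <- maxFilterMask(stack)$mask
  } else {
    stopifnot(is.logical(mask), all(dim(mask) == dim(stack)[1:2]))
    if (!any(mask)) stop("mask is empty", call. = FALSE)
  }
  fnorm <- normalizeStack(stack, mask,
                          limits = calibration$limits)
  rt <- removeTransient(fnorm, mask, config@transientsPresent)
  fnt <- despeckle(rt$f_nt, mask, config@medianFilter, config@meanFilter)
  anchors <- NULL
  suspended <- integer(0)
  if (config@transientsPresent) {
    anchors <- cycleAnchors(rt$f_a, config@transientCutoffPercent)
    suspended <- anchors$suspended
  }
  df <- differentialFilter(fnt, mask, config@searchDistance)
  sigmaCell <- if (!is.null(calibration$sigma_cell))
    calibration$sigma_cell else df$sigma_cell
  TT <- dim(fnt)[3]
  cand <- candidateMask(df$D, sigmaCell, config@sdDetection,
                        suspended, mask)
  thrMass <- config@intensityThreshold * sigmaCell
  clusters <- lapply(seq_len(TT), function(t)
    findClusters(cand[, , t], df$D[, , t], config@sizeThreshold, thrMass))
  events <- trackEvents(clusters, fnt, sigmaCell, config, anchors,
                        S = df$S)
  fin <- finalizeEvents(events, anchors, fnt, TT)
  new("LCRAnalysis",
      records = fin$records, traces = fin$traces, ensemble = fin$ensemble,
      fa = rt$f_a, anchors = if (is.null(anchors)) list() else anchors,
      sigmaCell = sigmaCell, mask = mask, events = events,
      config = config)
}

#' False-positive rate from an off-cell control substack
#'
#' Runs the identical detection procedure twice: once on the cell (using
#' its max-filter mask) and once treating a user-chosen off-cell rectangle
#' -- which contains instrumental noise but no LCRs -- as if it were the
#' cell area. The control run is performed under the cell run's calibration
#' (its normalization anchors and noise SD), so the very same instrument --
#' identical resolved thresholds in identical units -- is pointed at a
#' region where nothing but noise exists; recalibrating on the noise region
#' itself would stretch its gray scale ~10-fold and test a different
#' detector. Any event found in the control region is by construction a
#' false positive; normalizing both counts by their search areas gives a
#' dimensionless rate
#' \deqn{fp = 100 \cdot \frac{N_{ctrl}/A_{ctrl}}{N_{cell}/A_{cell}}}
#' comparable across region sizes. The rate is 0 when both runs find
#' nothing.
#'
#' @param stack an [ImageStack-class].
#' @param control_region off-cell rectangle \code{c(x, y, w, h)} (0-based)
#'   or an \code{"x,y,w,h"} string; must not overlap the cell mask.
#' @param config a [RunConfig-class].
#' @param cell_mask optional precomputed cell mask.
#' @return list with \code{control_events}, \code{cell_events},
#'   \code{control_area_px}, \code{cell_area_px}, \code{fp_rate_percent}.
#' @export
falsePositiveRate <- function(stack, control_region, config = runConfig(),
                              cell_mask = NULL) {
  d <- dim(stack)
  reg <- parseRegion(control_region, d[1], d[2], "control_region")
  if (is.null(cell_mask)) cell_mask <- maxFilterMask(stack)$mask
  ctrlMask <- matrix(FALSE, d[1], d[2])
  ctrlMask[reg$rows, reg$cols] <- TRUE
  if (any(ctrlMask & cell_mask))
    stop("control region overlaps the cell mask", call. = FALSE)
  cellRes <- detectLCRs(stack, config, mask = cell_mask)
  cellVals <- frames(stack)[rep(cell_mask, dim(stack)[3])]
  calib <- list(limits = range(cellVals), sigma_cell = cellRes@sigmaCell)
  ctrlRes <- tryCatch(detectLCRs(stack, config, mask = ctrlMask,
                                 calibration = calib),
                      error = function(e) NULL)
  nCtrl <- if (is.null(ctrlRes)) 0L else nrow(eventRecords(ctrlRes))
  nCell <- nrow(eventRecords(cellRes))
  aCtrl <- sum(ctrlMask); aCell <- sum(cell_mask)
  fp <- if (nCell == 0L) {
    if (nCtrl == 0L) 0 else Inf
  } else {
    100 * (nCtrl / aCtrl) * aCell / nCell
  }
  list(control_events = nCtrl, cell_events = nCell,
       control_area_px = aCtrl, cell_area_px = aCell,
       fp_rate_percent = fp)
}
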