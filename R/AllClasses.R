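#' @import methods
NULL

#' ImageStack: a 2D+time fluorescence recording
#'
#' Container for a multi-frame grayscale image stack together with the
#' acquisition metadata the downstream analysis needs. Frames are stored as a
#' numeric \code{H x W x T} array indexed \code{[row, column, frame]}; all
#' user-facing coordinates in this package are 0-based with \code{x} the
#' column index (increasing rightward) and \code{y} the row index (increasing
#' downward).
#'
#' @slot frames numeric array, \code{H x W x T}, finite and non-negative.
#' @slot pixelSizeUm positive scalar, pixel edge length in micrometres.
#' @slot frameIntervalMs positive scalar, inter-frame interval in
#'   milliseconds.
#'
#' @seealso [readStack()], [writeStack()], [simulateMovie()]
#' @export
setClass("ImageStack",
  representation(
    frames          = "array",
    pixelSizeUm     = "numeric",
    frameIntervalMs = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("frames must be a 3D array (H x W x T)")
  if (d[3] < 2L)
    return("stack must have >= 2 frames")
  if (d[1] < 8L || d[2] < 8L)
    return("frame dimensions must be >= 8 x 8 pixels")
  if (anyNA(object@frames) || any(!is.finite(object@frames)))
    return("intensities must be finite")
  if (any(object@frames < 0))
    return("intensities must be non-negative")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a positive scalar")
  if (length(object@frameIntervalMs) != 1L || object@frameIntervalMs <= 0)
    return("frameIntervalMs must be a positive scalar")
  TRUE
})

#' RunConfig: user-definable analysis parameters
#'
#' All tunable parameters of the stabilization and detection pipeline,
#' validated on construction. Names mirror the detector's user interface
#' vocabulary (search distance, SD detection, SD termination, transient
#' cutoff, size/intensity thresholds).
#'
#' @slot searchDistance integer >= 1; spatial averaging half-width of the
#'   differential filter. A value \code{d} averages over a
#'   \code{(2d+1) x (2d+1)} pixel window.
#' @slot sdDetection positive scalar; candidacy threshold as a multiple of
#'   the cell-wide SD of the differential signal.
#' @slot sdTermination positive scalar; decay-death threshold as a multiple
#'   of the same SD.
#' @slot transientCutoffPercent scalar in \code{[0, 100]}; level of the
#'   rising whole-cell transient (as a percentage of its nadir-to-peak
#'   excursion) beyond which LCR search is suspended.
#' @slot sizeThreshold integer >= 1; minimum pixel count for a newborn LCR.
#' @slot intensityThreshold non-negative scalar; minimum summed
#'   (transient-subtracted, normalized) intensity for a newborn LCR.
#' @slot medianFilter,meanFilter logical flags for the optional 3x3
#'   despeckling filters.
#' @slot transientsPresent logical; whether whole-cell transients exist in
#'   the recording (unset for e.g. permeabilized cells).
#' @slot triangleHeight positive scalar; mesh triangle height in pixels.
#' @slot matchThreshold positive scalar; contraction match sensitivity in
#'   percent (larger admits more matches).
#' @slot sgWindow odd integer; Savitzky-Golay window (columns).
#' @slot sgOrder integer < sgWindow; Savitzky-Golay polynomial order.
#'
#' @seealso [runConfig()], [readRunConfig()]
#' @export
setClass("RunConfig",
  representation(
    searchDistance         = "integer",
    sdDetection            = "numeric",
    sdTermination          = "numeric",
    transientCutoffPercent = "numeric",
    sizeThreshold          = "integer",
    intensityThreshold     = "numeric",
    medianFilter           = "logical",
    meanFilter             = "logical",
    transientsPresent      = "logical",
    triangleHeight         = "numeric",
    matchThreshold         = "numeric",
    sgWindow               = "integer",
    sgOrder                = "integer"
  )
)

setValidity("RunConfig", function(object) {
  sc1 <- function(x) length(x) == 1L && !is.na(x)
  if (!sc1(object@searchDistance) || object@searchDistance < 1L)
    return("search_distance must be an integer >= 1")
  if (!sc1(object@sdDetection) || object@sdDetection <= 0)
    return("sd_detection must be a positive real")
  if (!sc1(object@sdTermination) || object@sdTermination <= 0)
    return("sd_termination must be a positive real")
  if (!sc1(object@transientCutoffPercent) ||
      object@transientCutoffPercent < 0 || object@transientCutoffPercent > 100)
    return("transient_cutoff_percent must lie in [0, 100]")
  if (!sc1(object@sizeThreshold) || object@sizeThreshold < 1L)
    return("size_threshold must be an integer >= 1")
  if (!sc1(object@intensityThreshold) || object@intensityThreshold < 0)
    return("intensity_threshold must be non-negative")
  for (fl in c("medianFilter", "meanFilter", "transientsPresent"))
    if (!sc1(slot(object, fl)))
      return(sprintf("%s must be TRUE or FALSE", fl))
  if (!sc1(object@triangleHeight) || object@triangleHeight <= 0)
    return("triangle_height must be a positive real")
  if (!sc1(object@matchThreshold) || object@matchThreshold <= 0)
    return("match_threshold must be a positive real")
  if (!sc1(object@sgWindow) || object@sgWindow < 3L ||
      object@sgWindow %% 2L == 0L)
    return("sg_window must be an odd integer >= 3")
  if (!sc1(object@sgOrder) || object@sgOrder < 1L ||
      object@sgOrder >= object@sgWindow)
    return("sg_order must be a positive integer < sg_window")
  TRUE
})

#' CurvatureMap: local curvature of the cell spine over time
#'
#' Per-frame, per-column curvature \code{k(t, x)} of the intensity-weighted
#' centre-of-mass spine, the substrate on which contractions are matched and
#' guide lines tracked. Rows are frames, columns are image columns; entries
#' are \code{NA} outside the Savitzky-Golay interior of the defined spine
#' span.
#'
#' @slot k numeric \code{T x W} matrix of curvature values.
#' @slot zeta numeric \code{T x W} matrix of the (gap-filled) spine
#'   y-coordinates used for differentiation (0-based y).
#' @slot interpolated logical \code{T x W} matrix flagging spine entries
#'   that were filled by linear interpolation rather than measured.
#' @slot sgWindow,sgOrder Savitzky-Golay parameters used.
#' @export
setClass("CurvatureMap",
  representation(
    k            = "matrix",
    zeta         = "matrix",
    interpolated = "matrix",
    sgWindow     = "integer",
    sgOrder      = "integer"
  )
)

setValidity("CurvatureMap", function(object) {
  if (!all(dim(object@k) == dim(object@zeta)))
    return("k and zeta must have identical dimensions")
  if (!all(dim(object@k) == dim(object@interpolated)))
    return("interpolated flag matrix must match k dimensions")
  TRUE
})

#' TriangleMesh: per-frame tracked triangular grid
#'
#' The mesh that drives piecewise-affine stabilization. Vertices are the
#' tracked spine points plus, for each adjacent pair, one apex above and one
#' below the spine at a user-defined height; topology is identical in every
#' frame so each triangle defines a per-frame affine map to the reference
#' geometry.
#'
#' @slot vertices numeric array \code{T x nV x 2} of 0-based \code{(x, y)}
#'   vertex coordinates per frame.
#' @slot triangles integer \code{nT x 3} matrix of vertex indices (1-based,
#'   constant across frames).
#' @slot height positive scalar, apex height in pixels.
#' @export
setClass("TriangleMesh",
  representation(
    vertices  = "array",
    triangles = "matrix",
    height    = "numeric"
  )
)

setValidity("TriangleMesh", function(object) {
  d <- dim(object@vertices)
  if (length(d) != 3L || d[3] != 2L)
    return("vertices must be a T x nV x 2 array")
  if (ncol(object@triangles) != 3L)
    return("triangles must have 3 columns")
  if (any(object@triangles < 1L) || any(object@triangles > d[2]))
    return("triangle indices out of vertex range")
  if (object@height <= 0)
    return("triangle height must be positive")
  TRUE
})

#' LCRAnalysis: result of a full detection run
#'
#' Bundles the finalized per-event records, the per-event size traces and
#' their ensemble sum, the whole-cell average trace with its cycle anchors,
#' the scalar noise level the thresholds were measured against, the cell
#' mask, the internal event list (per-frame pixel sets) and the resolved
#' configuration.
#'
#' @slot records data.frame, one row per LCR (see [writeEventTable()] for
#'   the column contract).
#' @slot traces data.frame with columns \code{id, frame, area_px}: per-event
#'   size-versus-frame traces.
#' @slot ensemble numeric vector, per-frame sum of all event areas.
#' @slot fa numeric vector, per-frame cell-average normalized fluorescence.
#' @slot anchors list with \code{peaks}, \code{nadirs}, \code{suspended}
#'   (0-based frames), or empty when transients are absent.
#' @slot sigmaCell scalar SD of the differential signal over the cell.
#' @slot mask logical \code{H x W} cell mask.
#' @slot events list of internal event objects (per-frame pixel sets).
#' @slot config the [RunConfig-class] used.
#' @export
setClass("LCRAnalysis",
  representation(
    records   = "data.frame",
    traces    = "data.frame",
    ensemble  = "numeric",
    fa        = "numeric",
    anchors   = "list",
    sigmaCell = "numeric",
    mask      = "matrix",
    events    = "list",
    config    = "RunConfig"
  )
)
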