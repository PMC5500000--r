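#' Accessors for ImageStack and friends
#'
#' @param x an object.
#' @return \code{frames()} the raw \code{H x W x T} array; \code{nFrames()}
#'   the number of frames; \code{pixelSize()} the pixel edge in micrometres;
#'   \code{frameInterval()} the frame interval in milliseconds.
#' @name stack-accessors
#' @aliases frames nFrames pixelSize frameInterval
NULL

#' @rdname stack-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname stack-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname stack-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname stack-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname stack-accessors
#' @export
setMethod("frames", "ImageStack", function(x) x@frames)

#' @rdname stack-accessors
#' @export
setMethod("nFrames", "ImageStack", function(x) dim(x@frames)[3])

#' @rdname stack-accessors
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSizeUm)

#' @rdname stack-accessors
#' @export
setMethod("frameInterval", "ImageStack", function(x) x@frameIntervalMs)

#' @describeIn stack-accessors dimensions \code{c(H, W, T)}.
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@frames))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "ImageStack: %d frames of %d x %d px (%.4g um/px, %.4g ms/frame)\n",
    d[3], d[1], d[2], object@pixelSizeUm, object@frameIntervalMs))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@frames), max(object@frames)))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  kv <- configToList(object)
  for (k in names(kv)) cat(sprintf("  %-24s %s\n", k, format(kv[[k]])))
})

setMethod("show", "CurvatureMap", function(object) {
  cat(sprintf(
    "CurvatureMap: %d frames x %d columns (SG window %d, order %d)\n",
    nrow(object@k), ncol(object@k), object@sgWindow, object@sgOrder))
  cat(sprintf("  defined at %d of %d entries\n",
              sum(!is.na(object@k)), length(object@k)))
})

setMethod("show", "TriangleMesh", function(object) {
  d <- dim(object@vertices)
  cat(sprintf(
    "TriangleMesh: %d frames, %d vertices, %d triangles, height %.3g px\n",
    d[1], d[2], nrow(object@triangles), object@height))
})

setMethod("show", "LCRAnalysis", function(object) {
  cat(sprintf("LCRAnalysis: %d LCR(s) over %d frames\n",
              nrow(object@records), length(object@ensemble)))
  if (nrow(object@records) > 0) {
    cat(sprintf("  dead: %d  alive at end: %d\n",
                sum(object@records$dead), sum(!object@records$dead)))
  }
  cat(sprintf("  sigma_cell = %.4g\n", object@sigmaCell))
})

#' @describeIn LCRAnalysis-class finalized event table.
#' @param object,x an \code{LCRAnalysis}.
#' @export
setGeneric("eventRecords", function(x) standardGeneric("eventRecords"))

#' @rdname LCRAnalysis-class
#' @export
setMethod("eventRecords", "LCRAnalysis", function(x) x@records)

#' @describeIn LCRAnalysis-class per-event size-vs-frame traces.
#' @export
setGeneric("eventTraces", function(x) standardGeneric("eventTraces"))

#' @rdname LCRAnalysis-class
#' @export
setMethod("eventTraces", "LCRAnalysis", function(x) x@traces)

#' @describeIn LCRAnalysis-class per-frame sum of all event areas (the
#'   ensemble signal).
#' @export
setGeneric("ensembleTrace", function(x) standardGeneric("ensembleTrace"))

#' @rdname LCRAnalysis-class
#' @export
setMethod("ensembleTrace", "LCRAnalysis", function(x) x@ensemble)

#' @describeIn LCRAnalysis-class logical cell mask used for the run.
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))

#' @rdname LCRAnalysis-class
#' @export
setMethod("cellMask", "LCRAnalysis", function(x) x@mask)
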