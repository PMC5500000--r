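#' Create an ImageStack from an array
#'
#' @param frames numeric \code{H x W x T} array (\code{[row, column,
#'   frame]}) of non-negative intensities.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param frame_interval_ms frame interval in milliseconds.
#' @return an [ImageStack-class].
#' @export
imageStack <- function(frames, pixel_size_um = 1, frame_interval_ms = 10) {
  new("ImageStack", frames = frames,
      pixelSizeUm = as.numeric(pixel_size_um),
      frameIntervalMs = as.numeric(frame_interval_ms))
}

#' Read a multi-page grayscale TIFF as an ImageStack
#'
#' Frames are ordered by page index. Acquisition metadata (pixel size and
#' frame interval) is supplied by the caller or the run configuration and is
#' deliberately never guessed from TIFF tags: cameras and binning vary and
#' an explicit value beats an inferred one.
#'
#' @param path a multi-page grayscale TIFF (8- or 16-bit).
#' @inheritParams imageStack
#' @return an [ImageStack-class].
#' @seealso [writeStack()]
#' @export
readStack <- function(path, pixel_size_um = 1, frame_interval_ms = 10) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) < 2L)
    stop("stack must have >= 2 frames", call. = FALSE)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("input must be single-channel grayscale (RGB not supported)",
         call. = FALSE)
  d1 <- dim(pages[[1]])
  arr <- array(0, dim = c(d1[1], d1[2], length(pages)))
  for (t in seq_along(pages)) {
    if (!all(dim(pages[[t]]) == d1))
      stop("all pages must share the same dimensions", call. = FALSE)
    arr[, , t] <- pages[[t]]
  }
  imageStack(arr, pixel_size_um, frame_interval_ms)
}

#' Write an ImageStack as a multi-page grayscale TIFF
#'
#' Intensities are rounded and clipped to the declared bit depth; when
#' clipping occurs a warning reports how many samples were affected.
#'
#' @param stack an [ImageStack-class].
#' @param path destination path.
#' @param bits_per_sample 8 or 16.
#' @return invisibly, \code{path}.
#' @export
writeStack <- function(stack, path, bits_per_sample = 16L) {
  stopifnot(is(stack, "ImageStack"))
  if (!bits_per_sample %in% c(8L, 16L))
    stop("bits_per_sample must be 8 or 16", call. = FALSE)
  maxv <- 2^bits_per_sample - 1
  arr <- round(frames(stack))
  nClip <- sum(arr > maxv)
  if (nClip > 0)
    warning(sprintf("%d sample(s) exceeded %d and were clipped", nClip,
                    as.integer(maxv)))
  arr <- pmin(arr, maxv)
  pages <- lapply(seq_len(dim(arr)[3]), function(t) arr[, , t] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits_per_sample))
  invisible(path)
}

# fixed event-table column contract
.eventColumns <- c(
  "id", "max_x", "min_x", "max_y", "min_y", "start_area_px", "max_area_px",
  "path_area_px", "birth_from_nadir_frames", "lcr_cycle_frames",
  "birth_from_start_frames", "duration_frames", "half_max_amplitude",
  "dead", "dead_by_collision", "dead_by_transient",
  "dead_by_stochastic_attrition")

#' Write (and read back) the LCR event table
#'
#' One CSV row per LCR with a fixed, order-stable column set; booleans are
#' serialized as \code{true}/\code{false} literals. A companion CSV (same
#' path with suffix \code{_traces}) holds the per-event size-versus-frame
#' traces.
#'
#' @param records data.frame of finalized LCR records
#'   (from [finalizeEvents()] or [eventRecords()]).
#' @param path destination CSV path.
#' @param traces optional data.frame \code{(id, frame, area_px)} written to
#'   the companion file.
#' @return invisibly, \code{path}.
#' @export
writeEventTable <- function(records, path, traces = NULL) {
  out <- if (nrow(records) == 0) {
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol =
      length(.eventColumns))), .eventColumns)
  } else {
    if (!all(.eventColumns %in% names(records)))
      stop("records is missing required columns", call. = FALSE)
    records[, .eventColumns, drop = FALSE]
  }
  for (cc in names(out))
    if (is.logical(out[[cc]]))
      out[[cc]] <- ifelse(out[[cc]], "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(traces)) {
    tp <- sub("(\\.[^.]*)?$", "_traces\\1", path)
    utils::write.csv(traces, tp, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cc in c("dead", "dead_by_collision", "dead_by_transient",
               "dead_by_stochastic_attrition"))
    if (cc %in% names(df)) df[[cc]] <- df[[cc]] == "true"
  df
}

#' Export a curvature map for visual inspection
#'
#' Writes the \code{T x W} curvature matrix as CSV (frames as rows) so the
#' banded structure of bends can be inspected in any plotting tool.
#'
#' @param cmap a [CurvatureMap-class].
#' @param path destination CSV path.
#' @return invisibly, \code{path}.
#' @export
writeCurvatureMap <- function(cmap, path) {
  stopifnot(is(cmap, "CurvatureMap"))
  utils::write.table(cmap@k, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}
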