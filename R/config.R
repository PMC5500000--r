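#' Construct a run configuration
#'
#' Builds a validated [RunConfig-class] from named arguments. Defaults are
#' the package's reference operating point for fluo-4 recordings sampled at
#' ~10 ms/frame (see the methods vignette for how they were chosen).
#'
#' @param search_distance spatial averaging half-width (pixels); the
#'   differential filter averages over a \code{(2d+1)^2} window.
#' @param sd_detection candidacy threshold, in multiples of the cell-wide SD
#'   of the differential signal.
#' @param sd_termination decay-death threshold, same units.
#' @param transient_cutoff_percent percent of the nadir-to-peak excursion of
#'   the whole-cell transient beyond which LCR search is suspended.
#' @param size_threshold minimum pixel count of a newborn LCR.
#' @param intensity_threshold minimum summed differential-signal mass of a
#'   newborn LCR, in multiples of \code{sigma_cell} (scale-free, so the
#'   same value applies to a renormalized off-cell control run).
#' @param median_filter,mean_filter enable the optional 3x3 despeckling
#'   filters (median first when both are set).
#' @param transients_present whether the recording contains whole-cell
#'   transients; unset for permeabilized cells.
#' @param triangle_height stabilization mesh triangle height (pixels).
#' @param match_threshold contraction match sensitivity (percent; larger
#'   admits more matches).
#' @param sg_window,sg_order Savitzky-Golay window (odd) and polynomial
#'   order used for spine derivatives.
#' @return a validated \code{RunConfig}.
#' @examples
#' cfg <- runConfig(sd_detection = 1, size_threshold = 8)
#' cfg
#' @export
runConfig <- function(search_distance = 3L,
                      sd_detection = 1,
                      sd_termination = 1,
                      transient_cutoff_percent = 20,
                      size_threshold = 8L,
                      intensity_threshold = 165,
                      median_filter = FALSE,
                      mean_filter = FALSE,
                      transients_present = TRUE,
                      triangle_height = 20,
                      match_threshold = 20,
                      sg_window = 11L,
                      sg_order = 3L) {
  new("RunConfig",
      searchDistance         = as.integer(search_distance),
      sdDetection            = as.numeric(sd_detection),
      sdTermination          = as.numeric(sd_termination),
      transientCutoffPercent = as.numeric(transient_cutoff_percent),
      sizeThreshold          = as.integer(size_threshold),
      intensityThreshold     = as.numeric(intensity_threshold),
      medianFilter           = as.logical(median_filter),
      meanFilter             = as.logical(mean_filter),
      transientsPresent      = as.logical(transients_present),
      triangleHeight         = as.numeric(triangle_height),
      matchThreshold         = as.numeric(match_threshold),
      sgWindow               = as.integer(sg_window),
      sgOrder                = as.integer(sg_order))
}

# slot name <-> config-file key correspondence
.configKeys <- c(
  searchDistance         = "search_distance",
  sdDetection            = "sd_detection",
  sdTermination          = "sd_termination",
  transientCutoffPercent = "transient_cutoff_percent",
  sizeThreshold          = "size_threshold",
  intensityThreshold     = "intensity_threshold",
  medianFilter           = "median_filter",
  meanFilter             = "mean_filter",
  transientsPresent      = "transients_present",
  triangleHeight         = "triangle_height",
  matchThreshold         = "match_threshold",
  sgWindow               = "sg_window",
  sgOrder                = "sg_order")

configToList <- function(config) {
  out <- lapply(names(.configKeys), function(s) slot(config, s))
  names(out) <- unname(.configKeys)
  out
}

#' Read / write a run configuration file
#'
#' Configurations are plain-text YAML key-value files using the snake_case
#' parameter names of [runConfig()]. Unknown keys are an error (they are
#' almost always typos); missing keys fall back to the defaults unless
#' \code{strict} names them as required.
#'
#' @param path file path.
#' @param strict character vector of keys that must be present (used by the
#'   command-line interface to insist on explicit detection parameters).
#' @return \code{readRunConfig} returns a [RunConfig-class];
#'   \code{writeRunConfig} invisibly returns \code{path}.
#' @export
readRunConfig <- function(path, strict = character()) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- unname(.configKeys)
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(strict, names(raw))
  if (length(missing) > 0)
    stop("missing required config key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(runConfig, raw[intersect(names(raw), known)])
}

#' @rdname readRunConfig
#' @param config a [RunConfig-class].
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  yaml::write_yaml(configToList(config), path)
  invisible(path)
}

#' Write an audit copy of the resolved parameters next to outputs
#'
#' Every pipeline run records the fully-resolved parameter set so that
#' results always travel with the configuration that produced them.
#'
#' @param config a [RunConfig-class].
#' @param outDir output directory.
#' @param extra named list of additional entries (seed, input paths, ...).
#' @return invisibly, the path written.
#' @export
auditConfig <- function(config, outDir, extra = list()) {
  p <- file.path(outDir, "resolved_parameters.yaml")
  yaml::write_yaml(c(configToList(config), extra), p)
  invisible(p)
}
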