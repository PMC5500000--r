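#' Pacemaker-cycle anchors from the whole-cell trace
#'
#' Locates the AP-induced transient peaks (local maxima of the cell-average
#' trace above half its global range, one per excursion), the nadirs
#' between consecutive peaks, and the suspended frames: for each cycle,
#' frames on the rising limb where the trace has climbed past
#' \code{transient_cutoff_percent} of the nadir-to-peak excursion. During
#' suspended frames the detector stops looking for LCRs -- the onrushing
#' transient has engulfed the cytoplasm.
#'
#' @param f_a per-frame cell-average trace from [removeTransient()].
#' @param transient_cutoff_percent cutoff in \code{[0, 100]}; 0 suspends
#'   the whole nadir-to-peak limb, 100 only the peak itself.
#' @return list with 0-based \code{peaks}, \code{nadirs} (one per cycle,
#'   including the leading segment before the first peak) and
#'   \code{suspended} (sorted frame vector).
#' @export
cycleAnchors <- function(f_a, transient_cutoff_percent = 50) {
  TT <- length(f_a)
  rng <- range(f_a)
  if (diff(rng) <= 0) stop("no transient peak found (flat trace)",
                           call. = FALSE)
  mid <- rng[1] + 0.5 * diff(rng)
  # hysteresis peak picking: one peak per excursion above mid
  peaks <- integer(0)
  inHigh <- FALSE; argmax <- NA_integer_
  for (t in seq_len(TT)) {
    if (!inHigh && f_a[t] >= mid) { inHigh <- TRUE; argmax <- t }
    if (inHigh) {
      if (f_a[t] > f_a[argmax]) argmax <- t
      if (f_a[t] < mid || t == TT) {
        peaks <- c(peaks, argmax)
        inHigh <- FALSE
      }
    }
  }
  if (length(peaks) == 0L) stop("no transient peak found", call. = FALSE)
  # nadirs: leading segment plus between consecutive peaks
  nadirs <- integer(0)
  segStart <- 1L
  for (p in peaks) {
    seg <- segStart:p
    nadirs <- c(nadirs, seg[which.min(f_a[seg])])
    segStart <- p
  }
  suspended <- integer(0)
  for (i in seq_along(peaks)) {
    n <- nadirs[i]; p <- peaks[i]
    thr <- f_a[n] + (transient_cutoff_percent / 100) * (f_a[p] - f_a[n])
    seg <- n:p
    suspended <- c(suspended, seg[f_a[seg] >= thr])
  }
  list(peaks = peaks - 1L, nadirs = nadirs - 1L,
       suspended = sort(unique(suspended)) - 1L)
}

# internal: blank event record; bframe = pre-birth baseline frame used by
# the elevation-based termination test
newEvent <- function(id, birth, pixels) {
  list(id = id, birth = birth, bframe = max(birth - 1L, 0L), last = birth,
       dead = FALSE, mode = "none", death = NA_integer_,
       pixelsByFrame = stats::setNames(list(pixels), as.character(birth)))
}

# internal: 4-neighbourhood expansion of a pixel index set (H x W grid)
expandPixels <- function(px, H, W) {
  xy <- indexToXY(px, H)
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x, x - 1L, x + 1L, x, x)
  ys <- c(y, y, y, y - 1L, y + 1L)
  ok <- xs >= 0L & xs < W & ys >= 0L & ys < H
  unique(xs[ok] * H + ys[ok] + 1L)
}

#' Advance LCR identities by one frame
#'
#' Implements the lifecycle rules at frame \code{t}: a cluster that
#' overlaps or shares a 4-border with exactly one active LCR joins it; a
#' cluster bridging two or more LCRs triggers a collision in which the
#' largest LCR (by previous-frame area, ties to the lower id) survives and
#' absorbs all bridged pixels while the others die by collision; an LCR
#' whose pixels appear as several separated components keeps a single
#' identity covering all of them; and remaining birth-eligible clusters
#' found new LCRs. A pixel stays part of an LCR until the LCR terminates:
#' joining clusters are united with the event's previous pixels, and an LCR
#' that receives no cluster carries its pixels forward unchanged.
#'
#' @param clusters cluster list for frame t from [findClusters()].
#' @param active list of active event objects (internal representation).
#' @param t current frame (0-based).
#' @param H,W frame dimensions.
#' @param next_id next id to assign to a newborn.
#' @param S optional \code{H x W x T} array of the spatially averaged
#'   conditioned signal: carried pixels are retained only while their
#'   elevation above the event's pre-birth baseline frame,
#'   \code{S[p, t] - S[p, birth - 1]}, stays at or above
#'   \code{retain_level} (a pixel stays part of an LCR until its local
#'   signal has decayed back to where it started).
#' @param retain_level retention threshold
#'   (\code{sd_termination * sigma_cell} in the pipeline).
#' @return list with updated \code{active}, \code{dead} (newly dead by
#'   collision) and \code{next_id}.
#' @export
updateEvents <- function(clusters, active, t, H, W, next_id = 1L,
                         S = NULL, retain_level = -Inf) {
  nE <- length(active)
  nC <- length(clusters)
  touched <- vector("list", nC)  # event indices touched by each cluster
  if (nE > 0 && nC > 0) {
    prevSets <- lapply(active, function(e)
      e$pixelsByFrame[[as.character(t - 1L)]])
    expanded <- lapply(clusters, function(cl) expandPixels(cl$pixels, H, W))
    for (ci in seq_len(nC)) {
      touched[[ci]] <- which(vapply(prevSets, function(ps)
        !is.null(ps) && any(expanded[[ci]] %in% ps), logical(1)))
    }
  }
  # group events connected through shared clusters (collision groups)
  parent <- seq_len(nE)
  root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ci in seq_len(nC)) {
    ev <- touched[[ci]]
    if (length(ev) >= 2L) {
      r0 <- root(ev[1])
      for (e in ev[-1]) parent[root(e)] <- r0
    }
  }
  groups <- split(seq_len(nE), vapply(seq_len(nE), root, integer(1)))

  newPixels <- vector("list", nE)
  deadNow <- list()
  for (g in groups) {
    cls <- which(vapply(touched, function(tv) any(tv %in% g), logical(1)))
    px <- if (length(cls) > 0)
      unique(unlist(lapply(clusters[cls], `[[`, "pixels"))) else integer(0)
    if (length(g) == 1L) {
      newPixels[[g]] <- px          # may be empty -> carry later
    } else {
      # collision: survivor = most previous-frame pixels, tie -> lower id
      areas <- vapply(g, function(e)
        length(active[[e]]$pixelsByFrame[[as.character(t - 1L)]]),
        integer(1))
      ids <- vapply(g, function(e) active[[e]]$id, integer(1))
      surv <- g[order(-areas, ids)][1]
      # survivor incorporates the bridged clusters and the other events'
      # pixels
      lost <- unlist(lapply(setdiff(g, surv), function(e)
        active[[e]]$pixelsByFrame[[as.character(t - 1L)]]))
      newPixels[[surv]] <- unique(c(px, lost))
      for (e in setdiff(g, surv)) {
        active[[e]]$dead <- TRUE
        active[[e]]$mode <- "collision"
        active[[e]]$death <- t
        deadNow <- c(deadNow, list(active[[e]]))
      }
    }
  }
  survivors <- which(!vapply(active, `[[`, logical(1), "dead"))
  for (e in survivors) {
    prev <- active[[e]]$pixelsByFrame[[as.character(t - 1L)]]
    if (!is.null(S) && length(prev) > 0) {
      elev <- S[, , t + 1L][prev] -
        S[, , active[[e]]$bframe + 1L][prev]
      prev <- prev[elev >= retain_level]            # per-pixel attrition
    }
    px <- unique(c(prev, newPixels[[e]]))
    active[[e]]$pixelsByFrame[[as.character(t)]] <- px
    active[[e]]$last <- t
  }
  active <- active[survivors]
  # births from untouched, birth-eligible clusters
  for (ci in seq_len(nC)) {
    if (length(touched[[ci]]) == 0L && clusters[[ci]]$birth_eligible) {
      active[[length(active) + 1L]] <- newEvent(next_id, t,
                                                clusters[[ci]]$pixels)
      next_id <- next_id + 1L
    }
  }
  list(active = active, dead = deadNow, next_id = next_id)
}

#' Check termination of active LCRs at a frame
#'
#' An LCR dies by merging into the transient at the first suspended frame
#' it is alive for, and by stochastic attrition when its signal has decayed
#' away: the mean elevation of the spatially averaged signal over its
#' current pixels above the event's pre-birth baseline falls below
#' \code{sd_termination * sigma_cell}, or its pixel set has emptied. The
#' elevation (a change since birth) lives on the same scale as the
#' differential signal, so both detection and termination thresholds are
#' factors of the one cell-wide SD. On a clean fixture whose baseline is
#' zero the test reduces to mean signal below threshold. Newborns of the
#' current frame are subject to the same rules.
#'
#' @param active list of active event objects.
#' @param S \code{H x W x T} spatially averaged conditioned signal (or the
#'   conditioned stack itself).
#' @param sigma_cell scalar noise SD of the differential signal.
#' @param sd_termination threshold multiplier.
#' @param suspended logical: is frame t suspended?
#' @param t current frame (0-based).
#' @return list with \code{active} (still alive) and \code{dead} (newly
#'   dead this frame).
#' @export
checkTerminations <- function(active, S, sigma_cell,
                              sd_termination = 1, suspended = FALSE, t) {
  dead <- list()
  alive <- list()
  for (e in active) {
    px <- e$pixelsByFrame[[as.character(t)]]
    dies <- FALSE
    if (length(px) == 0L) {
      dies <- TRUE
      e$pixelsByFrame[[as.character(t)]] <- NULL    # drop empty frame
    } else if (!suspended) {
      elev <- S[, , t + 1L][px] - S[, , e$bframe + 1L][px]
      dies <- mean(elev) < sd_termination * sigma_cell
    }
    if (suspended && !dies) {
      e$dead <- TRUE; e$mode <- "transient"; e$death <- t
      dead <- c(dead, list(e))
    } else if (dies) {
      e$dead <- TRUE; e$mode <- "stochastic_attrition"; e$death <- t
      dead <- c(dead, list(e))
    } else {
      alive <- c(alive, list(e))
    }
  }
  list(active = alive, dead = dead)
}

#' Track LCR lifecycles across a whole recording
#'
#' Drives [updateEvents()] and [checkTerminations()] over every frame,
#' maintaining birth, growth, splitting, collision and the three death
#' modes.
#'
#' @param clusters_by_frame list (length T) of per-frame cluster lists from
#'   [findClusters()].
#' @param f_nt conditioned \code{H x W x T} array.
#' @param sigma_cell scalar noise SD of the differential signal (from
#'   [differentialFilter()]); both detection-side joins and termination are
#'   expressed as factors of it.
#' @param config a [RunConfig-class].
#' @param anchors cycle anchors from [cycleAnchors()], or \code{NULL} when
#'   transients are absent.
#' @param S optional spatially averaged conditioned stack (from
#'   [differentialFilter()]) used for retention/termination; \code{f_nt}
#'   itself when omitted.
#' @return list of finished event objects (dead or open at stack end),
#'   ordered by id.
#' @export
trackEvents <- function(clusters_by_frame, f_nt, sigma_cell, config,
                        anchors = NULL, S = NULL) {
  if (is.null(S)) S <- f_nt
  d <- dim(f_nt)
  TT <- d[3]
  suspended <- rep(FALSE, TT)
  if (!is.null(anchors) && length(anchors$suspended) > 0)
    suspended[anchors$suspended + 1L] <- TRUE
  active <- list()
  finished <- list()
  next_id <- 1L
  for (t0 in seq_len(TT) - 1L) {
    cl <- clusters_by_frame[[t0 + 1L]]
    upd <- updateEvents(cl, active, t0, d[1], d[2], next_id,
                        S = S,
                        retain_level = config@sdTermination * sigma_cell)
    active <- upd$active
    next_id <- upd$next_id
    finished <- c(finished, upd$dead)
    term <- checkTerminations(active, S, sigma_cell,
                              config@sdTermination, suspended[t0 + 1L], t0)
    active <- term$active
    finished <- c(finished, term$dead)
  }
  finished <- c(finished, active)  # open events at stack end
  finished[order(vapply(finished, `[[`, integer(1), "id"))]
}

#' Finalize tracked events into the output record table
#'
#' Derives the full per-LCR parameter set: bounding box of the path, start
#' / maximum / path areas, timing relative to the cycle (birth from nadir,
#' LCR cycle = frames since the preceding transient peak, birth from stack
#' start), inclusive duration, half-maximum amplitude on the conditioned
#' 0-255 scale, and the death bookkeeping. Also returns per-event
#' size-versus-frame traces and their per-frame ensemble sum.
#'
#' A negative birth-from-nadir marks an "early" LCR (born before the nadir
#' of its cycle). When transients are absent both cycle-referenced timings
#' are \code{NA}.
#'
#' @param events finished event list from [trackEvents()].
#' @param anchors cycle anchors, or \code{NULL} when transients are absent.
#' @param f_nt conditioned array (for amplitudes).
#' @param n_frames total frame count T.
#' @return list with \code{records} (data.frame, fixed column order),
#'   \code{traces} (\code{id, frame, area_px}) and \code{ensemble}
#'   (numeric, length T).
#' @export
finalizeEvents <- function(events, anchors, f_nt, n_frames) {
  H <- dim(f_nt)[1]
  TT <- n_frames
  ensemble <- numeric(TT)
  traceList <- list()
  rows <- list()
  hasCycle <- !is.null(anchors) && length(anchors$peaks) > 0
  for (e in events) {
    frames_e <- as.integer(names(e$pixelsByFrame))
    areas <- vapply(e$pixelsByFrame, length, integer(1))
    path <- unique(unlist(e$pixelsByFrame))
    xy <- indexToXY(path, H)
    lastOcc <- max(frames_e)
    endFrame <- if (e$dead) e$death else (TT - 1L)
    amp <- max(vapply(seq_along(frames_e), function(i)
      max(f_nt[, , frames_e[i] + 1L][e$pixelsByFrame[[i]]]), numeric(1)))
    bn <- NA_integer_; lc <- NA_integer_
    if (hasCycle) {
      peaks <- anchors$peaks; nadirs <- anchors$nadirs
      prev <- which(peaks <= e$birth)
      lc <- if (length(prev) > 0) e$birth - peaks[max(prev)] else NA_integer_
      # cycle containing the birth: nadir i belongs to the segment ending
      # at peak i; births after the last peak use the last segment's rules
      cyc <- findInterval(e$birth, c(-Inf, peaks))  # 1-based segment index
      cyc <- min(cyc, length(nadirs))
      bn <- e$birth - nadirs[cyc]
    }
    ensembleIdx <- frames_e + 1L
    ensemble[ensembleIdx] <- ensemble[ensembleIdx] + areas
    traceList[[length(traceList) + 1L]] <-
      data.frame(id = e$id, frame = frames_e, area_px = as.integer(areas))
    rows[[length(rows) + 1L]] <- data.frame(
      id = e$id,
      max_x = max(xy[, "x"]), min_x = min(xy[, "x"]),
      max_y = max(xy[, "y"]), min_y = min(xy[, "y"]),
      start_area_px = as.integer(areas[1]),
      max_area_px = as.integer(max(areas)),
      path_area_px = length(path),
      birth_from_nadir_frames = bn,
      lcr_cycle_frames = lc,
      birth_from_start_frames = e$birth,
      duration_frames = endFrame - e$birth + 1L,
      half_max_amplitude = amp / 2,
      dead = e$dead,
      dead_by_collision = identical(e$mode, "collision"),
      dead_by_transient = identical(e$mode, "transient"),
      dead_by_stochastic_attrition = identical(e$mode,
                                               "stochastic_attrition"))
  }
  records <- if (length(rows) > 0) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol =
      length(.eventColumns))), .eventColumns)
  traces <- if (length(traceList) > 0) do.call(rbind, traceList) else
    data.frame(id = integer(0), frame = integer(0), area_px = integer(0))
  list(records = records, traces = traces, ensemble = ensemble)
}

#' Hot-spot map of LCR occurrence
#'
#' Counts, per pixel, how many LCRs' travelled paths include that pixel --
#' the locations of predominant LCR occurrence across cycles.
#'
#' @param x an [LCRAnalysis-class] or a finished event list.
#' @param dims \code{c(H, W)} frame dimensions (taken from the mask for an
#'   \code{LCRAnalysis}).
#' @return integer \code{H x W} count matrix.
#' @export
hotspotMap <- function(x, dims = NULL) {
  events <- if (is(x, "LCRAnalysis")) x@events else x
  if (is(x, "LCRAnalysis")) dims <- dim(x@mask)
  if (is.null(dims)) stop("dims required", call. = FALSE)
  out <- matrix(0L, dims[1], dims[2])
  for (e in events) {
    path <- unique(unlist(e$pixelsByFrame))
    out[path] <- out[path] + 1L
  }
  out
}
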