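#' Simulate a ground-truthed pacemaker-cell movie
#'
#' Generates a 2D+time fluorescence recording that exercises every pipeline
#' stage: an elongated cell (a smooth intensity plateau with soft edges and
#' a gently curved midline) on a dark noisy background; periodic whole-cell
#' transients as a multiplicative waveform (3-frame upstroke, exponential
#' decay) over the cell; stochastic local release events as isotropic 2D
#' Gaussian blobs with a 2-frame linear rise and a 3-frame exponential
#' decay, born during diastole, optionally drifting to emulate propagation;
#' an optional known piecewise-affine contraction applied forward through a
#' triangular mesh; and additive Gaussian camera noise. The ground truth
#' (event list, transient anchors, deformation mesh, seed) is returned
#' alongside the stack.
#'
#' The event layout is drawn before the noise, so two calls differing only
#' in \code{noise_sd} share the same cell, transients and events.
#'
#' @param width,height,n_frames stack geometry (pixels, frames).
#' @param pixel_size_um,frame_interval_ms acquisition metadata.
#' @param background_level,cell_brightness mean background and cell plateau
#'   intensity (arbitrary camera units).
#' @param cycle_period_frames frames per pacemaker cycle.
#' @param transient_amplitude peak multiplicative amplitude of the
#'   whole-cell transient (1.5 means the cell brightens 2.5-fold).
#' @param n_events_per_cycle seeded LCRs per cycle (born in diastole,
#'   \code{min_separation_px} apart within a cycle).
#' @param event_amplitude peak added intensity of an event blob.
#' @param event_radius_px Gaussian sigma of the blob (pixels).
#' @param propagation_speed_px_per_frame centroid drift speed.
#' @param min_separation_px minimum centroid separation between events of
#'   the same cycle. "Well separated" must be judged at the detector's
#'   scale: a blob of sigma \code{r} occupies a disc of radius about
#'   \code{4r} and candidacy dilates it by the search distance, so discs of
#'   two events touch near \code{2 (4r + d)}; the default keeps seeded
#'   events beyond that.
#' @param noise_sd additive Gaussian noise SD.
#' @param contraction_amplitude fractional x-shortening at contraction peak
#'   (0 disables motion).
#' @param event_birth_frames optional explicit 0-based birth frames (must
#'   lie in diastole when transients are on).
#' @param seed RNG seed (integer); the simulation is bit-reproducible.
#' @return list with \code{stack} (an [ImageStack-class]) and \code{truth}
#'   (list: \code{events} data.frame with birth/death frames, birth
#'   centroid, amplitude, radius, speed, heading; \code{paths} list of
#'   per-frame centroids; \code{peak_frames}, \code{nadir_frames};
#'   \code{mesh} or NULL; \code{seed}).
#' @export
simulateMovie <- function(width = 256L, height = 64L, n_frames = 100L,
                          pixel_size_um = 0.2539, frame_interval_ms = 10,
                          background_level = 10, cell_brightness = 120,
                          cycle_period_frames = 50L,
                          transient_amplitude = 1.5,
                          n_events_per_cycle = 10L,
                          event_amplitude = 15,
                          event_radius_px = 2.5,
                          propagation_speed_px_per_frame = 0.5,
                          noise_sd = 3,
                          min_separation_px = 26,
                          contraction_amplitude = 0,
                          event_birth_frames = NULL,
                          seed = 1L) {
  W <- as.integer(width); H <- as.integer(height); TT <- as.integer(n_frames)
  set.seed(as.integer(seed))
  xs <- matrix(rep(0:(W - 1L), each = H), H, W)
  ys <- matrix(rep(0:(H - 1L), times = W), H, W)

  # cell: soft plateau around a curved midline, tapered ends
  mid <- H / 2 + 0.08 * H * sin(2 * pi * (0:(W - 1L)) / W + 0.7)
  halfT <- 0.30 * H
  xlo <- 0.04 * W; xhi <- 0.96 * W
  edge <- 1.5  # px softness
  profY <- 1 / (1 + exp((abs(ys - matrix(rep(mid, each = H), H, W)) -
                           halfT) / edge))
  profX <- 1 / (1 + exp((xlo - xs) / (2 * edge))) *
           1 / (1 + exp((xs - xhi) / (2 * edge)))
  cellProf <- profY * profX              # in [0, 1]

  # transient waveform: 3-frame linear upstroke, exponential decay (tau 8)
  firstPeak <- 10L
  w <- numeric(TT)
  peakFrames <- seq.int(firstPeak, TT - 1L, by = cycle_period_frames)
  for (p in peakFrames) {
    t <- 0:(TT - 1L)
    rise <- t >= p - 3L & t <= p
    w[rise] <- pmax(w[rise], 1 - (p - t[rise]) / 3)
    dec <- t > p
    w[dec] <- pmax(w[dec], exp(-(t[dec] - p) / 8))
  }

  # diastolic birth windows per cycle
  riseLife <- 2L
  decayTau <- 3
  life <- riseLife + ceiling(decayTau * log(10))  # amplitude down to ~5%
  allowed <- list()
  for (p in peakFrames) {
    lo <- p + 15L
    hi <- p + cycle_period_frames - 10L
    hi <- min(hi, TT - 2L)
    if (lo <= hi) allowed[[length(allowed) + 1L]] <- c(lo, hi)
  }

  # event layout (drawn before noise so layout is noise-invariant).
  # Events are placed with their blob support on the plateau proper (an
  # edge-straddling blob is truncated by the cell profile and falls below
  # its nominal amplitude), and the separation constraint is enforced only
  # among co-active events -- temporally disjoint events cannot interact.
  evs <- list()
  id <- 0L
  minSep <- min_separation_px
  margin <- 8
  midAt <- function(x) H / 2 + 0.08 * H * sin(2 * pi * x / W + 0.7)
  placedAll <- data.frame(x = numeric(0), y = numeric(0), b = integer(0))
  for (ci in seq_along(allowed)) {
    win <- allowed[[ci]]
    births <- if (!is.null(event_birth_frames)) {
      bf <- event_birth_frames[event_birth_frames >= win[1] &
                               event_birth_frames <= win[2]]
      bf
    } else if (n_events_per_cycle > 0) {
      sort(sample(seq.int(win[1], win[2]), n_events_per_cycle,
                  replace = TRUE))
    } else integer(0)
    for (b in births) {
      for (try in 1:500) {
        x0 <- stats::runif(1, xlo + 12, xhi - 12)
        m <- midAt(x0)
        y0 <- stats::runif(1, m - halfT + margin, m + halfT - margin)
        coActive <- abs(placedAll$b - b) <= life + 3L
        if (!any(coActive) ||
            min(sqrt((placedAll$x[coActive] - x0)^2 +
                     (placedAll$y[coActive] - y0)^2)) >= minSep)
          break
      }
      placedAll <- rbind(placedAll, data.frame(x = x0, y = y0, b = b))
      id <- id + 1L
      heading <- sample(c(0, pi), 1L) + stats::runif(1, -0.3, 0.3)
      evs[[id]] <- list(id = id, birth = as.integer(b),
                        death = as.integer(min(b + life - 1L, TT - 1L)),
                        x0 = x0, y0 = y0,
                        amplitude = event_amplitude,
                        radius = event_radius_px,
                        speed = propagation_speed_px_per_frame,
                        heading = heading)
    }
  }
  if (!is.null(event_birth_frames)) {
    bad <- setdiff(event_birth_frames,
                   unlist(lapply(allowed, function(a) seq.int(a[1], a[2]))))
    if (length(bad) > 0)
      stop("requested event birth frame(s) outside diastole: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  # render noiseless frames
  arr <- array(0, dim = c(H, W, TT))
  paths <- lapply(evs, function(e) {
    k <- 0:(e$death - e$birth)
    data.frame(frame = e$birth + k,
               x = e$x0 + e$speed * k * cos(e$heading),
               y = e$y0 + e$speed * k * sin(e$heading))
  })
  for (t in seq_len(TT)) {
    fr <- background_level +
      cell_brightness * cellProf * (1 + transient_amplitude * w[t])
    for (ei in seq_along(evs)) {
      e <- evs[[ei]]
      t0 <- t - 1L
      if (t0 < e$birth || t0 > e$death) next
      k <- t0 - e$birth
      amp <- if (k == 0L) e$amplitude * 0.5 else
        e$amplitude * exp(-(k - 1L) / decayTau)
      cx <- paths[[ei]]$x[k + 1L]; cy <- paths[[ei]]$y[k + 1L]
      r2 <- (xs - cx)^2 + (ys - cy)^2
      blob <- amp * exp(-r2 / (2 * e$radius^2))
      blob[r2 > (4 * e$radius)^2] <- 0
      fr <- fr + blob * cellProf
    }
    arr[, , t] <- fr
  }

  truthMesh <- NULL
  if (contraction_amplitude > 0) {
    # known piecewise-affine contraction synced to the transient waveform:
    # x-shortening toward the cell centre plus a vertical bow (contracting
    # cells bend, which is what deflects the curvature bands the tracker
    # relies on), through a spine mesh
    nPts <- 7L
    px <- seq(xlo + 4, xhi - 4, length.out = nPts)
    py <- stats::approx(0:(W - 1L), mid, xout = px)$y
    pts <- array(NA_real_, dim = c(TT, nPts, 2L))
    xc <- mean(px)
    for (t in seq_len(TT)) {
      sh <- 1 - contraction_amplitude * w[t]
      pts[t, , 1L] <- xc + (px - xc) * sh
      pts[t, , 2L] <- py + 1.5 * contraction_amplitude * H * w[t] *
        sin(2 * pi * (px - xlo) / (0.35 * W))
    }
    truthMesh <- buildMesh(pts, height = 0.45 * H)
    base <- imageStack(arr, pixel_size_um, frame_interval_ms)
    arr <- frames(deformStack(base, truthMesh, ref_frame = 0L,
                              background = background_level))
  }

  if (noise_sd > 0) {
    arr <- arr + stats::rnorm(length(arr), sd = noise_sd)
    arr[arr < 0] <- 0
  }

  events <- if (length(evs) > 0) do.call(rbind, lapply(evs, function(e)
    data.frame(id = e$id, birth_frame = e$birth, death_frame = e$death,
               x0 = e$x0, y0 = e$y0, amplitude = e$amplitude,
               radius = e$radius, speed = e$speed, heading = e$heading)))
  else data.frame(id = integer(0), birth_frame = integer(0),
                  death_frame = integer(0), x0 = numeric(0),
                  y0 = numeric(0), amplitude = numeric(0),
                  radius = numeric(0), speed = numeric(0),
                  heading = numeric(0))

  nadirs <- integer(0)
  if (length(peakFrames) > 0) {
    segStart <- 0L
    for (p in peakFrames) {
      seg <- segStart:p
      nadirs <- c(nadirs, seg[which.min(w[seg + 1L])])
      segStart <- p
    }
  }

  list(stack = imageStack(arr, pixel_size_um, frame_interval_ms),
       truth = list(events = events, paths = paths,
                    peak_frames = peakFrames, nadir_frames = nadirs,
                    waveform = w, cell_profile = cellProf,
                    mesh = truthMesh, seed = as.integer(seed)))
}

#' Score detected events against simulated ground truth
#'
#' Greedy one-to-one matching: truth and detected events are paired when
#' the detected birth frame lies within \code{tol_frames} of the true one
#' and the detected bounding-box centroid lies within \code{tol_px} of the
#' true birth centroid; among admissible pairs the closest (by centroid
#' distance, then frame difference) are matched first. Unmatched detections
#' count against precision; with no detections at all, precision is defined
#' as 1 (no false claims).
#'
#' @param truth truth list from [simulateMovie()].
#' @param records detected event records ([eventRecords()] /
#'   [finalizeEvents()]).
#' @param tol_frames birth-frame tolerance (default 2).
#' @param tol_px centroid tolerance in pixels (default 6).
#' @return list with \code{recall}, \code{precision},
#'   \code{birth_frame_mae}, \code{n_truth}, \code{n_detected},
#'   \code{n_matched}, and \code{matches} (data.frame of matched pairs).
#' @export
scoreDetection <- function(truth, records, tol_frames = 2, tol_px = 6) {
  te <- truth$events
  nT <- nrow(te); nD <- nrow(records)
  if (nD == 0L)
    return(list(recall = if (nT == 0) 1 else 0, precision = 1,
                birth_frame_mae = NA_real_, n_truth = nT, n_detected = 0L,
                n_matched = 0L,
                matches = data.frame(truth_id = integer(0),
                                     detected_id = integer(0))))
  dc <- data.frame(id = records$id,
                   cx = (records$min_x + records$max_x) / 2,
                   cy = (records$min_y + records$max_y) / 2,
                   birth = records$birth_from_start_frames)
  pairs <- list()
  for (i in seq_len(nT)) {
    dd <- sqrt((dc$cx - te$x0[i])^2 + (dc$cy - te$y0[i])^2)
    df <- abs(dc$birth - te$birth_frame[i])
    ok <- which(df <= tol_frames & dd <= tol_px)
    for (j in ok)
      pairs[[length(pairs) + 1L]] <- c(i, j, dd[j], df[j])
  }
  matchedT <- logical(nT); matchedD <- logical(nD)
  matches <- list()
  if (length(pairs) > 0) {
    P <- do.call(rbind, pairs)
    P <- P[order(P[, 3], P[, 4]), , drop = FALSE]
    for (r in seq_len(nrow(P))) {
      i <- P[r, 1]; j <- P[r, 2]
      if (!matchedT[i] && !matchedD[j]) {
        matchedT[i] <- TRUE; matchedD[j] <- TRUE
        matches[[length(matches) + 1L]] <-
          data.frame(truth_id = te$id[i], detected_id = dc$id[j],
                     frame_error = dc$birth[j] - te$birth_frame[i],
                     dist_px = P[r, 3])
      }
    }
  }
  nM <- sum(matchedT)
  mdf <- if (length(matches) > 0) do.call(rbind, matches) else
    data.frame(truth_id = integer(0), detected_id = integer(0),
               frame_error = integer(0), dist_px = numeric(0))
  list(recall = if (nT == 0) 1 else nM / nT,
       precision = nM / (nM + sum(!matchedD)),
       birth_frame_mae = if (nM > 0) mean(abs(mdf$frame_error)) else
         NA_real_,
       n_truth = nT, n_detected = nD, n_matched = nM, matches = mdf)
}
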