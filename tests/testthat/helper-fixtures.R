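# Shared fixtures and independent oracles, built in code at test time.

# tiny constant-background stack with a bright rectangular "cell"
blockStack <- function(H = 20, W = 24, T = 3, bg = 10, cell = 200,
                       rows = 6:15, cols = 8:19) {
  arr <- array(bg, dim = c(H, W, T))
  for (t in seq_len(T)) arr[rows, cols, t] <- cell
  imageStack(arr, pixel_size_um = 0.25, frame_interval_ms = 10)
}

# brute-force double-loop oracle for the differential filter
bruteDifferential <- function(f_nt, mask, d) {
  dm <- dim(f_nt)
  S <- array(0, dim = dm)
  for (t in seq_len(dm[3])) for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
    if (!mask[i, j]) next
    rs <- max(1, i - d):min(dm[1], i + d)
    cs <- max(1, j - d):min(dm[2], j + d)
    w <- f_nt[rs, cs, t][mask[rs, cs]]
    S[i, j, t] <- if (length(w) > 0) mean(w) else 0
  }
  D <- array(0, dim = dm)
  for (t in 2:dm[3]) D[, , t] <- (S[, , t] - S[, , t - 1]) * mask
  keep <- 2:dm[3]
  dv <- as.numeric(D[, , keep])[rep(mask, length(keep))]
  list(S = S, D = D, sigma_cell = sqrt(mean((dv - mean(dv))^2)))
}

# brute-force 4-connected components by repeated neighbourhood growth
bruteComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    H <- nrow(mask)
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% H + 1L; cc <- (p - 1L) %/% H + 1L
      for (np in c(if (r > 1) p - 1L, if (r < H) p + 1L,
                   if (cc > 1) p - H, if (cc < ncol(mask)) p + H)) {
        if (mask[np] && lab[np] == 0L) { lab[np] <- nxt; queue <- c(queue, np) }
      }
    }
  }
  lab
}

# minimal CurvatureMap wrapper for functions that only need the map shape
makeCmap <- function(k, zeta = NULL) {
  if (is.null(zeta)) zeta <- matrix(0, nrow(k), ncol(k))
  methods::new("CurvatureMap", k = k, zeta = zeta,
               interpolated = matrix(FALSE, nrow(k), ncol(k)),
               sgWindow = 11L, sgOrder = 3L)
}

# hand-built internal event object (shape used by trackEvents/finalizeEvents)
makeEvent <- function(id, birth, pixelsByFrame, dead = FALSE, mode = "none",
                      death = NA_integer_) {
  frames <- as.integer(names(pixelsByFrame))
  list(id = id, birth = birth, bframe = max(birth - 1L, 0L),
       last = max(frames), dead = dead, mode = mode, death = death,
       pixelsByFrame = pixelsByFrame)
}

# linear pixel index helper (1-based, column-major) from 0-based x/y
pix <- function(x, y, H) x * H + y + 1L
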