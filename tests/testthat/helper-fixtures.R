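# small in-code fixtures shared across tests

# constant-intensity cine of n frames
flat_cine <- function(n = 3, H = 8, W = 8, value = 100, frame_rate = 85) {
  cine_sequence(replicate(n, matrix(as.integer(value), H, W),
                          simplify = FALSE), frame_rate)
}

# cine with a flat bright square moving right by `step` px per frame
moving_square_cine <- function(n = 5, H = 30, W = 40, side = 6, step = 2,
                               bg = 40, fg = 230, frame_rate = 85) {
  frames <- lapply(seq_len(n), function(k) {
    f <- matrix(as.integer(bg), H, W)
    x0 <- 3 + (k - 1) * step
    f[11:(10 + side), x0:(x0 + side - 1)] <- as.integer(fg)
    f
  })
  cine_sequence(frames, frame_rate)
}

# independent edge-count perimeter oracle on a logical pixel-set matrix:
# counts unit edges from a set pixel to a non-set (or outside) 4-neighbour
perimeter_oracle <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!m[r, c]) next
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1L || rr > H || cc < 1L || cc > W || !m[rr, cc]) p <- p + 1L
    }
  }
  p
}

# independent 8-connectivity check by breadth-first flood fill
is_connected_8 <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) <= 1L) return(TRUE)
  seen <- matrix(FALSE, nrow(m), ncol(m))
  queue <- list(idx[1, ])
  seen[idx[1, 1], idx[1, 2]] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      rr <- p[1] + dr; cc <- p[2] + dc
      if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) &&
          m[rr, cc] && !seen[rr, cc]) {
        seen[rr, cc] <- TRUE
        queue[[length(queue) + 1L]] <- c(rr, cc)
      }
    }
  }
  sum(seen) == sum(m)
}

# layer labels for a single-layer pixel set, for component oracles
labels_from_mask <- function(m, layer = 5L) {
  lab <- matrix(NA_integer_, nrow(m), ncol(m))
  lab[m] <- layer
  lab
}
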