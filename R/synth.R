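#' Specify a synthetic speckle phantom
#'
#' Builds the specification for a cine phantom: speckled regions with known
#' motion (translation, rotation, or static pooling) over a uniform
#' background, periodic cardiac-cycle kinetics with a synchronised stylised
#' ECG, and additive sensor noise. Defaults emulate the acquisition regime
#' of catheter-echo cine loops: 8-bit grayscale at 85 frames/s with cyclic
#' motion. Two presets bracket the flow spectrum the indices are designed to
#' separate: `"active"` (a large coherently moving pool that travels during
#' the first part of each cycle and rests otherwise) and `"stale"` (the same
#' pool, static — only sensor noise).
#'
#' @param preset `"custom"`, `"active"` or `"stale"`.
#' @param shape frame dimensions `c(H, W)` in pixels.
#' @param frame_rate frames per second.
#' @param n_cycles number of cardiac cycles.
#' @param cycle_period cycle length in seconds.
#' @param regimes list of region descriptors from [phantom_region()]
#'   (ignored when a preset is chosen).
#' @param background background intensity (0-255).
#' @param noise_sd additive Gaussian sensor noise SD, intensity units.
#' @param respiration optional slow multiplicative modulation of motion,
#'   `list(period = seconds, amplitude = fraction)`.
#' @param seed integer RNG seed; a fixed seed makes the phantom
#'   bit-reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(preset = c("custom", "active", "stale"),
                         shape = c(96L, 96L), frame_rate = 85,
                         n_cycles = 3, cycle_period = 0.8,
                         regimes = list(), background = 40,
                         noise_sd = 4, respiration = NULL, seed = 1L) {
  preset <- match.arg(preset)
  H <- shape[1]; W <- shape[2]
  if (preset == "active") {
    # two bright blood pools sweeping in opposite directions during the
    # early part of each cycle, then resting: their leading/trailing edges
    # produce large coherent marginal-band components, so BMF is high and
    # phase-locked with a wide max-min swing, as in active atrial flow
    w <- round(0.21 * W); h <- round(0.42 * H); v <- max(1L, round(0.083 * W))
    m <- round(0.06 * W)
    regimes <- list(
      phantom_region(geometry = list(type = "rect", x0 = m, y0 = m,
                                     w = w, h = h),
                     motion = "translate", v = c(v, 0), duty = 0.1,
                     grain = 0, mean = 230),
      phantom_region(geometry = list(type = "rect", x0 = W - m - w,
                                     y0 = H - m - h, w = w, h = h),
                     motion = "translate", v = c(-v, 0), duty = 0.1,
                     grain = 0, mean = 230))
  } else if (preset == "stale") {
    # a pooled, stagnant speckle pool: only sensor noise separates frames
    regimes <- list(phantom_region(
      geometry = list(type = "disc", cx = W / 2, cy = H / 2, r = min(shape) / 3),
      motion = "static", grain = 5, contrast = 95))
  }
  sp <- structure(list(preset = preset, shape = as.integer(shape),
                       frame_rate = frame_rate, n_cycles = n_cycles,
                       cycle_period = cycle_period, regimes = regimes,
                       background = background, noise_sd = noise_sd,
                       respiration = respiration, seed = as.integer(seed)),
                  class = "phantom_spec")
  validate_phantom_spec(sp)
  sp
}

#' Describe one phantom region
#'
#' @param geometry `list(type = "rect", x0, y0, w, h)` (0-based pixel
#'   corner, x = column) or `list(type = "disc", cx, cy, r)`.
#' @param motion `"static"`, `"translate"` or `"rotate"`.
#' @param v translation velocity `c(dx, dy)` in px/frame.
#' @param omega rotation in rad/frame about the region centre.
#' @param duty fraction of the cycle during which the region moves (motion
#'   pauses for the rest, then the position resets at the next cycle start).
#' @param grain speckle grain size: Gaussian smoothing sigma in px of the
#'   white-noise texture (0 gives a flat region at intensity `mean`).
#' @param contrast speckle amplitude around `mean` (intensity units).
#' @param mean mean region intensity.
#' @return A region descriptor list.
#' @export
phantom_region <- function(geometry, motion = c("static", "translate", "rotate"),
                           v = c(0, 0), omega = 0, duty = 0.4,
                           grain = 1.2, contrast = 90, mean = 128) {
  motion <- match.arg(motion)
  list(geometry = geometry, motion = motion, v = v, omega = omega,
       duty = duty, grain = grain, contrast = contrast, mean = mean)
}

validate_phantom_spec <- function(sp) {
  stopifnot(sp$noise_sd >= 0, sp$frame_rate > 0, sp$cycle_period > 0,
            sp$n_cycles >= 1)
  H <- sp$shape[1]; W <- sp$shape[2]
  for (rg in sp$regimes) {
    g <- rg$geometry
    ok <- if (g$type == "rect") {
      g$x0 >= 0 && g$y0 >= 0 && g$x0 + g$w <= W && g$y0 + g$h <= H
    } else {
      g$cx - g$r >= 0 && g$cy - g$r >= 0 && g$cx + g$r <= W && g$cy + g$r <= H
    }
    if (!ok) stop("phantom region lies outside the frame", call. = FALSE)
  }
  invisible(sp)
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# separable Gaussian smoothing with replicate padding
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

in_geometry <- function(g, x, y) {
  if (g$type == "rect") {
    x >= g$x0 & x < g$x0 + g$w & y >= g$y0 & y < g$y0 + g$h
  } else {
    (x - g$cx)^2 + (y - g$cy)^2 <= g$r^2
  }
}

geometry_centre <- function(g) {
  if (g$type == "rect") c(g$x0 + g$w / 2, g$y0 + g$h / 2) else c(g$cx, g$cy)
}

#' Generate a phantom cine loop with ground truth
#'
#' Renders the phantom frame by frame: each region's speckle texture is a
#' fixed smoothed-white-noise field sampled by nearest neighbour under the
#' region's inverse motion map (integer displacements, so 8-bit arithmetic
#' stays exact), motion runs during the duty window of each cycle and the
#' position resets at every cycle start, then clipped Gaussian sensor noise
#' is added. The truth moved mask marks pixels of the noise-free frames
#' whose signed intensity change leaves the median differential band
#' (change >= 50 or <= -53) — derivable from raw frames alone, independent
#' of the analysis pipeline.
#'
#' @param sp a [phantom_spec()].
#' @return A list: `seq` (a [cine_sequence()] with synchronised ECG) and
#'   `truth` (`moved` — list of logical masks per consecutive frame pair,
#'   `r_peaks` — the cycle-start times delimiting the cycles, `thresholds`).
#' @export
make_phantom <- function(sp) {
  stopifnot(inherits(sp, "phantom_spec"))
  validate_phantom_spec(sp)
  H <- sp$shape[1]; W <- sp$shape[2]
  fpc <- round(sp$frame_rate * sp$cycle_period)      # frames per cycle
  n_fr <- fpc * sp$n_cycles
  px <- rep(seq_len(W), each = H) - 0.5              # pixel-centre x
  py <- rep(seq_len(H), times = W) - 0.5             # pixel-centre y
  with_seed(sp$seed, {
    textures <- lapply(sp$regimes, function(rg) {
      if (rg$grain <= 0 || rg$contrast <= 0) {
        matrix(rg$mean, H, W)                        # flat region
      } else {
        tx <- smooth_gaussian(matrix(stats::rnorm(H * W), H, W), rg$grain)
        tx <- (tx - mean(tx)) / stats::sd(as.vector(tx))
        matrix(pmax(0, pmin(255, rg$mean + rg$contrast * tx / 2)), H, W)
      }
    })
    clean <- vector("list", n_fr)
    for (f in seq_len(n_fr)) {
      t_f <- (f - 1) / sp$frame_rate
      into_cycle <- (f - 1) %% fpc                   # frames since cycle start
      img <- matrix(sp$background, H, W)
      for (ri in seq_along(sp$regimes)) {
        rg <- sp$regimes[[ri]]
        moved_steps <- min(into_cycle, floor(rg$duty * fpc))
        amp <- 1
        if (!is.null(sp$respiration)) {
          amp <- 1 + sp$respiration$amplitude *
            sin(2 * pi * t_f / sp$respiration$period)
        }
        if (rg$motion == "translate") {
          s <- round(rg$v * moved_steps * amp)
          qx <- px - s[1]; qy <- py - s[2]
        } else if (rg$motion == "rotate") {
          th <- rg$omega * moved_steps * amp
          ctr <- geometry_centre(rg$geometry)
          dx <- px - ctr[1]; dy <- py - ctr[2]
          qx <- ctr[1] + cos(-th) * dx - sin(-th) * dy
          qy <- ctr[2] + sin(-th) * dx + cos(-th) * dy
        } else {
          qx <- px; qy <- py
        }
        inside <- in_geometry(rg$geometry, qx, qy)
        # nearest-neighbour sample of the texture at the source position
        sr <- pmin(H, pmax(1L, as.integer(floor(qy) + 1L)))
        sc <- pmin(W, pmax(1L, as.integer(floor(qx) + 1L)))
        vals <- textures[[ri]][cbind(sr, sc)]
        img[matrix(inside, H, W)] <- vals[inside]
      }
      clean[[f]] <- matrix(as.integer(round(pmax(0, pmin(255, img)))), H, W)
    }
    frames <- if (sp$noise_sd > 0) {
      lapply(clean, function(fr) {
        n <- matrix(stats::rnorm(H * W, sd = sp$noise_sd), H, W)
        matrix(as.integer(round(pmax(0, pmin(255, fr + n)))), H, W)
      })
    } else clean
    ecg <- make_ecg(sp$cycle_period, sp$n_cycles + 1,
                    sample_rate = 250, seed = sp$seed)
    moved <- lapply(seq_len(n_fr - 1), function(i) {
      d <- clean[[i + 1]] - clean[[i]]
      d >= 50L | d <= -53L
    })
    list(
      seq = cine_sequence(frames, sp$frame_rate, ecg = ecg$trace,
                          source_modality = "SYNTH"),
      truth = list(moved = moved,
                   r_peaks = ecg$peaks,
                   thresholds = c(pos = 50L, neg = -53L),
                   frames_per_cycle = fpc)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a stylised synthetic ECG with known R-peak times
#'
#' One P-QRS-T complex per cycle built from Gaussian bumps, with the R peak
#' exactly at each cycle start `k * cycle_period` — the ground truth for
#' validating [detect_r_peaks()].
#'
#' @param cycle_period seconds per cycle.
#' @param n_cycles number of cycles (the trace spans `n_cycles *
#'   cycle_period` seconds and carries `n_cycles` truth peaks).
#' @param sample_rate Hz.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @param noise_sd additive Gaussian noise SD in normalised amplitude units.
#' @return A list: `trace` (an [ecg_trace()]) and `peaks` (truth R times).
#' @export
make_ecg <- function(cycle_period, n_cycles, sample_rate = 250,
                     seed = 1L, noise_sd = 0) {
  stopifnot(cycle_period > 0, n_cycles >= 1, sample_rate > 0)
  t <- seq(0, n_cycles * cycle_period - 1 / sample_rate, by = 1 / sample_rate)
  peaks <- (seq_len(n_cycles) - 1) * cycle_period
  bump <- function(centre, amp, width) amp * exp(-((t - centre)^2) / (2 * width^2))
  x <- numeric(length(t))
  for (p in peaks) {
    x <- x + bump(p, 1.0, 0.012)      # R
    x <- x - bump(p - 0.028, 0.12, 0.010)  # Q
    x <- x - bump(p + 0.030, 0.20, 0.012)  # S
    x <- x + bump(p + 0.25 * cycle_period, 0.25, 0.05)   # T
    x <- x + bump(p + 0.84 * cycle_period, 0.15, 0.03)   # next P
  }
  if (noise_sd > 0) {
    x <- with_seed(seed, x + stats::rnorm(length(x), sd = noise_sd))
  }
  list(trace = ecg_trace(x, sample_rate, offset = 0), peaks = peaks)
}
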