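test_that("component TI matches its closed forms", {
  expect_equal(component_ti(1, 4), 4 / (2 * sqrt(pi)))        # single pixel
  for (n in 1:6) {                                            # solid squares
    expect_equal(component_ti(n^2, 4 * n), 2 / sqrt(pi))
  }
  expect_equal(component_ti(3, 8), 8 / (2 * sqrt(3 * pi)))    # 1x3 bar
})

test_that("frame TI aggregates by area weighting with missing-value semantics", {
  mk_cs <- function(areas, perims, layers) {
    structure(list(
      components = tibble::tibble(component = seq_along(areas),
                                  layer = as.integer(layers),
                                  area = as.integer(areas),
                                  perimeter = as.numeric(perims)),
      pixel_map = matrix(NA_integer_, 1, 1),
      roi_area = 10000L, frame_pair = 1L), class = "component_set")
  }
  # equal areas, TIs 1.2 and 1.4 -> aggregate 1.3
  cs <- mk_cs(c(50, 50), 2 * sqrt(pi * 50) * c(1.2, 1.4), c(5, 5))
  expect_equal(frame_ti(cs)$ti, 1.3)
  # a single component's TI is the aggregate
  cs1 <- mk_cs(4, 8, 5)
  expect_equal(frame_ti(cs1)$ti, component_ti(4, 8))
  # areas 1 and 3: hand-computed weighted mean (1*1.1284 + 3*1.3028)/4
  cs2 <- mk_cs(c(1, 3), c(4, 8), c(5, 4))
  want <- (1 * component_ti(1, 4) + 3 * component_ti(3, 8)) / 4
  expect_equal(frame_ti(cs2)$ti, want)
  expect_equal(want, 1.2592, tolerance = 1e-4)
  # unweighted switch
  expect_equal(frame_ti(cs2, weighted = FALSE)$ti,
               mean(c(component_ti(1, 4), component_ti(3, 8))))
  # per-layer values
  ft <- frame_ti(cs2)
  expect_equal(unname(ft$ti_by_layer[5]), component_ti(1, 4))
  expect_equal(unname(ft$ti_by_layer[4]), component_ti(3, 8))
  expect_true(is.na(ft$ti_by_layer[3]))
  # no retained active component -> missing value, not an error
  cs3 <- mk_cs(10, 16, 3)
  expect_true(is.na(frame_ti(cs3)$ti))
})

test_that("TI respects its discrete lower bound on all connected 3x3 pixel sets", {
  # exhaustive enumeration: every 8-connected subset of a 3x3 window
  low <- 2 / sqrt(pi)
  n_checked <- 0L
  for (mask_bits in 1:511) {
    m <- matrix(bitwAnd(bitwShiftR(mask_bits, 0:8), 1L) == 1L, 3, 3)
    if (!is_connected_8(m)) next
    cs <- label_components(labels_from_mask(m), matrix(TRUE, 3, 3))
    expect_equal(nrow(cs$components), 1)
    ti <- component_ti(cs$components$area, cs$components$perimeter)
    expect_gte(ti, low - 1e-12)
    solid_square <- sum(m) %in% c(1, 4, 9) &&
      diff(range(which(m, arr.ind = TRUE)[, 1])) + 1 == sqrt(sum(m)) &&
      diff(range(which(m, arr.ind = TRUE)[, 2])) + 1 == sqrt(sum(m))
    if (solid_square) expect_equal(ti, low) else expect_gt(ti, low)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 200)  # most 3x3 subsets are connected
})

test_that("frame BMF is the retained-area percentage of the ROI", {
  # ROI 10000 px, retained areas {250, 300} at cutoff 200 -> 5.5
  cs <- structure(list(
    components = tibble::tibble(component = 1:3, layer = c(5L, 4L, 2L),
                                area = c(250L, 300L, 150L),
                                perimeter = c(100L, 80L, 60L)),
    pixel_map = matrix(NA_integer_, 1, 1),
    roi_area = 10000L, frame_pair = 1L), class = "component_set")
  expect_equal(frame_bmf(cs, 200), 5.5)
  expect_equal(frame_bmf(cs, 0), 7.0)
  expect_equal(frame_bmf(cs, 10000), 0)
  cs$roi_area <- 0L
  expect_error(frame_bmf(cs, 200), "ROI")
})

test_that("a full-cover differential yields BMF 100 at cutoff 0", {
  # all pixels in one marginal band covering the whole ROI
  f0 <- matrix(0L, 10, 10); f1 <- matrix(220L, 10, 10)
  d <- subtract_frames(f0, f1)
  cs <- label_components(band_layers(d), d$mask)
  expect_equal(frame_bmf(cs, 0, 1:5), 100)
  expect_equal(frame_bmf(cs, 0), 100)  # band 5 is an active layer
})

test_that("index_series has one row per frame pair with the configured BMF tracks", {
  sq <- moving_square_cine(n = 10)
  s <- index_series(sq, cutoffs = c(50, 100, 200, 500))
  expect_equal(nrow(s), 9)
  expect_named(s, c("frame", "time", "ti", paste0("ti_layer_", 1:5),
                    paste0("bmf_", c(50, 100, 200, 500))))
  cfg <- attr(s, "config")
  expect_equal(cfg$cutoffs, c(50, 100, 200, 500))
  expect_equal(cfg$active_layers, c(1L, 2L, 4L, 5L))
  # identical consecutive frames (static loop): BMF 0 under default layers
  s0 <- index_series(flat_cine(5), cutoffs = c(0, 50))
  expect_true(all(s0$bmf_0 == 0))
  expect_true(all(s0$bmf_50 == 0))
  expect_true(all(is.na(s0$ti)))       # nothing leaves the median band
})

test_that("BMF is non-increasing in cutoff frame-by-frame on random phantoms", {
  cuts <- c(0, 25, 50, 100, 200, 400)
  for (sd in 1:5) {
    sp <- phantom_spec("custom", shape = c(32L, 32L), frame_rate = 40,
                       n_cycles = 1, cycle_period = 0.2, noise_sd = 30,
                       seed = sd, regimes = list())
    s <- index_series(make_phantom(sp)$seq, cutoffs = cuts)
    b <- as.matrix(s[, paste0("bmf_", cuts)])
    expect_true(all(t(apply(b, 1, diff)) <= 1e-12))
  }
})

test_that("moving-square BMF at cutoff 0 equals the direct pixel-count oracle", {
  sq <- moving_square_cine(n = 5, side = 6, step = 2, bg = 40, fg = 230)
  s <- index_series(sq, cutoffs = 0)
  for (i in 1:4) {
    d <- abs(sq$frames[[i + 1]] - sq$frames[[i]])
    # oracle: pixels whose mapped value leaves the median band
    dd <- sq$frames[[i + 1]] - sq$frames[[i]]
    oracle <- 100 * sum(dd >= 50 | dd <= -53) / length(dd)
    expect_equal(s$bmf_0[i], oracle)
  }
})

test_that("aggregate TI is invariant to translating all components", {
  base <- matrix(FALSE, 20, 20); base[3:5, 3:8] <- TRUE; base[10, 10] <- TRUE
  shifted <- matrix(FALSE, 20, 20); shifted[9:11, 7:12] <- TRUE; shifted[16, 14] <- TRUE
  ti_of <- function(m) {
    cs <- label_components(labels_from_mask(m), matrix(TRUE, 20, 20))
    frame_ti(cs)$ti
  }
  expect_equal(ti_of(base), ti_of(shifted))
})

test_that("processing time grows about linearly with pixel count", {
  mk <- function(side) {
    sp <- phantom_spec("custom", shape = c(side, side), frame_rate = 40,
                       n_cycles = 1, cycle_period = 0.25, noise_sd = 25,
                       seed = 1, regimes = list())
    make_phantom(sp)$seq
  }
  small <- mk(24L); large <- mk(96L)   # 16x the pixels
  t_small <- system.time(index_series(small, cutoffs = 50))[["elapsed"]]
  t_large <- system.time(index_series(large, cutoffs = 50))[["elapsed"]]
  # generous envelope: 16x the work should cost far less than ~quadratic
  expect_lt(t_large, 16 * 16 * max(t_small, 0.02))
})
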