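test_that("the five bands partition [0,256) with widths 51,51,51,51,52", {
  L <- isophote_layers()
  expect_equal(L$hi - L$lo, c(51L, 51L, 51L, 51L, 52L))
  expect_equal(L$lo[1], 0L)
  expect_equal(L$hi[5], 256L)
  expect_equal(L$lo[-1], L$hi[-5])
  expect_equal(L$role, c("marginal", "medial", "median", "medial", "marginal"))
  expect_equal(L$color, c("violet", "blue", "white", "orange", "red"))
})

test_that("band assignment is total, unique, and half-open at boundaries", {
  vals <- matrix(0:255, 16, 16)
  d <- structure(list(values = vals, mask = matrix(TRUE, 16, 16),
                      frame_pair = c(1L, 2L)), class = "differential_frame")
  lab <- band_layers(d)
  expect_false(anyNA(lab))
  expect_true(all(lab %in% 1:5))
  # every value lands in exactly the band whose interval contains it
  L <- isophote_layers()
  for (k in 1:5) {
    expect_true(all(vals[lab == k] >= L$lo[k] & vals[lab == k] < L$hi[k]))
  }
  # spot boundaries: 128 is median, 255 marginal red, 51 blue not violet
  pick <- function(v) lab[which(vals == v)[1]]
  expect_equal(pick(128), 3L)
  expect_equal(pick(255), 5L)
  expect_equal(pick(51), 2L)
  expect_equal(pick(50), 1L)
  expect_equal(pick(204), 5L)
})

test_that("component labelling reports area and perimeter per the edge-count oracle", {
  # single isolated pixel
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  cs <- label_components(labels_from_mask(m), matrix(TRUE, 5, 5))
  expect_equal(nrow(cs$components), 1)
  expect_equal(cs$components$area, 1L)
  expect_equal(cs$components$perimeter, 4L)

  # 2x3 solid rectangle: area 6, perimeter 10 (oracle-verified)
  m <- matrix(FALSE, 6, 6); m[2:3, 2:4] <- TRUE
  expect_equal(perimeter_oracle(m), 10L)
  cs <- label_components(labels_from_mask(m), matrix(TRUE, 6, 6))
  expect_equal(cs$components$area, 6L)
  expect_equal(cs$components$perimeter, 10L)

  # diagonal touch is one component under 8-connectivity
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  cs <- label_components(labels_from_mask(m), matrix(TRUE, 4, 4))
  expect_equal(nrow(cs$components), 1)
  expect_equal(cs$components$area, 2L)
  expect_equal(cs$components$perimeter, 8L)
})

test_that("component perimeters match the oracle on random masks and holes count", {
  set.seed(11)
  for (rep in 1:8) {
    m <- matrix(stats::runif(100) < 0.45, 10, 10)
    cs <- label_components(labels_from_mask(m), matrix(TRUE, 10, 10))
    expect_equal(sum(cs$components$area), sum(m))
    # perimeters are even and >= 4; their sum matches the whole-set oracle
    expect_true(all(cs$components$perimeter %% 2L == 0L))
    expect_true(all(cs$components$perimeter >= 4L))
    expect_equal(sum(cs$components$perimeter), perimeter_oracle(m))
  }
  # a ring: inner boundary (the hole) counts toward the perimeter
  ring <- matrix(FALSE, 5, 5); ring[2:4, 2:4] <- TRUE; ring[3, 3] <- FALSE
  cs <- label_components(labels_from_mask(ring), matrix(TRUE, 5, 5))
  expect_equal(nrow(cs$components), 1)
  expect_equal(cs$components$perimeter, 12L + 4L)  # outer 12 + hole 4
})

test_that("every pixel set in a 4x4 window satisfies the square lower bound on perimeter", {
  # vectorised brute force over all 65535 non-empty 16-bit masks:
  # perimeter >= 4*sqrt(area), the solid-square minimum (subadditivity of
  # sqrt extends it to disconnected sets, so no connectivity filter needed)
  masks <- 1:65535
  bit <- function(k) bitwAnd(bitwShiftR(masks, k), 1L)  # cell k of a 4x4 grid
  cells <- vapply(0:15, bit, integer(65535))            # rows: mask, col: cell
  area <- rowSums(cells)
  horiz <- 0L; vert <- 0L
  for (r in 0:3) for (c in 0:2) {
    horiz <- horiz + cells[, r * 4 + c + 1] * cells[, r * 4 + c + 2]
  }
  for (r in 0:2) for (c in 0:3) {
    vert <- vert + cells[, r * 4 + c + 1] * cells[, (r + 1) * 4 + c + 1]
  }
  perim <- 4 * area - 2 * (horiz + vert)
  expect_true(all(perim >= 4 * sqrt(area) - 1e-9))
})

test_that("cutoff filtering keeps exactly the large components of active layers", {
  # three components in layer 5 with areas 2, 4 and 9
  m <- matrix(FALSE, 12, 12)
  m[1, 1:2] <- TRUE            # area 2
  m[4:5, 4:5] <- TRUE          # area 4
  m[8:10, 8:10] <- TRUE        # area 9
  cs <- label_components(labels_from_mask(m), matrix(TRUE, 12, 12))
  expect_equal(sort(cs$components$area), c(2L, 4L, 9L))
  expect_equal(nrow(apply_cutoff(cs, 0, 1:5)$components), 3)    # identity
  expect_equal(nrow(apply_cutoff(cs, 4, 1:5)$components), 2)
  expect_equal(nrow(apply_cutoff(cs, 1000, 1:5)$components), 0) # above ROI
  # inactive layer removes everything
  expect_equal(nrow(apply_cutoff(cs, 0, c(1, 2))$components), 0)
  expect_error(apply_cutoff(cs, 0, integer()), "active_layers")
  # roi_area unchanged by filtering
  expect_equal(apply_cutoff(cs, 4, 1:5)$roi_area, cs$roi_area)
})

test_that("retained area is monotone in cutoff and in layer inclusion", {
  set.seed(5)
  vals <- matrix(sample(0:255, 400, TRUE), 20, 20)
  d <- structure(list(values = vals, mask = matrix(TRUE, 20, 20),
                      frame_pair = c(1L, 2L)), class = "differential_frame")
  cs <- label_components(band_layers(d), d$mask)
  areas <- vapply(c(0, 1, 2, 4, 8, 16, 400),
                  function(co) sum(apply_cutoff(cs, co, 1:5)$components$area),
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
  a12 <- sum(apply_cutoff(cs, 2, c(1, 2))$components$area)
  a125 <- sum(apply_cutoff(cs, 2, c(1, 2, 5))$components$area)
  expect_true(a12 <= a125)
})

test_that("empty masks yield empty component sets", {
  cs <- label_components(matrix(NA_integer_, 5, 5), matrix(FALSE, 5, 5))
  expect_equal(nrow(cs$components), 0)
  expect_equal(cs$roi_area, 0)
})
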