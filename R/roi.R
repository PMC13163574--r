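#' Keyframed region-of-interest track
#'
#' Represents the dynamically delineated cardiac cavity: closed polygons on a
#' subset of frames (keyframes), resampled to a common vertex count so that
#' vertex-wise linear interpolation between bracketing keyframes is well
#' defined. Polygon coordinates are in pixel units with `x` = column and
#' `y` = row, 0-based; a pixel centre sits at (col + 0.5, row + 0.5).
#'
#' @param keyframes named list mapping frame index (coerced from names) to an
#'   n-by-2 matrix of (x, y) vertices, n >= 3, or a list with `$x`/`$y`.
#' @param vertex_count common vertex count after arc-length resampling.
#'
#' @return An object of class `roi_track`.
#' @export
roi_track <- function(keyframes, vertex_count = 64L) {
  if (length(keyframes) < 1L) {
    stop("an ROI track needs at least one keyframe", call. = FALSE)
  }
  idx <- as.integer(names(keyframes))
  if (anyNA(idx)) stop("keyframe names must be frame indices", call. = FALSE)
  polys <- lapply(keyframes, function(p) {
    p <- as_polygon_matrix(p)
    if (nrow(p) < 3L) stop("polygons need at least 3 vertices", call. = FALSE)
    if (polygon_self_intersects(p)) {
      stop("ROI polygons must be simple (non-self-intersecting)", call. = FALSE)
    }
    resample_polygon(p, vertex_count)
  })
  ord <- order(idx)
  structure(list(keyframes = polys[ord], indices = idx[ord],
                 vertex_count = as.integer(vertex_count)),
            class = "roi_track")
}

as_polygon_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2L)
    return(unname(p))
  }
  if (is.list(p) && !is.null(p$x) && !is.null(p$y)) {
    return(cbind(p$x, p$y))
  }
  stop("polygon must be an n-by-2 matrix or a list with $x and $y",
       call. = FALSE)
}

# proper (interior) crossing test for segments p1-p2 and p3-p4
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4L) return(FALSE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      if (i == 1L && j == n) next   # adjacent through closure
      if (segments_cross(p[i, ], p[i %% n + 1L, ], p[j, ], p[j %% n + 1L, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# resample a closed polygon to n vertices equally spaced by arc length,
# keeping the first vertex as anchor so correspondence is stable across
# keyframes drawn from the same starting point
resample_polygon <- function(p, n) {
  closed <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) {             # degenerate: all vertices coincide
    return(matrix(rep(p[1, ], each = n), ncol = 2))
  }
  target <- total * (seq_len(n) - 1) / n
  x <- stats::approx(cum, closed[, 1], xout = target, ties = "ordered")$y
  y <- stats::approx(cum, closed[, 2], xout = target, ties = "ordered")$y
  cbind(x, y)
}

#' Interpolate the ROI polygon for an arbitrary frame
#'
#' At a keyframe the stored polygon is returned unchanged; between two
#' keyframes the bracketing resampled polygons are interpolated vertex-wise
#' and linearly in frame index; before the first / after the last keyframe
#' the nearest keyframe polygon is held constant.
#'
#' @param track an [roi_track()].
#' @param frame frame index (same basis as the keyframe names).
#' @return An n-by-2 vertex matrix.
#' @export
interpolate_roi <- function(track, frame) {
  stopifnot(inherits(track, "roi_track"))
  idx <- track$indices
  if (frame <= idx[1]) return(track$keyframes[[1]])
  if (frame >= idx[length(idx)]) return(track$keyframes[[length(idx)]])
  hit <- which(idx == frame)
  if (length(hit)) return(track$keyframes[[hit]])
  lo <- max(which(idx < frame))
  hi <- lo + 1L
  w <- (frame - idx[lo]) / (idx[hi] - idx[lo])
  (1 - w) * track$keyframes[[lo]] + w * track$keyframes[[hi]]
}

#' Rasterize a polygon to a binary pixel mask
#'
#' A pixel (row r, col c; 1-based matrix indices) is inside when its centre
#' (c - 0.5, r - 0.5) in 0-based (x, y) coordinates lies inside the polygon
#' under the even-odd rule.
#'
#' @param polygon n-by-2 (x, y) vertex matrix.
#' @param shape integer vector `c(H, W)`.
#' @return Logical H-by-W matrix.
#' @export
rasterize_roi <- function(polygon, shape) {
  polygon <- as_polygon_matrix(polygon)
  stopifnot(length(shape) == 2L, all(shape >= 1))
  H <- shape[1]; W <- shape[2]
  cx <- rep(seq_len(W) - 0.5, each = H)   # pixel-centre x per column
  cy <- rep(seq_len(H) - 0.5, times = W)  # pixel-centre y per row
  inside <- point_in_polygon_eo(cx, cy, polygon)
  mask <- matrix(inside, nrow = H, ncol = W)
  if (!any(mask)) {
    warning("polygon covers no pixel centres: empty ROI mask", call. = FALSE)
  }
  mask
}

# vectorised even-odd (crossing number) containment; points exactly on an
# edge follow the half-open ray convention, which is immaterial for the
# half-integer pixel centres used here against integer-vertex polygons
point_in_polygon_eo <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read an ROI track from a JSON file
#'
#' The file maps keyframe indices to vertex lists:
#' `{"0": [[x1,y1],[x2,y2],...], "40": [...]}`.
#'
#' @param path JSON file path.
#' @param vertex_count resampled vertex count, see [roi_track()].
#' @return An [roi_track()].
#' @export
read_roi <- function(path, vertex_count = 64L) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  kf <- lapply(raw, function(v) {
    m <- if (is.matrix(v)) v else do.call(rbind, v)
    matrix(as.numeric(m), ncol = 2)
  })
  roi_track(kf, vertex_count = vertex_count)
}

#' Write an ROI track to JSON
#' @param track an [roi_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(track, path) {
  stopifnot(inherits(track, "roi_track"))
  obj <- stats::setNames(
    lapply(track$keyframes, function(p) unname(apply(p, 1, as.numeric, simplify = FALSE))),
    as.character(track$indices)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
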