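#' Dynamically subtracted (differential) frame
#'
#' Pixel-wise signed brightness difference of two consecutive frames inside
#' the ROI, mapped to grayscale so that mid-gray (128) means no change and
#' the black/white extremes mean maximal darkening/brightening — the most
#' movable blood. The raw difference d = next - prev lies in [-255, 255] and
#' is mapped as g = round((d + 255) / 2), rounding halves away from zero.
#'
#' @param prev,nxt integer matrices of equal dimension, values 0-255.
#' @param mask logical matrix of the same dimension; values are defined only
#'   where `mask` is `TRUE` (elsewhere `NA`).
#' @param frame_pair integer pair `(t, t + 1)` of the source frame indices.
#'
#' @return An object of class `differential_frame` with fields `values`
#'   (integer matrix, `NA` outside the mask), `mask`, and `frame_pair`.
#' @export
subtract_frames <- function(prev, nxt, mask = NULL, frame_pair = c(1L, 2L)) {
  if (!all(dim(prev) == dim(nxt))) {
    stop("frames must have identical dimensions", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(prev), ncol(prev))
  if (!all(dim(mask) == dim(prev))) {
    stop("mask must match the frame dimensions", call. = FALSE)
  }
  d <- matrix(as.integer(nxt) - as.integer(prev), nrow(prev), ncol(prev))
  g <- map_difference_gray(d)
  g[!mask] <- NA_integer_
  structure(list(values = g, mask = mask,
                 frame_pair = as.integer(frame_pair)),
            class = "differential_frame")
}

# g = round((d + 255)/2) with halves away from zero; argument is >= 0 here
# so this is floor(x + 0.5)
map_difference_gray <- function(d) {
  g <- (d + 255L)
  matrix(as.integer(floor(g / 2 + 0.5)), nrow(d), ncol(d))
}

#' Differential-frame series over a window of a cine sequence
#'
#' Workflow stage that turns `k` native frames into `k - 1` differential
#' frames. Each pair `(t, t + 1)` is masked with the ROI of its later frame
#' `t + 1`, since the differential is attributed to the later frame's time.
#'
#' @param seq a [cine_sequence()].
#' @param track an [roi_track()], or `NULL` to analyse the full frame.
#' @param window integer pair `(first, last)` native frame indices
#'   (1-based, inclusive); default the whole sequence.
#'
#' @return A list of `differential_frame` objects of length
#'   `diff(window) `, with a `times` attribute holding each differential
#'   frame's timestamp (the later source frame's time, seconds).
#' @export
differential_series <- function(seq, track = NULL, window = NULL) {
  stopifnot(inherits(seq, "cine_sequence"))
  if (is.null(window)) window <- c(1L, n_frames(seq))
  window <- as.integer(window)
  if (window[1] < 1L || window[2] > n_frames(seq) || diff(window) < 1L) {
    stop(sprintf("window [%d, %d] invalid for a %d-frame sequence",
                 window[1], window[2], n_frames(seq)), call. = FALSE)
  }
  shape <- dim(seq$frames[[1]])
  out <- vector("list", diff(window))
  times <- numeric(diff(window))
  for (i in seq_len(diff(window))) {
    t0 <- window[1] + i - 1L
    mask <- if (is.null(track)) {
      matrix(TRUE, shape[1], shape[2])
    } else {
      # ROI keyframes are 0-based frame indices; later frame t0 + 1 -> t0
      rasterize_roi(interpolate_roi(track, t0), shape)
    }
    out[[i]] <- subtract_frames(seq$frames[[t0]], seq$frames[[t0 + 1L]],
                                mask, frame_pair = c(t0, t0 + 1L))
    times[i] <- frame_time(seq, t0 + 1L)
  }
  attr(out, "times") <- times
  out
}
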