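#' Cine sequence container
#'
#' An ordered stack of 8-bit grayscale frames with acquisition timing and,
#' optionally, a synchronised ECG trace. This is the internal model every
#' reader and generator produces and every analysis stage consumes.
#'
#' @param frames list of integer matrices, all the same dimension, values 0-255.
#' @param frame_rate frames per second (positive).
#' @param pixel_spacing optional length-2 positive numeric, mm per pixel
#'   (row, column).
#' @param ecg optional [ecg_trace()].
#' @param source_modality one of `"ICE"`, `"TEE"`, `"TTE"`, `"MRI"`,
#'   `"ANGIO"`, `"SYNTH"`.
#' @param frame_times optional numeric vector of per-frame acquisition times
#'   in seconds; when absent, frame `k` is timestamped `(k - 1) / frame_rate`.
#'
#' @return An object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, frame_rate, pixel_spacing = NULL,
                          ecg = NULL, source_modality = "SYNTH",
                          frame_times = NULL) {
  if (!is.list(frames) || length(frames) < 2L) {
    stop("a cine sequence needs at least 2 frames", call. = FALSE)
  }
  frames <- lapply(frames, function(f) {
    if (!is.matrix(f)) stop("each frame must be a matrix", call. = FALSE)
    storage.mode(f) <- "integer"
    f
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share identical dimensions", call. = FALSE)
  }
  rng <- range(vapply(frames, function(f) range(f), integer(2)))
  if (rng[1] < 0L || rng[2] > 255L) {
    stop("frame intensities must lie within [0, 255]", call. = FALSE)
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("frame_rate must be a positive scalar", call. = FALSE)
  }
  if (!is.null(pixel_spacing)) {
    stopifnot(is.numeric(pixel_spacing), length(pixel_spacing) == 2L,
              all(pixel_spacing > 0))
  }
  if (!is.null(ecg) && !inherits(ecg, "ecg_trace")) {
    stop("ecg must be an ecg_trace", call. = FALSE)
  }
  source_modality <- match.arg(source_modality,
                               c("ICE", "TEE", "TTE", "MRI", "ANGIO", "SYNTH"))
  if (is.null(frame_times)) {
    frame_times <- (seq_along(frames) - 1) / frame_rate
  } else {
    stopifnot(length(frame_times) == length(frames))
  }
  structure(
    list(frames = frames, frame_rate = frame_rate,
         pixel_spacing = pixel_spacing, ecg = ecg,
         source_modality = source_modality, frame_times = frame_times),
    class = "cine_sequence"
  )
}

#' ECG trace attached to a cine sequence
#'
#' @param samples numeric amplitudes (at least 2).
#' @param sample_rate sampling frequency in Hz (positive).
#' @param offset time of the first ECG sample relative to the first frame,
#'   seconds (may be 0 or negative).
#'
#' @return An object of class `ecg_trace`.
#' @export
ecg_trace <- function(samples, sample_rate, offset = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 2L,
            is.numeric(sample_rate), length(sample_rate) == 1L,
            sample_rate > 0, is.numeric(offset), length(offset) == 1L)
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate, offset = offset),
            class = "ecg_trace")
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<cine_sequence> %d frames of %dx%d, %.1f fps, modality %s\n",
              length(x$frames), d[1], d[2], x$frame_rate, x$source_modality))
  if (!is.null(x$ecg)) {
    cat(sprintf("  ECG: %d samples at %g Hz\n",
                length(x$ecg$samples), x$ecg$sample_rate))
  } else {
    cat("  ECG: absent\n")
  }
  invisible(x)
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %d samples at %g Hz, %.2f s, offset %g s\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$offset))
  invisible(x)
}

#' Number of frames in a cine sequence
#' @param seq a [cine_sequence()].
#' @return integer frame count.
#' @export
n_frames <- function(seq) {
  stopifnot(inherits(seq, "cine_sequence"))
  length(seq$frames)
}

# time of native frame k (1-based): acquisition timestamp in seconds
frame_time <- function(seq, k) seq$frame_times[k]
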