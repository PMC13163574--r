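#' Detect R peaks in an ECG trace
#'
#' Classical QRS detection: band-pass filtering (5-15 Hz Butterworth),
#' differentiation, squaring, moving-window integration (150 ms), an
#' adaptive amplitude threshold, and a refractory window that suppresses
#' double detections. Each detection is refined to the local maximum of the
#' raw trace so peak times land on the R wave itself.
#'
#' @param ecg an [ecg_trace()].
#' @param refractory minimum spacing between peaks, seconds (default 0.2).
#' @return Numeric vector of strictly increasing peak times in seconds
#'   (relative to the first frame, i.e. including the trace offset). A flat
#'   or beatless trace returns `numeric(0)` with a warning.
#' @export
detect_r_peaks <- function(ecg, refractory = 0.2) {
  stopifnot(inherits(ecg, "ecg_trace"))
  x <- ecg$samples
  fs <- ecg$sample_rate
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    warning("flat ECG trace: no R peaks detected", call. = FALSE)
    return(numeric(0))
  }
  # reflect-pad so QRS complexes at the trace edges are detectable
  npad <- min(length(x) - 1L, round(0.5 * fs))
  xp <- c(rev(x[2:(npad + 1L)]), x, rev(x)[2:(npad + 1L)])
  # band-pass: clamp the upper edge below Nyquist for low sample rates
  hi <- min(15, 0.45 * fs)
  lo <- min(5, hi / 3)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, xp - mean(xp))
  sq <- c(0, diff(bp))^2
  w <- max(1L, round(0.150 * fs))
  integ <- stats::filter(sq, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  thr <- 0.35 * stats::quantile(integ, 0.995, names = FALSE)
  if (thr <= 0 || !any(integ > thr)) {
    warning("no QRS-like activity above threshold", call. = FALSE)
    return(numeric(0))
  }
  above <- integ > thr
  # rising edges of above-threshold runs
  starts <- which(diff(c(FALSE, above)) == 1)
  ends <- which(diff(c(above, FALSE)) == -1)
  ref_n <- round(refractory * fs)
  peaks <- integer(0)
  last <- -Inf
  half <- max(1L, round(0.10 * fs))
  for (k in seq_along(starts)) {
    seg <- starts[k]:ends[k]
    centre <- seg[which.max(integ[seg])]
    # refine on the (padded) raw trace around the integrated peak
    lo_i <- max(1L, centre - half); hi_i <- min(length(xp), centre + half)
    p <- lo_i + which.max(xp[lo_i:hi_i]) - 1L
    if (p - last >= ref_n) {
      peaks <- c(peaks, p)
      last <- p
    }
  }
  peaks <- peaks - npad                      # back to unpadded indices
  peaks <- peaks[peaks >= 1L & peaks <= length(x)]
  sort(unique((peaks - 1) / fs + ecg$offset))
}

#' Segment an index series into ECG-gated cardiac cycles
#'
#' The first `n_cycles` complete R-R intervals are mapped to differential
#' frames by timestamp containment (`r_onset <= t < r_next`). Atrial phase
#' boundaries are placed at fixed fractions of the R-R interval —
#' reservoir `[0, f1)`, conduit `[f1, f2)`, booster `[f2, 1)` — which
#' exactly partition each cycle. When the rhythm is too irregular (R-R
#' coefficient of variation above `max_rr_cv`, as in atrial fibrillation)
#' cycles are still delimited but phase boundaries are withheld.
#'
#' @param peaks R-peak times from [detect_r_peaks()], seconds.
#' @param series an [index_series()].
#' @param n_cycles number of consecutive cycles to analyse (default 3).
#' @param phase_fractions two increasing fractions in (0, 1); default
#'   `c(0.4, 0.75)`.
#' @param max_rr_cv R-R coefficient-of-variation limit for phase labelling.
#' @return A tibble of class `cardiac_cycles`, one row per cycle: `cycle`,
#'   `r_onset`, `r_next`, `reservoir_end`, `conduit_end` (absolute seconds,
#'   `NA` when phases are withheld), `n_frames`, and `frames` (list column
#'   of series row indices).
#' @export
segment_cycles <- function(peaks, series, n_cycles = 3,
                           phase_fractions = c(0.4, 0.75),
                           max_rr_cv = 0.15) {
  if (length(peaks) < n_cycles + 1) {
    stop(sprintf("need %d R peaks for %d cycles, found %d",
                 n_cycles + 1, n_cycles, length(peaks)), call. = FALSE)
  }
  stopifnot(length(phase_fractions) == 2L,
            phase_fractions[1] > 0, phase_fractions[2] < 1,
            phase_fractions[1] < phase_fractions[2])
  onset <- peaks[seq_len(n_cycles)]
  nxt <- peaks[seq_len(n_cycles) + 1]
  rr <- nxt - onset
  regular <- n_cycles < 2 || stats::sd(rr) / mean(rr) <= max_rr_cv
  if (!regular) {
    warning("irregular rhythm: atrial phase boundaries withheld",
            call. = FALSE)
  }
  # tolerant containment so frames timestamped exactly on a cycle boundary
  # are not lost to floating-point representation of index / frame_rate
  frames <- purrr::map2(onset, nxt, function(a, b) {
    eps <- 1e-9 * max(1, abs(b))
    which(series$time >= a - eps & series$time < b - eps)
  })
  out <- tibble::tibble(
    cycle = seq_len(n_cycles),
    r_onset = onset, r_next = nxt,
    reservoir_end = if (regular) onset + phase_fractions[1] * rr else NA_real_,
    conduit_end = if (regular) onset + phase_fractions[2] * rr else NA_real_,
    n_frames = lengths(frames),
    frames = frames
  )
  attr(out, "phase_fractions") <- phase_fractions
  class(out) <- c("cardiac_cycles", class(out))
  out
}

#' Label each series frame with its cycle and atrial phase
#'
#' @param series an [index_series()].
#' @param cycles a `cardiac_cycles` tibble from [segment_cycles()].
#' @return The series with `cycle` and `phase` columns added (`NA` outside
#'   the analysed cycles or when phases are withheld).
#' @export
annotate_phases <- function(series, cycles) {
  series$cycle <- NA_integer_
  series$phase <- NA_character_
  for (k in seq_len(nrow(cycles))) {
    i <- cycles$frames[[k]]
    series$cycle[i] <- cycles$cycle[k]
    if (!is.na(cycles$reservoir_end[k])) {
      t <- series$time[i]
      series$phase[i] <- dplyr::case_when(
        t < cycles$reservoir_end[k] ~ "reservoir",
        t < cycles$conduit_end[k] ~ "conduit",
        TRUE ~ "booster"
      )
    }
  }
  series
}

#' Average an index curve across cardiac cycles
#'
#' Each cycle's curve is linearly resampled onto `n_bins` points of
#' normalised cycle time `[0, 1)` and per-bin mean, sample SD (n - 1
#' denominator) and SE are computed; missing values are excluded bin-wise.
#' Cycles containing no frames are excluded with a warning.
#'
#' @param series an [index_series()].
#' @param cycles a `cardiac_cycles` tibble from [segment_cycles()].
#' @param value name of the series column to average; default the first
#'   BMF track.
#' @param n_bins resampled points per cycle (default 50).
#' @return A tibble of class `cycle_average`: `bin`, `phase_time`
#'   (normalised `[0, 1)`), `mean`, `sd`, `se`, `n` (cycles contributing to
#'   the bin); `n_cycles` and the value name travel as attributes.
#' @export
cycle_average <- function(series, cycles, value = NULL, n_bins = 50) {
  if (is.null(value)) {
    value <- grep("^bmf_", names(series), value = TRUE)[1]
  }
  stopifnot(value %in% names(series))
  usable <- which(cycles$n_frames > 0)
  if (length(usable) < nrow(cycles)) {
    warning(sprintf("%d cycle(s) contain no frames and were excluded",
                    nrow(cycles) - length(usable)), call. = FALSE)
  }
  if (length(usable) < 2) {
    stop("cycle averaging needs at least 2 cycles with frames", call. = FALSE)
  }
  u <- (seq_len(n_bins) - 1) / n_bins
  curves <- vapply(usable, function(k) {
    i <- cycles$frames[[k]]
    t <- (series$time[i] - cycles$r_onset[k]) /
      (cycles$r_next[k] - cycles$r_onset[k])
    v <- series[[value]][i]
    ok <- !is.na(v)
    if (sum(ok) == 0) return(rep(NA_real_, n_bins))
    if (sum(ok) == 1) return(rep(v[ok], n_bins))
    stats::approx(t[ok], v[ok], xout = u, rule = 2, ties = "ordered")$y
  }, numeric(n_bins))
  n <- rowSums(!is.na(curves))
  m <- rowMeans(curves, na.rm = TRUE)
  sdv <- apply(curves, 1, stats::sd, na.rm = TRUE)
  out <- tibble::tibble(bin = seq_len(n_bins), phase_time = u,
                        mean = m, sd = sdv, se = sdv / sqrt(n), n = n)
  attr(out, "n_cycles") <- length(usable)
  attr(out, "value") <- value
  class(out) <- c("cycle_average", class(out))
  out
}
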