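#' Turbulence index of a single component
#'
#' TI is the ratio of the component's actual pixel contour length to the
#' minimal possible perimeter of a circle of the same area:
#' \deqn{TI = P / (2 \sqrt{\pi A})}
#' with P the unit-edge perimeter and A the pixel area. Under the edge-count
#' convention the discrete lower bound is \eqn{2/\sqrt{\pi} \approx 1.128},
#' attained exactly by solid squares; more fragmented, fractal boundaries
#' push TI up.
#'
#' @param area component area in pixels (>= 1).
#' @param perimeter component unit-edge perimeter.
#' @return Dimensionless TI value (vectorised).
#' @export
component_ti <- function(area, perimeter) {
  stopifnot(all(area >= 1))
  perimeter / (2 * sqrt(pi * area))
}

#' Per-frame aggregate and per-layer turbulence index
#'
#' Per-layer TI is the area-weighted mean of the component TIs in that layer;
#' the aggregate TI is the area-weighted mean over all retained components of
#' the active layers (large pools dominate the flow field). A frame with no
#' retained component yields `NA`, carried — never zero-filled — so cycle
#' averaging is not biased.
#'
#' @param cs a `component_set` (apply [apply_cutoff()] first if a cutoff or
#'   layer restriction is wanted).
#' @param active_layers layers entering the aggregate; default
#'   [default_active_layers()].
#' @param weighted area-weighted (default) or unweighted component mean.
#' @return A list with `ti` (scalar, possibly `NA`) and `ti_by_layer`
#'   (named numeric of length 5, `NA` for empty layers).
#' @export
frame_ti <- function(cs, active_layers = default_active_layers(),
                     weighted = TRUE) {
  stopifnot(inherits(cs, "component_set"))
  comp <- cs$components
  ti <- component_ti(comp$area, comp$perimeter)
  w <- if (weighted) comp$area else rep(1, nrow(comp))
  by_layer <- vapply(1:5, function(l) {
    k <- comp$layer == l
    if (!any(k)) return(NA_real_)
    sum(ti[k] * w[k]) / sum(w[k])
  }, numeric(1))
  act <- comp$layer %in% active_layers
  agg <- if (!any(act)) NA_real_ else sum(ti[act] * w[act]) / sum(w[act])
  list(ti = agg, ti_by_layer = stats::setNames(by_layer, paste0("ti_layer_", 1:5)))
}

#' Per-frame blood mobility fraction at a pixel-area cutoff
#'
#' BMF is the percentage of the ROI occupied by retained components — the
#' active, movable blood clusters:
#' \deqn{BMF = 100 \cdot \sum A_{retained} / A_{ROI}}
#' where retention keeps components of the active layers with area >= cutoff.
#'
#' @param cs a `component_set` (unfiltered; the cutoff is applied here).
#' @param cutoff pixel-area cutoff (>= 0).
#' @param active_layers layers counted; default [default_active_layers()].
#' @return BMF percentage in [0, 100].
#' @export
frame_bmf <- function(cs, cutoff, active_layers = default_active_layers()) {
  stopifnot(inherits(cs, "component_set"))
  if (cs$roi_area <= 0) stop("ROI area must be positive", call. = FALSE)
  kept <- apply_cutoff(cs, cutoff, active_layers)$components
  100 * sum(kept$area) / cs$roi_area
}

#' Full index series over a cine window
#'
#' Runs the pipeline differential -> isophote banding -> component labelling
#' -> TI / BMF for every consecutive frame pair, one row per differential
#' frame. Deterministic given its inputs.
#'
#' @param seq a [cine_sequence()].
#' @param track an [roi_track()] or `NULL` for the full frame.
#' @param window native-frame window `(first, last)`; default whole sequence.
#' @param cutoffs numeric vector of pixel-area cutoffs for the BMF tracks
#'   (>= 1 value); default `c(50, 100, 200, 500)`.
#' @param active_layers layers entering TI/BMF; default
#'   [default_active_layers()].
#' @param ti_cutoff pixel-area cutoff applied before TI (default 0: all
#'   components of the active layers).
#' @param weighted_ti area-weighted aggregate TI (default) or unweighted.
#'
#' @return A tibble of class `index_series`, one row per differential frame:
#'   `frame` (later source-frame index), `time` (s), `ti`,
#'   `ti_layer_1..5`, and one `bmf_<cutoff>` column per cutoff. The analysis
#'   configuration travels in `attr(, "config")`.
#' @export
index_series <- function(seq, track = NULL, window = NULL,
                         cutoffs = c(50, 100, 200, 500),
                         active_layers = default_active_layers(),
                         ti_cutoff = 0, weighted_ti = TRUE) {
  stopifnot(length(cutoffs) >= 1L)
  ds <- differential_series(seq, track, window)
  times <- attr(ds, "times")
  rows <- purrr::map(seq_along(ds), function(i) {
    df <- ds[[i]]
    cs <- label_components(band_layers(df), df$mask,
                           frame_pair = df$frame_pair[1])
    ti <- frame_ti(apply_cutoff(cs, ti_cutoff, 1:5),  # keep all layers for
                   active_layers, weighted = weighted_ti) # per-layer TI

    bmf <- vapply(cutoffs, function(co) frame_bmf(cs, co, active_layers),
                  numeric(1))
    c(list(frame = df$frame_pair[2], time = times[i], ti = ti$ti),
      as.list(ti$ti_by_layer),
      stats::setNames(as.list(bmf), paste0("bmf_", cutoffs)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- list(
    cutoffs = cutoffs, active_layers = as.integer(active_layers),
    ti_cutoff = ti_cutoff,
    ti_aggregation = if (weighted_ti) "area_weighted" else "unweighted",
    frame_rate = seq$frame_rate,
    roi = if (is.null(track)) "full_frame" else
      sprintf("roi_track(%d keyframes)", length(track$indices))
  )
  class(out) <- c("index_series", class(out))
  out
}

#' @export
print.index_series <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<index_series> %d differential frames; layers {%s}; cutoffs {%s}\n",
              nrow(x), paste(cfg$active_layers, collapse = ","),
              paste(cfg$cutoffs, collapse = ",")))
  NextMethod()
}

# BMF column helper: series column name for a cutoff
bmf_col <- function(cutoff) paste0("bmf_", cutoff)
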