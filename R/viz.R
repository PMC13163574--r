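#' Colorize a differential frame by isophote layer
#'
#' Pure view: active-layer pixels are painted their palette colour
#' (violet / blue / white / orange / red for layers 1-5), inactive layers
#' and non-ROI pixels are rendered black. Never alters numeric results.
#'
#' @param labels layer-label matrix from [band_layers()].
#' @param active_layers layers painted; default [default_active_layers()].
#' @param palette tibble as returned by [isophote_layers()] (its `hex`
#'   column is the layer -> colour bijection).
#' @return An H x W x 3 numeric array (RGB in `[0, 1]`).
#' @export
colorize <- function(labels, active_layers = default_active_layers(),
                     palette = isophote_layers()) {
  stopifnot(is.matrix(labels))
  rgb_cols <- grDevices::col2rgb(palette$hex) / 255
  out <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  for (l in intersect(1:5, active_layers)) {
    sel <- !is.na(labels) & labels == l
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- rgb_cols[ch, l]
      out[, , ch] <- plane
    }
  }
  out
}

#' Recover the layer index from a palette colour
#'
#' Inverse of the layer -> colour bijection used by [colorize()].
#' @param hex colour string(s).
#' @param palette palette tibble, see [isophote_layers()].
#' @return Integer layer indices (`NA` for non-palette colours).
#' @export
layer_from_color <- function(hex, palette = isophote_layers()) {
  palette$layer[match(toupper(hex), toupper(palette$hex))]
}

#' Export colorized frames as an animation
#'
#' Writes the frame stack as a multi-frame TIFF (`.tif`/`.tiff`, frame count
#' preserved; a single frame yields a still) or as a directory of numbered
#' PNG frames plus an `fps.txt` sidecar for any other path.
#'
#' @param frames list of H x W x 3 RGB arrays from [colorize()].
#' @param path output path.
#' @param fps playback frame rate recorded with the export.
#' @return `path`, invisibly.
#' @export
export_cine <- function(frames, path, fps = 30) {
  if (length(frames) == 0L) stop("no frames to export", call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(frames, path)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(frames)) {
      png::writePNG(frames[[i]], file.path(path, sprintf("frame_%04d.png", i)))
    }
    writeLines(as.character(fps), file.path(path, "fps.txt"))
  }
  invisible(path)
}

#' Export an analysis to CSV + JSON
#'
#' Writes the per-frame index table as full-precision CSV (one row per
#' differential frame; re-reading reproduces the numbers exactly) and a JSON
#' bundle holding the analysis configuration (active layers, cutoffs, TI
#' aggregation, phase fractions), cycle annotations and averaged curves.
#'
#' @param series an [index_series()].
#' @param path output stem: writes `<path>_series.csv` and `<path>.json`.
#' @param cycles optional `cardiac_cycles` from [segment_cycles()].
#' @param averages optional `cycle_average` from [cycle_average()].
#' @param summaries optional patient-summary tibble.
#' @return Named character vector of the files written, invisibly.
#' @export
export_results <- function(series, path, cycles = NULL, averages = NULL,
                           summaries = NULL) {
  stopifnot(inherits(series, "index_series"))
  csv <- paste0(path, "_series.csv")
  readr::write_csv(tibble::as_tibble(series), csv)
  cfg <- attr(series, "config")
  bundle <- list(config = cfg)
  if (!is.null(cycles)) {
    bundle$config$phase_fractions <- attr(cycles, "phase_fractions")
    bundle$cycles <- tibble::as_tibble(cycles[setdiff(names(cycles), "frames")])
  }
  if (!is.null(averages)) {
    bundle$cycle_average <- list(value = attr(averages, "value"),
                                 n_cycles = attr(averages, "n_cycles"),
                                 curve = tibble::as_tibble(averages))
  }
  if (!is.null(summaries)) bundle$summaries <- summaries
  json <- paste0(path, ".json")
  jsonlite::write_json(bundle, json, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(c(series_csv = csv, bundle_json = json))
}

#' Re-read an exported per-frame series CSV
#' @param path the `_series.csv` file written by [export_results()].
#' @return Tibble of the per-frame table.
#' @export
read_series_csv <- function(path) {
  # all-NA tracks must come back numeric, not logical
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_double()))
}

#' @rdname autoplot.index_series
#' @export
plot_index_series <- function(object, values = NULL, ...) {
  autoplot.index_series(object, values = values, ...)
}

#' Plot methods for analysis results
#'
#' `autoplot.index_series()` draws the TI and BMF curves over time;
#' `autoplot.cycle_average()` draws the cycle-averaged curve with SD and SE
#' ribbons; `autoplot.group_comparison()` shows the per-group means with SD
#' error bars.
#'
#' @param object the fitted/derived object.
#' @param values series columns to draw (default TI plus every BMF track).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.index_series <- function(object, values = NULL, ...) {
  if (is.null(values)) {
    values <- c("ti", grep("^bmf_", names(object), value = TRUE))
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(values),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$index)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~index, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @rdname autoplot.index_series
#' @exportS3Method ggplot2::autoplot
autoplot.cycle_average <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$phase_time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "normalised cycle time",
                  y = attr(object, "value") %||% "value",
                  title = sprintf("average of %d cycles (mean ± SD, SE)",
                                  attr(object, "n_cycles"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.index_series
#' @exportS3Method ggplot2::autoplot
autoplot.group_comparison <- function(object, ...) {
  d <- tibble::tibble(
    group = c(object$group_1, object$group_2),
    mean = c(object$mean_1, object$mean_2),
    sd = c(object$sd_1, object$sd_2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = object$statistic,
                  subtitle = sprintf("%s, p = %.4f", object$method, object$p)) +
    ggplot2::theme_minimal()
}
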