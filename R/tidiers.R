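#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a group comparison
#'
#' One row per tested statistic with estimates and the two-tailed p-value,
#' in the broom column convention.
#'
#' @param x a `group_comparison` from [compare_groups()].
#' @param ... unused.
#' @return A tibble with `statistic_name`, `estimate` (difference of group
#'   means), `statistic` (U or t), `p.value`, `method`.
#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    statistic_name = x$statistic,
    estimate = x$mean_1 - x$mean_2,
    statistic = ifelse(x$method == "mann_whitney", x$U, x$t),
    p.value = x$p,
    method = x$method
  )
}

#' @rdname tidy.group_comparison
#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble::tibble(n_1 = x$n_1, n_2 = x$n_2, method = x$method, p.value = x$p)
}

#' One-row summary of an index series
#'
#' @param x an [index_series()].
#' @param ... unused.
#' @return A tibble with frame count, duration, TI mean, and per-cutoff
#'   BMF max / min / range over non-missing frames.
#' @exportS3Method generics::glance
glance.index_series <- function(x, ...) {
  bmf_cols <- grep("^bmf_", names(x), value = TRUE)
  out <- tibble::tibble(
    n_frames = nrow(x),
    duration = max(x$time) - min(x$time),
    ti_mean = mean(x$ti, na.rm = TRUE)
  )
  for (cl in bmf_cols) {
    v <- x[[cl]][!is.na(x[[cl]])]
    out[[paste0(cl, "_max")]] <- max(v)
    out[[paste0(cl, "_min")]] <- min(v)
    out[[paste0(cl, "_range")]] <- max(v) - min(v)
  }
  out
}

#' Tidy a cycle average
#'
#' @param x a [cycle_average()].
#' @param ... unused.
#' @return The per-bin tibble (already tidy) as a plain tibble.
#' @exportS3Method generics::tidy
tidy.cycle_average <- function(x, ...) tibble::as_tibble(x)
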