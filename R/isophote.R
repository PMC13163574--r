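#' The five-layer isophote palette
#'
#' The differential grayscale [0, 256) is partitioned into five equal-width
#' half-open bands (widths 51, 51, 51, 51, 52 — the remainder goes to the top
#' band). Layers 1 and 5 (violet, red) are the marginal bands — the most
#' movable blood; 2 and 4 (blue, orange) are medial; 3 (white) is the median
#' band, the most stable blood around zero difference.
#'
#' @return A tibble with one row per layer: `layer`, `role`, `color`,
#'   `lo`, `hi` (half-open interval `[lo, hi)`), and display `hex`.
#' @export
isophote_layers <- function() {
  tibble::tibble(
    layer = 1:5,
    role  = c("marginal", "medial", "median", "medial", "marginal"),
    color = c("violet", "blue", "white", "orange", "red"),
    lo    = c(0L, 51L, 102L, 153L, 204L),
    hi    = c(51L, 102L, 153L, 204L, 256L),
    hex   = c("#8F00FF", "#2060FF", "#FFFFFF", "#FF8C00", "#E81010")
  )
}

#' Default active layers: marginal + medial, median excluded
#'
#' The median band encodes the most stable blood; flow is visualised and
#' quantified from the remaining bands unless configured otherwise.
#' @return Integer vector `c(1, 2, 4, 5)`.
#' @export
default_active_layers <- function() c(1L, 2L, 4L, 5L)

#' Assign each masked differential pixel to its isophote layer
#'
#' @param diff a `differential_frame` from [subtract_frames()].
#' @return Integer matrix of layer labels 1-5 (`NA` outside the mask).
#' @export
band_layers <- function(diff) {
  stopifnot(inherits(diff, "differential_frame"))
  v <- diff$values
  lab <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  # equal-width bands of 51; values 204-255 all fall in layer 5
  lab[ok] <- pmin(v[ok] %/% 51L + 1L, 5L)
  lab
}

#' Label 8-connected components per isophote layer
#'
#' Components are 8-connected sets of same-layer masked pixels. Each carries
#' its area (pixel count) and perimeter: the number of unit pixel edges
#' adjacent to a pixel outside the component or outside the mask, counting
#' outer and inner (hole) boundaries alike.
#'
#' @param labels integer layer-label matrix from [band_layers()].
#' @param mask logical ROI mask of the same dimension.
#' @param frame_pair optional source-pair annotation carried through.
#' @return An object of class `component_set`: a list with `components`
#'   (tibble: `component`, `layer`, `area`, `perimeter`), `pixel_map`
#'   (integer matrix of component ids), `roi_area`, `frame_pair`.
#' @export
label_components <- function(labels, mask, frame_pair = NA_integer_) {
  stopifnot(all(dim(labels) == dim(mask)))
  H <- nrow(labels); W <- ncol(labels)
  lab <- labels
  lab[!mask] <- NA_integer_
  roi_area <- sum(mask)
  pix <- which(!is.na(lab))
  if (length(pix) == 0L) {
    return(structure(list(
      components = tibble::tibble(component = integer(), layer = integer(),
                                  area = integer(), perimeter = integer()),
      pixel_map = matrix(NA_integer_, H, W),
      roi_area = roi_area, frame_pair = frame_pair
    ), class = "component_set"))
  }
  comp_id <- connected_components_8(lab)
  ids <- sort(unique(comp_id[pix]))
  area <- tabulate(comp_id[pix], nbins = max(ids))[ids]
  per <- component_perimeters(comp_id)[ids]
  layer <- integer(length(ids))
  first_pix <- match(ids, comp_id[pix])
  layer <- lab[pix[first_pix]]
  structure(list(
    components = tibble::tibble(component = ids, layer = layer,
                                area = as.integer(area),
                                perimeter = as.integer(per)),
    pixel_map = comp_id,
    roi_area = roi_area,
    frame_pair = frame_pair
  ), class = "component_set")
}

# 8-connected labelling of same-valued cells in an integer matrix with NAs;
# returns an integer matrix of component ids (NA where input NA)
connected_components_8 <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  idx <- which(!is.na(lab))
  if (!length(idx)) return(matrix(NA_integer_, H, W))
  # build edges to E, S, SE, SW neighbours of equal layer
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  edges <- list()
  add_edges <- function(dr, dc) {
    ok <- r + dr >= 1L & r + dr <= H & c + dc >= 1L & c + dc <= W
    from <- idx[ok]
    to <- from + dr + dc * H
    same <- !is.na(lab[to]) & lab[to] == lab[from]
    cbind(from[same], to[same])
  }
  e <- rbind(add_edges(0L, 1L), add_edges(1L, 0L),
             add_edges(1L, 1L), add_edges(-1L, 1L))
  vid <- match(seq_len(H * W), idx)       # matrix index -> vertex id
  ev <- if (nrow(e)) as.vector(rbind(vid[e[, 1]], vid[e[, 2]])) else integer()
  g <- igraph::make_graph(ev, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- matrix(NA_integer_, H, W)
  out[idx] <- as.integer(comp)
  out
}

# perimeter per component id: 4*area - 2*(4-adjacent same-component pairs)
component_perimeters <- function(comp_id) {
  H <- nrow(comp_id); W <- ncol(comp_id)
  n <- max(comp_id, na.rm = TRUE)
  area <- tabulate(comp_id[!is.na(comp_id)], nbins = n)
  pairs <- integer(n)
  # horizontal neighbours
  a <- comp_id[, -W, drop = FALSE]; b <- comp_id[, -1, drop = FALSE]
  same <- !is.na(a) & !is.na(b) & a == b
  if (any(same)) pairs <- pairs + tabulate(a[same], nbins = n)
  # vertical neighbours
  a <- comp_id[-H, , drop = FALSE]; b <- comp_id[-1, , drop = FALSE]
  same <- !is.na(a) & !is.na(b) & a == b
  if (any(same)) pairs <- pairs + tabulate(a[same], nbins = n)
  4L * area - 2L * pairs
}

#' Filter a component set by layer membership and pixel-area cutoff
#'
#' Retains exactly the components whose layer is active and whose area is at
#' least `cutoff` pixels; `roi_area` is unchanged so downstream fractions
#' keep the full ROI as denominator.
#'
#' @param cs a `component_set`.
#' @param cutoff minimum component area in pixels (>= 0).
#' @param active_layers subset of 1-5; default [default_active_layers()].
#' @return A filtered `component_set`.
#' @export
apply_cutoff <- function(cs, cutoff, active_layers = default_active_layers()) {
  stopifnot(inherits(cs, "component_set"), cutoff >= 0)
  active_layers <- as.integer(active_layers)
  if (length(active_layers) == 0L || !all(active_layers %in% 1:5)) {
    stop("active_layers must be a non-empty subset of 1..5", call. = FALSE)
  }
  keep <- cs$components$layer %in% active_layers & cs$components$area >= cutoff
  cs$components <- cs$components[keep, , drop = FALSE]
  pm <- cs$pixel_map
  pm[!is.na(pm) & !(pm %in% cs$components$component)] <- NA_integer_
  cs$pixel_map <- pm
  cs
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components over ROI of %d px\n",
              nrow(x$components), x$roi_area))
  print(dplyr::count(x$components, .data$layer, wt = .data$area, name = "area_px"))
  invisible(x)
}
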