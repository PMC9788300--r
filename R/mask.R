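#' Build a habitat mask around a detector array
#'
#' Discretize the region of integration for the spatial integrals of the
#' SECR likelihood: a regular square grid covering all points within
#' `buffer_m` of any detector of the array (a union of discs rasterized on
#' the grid). A cell belongs to the mask if its centre is within the
#' buffer of at least one detector.
#'
#' @param array A [detector_array].
#' @param buffer_m Buffer width in metres (positive, and at least one cell
#'   side).
#' @param cell_side_m Side of the square grid cells in metres.
#' @return An object of class `"habitat_mask"`: list with `x`, `y` (cell
#'   centre coordinates, metres), `cell_side_m`, `cell_area_km2`,
#'   `buffer_m`, and `n_cells`.
#' @examples
#' tr <- grid_array("A1", centre = c(0, 0))
#' m <- build_mask(tr, buffer_m = 6000, cell_side_m = 750)
#' mask_area_km2(m)
#' @export
build_mask <- function(array, buffer_m, cell_side_m) {
  stopifnot(inherits(array, "detector_array"))
  if (!is.numeric(buffer_m) || buffer_m <= 0) stop("'buffer_m' must be > 0")
  if (!is.numeric(cell_side_m) || cell_side_m <= 0) {
    stop("'cell_side_m' must be > 0")
  }
  if (buffer_m < cell_side_m) {
    stop("'buffer_m' must be at least one cell side")
  }
  det <- array$detectors
  x0 <- min(det$x) - buffer_m
  x1 <- max(det$x) + buffer_m
  y0 <- min(det$y) - buffer_m
  y1 <- max(det$y) + buffer_m
  nx <- ceiling((x1 - x0) / cell_side_m)
  ny <- ceiling((y1 - y0) / cell_side_m)
  cx <- x0 + (seq_len(nx) - 0.5) * cell_side_m
  cy <- y0 + (seq_len(ny) - 0.5) * cell_side_m
  g <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  # min distance from each centre to any detector
  d2min <- rep(Inf, nrow(g))
  for (k in seq_len(nrow(det))) {
    d2 <- (g$x - det$x[k])^2 + (g$y - det$y[k])^2
    d2min <- pmin(d2min, d2)
  }
  keep <- d2min <= buffer_m^2
  structure(
    list(x = g$x[keep], y = g$y[keep],
         cell_side_m = cell_side_m,
         cell_area_km2 = (cell_side_m / 1000)^2,
         buffer_m = buffer_m,
         n_cells = sum(keep)),
    class = "habitat_mask")
}

#' Total mask area
#'
#' @param mask A [habitat_mask].
#' @return Area in km^2 (`n_cells * cell_area_km2`).
#' @export
mask_area_km2 <- function(mask) {
  stopifnot(inherits(mask, "habitat_mask"))
  mask$n_cells * mask$cell_area_km2
}

#' @export
print.habitat_mask <- function(x, ...) {
  cat(sprintf(
    "Habitat mask: %d cells of %.0f m (%.4g km2 each), buffer %.0f m, area %.1f km2\n",
    x$n_cells, x$cell_side_m, x$cell_area_km2, x$buffer_m,
    mask_area_km2(x)))
  invisible(x)
}

mask_points <- function(mask) cbind(x = mask$x, y = mask$y)
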