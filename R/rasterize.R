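# Polygon rasterization: pixel centers inside the polygon under the even-odd
# crossing rule. Continuous coordinates are 0-based with integer values at
# pixel centers (so matrix element [i, j] sits at (i-1, j-1)). The crossing
# test is half-open, so pixels whose centers lie exactly on a shared edge
# belong to exactly one of the two adjacent polygons.

# even-odd point-in-polygon. vr/vc: polygon vertices, pr/pc: query points.
points_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vr[i] > pr) != (vr[j] > pr)) &
      (pc < (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# order SW, SE, NW, NE -> perimeter cycle SW, SE, NE, NW
perimeter_order <- function(corner) match(c("SW", "SE", "NE", "NW"), corner)

#' Pixel index set covered by a plot polygon
#'
#' Rasterizes one polygon to the 1-based matrix indices of all pixels whose
#' centers fall strictly inside it (even-odd rule). Corners are taken in
#' perimeter order; polygons are clipped to the frame.
#'
#' @param polygon Tibble with `corner`, `row`, `col` for one plot (continuous
#'   0-based coordinates, as produced by [project_field()]).
#' @param n_rows,n_cols Frame dimensions in pixels.
#' @return Integer matrix with `row` and `col` columns (1-based indices).
#' @export
polygon_pixels <- function(polygon, n_rows, n_cols) {
  ord <- if ("corner" %in% names(polygon) &&
             all(c("SW", "SE", "NW", "NE") %in% polygon$corner)) {
    perimeter_order(polygon$corner)
  } else {
    seq_len(nrow(polygon))
  }
  vr <- polygon$row[ord]
  vc <- polygon$col[ord]
  r0 <- max(0L, floor(min(vr))); r1 <- min(n_rows - 1L, ceiling(max(vr)))
  c0 <- max(0L, floor(min(vc))); c1 <- min(n_cols - 1L, ceiling(max(vc)))
  if (r1 < r0 || c1 < c0) {
    return(cbind(row = integer(0), col = integer(0)))
  }
  grid <- expand.grid(row = r0:r1, col = c0:c1)
  keep <- points_in_polygon(grid$row, grid$col, vr, vc)
  cbind(row = grid$row[keep] + 1L, col = grid$col[keep] + 1L)
}

#' Mean red value inside a polygon
#'
#' Arithmetic mean of the red channel over the pixels whose centers lie
#' inside the polygon.
#'
#' @param frame Numeric array `H x W x 3` (0-255).
#' @param polygon See [polygon_pixels()].
#' @return Scalar mean red value.
#' @export
mean_red_in_polygon <- function(frame, polygon) {
  px <- polygon_pixels(polygon, dim(frame)[1], dim(frame)[2])
  if (nrow(px) == 0) abort("polygon covers zero pixels")
  red <- frame[, , 1]
  mean(red[px])
}
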