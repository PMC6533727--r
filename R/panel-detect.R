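#' Mask the panel's red square in a frame
#'
#' Thresholds the frame in RGB space (default R 251-255, G 0-159, B 0-255),
#' cleans the mask with a morphological closing then opening using a square
#' structuring element, and removes connected components smaller than
#' `min_square_area_px`. Exactly one component - the fiducial red square -
#' must remain.
#'
#' @param frame Numeric array `H x W x 3` with 8-bit channel values (0-255).
#' @param config A [camera_config()].
#' @return Logical matrix of the same `H x W` shape, `TRUE` on the red square.
#' @export
mask_red_square <- function(frame, config = camera_config()) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] >= 3)
  th <- config$red_threshold
  mask <- frame[, , 1] >= th$r[1] & frame[, , 1] <= th$r[2] &
    frame[, , 2] >= th$g[1] & frame[, , 2] <= th$g[2] &
    frame[, , 3] >= th$b[1] & frame[, , 3] <= th$b[2]
  se <- config$structuring_element_px
  if (se > 1) {
    brush <- suppressWarnings(EBImage::makeBrush(se, shape = "box"))
    img <- EBImage::Image(t(mask))
    img <- EBImage::opening(EBImage::closing(img, brush), brush)
    mask <- t(EBImage::imageData(img)) > 0.5
  }
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labels <- t(EBImage::imageData(lab))
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= config$min_square_area_px)
  if (length(keep) == 0) {
    abort(sprintf(
      "panel not found: no red component with area >= %g px (largest was %g px)",
      config$min_square_area_px, if (length(areas)) max(areas) else 0))
  }
  if (length(keep) > 1) {
    abort(sprintf("ambiguous panel: %d red components with areas %s px",
                  length(keep), paste(areas[keep], collapse = ", ")))
  }
  labels == keep
}

#' Locate the reference corner of the red-square mask
#'
#' The reference point is the leftmost pixel of the mask: the minimum column
#' index containing a `TRUE` pixel, and within that column the minimum row.
#'
#' @param mask Logical matrix from [mask_red_square()].
#' @return Integer vector `c(row, col)` (1-based matrix indices).
#' @export
locate_reference_corner <- function(mask) {
  hit <- which(colSums(mask) > 0)
  if (length(hit) == 0) abort("empty mask: no red pixels to locate")
  col <- hit[1]
  row <- which(mask[, col])[1]
  c(row = row, col = col)
}

#' Classify the panel's rotation direction
#'
#' Samples the mean red value of the `probe_length_px` pixels directly below
#' and above the reference corner (same column). A mean above
#' `white_mean_threshold` indicates the white panel surface; lower values
#' indicate ground. White below / ground above marks a northeastward panel
#' rotation; the mirrored case marks southwest; white on both sides marks
#' northwest and ground on both sides southeast.
#'
#' @param frame Numeric array `H x W x 3` (0-255).
#' @param corner `c(row, col)` from [locate_reference_corner()].
#' @param config A [camera_config()].
#' @return One of `"NE"`, `"NW"`, `"SE"`, `"SW"`.
#' @export
classify_rotation_direction <- function(frame, corner, config = camera_config()) {
  L <- config$probe_length_px
  r <- corner[[1]]; c <- corner[[2]]
  H <- dim(frame)[1]
  if (r - L < 1 || r + L > H) {
    abort(sprintf("probe of %d px extends outside the frame at row %d", L, r))
  }
  below <- mean(frame[(r + 1):(r + L), c, 1])
  above <- mean(frame[(r - L):(r - 1), c, 1])
  w <- config$white_mean_threshold
  if (below > w && above <= w) "NE"
  else if (above > w && below <= w) "SW"
  else if (above > w && below > w) "NW"
  else "SE"
}

# Corner estimates for the masked square. Raw extreme pixels carry up to
# half an edge-plateau of quantization error near axis-aligned rotations, so
# the four corners are read off the minimum-area rotated rectangle fitted to
# the mask's convex hull (rotating calipers) - equivalent to the extreme
# points for an ideal square but subpixel-stable on rasterized ones.
mask_extremes <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  rect <- min_area_rect(px[, 1], px[, 2])
  rows <- rect[, 1]; cols <- rect[, 2]
  list(
    left   = c(row = rows[which.min(cols)], col = min(cols)),
    right  = c(row = rows[which.max(cols)], col = max(cols)),
    top    = c(row = min(rows), col = cols[which.min(rows)]),
    bottom = c(row = max(rows), col = cols[which.max(rows)])
  )
}

# minimum-area rotated rectangle of a point set; returns a 4 x 2 matrix of
# (row, col) corners
min_area_rect <- function(r, c) {
  hull <- grDevices::chull(c, r)
  hr <- r[hull]; hc <- c[hull]
  n <- length(hull)
  best <- NULL; best_area <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    dr <- hr[j] - hr[i]; dc <- hc[j] - hc[i]
    len <- sqrt(dr^2 + dc^2)
    if (len == 0) next
    u <- c(dr, dc) / len          # along-edge unit vector
    v <- c(-u[2], u[1])           # normal
    pu <- hr * u[1] + hc * u[2]
    pv <- hr * v[1] + hc * v[2]
    area <- diff(range(pu)) * diff(range(pv))
    if (area < best_area) {
      best_area <- area
      eu <- range(pu); ev <- range(pv)
      best <- rbind(
        eu[1] * u + ev[1] * v, eu[1] * u + ev[2] * v,
        eu[2] * u + ev[2] * v, eu[2] * u + ev[1] * v)
    }
  }
  if (is.null(best)) rbind(c(r[1], c[1]))[rep(1, 4), , drop = FALSE] else best
}

#' Compute the camera-to-field offset angle
#'
#' From the masked red square, measures the row extent (AB) and column extent
#' (BC) of the square edge adjacent to the reference corner - the edge running
#' to the topmost mask point for NE/SE rotations, or to the bottommost point
#' for SW/NW - and triangulates the offset angle between camera and field
#' axes. Northeastward rotations return `-90 - atand(AB/BC)`; the other three
#' directions return `atand(AB/BC)`.
#'
#' @param mask Logical matrix from [mask_red_square()].
#' @param corner `c(row, col)` reference corner (unused beyond validation;
#'   the edge is identified from the mask extremes).
#' @param direction Rotation direction from [classify_rotation_direction()].
#' @return Offset angle in degrees.
#' @export
compute_theta_off <- function(mask, corner, direction) {
  direction <- match.arg(direction, c("NE", "NW", "SE", "SW"))
  if (!any(mask)) abort("empty mask")
  ex <- mask_extremes(mask)
  other <- if (direction %in% c("NE", "SE")) ex$top else ex$bottom
  ab <- abs(other[["row"]] - ex$left[["row"]])
  bc <- abs(other[["col"]] - ex$left[["col"]])
  if (bc == 0) abort("degenerate mask: zero column extent on the corner edge")
  if (direction == "NE") -90 - atand(ab / bc) else atand(ab / bc)
}

#' Detect the panel in a still frame
#'
#' Convenience wrapper running [mask_red_square()],
#' [locate_reference_corner()], [classify_rotation_direction()] and
#' [compute_theta_off()] in sequence.
#'
#' @inheritParams mask_red_square
#' @return A list of class `panel_detection`: `corner` (row, col),
#'   `direction`, `theta_off_deg`, and `red_square_mask`.
#' @export
detect_panel <- function(frame, config = camera_config()) {
  mask <- mask_red_square(frame, config)
  corner <- locate_reference_corner(mask)
  direction <- classify_rotation_direction(frame, corner, config)
  theta <- compute_theta_off(mask, corner, direction)
  structure(list(corner = corner, direction = direction,
                 theta_off_deg = theta, red_square_mask = mask),
            class = "panel_detection")
}

#' @export
print.panel_detection <- function(x, ...) {
  cat("<panel_detection>\n")
  cat(sprintf("  corner: (row %d, col %d); direction: %s; theta_off: %.2f deg\n",
              x$corner[[1]], x$corner[[2]], x$direction, x$theta_off_deg))
  cat(sprintf("  red square area: %d px\n", sum(x$red_square_mask)))
  invisible(x)
}
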