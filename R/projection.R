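#' Rotate field-design points into the camera frame
#'
#' Rotates 2D field coordinates clockwise about the panel-center origin so the
#' field axes line up with the camera axes. The effective rotation angle is
#' the panel offset angle, plus 180 degrees for a southwestern rotation or 90
#' degrees for a southeastern one; for those two directions all coordinates
#' are also negated first. The rotation matrix acts on stacked (y; x) rows.
#'
#' @param points Data frame/tibble with `x` and `y` columns (field units).
#' @param theta_off_deg Offset angle from [compute_theta_off()].
#' @param direction Rotation direction, one of `"NE"`, `"NW"`, `"SE"`, `"SW"`.
#' @return The input tibble with `x_rot` and `y_rot` columns added.
#' @export
#' @examples
#' rotate_field_points(tibble::tibble(x = 2, y = 1), 90, "NE")
rotate_field_points <- function(points, theta_off_deg, direction) {
  direction <- match.arg(direction, c("NE", "NW", "SE", "SW"))
  eff <- theta_off_deg + switch(direction, NE = 0, NW = 0, SW = 180, SE = 90)
  flip <- if (direction %in% c("SE", "SW")) -1 else 1
  yx <- rbind(flip * points$y, flip * points$x)
  rot <- matrix(c(cosd(eff), -sind(eff), sind(eff), cosd(eff)), 2, 2)
  out <- rot %*% yx
  mutate(as_tibble(points), y_rot = out[1, ], x_rot = out[2, ])
}

#' Cartesian to spherical coordinates on the image hemisphere
#'
#' Latitude is the inverse sine of the ratio of the vertical distance to the
#' 3D distance from the lens to the point; longitude is the four-quadrant
#' inverse tangent of y over x.
#'
#' @param x_rot,y_rot Rotated field coordinates.
#' @param z_eff Vertical distance from the camera to the canopy point
#'   (must be > 0; see the `z_mode` option of [camera_config()]).
#' @return A tibble with `latitude_deg` (0-90) and `longitude_deg`
#'   (-180, 180].
#' @export
cartesian_to_spherical <- function(x_rot, y_rot, z_eff) {
  if (any(z_eff <= 0)) {
    abort("z_eff must be > 0: the canopy must sit below the camera (check `camera_height` and `z_mode`)")
  }
  tibble(
    latitude_deg = asind(z_eff / sqrt(x_rot^2 + y_rot^2 + z_eff^2)),
    longitude_deg = atan2d(y_rot, x_rot)
  )
}

#' Radial image fraction from latitude
#'
#' Empirical lens model of the hemispherical camera: the fraction of the
#' image size out to a point is a fixed quadratic in its latitude,
#' `D = phi^2 * 1e-7 - phi * 5e-3 + 0.3609`, strictly decreasing on
#' 0-90 degrees (points nearer the horizon land further from image center).
#'
#' @param phi_deg Latitude in degrees, within `[0, 90]`.
#' @return Radial fraction `D` of the image size.
#' @export
#' @examples
#' latitude_to_radial_fraction(0)    # 0.3609
#' latitude_to_radial_fraction(50)   # 0.11115
latitude_to_radial_fraction <- function(phi_deg) {
  if (any(phi_deg < 0 | phi_deg > 90)) {
    abort("latitude must be within [0, 90] degrees")
  }
  phi_deg^2 * 1e-7 - phi_deg * 5e-3 + 0.3609
}

#' Split the radial fraction into signed row and column fractions
#'
#' A law-of-sines step converts the radial fraction and longitude into row
#' and column fractions of the image, then signs are applied from the
#' longitude quadrant: longitudes in (0, 180] put the point above image
#' center (negative row fraction); longitudes in [-90, 90) put it right of
#' center (positive column fraction).
#'
#' @param D Radial fraction (>= 0).
#' @param theta_deg Longitude in degrees, (-180, 180].
#' @return A tibble with signed fractions `R` (rows) and `C` (columns).
#' @export
spherical_to_signed_fractions <- function(D, theta_deg) {
  r_mag <- D * abs(sind(theta_deg)) / sind(90)
  c_mag <- sqrt(pmax(D^2 - r_mag^2, 0))
  r_sign <- ifelse(theta_deg > 0 & theta_deg <= 180, -1, 1)
  c_sign <- ifelse(theta_deg >= -90 & theta_deg < 90, 1, -1)
  tibble(R = r_sign * r_mag, C = c_sign * c_mag)
}

#' Convert signed image fractions to pixel indices
#'
#' Fractions are scaled by the image size and offset by half the image size,
#' so (0, 0) maps to image center. Coordinates are continuous and 0-based
#' (row 0 at top); they are rasterized only when a polygon is cropped.
#'
#' @param R,C Signed row/column fractions.
#' @param image_size_px Frame edge length in pixels.
#' @return A tibble with continuous `row` and `col` pixel coordinates.
#' @export
#' @examples
#' fractions_to_pixel_index(0, 0, 2880)  # image center (1440, 1440)
fractions_to_pixel_index <- function(R, C, image_size_px) {
  if (image_size_px <= 0) abort("image_size_px must be > 0")
  tibble(row = R * image_size_px + image_size_px / 2,
         col = C * image_size_px + image_size_px / 2)
}

#' Project a field design onto hemispherical-image pixel polygons
#'
#' Composes the full demarcation chain for every canopy corner of every plot:
#' rotation by the detected offset angle, spherical coordinates, the
#' empirical radial lens model, signed row/column fractions, and pixel
#' indices. The result demarcates one four-corner polygon per plot.
#'
#' @param design Long tibble from [parse_plot_coordinates()] (one row per
#'   plot corner, with `z`, `x`, `y`).
#' @param detection A [detect_panel()] result, or a list with
#'   `theta_off_deg` and `direction`.
#' @param config A [camera_config()].
#' @return A tibble of class `plot_polygons`: one row per plot corner with
#'   identity columns, `corner`, continuous `row`/`col` pixel coordinates,
#'   and `in_frame`. Corners projecting outside the frame raise a warning
#'   but are retained.
#' @export
project_field <- function(design, detection, config = camera_config()) {
  z_eff <- if (config$z_mode == "drop") config$camera_height - design$z else design$z
  rot <- rotate_field_points(design, detection$theta_off_deg, detection$direction)
  sph <- cartesian_to_spherical(rot$x_rot, rot$y_rot, z_eff)
  D <- latitude_to_radial_fraction(sph$latitude_deg)
  rc <- spherical_to_signed_fractions(D, sph$longitude_deg)
  px <- fractions_to_pixel_index(rc$R, rc$C, config$image_size_px)
  out <- mutate(as_tibble(design),
                row = px$row, col = px$col,
                in_frame = px$row >= 0 & px$row <= config$image_size_px &
                  px$col >= 0 & px$col <= config$image_size_px)
  if (any(!out$in_frame)) {
    warn(sprintf("%d plot corner(s) project outside the frame; polygons retained",
                 sum(!out$in_frame)))
  }
  class(out) <- c("plot_polygons", class(out))
  attr(out, "image_size_px") <- config$image_size_px
  attr(out, "theta_off_deg") <- detection$theta_off_deg
  attr(out, "direction") <- detection$direction
  out
}

#' Write projected polygons to CSV
#'
#' One row per plot: the plot name followed by the eight pixel coordinates
#' (row, col for SW, SE, NW, NE).
#'
#' @param polygons A `plot_polygons` tibble from [project_field()].
#' @param path Output CSV path.
#' @export
write_polygons_csv <- function(polygons, path) {
  wide <- tidyr::pivot_wider(
    select(as_tibble(polygons), "plot_row", "name", "corner", "row", "col"),
    names_from = "corner", values_from = c("row", "col"),
    names_glue = "{corner}_{.value}")
  wide <- select(wide, "name", "SW_row", "SW_col", "SE_row", "SE_col",
                 "NW_row", "NW_col", "NE_row", "NE_col")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
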