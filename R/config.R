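#' Camera and detection configuration
#'
#' Bundles the acquisition geometry and panel-detection thresholds used across
#' the pipeline. Defaults reflect the reference camera system: a hemispherical
#' camera recording 2880 x 2880 px frames at 24 fps, mounted 2.7 m above the
#' field, with a red fiducial square detected by an RGB threshold.
#'
#' @param image_size_px Frame edge length in pixels (frames are square).
#' @param frame_rate_fps Video frame rate in frames per second.
#' @param camera_height Camera lens height above ground, in the same (arbitrary)
#'   length units as the field-design coordinates and plant heights.
#' @param red_threshold Named list of inclusive per-channel ranges (`r`, `g`,
#'   `b`, each a length-2 vector in 0-255) defining "red square" pixels.
#' @param min_square_area_px Connected components smaller than this are removed
#'   from the red mask (the true square covers about 6000 px near frame
#'   center at the default resolution).
#' @param probe_length_px Length of the vertical probe segments above/below the
#'   reference corner used to classify the rotation direction.
#' @param white_mean_threshold Mean red value above which a probe segment is
#'   called "white panel" rather than ground.
#' @param structuring_element_px Side of the square structuring element used to
#'   clean the red mask (rounded up to the next odd integer internally).
#' @param z_mode How the plant-height column is turned into the vertical
#'   distance used by the spherical projection: `"drop"` (default) uses
#'   `camera_height - plant_height`, i.e. the vertical drop from the lens to
#'   the canopy; `"literal"` uses the column value as-is.
#'
#' @return A list of class `camera_config`.
#' @export
#' @examples
#' cfg <- camera_config()
#' cfg$image_size_px
camera_config <- function(image_size_px = 2880,
                          frame_rate_fps = 24,
                          camera_height = 2.7,
                          red_threshold = list(r = c(251, 255),
                                               g = c(0, 159),
                                               b = c(0, 255)),
                          min_square_area_px = 5000,
                          probe_length_px = 40,
                          white_mean_threshold = 245,
                          structuring_element_px = 4,
                          z_mode = c("drop", "literal")) {
  z_mode <- match.arg(z_mode)
  if (!is.numeric(image_size_px) || image_size_px <= 0 ||
      image_size_px %% 2 != 0) {
    abort("`image_size_px` must be a positive even integer.")
  }
  if (!is.numeric(frame_rate_fps) || frame_rate_fps <= 0) {
    abort("`frame_rate_fps` must be > 0.")
  }
  for (ch in c("r", "g", "b")) {
    rng <- red_threshold[[ch]]
    if (is.null(rng) || length(rng) != 2 || any(rng < 0) || any(rng > 255) ||
        rng[1] > rng[2]) {
      abort(sprintf("`red_threshold$%s` must be an increasing range in [0, 255].", ch))
    }
  }
  structure(list(
    image_size_px = as.integer(image_size_px),
    frame_rate_fps = frame_rate_fps,
    camera_height = camera_height,
    red_threshold = red_threshold,
    min_square_area_px = min_square_area_px,
    probe_length_px = as.integer(probe_length_px),
    white_mean_threshold = white_mean_threshold,
    structuring_element_px = as.integer(structuring_element_px),
    z_mode = z_mode
  ), class = "camera_config")
}

#' Read a camera configuration from a YAML file
#'
#' Fields mirror the arguments of [camera_config()]; missing fields take the
#' defaults. `red_threshold` is given as a mapping with `r`, `g`, `b` entries.
#'
#' @param path Path to a YAML file.
#' @return A `camera_config` object.
#' @export
read_camera_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(camera_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warn(sprintf("Ignoring unknown config fields: %s",
                 paste(unknown, collapse = ", ")))
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(args$red_threshold)) {
    args$red_threshold <- lapply(args$red_threshold, as.numeric)
  }
  do.call(camera_config, args)
}

#' @export
print.camera_config <- function(x, ...) {
  cat("<camera_config>\n")
  cat(sprintf("  image: %d x %d px @ %g fps, camera height %g (z_mode = %s)\n",
              x$image_size_px, x$image_size_px, x$frame_rate_fps,
              x$camera_height, x$z_mode))
  cat(sprintf("  red threshold: R %g-%g, G %g-%g, B %g-%g; min area %g px\n",
              x$red_threshold$r[1], x$red_threshold$r[2],
              x$red_threshold$g[1], x$red_threshold$g[2],
              x$red_threshold$b[1], x$red_threshold$b[2],
              x$min_square_area_px))
  invisible(x)
}
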