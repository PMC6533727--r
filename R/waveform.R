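#' Extract panel-normalized red waveforms
#'
#' For every frame and plot polygon, computes the mean red value inside the
#' polygon divided by the mean red value of the panel's red square in that
#' same frame. The panel mask geometry is frozen (taken from the analysis
#' still); its red value is re-sampled each frame, so global illumination
#' changes cancel in the ratio.
#'
#' @param frames One of: a list of `H x W x 3` numeric arrays (0-255), or a
#'   path to a directory of numbered PNG frames (read in lexicographic
#'   order). Extract frames from video containers upstream with standard
#'   tools.
#' @param polygons A `plot_polygons` tibble from [project_field()].
#' @param panel_mask Logical matrix from [mask_red_square()].
#' @param config A [camera_config()] (supplies the frame rate).
#' @return A long tibble of class `waveform_tbl`: `frame` (1-based),
#'   `time_s`, `plot`, `value` (normalized red, > 0). One row per frame per
#'   plot; the attribute `fps` carries the frame rate.
#' @export
extract_normalized_waveforms <- function(frames, polygons, panel_mask,
                                         config = camera_config()) {
  if (!any(panel_mask)) abort("panel_mask is empty")
  loader <- frame_loader(frames)
  n_frames <- loader$n
  dims <- dim(loader$get(1))
  if (any(dim(panel_mask) != dims[1:2])) {
    abort("panel_mask shape does not match the frames")
  }
  poly_tbl <- as_tibble(polygons)
  plot_names <- if (!is.null(poly_tbl$name)) unique(poly_tbl$name) else
    unique(as.character(poly_tbl$plot_row))
  key <- if (!is.null(poly_tbl$name)) poly_tbl$name else as.character(poly_tbl$plot_row)
  idx_sets <- lapply(plot_names, function(p) {
    px <- polygon_pixels(poly_tbl[key == p, ], dims[1], dims[2])
    if (nrow(px) == 0) abort(sprintf("polygon for plot '%s' covers zero pixels", p))
    (px[, 2] - 1L) * dims[1] + px[, 1]  # linear indices into the red channel
  })
  panel_idx <- which(panel_mask)
  values <- matrix(NA_real_, n_frames, length(plot_names))
  for (f in seq_len(n_frames)) {
    fr <- loader$get(f)
    if (!identical(dim(fr)[1:2], dims[1:2])) {
      abort(sprintf("frame %d has a different shape than frame 1", f))
    }
    red <- fr[, , 1]
    panel_red <- mean(red[panel_idx])
    if (panel_red == 0) abort(sprintf("panel mean red is 0 in frame %d", f))
    values[f, ] <- vapply(idx_sets, function(ix) mean(red[ix]), 0) / panel_red
  }
  out <- tibble(
    frame = rep(seq_len(n_frames), times = length(plot_names)),
    time_s = (rep(seq_len(n_frames), times = length(plot_names)) - 1) /
      config$frame_rate_fps,
    plot = rep(plot_names, each = n_frames),
    value = as.vector(values)
  )
  class(out) <- c("waveform_tbl", class(out))
  attr(out, "fps") <- config$frame_rate_fps
  out
}

# uniform access to frame sequences
frame_loader <- function(frames) {
  if (is.character(frames) && length(frames) == 1 && dir.exists(frames)) {
    files <- sort(list.files(frames, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) abort(sprintf("no PNG frames found in %s", frames))
    list(n = length(files),
         get = function(i) png::readPNG(files[i])[, , 1:3, drop = FALSE] * 255)
  } else if (is.list(frames)) {
    list(n = length(frames), get = function(i) frames[[i]])
  } else {
    abort("`frames` must be a list of arrays or a directory of PNG frames")
  }
}

#' Write waveforms in the wide tab-delimited exchange format
#'
#' One header row of plot names, one row per frame.
#'
#' @param waveforms A `waveform_tbl`.
#' @param path Output path (conventionally the video stem plus `.txt`).
#' @export
write_waveforms <- function(waveforms, path) {
  wide <- tidyr::pivot_wider(as_tibble(waveforms)[, c("frame", "plot", "value")],
                             names_from = "plot", values_from = "value")
  wide$frame <- NULL
  write.table(wide, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read waveforms written by [write_waveforms()]
#'
#' @param path Tab-delimited file, header of plot names, one row per frame.
#' @param fps Frame rate to attach.
#' @return A `waveform_tbl`.
#' @export
read_waveforms <- function(path, fps = 24) {
  wide <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  out <- tidyr::pivot_longer(
    mutate(as_tibble(wide), frame = seq_len(nrow(wide))),
    -"frame", names_to = "plot", values_to = "value")
  out <- arrange(mutate(out, time_s = (.data$frame - 1) / fps), .data$plot, .data$frame)
  out <- out[, c("frame", "time_s", "plot", "value")]
  class(out) <- c("waveform_tbl", class(out))
  attr(out, "fps") <- fps
  out
}
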