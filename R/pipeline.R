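#' Run the plot-demarcation stage
#'
#' Reads the field-design files, detects the panel in the analysis still,
#' projects the design onto pixel polygons, and (optionally) writes the
#' polygon CSV plus one cropped overlay PNG per plot.
#'
#' @param still Path to the analysis still frame (PNG) or an `H x W x 3`
#'   array (0-255).
#' @param names_file,coords_file Field-design file paths (see
#'   [read_plot_names()] / [read_plot_coordinates()]).
#' @param config A [camera_config()].
#' @param out_dir Output directory; `NULL` skips file output.
#' @return Invisibly, a list with `detection`, `polygons`, and output paths.
#' @export
run_plotfinder <- function(still, names_file, coords_file,
                           config = camera_config(), out_dir = NULL) {
  frame <- load_frame(still)
  plots <- read_plot_names(names_file)
  design <- read_plot_coordinates(coords_file, plots = plots)
  detection <- detect_panel(frame, config)
  polygons <- project_field(design, detection, config)
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$polygons_csv <- file.path(out_dir, "plot_polygons.csv")
    write_polygons_csv(polygons, paths$polygons_csv)
    paths$overlays <- vapply(unique(polygons$name), function(p) {
      crop <- crop_polygon(frame, polygons[polygons$name == p, ])
      fp <- file.path(out_dir, paste0(p, ".png"))
      png::writePNG(crop / 255, fp)
      fp
    }, "")
    paths$manifest <- write_manifest(out_dir, "plotfinder", list(
      names_file = names_file, coords_file = coords_file,
      theta_off_deg = detection$theta_off_deg,
      direction = detection$direction,
      n_plots = length(unique(polygons$name))))
  }
  invisible(list(detection = detection, polygons = polygons, paths = paths))
}

# bounding-box crop with the outside of the polygon dimmed
crop_polygon <- function(frame, polygon) {
  px <- polygon_pixels(polygon, dim(frame)[1], dim(frame)[2])
  if (nrow(px) == 0) abort("polygon covers zero pixels")
  r <- range(px[, 1]); c <- range(px[, 2])
  crop <- frame[r[1]:r[2], c[1]:c[2], , drop = FALSE] * 0.35
  local_idx <- cbind(px[, 1] - r[1] + 1L, px[, 2] - c[1] + 1L)
  for (ch in 1:3) {
    idx <- (ch - 1L) * nrow(crop) * ncol(crop) +
      (local_idx[, 2] - 1L) * nrow(crop) + local_idx[, 1]
    crop[idx] <- crop[idx] / 0.35
  }
  crop
}

load_frame <- function(x) {
  if (is.character(x)) {
    png::readPNG(x)[, , 1:3, drop = FALSE] * 255
  } else {
    x
  }
}

#' Run the movement-extraction stage
#'
#' Extracts panel-normalized waveforms from a frame sequence, filters and
#' peak-analyzes each plot, and writes the waveform table, per-plot cycle
#' files, and the condensed movement summary.
#'
#' @param frames Frame source (see [extract_normalized_waveforms()]).
#' @param polygons A `plot_polygons` tibble.
#' @param panel_mask Logical red-square mask from the analysis still.
#' @param config A [camera_config()].
#' @param spec A [filter_spec()].
#' @param out_dir Output directory; `NULL` skips file output.
#' @param video_name Stem used for the waveform file name.
#' @return Invisibly, a list with `waveforms`, `summary`, and output paths.
#' @export
run_movement <- function(frames, polygons, panel_mask,
                         config = camera_config(), spec = filter_spec(),
                         out_dir = NULL, video_name = "video") {
  waveforms <- extract_normalized_waveforms(frames, polygons, panel_mask, config)
  n <- sum(waveforms$plot == waveforms$plot[1])
  filt <- design_bandpass(spec, config$frame_rate_fps, max_length = n)
  summary <- analyze_movement(waveforms, filter = filt)
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, video_name), showWarnings = FALSE, recursive = TRUE)
    paths$waveforms <- file.path(out_dir, paste0(video_name, ".txt"))
    write_waveforms(waveforms, paths$waveforms)
    paths$cycles <- vapply(unique(waveforms$plot), function(p) {
      w <- waveforms$value[waveforms$plot == p]
      cyc <- detect_cycles(bandpass_waveform(w, filt), config$frame_rate_fps)
      fp <- file.path(out_dir, video_name, paste0(p, ".txt"))
      write.table(cyc[, c("frequency", "area")], fp, sep = "\t",
                  row.names = FALSE, quote = FALSE)
      fp
    }, "")
    paths$summary <- file.path(out_dir, paste0(video_name, "_summary.csv"))
    utils::write.csv(summary, paths$summary, row.names = FALSE)
    paths$manifest <- write_manifest(out_dir, "movement", list(
      video = video_name, n_frames = n,
      filter_taps = length(filt$taps)))
  }
  invisible(list(waveforms = waveforms, summary = summary, filter = filt,
                 paths = paths))
}

#' Run the statistical stage
#'
#' Fits the RCB expected-mean-squares ANOVA and LSD mean separations for one
#' response on one or more movement-summary tables (one per video date,
#' analyzed separately).
#'
#' @param summaries A movement-summary tibble, or a character vector of
#'   summary CSV paths (each analyzed as one video date).
#' @param response Response column (`"mean_freq"` or a bin column).
#' @param positions Optional tibble mapping `plot` to `position` when the
#'   summaries lack a position column.
#' @param alpha Significance level.
#' @param correction P-value correction for the LSD tests.
#' @param out_dir Output directory; `NULL` skips file output.
#' @return Invisibly, a list per video date with `anova` and `means`.
#' @export
run_stats <- function(summaries, response = "mean_freq", positions = NULL,
                      alpha = 0.05, correction = "fdr", out_dir = NULL) {
  if (is.character(summaries)) {
    tabs <- lapply(summaries, function(p) as_tibble(utils::read.csv(p, check.names = FALSE)))
    names(tabs) <- sub("\\.csv$", "", basename(summaries))
  } else {
    tabs <- list(summary = as_tibble(summaries))
  }
  results <- lapply(names(tabs), function(nm) {
    tab <- tabs[[nm]]
    if (!"position" %in% names(tab)) {
      if (is.null(positions)) abort("summaries lack a position column and no `positions` map was given")
      tab <- left_join(tab, positions, by = "plot")
    }
    if (!response %in% names(tab)) {
      abort(sprintf("unknown response '%s'; available: %s", response,
                    paste(setdiff(names(tab), c("plot", "cultivar", "crop",
                                                "planting_date", "rep",
                                                "position", "valid")),
                          collapse = ", ")))
    }
    if ("valid" %in% names(tab) && any(!tab$valid)) {
      warn(sprintf("[%s] dropping %d plot(s) with no in-band cycles", nm,
                   sum(!tab$valid)))
      tab <- tab[tab$valid, ]
    }
    an <- anova_ems(tab, response)
    ms <- lsd_mean_separation(an, "cultivar", alpha = alpha,
                              correction = correction)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(tidy(an), file.path(out_dir, sprintf("%s_%s_anova.csv", nm, response)),
                       row.names = FALSE)
      utils::write.csv(tidy(ms), file.path(out_dir, sprintf("%s_%s_means.csv", nm, response)),
                       row.names = FALSE)
    }
    list(anova = an, means = ms)
  })
  names(results) <- names(tabs)
  invisible(results)
}

write_manifest <- function(out_dir, stage, extra) {
  fp <- file.path(out_dir, paste0(stage, "_manifest.json"))
  files <- setdiff(list.files(out_dir, recursive = TRUE), basename(fp))
  sums <- vapply(file.path(out_dir, files), function(f) {
    unname(tools::md5sum(f))
  }, "")
  manifest <- c(list(stage = stage,
                     version = as.character(utils::packageVersion("plotwave")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     outputs = as.list(setNames(sums, files))), extra)
  jsonlite::write_json(manifest, fp, auto_unbox = TRUE, pretty = TRUE)
  fp
}
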