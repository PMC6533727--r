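#' Synthetic field design
#'
#' Builds a small field design mimicking the reference trial layout: single
#' crop rows 3.04 m long at 30 cm spacing running perpendicular to the
#' camera track, with an inner replicate band near the track and an outer
#' band further away. The geometry rows describe the 929 cm^2 canopy-height
#' analysis sub-regions (one edge along the row center), which is what the
#' movement pipeline consumes.
#'
#' @param n_inner,n_outer Number of plots in the inner/outer bands.
#' @param inner_y,outer_y Perpendicular distance (m) from the track to each
#'   band (defaults match the reference trial: 2.28 and 6.86 m).
#' @param plant_height Canopy height (m) written to the z column.
#' @param row_pitch Spacing between analyzed rows along the track (m).
#' @param region_side Side length (m) of the square analysis sub-region
#'   (default sqrt(929 cm^2) = 0.3048 m).
#' @param planting_date Planting-date code used in the plot names.
#' @return A long design tibble (one row per plot corner) with identity
#'   columns, `position` (inner/outer), `z`, `corner`, `x`, `y` - the format
#'   [project_field()] consumes.
#' @export
synth_field_design <- function(n_inner = 4, n_outer = 4,
                               inner_y = 2.28, outer_y = 6.86,
                               plant_height = 0.9, row_pitch = 0.6,
                               region_side = 0.3048, planting_date = 2) {
  cultivars <- c("Gopher_oat", "Conlon_barley", "Linkert_wheat", "Quest_barley",
                 "Reins_oat", "Shelly_wheat", "Stellar_barley", "Rollag_wheat")
  one_band <- function(n, y0, position, rep_codes) {
    xs <- (seq_len(n) - (n + 1) / 2) * row_pitch
    purrr::map_dfr(seq_len(n), function(i) {
      cc <- strsplit(cultivars[(i - 1) %% length(cultivars) + 1], "_")[[1]]
      nm <- paste0(cc[1], "_", cc[2], "_", planting_date,
                   rep_codes[(i - 1) %% length(rep_codes) + 1])
      # square sub-region: x spans the row center +/- side/2, y extends away
      x0 <- xs[i] - region_side / 2
      x1 <- xs[i] + region_side / 2
      y1 <- y0 + region_side
      tibble(name = nm, cultivar = cc[1], crop = cc[2],
             planting_date = planting_date,
             rep = rep_codes[(i - 1) %% length(rep_codes) + 1],
             position = position,
             z = plant_height,
             corner = c("SW", "SE", "NW", "NE"),
             x = c(x0, x1, x0, x1),
             y = c(y0, y0, y1, y1))
    })
  }
  inner <- one_band(n_inner, inner_y, "inner", c("A", "B"))
  outer <- one_band(n_outer, outer_y, "outer", c("C", "D"))
  out <- bind_rows(inner, outer)
  # disambiguate duplicated names across bands
  out$name <- paste0(out$cultivar, "_", out$crop, "_", out$planting_date, out$rep)
  mutate(out, plot_row = match(.data$name, unique(.data$name)))
}

#' Synthetic scene ground truth
#'
#' Describes a rendered panel scene: the panel rotation magnitude and
#' direction, the red-square placement, and the field design. The rendered
#' rotation is chosen so that the offset-angle triangulation recovers
#' `theta_deg` for the given direction (northeastward scenes recover
#' `-90 - theta_deg`, the other directions recover `theta_deg`).
#'
#' @param theta_deg Rotation magnitude in degrees, strictly inside (0, 90)
#'   (0 and 90 leave no unambiguous leftmost corner).
#' @param direction One of `"NE"`, `"NW"`, `"SE"`, `"SW"`.
#' @param design Field design from [synth_field_design()].
#' @param square_side_px Red-square side in pixels (`NULL`: scaled so the
#'   square covers about the fraction of the frame the reference panel did).
#' @param center_offset_px Offset of the square center from image center
#'   (row, col).
#' @return A list of class `scene_truth`.
#' @export
scene_truth <- function(theta_deg, direction = "SW",
                        design = synth_field_design(),
                        square_side_px = NULL,
                        center_offset_px = c(0, 0)) {
  direction <- match.arg(direction, c("NE", "NW", "SE", "SW"))
  if (theta_deg <= 0 || theta_deg >= 90) {
    abort("theta_deg must lie strictly inside (0, 90); axis-aligned panels have no unambiguous leftmost corner")
  }
  structure(list(theta_deg = theta_deg, direction = direction,
                 design = design, square_side_px = square_side_px,
                 center_offset_px = center_offset_px),
            class = "scene_truth")
}

#' Expected offset angle for a scene
#'
#' @param scene A [scene_truth()].
#' @return The offset angle [compute_theta_off()] should report.
#' @export
theta_off_expected <- function(scene) {
  if (scene$direction == "NE") -90 - scene$theta_deg else scene$theta_deg
}

# fill an arbitrary convex polygon (continuous 0-based coords) into channels;
# vr may also be a polygon tibble with corner labels (vc ignored then)
fill_polygon <- function(frame, vr, vc = NULL, rgb) {
  poly <- if (is.data.frame(vr)) vr else tibble(row = vr, col = vc)
  px <- polygon_pixels(poly, dim(frame)[1], dim(frame)[2])
  if (nrow(px) == 0) return(frame)
  for (ch in 1:3) {
    idx <- (ch - 1L) * dim(frame)[1] * dim(frame)[2] +
      (px[, 2] - 1L) * dim(frame)[1] + px[, 1]
    frame[idx] <- rgb[ch]
  }
  frame
}

# red-square corner coordinates (continuous, 0-based) for a scene
scene_square_corners <- function(scene, config) {
  S <- config$image_size_px
  side <- scene$square_side_px %||% max(31, round(0.0268 * S))
  h <- side / 2
  rho <- if (scene$direction %in% c("NE", "SE")) scene$theta_deg else 90 - scene$theta_deg
  base <- rbind(r = c(-h, -h, h, h), c = c(-h, h, h, -h))
  rot <- matrix(c(cosd(rho), sind(rho), -sind(rho), cosd(rho)), 2, 2)
  pts <- rot %*% base
  ctr <- S / 2 + scene$center_offset_px
  list(row = pts[1, ] + ctr[1], col = pts[2, ] + ctr[2], side = side)
}

#' Render a hemispherical panel still frame
#'
#' Draws a seeded textured ground, the white panel blocks implied by the
#' scene's rotation direction, a pure-red fiducial square rotated so the
#' detection chain should recover the scene's angle, and darkened
#' plant-row stripes at the plots' projected positions (the forward mapping
#' reuses the projection chain, so geometry round trips are consistency
#' checks; angle and direction recovery remain genuine measurements).
#'
#' @param scene A [scene_truth()].
#' @param config A [camera_config()].
#' @param seed Integer seed for the ground texture.
#' @param draw_plots Whether to paint the plot-row stripes.
#' @return Numeric array `S x S x 3` of 8-bit values.
#' @export
render_panel_frame <- function(scene, config = camera_config(), seed = 1,
                               draw_plots = TRUE) {
  S <- config$image_size_px
  set.seed(seed)
  ground_r <- matrix(pmin(pmax(round(110 + rnorm(S * S, 0, 12)), 60), 180), S, S)
  frame <- array(0, dim = c(S, S, 3))
  frame[, , 1] <- ground_r
  frame[, , 2] <- pmin(pmax(ground_r - 20 + round(rnorm(S * S, 0, 6)), 30), 200)
  frame[, , 3] <- pmin(pmax(ground_r - 50 + round(rnorm(S * S, 0, 6)), 10), 160)
  sq <- scene_square_corners(scene, config)
  # leftmost corner of the exact square geometry
  iL <- which.min(sq$col)
  rL <- sq$row[iL]; cL <- sq$col[iL]
  wh <- max(60, round(0.05 * S))
  white <- c(255, 255, 255)
  draw_rect <- function(fr, r0, r1, c0, c1) {
    fill_polygon(fr, c(r0, r0, r1, r1), c(c0, c1, c1, c0), rgb = white)
  }
  if (scene$direction %in% c("NE", "NW")) {  # white below the corner
    frame <- draw_rect(frame, rL + 1, rL + 1 + wh, cL - wh / 2, cL + wh / 2)
  }
  if (scene$direction %in% c("SW", "NW")) {  # white above the corner
    frame <- draw_rect(frame, rL - 1 - wh, rL - 1, cL - wh / 2, cL + wh / 2)
  }
  frame <- fill_polygon(frame, sq$row, sq$col, rgb = c(253, 30, 40))
  if (draw_plots) {
    det <- list(theta_off_deg = theta_off_expected(scene),
                direction = scene$direction)
    polys <- suppressWarnings(project_field(scene$design, det, config))
    for (p in unique(polys$plot_row)) {
      pp <- polys[polys$plot_row == p, ]
      frame <- fill_polygon(frame, pp, rgb = c(70, 110, 45))
    }
  }
  frame
}

#' Waveform ground truth
#'
#' Parameters of one plot's simulated normalized-red series: a canopy-sway
#' sinusoid inside the analyzable band, a slow high-amplitude drift standing
#' in for passing-cloud lighting changes (< 0.5 Hz), and white noise.
#'
#' @param freq_hz Oscillation frequency (Hz).
#' @param amplitude Oscillation amplitude in normalized red units.
#' @param drift_freq_hz Drift frequency, must be < 0.5 Hz.
#' @param drift_amplitude Drift amplitude (normalized red units).
#' @param noise_sd White-noise standard deviation.
#' @param base Baseline normalized red value.
#' @param duration_s Duration in seconds.
#' @param fps Frame rate.
#' @param phase Oscillation phase offset (radians).
#' @return A list of class `waveform_truth`.
#' @export
waveform_truth <- function(freq_hz, amplitude = 0.01, drift_freq_hz = 0.15,
                           drift_amplitude = 0.05, noise_sd = 0.002,
                           base = 0.6, duration_s = 120, fps = 24, phase = 0) {
  if (drift_freq_hz >= 0.5) abort("drift frequency must be < 0.5 Hz")
  structure(list(freq_hz = freq_hz, amplitude = amplitude,
                 drift_freq_hz = drift_freq_hz,
                 drift_amplitude = drift_amplitude, noise_sd = noise_sd,
                 base = base, duration_s = duration_s, fps = fps,
                 phase = phase), class = "waveform_truth")
}

#' Simulate a normalized-red waveform
#'
#' `w[n] = base + A sin(2 pi f t + phase) + A_d sin(2 pi f_d t) + e[n]`,
#' with `e ~ N(0, noise_sd^2)` and `t = n / fps`.
#'
#' @param truth A [waveform_truth()].
#' @param seed Integer seed for the noise.
#' @return Numeric vector of `duration_s * fps` samples.
#' @export
simulate_waveform <- function(truth, seed = 1) {
  n <- round(truth$duration_s * truth$fps)
  t <- (seq_len(n) - 1) / truth$fps
  set.seed(seed)
  truth$base +
    truth$amplitude * sin(2 * pi * truth$freq_hz * t + truth$phase) +
    truth$drift_amplitude * sin(2 * pi * truth$drift_freq_hz * t) +
    rnorm(n, 0, truth$noise_sd)
}

#' Render a synthetic video of oscillating plots
#'
#' Starts from the scene's rendered still, then per frame multiplies each
#' plot region's red channel by `1 + osc + drift + noise` according to that
#' plot's [waveform_truth()], and the whole frame by a slow global
#' illumination gain that the panel's red square tracks, so panel
#' normalization cancels it downstream.
#'
#' @param scene A [scene_truth()].
#' @param truths Named list of [waveform_truth()] objects, one per plot name
#'   in the scene design.
#' @param n_frames Number of frames.
#' @param config A [camera_config()].
#' @param seed Integer seed (texture and per-plot noise).
#' @param gain Function of frame index returning the global illumination
#'   gain (kept at or below 1 so the 8-bit red square does not clip).
#' @return List with `frames` (list of arrays), `polygons` (projected
#'   `plot_polygons`), and `panel_mask` from the analysis still.
#' @export
render_synthetic_video <- function(scene, truths, n_frames,
                                   config = camera_config(), seed = 1,
                                   gain = function(f) 0.9 + 0.08 * sin(2 * pi * 0.1 * (f - 1) / config$frame_rate_fps)) {
  still <- render_panel_frame(scene, config, seed = seed, draw_plots = TRUE)
  panel_mask <- mask_red_square(still, config)
  det <- list(theta_off_deg = theta_off_expected(scene),
              direction = scene$direction)
  polys <- suppressWarnings(project_field(scene$design, det, config))
  plot_names <- unique(polys$name)
  if (!setequal(names(truths), plot_names)) {
    abort("`truths` must be a named list with one waveform_truth per plot in the design")
  }
  S <- dim(still)[1]
  idx_sets <- lapply(plot_names, function(p) {
    px <- polygon_pixels(polys[polys$name == p, ], S, S)
    (px[, 2] - 1L) * S + px[, 1]
  })
  names(idx_sets) <- plot_names
  set.seed(seed + 1)
  seeds <- sample.int(2^30, length(plot_names))
  mods <- lapply(seq_along(plot_names), function(i) {
    tr <- truths[[plot_names[i]]]
    set.seed(seeds[i])
    t <- (seq_len(n_frames) - 1) / config$frame_rate_fps
    1 + tr$amplitude * sin(2 * pi * tr$freq_hz * t + tr$phase) +
      tr$drift_amplitude * sin(2 * pi * tr$drift_freq_hz * t) +
      rnorm(n_frames, 0, tr$noise_sd)
  })
  frames <- vector("list", n_frames)
  base_red <- still[, , 1]
  for (f in seq_len(n_frames)) {
    red <- base_red
    for (i in seq_along(plot_names)) {
      red[idx_sets[[i]]] <- red[idx_sets[[i]]] * mods[[i]][f]
    }
    fr <- still
    g <- gain(f)
    fr[, , 1] <- round(pmin(pmax(red * g, 0), 255))
    fr[, , 2] <- round(pmin(still[, , 2] * g, 255))
    fr[, , 3] <- round(pmin(still[, , 3] * g, 255))
    frames[[f]] <- fr
  }
  list(frames = frames, polygons = polys, panel_mask = panel_mask,
       still = still)
}

#' Simulate an RCB movement dataset
#'
#' Generates per-plot movement responses under the randomized-complete-block
#' structure: grand mean plus optional cultivar, planting-date and
#' (nested) position effects, optional cultivar x planting-date interaction
#' noise, and iid Gaussian error. The default grand mean of 1.37 Hz matches
#' the average natural frequency the movement pipeline is built around.
#'
#' @param cultivars,planting_dates Level names (or counts).
#' @param positions Position levels.
#' @param reps Replicates per cultivar x planting date x position cell.
#' @param grand_mean Baseline response.
#' @param cultivar_effects,planting_date_effects,position_effects Optional
#'   per-level effect vectors (recycled to the level count; default all 0).
#' @param interaction_sd Standard deviation of random cultivar x
#'   planting-date interaction effects (0 = none).
#' @param sigma Residual standard deviation.
#' @param seed Integer seed.
#' @return Tibble with `cultivar`, `planting_date`, `position`, `rep`,
#'   `response`.
#' @export
simulate_movement_dataset <- function(cultivars = 4, planting_dates = 4,
                                      positions = c("inner", "outer"),
                                      reps = 2, grand_mean = 1.37,
                                      cultivar_effects = 0,
                                      planting_date_effects = 0,
                                      position_effects = 0,
                                      interaction_sd = 0, sigma = 0.1,
                                      seed = 1) {
  lev <- function(x, prefix) if (is.numeric(x) && length(x) == 1)
    paste0(prefix, seq_len(x)) else as.character(x)
  cu <- lev(cultivars, "C"); pd <- lev(planting_dates, "PD")
  set.seed(seed)
  ce <- rep_len(cultivar_effects, length(cu))
  pe <- rep_len(planting_date_effects, length(pd))
  qe <- rep_len(position_effects, length(positions))
  ie <- matrix(rnorm(length(cu) * length(pd), 0, interaction_sd),
               length(cu), length(pd))
  grid <- expand.grid(rep = seq_len(reps), position = positions,
                      planting_date = pd, cultivar = cu,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(grid$cultivar, cu); j <- match(grid$planting_date, pd)
  k <- match(grid$position, positions)
  grid$response <- grand_mean + ce[i] + pe[j] + qe[k] + ie[cbind(i, j)] +
    rnorm(nrow(grid), 0, sigma)
  as_tibble(grid[, c("cultivar", "planting_date", "position", "rep", "response")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
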