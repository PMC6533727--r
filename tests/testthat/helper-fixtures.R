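# Shared fixtures. Test scenes render at 720 px (detection geometry) or
# 360 px (video pipeline) with the fiducial square scaled up relative to the
# frame so corner quantization stays well below the 1-degree tolerance.

test_config <- function(image_size_px = 720, ...) {
  camera_config(image_size_px = image_size_px, min_square_area_px = 8000, ...)
}

video_config <- function() {
  camera_config(image_size_px = 360, min_square_area_px = 4000)
}

# filter template usable on short (a few hundred sample) signals: wider
# transitions and less attenuation keep the FIR shorter than the signal
relaxed_spec <- function() {
  filter_spec(fstop1 = 0.01, fpass1 = 0.08, fpass2 = 0.40, fstop2 = 0.60,
              astop_db = 40, apass_db = 5)
}

test_scene <- function(theta = 20, direction = "SW", config = test_config(),
                       design = synth_field_design()) {
  scene_truth(theta, direction, design = design,
              square_side_px = round(config$image_size_px * 150 / 720))
}

# small oscillating-plot video shared by the waveform/pipeline tests
cached_video <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- video_config()
      design <- synth_field_design(n_inner = 2, n_outer = 1)
      scene <- test_scene(25, "SW", cfg, design)
      plots <- unique(design$name)
      truths <- list(
        waveform_truth(1.5, amplitude = 0.012, drift_freq_hz = 0.05,
                       drift_amplitude = 0.03, noise_sd = 0.001, fps = 24),
        waveform_truth(2.5, amplitude = 0.025, drift_freq_hz = 0.05,
                       drift_amplitude = 0.03, noise_sd = 0.001, fps = 24),
        waveform_truth(1.5, amplitude = 0, drift_freq_hz = 0.05,
                       drift_amplitude = 0.0, noise_sd = 0, fps = 24)
      )
      names(truths) <- plots
      cache <<- c(render_synthetic_video(scene, truths, n_frames = 240,
                                         config = cfg, seed = 11),
                  list(config = cfg, truths = truths, scene = scene))
    }
    cache
  }
})

# independent convex point-in-polygon oracle: a point is inside a convex
# polygon iff all edge cross products share a sign (strictly, to exclude
# boundary points like the rasterizer does)
convex_pip_oracle <- function(pr, pc, vr, vc) {
  n <- length(vr)
  sides <- sapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    (vr[j] - vr[i]) * (pc - vc[i]) - (vc[j] - vc[i]) * (pr - vr[i])
  })
  apply(sides, 1, function(s) all(s > 0) || all(s < 0))
}

# brute-force balanced ANOVA decomposition by explicit group-mean summation
ems_anova_oracle <- function(d) {
  y <- d$response
  g <- mean(y)
  mc <- tapply(y, d$cultivar, mean)
  mp <- tapply(y, d$planting_date, mean)
  mcp <- tapply(y, list(d$cultivar, d$planting_date), mean)
  mpk <- tapply(y, list(d$planting_date, d$position), mean)
  mcpk <- tapply(y, list(d$cultivar, d$planting_date, d$position), mean)
  nc <- table(d$cultivar); np <- table(d$planting_date)
  ncp <- table(d$cultivar, d$planting_date)
  npk <- table(d$planting_date, d$position)
  ncpk <- table(d$cultivar, d$planting_date, d$position)
  ss_c <- sum(nc * (mc - g)^2)
  ss_p <- sum(np * (mp - g)^2)
  ss_pk <- sum(npk * (mpk - rep(mp, times = ncol(mpk)))^2)
  ss_cp <- sum(ncp * (mcp - outer(mc, rep(1, length(mp))) -
                        outer(rep(1, length(mc)), mp) + g)^2)
  ss_cpk <- 0
  for (k in seq_len(dim(mcpk)[3])) {
    dev <- mcpk[, , k] - mcp - outer(rep(1, nrow(mcp)), mpk[, k]) +
      outer(rep(1, nrow(mcp)), mp)
    ss_cpk <- ss_cpk + sum(ncpk[, , k] * dev^2)
  }
  ss_tot <- sum((y - g)^2)
  ss_e <- ss_tot - ss_c - ss_p - ss_pk - ss_cp - ss_cpk
  a <- length(mc); b <- length(mp); q <- dim(mcpk)[3]
  df <- c(a - 1, b - 1, b * (q - 1), (a - 1) * (b - 1), (a - 1) * b * (q - 1))
  df <- c(df, length(y) - 1 - sum(df))
  ss <- c(ss_c, ss_p, ss_pk, ss_cp, ss_cpk, ss_e)
  ms <- ss / df
  f <- c(ms[1] / ms[5], ms[2] / ms[3], ms[3] / ms[6], ms[4] / ms[5], ms[5] / ms[6])
  list(ss = ss, df = df, ms = ms, f = f)
}
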