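#' Bandpass filter specification
#'
#' Band edges are expressed as fractions of the analyzable band (0 to half
#' the frame rate; 0-12 Hz at 24 fps). Defaults follow the movement-analysis
#' template: stop up to 3%, pass 4-40%, stop from 50%, with 100 dB stopband
#' attenuation and 5 dB passband ripple. At 24 fps the edges are
#' 0.36 / 0.48 / 4.8 / 6.0 Hz.
#'
#' @param fstop1,fpass1,fpass2,fstop2 Band-edge fractions,
#'   `0 < fstop1 < fpass1 < fpass2 < fstop2 < 1`.
#' @param astop_db Minimum stopband attenuation in dB.
#' @param apass_db Maximum passband ripple in dB.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(fstop1 = 0.03, fpass1 = 0.04,
                        fpass2 = 0.40, fstop2 = 0.50,
                        astop_db = 100, apass_db = 5) {
  e <- c(fstop1, fpass1, fpass2, fstop2)
  if (any(diff(e) <= 0) || e[1] <= 0 || e[4] >= 1) {
    abort("band edges must satisfy 0 < fstop1 < fpass1 < fpass2 < fstop2 < 1")
  }
  structure(list(fstop1 = fstop1, fpass1 = fpass1, fpass2 = fpass2,
                 fstop2 = fstop2, astop_db = astop_db, apass_db = apass_db),
            class = "filter_spec")
}

#' Analyzable-band upper limit
#'
#' Half the frame rate: a 24 fps recording supports frequencies up to 12 Hz,
#' and filter-edge fractions are interpreted against this bound.
#'
#' @param frame_rate_fps Frames per second.
#' @return Upper frequency bound in Hz.
#' @export
#' @examples
#' analyzable_band_hz(24)  # 12
analyzable_band_hz <- function(frame_rate_fps) {
  if (frame_rate_fps <= 0) abort("frame_rate_fps must be > 0")
  frame_rate_fps / 2
}

#' Band edges of a filter specification in Hz
#'
#' @param spec A [filter_spec()].
#' @param frame_rate_fps Frames per second.
#' @return Named numeric vector `fstop1`, `fpass1`, `fpass2`, `fstop2` (Hz).
#' @export
band_edges_hz <- function(spec, frame_rate_fps) {
  ny <- analyzable_band_hz(frame_rate_fps)
  c(fstop1 = spec$fstop1, fpass1 = spec$fpass1,
    fpass2 = spec$fpass2, fstop2 = spec$fstop2) * ny
}

#' Design the bandpass FIR filter
#'
#' Realizes a linear-phase FIR whose magnitude response meets the
#' specification: attenuation of at least `astop_db` (within a 5 dB
#' measurement tolerance) below `fstop1` and above `fstop2`, and ripple
#' within `apass_db` across the passband. The filter is a Kaiser-windowed
#' sinc whose length is grown from the analytic estimate until the measured
#' response conforms; the response is verified on a dense frequency grid at
#' design time.
#'
#' @param spec A [filter_spec()].
#' @param frame_rate_fps Frames per second.
#' @param max_length Optional cap on filter length; signals shorter than the
#'   filter cannot be processed, so designs exceeding the cap error and name
#'   the minimum usable signal length.
#' @return A list of class `fir_bandpass`: `taps`, `edges_hz`, `fs`,
#'   `achieved` (measured stopband attenuation and passband ripple, dB).
#' @export
design_bandpass <- function(spec = filter_spec(), frame_rate_fps = 24,
                            max_length = Inf) {
  edges <- band_edges_hz(spec, frame_rate_fps)
  fs <- frame_rate_fps
  ny <- fs / 2
  a_target <- spec$astop_db
  trans_hz <- min(edges["fpass1"] - edges["fstop1"],
                  edges["fstop2"] - edges["fpass2"])
  beta <- kaiser_beta(a_target + 5)
  dw <- 2 * pi * trans_hz / fs
  n <- ceiling((a_target + 5 - 7.95) / (2.285 * dw))
  if (n %% 2 == 1) n <- n + 1
  cutoffs <- c(mean(edges[c("fstop1", "fpass1")]),
               mean(edges[c("fpass2", "fstop2")])) / ny
  for (trial in 1:8) {
    taps <- signal::fir1(n, cutoffs, type = "pass",
                         window = signal::kaiser(n + 1, beta))
    ach <- measure_response(taps, fs, edges)
    ok <- ach["stop_db"] >= a_target - 5 && ach["pass_db"] <= spec$apass_db
    if (ok) break
    n <- ceiling(n * 1.25)
    if (n %% 2 == 1) n <- n + 1
  }
  if (!ok) {
    abort(sprintf("could not meet the filter spec (achieved %.1f dB stopband, %.2f dB ripple)",
                  ach["stop_db"], ach["pass_db"]))
  }
  if (length(taps) > max_length) {
    abort(sprintf(
      "filter needs %d taps, longer than the allowed signal length %g; signals must have at least %d samples (or relax `astop_db`/widen the transition bands)",
      length(taps), max_length, length(taps)))
  }
  structure(list(taps = as.numeric(taps), edges_hz = edges, fs = fs,
                 spec = spec, achieved = ach),
            class = "fir_bandpass")
}

kaiser_beta <- function(a) {
  if (a > 50) 0.1102 * (a - 8.7)
  else if (a >= 21) 0.5842 * (a - 21)^0.4 + 0.07886 * (a - 21)
  else 0
}

measure_response <- function(taps, fs, edges, n_grid = 16384) {
  H <- abs(signal::freqz(taps, 1, n = n_grid, Fs = fs)$h)
  frq <- seq(0, fs / 2, length.out = n_grid)
  in_stop <- frq <= edges["fstop1"] | frq >= edges["fstop2"]
  in_pass <- frq >= edges["fpass1"] & frq <= edges["fpass2"]
  stop_db <- -20 * log10(max(H[in_stop]))
  pass_db <- 20 * log10(max(H[in_pass])) - 20 * log10(min(H[in_pass]))
  c(stop_db = stop_db, pass_db = pass_db)
}

#' Frequency response of a designed filter
#'
#' @param filter A `fir_bandpass`.
#' @param freqs_hz Frequencies at which to evaluate.
#' @return Tibble with `freq_hz`, `magnitude`, `magnitude_db`.
#' @export
filter_response <- function(filter, freqs_hz) {
  k <- seq_along(filter$taps) - 1
  H <- vapply(freqs_hz, function(f) {
    abs(sum(filter$taps * exp(-2i * pi * f * k / filter$fs)))
  }, 0)
  tibble(freq_hz = freqs_hz, magnitude = H, magnitude_db = 20 * log10(H))
}

#' @export
print.fir_bandpass <- function(x, ...) {
  cat("<fir_bandpass>\n")
  cat(sprintf("  %d taps at %g fps; edges %s Hz\n", length(x$taps), x$fs,
              paste(signif(x$edges_hz, 3), collapse = " / ")))
  cat(sprintf("  measured: %.1f dB stopband, %.3f dB passband ripple\n",
              x$achieved["stop_db"], x$achieved["pass_db"]))
  invisible(x)
}

#' Bandpass-filter a waveform
#'
#' Single forward pass of the FIR over the mean-centered signal (the filter
#' rejects DC, so removing the mean first only suppresses the start-up
#' transient). Causal filtering delays all features by the group delay
#' equally, leaving peak spacing and inter-peak areas unchanged. Output
#' length equals input length and the result is centered at zero.
#'
#' @param waveform Numeric vector (one plot's normalized red series).
#' @param filter A `fir_bandpass` from [design_bandpass()].
#' @return Filtered numeric vector of the same length.
#' @export
bandpass_waveform <- function(waveform, filter) {
  n <- length(waveform)
  if (n < length(filter$taps)) {
    abort(sprintf("signal of %d samples is shorter than the %d-tap filter; need at least %d samples",
                  n, length(filter$taps), length(filter$taps)))
  }
  as.numeric(signal::filter(filter$taps, 1, waveform - mean(waveform)))
}

# topographic prominence of each candidate peak: height above the higher of
# the two bases, where each base is the minimum between the peak and the
# nearest higher sample on that side (or the signal end).
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    higher <- which(left > h)
    lbase <- min(left[seq.int(from = if (length(higher)) max(higher) + 1 else 1,
                              to = p - 1)])
    right <- x[seq.int(p + 1, length(x))]
    higher <- which(right > h)
    rbase <- min(right[seq_len(if (length(higher)) min(higher) - 1 else length(right))])
    h - max(lbase, rbase)
  }, 0)
}

# local maxima; plateaus contribute their leftmost sample
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  # collapse zero runs: a plateau is a peak if the last nonzero diff before it
  # is positive and the first nonzero diff after it is negative
  rising <- d > 0
  falling <- d < 0
  cand <- integer(0)
  state <- 0L  # last nonzero slope sign
  start <- NA_integer_
  for (i in seq_len(n - 1)) {
    if (rising[i]) {
      state <- 1L
      start <- NA_integer_
    } else if (falling[i]) {
      if (state == 1L) {
        cand <- c(cand, if (is.na(start)) i else start)
      }
      state <- -1L
      start <- NA_integer_
    } else if (state == 1L && is.na(start)) {
      start <- i  # plateau begins after a rise; leftmost plateau sample
    }
  }
  cand
}

#' Detect movement cycles in a filtered waveform
#'
#' Finds local maxima with topographic prominence of at least
#' `min_prominence` (0.005 normalized red units - a 0.5% red change). Each
#' consecutive peak pair defines one cycle: its frequency is the frame rate
#' divided by the peak spacing in frames, and its amplitude is the total
#' absolute area under the filtered curve between the peaks (rectangle rule;
#' left peak exclusive, right peak inclusive). The first peak anchors the
#' first cycle but contributes no row.
#'
#' @param filtered Zero-centered filtered waveform.
#' @param frame_rate_fps Frames per second.
#' @param min_prominence Peak-acceptance prominence threshold.
#' @return A tibble with one row per cycle: `frequency` (Hz), `area` (raw
#'   normalized-red x frame units) and `area_pct` (the same in percent
#'   units). Empty (zero rows) when fewer than two peaks qualify. The
#'   attribute `peaks` carries the accepted peak sample indices.
#' @export
detect_cycles <- function(filtered, frame_rate_fps = 24, min_prominence = 0.005) {
  cand <- local_maxima(filtered)
  if (length(cand) > 0) {
    prom <- peak_prominences(filtered, cand)
    peaks <- cand[prom >= min_prominence]
  } else {
    peaks <- integer(0)
  }
  if (length(peaks) < 2) {
    out <- tibble(frequency = numeric(0), area = numeric(0), area_pct = numeric(0))
    attr(out, "peaks") <- peaks
    return(out)
  }
  d <- diff(peaks)
  areas <- vapply(seq_len(length(peaks) - 1), function(i) {
    sum(abs(filtered[(peaks[i] + 1):peaks[i + 1]]))
  }, 0)
  out <- tibble(frequency = frame_rate_fps / d, area = areas,
                area_pct = 100 * areas)
  attr(out, "peaks") <- peaks
  out
}

#' Summarize plot movement from its cycle table
#'
#' Cycles outside the pass range (0.5-4.9 Hz) are discarded; the retained
#' frequencies give the plot's natural-frequency statistics (mean, median,
#' standard deviation), and the retained cycle areas are accumulated into
#' 0.2 Hz bins spanning 0.5-4.7 Hz (21 bins; the 1.1-1.3 Hz bin is the
#' headline amplitude response). Bin areas are reported in percent
#' normalized-red units.
#'
#' @param cycles Tibble from [detect_cycles()].
#' @param pass_range Length-2 frequency interval retained for statistics.
#' @param bin_width Bin width in Hz.
#' @param bin_range Interval covered by the bins (left-closed bins).
#' @return A one-row tibble: `mean_freq`, `median_freq`, `sd_freq`,
#'   `n_cycles`, `valid`, then one `bin_<lo>_<hi>` column per bin. With zero
#'   retained cycles the statistics are `NA`, `valid` is `FALSE`, and a
#'   warning is raised.
#' @export
summarize_movement <- function(cycles, pass_range = c(0.5, 4.9),
                               bin_width = 0.2, bin_range = c(0.5, 4.7)) {
  keep <- cycles[cycles$frequency >= pass_range[1] &
                   cycles$frequency <= pass_range[2], ]
  lo <- round(seq(bin_range[1], bin_range[2] - bin_width / 2, by = bin_width), 10)
  hi <- round(lo + bin_width, 10)
  bin_names <- sprintf("bin_%s_%s", format(lo, trim = TRUE), format(hi, trim = TRUE))
  bins <- vapply(seq_along(lo), function(k) {
    sum(keep$area_pct[keep$frequency >= lo[k] & keep$frequency < hi[k]])
  }, 0)
  if (nrow(keep) == 0) {
    warn("no cycles within the pass range; movement summary flagged invalid")
    stats <- tibble(mean_freq = NA_real_, median_freq = NA_real_,
                    sd_freq = NA_real_, n_cycles = 0L, valid = FALSE)
  } else {
    stats <- tibble(
      mean_freq = mean(keep$frequency),
      median_freq = median(keep$frequency),
      sd_freq = if (nrow(keep) > 1) sd(keep$frequency) else 0,
      n_cycles = nrow(keep),
      valid = TRUE
    )
  }
  dplyr::bind_cols(stats, as_tibble(as.list(setNames(bins, bin_names))))
}

#' Analyze all plots of a waveform table
#'
#' Runs [bandpass_waveform()], [detect_cycles()] and [summarize_movement()]
#' on every plot column of a waveform table and binds the per-plot summary
#' rows, with identity columns parsed from the plot names where they follow
#' the `Cultivar_Crop_PlantingDateRep` convention.
#'
#' @param waveforms A `waveform_tbl` from [extract_normalized_waveforms()].
#' @param filter A `fir_bandpass`; by default designed from `spec` and the
#'   table's frame rate.
#' @param spec A [filter_spec()] used when `filter` is `NULL`.
#' @param min_prominence Passed to [detect_cycles()].
#' @param ... Passed to [summarize_movement()].
#' @return A tibble with one row per plot: `plot`, parsed identity columns
#'   when available, and the [summarize_movement()] columns.
#' @export
analyze_movement <- function(waveforms, filter = NULL, spec = filter_spec(),
                             min_prominence = 0.005, ...) {
  fps <- attr(waveforms, "fps")
  if (is.null(fps)) abort("waveform table has no `fps` attribute")
  plots <- unique(waveforms$plot)
  n <- sum(waveforms$plot == plots[1])
  if (is.null(filter)) {
    filter <- design_bandpass(spec, fps, max_length = n)
  }
  rows <- lapply(plots, function(p) {
    w <- waveforms$value[waveforms$plot == p]
    filt <- bandpass_waveform(w, filter)
    cyc <- detect_cycles(filt, fps, min_prominence)
    dplyr::bind_cols(tibble(plot = p), summarize_movement(cyc, ...))
  })
  out <- bind_rows(rows)
  ids <- tryCatch(parse_plot_names(out$plot), error = function(e) NULL)
  if (!is.null(ids)) {
    out <- dplyr::bind_cols(select(ids, "cultivar", "crop", "planting_date", "rep"),
                            out)
    out <- out[, c("plot", "cultivar", "crop", "planting_date", "rep",
                   setdiff(names(out), c("plot", "cultivar", "crop",
                                         "planting_date", "rep")))]
  }
  out
}
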