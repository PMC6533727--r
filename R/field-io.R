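#' Parse plot names
#'
#' Plot names follow the convention `Cultivar_Crop_PlantingDateRep`
#' (for example `Gopher_oat_4A`): three underscore-separated tokens, the last
#' being a planting-date integer immediately followed by a replicate code.
#' One plot per line, listed in the field's serpentine order.
#'
#' @param lines Character vector of plot-name lines (or a single file path,
#'   see [read_plot_names()]).
#' @return A tibble with one row per plot: `name`, `cultivar`, `crop`,
#'   `planting_date` (integer), `rep`, and `serpentine_index` (0-based line
#'   order).
#' @export
#' @examples
#' parse_plot_names(c("Gopher_oat_4A", "Linkert_wheat_1B"))
parse_plot_names <- function(lines) {
  lines <- trimws(lines)
  if (any(!nzchar(lines))) {
    abort(sprintf("Empty plot-name line(s): %s",
                  paste(which(!nzchar(lines)), collapse = ", ")))
  }
  pat <- "^([^_]+)_([^_]+)_([0-9]+)([A-Za-z]+)$"
  bad <- which(!grepl(pat, lines))
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed plot name on line %d: '%s' (expected Cultivar_Crop_PlantingDateRep)",
      bad[1], lines[bad[1]]))
  }
  m <- regmatches(lines, regexec(pat, lines))
  tibble(
    name = lines,
    cultivar = vapply(m, `[`, "", 2),
    crop = vapply(m, `[`, "", 3),
    planting_date = as.integer(vapply(m, `[`, "", 4)),
    rep = vapply(m, `[`, "", 5),
    serpentine_index = seq_along(lines) - 1L
  )
}

#' Format plot identities back into name strings
#'
#' Inverse of [parse_plot_names()]: `format_plot_names(parse_plot_names(x))`
#' returns `x`.
#'
#' @param plots Tibble with `cultivar`, `crop`, `planting_date`, `rep` columns.
#' @return Character vector of `Cultivar_Crop_PlantingDateRep` names.
#' @export
format_plot_names <- function(plots) {
  paste0(plots$cultivar, "_", plots$crop, "_", plots$planting_date, plots$rep)
}

#' Read a plot-names file
#'
#' @param path Plain-text file, one plot name per line.
#' @return See [parse_plot_names()].
#' @export
read_plot_names <- function(path) {
  if (!file.exists(path)) abort(sprintf("Plot-names file not found: %s", path))
  parse_plot_names(readLines(path, warn = FALSE))
}

#' Parse plot canopy-corner coordinates
#'
#' Each row describes one plot's canopy rectangle in field units with the
#' origin at the panel center: a plant height `z`, then (x, y) pairs for the
#' SW, SE, NW and NE corners (9 numeric fields in total). The x axis runs
#' along the camera track, y perpendicular to it. Row order pairs one-to-one
#' with the plot-names file for the same panel.
#'
#' @param rows A numeric matrix/data frame with 9 columns, or a character
#'   vector of whitespace-delimited lines.
#' @param plots Optional tibble from [parse_plot_names()]; if given, the row
#'   count must match and identity columns are bound on.
#' @return A tibble with one row per plot corner (`corner` in SW/SE/NW/NE
#'   order): `plot_row`, `z`, `corner`, `x`, `y`, plus identity columns when
#'   `plots` is supplied.
#' @export
parse_plot_coordinates <- function(rows, plots = NULL) {
  if (is.character(rows)) {
    rows <- rows[nzchar(trimws(rows))]
    parsed <- lapply(strsplit(trimws(rows), "[ \t]+"), function(x) {
      suppressWarnings(as.numeric(x))
    })
    nf <- lengths(parsed)
    if (any(nf != 9)) {
      abort(sprintf("Coordinate row %d has %d fields (expected 9: z then x,y for SW, SE, NW, NE)",
                    which(nf != 9)[1], nf[which(nf != 9)[1]]))
    }
    rows <- do.call(rbind, parsed)
  } else {
    rows <- as.matrix(rows)
    if (ncol(rows) != 9) {
      abort(sprintf("Coordinate table has %d columns (expected 9)", ncol(rows)))
    }
    storage.mode(rows) <- "double"
  }
  if (anyNA(rows)) {
    abort(sprintf("Non-numeric field in coordinate row %d",
                  which(apply(rows, 1, anyNA))[1]))
  }
  if (any(rows[, 1] < 0)) {
    abort("Plant heights (column 1) must be >= 0.")
  }
  if (!is.null(plots) && nrow(plots) != nrow(rows)) {
    abort(sprintf("Plot-names file has %d rows but coordinates file has %d; they must match.",
                  nrow(plots), nrow(rows)))
  }
  corners <- c("SW", "SE", "NW", "NE")
  out <- tibble(
    plot_row = rep(seq_len(nrow(rows)), each = 4L),
    z = rep(rows[, 1], each = 4L),
    corner = rep(corners, nrow(rows)),
    x = as.vector(t(rows[, c(2, 4, 6, 8)])),
    y = as.vector(t(rows[, c(3, 5, 7, 9)]))
  )
  if (!is.null(plots)) {
    ids <- mutate(plots, plot_row = seq_len(nrow(plots)))
    out <- left_join(out, ids, by = "plot_row")
    out <- select(out, "plot_row", "name", "cultivar", "crop",
                  "planting_date", "rep", "serpentine_index",
                  "z", "corner", "x", "y")
  }
  out
}

#' Read a plot-coordinates file
#'
#' @param path Whitespace- or tab-delimited numeric text file, 9 columns.
#' @inheritParams parse_plot_coordinates
#' @return See [parse_plot_coordinates()].
#' @export
read_plot_coordinates <- function(path, plots = NULL) {
  if (!file.exists(path)) abort(sprintf("Plot-coordinates file not found: %s", path))
  parse_plot_coordinates(readLines(path, warn = FALSE), plots = plots)
}

#' Write plot coordinates back to the 9-column text format
#'
#' @param design Tibble from [parse_plot_coordinates()].
#' @param path Output file path.
#' @export
write_plot_coordinates <- function(design, path) {
  wide <- design_to_matrix(design)
  write.table(wide, path, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}

# long (plot_row, corner, x, y, z) -> 9-column matrix
design_to_matrix <- function(design) {
  rows <- sort(unique(design$plot_row))
  out <- matrix(NA_real_, length(rows), 9)
  for (i in seq_along(rows)) {
    d <- design[design$plot_row == rows[i], ]
    out[i, 1] <- d$z[1]
    for (j in seq_along(c("SW", "SE", "NW", "NE"))) {
      cr <- d[d$corner == c("SW", "SE", "NW", "NE")[j], ]
      out[i, 2 * j] <- cr$x
      out[i, 2 * j + 1] <- cr$y
    }
  }
  out
}

#' Parse a video filename
#'
#' Videos follow `FLYmm_dd_yy_pn.mp4`, with `n` the panel number.
#'
#' @param name Filename (with or without directory).
#' @return A tibble row: `month`, `day`, `year` (expanded to 2000 + yy),
#'   `panel`.
#' @export
#' @examples
#' parse_video_filename("FLY07_12_17_p2.mp4")
parse_video_filename <- function(name) {
  base <- basename(name)
  pat <- "^FLY([0-9]{2})_([0-9]{2})_([0-9]{2})_p([0-9]+)(\\.mp4)?$"
  m <- regexec(pat, base)
  g <- regmatches(base, m)[[1]]
  if (length(g) == 0) {
    abort(sprintf("Video name '%s' does not match FLYmm_dd_yy_pn.mp4", base))
  }
  month <- as.integer(g[2]); day <- as.integer(g[3])
  year <- 2000L + as.integer(g[4]); panel <- as.integer(g[5])
  if (month < 1 || month > 12 || day < 1 || day > 31 ||
      is.na(as.Date(sprintf("%04d-%02d-%02d", year, month, day),
                    format = "%Y-%m-%d"))) {
    abort(sprintf("Video name '%s' encodes an invalid calendar date", base))
  }
  tibble(month = month, day = day, year = year, panel = panel)
}
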