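#' Probe geometry: the 108-channel forehead DOT layout
#'
#' The continuous-wave DOT probe modelled here spans the forehead with 12
#' sources and 15 detectors forming 108 measurement channels at nominal
#' source-detector separations of 15, 30, 36 and 45 mm (40/20/32/16 channels
#' respectively). Channels are defined by a table carrying the channel
#' midpoint, in-plane axis and nominal separation; per-channel source and
#' detector positions are synthesized as midpoint +/- (separation/2) * axis.
#'
#' @name probe-geometry
NULL

.ALLOWED_SEPARATIONS <- c(15, 30, 36, 45)
.SEPARATION_TOL <- 2

#' Build the default channel table
#'
#' Deterministically generates the package's default probe fixture: 108
#' channels whose separation multiset is exactly \{15 mm x 40, 30 mm x 20,
#' 36 mm x 32, 45 mm x 16\}, with midpoints spread over a 120 mm x 40 mm
#' forehead patch (x = left(-)/right(+), y = inferior/superior, both mm) and
#' source/detector ids drawn from 12 sources and 15 detectors.
#'
#' @return A data.frame with columns `channel_id`, `source_id`,
#'   `detector_id`, `nominal_separation_mm`, `midpoint_x`, `midpoint_y`,
#'   `axis_x`, `axis_y`.
#' @export
default_probe_table <- function() {
  seps <- rep(.ALLOWED_SEPARATIONS, times = c(40, 20, 32, 16))
  n <- length(seps)
  idx <- seq_len(n) - 1L
  # midpoints on a 24 x 5 raster covering about [-57.5, 57.5] x [4, 36] mm
  mx <- (idx %% 24L) * 5 - 57.5
  my <- (idx %/% 24L) * 8 + 4
  # alternate channel axes between horizontal, vertical and diagonals
  ang <- (idx %% 4L) * (pi / 4)
  data.frame(
    channel_id = sprintf("C%03d", seq_len(n)),
    source_id = sprintf("S%02d", (idx %% 12L) + 1L),
    detector_id = sprintf("D%02d", (idx %% 15L) + 1L),
    nominal_separation_mm = seps,
    midpoint_x = mx,
    midpoint_y = my,
    axis_x = round(cos(ang), 10),
    axis_y = round(sin(ang), 10),
    stringsAsFactors = FALSE
  )
}

.PROBE_COLUMNS <- c(
  "channel_id", "source_id", "detector_id", "nominal_separation_mm",
  "midpoint_x", "midpoint_y", "axis_x", "axis_y"
)

#' Load a probe layout from a channel table
#'
#' Reads a tab-separated channel table (see [default_probe_table()] for the
#' column contract), validates it, and synthesizes per-channel source and
#' detector positions on the scalp plane z = 0.
#'
#' @param path Path to a TSV file with a header row, or a data.frame already
#'   in channel-table form.
#' @param wavelengths Operating wavelengths in nm.
#' @return An object of class `probe_layout`: list with `channels`
#'   (validated table plus synthesized `source_x/y/z`, `detector_x/y/z`),
#'   `optodes` (unique source/detector ids with roles), and `wavelengths`.
#' @export
load_probe <- function(path, wavelengths = c(760, 830)) {
  tab <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) stop("probe file not found: ", path)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (nrow(tab) == 0L) stop("probe format error: channel table is empty")
  missing_cols <- setdiff(.PROBE_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("probe format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$channel_id)) {
    stop("probe validation error: duplicate channel id(s): ",
         paste(unique(tab$channel_id[duplicated(tab$channel_id)]), collapse = ", "))
  }
  sep <- tab$nominal_separation_mm
  dev <- vapply(sep, function(s) min(abs(s - .ALLOWED_SEPARATIONS)), numeric(1))
  if (any(dev > .SEPARATION_TOL)) {
    bad <- tab$channel_id[dev > .SEPARATION_TOL]
    stop("probe geometry error: separation outside 15/30/36/45 mm (+/- 2 mm) for ",
         paste(bad, collapse = ", "))
  }
  axis_norm <- sqrt(tab$axis_x^2 + tab$axis_y^2)
  # geometric separation of synthesized optodes is nominal * |axis|
  if (any(abs(sep * axis_norm - sep) > .SEPARATION_TOL)) {
    bad <- tab$channel_id[abs(sep * axis_norm - sep) > .SEPARATION_TOL]
    stop("probe geometry error: geometric separation inconsistent with nominal for ",
         paste(bad, collapse = ", "))
  }
  ux <- tab$axis_x / axis_norm
  uy <- tab$axis_y / axis_norm
  tab$axis_x <- ux
  tab$axis_y <- uy
  tab$source_x <- tab$midpoint_x - sep / 2 * ux
  tab$source_y <- tab$midpoint_y - sep / 2 * uy
  tab$source_z <- 0
  tab$detector_x <- tab$midpoint_x + sep / 2 * ux
  tab$detector_y <- tab$midpoint_y + sep / 2 * uy
  tab$detector_z <- 0
  optodes <- rbind(
    data.frame(id = unique(tab$source_id), role = "source", stringsAsFactors = FALSE),
    data.frame(id = unique(tab$detector_id), role = "detector", stringsAsFactors = FALSE)
  )
  structure(
    list(channels = tab, optodes = optodes, wavelengths = sort(wavelengths)),
    class = "probe_layout"
  )
}

#' Write the default probe fixture to disk
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_default_probe <- function(path) {
  utils::write.table(default_probe_table(), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.probe_layout <- function(x, ...) {
  cat("<probe_layout> ", nrow(x$channels), " channels, ",
      sum(x$optodes$role == "source"), " sources, ",
      sum(x$optodes$role == "detector"), " detectors; wavelengths ",
      paste(x$wavelengths, collapse = "/"), " nm\n", sep = "")
  invisible(x)
}

#' Histogram of source-detector separations
#'
#' Counts channels per nominal separation. For the default fixture this is
#' 40/20/32/16 channels at 15/30/36/45 mm and the counts partition the 108
#' channels.
#'
#' @param layout A `probe_layout`.
#' @return Named integer vector, names = separation in mm, sorted ascending.
#' @export
separation_histogram <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  tab <- table(layout$channels$nominal_separation_mm)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(as.numeric(names(out)))]
}
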