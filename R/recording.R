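#' Multi-channel optical recordings
#'
#' Raw data are two-wavelength (760/830 nm) light-intensity time series per
#' channel, sampled at 5 Hz, with named tilt-event markers (`tilt_start`,
#' `tilt_70`, `tilt_down`) in seconds on the same clock as the time axis.
#'
#' @name optical-recording
NULL

#' Construct an optical recording
#'
#' @param intensities Numeric array channel x wavelength x time, arbitrary
#'   detector units, strictly positive.
#' @param sampling_rate Sampling frequency, Hz.
#' @param events Named numeric vector of event times (s); must include
#'   `tilt_start` and `tilt_down` for downstream phase segmentation and be
#'   strictly increasing in time.
#' @param time Optional time axis (s); defaults to starting 20 s before
#'   `tilt_start` so the conventional baseline is covered.
#' @param channel_ids Optional channel identifiers.
#' @param wavelengths Wavelengths (nm) along dim 2.
#' @return Object of class `optical_recording`.
#' @export
optical_recording <- function(intensities, sampling_rate = 5, events,
                              time = NULL, channel_ids = NULL,
                              wavelengths = c(760, 830)) {
  if (length(dim(intensities)) != 3L) {
    stop("intensities must be a channel x wavelength x time array")
  }
  if (dim(intensities)[2] != length(wavelengths)) {
    stop("wavelength dimension mismatch")
  }
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(names(events)) || any(names(events) == "")) {
    stop("event error: events must be named")
  }
  if (is.unsorted(events, strictly = TRUE)) {
    stop("event error: events must be strictly ordered in time")
  }
  nt <- dim(intensities)[3]
  if (is.null(time)) {
    t0 <- if ("tilt_start" %in% names(events)) events[["tilt_start"]] - 20 else 0
    time <- t0 + (seq_len(nt) - 1) / sampling_rate
  }
  if (length(time) != nt) stop("time axis length mismatch")
  if (is.null(channel_ids)) channel_ids <- sprintf("C%03d", seq_len(dim(intensities)[1]))
  dimnames(intensities) <- list(channel_ids, paste0("w", wavelengths), NULL)
  structure(
    list(intensities = intensities, sampling_rate = sampling_rate,
         events = events, time = time, channel_ids = channel_ids,
         wavelengths = wavelengths),
    class = "optical_recording"
  )
}

#' @export
print.optical_recording <- function(x, ...) {
  cat("<optical_recording> ", length(x$channel_ids), " channels x ",
      length(x$wavelengths), " wavelengths x ", length(x$time),
      " samples @ ", x$sampling_rate, " Hz; events: ",
      paste(sprintf("%s=%gs", names(x$events), x$events), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a recording to long-format CSV plus an events CSV
#'
#' @param rec An `optical_recording`.
#' @param path Intensity CSV path (columns time_s, channel, wavelength_nm,
#'   intensity); the events file is written next to it as
#'   `<path>.events.csv` unless `events_path` is given.
#' @param events_path Optional events CSV path (columns name, time_s).
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path, events_path = paste0(path, ".events.csv")) {
  stopifnot(inherits(rec, "optical_recording"))
  d <- dim(rec$intensities)
  df <- data.frame(
    time_s = rep(rec$time, each = d[1] * d[2]),
    channel = rep(rec$channel_ids, times = d[2] * d[3]),
    wavelength_nm = rep(rep(rec$wavelengths, each = d[1]), times = d[3]),
    intensity = as.vector(rec$intensities)
  )
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(data.frame(name = names(rec$events), time_s = unname(rec$events)),
                   events_path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from long-format CSV plus an events CSV
#'
#' @param path Intensity CSV as written by [write_recording_csv()].
#' @param events_path Events CSV path.
#' @param sampling_rate Sampling frequency (Hz); inferred from the time axis
#'   when NULL.
#' @return An `optical_recording`.
#' @export
read_recording_csv <- function(path, events_path = paste0(path, ".events.csv"),
                               sampling_rate = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "channel", "wavelength_nm", "intensity")
  if (!all(need %in% names(df))) {
    stop("recording format error: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  events <- stats::setNames(ev$time_s, ev$name)
  times <- sort(unique(df$time_s))
  channels <- unique(df$channel)
  wls <- sort(unique(df$wavelength_nm))
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(diff(times))
  arr <- array(NA_real_, dim = c(length(channels), length(wls), length(times)))
  ci <- match(df$channel, channels)
  wi <- match(df$wavelength_nm, wls)
  ti <- match(df$time_s, times)
  arr[cbind(ci, wi, ti)] <- df$intensity
  if (anyNA(arr)) stop("recording format error: incomplete channel/wavelength/time grid")
  optical_recording(arr, sampling_rate = sampling_rate, events = events,
                    time = times, channel_ids = channels, wavelengths = wls)
}
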