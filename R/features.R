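#' HUTT phases, rate-of-HbO-change features and pointwise statistics
#'
#' The tilt protocol has four contiguous phases: a 20-s supine baseline, a
#' dynamic tilt (supine to 70 degrees, nominally 15 s), a static tilt whose
#' duration varies between subjects, and a post-tilt return to supine. The
#' headline oxygenation feature is the slope of the gyrus-averaged HbO
#' change fitted over the 15-60 s window spanning the end of the dynamic
#' tilt and the early static tilt, reported in 1e-4 mM/DPF per minute.
#'
#' @name hutt-features
NULL

#' Time-unit convention for the reported rate of HbO change
#' (seconds of series time per reporting unit: 60 => per minute)
#' @export
RATE_TIME_UNIT_S <- 60

#' Segment the HUTT phases from event markers
#'
#' @param events Named numeric vector with `tilt_start` and `tilt_down`
#'   (seconds, tilt_start is time 0 of the relative axis).
#' @param t_static_offset Seconds after tilt onset at which the static
#'   phase begins (nominal dynamic-tilt duration).
#' @param t_end Optional end of the recording (s, relative); defaults to
#'   60 s after `tilt_down`.
#' @return Object of class `phase_schedule`: data.frame of phases with
#'   `start`/`end` (s relative to tilt onset), contiguous and increasing.
#' @export
segment_phases <- function(events, t_static_offset = 15, t_end = NULL) {
  if (!all(c("tilt_start", "tilt_down") %in% names(events))) {
    stop("event error: events must contain tilt_start and tilt_down")
  }
  t0 <- events[["tilt_start"]]
  tdown <- events[["tilt_down"]] - t0
  if (tdown <= t_static_offset) {
    stop("event error: tilt_down must come after static-phase onset")
  }
  if (is.null(t_end)) t_end <- tdown + 60
  ph <- data.frame(
    phase = c("baseline", "dynamic", "static", "post"),
    start = c(-20, 0, t_static_offset, tdown),
    end = c(0, t_static_offset, tdown, t_end)
  )
  structure(list(phases = ph, t_static = t_static_offset, t_down = tdown),
            class = "phase_schedule")
}

#' Rate of HbO change per gyrus
#'
#' Ordinary least-squares slope of the gyrus-averaged HbO change against
#' time over the fit window (default 15-60 s, dynamic-to-static tilt),
#' rescaled to the reporting convention (1e-4 mM/DPF per minute). The
#' global rate is the arithmetic mean of the six gyrus slopes.
#'
#' @param rs A `region_series` (time axis relative to tilt onset).
#' @param window Length-2 numeric fit window (s).
#' @return Object of class `rate_feature`: named numeric `rates` per region
#'   and scalar `global_rate`.
#' @export
rate_of_change <- function(rs, window = c(15, 60)) {
  stopifnot(inherits(rs, "region_series"))
  sel <- rs$time >= window[1] & rs$time <= window[2]
  if (sum(sel) < 3) stop("data error: fewer than 3 samples in fit window")
  tt <- rs$time[sel]
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  slopes <- as.vector(rs$hbo[, sel, drop = FALSE] %*% tc) / denom
  rates <- slopes * RATE_TIME_UNIT_S
  names(rates) <- rs$region_names
  structure(list(rates = rates, global_rate = mean(rates), window = window),
            class = "rate_feature")
}

#' Assign PD-NOR subjects to the POS/NEG subgroup
#'
#' Subjects with normal tilt-test results (`PD-NOR`) are split by the sign
#' of their global rate of HbO change: positive -> `PD-POS`, negative ->
#' `PD-NEG` (an exactly zero rate, a measure-zero event, goes to `PD-POS`).
#' Any other label passes through unchanged.
#'
#' @param feature A `rate_feature` (or the numeric global rate).
#' @param label Group label.
#' @return Character label.
#' @export
assign_subgroup <- function(feature, label) {
  if (label != "PD-NOR") return(label)
  g <- if (inherits(feature, "rate_feature")) feature$global_rate else feature
  if (g >= 0) "PD-POS" else "PD-NEG"
}

# vectorized Welch t over time samples; a/b are subject x time matrices.
# Degenerate rule: zero variance in both groups at a time point -> p = 1.
.welch_rows <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)), 1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
  list(mean_a = ma, mean_b = mb, t = tstat, p = p)
}

# paired t over time samples; d is subject x time matrix of differences
.paired_rows <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- apply(d, 2, stats::var)
  tstat <- ifelse(v > 0, m / sqrt(v / n), 0)
  p <- ifelse(v > 0, 2 * stats::pt(-abs(tstat), n - 1), 1)
  list(mean_d = m, t = tstat, p = p)
}

#' Pointwise two-tailed group comparison of HbO trajectories
#'
#' Welch's unequal-variance two-sample t-test at every time sample of every
#' region, flagging samples with p < `alpha`. No multiplicity correction is
#' applied: the flags correspond to the per-timepoint significance bars of
#' a group-comparison trajectory plot.
#'
#' @param group_a,group_b Lists of `region_series` on a common time grid
#'   (at least 2 subjects each).
#' @param alpha Significance level.
#' @return Object of class `timepoint_stats`: data.frame with region,
#'   time_s, group means, t, p, significant.
#' @export
pointwise_ttest <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("at least 2 subjects per group are required")
  }
  time <- group_a[[1]]$time
  regions <- group_a[[1]]$region_names
  out <- vector("list", length(regions))
  for (r in seq_along(regions)) {
    a <- t(vapply(group_a, function(s) s$hbo[r, ], numeric(length(time))))
    b <- t(vapply(group_b, function(s) s$hbo[r, ], numeric(length(time))))
    w <- .welch_rows(a, b)
    out[[r]] <- data.frame(
      region = regions[r], time_s = time, mean_a = w$mean_a,
      mean_b = w$mean_b, t = w$t, p = w$p, significant = w$p < alpha
    )
  }
  structure(list(stats = do.call(rbind, out), alpha = alpha,
                 comparison = "group"),
            class = "timepoint_stats")
}

#' Pointwise left-right laterality test
#'
#' Paired two-tailed t-test of the within-subject left-minus-right HbO
#' difference for each gyrus pair at every time sample.
#'
#' @param group List of `region_series` (>= 2 subjects, both hemispheres).
#' @param alpha Significance level.
#' @return A `timepoint_stats` whose `region` column names the gyrus pair
#'   (`SFG`, `MFG`, `MedFG`).
#' @export
laterality_ttest <- function(group, alpha = 0.05) {
  if (length(group) < 2) stop("at least 2 subjects are required")
  time <- group[[1]]$time
  regions <- group[[1]]$region_names
  pairs <- list(SFG = c("L-SFG", "R-SFG"), MFG = c("L-MFG", "R-MFG"),
                MedFG = c("L-MedFG", "R-MedFG"))
  out <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    li <- match(pairs[[k]][1], regions)
    ri <- match(pairs[[k]][2], regions)
    if (is.na(li) || is.na(ri)) stop("both hemispheres must be present")
    d <- t(vapply(group, function(s) s$hbo[li, ] - s$hbo[ri, ],
                  numeric(length(time))))
    w <- .paired_rows(d)
    out[[k]] <- data.frame(
      region = names(pairs)[k], time_s = time, mean_diff = w$mean_d,
      t = w$t, p = w$p, significant = w$p < alpha
    )
  }
  structure(list(stats = do.call(rbind, out), alpha = alpha,
                 comparison = "laterality"),
            class = "timepoint_stats")
}

#' Fraction of significant time points per region within a time window
#' @param ts A `timepoint_stats`.
#' @param window Length-2 time window (s), default the whole series.
#' @return Named numeric vector of flag fractions per region.
#' @export
significant_fraction <- function(ts, window = NULL) {
  st <- ts$stats
  if (!is.null(window)) st <- st[st$time_s >= window[1] & st$time_s < window[2], ]
  vapply(split(st$significant, st$region), mean, numeric(1))
}

#' Export pointwise statistics as tidy CSV
#' @param ts A `timepoint_stats`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(ts, path) {
  df <- cbind(comparison = ts$comparison, ts$stats)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
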