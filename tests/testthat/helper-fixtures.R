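# shared fixtures, built in code at test time

default_layout <- function() load_probe(default_probe_table())

small_grid_setup <- function() {
  grid <- voxel_grid()
  atlas <- build_region_atlas(grid)
  list(grid = grid, atlas = atlas)
}

# cached sensitivity matrix for the default layout/grid (built once per run)
.sens_cache <- new.env(parent = emptyenv())
default_sensitivity <- function() {
  if (is.null(.sens_cache$sens)) {
    .sens_cache$sens <- build_sensitivity(default_layout(), voxel_grid())
  }
  .sens_cache$sens
}

# a tiny recording with constant intensities and standard events
constant_recording <- function(n_channels = 4, nt = 300, level = 100, fs = 5) {
  arr <- array(level, dim = c(n_channels, 2, nt))
  optical_recording(arr, sampling_rate = fs,
                    events = c(tilt_start = 20, tilt_70 = 35, tilt_down = 50),
                    time = (seq_len(nt) - 1) / fs)
}

# region series with an exact linear HbO segment over the fit window
linear_region_series <- function(intercept = 0, slope_per_s = 0.01,
                                 fs = 5, t_end = 120) {
  time <- seq(-20, t_end, by = 1 / fs)
  hbo <- matrix(rep(intercept + slope_per_s * time, each = 6), nrow = 6)
  region_series(hbo, -0.3 * hbo, time,
                events = c(tilt_start = 0, tilt_70 = 15, tilt_down = 100),
                sampling_rate = fs)
}

# list of region series on a common grid from a cohort subset
cohort_series <- function(cohort, templates) {
  labs <- vapply(cohort$subjects, `[[`, character(1), "template")
  series <- lapply(cohort$subjects[labs %in% templates], `[[`, "regions")
  tmax <- min(vapply(series, function(s) max(s$time), numeric(1)))
  lapply(series, function(s) {
    k <- s$time <= tmax
    region_series(s$hbo[, k, drop = FALSE], s$hb[, k, drop = FALSE],
                  s$time[k], s$events, s$sampling_rate, s$region_names)
  })
}
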