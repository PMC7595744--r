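#' Synthetic HUTT cohort generator
#'
#' Generates cohorts with the statistical structure of the study
#' population: group-specific gyrus-level HbO trajectories (healthy
#' controls and PD-POS dip during the dynamic tilt then recover; PD-OH and
#' PD-NEG rise then decline without recovery, with a right-hemisphere
#' deficit), rate-of-HbO-change distributions and clinical covariates
#' calibrated to the published group summaries, physiological oscillations,
#' drift, and optional motion spikes. `region_direct` mode emits
#' gyrus-level series directly (the fast path); `full_optical` mode
#' forward-projects voxel images through the sensitivity matrix to produce
#' channel-level optical recordings for end-to-end pipeline tests.
#'
#' @name synthetic-cohort
NULL

#' Group calibration templates
#'
#' Per-group mean and sd of the global rate of HbO change
#' (1e-4 mM/DPF per minute), the dynamic-tilt transient sign, the
#' right-hemisphere deficit multiplier, and the clinical covariate
#' distributions, following the published cohort summaries. The deficit
#' multiplier reallocates the rate mean between hemispheres
#' (left = 2m/(1+k), right = 2mk/(1+k)) so the group mean global rate is
#' preserved.
#'
#' @return Named list of group templates.
#' @export
group_templates <- function() {
  list(
    "HC" = list(
      rate_mean = 7, rate_sd = 8.1, transient_sign = -1, right_deficit = 1,
      age = c(68.1, 4.5), male_p = 0.429, hypertension_p = 0,
      hy_stage = NULL, updrs3 = NULL, compass = NULL, cass = NULL,
      mmse = NULL, moca = NULL
    ),
    "PD-OH" = list(
      rate_mean = -5.6, rate_sd = 6.7, transient_sign = 1, right_deficit = 1.3,
      age = c(71.9, 9.1), male_p = 0.50, hypertension_p = 0.40,
      hy_stage = c(2.3, 0.5), updrs3 = c(28.5, 11.9), compass = c(31.7, 21.5),
      cass = c(4.6, 1.9), mmse = c(25.1, 5.1), moca = c(20.6, 6.7)
    ),
    "PD-POS" = list(
      rate_mean = 8.5, rate_sd = 6.3, transient_sign = -1, right_deficit = 1,
      age = c(70.1, 6.2), male_p = 0.765, hypertension_p = 0.588,
      hy_stage = c(2.2, 0.9), updrs3 = c(23.1, 9.8), compass = c(11.6, 6.6),
      cass = c(3.6, 1.6), mmse = c(26.3, 3.3), moca = c(22.8, 4.6)
    ),
    "PD-NEG" = list(
      rate_mean = -9.9, rate_sd = 9.9, transient_sign = 1, right_deficit = 1.3,
      age = c(65.7, 12.7), male_p = 0.583, hypertension_p = 0.333,
      hy_stage = c(1.9, 0.9), updrs3 = c(24.1, 17.2), compass = c(29, 26.3),
      cass = c(2.4, 1.9), mmse = c(25.5, 5.7), moca = c(21.6, 8.9)
    )
  )
}

# prevalence of the motor/non-motor symptom flags in PD groups (stand-ins;
# the published table reports no group-wise values for these)
.MOTOR_P <- 0.4
.NONMOTOR_P <- 0.6

#' Cohort specification
#'
#' @param sizes Named group sizes; defaults to the analyzed cohort (7 HC,
#'   10 PD-OH, 17 PD-POS, 12 PD-NEG).
#' @param seed Integer seed fixing all randomness.
#' @param mode `"region_direct"` (gyrus series, fast) or `"full_optical"`
#'   (channel-level recordings through the forward model).
#' @param replicates Replicate-cohort count for replicate protocols.
#' @param rho Inter-region correlation of the six gyrus rates.
#' @param noise A noise specification from [noise_spec()].
#' @param timing List: baseline_s, dynamic_s, static_s, static_jitter_s,
#'   post_s, fs.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(sizes = c("HC" = 7, "PD-OH" = 10, "PD-POS" = 17,
                                  "PD-NEG" = 12),
                        seed = 1, mode = c("region_direct", "full_optical"),
                        replicates = 1, rho = 0.8, noise = noise_spec(),
                        timing = list(baseline_s = 20, dynamic_s = 15,
                                      static_s = 180, static_jitter_s = 30,
                                      post_s = 60, fs = 5)) {
  mode <- match.arg(mode)
  if (any(sizes < 0)) stop("group sizes must be >= 0")
  if (!all(names(sizes) %in% names(group_templates()))) {
    stop("label error: unknown group(s) ",
         paste(setdiff(names(sizes), names(group_templates())), collapse = ", "))
  }
  structure(
    list(sizes = sizes, seed = seed, mode = mode, replicates = replicates,
         rho = rho, noise = noise, timing = timing),
    class = "cohort_spec"
  )
}

#' Physiological and instrumental noise specification
#'
#' Sinusoidal physiological oscillations (cardiac ~1.1 Hz, respiratory
#' ~0.25 Hz, Mayer waves ~0.1 Hz) with random phases, white measurement
#' noise, random-walk drift, and Poisson motion spikes. Amplitudes are in
#' the region-series unit (1e-4 mM/DPF) except the channel-level spike
#' amplitude, which applies to optical density.
#'
#' @param cardiac_amp,resp_amp,mayer_amp Sinusoid amplitudes.
#' @param white_sd White-noise standard deviation.
#' @param drift_sd Random-walk step standard deviation (per sample).
#' @param spike_rate Motion-spike rate (per second, channel mode only).
#' @param spike_amp Spike amplitude (OD units, channel mode only).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(cardiac_amp = 0.1, resp_amp = 0.2, mayer_amp = 0.3,
                       white_sd = 0.3, drift_sd = 0.02,
                       spike_rate = 0.02, spike_amp = 0.05) {
  vals <- c(cardiac_amp, resp_amp, mayer_amp, white_sd, drift_sd,
            spike_rate, spike_amp)
  if (any(vals < 0)) stop("noise parameters must be nonnegative")
  structure(
    list(cardiac_amp = cardiac_amp, resp_amp = resp_amp,
         mayer_amp = mayer_amp, white_sd = white_sd, drift_sd = drift_sd,
         spike_rate = spike_rate, spike_amp = spike_amp),
    class = "noise_spec"
  )
}

#' Zero-noise specification (for exact-recovery tests)
#' @return A `noise_spec` with all components zero.
#' @export
zero_noise <- function() {
  noise_spec(0, 0, 0, 0, 0, 0, 0)
}

#' Sample clinical covariates for one or more subjects
#'
#' Continuous covariates are drawn from normal distributions with the
#' published group means and sds, truncated to their valid ranges
#' (H&Y in [1,5], MMSE/MoCA in [0,30], UPDRS-III in [0,108], COMPASS in
#' [0,100], CASS in [0,10]) by redrawing; binary covariates are Bernoulli
#' with the published proportions. Healthy controls get demographics only
#' (PD-severity fields are NA).
#'
#' @param group Group label.
#' @param n Number of subjects.
#' @return data.frame of covariates.
#' @export
sample_clinical <- function(group, n = 1) {
  tpl <- group_templates()[[group]]
  if (is.null(tpl)) stop("label error: unknown group ", group)
  rtrunc <- function(n, ms, lo, hi) {
    if (is.null(ms)) return(rep(NA_real_, n))
    x <- stats::rnorm(n, ms[1], ms[2])
    bad <- x < lo | x > hi
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), ms[1], ms[2])
      bad <- x < lo | x > hi
    }
    x
  }
  is_pd <- group != "HC"
  data.frame(
    age = rtrunc(n, tpl$age, 18, 100),
    sex = stats::rbinom(n, 1, tpl$male_p),
    hypertension = stats::rbinom(n, 1, tpl$hypertension_p),
    hy_stage = rtrunc(n, tpl$hy_stage, 1, 5),
    updrs3 = rtrunc(n, tpl$updrs3, 0, 108),
    compass = rtrunc(n, tpl$compass, 0, 100),
    cass = rtrunc(n, tpl$cass, 0, 10),
    mmse = rtrunc(n, tpl$mmse, 0, 30),
    moca = rtrunc(n, tpl$moca, 0, 30),
    motor_symptom = if (is_pd) stats::rbinom(n, 1, .MOTOR_P) else rep(NA_real_, n),
    nonmotor_symptom = if (is_pd) stats::rbinom(n, 1, .NONMOTOR_P) else rep(NA_real_, n)
  )
}

# per-region rate means for a group: hemisphere reallocation preserving the
# group mean (left = 2m/(1+k), right = 2mk/(1+k), k = right_deficit)
.region_rate_means <- function(tpl) {
  m <- tpl$rate_mean
  k <- tpl$right_deficit
  left <- 2 * m / (1 + k)
  right <- 2 * m * k / (1 + k)
  stats::setNames(ifelse(grepl("^L", REGION_NAMES), left, right), REGION_NAMES)
}

# draw n x 6 matrix of region rates: equicorrelated multivariate normal
.draw_region_rates <- function(n, tpl, rho) {
  mu <- .region_rate_means(tpl)
  p <- length(mu)
  Sigma <- tpl$rate_sd^2 * ((1 - rho) * diag(p) + rho)
  r <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
  if (n == 1) r <- matrix(r, 1)
  colnames(r) <- REGION_NAMES
  r
}

#' Build one true gyrus HbO trajectory
#'
#' Piecewise path on the relative time axis: zero over the baseline; a
#' smooth monotone transient of the group's sign over the dynamic tilt
#' reaching `transient_amp` at the static-tilt onset; a linear segment over
#' the rate fit window (15-60 s) with the supplied slope; a plateau for the
#' rest of the static tilt; an exponential return toward baseline after
#' tilt-down. The realized slope over the fit window equals `rate` exactly.
#'
#' @param time Time axis (s, 0 = tilt onset).
#' @param rate Slope over the fit window, 1e-4 mM/DPF per minute.
#' @param transient_sign -1 (dip) or +1 (rise) during dynamic tilt.
#' @param t_down Tilt-down time (s).
#' @param transient_amp Dynamic-tilt transient amplitude (1e-4 mM/DPF).
#' @param t_static Static-tilt onset (s).
#' @param fit_end End of the linear-rate segment (s).
#' @param post_tau Post-tilt recovery time constant (s).
#' @return Numeric trajectory, same length as `time`.
#' @export
build_trajectory <- function(time, rate, transient_sign, t_down,
                             transient_amp = 2, t_static = 15,
                             fit_end = 60, post_tau = 20) {
  slope_s <- rate / RATE_TIME_UNIT_S  # per second
  v <- numeric(length(time))
  v15 <- transient_sign * transient_amp
  dyn <- time > 0 & time < t_static
  v[dyn] <- v15 * sin(pi / 2 * time[dyn] / t_static)
  lin <- time >= t_static & time <= fit_end
  v[lin] <- v15 + slope_s * (time[lin] - t_static)
  v_fit_end <- v15 + slope_s * (fit_end - t_static)
  plateau <- time > fit_end & time < t_down
  v[plateau] <- v_fit_end
  post <- time >= t_down
  v[post] <- v_fit_end * exp(-(time[post] - t_down) / post_tau)
  v
}

# additive region-level noise for one series
.region_noise <- function(time, fs, noise) {
  n <- length(time)
  out <- numeric(n)
  for (comp in list(c(1.1, noise$cardiac_amp), c(0.25, noise$resp_amp),
                    c(0.1, noise$mayer_amp))) {
    if (comp[2] > 0) {
      out <- out + comp[2] * sin(2 * pi * comp[1] * time + stats::runif(1, 0, 2 * pi))
    }
  }
  if (noise$white_sd > 0) out <- out + stats::rnorm(n, 0, noise$white_sd)
  if (noise$drift_sd > 0) out <- out + cumsum(stats::rnorm(n, 0, noise$drift_sd))
  out
}

# simulate one subject's true region series (+ truth record)
.simulate_subject_regions <- function(id, group, spec) {
  tm <- spec$timing
  jitter <- if (tm$static_jitter_s > 0) {
    stats::runif(1, -tm$static_jitter_s, tm$static_jitter_s)
  } else 0
  t_down <- tm$dynamic_s + tm$static_s + jitter
  time <- seq(-tm$baseline_s, t_down + tm$post_s, by = 1 / tm$fs)
  events <- c(tilt_start = 0, tilt_70 = tm$dynamic_s, tilt_down = t_down)
  tpl <- group_templates()[[group]]
  rates <- .draw_region_rates(1, tpl, spec$rho)[1, ]
  hbo <- matrix(0, length(REGION_NAMES), length(time))
  for (r in seq_along(REGION_NAMES)) {
    hbo[r, ] <- build_trajectory(time, rates[r], tpl$transient_sign, t_down) +
      .region_noise(time, tm$fs, spec$noise)
  }
  hb <- -0.3 * hbo
  if (spec$noise$white_sd > 0) {
    hb <- hb + matrix(stats::rnorm(length(hb), 0, spec$noise$white_sd / 3),
                      nrow(hb))
  }
  rs <- region_series(hbo, hb, time, events, sampling_rate = tm$fs)
  clin <- sample_clinical(group, 1)
  list(id = id, template = group, regions = rs, true_rates = rates,
       true_global_rate = mean(rates), clinical = clin, events = events)
}

#' Generate a synthetic cohort
#'
#' Draws subjects per group (defaults: 7 HC, 10 PD-OH, 17 PD-POS, 12
#' PD-NEG), reproducibly from the spec's seed. Subjects from the PD-POS and
#' PD-NEG templates are (re)labelled by the sign rule applied to their true
#' global rate, so a cohort's realized labels can differ from its
#' templates, exactly as subgrouping does on real data. In `full_optical`
#' mode each subject also carries an `optical_recording` produced by
#' [project_to_channels()].
#'
#' @param spec A `cohort_spec`.
#' @param sens Optional `sensitivity_matrix` with an `atlas` attached
#'   (required for `full_optical` mode).
#' @param atlas Optional `region_atlas` (full_optical mode).
#' @return Object of class `synthetic_cohort`: list of subjects, each with
#'   `id`, `template`, `label`, `regions`, `true_rates`,
#'   `true_global_rate`, `clinical`, and optionally `recording`.
#' @export
generate_cohort <- function(spec, sens = NULL, atlas = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  subjects <- list()
  i <- 0L
  for (g in names(spec$sizes)) {
    for (k in seq_len(spec$sizes[[g]])) {
      i <- i + 1L
      s <- .simulate_subject_regions(sprintf("S%03d", i), g, spec)
      s$label <- if (g %in% c("PD-POS", "PD-NEG")) {
        assign_subgroup(s$true_global_rate, "PD-NOR")
      } else {
        g
      }
      if (spec$mode == "full_optical") {
        if (is.null(sens) || is.null(atlas)) {
          stop("full_optical mode requires a sensitivity matrix and atlas")
        }
        s$recording <- project_to_channels(s, sens, atlas, spec$noise)
      }
      subjects[[i]] <- s
    }
  }
  structure(list(subjects = subjects, spec = spec), class = "synthetic_cohort")
}

#' Forward-project a subject's region trajectories to channel intensities
#'
#' Paints the true gyrus trajectories into the labelled voxels of the
#' atlas, composes per-wavelength absorption perturbations through the
#' extinction coefficients, applies the sensitivity matrix to obtain
#' channel optical-density changes, adds channel-level noise (physiological
#' sinusoids, white noise, drift, Poisson motion spikes), and exponentiates
#' around a reference intensity to produce positive raw intensities.
#'
#' @param subject A subject entry from [generate_cohort()].
#' @param sens A `sensitivity_matrix`.
#' @param atlas A `region_atlas` on the sensitivity grid.
#' @param noise A `noise_spec`.
#' @param ext Extinction table.
#' @param ref_intensity Reference intensity level (detector units).
#' @return An `optical_recording`.
#' @export
project_to_channels <- function(subject, sens, atlas, noise = noise_spec(),
                                ext = extinction_table(),
                                ref_intensity = 1000) {
  if (!identical(sens$grid$shape, atlas$grid$shape)) {
    stop("shape error: sensitivity grid does not match atlas grid")
  }
  rs <- subject$regions
  nt <- length(rs$time)
  nvox <- sens$grid$n_voxels
  hbo_vox <- matrix(0, nvox, nt)
  hb_vox <- matrix(0, nvox, nt)
  for (r in seq_along(rs$region_names)) {
    vox <- atlas$labels == r
    hbo_vox[vox, ] <- matrix(rs$hbo[r, ] * 1e-4, sum(vox), nt, byrow = TRUE)
    hb_vox[vox, ] <- matrix(rs$hb[r, ] * 1e-4, sum(vox), nt, byrow = TRUE)
  }
  dmua <- .compose_dmua(hbo_vox, hb_vox, sens$wavelengths, ext)
  nchan <- length(sens$channel_ids)
  fs <- rs$sampling_rate
  # absolute clock starting at 0 with tilt_start at baseline_s
  t_abs <- rs$time - rs$time[1]
  events <- rs$events - rs$time[1]
  arr <- array(0, dim = c(nchan, length(sens$wavelengths), nt))
  for (k in seq_along(sens$wavelengths)) {
    y <- sens$A[[k]] %*% dmua[[k]]
    for (c in seq_len(nchan)) {
      ch_noise <- numeric(nt)
      for (comp in list(c(1.1, noise$cardiac_amp), c(0.25, noise$resp_amp),
                        c(0.1, noise$mayer_amp))) {
        if (comp[2] > 0) {
          ch_noise <- ch_noise + comp[2] * 1e-3 *
            sin(2 * pi * comp[1] * t_abs + stats::runif(1, 0, 2 * pi))
        }
      }
      if (noise$white_sd > 0) {
        ch_noise <- ch_noise + stats::rnorm(nt, 0, noise$white_sd * 1e-3)
      }
      if (noise$drift_sd > 0) {
        ch_noise <- ch_noise + cumsum(stats::rnorm(nt, 0, noise$drift_sd * 1e-3))
      }
      if (noise$spike_rate > 0) {
        n_spikes <- stats::rpois(1, noise$spike_rate * nt / fs)
        if (n_spikes > 0) {
          at <- sample.int(nt, min(n_spikes, nt))
          width <- max(1L, round(fs / 2))
          for (a in at) {
            idx <- a:min(nt, a + width - 1L)
            ch_noise[idx] <- ch_noise[idx] + noise$spike_amp *
              sample(c(-1, 1), 1) * exp(-(seq_along(idx) - 1) / (width / 3))
          }
        }
      }
      arr[c, k, ] <- ref_intensity * 10^(-(y[c, ] + ch_noise))
    }
  }
  optical_recording(arr, sampling_rate = fs, events = events, time = t_abs,
                    channel_ids = sens$channel_ids,
                    wavelengths = sens$wavelengths)
}

#' Extract the feature table from a simulated cohort
#'
#' Runs the rate-of-change extractor on every subject's region series and
#' binds the clinical covariates and labels.
#'
#' @param cohort A `synthetic_cohort`.
#' @param window Rate fit window (s).
#' @return Feature table data.frame (one row per subject).
#' @export
cohort_feature_table <- function(cohort, window = c(15, 60)) {
  rows <- lapply(cohort$subjects, function(s) {
    rf <- rate_of_change(s$regions, window)
    rates <- as.list(rf$rates)
    names(rates) <- paste0("rate_", gsub("-", "_", names(rf$rates)))
    cbind(
      data.frame(subject = s$id, label = s$label, template = s$template,
                 stringsAsFactors = FALSE),
      as.data.frame(rates),
      data.frame(global_rate = rf$global_rate),
      s$clinical
    )
  })
  do.call(rbind, rows)
}

#' Directly sample a feature table (no time series)
#'
#' The fast calibration path: the six gyrus rates are drawn per subject
#' from the group's equicorrelated multivariate normal (published mean and
#' sd, inter-region correlation `rho`), clinical covariates are sampled
#' from their group distributions, and PD-POS/PD-NEG template subjects are
#' relabelled by the sign rule applied to the global rate (mean of the six
#' region rates).
#'
#' @param spec A `cohort_spec` (only sizes, seed and rho are used).
#' @return Feature table data.frame.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  tpls <- group_templates()
  rows <- list()
  i <- 0L
  for (g in names(spec$sizes)) {
    n <- spec$sizes[[g]]
    if (n == 0) next
    rates <- .draw_region_rates(n, tpls[[g]], spec$rho)
    clin <- sample_clinical(g, n)
    global <- rowMeans(rates)
    label <- if (g %in% c("PD-POS", "PD-NEG")) {
      vapply(global, assign_subgroup, character(1), label = "PD-NOR")
    } else {
      rep(g, n)
    }
    df <- data.frame(subject = sprintf("S%03d", i + seq_len(n)),
                     label = label, template = g, stringsAsFactors = FALSE)
    rate_df <- as.data.frame(rates)
    names(rate_df) <- paste0("rate_", gsub("-", "_", colnames(rates)))
    rows[[length(rows) + 1L]] <- cbind(df, rate_df,
                                       data.frame(global_rate = global), clin)
    i <- i + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort manifest as JSON
#' @param cohort A `synthetic_cohort`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  manifest <- list(
    seed = cohort$spec$seed,
    mode = cohort$spec$mode,
    sizes = as.list(cohort$spec$sizes),
    subjects = lapply(cohort$subjects, function(s) {
      list(id = s$id, template = s$template, label = s$label,
           true_global_rate = s$true_global_rate,
           tilt_down_s = unname(s$events[["tilt_down"]]))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
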