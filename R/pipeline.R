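#' Pipeline orchestration
#'
#' One validated configuration drives the whole chain: simulate ->
#' (preprocess -> reconstruct, in full_optical mode) -> features -> stats
#' -> classify -> report. Identical config and seed give identical numeric
#' outputs; every output file is listed in a manifest with its checksum.
#'
#' @name pipeline
NULL

#' Default run configuration
#'
#' Every tunable of the pipeline with its default. Override via
#' [run_config()]; unknown keys are rejected.
#'
#' @return Nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    mode = "region_direct",
    cohort = list(
      sizes = list("HC" = 7, "PD-OH" = 10, "PD-POS" = 17, "PD-NEG" = 12),
      rho = 0.8,
      replicates = 1
    ),
    preprocessing = list(
      cutoff_hz = 0.2, window = 5, wavelet = "db5", alpha = 1.5, dpf = 1,
      min_intensity = 0.01, max_intensity = 1e6, extinction_file = NULL
    ),
    reconstruction = list(
      grid_shape = c(24, 12, 8), grid_spacing = 5,
      mua_760 = 0.017, mua_830 = 0.019, musp = 1.0,
      lambda_reg = 0.01, beta = 0.1
    ),
    features = list(fit_window = c(15, 60)),
    classifier = list(n_trees = 1000, m_try = NULL, replicates = 1,
                      importance = TRUE)
  )
}

# recursively overlay user values on defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- paste0(path, key)
    if (!key %in% names(defaults)) {
      stop("config error: unknown key '", full, "'")
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- .merge_config(defaults[[key]], as.list(user[[key]]),
                                       paste0(full, "$"))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Build and validate a run configuration
#'
#' @param config Named list of overrides, or a path to a JSON file of
#'   overrides.
#' @return Validated config list (class `run_config`).
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- .merge_config(default_run_config(), config)
  if (!cfg$mode %in% c("region_direct", "full_optical")) {
    stop("config error: mode must be region_direct or full_optical")
  }
  structure(cfg, class = "run_config")
}

#' Run the pipeline end to end
#'
#' Executes simulate -> (preprocess -> reconstruct in full_optical mode) ->
#' features -> stats -> classify and writes CSV/JSON outputs plus a
#' provenance manifest under `out_dir`.
#'
#' @param config A `run_config`, override list, or JSON path.
#' @param out_dir Output directory (created if needed); NULL to skip
#'   writing files.
#' @return Object of class `run_report`: `feature_table`, `trial_results`,
#'   `group_stats`, `laterality`, `files` (manifest with checksums),
#'   `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  sizes <- unlist(cfg$cohort$sizes)
  spec <- cohort_spec(sizes = sizes, seed = cfg$seed, mode = cfg$mode,
                      rho = cfg$cohort$rho,
                      replicates = cfg$cohort$replicates)

  if (cfg$mode == "full_optical") {
    layout <- load_probe(default_probe_table())
    grid <- voxel_grid(cfg$reconstruction$grid_shape,
                       cfg$reconstruction$grid_spacing)
    atlas <- build_region_atlas(grid)
    props <- optical_properties(
      mua = c(w760 = cfg$reconstruction$mua_760,
              w830 = cfg$reconstruction$mua_830),
      musp = cfg$reconstruction$musp)
    sens <- build_sensitivity(layout, grid, props)
    ext <- extinction_table(cfg$preprocessing$extinction_file)
    cohort <- generate_cohort(spec, sens = sens, atlas = atlas)
    # re-derive each subject's region series through the measurement chain
    for (i in seq_along(cohort$subjects)) {
      od <- intensity_to_od(cohort$subjects[[i]]$recording)
      od <- lowpass(od, cutoff = cfg$preprocessing$cutoff_hz)
      od <- moving_average(od, window = cfg$preprocessing$window)
      od <- wavelet_despike(od, alpha = cfg$preprocessing$alpha)
      imgs <- invert_dot(sens, od, lambda_reg = cfg$reconstruction$lambda_reg,
                         beta = cfg$reconstruction$beta)
      rs <- region_average(unmix_images(imgs, ext), atlas)
      cohort$subjects[[i]]$regions <- baseline_correct(rs)
    }
  } else {
    cohort <- generate_cohort(spec)
  }

  features <- cohort_feature_table(cohort, window = cfg$features$fit_window)

  by_label <- split(seq_along(cohort$subjects),
                    vapply(cohort$subjects, `[[`, character(1), "label"))
  series_of <- function(idx) lapply(cohort$subjects[idx], `[[`, "regions")
  group_stats <- NULL
  if (all(c("HC", "PD-OH") %in% names(by_label)) &&
      min(lengths(by_label[c("HC", "PD-OH")])) >= 2) {
    both <- .common_grid(series_of(c(by_label[["HC"]], by_label[["PD-OH"]])))
    n_hc <- length(by_label[["HC"]])
    group_stats <- pointwise_ttest(both[seq_len(n_hc)], both[-seq_len(n_hc)])
  }
  laterality <- lapply(by_label, function(idx) {
    if (length(idx) < 2) return(NULL)
    laterality_ttest(.common_grid(series_of(idx)))
  })

  trial_results <- run_trials(features, n_trees = cfg$classifier$n_trees,
                              seed = cfg$seed,
                              importance = cfg$classifier$importance)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "features.csv")
    write_feature_table(features, f1)
    f2 <- file.path(out_dir, "trial_results.json")
    write_trial_results_json(trial_results, f2)
    f3 <- file.path(out_dir, "cohort_manifest.json")
    write_cohort_manifest(cohort, f3)
    files <- c(f1, f2, f3)
    if (!is.null(group_stats)) {
      f4 <- file.path(out_dir, "group_stats.csv")
      write_stats_csv(group_stats, f4)
      files <- c(files, f4)
    }
  }
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  structure(
    list(feature_table = features, trial_results = trial_results,
         group_stats = group_stats, laterality = laterality,
         files = manifest, config = cfg, cohort = cohort),
    class = "run_report"
  )
}

# truncate a list of region series to a shared time grid (subjects differ
# in static duration; statistics need a common axis)
.common_grid <- function(series) {
  tmax <- min(vapply(series, function(s) max(s$time), numeric(1)))
  lapply(series, function(s) {
    keep <- s$time <= tmax
    region_series(s$hbo[, keep, drop = FALSE], s$hb[, keep, drop = FALSE],
                  s$time[keep], s$events, s$sampling_rate, s$region_names)
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", nrow(x$feature_table), " subjects; trials:\n", sep = "")
  for (r in x$trial_results) print(r)
  invisible(x)
}

#' Render the standard report figures
#'
#' Writes one file per available figure analogue: gyrus HbO trajectories
#' with significance bars, OOB accuracy bars, feature-importance bars, and
#' per-group rate box plots. Content is deterministic given the inputs;
#' missing results are skipped with a warning.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory for plot files.
#' @param device Plot file extension (`"pdf"` or `"png"`).
#' @return Character vector of written files, invisibly.
#' @export
report_figures <- function(report, out_dir, device = "pdf") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  save_plot <- function(p, name) {
    f <- file.path(out_dir, paste0(name, ".", device))
    ggplot2::ggsave(f, p, width = 8, height = 5)
    written <<- c(written, f)
  }

  ft <- report$feature_table
  p_box <- ggplot2::ggplot(ft, ggplot2::aes(x = label, y = global_rate)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Rate of HbO change (1e-4 mM/DPF per min)",
                  title = "Global rate of HbO change by group") +
    ggplot2::theme_minimal()
  save_plot(p_box, "rate_boxplot")

  acc <- data.frame(
    trial = vapply(report$trial_results, `[[`, character(1), "trial"),
    accuracy = 100 * vapply(report$trial_results, `[[`, numeric(1),
                            "oob_accuracy_mean")
  )
  p_acc <- ggplot2::ggplot(acc, ggplot2::aes(x = trial, y = accuracy)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "OOB accuracy (%)",
                  title = "Classification accuracy per trial") +
    ggplot2::theme_minimal()
  save_plot(p_acc, "accuracy_bars")

  imp1 <- report$trial_results[[1]]$importance
  if (!is.null(imp1)) {
    imp_df <- do.call(rbind, lapply(report$trial_results, function(r) {
      data.frame(trial = r$trial, feature = names(r$importance),
                 importance = unname(r$importance))
    }))
    imp_df$feature <- stats::reorder(imp_df$feature, imp_df$importance)
    p_imp <- ggplot2::ggplot(imp_df,
                             ggplot2::aes(x = feature, y = importance)) +
      ggplot2::geom_col() + ggplot2::coord_flip() +
      ggplot2::facet_wrap(~trial) +
      ggplot2::labs(x = NULL, y = "Normalized permutation importance") +
      ggplot2::theme_minimal()
    save_plot(p_imp, "importance_bars")
  } else {
    warning("importance results missing; importance figure skipped")
  }

  if (!is.null(report$group_stats)) {
    st <- report$group_stats$stats
    p_ts <- ggplot2::ggplot(st, ggplot2::aes(x = time_s)) +
      ggplot2::geom_line(ggplot2::aes(y = mean_a, colour = "group A")) +
      ggplot2::geom_line(ggplot2::aes(y = mean_b, colour = "group B")) +
      ggplot2::geom_point(data = st[st$significant, ],
                          ggplot2::aes(y = 0), shape = 15, size = 0.4,
                          colour = "darkgreen") +
      ggplot2::facet_wrap(~region) +
      ggplot2::labs(x = "Time from tilt onset (s)",
                    y = "HbO change (1e-4 mM/DPF)", colour = NULL,
                    title = "Group HbO trajectories with pointwise significance") +
      ggplot2::theme_minimal()
    save_plot(p_ts, "group_trajectories")
  } else {
    warning("group statistics missing; trajectory figure skipped")
  }
  invisible(written)
}
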