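test_that("clinical covariates match their calibrated distributions", {
  set.seed(21)
  oh <- sample_clinical("PD-OH", 10000)
  # sample mean of CASS close to its calibration target (SE ~ 0.019)
  expect_lt(abs(mean(oh$cass) - 4.6), 0.1)
  expect_true(all(oh$hy_stage >= 1 & oh$hy_stage <= 5))
  expect_true(all(oh$mmse >= 0 & oh$mmse <= 30))
  expect_lt(abs(mean(oh$sex) - 0.5), 0.02)

  hc <- sample_clinical("HC", 5)
  expect_true(all(is.na(hc$hy_stage)))
  expect_true(all(is.na(hc$updrs3)))
  expect_true(all(is.na(hc$motor_symptom)))
  expect_true(all(!is.na(hc$age)))

  expect_error(sample_clinical("NOPE"), "label error")
})

test_that("trajectories carry their stored slope exactly and by group sign", {
  time <- seq(-20, 255, by = 0.2)

  v <- build_trajectory(time, rate = 12, transient_sign = 1, t_down = 195)
  sel <- time >= 15 & time <= 60
  fit <- stats::lm(v[sel] ~ time[sel])
  expect_equal(unname(stats::coef(fit)[2]) * 60, 12, tolerance = 1e-9)
  expect_equal(max(abs(v[time < 0])), 0)  # flat baseline

  # negative-rate group: value falls from static onset to fit end
  v_neg <- build_trajectory(time, rate = -9.9, transient_sign = 1,
                            t_down = 195)
  expect_lt(v_neg[which.min(abs(time - 60))], v_neg[which.min(abs(time - 15))])

  # dynamic transient signs: dip for HC-like, rise for OH-like
  v_hc <- build_trajectory(time, rate = 7, transient_sign = -1, t_down = 195)
  expect_lt(v_hc[which.min(abs(time - 10))], 0)
  expect_gt(v_neg[which.min(abs(time - 10))], 0)

  # right-hemisphere deficit: OH right-SFG slopes below left-SFG in the mean
  set.seed(22)
  tpl <- group_templates()[["PD-OH"]]
  draws <- huttdot:::.draw_region_rates(1000, tpl, rho = 0.8)
  expect_lt(mean(draws[, "R-SFG"]), mean(draws[, "L-SFG"]))
  # ... while the overall mean matches the group calibration
  expect_lt(abs(mean(rowMeans(draws)) - tpl$rate_mean), 3 * 6.7 / sqrt(1000))
})

test_that("cohort generation is reproducible with the analyzed group sizes", {
  spec <- cohort_spec(seed = 23)
  coh <- generate_cohort(spec)
  expect_length(coh$subjects, 46)
  templates <- vapply(coh$subjects, `[[`, character(1), "template")
  expect_equal(as.vector(table(templates)[c("HC", "PD-OH", "PD-POS", "PD-NEG")]),
               c(7L, 10L, 17L, 12L))

  # labels follow the sign rule applied to the realized global rate
  for (s in coh$subjects) {
    if (s$template %in% c("PD-POS", "PD-NEG")) {
      expect_equal(s$label, if (s$true_global_rate >= 0) "PD-POS" else "PD-NEG")
    } else {
      expect_equal(s$label, s$template)
    }
  }

  # extractor recovers the stored slope to machine precision without noise
  spec0 <- cohort_spec(sizes = c("HC" = 2), seed = 24, noise = zero_noise(),
                       timing = list(baseline_s = 20, dynamic_s = 15,
                                     static_s = 180, static_jitter_s = 0,
                                     post_s = 60, fs = 5))
  coh0 <- generate_cohort(spec0)
  for (s in coh0$subjects) {
    rf <- rate_of_change(s$regions)
    expect_equal(unname(rf$rates), unname(s$true_rates), tolerance = 1e-9)
  }

  # same seed -> byte-identical feature CSVs
  f1 <- tempfile(); f2 <- tempfile()
  write_feature_table(cohort_feature_table(generate_cohort(spec)), f1)
  write_feature_table(cohort_feature_table(generate_cohort(spec)), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # different seeds -> different rates, same group means within sampling error
  ft_a <- generate_feature_table(cohort_spec(sizes = c("PD-POS" = 400), seed = 25))
  ft_b <- generate_feature_table(cohort_spec(sizes = c("PD-POS" = 400), seed = 26))
  expect_false(any(ft_a$global_rate == ft_b$global_rate))
  se <- 6.3 / sqrt(400)
  expect_lt(abs(mean(ft_a$global_rate) - mean(ft_b$global_rate)), 6 * se)
})

test_that("directly sampled feature tables are calibrated and relabelled", {
  spec <- cohort_spec(sizes = c("PD-POS" = 10000), seed = 27)
  ft <- generate_feature_table(spec)
  expect_lt(abs(mean(ft$global_rate) - 8.5), 0.3)
  expect_true(all(ft$global_rate[ft$label == "PD-POS"] >= 0))
  expect_true(all(ft$global_rate[ft$label == "PD-NEG"] < 0))

  # HC rows never reach a trial table
  spec2 <- cohort_spec(sizes = c("HC" = 5, "PD-OH" = 6, "PD-POS" = 8,
                                 "PD-NEG" = 6), seed = 28)
  ft2 <- generate_feature_table(spec2)
  expect_message(res <- run_trials(ft2, n_trees = 60, seed = 29,
                                   importance = FALSE), "excluding 5 HC")
})

test_that("forward projection produces physical recordings", {
  sens <- default_sensitivity()
  s <- small_grid_setup()

  spec <- cohort_spec(sizes = c("PD-OH" = 1), seed = 30, noise = zero_noise())
  coh <- generate_cohort(spec)
  subj <- coh$subjects[[1]]

  # zero trajectories + zero noise -> constant intensities
  flat <- subj
  flat$regions$hbo[] <- 0
  flat$regions$hb[] <- 0
  rec0 <- project_to_channels(flat, sens, s$atlas, zero_noise())
  expect_equal(max(abs(rec0$intensities - rec0$intensities[1, 1, 1])), 0)

  rec <- project_to_channels(subj, sens, s$atlas, zero_noise())
  expect_true(all(rec$intensities > 0))

  # spike count follows the configured rate (Poisson oracle)
  ns <- noise_spec(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                   white_sd = 0, drift_sd = 0, spike_rate = 0.05,
                   spike_amp = 0.5)
  set.seed(31)
  rec_sp <- project_to_channels(flat, sens, s$atlas, ns)
  od <- -log10(rec_sp$intensities[, 1, ] / 1000)
  n_spiky <- sum(apply(abs(od) > 0.25, 1, any))
  duration <- length(rec_sp$time) / rec_sp$sampling_rate
  lambda <- 0.05 * duration  # expected spikes per channel
  p_spike <- 1 - exp(-lambda) # fraction of channels with >= 1 spike
  expect_lt(abs(n_spiky / 108 - p_spike), 4 * sqrt(p_spike * (1 - p_spike) / 108) + 0.05)
})
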