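test_that("phase segmentation follows the tilt events", {
  ph <- segment_phases(c(tilt_start = 0, tilt_down = 195))
  st <- ph$phases[ph$phases$phase == "static", ]
  expect_equal(c(st$start, st$end), c(15, 195))
  expect_equal(ph$phases$start[-1], ph$phases$end[-4])  # contiguous

  # per-subject varying static durations are honored
  ph2 <- segment_phases(c(tilt_start = 0, tilt_down = 150))
  expect_equal(ph2$t_down, 150)
  expect_false(ph2$t_down == ph$t_down)

  expect_error(segment_phases(c(tilt_start = 0, tilt_down = 10)), "event error")
  expect_error(segment_phases(c(tilt_start = 0)), "event error")
})

test_that("rate extraction is exact on lines and matches OLS theory on noise", {
  rs <- linear_region_series(intercept = 2, slope_per_s = 0.03)
  rf <- rate_of_change(rs)
  expect_equal(unname(rf$rates), rep(0.03 * 60, 6), tolerance = 1e-10)
  expect_equal(rf$global_rate, mean(rf$rates))

  flat <- linear_region_series(intercept = 4, slope_per_s = 0)
  expect_equal(max(abs(rate_of_change(flat)$rates)), 0)

  # shift invariance
  rs2 <- rs
  rs2$hbo <- rs2$hbo + 11
  expect_equal(rate_of_change(rs2)$rates, rf$rates)

  # line + Gaussian noise: slope within 4 closed-form standard errors
  set.seed(10)
  b <- 0.05; sigma <- 0.5
  rs3 <- linear_region_series(slope_per_s = b)
  rs3$hbo <- rs3$hbo + matrix(rnorm(length(rs3$hbo), 0, sigma), 6)
  sel <- rs3$time >= 15 & rs3$time <= 60
  tt <- rs3$time[sel]
  se <- sigma / sqrt(sum((tt - mean(tt))^2))  # OLS slope sampling sd
  got <- rate_of_change(rs3)$rates / 60
  expect_true(all(abs(got - b) < 4 * se))

  short <- linear_region_series(t_end = 10)
  expect_error(rate_of_change(short), "data error")
})

test_that("subgroup assignment follows the sign rule", {
  expect_equal(assign_subgroup(8.5, "PD-NOR"), "PD-POS")
  expect_equal(assign_subgroup(-9.9, "PD-NOR"), "PD-NEG")
  expect_equal(assign_subgroup(0, "PD-NOR"), "PD-POS")  # tie-break
  expect_equal(assign_subgroup(-3, "HC"), "HC")
  expect_equal(assign_subgroup(-3, "PD-OH"), "PD-OH")

  # partition property: every PD-NOR rate maps to exactly one subgroup
  set.seed(11)
  labs <- vapply(rnorm(200), assign_subgroup, character(1), label = "PD-NOR")
  expect_true(all(labs %in% c("PD-POS", "PD-NEG")))
})

test_that("pointwise Welch test matches stats::t.test and detects shifts", {
  set.seed(12)
  mk <- function(shift = 0, n = 6, noise = 1) {
    lapply(seq_len(n), function(i) {
      rs <- linear_region_series()
      rs$hbo <- matrix(rnorm(length(rs$hbo), 0, noise), 6) +
        shift * outer(rep(1, 6), as.numeric(rs$time >= 15))
      rs$hbt <- rs$hbo + rs$hb
      rs
    })
  }
  a <- mk(); b <- mk()
  ts <- pointwise_ttest(a, b)

  # cross-check a handful of samples against the reference implementation
  time <- a[[1]]$time
  for (idx in c(3, 100, 400)) {
    av <- vapply(a, function(s) s$hbo[2, idx], numeric(1))
    bv <- vapply(b, function(s) s$hbo[2, idx], numeric(1))
    ref <- stats::t.test(av, bv)
    row <- ts$stats[ts$stats$region == "R-SFG" & ts$stats$time_s == time[idx], ]
    expect_equal(row$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(row$p, ref$p.value, tolerance = 1e-10)
  }

  # identical groups: no significant samples (t = 0 everywhere)
  same <- pointwise_ttest(a, a)
  expect_equal(sum(same$stats$significant), 0)

  # 3-sigma mean shift confined to the static phase: high detection there
  g1 <- mk(shift = 0, n = 12)
  g2 <- mk(shift = 3, n = 12)
  det <- pointwise_ttest(g1, g2)
  expect_gt(mean(significant_fraction(det, window = c(16, 120))), 0.9)
  expect_lt(mean(significant_fraction(det, window = c(-20, 0))), 0.3)
})

test_that("laterality test is a paired t and flags asymmetric cohorts", {
  set.seed(13)
  # perfectly symmetric subjects: zero differences, degenerate p = 1
  sym <- lapply(1:5, function(i) {
    rs <- linear_region_series()
    m <- rnorm(length(rs$time))
    rs$hbo <- matrix(rep(m, each = 6), 6)
    rs$hbt <- rs$hbo + rs$hb
    rs
  })
  lt <- laterality_ttest(sym)
  expect_equal(sum(lt$stats$significant), 0)

  # right slope deflated 50%: flags concentrate in the static phase
  asym <- lapply(1:12, function(i) {
    rs <- linear_region_series(slope_per_s = 0)
    rs$hbo <- matrix(rep(0.05 * pmax(rs$time, 0), each = 6), nrow = 6,
                     dimnames = list(rs$region_names, NULL))
    right <- grepl("^R", rs$region_names)
    rs$hbo[right, ] <- rs$hbo[right, ] * 0.5
    rs$hbo <- rs$hbo + matrix(rnorm(length(rs$hbo), 0, 0.3), 6)
    rs$hbt <- rs$hbo + rs$hb
    rs
  })
  lt2 <- laterality_ttest(asym)
  expect_gt(mean(significant_fraction(lt2, window = c(60, 120))), 0.8)
  expect_lt(mean(significant_fraction(lt2, window = c(-20, 0))), 0.3)

  # paired toy triplet vs the reference implementation
  lv <- c(1.2, 0.8, 1.5); rv <- c(0.9, 0.7, 1.1)
  toy <- lapply(1:3, function(i) {
    rs <- linear_region_series(t_end = 5)
    rs$hbo[] <- 0
    rs$hbo[1, ] <- lv[i]  # L-SFG
    rs$hbo[2, ] <- rv[i]  # R-SFG
    rs$hbt <- rs$hbo + rs$hb
    rs
  })
  lt3 <- laterality_ttest(toy)
  ref <- stats::t.test(lv, rv, paired = TRUE)
  row <- lt3$stats[lt3$stats$region == "SFG", ][1, ]
  expect_equal(row$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(row$p, ref$p.value, tolerance = 1e-10)
})
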