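test_that("optical density conversion matches the per-sample log ratio", {
  rec <- constant_recording()
  od <- intensity_to_od(rec)
  expect_equal(max(abs(od$od)), 0)

  # I = Iref/10 gives OD 1 outside the reference window
  rec2 <- constant_recording()
  rec2$intensities[, , 150:300] <- 10
  od2 <- intensity_to_od(rec2, reference_window = c(0, 10))
  expect_equal(od2$od[1, 1, 200], 1)

  # random positive series vs an independent elementwise oracle
  set.seed(1)
  rec3 <- constant_recording()
  rec3$intensities[] <- exp(rnorm(length(rec3$intensities), log(100), 0.2))
  od3 <- intensity_to_od(rec3, reference_window = c(0, 20))
  sel <- rec3$time >= 0 & rec3$time < 20
  for (c in 1:2) for (w in 1:2) {
    iref <- exp(mean(log(rec3$intensities[c, w, sel])))
    expect_equal(od3$od[c, w, ], -log10(rec3$intensities[c, w, ] / iref))
  }
  # zero mean over reference window
  expect_lt(max(abs(apply(od3$od[, , sel, drop = FALSE], c(1, 2), mean))), 1e-12)

  rec4 <- constant_recording()
  rec4$intensities[2, 1, 5] <- -1
  expect_error(intensity_to_od(rec4), "C002")
})

test_that("low-pass filter has unit DC gain and the expected rolloff", {
  expect_equal(lowpass(rep(3, 400)), rep(3, 400), tolerance = 1e-9)

  t <- (0:999) / 5
  hi <- sin(2 * pi * 1.0 * t)
  expect_lt(sqrt(mean(lowpass(hi)^2)) / sqrt(mean(hi^2)), 0.05)

  lo <- sin(2 * pi * 0.05 * t)
  out <- lowpass(lo)
  mid <- 200:800  # ignore filter edge transients
  expect_equal(max(abs(out[mid])), max(abs(lo[mid])), tolerance = 0.02)

  expect_error(lowpass(rnorm(5)), "length error")
  expect_error(lowpass(rnorm(100), cutoff = 3, sampling_rate = 5), "Nyquist")
})

test_that("moving average equals the brute-force shrinking-window mean", {
  x <- rnorm(57)
  expect_equal(moving_average(x, 1), x)

  ramp <- seq(0, 10, length.out = 101)
  expect_equal(moving_average(ramp, 5)[3:99], ramp[3:99])

  out <- moving_average(x, 5)
  oracle <- vapply(seq_along(x), function(i) {
    mean(x[max(1, i - 2):min(length(x), i + 2)])
  }, numeric(1))
  expect_equal(out, oracle)

  expect_error(moving_average(rnorm(3), 5), "length error")
  expect_error(moving_average(rnorm(10), 4), "odd")
})

test_that("the wavelet transform reconstructs perfectly", {
  set.seed(2)
  x <- cumsum(rnorm(700))
  w <- modwt(x)
  expect_equal(imodwt(w), x, tolerance = 1e-8)
})

test_that("wavelet despiking removes spikes and preserves slow signal", {
  t <- seq(0, 200, by = 0.2)
  slow <- 2 * sin(2 * pi * 0.02 * t)
  d0 <- wavelet_despike(slow)
  expect_lt(sqrt(mean((d0 - slow)^2)) / sqrt(mean(slow^2)), 0.01)

  spiked <- slow
  spike_at <- 500
  spiked[spike_at] <- spiked[spike_at] + 20
  d1 <- wavelet_despike(spiked)
  expect_gt(1 - abs(d1[spike_at] - slow[spike_at]) / 20, 0.80)

  # coefficients are only zeroed: energy cannot grow
  expect_lte(sum(d1^2), sum(spiked^2))

  # near-idempotence: a second application changes the series RMS < 1%
  d2 <- wavelet_despike(d1)
  expect_lt(abs(sqrt(mean(d2^2)) - sqrt(mean(d1^2))) / sqrt(mean(d1^2)), 0.01)
  set.seed(9)
  od_like <- 0.02 * sin(2 * pi * 0.02 * t) + rnorm(length(t), 0, 0.005)
  od_like[300] <- od_like[300] + 0.2
  e1 <- wavelet_despike(od_like)
  e2 <- wavelet_despike(e1)
  expect_lt(abs(sqrt(mean(e2^2)) - sqrt(mean(e1^2))) / sqrt(mean(e1^2)), 0.01)

  expect_warning(wavelet_despike(rnorm(10)), "too short")
})

test_that("MBLL inverts a forward-constructed system exactly", {
  lay <- default_layout()
  ext <- extinction_table()
  nc <- nrow(lay$channels); nt <- 40
  set.seed(3)
  hbo <- matrix(rnorm(nc * nt, 0, 1e-3), nc)
  hb <- matrix(rnorm(nc * nt, 0, 1e-3), nc)
  d_cm <- lay$channels$nominal_separation_mm / 10
  od_arr <- array(0, c(nc, 2, nt))
  for (c in seq_len(nc)) {
    od_arr[c, 1, ] <- (ext["w760", "hbo"] * hbo[c, ] + ext["w760", "hb"] * hb[c, ]) * d_cm[c]
    od_arr[c, 2, ] <- (ext["w830", "hbo"] * hbo[c, ] + ext["w830", "hb"] * hb[c, ]) * d_cm[c]
  }
  od <- structure(
    list(od = od_arr, time = seq_len(nt) / 5, events = c(tilt_start = 4),
         sampling_rate = 5, channel_ids = lay$channels$channel_id,
         wavelengths = c(760, 830)),
    class = "od_series"
  )
  h <- mbll(od, lay)
  expect_lt(max(abs(h$hbo - hbo)), 1e-10)
  expect_lt(max(abs(h$hb - hb)), 1e-10)
  expect_equal(h$hbt, h$hbo + h$hb)

  od$od[] <- 0
  h0 <- mbll(od, lay)
  expect_equal(max(abs(h0$hbt)), 0)

  bad_ext <- ext
  bad_ext["w830", ] <- bad_ext["w760", ]
  expect_error(mbll(od, lay, ext = bad_ext), "singular")

  od$channel_ids[1] <- "NOPE"
  expect_error(mbll(od, lay), "key error")
})

test_that("baseline correction zeroes the baseline and ignores offsets", {
  rs <- linear_region_series(intercept = 5, slope_per_s = 0.02)
  out <- baseline_correct(rs)
  sel <- out$time >= -20 & out$time < 0
  expect_lt(max(abs(rowMeans(out$hbo[, sel]))), 1e-12)

  # constant offset invariance
  rs2 <- rs
  rs2$hbo <- rs2$hbo + 7
  expect_equal(baseline_correct(rs2)$hbo, out$hbo)

  expect_error(baseline_correct(rs, baseline_window = c(1e5, 2e5)), "bounds")
})

test_that("QC excludes dead and saturated channels and flags subjects", {
  rec <- constant_recording(n_channels = 8)
  qc <- qc_channels(rec, min_intensity = 1, max_intensity = 1e4)
  expect_true(all(qc$channels$included))
  expect_false(qc$excluded_subject)

  rec$intensities[3, , ] <- 0.1  # dead channel
  rec$intensities[5, 1, 10] <- 1e5  # saturated sample
  qc2 <- qc_channels(rec, min_intensity = 1, max_intensity = 1e4)
  expect_equal(which(!qc2$channels$included), c(3L, 5L))

  rec$intensities[1:5, , ] <- 0.1
  qc3 <- qc_channels(rec, min_intensity = 1, max_intensity = 1e4)
  expect_true(qc3$excluded_subject)

  rec$intensities[] <- 0.1
  qc4 <- qc_channels(rec, min_intensity = 1, max_intensity = 1e4)
  expect_error(apply_qc(rec, qc4), "subject rejected")
})

test_that("the channel chain is invariant to per-channel intensity scaling", {
  lay <- load_probe(default_probe_table()[1:4, ])
  set.seed(4)
  nt <- 400
  arr <- array(exp(rnorm(4 * 2 * nt, log(100), 0.1)), c(4, 2, nt))
  rec <- optical_recording(arr, sampling_rate = 5,
                           events = c(tilt_start = 20, tilt_down = 60),
                           time = (seq_len(nt) - 1) / 5)
  scaled <- rec
  scaled$intensities <- sweep(rec$intensities, 1, c(2, 0.5, 3, 10), "*")
  h1 <- preprocess_recording(rec, lay)$hemo
  h2 <- preprocess_recording(scaled, lay)$hemo
  expect_equal(h1$hbo, h2$hbo, tolerance = 1e-10)
  expect_equal(h1$hbt, h1$hbo + h1$hb)
})
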