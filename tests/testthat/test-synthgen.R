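test_that("background generator honors rms, determinism and the zero case", {
  b1 <- make_background(background_spec(2, 60, fs = FS, rms = 10, seed = 7))
  b2 <- make_background(background_spec(2, 60, fs = FS, rms = 10, seed = 7))
  expect_identical(b1$data, b2$data)
  expect_equal(sd(b1$data[1, ]), 10, tolerance = 1e-6)
  b0 <- make_background(background_spec(1, 60, fs = FS, rms = 0, seed = 1))
  expect_true(all(b0$data == 0))
  expect_error(background_spec(1, -5), "positive")
})

test_that("background spectral exponent is recovered by the slope estimator", {
  for (s in c(0, 2)) {
    bg <- make_background(background_spec(1, 600, fs = FS,
                                          one_over_f_slope = s, rms = 15,
                                          seed = 100 + s))
    sl <- spectral_slope(welch_psd(bg$data[1, ], FS))
    expect_equal(sl, -s, tolerance = 0.1)
  }
})

test_that("SO injection respects density, non-overlap and the zero case", {
  bg <- quick_background(600, rms = 0, seed = 1)
  out <- inject_so(bg, so_spec(density = 8), seed = 2)
  k <- nrow(out$truth)
  # Poisson draw around 80 for 10 minutes
  expect_gt(k, 80 - 4 * sqrt(80))
  expect_lt(k, 80 + 4 * sqrt(80))
  o <- order(out$truth$start)
  expect_true(all(diff(out$truth$start[o]) >
                    (out$truth$end[o][-k] - out$truth$start[o][-k])[1] * 0))
  expect_true(all(out$truth$start[o][-1] > out$truth$end[o][-k]))
  out0 <- inject_so(bg, so_spec(density = 8), seed = 2, n_events = 0)
  expect_identical(out0$rec$data, bg$data)
  expect_error(inject_so(bg, so_spec(density = 8), n_events = 5000),
               "density too high")
})

test_that("injected SOs on silent background are fully recovered in absolute mode", {
  bg <- quick_background(600, rms = 0, seed = 1)
  out <- inject_so(bg, so_spec(density = 6, neg_peak_amp = -60,
                               pos_peak_amp = 50), seed = 3, n_events = 40)
  ev <- detect_so(out$rec$data[1, ], FS,
                  cfg = so_detector_config(mode = "absolute"))
  expect_equal(interval_recall(out$truth, ev), 1.0)
})

test_that("spindle chirp parameter is realized in the waveform", {
  sp <- spindle_spec(15, density = 3, duration_mean = 1, amplitude = 40,
                     chirp = -1)
  wf <- sleepmicro:::spindle_waveform(sp, FS)
  est <- chirp_from_zero_crossings(wf, FS)
  expect_equal(unname(est["chirp"]), -1, tolerance = 0.05)
  expect_equal(unname(est["obs_freq"]), 15, tolerance = 0.1)
})

test_that("coupled spindle placement hits the requested SO phase", {
  bg <- quick_background(900, rms = 5, seed = 4)
  sos <- so_spec(density = 6, neg_peak_amp = -70, pos_peak_amp = 45)
  o1 <- inject_so(bg, sos, seed = 5, n_events = 80)
  sp <- spindle_spec(15, density = 4, duration_mean = 1, amplitude = 25,
                     chirp = 0, coupling_phase = 240, coupling_kappa = 20)
  o2 <- inject_spindles(o1$rec, sp, so_truth = o1$truth, so_spec_used = sos,
                        seed = 6, n_events = 60)
  ph <- so_phase(o2$rec$data[1, ], FS)
  z <- mean(exp(1i * ph[o2$truth$peak] * pi / 180))
  ang <- (Arg(z) * 180 / pi) %% 360
  expect_lt(circ_diff(ang, 240), 5)
  expect_error(inject_spindles(bg, sp, so_truth = NULL), "SO truth")
})

test_that("simulate_subject keeps events inside N2 epochs with exact densities", {
  sub <- simulate_subject(background_spec(1, 1200, fs = FS, rms = 20,
                                          seed = 9),
                          so = so_spec(density = 5),
                          slow = spindle_spec(11, density = 2,
                                              amplitude = 25),
                          fast = spindle_spec(15, density = 3,
                                              amplitude = 25),
                          n2_fraction = 0.9, seed = 9)
  expect_equal(sum(sub$stages$stages == "N2"), 36)
  expect_equal(nrow(sub$truth$fast), round(3 * sub$n2_minutes))
  mask <- stage_sample_mask(sub$stages, FS, ncol(sub$rec$data))
  for (tab in sub$truth)
    expect_true(all(mask[tab$start] & mask[tab$end]))
  expect_error(simulate_subject(background_spec(1, 20, fs = FS, seed = 1)),
               "shorter than one")
})

test_that("cohort metric mode delivers the requested standardized effects", {
  cs <- cohort_spec(60, 60, effect_sizes = c(a = 1, b = 0), seed = 11)
  sim <- simulate_cohort_metrics(cs, n_channels = 3)
  expect_equal(dim(sim$metrics$a), c(120, 3))
  d <- mean(sim$metrics$a[sim$covariates$group == "case", 1]) -
    mean(sim$metrics$a[sim$covariates$group == "control", 1])
  expect_equal(d, 1, tolerance = 0.5)
  expect_error(cohort_spec(0, 10), "positive")
  expect_error(simulate_cohort_metrics(cs, age_slopes = c(zz = 1)),
               "unknown metric")
  sim2 <- simulate_cohort_metrics(cs, n_channels = 3)
  expect_identical(sim$metrics$a, sim2$metrics$a)
})
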