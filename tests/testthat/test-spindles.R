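test_that("Morlet magnitude responds to in-band tones and rejects off-band ones", {
  t <- (0:(FS * 10 - 1)) / FS
  cfg <- spindle_detector_config(15)
  m15 <- cwt_magnitude(sin(2 * pi * 15 * t), FS, cfg)
  mid <- (2 * FS):(8 * FS)
  expect_lt(sd(m15[mid]) / mean(m15[mid]), 0.01)  # ~constant in steady state
  m5 <- cwt_magnitude(sin(2 * pi * 5 * t), FS, cfg)
  expect_lt(mean(m5[mid]), 0.1 * mean(m15[mid]))
  expect_true(all(cwt_magnitude(numeric(FS * 5), FS, cfg) == 0))
  expect_error(cwt_magnitude(t, FS, spindle_detector_config(150)), "Nyquist")
})

test_that("detector recovers an injected burst and is amplitude-scale-equivariant", {
  bg <- quick_background(300, rms = 20, seed = 21)
  sp <- spindle_spec(15, density = 1, duration_mean = 1,
                     amplitude = snr_amplitude(bg$data[1, ], 6), chirp = 0)
  out <- inject_spindles(bg, sp, seed = 22, n_events = 1)
  ev <- detect_spindles(out$rec$data[1, ], FS,
                        cfg = spindle_detector_config(15))
  expect_equal(nrow(ev), 1)
  expect_equal(interval_recall(out$truth, ev), 1)
  ev2 <- detect_spindles(out$rec$data[1, ] * 3.7, FS,
                         cfg = spindle_detector_config(15))
  expect_equal(ev$start, ev2$start)
  expect_equal(ev$end, ev2$end)
  expect_error(detect_spindles(out$rec$data[1, ], FS,
                               mask = rep(FALSE, 300 * FS)), "mask")
})

test_that("raising the core threshold never increases the event count", {
  bg <- quick_background(600, rms = 20, seed = 23)
  sp <- spindle_spec(15, density = 3, duration_mean = 1,
                     amplitude = snr_amplitude(bg$data[1, ], 4), chirp = 0)
  out <- inject_spindles(bg, sp, seed = 24, n_events = 30)
  counts <- vapply(c(3.5, 4.5, 5.5, 6.5), function(th)
    nrow(detect_spindles(out$rec$data[1, ], FS,
                         cfg = spindle_detector_config(15, core_thresh = th))),
    0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("slow and fast detectors separate 11 and 15 Hz targets", {
  bg <- quick_background(600, rms = 20, seed = 25)
  amp <- snr_amplitude(bg$data[1, ], 6)
  out <- inject_spindles(bg, spindle_spec(15, 3, 1, amp, 0), seed = 26,
                         n_events = 25)
  ev_fast <- detect_spindles(out$rec$data[1, ], FS,
                             cfg = spindle_detector_config(15))
  ev_slow <- detect_spindles(out$rec$data[1, ], FS,
                             cfg = spindle_detector_config(11))
  expect_gt(interval_recall(out$truth, ev_fast), 0.85)
  # cross-talk: the 11 Hz detector picks up under 15% of the 15 Hz events
  expect_lt(nrow(ev_slow) / nrow(out$truth), 0.15)
})

test_that("zero-crossing chirp is exact on stationary tones and symmetric under reversal", {
  t <- (0:(FS - 1)) / FS
  tone <- sin(2 * pi * 13 * t)
  est <- chirp_from_zero_crossings(tone, FS)
  expect_equal(unname(est["chirp"]), 0, tolerance = 0.02)
  expect_equal(unname(est["obs_freq"]), 13, tolerance = 0.05)
  sp <- spindle_spec(15, 3, 1, 40, chirp = -1)
  wf <- sleepmicro:::spindle_waveform(sp, FS)
  fwd <- chirp_from_zero_crossings(wf, FS)
  rev_ <- chirp_from_zero_crossings(rev(wf), FS)
  expect_equal(unname(rev_["chirp"]), -unname(fwd["chirp"]), tolerance = 1e-12)
  short <- sin(2 * pi * 13 * t[1:40])
  expect_true(is.na(chirp_from_zero_crossings(short, FS)["chirp"]))
})

test_that("band-ratio QC keeps sigma bursts and rejects broadband artifacts", {
  bg <- quick_background(300, rms = 20, seed = 27)
  amp <- snr_amplitude(bg$data[1, ], 6)
  out <- inject_spindles(bg, spindle_spec(15, 1, 1, amp, 0), seed = 28,
                         n_events = 5)
  ev <- detect_spindles(out$rec$data[1, ], FS,
                        cfg = spindle_detector_config(15))
  kept <- qc_spindles(ev, out$rec$data[1, ], FS, center_freq = 15)
  expect_equal(nrow(kept), nrow(ev))
  # broadband artifact crossing the wavelet threshold: big amplitude steps
  x <- bg$data[1, ]
  art <- seq(100 * FS, 100 * FS + FS)
  set.seed(29)
  x[art] <- x[art] + rnorm(length(art), sd = 30 * sd(x))
  ev_a <- detect_spindles(x, FS, cfg = spindle_detector_config(15))
  in_art <- ev_a[ev_a$start <= max(art) & ev_a$end >= min(art), ]
  if (nrow(in_art)) {
    kept_a <- qc_spindles(in_art, x, FS, center_freq = 15)
    expect_equal(nrow(kept_a), 0)
  }
  expect_equal(nrow(qc_spindles(empty_events <- ev[0, ], x, FS)), 0)
})

test_that("spindle metrics summarize correctly and recover injected amplitude", {
  expect_error(spindle_metrics(data.frame(), 0), "positive")
  bg <- quick_background(600, rms = 20, seed = 31)
  out <- inject_spindles(bg, spindle_spec(15, 3, 1, 40, 0), seed = 32,
                         n_events = 30)
  ev <- detect_spindles(out$rec$data[1, ], FS,
                        cfg = spindle_detector_config(15))
  m <- spindle_metrics(ev, 10)
  expect_equal(m$density, nrow(ev) / 10)
  expect_equal(m$amplitude, 40, tolerance = 0.1 * 40)
  m0 <- spindle_metrics(ev[0, ], 10)
  expect_equal(m0$density, 0)
  expect_true(is.na(m0$amplitude))
})
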