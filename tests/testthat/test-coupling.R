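test_that("SO phase convention: 0 at positive peak, 180 at trough, 270 rising", {
  t <- (0:(FS * 30 - 1)) / FS
  ph <- so_phase(cos(2 * pi * 1 * t), FS)
  i_peak <- 10 * FS + 1
  expect_lt(circ_diff(ph[i_peak], 0), 1)
  expect_lt(circ_diff(ph[i_peak + FS / 2], 180), 1)
  expect_lt(circ_diff(ph[i_peak + round(0.75 * FS)], 270), 5)
})

test_that("coupling metrics handle degenerate and uniform phase sets", {
  so <- data.frame(start = c(100, 500), end = c(300, 700))
  ph <- rep(240, 1000)
  sp <- data.frame(start = c(120, 520), end = c(180, 580),
                   peak = c(150, 550))
  cm <- coupling_metrics(sp, so, ph)
  expect_equal(cm$magnitude_raw, 1.0)
  expect_equal(cm$mean_angle, 240)
  expect_equal(cm$overlap_raw, 1.0)
  # uniform grid of 18 phases -> zero resultant
  ph2 <- seq(0, 350, 20)[1:18]
  sp2 <- data.frame(start = 1:18, end = 1:18, peak = 1:18)
  cm2 <- coupling_metrics(sp2, so, ph2[sp2$peak])
  expect_lt(cm2$magnitude_raw, 1e-10)
  cm0 <- coupling_metrics(sp2[0, ], so, ph2)
  expect_true(is.na(cm0$magnitude_raw))
})

test_that("von Mises concentration maps to the Bessel-ratio resultant length", {
  set.seed(61)
  th <- sleepmicro:::rvonmises(500, 240 * pi / 180, 2)
  r <- Mod(mean(exp(1i * th)))
  expect_equal(r, besselI(2, 1) / besselI(2, 0), tolerance = 0.05)
})

test_that("surrogate Z-scores separate coupled from uniform placements", {
  bg <- quick_background(900, rms = 5, seed = 62)
  sos <- so_spec(density = 6, neg_peak_amp = -70, pos_peak_amp = 45)
  o1 <- inject_so(bg, sos, seed = 63, n_events = 80)
  ph <- so_phase(o1$rec$data[1, ], FS)
  so_ev <- detect_so(o1$rec$data[1, ], FS,
                     cfg = so_detector_config(mode = "absolute"))
  mask <- rep(TRUE, ncol(o1$rec$data))
  # peaks fixed at one phase
  so_samples <- unlist(lapply(seq_len(nrow(so_ev)), function(i)
    so_ev$start[i]:so_ev$end[i]))
  target <- so_samples[circ_diff(ph[so_samples], 240) < 3][1:100]
  spn <- data.frame(start = target - 50, end = target + 50, peak = target)
  cm <- coupling_metrics(spn, so_ev, ph)
  sn <- surrogate_normalize(cm, spn, so_ev, ph, mask, n_shuffles = 500,
                            seed = 64)
  expect_gt(sn$magnitude_z, 5)
  expect_lt(sn$magnitude_p, 0.01)
  # spindles placed only inside SOs beat a density-matched uniform null
  expect_gt(sn$overlap_z, 3)
})

test_that("instantaneous frequency tracks tones, sweeps and ignores the envelope", {
  t <- (0:(FS * 10 - 1)) / FS
  mid <- (2 * FS):(8 * FS)
  f13 <- instantaneous_frequency(sin(2 * pi * 13 * t), FS, 13)
  expect_lt(max(abs(f13[mid] - 13)), 0.05
  )
  # linear sweep 12 -> 14 Hz
  finst <- 12 + 2 * t / 10
  sweep <- sin(2 * pi * cumsum(finst) / FS)
  fest <- instantaneous_frequency(sweep, FS, 13)
  expect_lt(max(abs(fest[mid] - finst[mid])), 0.1)
  # amplitude modulation leaves frequency unchanged
  am <- (1 + 0.5 * sin(2 * pi * 0.5 * t)) * sin(2 * pi * 13 * t)
  fam <- instantaneous_frequency(am, FS, 13)
  expect_lt(max(abs(fam[mid] - 13)), 0.1)
})

test_that("phase/frequency profiles recover constructed modulations", {
  # frequency = 13 + cos(SO phase): bin means trace the cosine
  n <- FS * 100
  ph <- ((0:(n - 1)) / FS * 0.8 * 360 + 360 * runif(1)) %% 360
  fr <- 13 + cos(ph * pi / 180)
  starts <- round(seq(1, n - 2 * FS, length.out = 40))
  ev <- data.frame(start = starts, end = starts + round(1.25 * FS) - 1)
  pf <- phase_freq_profiles(ev, fr, ph)
  expected <- 13 + cos(seq(10, 350, 20) * pi / 180)
  expect_lt(max(abs(pf$freq_by_phase_bin - expected), na.rm = TRUE), 0.1)
  expect_gt(pf$circ_lin_r, 0.99)
  # deceleration: strictly decreasing quintile means
  fr2 <- rep(15, n)
  for (i in seq_len(nrow(ev))) {
    idx <- ev$start[i]:ev$end[i]
    fr2[idx] <- 15.5 - seq(0, 1, length.out = length(idx))
  }
  pf2 <- phase_freq_profiles(ev, fr2, ph)
  expect_true(all(diff(pf2$freq_by_quintile) < 0))
  # single event: the joint matrix is exactly that event's own profile
  pf1 <- phase_freq_profiles(ev[1, ], fr, ph)
  idx <- ev$start[1]:ev$end[1]
  quint <- pmin(floor(5 * (seq_along(idx) - 1) / length(idx)) + 1, 5)
  bin <- pmin(floor(ph[idx] / 20) + 1, 18)
  manual <- tapply(fr[idx], list(factor(quint, levels = 1:5),
                                 factor(bin, levels = 1:18)), mean)
  expect_equal(unname(pf1$joint), unname(as.matrix(manual)),
               tolerance = 1e-12)
})

test_that("circular-linear correlation matches its regression-based oracle", {
  th <- seq(10, 350, 20)
  expect_equal(circ_linear_corr(th, cos((th - 77) * pi / 180)), 1,
               tolerance = 1e-10)
  expect_equal(circ_linear_corr(th, rep(3, 18)), 0)
  # independent oracle: sqrt of R^2 from lm(v ~ cos + sin)
  set.seed(65)
  for (i in 1:20) {
    v <- rnorm(18)
    r_pkg <- circ_linear_corr(th, v)
    r_lm <- sqrt(summary(lm(v ~ cos(th * pi / 180) +
                              sin(th * pi / 180)))$r.squared)
    expect_equal(r_pkg, r_lm, tolerance = 1e-12)
  }
})

test_that("rotation of all phases shifts the mean angle and nothing else", {
  set.seed(66)
  th <- (sleepmicro:::rvonmises(200, 4, 5) * 180 / pi) %% 360
  sp <- data.frame(start = 1:200, end = 1:200, peak = 1:200)
  so <- data.frame(start = 1, end = 200)
  cm <- coupling_metrics(sp, so, th)
  for (delta in c(30, 150)) {
    cmr <- coupling_metrics(sp, so, (th + delta) %% 360)
    expect_lt(circ_diff(cmr$mean_angle, cm$mean_angle + delta), 1e-6)
    expect_equal(cmr$magnitude_raw, cm$magnitude_raw, tolerance = 1e-12)
  }
})

test_that("cubic frequency models attribute variance to the right basis", {
  q <- 1:5
  cubic <- 0.3 * (q - 3) - 0.1 * (q - 3)^3
  jp <- matrix(rep(14 + cubic, 18), 5, 18)
  r2 <- fit_freq_model(jp)
  expect_gt(r2["progression"], 0.99)
  expect_lt(abs(r2["phase"]), 0.1)
  th <- (seq_len(18) - 0.5) * 20 * pi / 180
  jph <- matrix(rep(14 + cos(th), each = 5), 5, 18)
  r2b <- fit_freq_model(jph)
  expect_gt(r2b["phase"], 0.99)
  # additive construction: combined beats both single bases
  jadd <- outer(cubic, cos(th), "+") + 14
  r2c <- fit_freq_model(jadd)
  expect_gte(r2c["combined"], max(r2c["progression"], r2c["phase"]))
  expect_gt(r2c["combined"], 0.99)
})
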