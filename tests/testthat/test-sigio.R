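test_that("EDF write/read round trip is exact to one quantization step", {
  bg <- quick_background(30, rms = 20, seed = 2, n_channels = 3)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(bg, path)
  back <- read_edf(path)
  lsb <- max(abs(bg$data)) / 32767
  expect_lt(max(abs(back$data - bg$data)), 1.5 * lsb)
  expect_equal(back$fs, FS)
  expect_equal(back$channel_names, bg$channel_names)
  expect_error(read_edf(file.path(tempdir(), "nope.edf")), "not found")
})

test_that("stage TSV round trips", {
  ann <- new_stage_annotation(c("W", "N1", "N2", "N2", "N3", "R"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stage_tsv(ann, path)
  back <- read_stage_tsv(path)
  expect_equal(back$stages, ann$stages)
})

test_that("preprocess re-references, resamples and bandpasses", {
  t5 <- (0:(500 * 30 - 1)) / 500
  raw <- rbind(sin(2 * pi * 10 * t5) * 20 + sin(2 * pi * 50 * t5) * 20,
               rnorm(length(t5)), rnorm(length(t5)))
  rec <- new_recording(raw, 500, channel_names = c("C3", "M1", "M2"))
  pp <- preprocess(rec, mastoid_labels = c("M1", "M2"))
  expect_equal(pp$fs, 200)
  expect_equal(ncol(pp$data), 6000)
  expect_equal(pp$reference, "linked-mastoid")
  psd <- welch_psd(pp$data[1, ], 200, fmin = 0, fmax = 100)
  # 50 Hz attenuated by >= 20 dB relative to the passband 10 Hz line
  expect_lt(psd$power[psd$freq == 50], psd$power[psd$freq == 10] / 100)
  expect_error(preprocess(rec), "mastoid")
  # DC offset removed
  dc <- preprocess(new_recording(matrix(100 + rnorm(6000), 1), 200),
                   already_referenced = TRUE)
  expect_lt(abs(mean(dc$data)), 0.1)
  # already at 200 Hz: length preserved
  same <- preprocess(new_recording(matrix(rnorm(6000), 1), 200),
                     already_referenced = TRUE)
  expect_equal(ncol(same$data), 6000)
})

test_that("Hjorth parameters match closed forms and scale rules", {
  t <- (0:5999) / FS
  x <- rnorm(6000)
  h <- hjorth(x, FS)
  expect_equal(unname(h["activity"]), var(x))
  tone <- sin(2 * pi * 10 * t)
  ht <- hjorth(tone, FS)
  expect_equal(unname(ht["mobility"]), 2 * FS * sin(pi * 10 / FS),
               tolerance = 1e-3)
  h2 <- hjorth(2 * x, FS)
  expect_equal(unname(h2["activity"]), 4 * var(x))
  expect_equal(unname(h2["mobility"]), unname(h["mobility"]))
  hc <- hjorth(rep(1, 100), FS)
  expect_equal(unname(hc["activity"]), 0)
  expect_true(is.na(hc["mobility"]))
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  pos <- sleepmicro:::default_positions(12)
  # constant field: interpolation must reproduce it
  sig <- sin((1:100) / 5)
  rec <- new_recording(matrix(rep(sig, each = 12), 12, 100), FS,
                       positions = pos)
  out <- interpolate_spherical_spline(rec, 4)
  expect_lt(max(abs(out$data[4, ] - sig)), 1e-6)
  # linear potential gradient: small error at an interior channel
  field <- as.numeric(pos %*% c(1, 0.5, 0.2))
  recf <- new_recording(matrix(field, 12, 50), FS, positions = pos)
  outf <- interpolate_spherical_spline(recf, 6)
  expect_lt(abs(outf$data[6, 1] - field[6]), 0.05 * max(abs(field)))
  expect_true(all(is.finite(outf$data)))
  # good channels untouched
  expect_identical(outf$data[1, ], recf$data[1, ])
  recn <- new_recording(matrix(rnorm(1200), 12, 100), FS)
  expect_error(interpolate_spherical_spline(recn, 1), "positions")
})

test_that("artifact pipeline flags constructed artifacts and leaves clean data alone", {
  bg <- quick_background(600, rms = 20, seed = 3, n_channels = 12)
  ann <- new_stage_annotation(rep("N2", 20), n_channels = 12)
  clean <- artifact_pipeline(bg, ann)
  expect_length(clean$bad_channels, 0)
  n_drop <- sum(apply(clean$ann$mask == "dropped", 1, any))
  expect_lte(n_drop, 1)
  # a 10x-amplitude channel is flagged at stage 1
  bad <- bg
  bad$data[5, ] <- bad$data[5, ] * 10
  res <- artifact_pipeline(bad, ann)
  expect_true(5 %in% res$bad_channels)
  expect_true(all(res$ann$mask[, 5] %in% c("interpolated", "dropped")))
  # a 600 uV artifact epoch ends up dropped or interpolated
  bad2 <- bg
  idx <- sleepmicro:::epoch_indices(7, FS)
  bad2$data[3, idx[1:500]] <- 600
  res2 <- artifact_pipeline(bad2, ann)
  expect_true(res2$ann$mask[7, 3] %in% c("interpolated", "dropped"))
})

test_that("retained epochs are identical across channels and the pipeline is near-idempotent", {
  bg <- quick_background(600, rms = 20, seed = 5, n_channels = 10)
  ann <- new_stage_annotation(rep(c("N2", "N3"), each = 10), n_channels = 10)
  res <- artifact_pipeline(bg, ann)
  dropped <- res$ann$mask == "dropped"
  # mask consistency: dropping is global
  expect_true(all(apply(dropped, 1, function(r) all(r) || !any(r))))
  # second pass flags (almost) nothing new
  res2 <- artifact_pipeline(res$rec, res$ann)
  extra <- sum(apply(res2$ann$mask == "dropped", 1, any)) -
    sum(apply(dropped, 1, any))
  expect_lte(extra, ceiling(0.01 * length(ann$stages)))
})
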