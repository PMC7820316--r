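test_that("template peaks where placed and has unit window RMS", {
  tpl <- make_template(100, 20)
  t_ms <- (seq_len(600) - 1) / 1200 * 1000
  pk <- t_ms[which.max(abs(tpl))]
  expect_gte(pk, 45); expect_lte(pk, 150)
  expect_equal(rms(extract_window(tpl, c(45, 150))), 1, tolerance = 1e-9)
  expect_equal(rms(extract_window(make_template(70, 6), c(45, 150))), 1,
               tolerance = 1e-9)
  expect_error(make_template(30, 15), "outside the record|signal window")
  expect_error(make_template(100, -1), "positive")
})

test_that("shifting peak_time shifts the template by whole samples", {
  # supports kept inside the signal window so the normalisation constant
  # is shift-invariant and the +20 ms shift is exactly 24 samples
  tpl1 <- make_template(90, 5)
  tpl2 <- make_template(110, 5)
  expect_equal(tpl2[25:600], tpl1[1:576], tolerance = 1e-12)
})

test_that("analytic amplitude calibration inverts the SNR expectation", {
  expect_equal(calibrate_amplitude(4.07, 1), sqrt(4.07^2 - 1),
               tolerance = 1e-12)
  expect_lt(calibrate_amplitude(1 + 1e-9, 1), 1e-4)
  expect_equal(calibrate_amplitude(3, 2), 2 * calibrate_amplitude(3, 1),
               tolerance = 1e-12)
  expect_error(calibrate_amplitude(1, 1), "exceed 1")
  expect_error(calibrate_amplitude(0.5, 1), "exceed 1")
})

test_that("generate_eye is a pure function of (config, preset, seed)", {
  cfg <- quick_config()
  pr <- quick_preset()
  a <- generate_eye(cfg, pr, seed = 123)
  b <- generate_eye(cfg, pr, seed = 123)
  expect_identical(a$data, b$data)
  c <- generate_eye(cfg, pr, seed = 124)
  expect_false(identical(a$data, c$data))
})

test_that("generated records are band-limited to 1-35 Hz", {
  rec <- generate_eye(quick_config(), quick_preset(), seed = 5)
  f <- (seq_len(600) - 1) * 1200 / 600
  f <- ifelse(f > 600, f - 1200, f)
  keep <- abs(f) >= 1 & abs(f) <= 35
  for (s in c(1, 17, 60)) for (ch in c(1, 4)) {
    X <- Mod(fft(rec$data[s, ch, ]))^2
    expect_gt(sum(X[keep]) / sum(X), 0.99)
  }
})

test_that("noise-only ensembles land in the best-channel bias band", {
  cfg <- quick_config()
  pr <- quick_preset(amplitude = 0)
  snrs <- vapply(1:30, function(i) eye_snr(generate_eye(cfg, pr, seed = i)),
                 numeric(1))
  expect_gt(mean(snrs), 1)
  expect_lt(mean(snrs), 2)
})

test_that("zero jitter and near-zero noise reproduce the clean template", {
  cfg <- quick_config(latency_jitter_sd = 0, noise_sigma = 1e-8)
  pr <- quick_preset()
  rec <- generate_eye(cfg, pr, seed = 9)
  ndb <- build_normative_db(1, cfg, pr, seed = 11)
  # per-sector latency against its own normative template is 0 everywhere
  lat <- vapply(seq_len(60), function(s)
    sector_latency(rec$data[s, best_channel(rec, s), ],
                   ndb$templates[s, ]), numeric(1))
  expect_true(all(lat == 0))
})

test_that("cohorts carry the study imbalance and event layout", {
  coh <- generate_cohort(5, 10, seed = 3)
  expect_length(coh$records, 15)
  expect_equal(sum(coh$labels$group == "RIS_conv"), 5)
  expect_equal(sum(coh$events$event), 5)
  expect_equal(sum(coh$events$event == 1 & coh$events$time_months <= 12), 4)
  expect_true(all(coh$events$time_months[coh$events$event == 0] >= 24))
  expect_named(coh$records[["P01"]], c("OD", "OS"))
  expect_s3_class(coh$records[["P01"]]$OD, "mfvep_record")

  none <- generate_cohort(0, 4, seed = 3)
  expect_true(all(none$events$event == 0))

  # labels and events are deterministic in the seed
  coh2 <- generate_cohort(5, 10, seed = 3)
  expect_identical(coh$events, coh2$events)
  expect_identical(coh$records$P05$OS$data, coh2$records$P05$OS$data)
})

test_that("normative database is the mean best-channel waveform", {
  cfg <- quick_config(latency_jitter_sd = 0, noise_sigma = 1e-8)
  pr <- quick_preset()
  ndb <- build_normative_db(1, cfg, pr, seed = 2)
  expect_equal(dim(ndb$templates), c(60L, 600L))
  # with negligible noise each template equals the clean filtered evoked
  # waveform up to the sector gain and amplitude
  clean <- bandpass_fft(evoked_waveform(cfg, pr))
  g <- default_sector_gains()
  for (s in c(1, 30, 60))
    expect_equal(ndb$templates[s, ], clean * g[s] * pr$amplitude_scale,
                 tolerance = 1e-6)
  expect_error(build_normative_db(0, cfg, pr), ">= 1")
})

test_that("normative-template noise shrinks with the averaging count", {
  cfg <- quick_config(latency_jitter_sd = 0)
  pr <- quick_preset()
  clean <- bandpass_fft(evoked_waveform(cfg, pr))
  g <- default_sector_gains()
  resid_rms <- function(n_healthy) {
    ndb <- build_normative_db(n_healthy, cfg, pr, seed = 7)
    mean(vapply(seq_len(60), function(s)
      rms(ndb$templates[s, ] - clean * g[s] * pr$amplitude_scale),
      numeric(1)))
  }
  r1 <- resid_rms(1)
  r9 <- resid_rms(9)
  # 1/sqrt(n) law on the noise part: expect about a 3x reduction
  expect_lt(r9, r1 / 2)
  expect_gt(r9, r1 / 4.5)
})
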