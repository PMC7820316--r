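test_that("db7 tabulation matches independently computed wavelet values", {
  # frozen reference values of psi(t) computed with PyWavelets
  # (wavefun level 10) during development
  ref <- c(`2` = -0.00480423187264002, `4` = 0.06517352154482071,
           `5.5` = 0.4728994335254816, `6` = 0.2780591401477177,
           `6.5` = -1.1013220144963554, `7` = 1.0488711750005346,
           `8` = 0.2231008686854197, `10` = -0.00043486509934189386)
  got <- mfvepris:::db7_psi(as.numeric(names(ref)))
  expect_equal(got, unname(ref), tolerance = 1e-12)
  expect_equal(mfvepris:::db7_psi(c(-1, 13.5)), c(0, 0))
  # unit L2 norm over the support
  tab <- mfvepris:::db7_wavefun(10)
  expect_equal(sum(tab$values^2) * tab$step, 1, tolerance = 1e-6)
})

test_that("CWT modulus is zero for zero input and homogeneous of degree 1", {
  scales <- c(4, 8, 16)
  z <- cwt_modulus(numeric(600), scales)
  expect_true(all(z$modulus == 0))
  expect_equal(nmax(z), 0L)
  expect_error(bmax(z), "all-zero")

  set.seed(3)
  x <- bandpass_fft(rnorm(600))
  r1 <- cwt_modulus(x, scales)
  r2 <- cwt_modulus(2 * x, scales)
  expect_equal(r2$modulus, 2 * r1$modulus, tolerance = 1e-12)

  expect_error(cwt_modulus(x, c(-1, 4)), "positive")
  expect_error(cwt_modulus(c(x[-1], NA), scales), "finite")
})

test_that("FFT CWT agrees with a direct double-loop integration oracle", {
  set.seed(5)
  n <- 64
  x <- rnorm(n)
  scales <- c(2, 3, 4)
  got <- cwt_modulus(x, scales, fs = 1200)$modulus
  # independent oracle: literal sum over t of x(t) psi((t - b')/a)/sqrt(a),
  # with b' the centre-aligned translation
  want <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    a <- scales[si]
    C <- round(13 * a / 2)
    for (b in 0:(n - 1)) {
      acc <- 0
      for (t in 0:(n - 1)) {
        arg <- (t - (b - C)) / a
        if (arg >= 0 && arg <= 13)
          acc <- acc + x[t + 1] * mfvepris:::db7_psi(arg) / sqrt(a)
      }
      want[si, b + 1] <- abs(acc)
    }
  }
  expect_lt(max(abs(got - want)) / max(want), 1e-6)
})

test_that("FFT and direct convolution engines agree", {
  set.seed(6)
  x <- bandpass_fft(rnorm(600))
  scales <- c(8, 16, 32)
  a <- cwt_modulus(x, scales, method = "fft")$modulus
  b <- cwt_modulus(x, scales, method = "direct")$modulus
  expect_lt(max(abs(a - b)) / max(b), 1e-9)
})

test_that("b_max finds a dilated db7 wavelet where it was planted", {
  a0 <- 20
  k <- 0:(13 * a0)
  w <- mfvepris:::db7_psi(k / a0)
  x <- numeric(600)
  C <- round(13 * a0 / 2)
  t0_idx <- 300
  x[(t0_idx - C) + k + 1] <- w
  r <- cwt_modulus(x)
  t0_ms <- (t0_idx) / 1200 * 1000
  expect_lt(abs(bmax(r) - t0_ms), 1)     # within ~one sample
})

test_that("b_max is shift-equivariant and amplitude-invariant", {
  x <- bandpass_fft(evoked_waveform(quick_config(), quick_preset(peak = 90)))
  r0 <- cwt_modulus(x)
  r1 <- cwt_modulus(mfvepris:::shift_waveform(x, 50))
  expect_equal(bmax(r1) - bmax(r0), 50 / 1200 * 1000, tolerance = 1e-9)
  expect_equal(bmax(cwt_modulus(3 * x)), bmax(r0))
  expect_equal(nmax(cwt_modulus(3 * x)), nmax(r0))
  expect_equal(nmax(r1), nmax(r0))       # shift-invariant count
})

test_that("local-maxima count matches an exhaustive scan on a clean bump", {
  x <- bandpass_fft(make_template(100, 12))
  r <- cwt_modulus(x)
  M <- r$modulus
  cut <- max(M) / 3
  naive <- 0L
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    v <- M[i, j]
    if (v <= cut) next
    nb <- M[max(1, i - 1):min(nrow(M), i + 1),
            max(1, j - 1):min(ncol(M), j + 1)]
    if (sum(nb == v) != 1) next              # plateau-free surface expected
    if (v > max(nb[nb != v])) naive <- naive + 1L
  }
  expect_equal(nmax(r), naive)
})

test_that("two well-separated bumps double the local-maxima count", {
  scales <- 4:16                     # dilated support <= 208 samples
  b1 <- make_template(125, 6)
  b2 <- mfvepris:::shift_waveform(b1, 300)   # identical copy at 375 ms
  one <- cwt_modulus(b1, scales)
  both <- cwt_modulus(b1 + b2, scales)
  expect_equal(nmax(both), 2L * nmax(one))
})

test_that("raising the threshold never increases the count", {
  set.seed(12)
  for (i in 1:3) {
    x <- bandpass_fft(rnorm(600))
    r <- cwt_modulus(x)
    expect_lte(nmax(r, 1 / 2), nmax(r, 1 / 3))
  }
})

test_that("eye-level scalogram means reduce to single-sector values", {
  one <- generate_eye(quick_config(), quick_preset(), seed = 18)
  rep_rec <- mfvep_record(one$data[rep(2, 60), , , drop = FALSE])
  bc <- best_channel(rep_rec, 1)
  r <- cwt_modulus(rep_rec$data[1, bc, ])
  out <- eye_cwt_features(rep_rec)
  expect_equal(out$bmax_mean, bmax(r))
  expect_equal(out$nmax_mean, as.numeric(nmax(r)))
  # fast path (no local-maxima count) gives the same b_max
  out2 <- eye_cwt_features(rep_rec, compute_nmax = FALSE)
  expect_equal(out2$bmax_mean, out$bmax_mean)
})

test_that("zero jitter makes per-sector b_max deterministic across sectors", {
  cfg <- quick_config(latency_jitter_sd = 0, noise_sigma = 1e-8)
  rec <- generate_eye(cfg, quick_preset(), seed = 4)
  out <- eye_cwt_features(rec, per_sector = TRUE, compute_nmax = FALSE)
  expect_equal(sd(out$bmax_sector), 0)
})
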