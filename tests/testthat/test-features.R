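fs <- 128
tt <- (0:511) / fs
tone10 <- sin(2 * pi * 10 * tt)

test_that("Welch density matches flat-spectrum and pure-tone oracles", {
  cfg <- welch_config(fs)
  expect_true(all(welch_psd(rep(0, 512), cfg)$s == 0))

  set.seed(3)
  w <- rnorm(2^15)
  p <- welch_psd(w, cfg)
  inner <- p$s[p$freq > 0 & p$freq < fs / 2]
  # unit-variance white noise has one-sided density 2/fs = 1/64 per Hz
  expect_equal(mean(inner), 1 / 64, tolerance = 0.1)
  # Parseval: integrated density ~ signal variance
  expect_equal(sum(p$s) * fs / cfg$L, stats::var(w), tolerance = 0.1)

  long_tone <- sin(2 * pi * 10 * (0:(2^15 - 1)) / fs)
  p2 <- welch_psd(long_tone, welch_config(fs, L = 256))
  expect_equal(p2$freq[which.max(p2$s)], 10)
  expect_error(welch_psd(rnorm(64), welch_config(fs, L = 128)), "shorter")
})

test_that("PSD band features follow the alpha/beta/gamma/delta layout", {
  p <- welch_psd(tone10, welch_config(fs, L = 256))
  f <- psd_band_features(p)
  expect_length(f, 12)
  expect_named(f, c(t(outer(paste0("psd_", c("alpha", "beta", "gamma",
                                             "delta")),
                            c("max", "mean", "var"), paste, sep = "_"))))
  expect_gt(f["psd_alpha_max"], f["psd_beta_max"])
  expect_gt(f["psd_alpha_max"], f["psd_gamma_max"])
  expect_gt(f["psd_alpha_max"], f["psd_delta_max"])
  # flat synthetic spectrum: every band mean equal, variance 0
  flat <- list(s = rep(3, 65), freq = (0:64) * fs / 128)
  ff <- psd_band_features(flat)
  expect_true(all(ff[grep("mean", names(ff))] == 3))
  expect_true(all(ff[grep("var", names(ff))] == 0))
  expect_error(
    psd_band_features(p, bands = list(alpha = c(8, 13), beta = c(13, 30),
                                      gamma = c(63.9, 64), delta = c(0.5, 4))),
    "gamma")
})

test_that("Hjorth parameters match the analytic sinusoid values", {
  long10 <- sin(2 * pi * 10 * (0:(2^14 - 1)) / fs)
  h <- hjorth_features(long10, welch_config(fs, L = 256))
  expect_length(h, 9)
  # mobility of a pure f Hz tone is 2*pi*f rad/s; complexity is 1
  expect_equal(unname(h["hjorth_mobility_mean"]), 2 * pi * 10,
               tolerance = 0.02)
  expect_equal(unname(h["hjorth_complexity_mean"]), 1, tolerance = 0.02)
  # activity equals the segment sample variance (constant across segments)
  seg_var <- stats::var(long10[1:256])
  expect_equal(unname(h["hjorth_activity_mean"]), seg_var, tolerance = 1e-6)
  expect_error(hjorth_features(rep(1, 512), welch_config(fs)), "constant")
})

test_that("Hjorth complexity grows with signal bandwidth", {
  # complexity is a relative-bandwidth measure: a narrowband signal (tone
  # plus a little noise) must score lower than broadband white noise
  cfg <- welch_config(fs)
  t_long <- (0:2047) / fs
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    narrow <- sin(2 * pi * 10 * t_long) + 0.01 * rnorm(2048)
    broad <- rnorm(2048)
    h_n <- hjorth_features(narrow, cfg)["hjorth_complexity_mean"]
    h_b <- hjorth_features(broad, cfg)["hjorth_complexity_mean"]
    if (h_n < h_b) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("Morlet amplitudes are frequency selective and scale linearly", {
  cfg <- wavelet_config(fs)
  expect_true(all(cwt_features(rep(0, 512), cfg) == 0))
  cw <- cwt_features(tone10, cfg)
  expect_length(cw, 12)
  expect_gt(cw["cwt_alpha_mean"], cw["cwt_beta_mean"])
  expect_gt(cw["cwt_alpha_mean"], cw["cwt_gamma_mean"])
  expect_gt(cw["cwt_alpha_mean"], cw["cwt_delta_mean"])
  cw3 <- cwt_features(3 * tone10, cfg)
  expect_equal(unname(cw3[c("cwt_alpha_max", "cwt_alpha_mean")]),
               3 * unname(cw[c("cwt_alpha_max", "cwt_alpha_mean")]),
               tolerance = 1e-9)
  expect_equal(unname(cw3["cwt_alpha_var"]), 9 * unname(cw["cwt_alpha_var"]),
               tolerance = 1e-9)
  expect_warning(wavelet_config(fs = 96), "Nyquist")
})

test_that("the discrete transform reconstructs perfectly and places the tone
           in alpha", {
  set.seed(10)
  z <- rnorm(512)
  dec <- dwt_decompose(z, 6)
  recon <- Reduce(`+`, dec$details) + dec$approx
  expect_lt(max(abs(recon - z)), 1e-8)
  expect_error(dwt_decompose(rnorm(100), 6), "multiple")

  cfg <- wavelet_config(fs)
  expect_true(all(dwt_features(rep(0, 512), cfg) == 0))
  dw <- dwt_features(tone10, cfg)
  expect_length(dw, 12)
  expect_gt(dw["dwt_alpha_mean"], dw["dwt_beta_mean"])
  expect_gt(dw["dwt_alpha_mean"], dw["dwt_gamma_mean"])
  expect_gt(dw["dwt_alpha_mean"], dw["dwt_delta_mean"])
})

test_that("a signal yields exactly 45 deterministic, amplitude-equivariant
           features", {
  set.seed(4)
  y <- tone10 + 0.3 * rnorm(512)
  f1 <- extract_signal_features(y, fs)
  expect_length(f1, 45)
  expect_false(anyDuplicated(names(f1)) > 0)
  expect_true(all(is.finite(f1)))
  expect_identical(f1, extract_signal_features(y, fs))

  # amplitude equivariance: k on amplitudes, k^2 on powers/variances,
  # Hjorth mobility/complexity invariant
  f2 <- extract_signal_features(2 * y, fs)
  amp <- grep("^(cwt|dwt)_.*_(max|mean)$", names(f1), value = TRUE)
  expect_equal(unname(f2[amp]), 2 * unname(f1[amp]), tolerance = 1e-8)
  pow <- grep("^psd_.*_(max|mean)$", names(f1), value = TRUE)
  expect_equal(unname(f2[pow]), 4 * unname(f1[pow]), tolerance = 1e-8)
  inv <- grep("hjorth_(mobility|complexity)", names(f1), value = TRUE)
  expect_equal(unname(f2[inv]), unname(f1[inv]), tolerance = 1e-8)

  expect_error(extract_signal_features(rep(0, 512), fs), "hjorth")
})

test_that("circular shifts barely move band means of a stationary signal", {
  set.seed(6)
  y <- as.numeric(stats::filter(rnorm(4096), rep(1 / 4, 4), circular = TRUE))
  f1 <- extract_signal_features(y, fs)
  f2 <- extract_signal_features(c(y[-(1:100)], y[1:100]), fs)
  means <- grep("_(mean)$", names(f1), value = TRUE)
  rel <- abs(f2[means] - f1[means]) / pmax(abs(f1[means]), 1e-12)
  expect_lt(max(rel), 0.05)
})

test_that("the trial-by-feature matrix assembles 45 columns per signal", {
  set.seed(5)
  trials <- lapply(1:3, function(i) matrix(rnorm(2 * 512), 2))
  Xi <- build_feature_matrix(trials, fs)
  expect_equal(dim(Xi), c(3, 90))
  expect_equal(anyDuplicated(colnames(Xi)), 0)
  expect_true(all(grepl("^s0[12]::", colnames(Xi))))

  one <- build_feature_matrix(list(matrix(rnorm(512), 1)), fs)
  expect_equal(dim(one), c(1, 45))

  ragged <- list(matrix(rnorm(2 * 512), 2), matrix(rnorm(3 * 512), 3))
  expect_error(build_feature_matrix(ragged, fs), "same signal count")
})
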