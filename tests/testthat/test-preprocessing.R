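test_that("epoch averaging is the pointwise mean with merged labels", {
  t <- seq(-100, 899, by = 1)
  x <- toy_epoch(sin(t / 50), time_ms = t, group = "elderly",
                 condition = "correct")
  expect_equal(average_epochs(list(x))$amplitude_uV, x$amplitude_uV)

  neg <- toy_epoch(-x$amplitude_uV, time_ms = t, group = "elderly",
                   condition = "incorrect")
  avg <- average_epochs(list(x, neg))
  expect_true(all(avg$amplitude_uV == 0))
  expect_identical(avg$group, "elderly")        # uniform label kept
  expect_identical(avg$condition, NA_character_) # mixed label dropped

  expect_error(average_epochs(list()), "empty")
  shifted <- toy_epoch(x$amplitude_uV, time_ms = t + 1)
  expect_error(average_epochs(list(x, shifted)), "time axes")
})

test_that("averaging n noisy epochs shrinks the residual like 1/sqrt(n)", {
  t <- seq(-100, 899, by = 1)
  clean <- bump_trace(t, 400, 8, 30)
  sigma <- 2
  set.seed(11)
  eps <- lapply(1:50, function(i) {
    toy_epoch(clean + rnorm(length(t), sd = sigma), time_ms = t)
  })
  resid <- average_epochs(eps)$amplitude_uV - clean
  expect_equal(sd(resid), sigma / sqrt(50), tolerance = 0.15)
})

test_that("ROI averaging picks and averages the named channels", {
  t <- seq(-100, 399, by = 1)
  a <- sin(t / 40)
  b <- cos(t / 25)
  ch <- cbind(Pz = a, Oz = b, Cz = a * 0 + 1)
  me <- erp_multichannel(t, ch, 1000)
  expect_equal(roi_average(me, "Pz")$amplitude_uV, a)
  expect_equal(roi_average(me, c("Pz", "Oz"))$amplitude_uV, (a + b) / 2)
  twelve <- matrix(rep(a, 12), ncol = 12)
  colnames(twelve) <- paste0("ch", 1:12)
  expect_equal(roi_average(erp_multichannel(t, twelve, 1000),
                           paste0("ch", 1:12))$amplitude_uV, a)
  expect_error(roi_average(me, c("Pz", "POz")), "POz")
})

test_that("moving-average smoothing matches the direct convolution oracle", {
  expect_equal(smooth_signal(rep(5, 100), 20, 1000), rep(5, 100))

  # unit impulse at 1000 Hz, 20 ms window: forced-odd 21-sample window
  imp <- c(rep(0, 200), 1, rep(0, 200))
  sm <- smooth_signal(imp, 20, 1000)
  expect_equal(sm[191:211], rep(1 / 21, 21))
  expect_true(all(sm[c(1:190, 212:401)] == 0))

  # 100 Hz sinusoid attenuated below 0.2x by the 21-sample window
  t <- seq(0, 0.999, by = 1e-3)
  s <- sin(2 * pi * 100 * t)
  sm <- smooth_signal(s, 20, 1000)
  expect_lt(max(abs(sm[100:900])), 0.2)
  # the attenuation agrees with the moving-average frequency response
  gain <- abs(sum(exp(2i * pi * 100 * (-10:10) / 1000))) / 21
  expect_equal(max(abs(sm[100:900])), gain, tolerance = 0.05)

  expect_error(smooth_signal(1:5, 20, 1000), "longer than the signal")
})

test_that("zero-phase band-pass keeps in-band content unshifted and kills
           out-of-band content", {
  expect_true(all(zero_phase_bandpass(numeric(500),
                                      sample_rate_hz = 1000) == 0))

  t <- seq(0, 2.999, by = 1e-3)
  in_band <- sin(2 * pi * 10 * t)
  out <- zero_phase_bandpass(in_band, sample_rate_hz = 1000)
  core <- 500:2500  # away from the filter transients at the edges
  gain <- as.numeric(coef(lm(out[core] ~ in_band[core] - 1)))
  expect_gte(gain, 0.95)
  expect_lte(gain, 1.05)
  # lag of maximum cross-correlation is zero
  cc <- ccf(out[core], in_band[core], lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  low <- sin(2 * pi * 1 * t)
  filt_low <- zero_phase_bandpass(low, sample_rate_hz = 1000)
  expect_lt(max(abs(filt_low[core])), 0.2)

  expect_error(zero_phase_bandpass(in_band, band_hz = c(4, 600),
                                   sample_rate_hz = 1000), "Nyquist")
})

test_that("variants compose as documented and preserve length", {
  t <- seq(-200, 1299, by = 1)
  ep <- toy_epoch(bump_trace(t, c(300, 600), c(-4, 6), c(25, 30)) +
                    sin(t / 90), time_ms = t)
  expect_identical(apply_variant(ep, "original_avg")$amplitude_uV,
                   ep$amplitude_uV)
  sm <- apply_variant(ep, "smoothed")
  expect_equal(sm$amplitude_uV,
               smooth_signal(ep$amplitude_uV, 20, 1000))
  zp <- apply_variant(ep, "zero_phase")
  zps <- apply_variant(ep, "zero_phase_smoothed")
  expect_equal(zps$amplitude_uV,
               smooth_signal(zp$amplitude_uV, 20, 1000))
  for (v in c("original_avg", "smoothed", "zero_phase",
              "zero_phase_smoothed")) {
    out <- apply_variant(ep, v)
    expect_length(out$amplitude_uV, length(ep$amplitude_uV))
    expect_identical(out$variant, v)
  }
  expect_error(preprocessing_variant("bandstop"))
})

test_that("every variant is linear", {
  t <- seq(-200, 1299, by = 1)
  set.seed(21)
  x <- toy_epoch(rnorm(length(t)), time_ms = t)
  y <- toy_epoch(bump_trace(t, 400, 5, 40), time_ms = t)
  combo <- toy_epoch(2 * x$amplitude_uV - 3 * y$amplitude_uV, time_ms = t)
  for (v in c("smoothed", "zero_phase", "zero_phase_smoothed")) {
    lhs <- apply_variant(combo, v)$amplitude_uV
    rhs <- 2 * apply_variant(x, v)$amplitude_uV -
      3 * apply_variant(y, v)$amplitude_uV
    # forward-backward filtering of a near-unstable low-band design loses
    # a few digits to cancellation, so the tolerance is looser than
    # machine precision
    expect_equal(lhs, rhs, tolerance = 1e-5)
  }
})
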