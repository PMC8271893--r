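test_that("N200 detection picks the deepest local minimum in its window", {
  t <- seq(-100, 1099, by = 1)
  ep <- toy_epoch(bump_trace(t, 250, -5, 20), time_ms = t)
  expect_equal(detect_n200(ep), 250)

  two <- toy_epoch(bump_trace(t, c(180, 300), c(-2, -5), c(15, 15)),
                   time_ms = t)
  expect_equal(detect_n200(two), 300)

  rising <- toy_epoch(t / 100, time_ms = t)
  expect_equal(detect_n200(rising), 150)  # window start is the minimum

  short <- toy_epoch(rnorm(100), time_ms = seq(-50, 49, by = 1))
  expect_error(detect_n200(short), "outside the epoch span")
})

test_that("P300 detection falls back to the fixed-gap-time window", {
  t <- seq(-100, 1099, by = 1)
  ep <- toy_epoch(bump_trace(t, 350, 6, 25), time_ms = t)
  hit <- detect_p300(ep, n200_ms = 230)
  expect_equal(hit$latency_ms, 350)
  expect_false(hit$via_fgt)

  # strictly increasing across 250-500 with a local max at 560:
  # no interior peak in the standard window, so the FGT window
  # [330+150, 330+350] finds it (ramp plateaus at 500 so the bump peak
  # stays exactly at 560)
  late <- toy_epoch(pmin(t, 500) / 100 + bump_trace(t, 560, 4, 25),
                    time_ms = t)
  hit <- detect_p300(late, n200_ms = 330)
  expect_equal(hit$latency_ms, 560)
  expect_true(hit$via_fgt)

  # monotone trace without any local max anywhere: global max of the
  # FGT window, still flagged via_fgt
  mono <- toy_epoch(t / 100, time_ms = t)
  hit <- detect_p300(mono, n200_ms = 300)
  expect_true(hit$via_fgt)
  expect_equal(hit$latency_ms, 300 + 250 + 100)

  # FGT guarantee: via_fgt results stay within n200 + 250 +/- 100
  for (seed in 1:25) {
    ep <- random_trace(seed)
    n200 <- detect_n200(ep)
    hit <- suppressWarnings(detect_p300(ep, n200))
    if (hit$via_fgt) {
      expect_lte(abs(hit$latency_ms - (n200 + 250)), 100)
      expect_gte(hit$latency_ms, n200 + 150)
      expect_lte(hit$latency_ms, n200 + 350)
    }
  }

  ts <- seq(-100, 519, by = 1)
  stub <- toy_epoch(ts / 100, time_ms = ts)  # no peak; FGT needs 690 ms
  expect_error(detect_p300(stub, n200_ms = 340), "beyond the epoch end")
})

test_that("N400/P600 searches start after the preceding component", {
  t <- seq(-100, 1099, by = 1)
  ep <- toy_epoch(bump_trace(t, 510, -5, 20), time_ms = t)
  expect_equal(detect_n400(ep, p300_ms = 400), 510)

  two <- toy_epoch(bump_trace(t, c(300, 540), c(-6, -4), c(15, 15)),
                   time_ms = t)
  expect_equal(detect_n400(two, p300_ms = 400), 540)  # 300 is before P300

  flat <- toy_epoch(rep(1, length(t)), time_ms = t)
  expect_equal(detect_n400(flat, p300_ms = 400), 400)  # range start
  expect_warning(out <- detect_n400(flat, p300_ms = 620), "empty")
  expect_true(is.na(out))

  ep6 <- toy_epoch(bump_trace(t, 640, 6, 25), time_ms = t)
  expect_equal(detect_p600(ep6, n400_ms = 520), 640)
  two6 <- toy_epoch(bump_trace(t, c(520, 660), c(8, 5), c(15, 15)),
                    time_ms = t)
  expect_equal(detect_p600(two6, n400_ms = 530), 660)  # 520 is before N400
})

test_that("detectors agree with the brute-force oracle on random traces", {
  for (seed in 1:100) {
    ep <- random_trace(seed)
    want <- oracle_detect(ep)
    got <- suppressWarnings(detect_components(ep))
    expect_equal(got$n200_ms, want$n200)
    expect_equal(got$p300_ms, want$p300)
    expect_identical(got$p300_via_fgt, want$via_fgt)
    expect_equal(got$n400_ms, want$n400)
    expect_equal(got$p600_ms, want$p600)
  }
})

test_that("detected components are ordered on noiseless defaults", {
  for (g in c("elderly", "youth")) {
    for (cond in c("correct", "incorrect")) {
      cfg <- synthetic_config(g, cond, noise_sd_uV = 0)
      det <- detect_components(make_erp_epoch(cfg, seed = 1))
      lats <- c(det$n200_ms, det$p300_ms, det$n400_ms, det$p600_ms)
      expect_false(is.unsorted(lats, strictly = TRUE))
    }
  }
})

test_that("the prominence threshold filters shallow peaks", {
  t <- seq(-100, 1099, by = 1)
  # a 0.5 uV ripple on a rising flank plus a genuine 6 uV peak at 560
  x <- t / 200 + bump_trace(t, c(420, 560), c(0.5, 6), c(10, 20))
  ep <- toy_epoch(x, time_ms = t)
  loose <- detect_p300(ep, n200_ms = 230,
                       detection_config(prominence_uV = 0))
  expect_false(loose$via_fgt)  # the ripple counts as an interior peak
  strict <- detect_p300(ep, n200_ms = 230,
                        detection_config(prominence_uV = 2))
  expect_true(strict$via_fgt)  # ripple rejected; falls back to FGT
})

test_that("feature windows cut 1 s from the N200 and resample to 70", {
  cfg <- synthetic_config("elderly", noise_sd_uV = 0)
  ep <- make_erp_epoch(cfg, seed = 1)
  seg <- extract_feature_window(ep, 236)
  expect_length(seg$amplitude_uV, 1000)
  expect_equal(seg$time_ms[1], 236)
  expect_equal(seg$time_ms[length(seg$time_ms)], 1235)
  idx <- which(ep$time_ms >= 236 & ep$time_ms < 1236)
  expect_identical(seg$amplitude_uV, ep$amplitude_uV[idx])

  short <- toy_epoch(rnorm(500), time_ms = seq(-100, 399, by = 1))
  expect_error(extract_feature_window(short, 236), "does not cover")

  expect_length(resample_features(seg), 70)
  const <- list(time_ms = 0:99, amplitude_uV = rep(3.5, 100))
  expect_equal(resample_features(const, 70), rep(3.5, 70))
  ramp <- list(time_ms = 0:99, amplitude_uV = seq(0, 1, length.out = 100))
  expect_equal(resample_features(ramp, 70), seq(0, 1, length.out = 70))
  expect_equal(resample_features(ramp, 100), ramp$amplitude_uV)
  expect_error(resample_features(ramp, 1), "at least 2")
})
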