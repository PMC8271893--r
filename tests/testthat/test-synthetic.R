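test_that("component and config validation enforce polarity and ordering", {
  expect_error(erp_component("N200", 250, 5, 20), "negative amplitude")
  expect_error(erp_component("P300", 350, -5, 20), "positive amplitude")
  expect_error(erp_component("P300", 350, 5, -1), "width_ms")
  comps <- list(erp_component("P300", 398, 8, 20),
                erp_component("N200", 450, -5, 15))
  expect_error(synthetic_config("elderly", components = comps),
               "strictly increase")
  expect_error(synthetic_config("elderly", epoch_span_ms = c(100, 2000)),
               "start < 0 < end")
  expect_error(synthetic_config("elderly", noise_sd_uV = -1), "noise_sd_uV")
  expect_error(synthetic_config("elderly", p_different = 1.5), "p_different")
})

test_that("noiseless epochs carry exactly the configured morphology", {
  cfg0 <- synthetic_config("elderly", components = list(), noise_sd_uV = 0)
  expect_true(all(make_erp_epoch(cfg0, seed = 1)$amplitude_uV == 0))

  cfg <- synthetic_config("elderly", "correct", noise_sd_uV = 0)
  ep <- make_erp_epoch(cfg, seed = 1)
  det <- detect_components(ep)
  # configured latencies are the oracle; recovery within one sample period
  expect_equal(det$n200_ms, 236, tolerance = 0, ignore_attr = TRUE)
  expect_lte(abs(det$p300_ms - 398), 1)
  expect_lte(abs(det$n400_ms - 509), 1)
  expect_lte(abs(det$p600_ms - 640), 1)

  # incorrect condition shifts each component by the configured gap
  cfg_i <- synthetic_config("elderly", "incorrect", noise_sd_uV = 0)
  det_i <- detect_components(make_erp_epoch(cfg_i, seed = 1))
  shifts <- default_latency_shifts("elderly")
  expect_lte(abs(det_i$n200_ms - (236 + shifts[["N200"]])), 1)
  expect_lte(abs(det_i$p300_ms - (398 + shifts[["P300"]])), 1)
  expect_lte(abs(det_i$n400_ms - (509 + shifts[["N400"]])), 1)
  expect_lte(abs(det_i$p600_ms - (640 + shifts[["P600"]])), 1)
})

test_that("identical config and seed give identical traces", {
  cfg <- synthetic_config("youth", "incorrect")
  a <- make_erp_epoch(cfg, seed = 42)
  b <- make_erp_epoch(cfg, seed = 42)
  expect_identical(a$amplitude_uV, b$amplitude_uV)
  c <- make_erp_epoch(cfg, seed = 43)
  expect_false(identical(a$amplitude_uV, c$amplitude_uV))
})

test_that("incorrect trials carry the configured extra fluctuation", {
  base <- synthetic_config("elderly", "correct", components = list(),
                           noise_sd_uV = 3, fluctuation_gain_incorrect = 2)
  noisy <- synthetic_config("elderly", "incorrect", components = list(),
                            noise_sd_uV = 3, fluctuation_gain_incorrect = 2)
  sd_c <- sd(make_erp_epoch(base, seed = 7)$amplitude_uV)
  sd_i <- sd(make_erp_epoch(noisy, seed = 7)$amplitude_uV)
  expect_equal(sd_c, 3, tolerance = 1e-6)
  expect_equal(sd_i, 6, tolerance = 1e-6)
})

test_that("trial logs respect counts, error rate and the different/same mix", {
  cfg <- synthetic_config("elderly")
  expect_equal(nrow(make_trial_log(cfg, 0, seed = 1)), 0)

  # count conservation: n_subjects x 3 shapes x n_trials_per_shape
  log4 <- make_trial_log(cfg, 4, seed = 1)
  expect_equal(nrow(log4), 4 * 3 * 20)
  expect_equal(length(unique(log4$subject_id)), 4)

  # Go/Nogo correctness invariant holds row by row
  implied <- (log4$is_different & log4$response == "left") |
    (!log4$is_different & log4$response == "right")
  expect_identical(log4$is_correct, implied)
  expect_true(all(!log4$is_correct[log4$response == "none"]))
  expect_true(all(is.na(log4$response_time_ms[log4$response == "none"])))
  expect_true(all(log4$response_time_ms[log4$response != "none"] <= 1800))

  # ~2000 trials at error_rate 0.2: empirical rate inside the 99% binomial
  # interval [0.18, 0.22]
  cfg2 <- synthetic_config("elderly", error_rate = 0.2)
  log_big <- make_trial_log(cfg2, 34, seed = 5)
  expect_equal(nrow(log_big), 2040)
  expect_gte(mean(!log_big$is_correct), 0.18)
  expect_lte(mean(!log_big$is_correct), 0.22)

  # share of "different" trials within 3 binomial SDs of 0.75
  p_hat <- mean(log_big$is_different)
  expect_lte(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / nrow(log_big)))
})

test_that("dataset bundles conserve counts and are reproducible", {
  cfgs <- default_dataset_configs("elderly")
  b <- make_dataset(cfgs, n_subjects = 1, seed = 3)
  expect_equal(nrow(b$trials), 60)        # one subject, 3 shapes, 20 trials
  expect_equal(length(b$epochs), 60)      # one epoch per trial
  # epoch condition labels mirror the trial outcomes
  conds <- vapply(b$epochs, `[[`, character(1), "condition")
  expect_identical(conds,
                   ifelse(b$trials$is_correct, "correct", "incorrect"))

  dup <- list(elderly = cfgs$elderly, elderly = cfgs$elderly)
  expect_error(make_dataset(dup, n_subjects = 1, seed = 1), "duplicate")

  # fixed seed: byte-identical serialized bundles
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_epoch_bundle(make_dataset(cfgs, n_subjects = 1, seed = 9), f1)
  write_epoch_bundle(make_dataset(cfgs, n_subjects = 1, seed = 9), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("configured P300 shift is recovered from grand-average traces", {
  # Monte-Carlo: the +29 ms elderly shift parameter is the oracle
  gap_one_seed <- function(seed) {
    b <- make_dataset(default_dataset_configs("elderly"),
                      n_subjects = 4, seed = seed)
    cond <- vapply(b$epochs, `[[`, character(1), "condition")
    det <- lapply(c("correct", "incorrect"), function(cd) {
      grand <- average_epochs(b$epochs[cond == cd])
      detect_components(apply_variant(grand, "zero_phase_smoothed"))
    })
    det[[2]]$p300_ms - det[[1]]$p300_ms
  }
  gaps <- vapply(1:15, gap_one_seed, numeric(1))
  expect_lte(abs(mean(gaps) - 29), 5)
})
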