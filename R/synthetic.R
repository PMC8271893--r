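#' ERP component specification
#'
#' One deflection of the simulated event-related potential, modelled as a
#' Gaussian bump `amplitude * exp(-(t - latency)^2 / (2 * width^2))`.
#' Negative components (N200, N400) must have negative amplitude, positive
#' components (P300, P600) positive amplitude.
#'
#' @param name One of `"N200"`, `"P300"`, `"N400"`, `"P600"`.
#' @param latency_ms Peak latency in ms after stimulus onset (> 0).
#' @param amplitude_uV Peak amplitude in microvolts (sign fixed by `name`).
#' @param width_ms Standard deviation of the Gaussian bump in ms (> 0).
#' @return An object of class `erp_component`.
#' @export
erp_component <- function(name, latency_ms, amplitude_uV, width_ms) {
  name <- match.arg(name, c("N200", "P300", "N400", "P600"))
  if (!is.finite(latency_ms) || latency_ms <= 0) {
    stop("latency_ms must be positive")
  }
  if (!is.finite(width_ms) || width_ms <= 0) {
    stop("width_ms must be positive")
  }
  negative <- name %in% c("N200", "N400")
  if (negative && amplitude_uV >= 0) {
    stop(name, " must have negative amplitude")
  }
  if (!negative && amplitude_uV <= 0) {
    stop(name, " must have positive amplitude")
  }
  structure(
    list(name = name, latency_ms = latency_ms,
         amplitude_uV = amplitude_uV, width_ms = width_ms),
    class = "erp_component"
  )
}

#' Default ERP components per group
#'
#' Component latencies default to the group-level mean correct-answer
#' latencies observed in the traffic-sign Go/Nogo study this package models
#' (elderly: 236/398/509/640 ms, youth: 220/396/507/626 ms for
#' N200/P300/N400/P600). Amplitudes and widths are the package's own choices
#' of realistic smoothed-ERP morphology; see the methods vignette.
#'
#' @param group `"elderly"` or `"youth"`.
#' @return List of four [erp_component()] objects in temporal order.
#' @export
default_components <- function(group = c("elderly", "youth")) {
  group <- match.arg(group)
  lat <- switch(group,
    elderly = c(N200 = 236, P300 = 398, N400 = 509, P600 = 640),
    youth   = c(N200 = 220, P300 = 396, N400 = 507, P600 = 626)
  )
  amp <- c(N200 = -5, P300 = 8, N400 = -5, P600 = 6)
  wid <- c(N200 = 15, P300 = 20, N400 = 18, P600 = 20)
  lapply(names(lat), function(nm) {
    erp_component(nm, lat[[nm]], amp[[nm]], wid[[nm]])
  })
}

#' Default incorrect-answer latency shifts per group
#'
#' The per-component latency difference (incorrect minus correct, ms) applied
#' when simulating incorrect-answer epochs: elderly +12/+29/+14/-12, youth
#' +32/+31/-7/+20 for N200/P300/N400/P600, the gap times observed in the
#' study this package models.
#'
#' @inheritParams default_components
#' @return Named numeric vector of shifts in ms.
#' @export
default_latency_shifts <- function(group = c("elderly", "youth")) {
  group <- match.arg(group)
  switch(group,
    elderly = c(N200 = 12, P300 = 29, N400 = 14, P600 = -12),
    youth   = c(N200 = 32, P300 = 31, N400 = -7, P600 = 20)
  )
}

#' Default per-shape error rates per group
#'
#' Probability of an incorrect answer per traffic-sign shape, defaulting to
#' the published per-shape error percentages (elderly 24.1/18.5/19.8%,
#' youth 12.4/16.2/15.3% for triangle/circle/rectangle).
#'
#' @inheritParams default_components
#' @return Named numeric vector of probabilities.
#' @export
default_error_rates <- function(group = c("elderly", "youth")) {
  group <- match.arg(group)
  switch(group,
    elderly = c(triangle = 0.241, circle = 0.185, rectangle = 0.198),
    youth   = c(triangle = 0.124, circle = 0.162, rectangle = 0.153)
  )
}

#' Configuration of the synthetic Go/Nogo ERP generator
#'
#' Bundles every knob of the simulator: the component set, the
#' incorrect-answer latency shifts, the band-limited noise model, the
#' fluctuation gain applied to incorrect trials, the sampling grid, and the
#' behavioral task parameters (20 trials per shape, 75% "different" stimuli,
#' 1.8 s response window).
#'
#' @param group `"elderly"` or `"youth"`.
#' @param condition `"correct"` or `"incorrect"`; incorrect epochs get the
#'   latency shifts and the fluctuation gain.
#' @param components List of [erp_component()] objects with strictly
#'   increasing latencies in the order N200 < P300 < N400 < P600.
#' @param incorrect_latency_shift_ms Named per-component shift in ms added to
#'   the latencies when `condition = "incorrect"`.
#' @param noise_sd_uV Standard deviation (uV) of the band-limited noise added
#'   to each epoch (after band-passing), >= 0.
#' @param noise_band_hz Length-2 pass band (Hz) of the noise.
#' @param fluctuation_gain_incorrect Multiplier (>= 1) on the noise sd for
#'   incorrect-condition epochs ("fluctuation is more severe" on errors).
#' @param sample_rate_hz Sampling rate in Hz (default 1000).
#' @param epoch_span_ms Length-2 epoch span in ms, closed at the start and
#'   open at the end, with `start < 0 < end` (default -1000..2000).
#' @param n_trials_per_shape Trials per traffic-sign shape (default 20).
#' @param p_different Probability that a trial shows a "different" pair
#'   (default 0.75).
#' @param error_rate Scalar or named per-shape probability of an incorrect
#'   answer.
#' @param no_response_share Share of incorrect trials that are timeouts
#'   (response `"none"`) rather than wrong clicks (default 0.2).
#' @param response_window_ms Response deadline in ms (default 1800).
#' @param rt_mean_ms,rt_sd_ms Response-time distribution (normal, truncated
#'   to 150 ms..deadline); the default mean is 900 ms for elderly and 700 ms
#'   for youth.
#' @param stimulus_duration_ms Stimulus display duration recorded as
#'   metadata (default 200 ms; not used by the simulation itself).
#' @param seed Optional integer seed recorded in the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(group = c("elderly", "youth"),
                             condition = c("correct", "incorrect"),
                             components = default_components(group),
                             incorrect_latency_shift_ms =
                               default_latency_shifts(group),
                             noise_sd_uV = 4,
                             noise_band_hz = c(4, 30),
                             fluctuation_gain_incorrect = 2,
                             sample_rate_hz = 1000,
                             epoch_span_ms = c(-1000, 2000),
                             n_trials_per_shape = 20L,
                             p_different = 0.75,
                             error_rate = default_error_rates(group),
                             no_response_share = 0.2,
                             response_window_ms = 1800,
                             rt_mean_ms = NULL,
                             rt_sd_ms = 150,
                             stimulus_duration_ms = 200,
                             seed = NULL) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  if (length(components) > 0) {
    ok <- vapply(components, inherits, logical(1), "erp_component")
    if (!all(ok)) stop("components must be erp_component objects")
    lats <- vapply(components, `[[`, numeric(1), "latency_ms")
    ord <- match(vapply(components, `[[`, character(1), "name"),
                 c("N200", "P300", "N400", "P600"))
    if (is.unsorted(ord, strictly = TRUE) ||
        is.unsorted(lats, strictly = TRUE)) {
      stop("component latencies must strictly increase in the order ",
           "N200 < P300 < N400 < P600")
    }
  }
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive")
  }
  if (noise_sd_uV < 0) stop("noise_sd_uV must be >= 0")
  if (fluctuation_gain_incorrect < 1) {
    stop("fluctuation_gain_incorrect must be >= 1")
  }
  if (length(epoch_span_ms) != 2 || epoch_span_ms[1] >= 0 ||
      epoch_span_ms[2] <= 0) {
    stop("epoch_span_ms must satisfy start < 0 < end")
  }
  if (p_different < 0 || p_different > 1) {
    stop("p_different must lie in [0, 1]")
  }
  if (any(error_rate < 0) || any(error_rate > 1)) {
    stop("error_rate must lie in [0, 1]")
  }
  if (no_response_share < 0 || no_response_share > 1) {
    stop("no_response_share must lie in [0, 1]")
  }
  if (is.null(rt_mean_ms)) {
    rt_mean_ms <- if (group == "elderly") 900 else 700
  }
  structure(
    list(
      group = group, condition = condition, components = components,
      incorrect_latency_shift_ms = incorrect_latency_shift_ms,
      noise_sd_uV = noise_sd_uV, noise_band_hz = as.numeric(noise_band_hz),
      fluctuation_gain_incorrect = fluctuation_gain_incorrect,
      sample_rate_hz = sample_rate_hz,
      epoch_span_ms = as.numeric(epoch_span_ms),
      n_trials_per_shape = as.integer(n_trials_per_shape),
      p_different = p_different, error_rate = error_rate,
      no_response_share = no_response_share,
      response_window_ms = response_window_ms,
      rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
      stimulus_duration_ms = stimulus_duration_ms, seed = seed
    ),
    class = "synthetic_config"
  )
}

# time grid of a config: [start, end) at the configured rate
.config_time_grid <- function(config) {
  dt <- 1000 / config$sample_rate_hz
  seq(config$epoch_span_ms[1], config$epoch_span_ms[2] - dt / 2, by = dt)
}

#' Simulate one stimulus-locked ERP epoch
#'
#' The trace is the sum of the configured Gaussian component bumps (with the
#' per-component latency shift applied when `condition = "incorrect"`) plus
#' band-limited Gaussian noise rescaled to sd
#' `noise_sd_uV * fluctuation_gain_incorrect^(condition == "incorrect")`.
#' Deterministic for a fixed `(config, seed)`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @param subject_id,shape Optional labels stored on the epoch.
#' @return An [erp_epoch()].
#' @export
make_erp_epoch <- function(config, seed = NULL, subject_id = NA_character_,
                           shape = NA_character_) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  time_ms <- .config_time_grid(config)
  amp <- numeric(length(time_ms))
  incorrect <- config$condition == "incorrect"
  for (comp in config$components) {
    lat <- comp$latency_ms
    if (incorrect) {
      shift <- config$incorrect_latency_shift_ms[[comp$name]]
      if (!is.null(shift) && !is.na(shift)) lat <- lat + shift
    }
    amp <- amp + comp$amplitude_uV *
      exp(-(time_ms - lat)^2 / (2 * comp$width_ms^2))
  }
  sd_target <- config$noise_sd_uV *
    if (incorrect) config$fluctuation_gain_incorrect else 1
  if (sd_target > 0) {
    noise <- zero_phase_bandpass(
      stats::rnorm(length(time_ms)),
      band_hz = config$noise_band_hz,
      sample_rate_hz = config$sample_rate_hz
    )
    amp <- amp + noise * sd_target / stats::sd(noise)
  }
  erp_epoch(time_ms, amp, config$sample_rate_hz,
            subject_id = subject_id, group = config$group,
            condition = config$condition, shape = shape)
}

.shapes <- c("triangle", "circle", "rectangle")

# per-shape error probability from a scalar or named vector
.shape_error_rate <- function(config, shape) {
  er <- config$error_rate
  if (length(er) == 1L && is.null(names(er))) return(unname(er))
  if (!shape %in% names(er)) stop("no error_rate for shape ", shape)
  unname(er[[shape]])
}

# one simulated trial outcome; uses the current RNG stream
.simulate_trial <- function(config, shape) {
  is_different <- stats::runif(1) < config$p_different
  correct <- stats::runif(1) >= .shape_error_rate(config, shape)
  rt <- function(extra = 0) {
    min(max(stats::rnorm(1, config$rt_mean_ms + extra, config$rt_sd_ms), 150),
        config$response_window_ms)
  }
  if (correct) {
    response <- if (is_different) "left" else "right"
    response_time <- rt()
  } else if (stats::runif(1) < config$no_response_share) {
    response <- "none"
    response_time <- NA_real_
  } else {
    response <- if (is_different) "right" else "left"
    response_time <- rt(100)  # wrong clicks tend to be slower
  }
  list(is_different = is_different, response = response,
       response_time_ms = response_time, is_correct = correct)
}

#' Simulate a Go/Nogo behavioral trial log
#'
#' Per subject and traffic-sign shape, draws `n_trials_per_shape` trials:
#' the ground truth ("different" vs "same" pair) with probability
#' `p_different`, correctness with probability `1 - error_rate`, and the
#' response key implied by the Go/Nogo rule (left click for "different",
#' right click for "same"; errors are wrong clicks or, with probability
#' `no_response_share`, timeouts with response `"none"`).
#'
#' @param config A [synthetic_config()].
#' @param n_subjects Number of subjects (>= 0).
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @return A data frame of trial records with columns `subject_id`, `group`,
#'   `shape`, `trial_index`, `is_different`, `response`, `response_time_ms`,
#'   `is_correct`.
#' @export
make_trial_log <- function(config, n_subjects, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"), n_subjects >= 0)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_subjects * length(.shapes) *
                   config$n_trials_per_shape)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("%s_%02d", config$group, s)
    for (shape in .shapes) {
      for (i in seq_len(config$n_trials_per_shape)) {
        tr <- .simulate_trial(config, shape)
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject_id = sid, group = config$group, shape = shape,
          trial_index = i, is_different = tr$is_different,
          response = tr$response, response_time_ms = tr$response_time_ms,
          is_correct = tr$is_correct, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L) {
    return(data.frame(
      subject_id = character(), group = character(), shape = character(),
      trial_index = integer(), is_different = logical(),
      response = character(), response_time_ms = numeric(),
      is_correct = logical(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Default generator configurations for a full dataset
#'
#' One correct-condition and one incorrect-condition [synthetic_config()]
#' per requested group, at the package defaults.
#'
#' @param groups Character vector of group names.
#' @param ... Passed on to [synthetic_config()] (same overrides for every
#'   group/condition).
#' @return Named list: `configs[[group]]$correct` / `$incorrect`.
#' @export
default_dataset_configs <- function(groups = c("elderly", "youth"), ...) {
  out <- lapply(groups, function(g) {
    list(correct = synthetic_config(g, "correct", ...),
         incorrect = synthetic_config(g, "incorrect", ...))
  })
  names(out) <- groups
  out
}

#' Simulate a complete dataset bundle
#'
#' Generates, for every group, subject and shape, `n_trials_per_shape` trial
#' records and one epoch per trial; the epoch is drawn from the correct- or
#' incorrect-condition config according to the simulated trial outcome, so
#' behavioral summaries and classifiers can consume the bundle directly.
#'
#' @param configs Named list as produced by [default_dataset_configs()]:
#'   per group, a list with `correct` and `incorrect`
#'   [synthetic_config()] entries.
#' @param n_subjects Subjects per group (default 10).
#' @param seed Integer seed driving the whole bundle.
#' @return An object of class `erp_bundle`: list with `epochs` (list of
#'   [erp_epoch()], one per trial), `trials` (trial-log data frame), and
#'   `seed`.
#' @export
make_dataset <- function(configs = default_dataset_configs(),
                         n_subjects = 10, seed = 1) {
  if (length(configs) == 0) stop("at least one group config is required")
  ids <- unlist(lapply(names(configs), function(g) {
    sprintf("%s_%02d", g, seq_len(n_subjects))
  }))
  if (anyDuplicated(ids)) stop("duplicate subject ids across groups")
  set.seed(seed)
  epochs <- list()
  trial_rows <- list()
  for (g in names(configs)) {
    cfg_c <- configs[[g]]$correct
    cfg_i <- configs[[g]]$incorrect
    stopifnot(inherits(cfg_c, "synthetic_config"),
              inherits(cfg_i, "synthetic_config"))
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("%s_%02d", g, s)
      for (shape in .shapes) {
        for (i in seq_len(cfg_c$n_trials_per_shape)) {
          tr <- .simulate_trial(cfg_c, shape)
          cfg <- if (tr$is_correct) cfg_c else cfg_i
          ep <- make_erp_epoch(cfg, subject_id = sid, shape = shape)
          epochs[[length(epochs) + 1L]] <- ep
          trial_rows[[length(trial_rows) + 1L]] <- data.frame(
            subject_id = sid, group = g, shape = shape, trial_index = i,
            is_different = tr$is_different, response = tr$response,
            response_time_ms = tr$response_time_ms,
            is_correct = tr$is_correct, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  structure(
    list(epochs = epochs, trials = do.call(rbind, trial_rows), seed = seed),
    class = "erp_bundle"
  )
}

#' @export
print.erp_bundle <- function(x, ...) {
  cat(sprintf("<erp_bundle> %d epochs, %d trial records, seed %s\n",
              length(x$epochs), nrow(x$trials), format(x$seed)))
  invisible(x)
}

#' Average epochs per subject, shape and answer condition
#'
#' The per-person averaged ERP used throughout the analysis: all epochs of a
#' bundle sharing subject, shape and condition are averaged pointwise.
#'
#' @param bundle An `erp_bundle` from [make_dataset()].
#' @return List of averaged [erp_epoch()] objects.
#' @export
average_condition_epochs <- function(bundle) {
  stopifnot(inherits(bundle, "erp_bundle"))
  keys <- vapply(bundle$epochs, function(e) {
    paste(e$subject_id, e$shape, e$condition, sep = "|")
  }, character(1))
  lapply(split(bundle$epochs, keys), average_epochs)
}
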