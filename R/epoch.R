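#' Stimulus-locked ERP epoch
#'
#' A single-channel event-related potential trace: a uniformly sampled time
#' axis in milliseconds relative to stimulus onset (which must lie inside the
#' span) and the corresponding amplitudes in microvolts, together with the
#' labels the downstream analysis needs (subject, group, answer condition,
#' traffic-sign shape).
#'
#' @param time_ms Numeric vector of sample times in ms, uniformly spaced and
#'   increasing; stimulus onset (0 ms) must lie inside the span.
#' @param amplitude_uV Numeric vector of amplitudes in microvolts, same
#'   length as `time_ms`.
#' @param sample_rate_hz Sampling rate in Hz; must agree with the spacing of
#'   `time_ms`.
#' @param subject_id,group,condition,shape Optional character labels.
#'   `group` is one of `"elderly"`/`"youth"`, `condition` one of
#'   `"correct"`/`"incorrect"`, `shape` one of
#'   `"triangle"`/`"circle"`/`"rectangle"`.
#' @param variant Preprocessing variant tag already applied to the trace
#'   (`"original_avg"` for raw/averaged data).
#' @return An object of class `erp_epoch`.
#' @export
erp_epoch <- function(time_ms, amplitude_uV, sample_rate_hz,
                      subject_id = NA_character_, group = NA_character_,
                      condition = NA_character_, shape = NA_character_,
                      variant = "original_avg") {
  time_ms <- as.numeric(time_ms)
  amplitude_uV <- as.numeric(amplitude_uV)
  if (length(time_ms) < 2L) {
    stop("an epoch needs at least two samples")
  }
  if (length(time_ms) != length(amplitude_uV)) {
    stop("time_ms and amplitude_uV must have the same length")
  }
  dt <- diff(time_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    stop("time axis must be uniformly sampled and increasing")
  }
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a positive number")
  }
  if (abs(1000 / mean(dt) - sample_rate_hz) > 1e-6 * sample_rate_hz) {
    stop("sample_rate_hz does not match the spacing of time_ms")
  }
  if (time_ms[1L] > 0 || time_ms[length(time_ms)] < 0) {
    stop("stimulus onset (0 ms) must lie inside the epoch span")
  }
  structure(
    list(
      time_ms = time_ms,
      amplitude_uV = amplitude_uV,
      sample_rate_hz = sample_rate_hz,
      subject_id = as.character(subject_id),
      group = as.character(group),
      condition = as.character(condition),
      shape = as.character(shape),
      variant = as.character(variant)
    ),
    class = "erp_epoch"
  )
}

#' @export
print.erp_epoch <- function(x, ...) {
  cat(sprintf(
    "<erp_epoch> %d samples @ %g Hz, %g..%g ms [%s/%s/%s/%s, variant=%s]\n",
    length(x$time_ms), x$sample_rate_hz, x$time_ms[1L],
    x$time_ms[length(x$time_ms)], x$subject_id, x$group, x$condition,
    x$shape, x$variant
  ))
  invisible(x)
}

#' Multichannel stimulus-locked epoch
#'
#' Holds one epoch recorded on several electrodes at once, as a
#' samples-by-channels matrix with electrode names as column names.
#' Region-of-interest averaging ([roi_average()]) collapses it to a single
#' [erp_epoch()].
#'
#' @param time_ms Uniform sample times in ms (onset inside the span).
#' @param channels Numeric matrix, one column per electrode, with column
#'   names; `nrow(channels)` must equal `length(time_ms)`.
#' @param sample_rate_hz Sampling rate in Hz.
#' @inheritParams erp_epoch
#' @return An object of class `erp_multichannel`.
#' @export
erp_multichannel <- function(time_ms, channels, sample_rate_hz,
                             subject_id = NA_character_,
                             group = NA_character_,
                             condition = NA_character_,
                             shape = NA_character_) {
  channels <- as.matrix(channels)
  if (is.null(colnames(channels)) || anyNA(colnames(channels))) {
    stop("channels must have electrode names as column names")
  }
  if (nrow(channels) != length(time_ms)) {
    stop("channels must have one row per sample of time_ms")
  }
  # reuse the single-channel validation for the time axis
  probe <- erp_epoch(time_ms, channels[, 1L], sample_rate_hz)
  structure(
    list(
      time_ms = probe$time_ms,
      channels = channels,
      sample_rate_hz = sample_rate_hz,
      subject_id = as.character(subject_id),
      group = as.character(group),
      condition = as.character(condition),
      shape = as.character(shape)
    ),
    class = "erp_multichannel"
  )
}

# single value if all entries agree (NA-tolerant), otherwise NA
.uniform_or_na <- function(values) {
  values <- values[!is.na(values)]
  u <- unique(values)
  if (length(u) == 1L) u else NA_character_
}
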