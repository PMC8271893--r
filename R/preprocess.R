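#' Preprocessing variant
#'
#' The four signal-processing variants applied to a person's averaged ERP
#' before component detection:
#' `original_avg` (no further processing), `smoothed` (20 ms moving
#' average), `zero_phase` (4-30 Hz zero-phase band-pass), and
#' `zero_phase_smoothed` (filter, then smooth).
#'
#' @param tag One of `"original_avg"`, `"smoothed"`, `"zero_phase"`,
#'   `"zero_phase_smoothed"`.
#' @param smoothing_window_ms Moving-average window in ms (default 20).
#' @param band_hz Pass band in Hz (default 4-30).
#' @param filter_order Butterworth order (default 4), applied
#'   forward-backward.
#' @return An object of class `preprocessing_variant`.
#' @export
preprocessing_variant <- function(tag = c("original_avg", "smoothed",
                                          "zero_phase",
                                          "zero_phase_smoothed"),
                                  smoothing_window_ms = 20,
                                  band_hz = c(4, 30),
                                  filter_order = 4L) {
  tag <- match.arg(tag)
  if (smoothing_window_ms <= 0) stop("smoothing_window_ms must be positive")
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[1] >= band_hz[2]) {
    stop("band_hz must satisfy 0 < low < high")
  }
  structure(
    list(tag = tag, smoothing_window_ms = smoothing_window_ms,
         band_hz = as.numeric(band_hz), filter_order = as.integer(filter_order)),
    class = "preprocessing_variant"
  )
}

#' Pointwise average of epochs
#'
#' @param epochs Non-empty list of [erp_epoch()] objects with identical time
#'   axes.
#' @return An [erp_epoch()] whose amplitude is the pointwise mean; labels
#'   are kept where uniform across the inputs and dropped (NA) otherwise.
#' @export
average_epochs <- function(epochs) {
  if (length(epochs) == 0) stop("cannot average an empty list of epochs")
  stopifnot(all(vapply(epochs, inherits, logical(1), "erp_epoch")))
  t0 <- epochs[[1L]]$time_ms
  same <- vapply(epochs, function(e) {
    length(e$time_ms) == length(t0) && max(abs(e$time_ms - t0)) < 1e-9
  }, logical(1))
  if (!all(same)) stop("epochs have mismatched time axes")
  amp <- rowMeans(vapply(epochs, `[[`, numeric(length(t0)), "amplitude_uV"))
  pick <- function(field) {
    .uniform_or_na(vapply(epochs, `[[`, character(1), field))
  }
  erp_epoch(t0, amp, epochs[[1L]]$sample_rate_hz,
            subject_id = pick("subject_id"), group = pick("group"),
            condition = pick("condition"), shape = pick("shape"),
            variant = pick("variant"))
}

#' Region-of-interest channel average
#'
#' Averages the named electrodes of a multichannel epoch pointwise, the way
#' the centro-parieto-occipital region of interest is collapsed to a single
#' analysis trace. The default 12-channel list is configurable.
#'
#' @param epoch An [erp_multichannel()].
#' @param channel_names Electrodes to average (all must be present).
#' @return An [erp_epoch()].
#' @export
roi_average <- function(epoch,
                        channel_names = c("CP1", "CPz", "CP2", "P3", "Pz",
                                          "P4", "PO3", "POz", "PO4", "O1",
                                          "Oz", "O2")) {
  stopifnot(inherits(epoch, "erp_multichannel"))
  missing <- setdiff(channel_names, colnames(epoch$channels))
  if (length(missing) > 0) {
    stop("channel(s) not present: ", paste(missing, collapse = ", "))
  }
  sub <- epoch$channels[, channel_names, drop = FALSE]
  erp_epoch(epoch$time_ms, rowMeans(sub), epoch$sample_rate_hz,
            subject_id = epoch$subject_id, group = epoch$group,
            condition = epoch$condition, shape = epoch$shape)
}

#' Centered moving-average smoothing
#'
#' Window length is `round(window_ms * sample_rate_hz / 1000)` samples,
#' forced odd so the window is centered; near the edges the window shrinks
#' to the available samples rather than padding, so no data is invented and
#' the output has the input's length.
#'
#' @param x Numeric signal.
#' @param window_ms Window width in ms (> 0; default 20).
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Smoothed numeric signal, same length as `x`.
#' @export
smooth_signal <- function(x, window_ms = 20, sample_rate_hz) {
  if (window_ms <= 0) stop("window_ms must be positive")
  n <- length(x)
  len <- round(window_ms * sample_rate_hz / 1000)
  if (len %% 2 == 0) len <- len + 1
  len <- max(len, 1L)
  if (len > n) stop("smoothing window is longer than the signal")
  half <- (len - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), cancelling the phase shift: for any in-band
#' sinusoid the lag of maximum cross-correlation between input and output
#' is zero.
#'
#' @param x Numeric signal.
#' @param band_hz Length-2 pass band in Hz; the upper edge must be below
#'   the Nyquist frequency.
#' @param order Butterworth design order (default 4).
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Filtered numeric signal, same length as `x`.
#' @export
zero_phase_bandpass <- function(x, band_hz = c(4, 30), order = 4L,
                                sample_rate_hz) {
  nyq <- sample_rate_hz / 2
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[1] >= band_hz[2]) {
    stop("band_hz must satisfy 0 < low < high")
  }
  if (band_hz[2] >= nyq) {
    stop("upper band edge must be below the Nyquist frequency (",
         nyq, " Hz)")
  }
  if (length(x) <= 9 * order) {
    stop("signal too short for stable forward-backward filtering")
  }
  bf <- signal::butter(order, band_hz / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Apply a preprocessing variant to an epoch
#'
#' `original_avg` returns the (already averaged) epoch unchanged;
#' `smoothed` applies [smooth_signal()]; `zero_phase` applies
#' [zero_phase_bandpass()]; `zero_phase_smoothed` filters first and then
#' smooths.
#'
#' @param epoch An [erp_epoch()].
#' @param variant A [preprocessing_variant()] or a variant tag string.
#' @return The processed [erp_epoch()], with its `variant` field set.
#' @export
apply_variant <- function(epoch, variant = preprocessing_variant()) {
  stopifnot(inherits(epoch, "erp_epoch"))
  if (is.character(variant)) variant <- preprocessing_variant(variant)
  stopifnot(inherits(variant, "preprocessing_variant"))
  amp <- epoch$amplitude_uV
  rate <- epoch$sample_rate_hz
  amp <- switch(variant$tag,
    original_avg = amp,
    smoothed = smooth_signal(amp, variant$smoothing_window_ms, rate),
    zero_phase = zero_phase_bandpass(amp, variant$band_hz,
                                     variant$filter_order, rate),
    zero_phase_smoothed = smooth_signal(
      zero_phase_bandpass(amp, variant$band_hz, variant$filter_order, rate),
      variant$smoothing_window_ms, rate
    ),
    stop("unknown variant tag: ", variant$tag)
  )
  out <- epoch
  out$amplitude_uV <- amp
  out$variant <- variant$tag
  out
}
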