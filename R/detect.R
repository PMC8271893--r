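#' Component detection configuration
#'
#' Search windows and fallback parameters of the automated
#' N200/P300/N400/P600 latency detector. The P300 fallback is anchored on
#' the detected N200 with a fixed gap time (FGT) of 250 ms: when no suitable
#' positive peak exists in the standard 250-500 ms window, the search moves
#' to `n200 + fgt_ms +/- fgt_halfwidth_ms`.
#'
#' @param n200_range_ms,p300_range_ms,n400_range_ms,p600_range_ms Length-2
#'   search windows in ms (defaults 150-350, 250-500, 250-600, 500-800).
#' @param fgt_ms Fixed gap time from N200 to the fallback P300 search
#'   center (default 250).
#' @param fgt_halfwidth_ms Half-width of the fallback window (default 100).
#' @param prominence_uV Minimum prominence (uV) a local extremum must have
#'   to count as an "appropriate" peak (default 0: any interior local
#'   extremum qualifies).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(n200_range_ms = c(150, 350),
                             p300_range_ms = c(250, 500),
                             n400_range_ms = c(250, 600),
                             p600_range_ms = c(500, 800),
                             fgt_ms = 250,
                             fgt_halfwidth_ms = 100,
                             prominence_uV = 0) {
  for (rng in list(n200_range_ms, p300_range_ms, n400_range_ms,
                   p600_range_ms)) {
    if (length(rng) != 2 || rng[1] >= rng[2]) {
      stop("search ranges must be ordered length-2 vectors")
    }
  }
  if (fgt_ms <= 0) stop("fgt_ms must be positive")
  if (fgt_halfwidth_ms <= 0) stop("fgt_halfwidth_ms must be positive")
  if (prominence_uV < 0) stop("prominence_uV must be >= 0")
  structure(
    list(n200_range_ms = n200_range_ms, p300_range_ms = p300_range_ms,
         n400_range_ms = n400_range_ms, p600_range_ms = p600_range_ms,
         fgt_ms = fgt_ms, fgt_halfwidth_ms = fgt_halfwidth_ms,
         prominence_uV = prominence_uV),
    class = "detection_config"
  )
}

# indices of strict interior local maxima of v
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  idx
}

# prominence of the local maximum at index i of v: height above the higher
# of the two minima separating it from higher ground (or the window edge)
.prominence <- function(v, i) {
  n <- length(v)
  left <- if (i > 1) {
    higher <- which(v[1:(i - 1)] > v[i])
    from <- if (length(higher)) max(higher) + 1L else 1L
    min(v[from:(i - 1)])
  } else v[i]
  right <- if (i < n) {
    higher <- which(v[(i + 1):n] > v[i])
    to <- if (length(higher)) i + min(higher) - 1L else n
    min(v[(i + 1):to])
  } else v[i]
  v[i] - max(left, right)
}

# Extremum scan shared by all four detectors.  mode "max" looks for positive
# peaks, "min" for negative ones (by negating).  Returns the time of the
# best interior local extremum with prominence >= threshold (largest
# amplitude, earliest on ties) restricted to times > after, or, when none
# exists and fallback is allowed, the global extremum of the window
# (earliest on ties).  interior reports which branch fired.
.scan_extremum <- function(epoch, lo, hi, mode = c("max", "min"),
                           prominence = 0, after = -Inf,
                           fallback = TRUE) {
  mode <- match.arg(mode)
  t <- epoch$time_ms
  if (lo < t[1L] || hi > t[length(t)]) {
    stop(sprintf("search range %g..%g ms lies outside the epoch span", lo, hi))
  }
  sel <- which(t >= lo - 1e-9 & t <= hi + 1e-9)
  v <- epoch$amplitude_uV[sel]
  if (mode == "min") v <- -v
  cand <- .local_maxima(v)
  cand <- cand[t[sel][cand] > after]
  if (length(cand) > 0 && prominence > 0) {
    cand <- cand[vapply(cand, function(i) .prominence(v, i),
                        numeric(1)) >= prominence]
  }
  if (length(cand) > 0) {
    best <- cand[which.max(v[cand])]
    return(list(time_ms = t[sel][best], interior = TRUE))
  }
  if (!fallback) return(list(time_ms = NA_real_, interior = FALSE))
  list(time_ms = t[sel][which.max(v)], interior = FALSE)
}

#' Detect the N200 latency
#'
#' Time of the most negative interior local minimum within the N200 search
#' window (150-350 ms by default); if the window contains no interior local
#' minimum, the time of the window's global minimum.
#'
#' @param epoch An [erp_epoch()] covering the search range.
#' @param config A [detection_config()].
#' @return Latency in ms.
#' @export
detect_n200 <- function(epoch, config = detection_config()) {
  r <- config$n200_range_ms
  .scan_extremum(epoch, r[1], r[2], "min",
                 prominence = config$prominence_uV)$time_ms
}

#' Detect the P300 latency with the fixed-gap-time fallback
#'
#' First searches the standard window (250-500 ms by default) for an
#' interior local maximum with sufficient prominence at a time later than
#' the detected N200. When none is found — e.g. because the N200 itself was
#' late and pushed the P300 out of the standard range — the search is
#' repeated in the fixed-gap-time window `n200 + fgt_ms +/-
#' fgt_halfwidth_ms`; if that also contains no qualifying local maximum,
#' the global maximum of the FGT window is returned.
#'
#' @param epoch An [erp_epoch()].
#' @param n200_ms Detected N200 latency in ms.
#' @param config A [detection_config()].
#' @return List with `latency_ms` and `via_fgt` (`TRUE` when the fallback
#'   window was used).
#' @export
detect_p300 <- function(epoch, n200_ms, config = detection_config()) {
  r <- config$p300_range_ms
  hit <- .scan_extremum(epoch, r[1], r[2], "max",
                        prominence = config$prominence_uV,
                        after = n200_ms, fallback = FALSE)
  if (hit$interior) {
    return(list(latency_ms = hit$time_ms, via_fgt = FALSE))
  }
  lo <- n200_ms + config$fgt_ms - config$fgt_halfwidth_ms
  hi <- n200_ms + config$fgt_ms + config$fgt_halfwidth_ms
  if (hi > epoch$time_ms[length(epoch$time_ms)]) {
    stop("fixed-gap-time window extends beyond the epoch end")
  }
  hit <- .scan_extremum(epoch, lo, hi, "max",
                        prominence = config$prominence_uV,
                        after = n200_ms, fallback = TRUE)
  list(latency_ms = hit$time_ms, via_fgt = TRUE)
}

#' Detect the N400 latency
#'
#' Most negative interior local minimum between the detected P300 and the
#' end of the N400 window (600 ms by default); falls back to the window's
#' global minimum. Constraining the window start to the P300 enforces the
#' component order even though the nominal search ranges overlap.
#'
#' @param epoch An [erp_epoch()].
#' @param p300_ms Detected P300 latency in ms.
#' @param config A [detection_config()].
#' @return Latency in ms, or `NA` (with a warning) when the P300 lies at or
#'   beyond the window end.
#' @export
detect_n400 <- function(epoch, p300_ms, config = detection_config()) {
  r <- config$n400_range_ms
  lo <- max(r[1], p300_ms)
  if (lo >= r[2]) {
    warning("empty N400 search range (P300 at ", p300_ms, " ms)")
    return(NA_real_)
  }
  .scan_extremum(epoch, lo, r[2], "min",
                 prominence = config$prominence_uV)$time_ms
}

#' Detect the P600 latency
#'
#' Largest interior local maximum between the detected N400 and the end of
#' the P600 window (800 ms by default); falls back to the window's global
#' maximum.
#'
#' @param epoch An [erp_epoch()].
#' @param n400_ms Detected N400 latency in ms.
#' @param config A [detection_config()].
#' @return Latency in ms, or `NA` (with a warning) when the N400 lies at or
#'   beyond the window end.
#' @export
detect_p600 <- function(epoch, n400_ms, config = detection_config()) {
  r <- config$p600_range_ms
  if (is.na(n400_ms)) {
    warning("no N400 latency available; P600 not detected")
    return(NA_real_)
  }
  lo <- max(r[1], n400_ms)
  if (lo >= r[2]) {
    warning("empty P600 search range (N400 at ", n400_ms, " ms)")
    return(NA_real_)
  }
  .scan_extremum(epoch, lo, r[2], "max",
                 prominence = config$prominence_uV)$time_ms
}

#' Detect all four components of an averaged trace
#'
#' Runs the N200 -> P300 (with FGT fallback) -> N400 -> P600 chain and
#' returns one row of component latencies together with the epoch's labels.
#'
#' @param epoch An [erp_epoch()].
#' @param config A [detection_config()].
#' @return One-row data frame with columns `subject_id`, `group`,
#'   `condition`, `shape`, `variant`, `n200_ms`, `p300_ms`,
#'   `p300_via_fgt`, `n400_ms`, `p600_ms`.
#' @export
detect_components <- function(epoch, config = detection_config()) {
  n200 <- detect_n200(epoch, config)
  p300 <- detect_p300(epoch, n200, config)
  n400 <- detect_n400(epoch, p300$latency_ms, config)
  p600 <- detect_p600(epoch, n400, config)
  data.frame(
    subject_id = epoch$subject_id, group = epoch$group,
    condition = epoch$condition, shape = epoch$shape,
    variant = epoch$variant,
    n200_ms = n200, p300_ms = p300$latency_ms,
    p300_via_fgt = p300$via_fgt, n400_ms = n400, p600_ms = p600,
    stringsAsFactors = FALSE
  )
}

#' Extract the 1-second feature window anchored on the N200
#'
#' Cuts the contiguous segment `[n200, n200 + duration)` from an epoch; this
#' window, which spans the main ERP components, feeds both classifiers.
#'
#' @param epoch An [erp_epoch()].
#' @param n200_ms Window start in ms (typically the detected N200).
#' @param duration_ms Window length in ms (default 1000).
#' @return An object of class `erp_segment`: list with `time_ms`,
#'   `amplitude_uV`, `sample_rate_hz` and the epoch's labels.
#' @export
extract_feature_window <- function(epoch, n200_ms, duration_ms = 1000) {
  stopifnot(inherits(epoch, "erp_epoch"))
  dt <- 1000 / epoch$sample_rate_hz
  t <- epoch$time_ms
  if (n200_ms < t[1L] - 1e-9 ||
      n200_ms + duration_ms - dt > t[length(t)] + 1e-9) {
    stop("epoch does not cover the requested feature window")
  }
  sel <- which(t >= n200_ms - 1e-9 & t < n200_ms + duration_ms - 1e-9)
  structure(
    list(time_ms = t[sel], amplitude_uV = epoch$amplitude_uV[sel],
         sample_rate_hz = epoch$sample_rate_hz,
         subject_id = epoch$subject_id, group = epoch$group,
         condition = epoch$condition, shape = epoch$shape,
         variant = epoch$variant),
    class = "erp_segment"
  )
}

#' Resample a segment to a fixed-length feature vector
#'
#' Linear interpolation at `n_points` evenly spaced times spanning the
#' segment, producing the fixed-length input vector of the MLP classifier
#' (70 values for the 1-s window by default).
#'
#' @param segment An `erp_segment` from [extract_feature_window()] or an
#'   [erp_epoch()].
#' @param n_points Output length (>= 2; default 70).
#' @return Numeric vector of length `n_points`.
#' @export
resample_features <- function(segment, n_points = 70) {
  if (n_points < 2) stop("n_points must be at least 2")
  t <- segment$time_ms
  if (length(t) < 2) stop("segment must contain at least 2 samples")
  xout <- seq(t[1L], t[length(t)], length.out = n_points)
  stats::approx(t, segment$amplitude_uV, xout = xout)$y
}
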