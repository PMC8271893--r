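# shared fixtures and independent oracles, built in code at test time

# single-channel epoch on a uniform grid, labels optional
toy_epoch <- function(amplitude, time_ms = NULL, rate = 1000, ...) {
  if (is.null(time_ms)) {
    time_ms <- seq(-100, by = 1000 / rate, length.out = length(amplitude))
  }
  erp_epoch(time_ms, amplitude, rate, ...)
}

# Gaussian bump trace on a grid
bump_trace <- function(time_ms, latency, amplitude, width) {
  out <- numeric(length(time_ms))
  for (i in seq_along(latency)) {
    out <- out + amplitude[i] * exp(-(time_ms - latency[i])^2 /
                                      (2 * width[i]^2))
  }
  out
}

# random many-bump trace for detector fuzzing: 6 bumps of either polarity
# plus smooth low-frequency noise, on -100..1100 ms at 500 Hz
random_trace <- function(seed) {
  set.seed(seed)
  t <- seq(-100, 1100, by = 2)
  centers <- runif(6, 100, 900)
  amps <- runif(6, 2, 8) * sample(c(-1, 1), 6, replace = TRUE)
  widths <- runif(6, 15, 40)
  x <- bump_trace(t, centers, amps, widths)
  slow <- stats::filter(rnorm(length(t), sd = 2), rep(1 / 25, 25),
                        circular = TRUE)
  toy_epoch(x + as.numeric(slow), time_ms = t, rate = 500)
}

# ---- independent detection oracle: explicit loops over local extrema ----

oracle_local_extrema <- function(v, maxima = TRUE) {
  idx <- integer(0)
  for (i in seq_along(v)) {
    if (i == 1 || i == length(v)) next
    if (maxima && v[i] > v[i - 1] && v[i] > v[i + 1]) idx <- c(idx, i)
    if (!maxima && v[i] < v[i - 1] && v[i] < v[i + 1]) idx <- c(idx, i)
  }
  idx
}

# best extremum in [lo, hi]: largest/most-negative interior local extremum
# (earliest tie), else the window's global extremum (earliest tie)
oracle_pick <- function(t, v, lo, hi, maxima = TRUE, after = -Inf,
                        fallback = TRUE) {
  keep <- t >= lo & t <= hi
  tt <- t[keep]
  vv <- v[keep]
  cand <- oracle_local_extrema(vv, maxima)
  cand <- cand[tt[cand] > after]
  if (length(cand) > 0) {
    best <- cand[1]
    for (i in cand) {
      if ((maxima && vv[i] > vv[best]) || (!maxima && vv[i] < vv[best])) {
        best <- i
      }
    }
    return(list(time = tt[best], interior = TRUE))
  }
  if (!fallback) return(list(time = NA_real_, interior = FALSE))
  best <- 1
  for (i in seq_along(vv)) {
    if ((maxima && vv[i] > vv[best]) || (!maxima && vv[i] < vv[best])) {
      best <- i
    }
  }
  list(time = tt[best], interior = FALSE)
}

# full component chain with the fixed-gap-time fallback, mirrored naively
oracle_detect <- function(epoch, fgt = 250, halfwidth = 100) {
  t <- epoch$time_ms
  v <- epoch$amplitude_uV
  n200 <- oracle_pick(t, v, 150, 350, maxima = FALSE)$time
  p <- oracle_pick(t, v, 250, 500, maxima = TRUE, after = n200,
                   fallback = FALSE)
  if (p$interior) {
    p300 <- p$time
    via_fgt <- FALSE
  } else {
    p300 <- oracle_pick(t, v, n200 + fgt - halfwidth,
                        n200 + fgt + halfwidth, maxima = TRUE,
                        after = n200)$time
    via_fgt <- TRUE
  }
  n400 <- if (max(250, p300) >= 600) NA_real_ else {
    oracle_pick(t, v, max(250, p300), 600, maxima = FALSE)$time
  }
  p600 <- if (is.na(n400) || max(500, n400) >= 800) NA_real_ else {
    oracle_pick(t, v, max(500, n400), 800, maxima = TRUE)$time
  }
  list(n200 = n200, p300 = p300, via_fgt = via_fgt, n400 = n400,
       p600 = p600)
}
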