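#' Mean and population standard deviation
#'
#' The summary convention used for all group-level tables: arithmetic mean
#' and the population standard deviation (divisor `n`, not `n - 1`).
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(mean = ..., sd = ...)`.
#' @export
mean_and_popsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) {
    stop("values must be a non-empty numeric vector without NAs")
  }
  m <- mean(values)
  c(mean = m, sd = sqrt(mean((values - m)^2)))
}

#' Summarize Go/Nogo behavior per group and shape
#'
#' Per group and traffic-sign shape: mean and population SD of the
#' per-subject correct and incorrect answer counts, plus two error-rate
#' conventions — `error_rate`, the ratio of mean counts
#' `mean_incorrect / (mean_correct + mean_incorrect)` (the convention the
#' group-average rows of published summaries follow), and
#' `error_rate_subject`, the mean of the per-subject error ratios.
#'
#' @param trials Trial-log data frame as produced by [make_trial_log()] /
#'   [make_dataset()] (columns `subject_id`, `group`, `shape`,
#'   `is_correct` required).
#' @return Data frame with one row per group and shape.
#' @export
summarize_behavior <- function(trials) {
  required <- c("subject_id", "group", "shape", "is_correct")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0) {
    stop("trial log is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(trials) == 0) stop("trial log is empty")
  out <- list()
  for (g in unique(trials$group)) {
    for (sh in unique(trials$shape[trials$group == g])) {
      sub <- trials[trials$group == g & trials$shape == sh, ]
      n_correct <- tapply(sub$is_correct, sub$subject_id, sum)
      n_total <- tapply(sub$is_correct, sub$subject_id, length)
      keep <- n_total > 0
      if (!all(keep)) {
        warning("excluding subject(s) with zero trials: ",
                paste(names(n_total)[!keep], collapse = ", "))
      }
      n_correct <- as.numeric(n_correct[keep])
      n_incorrect <- as.numeric(n_total[keep]) - n_correct
      mc <- mean_and_popsd(n_correct)
      mi <- mean_and_popsd(n_incorrect)
      out[[length(out) + 1L]] <- data.frame(
        group = g, shape = sh,
        n_subjects = sum(keep),
        mean_correct = mc[["mean"]], sd_correct = mc[["sd"]],
        mean_incorrect = mi[["mean"]], sd_incorrect = mi[["sd"]],
        error_rate = mi[["mean"]] / (mc[["mean"]] + mi[["mean"]]),
        error_rate_subject =
          mean(n_incorrect / (n_correct + n_incorrect)),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Summarize component latencies
#'
#' Mean and population SD of each detected component latency, grouped by
#' the requested label columns (group and answer condition by default) —
#' the arithmetic behind group-level latency tables.
#'
#' @param detections Data frame of detector output rows
#'   ([detect_components()]) with columns `n200_ms`, `p300_ms`, `n400_ms`,
#'   `p600_ms` and the grouping labels.
#' @param by Character vector of grouping columns.
#' @return Long data frame: grouping columns, `component`, `mean_ms`,
#'   `sd_ms`, `n`.
#' @export
summarize_latencies <- function(detections, by = c("group", "condition")) {
  comps <- c(n200 = "n200_ms", p300 = "p300_ms",
             n400 = "n400_ms", p600 = "p600_ms")
  missing <- setdiff(c(by, unname(comps)), names(detections))
  if (length(missing) > 0) {
    stop("detections are missing column(s): ",
         paste(missing, collapse = ", "))
  }
  key <- interaction(detections[by], drop = TRUE, lex.order = TRUE)
  out <- list()
  for (lev in levels(key)) {
    sub <- detections[key == lev, ]
    for (comp in names(comps)) {
      vals <- sub[[comps[[comp]]]]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) next
      ms <- mean_and_popsd(vals)
      row <- sub[1L, by, drop = FALSE]
      row$component <- toupper(comp)
      row$mean_ms <- ms[["mean"]]
      row$sd_ms <- ms[["sd"]]
      row$n <- length(vals)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correct-vs-incorrect latency gap times
#'
#' Per-component gap `mean_incorrect - mean_correct` in ms, rounded to the
#' configured number of digits (whole milliseconds by default). Components
#' present on only one side yield no gap.
#'
#' @param correct,incorrect Named numeric vectors of mean latencies (names
#'   are component labels), or data frames from [summarize_latencies()]
#'   restricted to a single group (columns `component`, `mean_ms`).
#' @param digits Digits for rounding, or `NULL` for no rounding.
#' @return Named numeric vector of gaps in ms.
#' @export
latency_gaps <- function(correct, incorrect, digits = 0) {
  as_vec <- function(x) {
    if (is.data.frame(x)) {
      stats::setNames(x$mean_ms, x$component)
    } else {
      x
    }
  }
  correct <- as_vec(correct)
  incorrect <- as_vec(incorrect)
  comps <- intersect(names(correct), names(incorrect))
  if (length(comps) == 0) stop("no shared components between the summaries")
  gaps <- incorrect[comps] - correct[comps]
  if (!is.null(digits)) gaps <- round(gaps, digits)
  gaps
}

#' Published reference summary tables
#'
#' The group-level reference values of the elderly/young traffic-sign
#' Go/Nogo study this package models, shipped as plain-text data:
#' per-shape correct/incorrect answer counts and error percentages
#' (`behavior`), per-shape component latencies with the published
#' group-average (`avg`) and population-SD (`std`) rows (`latencies`), and
#' the published 4-fold cross-validation fold accuracies per preprocessing
#' variant (`cv_folds`). They serve as inputs for validating the summary
#' arithmetic.
#'
#' @return List of three data frames: `behavior`, `latencies`, `cv_folds`.
#' @export
reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "erpsign",
                                  mustWork = TRUE)
  list(
    behavior = utils::read.csv(path("reference_behavior_counts.csv"),
                               stringsAsFactors = FALSE),
    latencies = utils::read.csv(path("reference_component_latencies.csv"),
                                stringsAsFactors = FALSE),
    cv_folds = utils::read.csv(path("reference_cv_folds.csv"),
                               stringsAsFactors = FALSE)
  )
}
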