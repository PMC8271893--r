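#' Fit a univariate Gaussian mixture by expectation-maximisation
#'
#' The unsupervised correct-answer model: amplitude samples of the 1-s
#' feature windows, pooled over all correct-answer traces, are clustered
#' into `n_components` univariate Gaussians. Initialisation is
#' deterministic — quantile-spread means, equal weights, pooled variance —
#' and the EM iterations stop when the relative log-likelihood improvement
#' falls below `tol`. The log-likelihood is checked to be non-decreasing at
#' every iteration.
#'
#' @param samples Numeric vector of observations (at least `n_components`).
#' @param n_components Number of mixture components (default 10).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @param var_floor Lower bound on component variances; defaults to
#'   `1e-6 * var(samples)`. Components hitting the floor are flagged.
#' @param seed Optional seed (the fit itself is deterministic; accepted for
#'   interface symmetry with the other learners).
#' @return An object of class `gmm_model`: `weights`, `means`, `variances`,
#'   `loglik_trace`, `final_loglik`, `converged`, `n_iter`, `var_floored`.
#' @export
fit_gmm_em <- function(samples, n_components = 10, tol = 1e-6,
                       max_iter = 500, var_floor = NULL, seed = NULL) {
  x <- as.numeric(samples)
  n <- length(x)
  k <- as.integer(n_components)
  if (k < 1) stop("n_components must be >= 1")
  if (n < k) stop("need at least n_components samples")
  if (!is.null(seed)) set.seed(seed)
  pooled_var <- mean((x - mean(x))^2)
  if (pooled_var == 0) pooled_var <- .Machine$double.eps
  if (is.null(var_floor)) var_floor <- 1e-6 * pooled_var
  means <- as.numeric(stats::quantile(x, probs = seq_len(k) / (k + 1),
                                      names = FALSE, type = 7))
  vars <- rep(pooled_var, k)
  weights <- rep(1 / k, k)
  loglik <- numeric(0)
  floored <- FALSE
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step in log space; columns are components
    logdens <- vapply(seq_len(k), function(j) {
      log(weights[j]) + stats::dnorm(x, means[j], sqrt(vars[j]), log = TRUE)
    }, numeric(n))
    logdens <- matrix(logdens, nrow = n)
    m <- apply(logdens, 1L, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    ll <- sum(lse)
    loglik <- c(loglik, ll)
    if (iter > 1) {
      prev <- loglik[iter - 1L]
      if (ll < prev - 1e-8 * (abs(prev) + 1)) {
        stop("EM log-likelihood decreased; this should never happen")
      }
      if (abs(ll - prev) < tol * (abs(prev) + 1e-12)) {
        converged <- TRUE
        break
      }
    }
    resp <- exp(logdens - lse)
    nk <- colSums(resp)
    nk <- pmax(nk, .Machine$double.xmin)
    weights <- nk / n
    means <- colSums(resp * x) / nk
    vars <- colSums(resp * (outer(x, means, "-"))^2) / nk
    if (any(vars < var_floor)) {
      vars <- pmax(vars, var_floor)
      floored <- TRUE
    }
  }
  structure(
    list(weights = weights, means = means, variances = vars,
         n_components = k, loglik_trace = loglik,
         final_loglik = loglik[length(loglik)],
         converged = converged, n_iter = length(loglik),
         var_floored = floored),
    class = "gmm_model"
  )
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf(
    "<gmm_model> %d components, loglik %.3f (%s after %d iterations)\n",
    x$n_components, x$final_loglik,
    if (x$converged) "converged" else "not converged", x$n_iter
  ))
  invisible(x)
}

#' Mixture log-likelihood of a sample set
#'
#' `sum_i log sum_k weight_k * N(x_i; mean_k, var_k)`, evaluated with
#' log-sum-exp to guard against underflow.
#'
#' @param model A fitted [fit_gmm_em()] model.
#' @param samples Numeric vector of observations.
#' @return Total log-likelihood (scalar).
#' @export
gmm_loglik <- function(model, samples) {
  stopifnot(inherits(model, "gmm_model"))
  x <- as.numeric(samples)
  if (length(x) == 0) stop("samples must be non-empty")
  logdens <- vapply(seq_len(model$n_components), function(j) {
    log(model$weights[j]) +
      stats::dnorm(x, model$means[j], sqrt(model$variances[j]), log = TRUE)
  }, numeric(length(x)))
  logdens <- matrix(logdens, nrow = length(x))
  m <- apply(logdens, 1L, max)
  sum(m + log(rowSums(exp(logdens - m))))
}

#' Log-likelihood difference between correct and incorrect data
#'
#' Scores correct-answer and incorrect-answer samples under a mixture model
#' fitted to correct-answer training data and reports
#' `|ll_correct| - |ll_incorrect|`. The better the model separates the two
#' answer classes, the smaller (more negative) the difference.
#'
#' @param model A [fit_gmm_em()] model fitted on correct-answer data.
#' @param correct_samples,incorrect_samples Non-empty numeric vectors.
#' @return An object of class `loglik_result`: `ll_correct`,
#'   `ll_incorrect`, `difference`.
#' @export
loglik_difference <- function(model, correct_samples, incorrect_samples) {
  if (length(correct_samples) == 0 || length(incorrect_samples) == 0) {
    stop("both sample sets must be non-empty")
  }
  ll_c <- gmm_loglik(model, correct_samples)
  ll_i <- gmm_loglik(model, incorrect_samples)
  structure(
    list(ll_correct = ll_c, ll_incorrect = ll_i,
         difference = abs(ll_c) - abs(ll_i)),
    class = "loglik_result"
  )
}

#' @export
print.loglik_result <- function(x, ...) {
  cat(sprintf(
    "<loglik_result> ll_correct %.2f, ll_incorrect %.2f, |C|-|I| = %.2f\n",
    x$ll_correct, x$ll_incorrect, x$difference
  ))
  invisible(x)
}
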