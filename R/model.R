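#' Fit the local linear multi-predictor Poisson regression model
#'
#' Fits one local model at every observation point and bundles them with
#' the training data, kernel specification and a global Poisson GLM
#' baseline into a queryable model object.
#'
#' @param data A [count_dataset()].
#' @param spec A [kernel_spec()].
#' @param opts A [fit_options()].
#' @param global Logical; also fit the global baseline (default `TRUE`).
#' @return Object of class `llp_model`: `data`, `spec`, `opts`, `fits`
#'   (one per observation, see [fit_at_observations()]), `global_fit`.
#' @export
#' @examples
#' d <- simulate_counts(simulation_scenario(n = 50, seed = 1))
#' m <- llp_model(d, kernel_spec("gaussian", c(0.4, 0.4)))
#' head(fitted_means(m))
llp_model <- function(data, spec, opts = fit_options(), global = TRUE) {
  fits <- fit_at_observations(data, spec, opts)
  structure(list(
    data = data,
    spec = spec,
    opts = opts,
    fits = fits,
    global_fit = if (global) fit_global(data, opts) else NULL
  ), class = "llp_model")
}

#' @export
print.llp_model <- function(x, ...) {
  ok <- vapply(x$fits, inherits, logical(1), "local_fit")
  cat(sprintf("Local linear Poisson regression: %d local fits (%d failed), %s kernel, h = (%s)\n",
              length(x$fits), sum(!ok), x$spec$family,
              paste(format(x$spec$bandwidths), collapse = ", ")))
  invisible(x)
}

#' Evaluate one stored local model at a query point
#'
#' Returns `exp(b0 + sum_j b1j (x_j - x0_j))`, the local model's mean
#' estimate at `x`. A warning (not an error) is raised when `x` lies
#' outside the fit's validity window `(x0_j - h_j, x0_j + h_j)`, where the
#' first-order Taylor approximation is not guaranteed to hold.
#'
#' @param fit A converged `local_fit`.
#' @param x Numeric query point (length `p`).
#' @param round_mode `"none"` (default) returns the positive real mean;
#'   `"nearest"` rounds to the nearest integer count.
#' @return Predicted mean (or integer count).
#' @export
evaluate_local_model <- function(fit, x, round_mode = c("none", "nearest")) {
  round_mode <- match.arg(round_mode)
  stopifnot(inherits(fit, "local_fit"))
  x <- as.numeric(x)
  p <- length(fit$x0)
  if (length(x) != p) stop(sprintf("x must have length %d", p), call. = FALSE)
  if (!is.null(fit$window)) {
    outside <- x <= fit$window[, "lower"] | x >= fit$window[, "upper"]
    if (any(outside)) {
      warning(sprintf(
        "query point lies outside the validity window in coordinate(s): %s",
        paste(which(outside), collapse = ", ")), call. = FALSE)
    }
  }
  mu <- exp(fit$beta[1] + sum(fit$beta[-1] * (x - fit$x0)))
  if (round_mode == "nearest") round(mu) else unname(mu)
}

#' Predict Poisson means at new points
#'
#' @param object An [llp_model()].
#' @param newdata Numeric matrix or data frame of query points (`m x p`).
#' @param strategy `"refit"` (default) fits a fresh local model at each
#'   query point — the statistically correct choice for arbitrary points;
#'   `"nearest_fit"` evaluates the stored local fit whose centre is closest
#'   in bandwidth-scaled Euclidean distance (ties to the lowest point
#'   index), mirroring the use of per-observation stored models with
#'   validity windows.
#' @param ... Unused.
#' @return Length-`m` vector of positive predicted means; under `refit`,
#'   rows whose local fit is degenerate yield `NA` with a warning and the
#'   batch continues.
#' @export
predict.llp_model <- function(object, newdata,
                              strategy = c("refit", "nearest_fit"), ...) {
  strategy <- match.arg(strategy)
  Xnew <- as.matrix(newdata)
  p <- ncol(object$data$X)
  if (ncol(Xnew) != p) stop(sprintf("newdata must have %d columns", p), call. = FALSE)
  if (strategy == "refit") {
    vapply(seq_len(nrow(Xnew)), function(r) {
      tryCatch(
        exp(fit_local(object$data, Xnew[r, ], object$spec, object$opts)$beta[1]),
        error = function(e) {
          warning(sprintf("prediction failed at row %d: %s", r,
                          conditionMessage(e)), call. = FALSE)
          NA_real_
        })
    }, numeric(1))
  } else {
    h <- object$spec$bandwidths
    centres <- t(vapply(object$fits, function(f) {
      if (inherits(f, "local_fit")) f$x0 else rep(Inf, p)
    }, numeric(p)))
    vapply(seq_len(nrow(Xnew)), function(r) {
      d2 <- colSums((t(centres) - Xnew[r, ])^2 / h^2)
      idx <- which.min(d2)  # which.min ties to the lowest index
      suppressWarnings(evaluate_local_model(object$fits[[idx]], Xnew[r, ]))
    }, numeric(1))
  }
}

#' Fitted means of the local model
#'
#' The fitted mean at observation `i` is `exp(b0)` of the local fit
#' centered there; failed fits yield `NA`.
#'
#' @param model An [llp_model()].
#' @return Length-`n` vector of fitted means.
#' @export
fitted_means <- function(model) {
  stopifnot(inherits(model, "llp_model"))
  vapply(model$fits, function(f) {
    if (inherits(f, "local_fit")) exp(f$beta[1]) else NA_real_
  }, numeric(1))
}

#' In-sample Poisson log-likelihood comparison
#'
#' Summed Poisson log-density of the observed counts at the fitted means,
#' reported for the local model and (when available) the global baseline,
#' so the two fits can be compared on the same scale.
#'
#' @param model An [llp_model()].
#' @return List with `local` and `global` summed log-densities (the global
#'   entry is `NA` when no baseline was fitted) and the corresponding
#'   Poisson `deviance` values.
#' @export
in_sample_loglik <- function(model) {
  y <- model$data$y
  mu_l <- fitted_means(model)
  ok <- !is.na(mu_l)
  ll_local <- sum(stats::dpois(y[ok], mu_l[ok], log = TRUE))
  dev <- function(mu) {
    2 * sum(ifelse(y[ok] > 0, y[ok] * log(y[ok] / mu[ok]), 0) - (y[ok] - mu[ok]))
  }
  if (!is.null(model$global_fit)) {
    mu_g <- model$global_fit$fitted
    list(local = ll_local,
         global = sum(stats::dpois(y[ok], mu_g[ok], log = TRUE)),
         deviance = c(local = dev(mu_l), global = dev(mu_g)))
  } else {
    list(local = ll_local, global = NA_real_,
         deviance = c(local = dev(mu_l), global = NA_real_))
  }
}
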