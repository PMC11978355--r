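#' Fitting options for Newton-Raphson maximization
#'
#' @param epsilon Positive convergence threshold: iteration stops when the
#'   L2 norm of the parameter change falls to `epsilon` or below.
#' @param max_iter Maximum number of Newton iterations.
#' @param safeguard Logical; when `TRUE` (default) a step is halved (up to
#'   30 times) whenever it would decrease the log-likelihood or overflow the
#'   fitted means, so the likelihood is non-decreasing across accepted
#'   steps. `FALSE` recovers the plain Newton update.
#' @param ridge Non-negative amount, scaled by `trace(-H)/(p+1)`, added to
#'   the diagonal of the negative Hessian before solving, to stabilize
#'   near-singular systems.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(epsilon = 1e-6, max_iter = 100L, safeguard = TRUE,
                        ridge = 1e-10) {
  stopifnot(epsilon > 0, max_iter >= 1, ridge >= 0)
  structure(list(epsilon = epsilon, max_iter = as.integer(max_iter),
                 safeguard = isTRUE(safeguard), ridge = ridge),
            class = "fit_options")
}

#' Ordinary-least-squares initialization
#'
#' Regresses the raw counts on the raw predictors with an intercept and
#' re-expresses the coefficients in coordinates centered at `x0`: the
#' centered intercept is the raw intercept plus the slopes dotted with
#' `x0`; the slopes are unchanged.
#'
#' @param data A [count_dataset()].
#' @param x0 Evaluation point (length `p`).
#' @return Length-`(p+1)` numeric starting value (centered intercept first).
#' @export
ols_init <- function(data, x0) {
  Xs <- cbind(1, data$X)
  fit <- stats::lm.fit(Xs, data$y)
  if (fit$rank < ncol(Xs)) {
    stop("OLS initialization failed: raw design is rank deficient; use the log-mean fallback start",
         call. = FALSE)
  }
  b <- fit$coefficients
  c(b[1] + sum(b[-1] * as.numeric(x0)), b[-1])
}

# Fallback start when OLS is unusable: log weight-averaged response for the
# intercept, zero slopes. Keeps the initial linear predictor on the log scale.
fallback_init <- function(design) {
  ybar <- sum(design$w * design$y) / sum(design$w)
  c(log(max(ybar, 1)), rep(0, ncol(design$Xc) - 1L))
}

# The OLS start works on the raw count scale, so its linear predictor can sit
# far above the log-scale optimum (or overflow outright). Keep it only when it
# gives a better weighted log-likelihood than the log-mean fallback.
choose_init <- function(design, ols) {
  fb <- fallback_init(design)
  if (is.null(ols)) return(fb)
  ll_ols <- local_loglik(design, ols)
  ll_fb <- local_loglik(design, fb)
  if (is.finite(ll_ols) && ll_ols >= ll_fb) ols else fb
}

#' Newton-Raphson maximization of the local likelihood
#'
#' Iterates `beta <- beta - H^{-1} g` on the weighted Poisson
#' log-likelihood until the L2 norm of the parameter change is at most
#' `epsilon`, with optional step-halving safeguard and a small ridge on the
#' negative Hessian diagonal for near-singular systems.
#'
#' @param design A `local_design` from [build_local_design()].
#' @param init Length-`(p+1)` starting coefficient vector.
#' @param opts A [fit_options()].
#' @return An object of class `local_fit`: `beta`, `x0`, `converged`,
#'   `n_iter`, `loglik`, `fisher` (information at the solution),
#'   `score_max` (max-abs score at the solution), `effective_weight`
#'   (sum of kernel weights). The validity `window` is attached by
#'   [fit_local()].
#' @export
newton_raphson <- function(design, init, opts = fit_options()) {
  beta <- as.numeric(init)
  k <- ncol(design$Xc)
  if (length(beta) != k) stop("init has the wrong length", call. = FALSE)
  ll <- local_loglik(design, beta)
  converged <- FALSE
  iter <- 0L
  for (m in seq_len(opts$max_iter)) {
    iter <- m
    g <- local_score(design, beta)
    info <- fisher_information(design, beta)
    if (!all(is.finite(g)) || !all(is.finite(info))) {
      stop(sprintf("fit diverged at x0 = (%s): non-finite score or information",
                   paste(format(design$x0), collapse = ", ")), call. = FALSE)
    }
    if (opts$ridge > 0) {
      info <- info + diag(opts$ridge * sum(diag(info)) / k, k)
    }
    delta <- tryCatch(solve(info, g), error = function(e) {
      stop(sprintf("singular information matrix at x0 = (%s)",
                   paste(format(design$x0), collapse = ", ")), call. = FALSE)
    })
    step <- 1
    beta_new <- beta + delta
    ll_new <- local_loglik(design, beta_new)
    if (opts$safeguard) {
      halvings <- 0L
      while ((!is.finite(ll_new) || ll_new < ll - 1e-10 * (1 + abs(ll))) &&
             halvings < 30L) {
        step <- step / 2
        beta_new <- beta + step * delta
        ll_new <- local_loglik(design, beta_new)
        halvings <- halvings + 1L
      }
    }
    move <- sqrt(sum((step * delta)^2))
    beta <- beta_new
    ll <- ll_new
    if (move <= opts$epsilon) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    x0 = unname(design$x0),
    beta = unname(beta),
    converged = converged,
    n_iter = iter,
    loglik = ll,
    fisher = fisher_information(design, beta),
    score_max = max(abs(local_score(design, beta))),
    effective_weight = sum(design$w),
    window = NULL
  ), class = "local_fit")
}

#' @export
print.local_fit <- function(x, ...) {
  cat(sprintf("Local Poisson fit at x0 = (%s)\n",
              paste(format(x$x0), collapse = ", ")))
  cat("  beta:", paste(format(x$beta), collapse = "  "), "\n")
  cat(sprintf("  converged: %s in %d iterations, loglik %.6g\n",
              x$converged, x$n_iter, x$loglik))
  invisible(x)
}

#' Fit the local linear Poisson model at one evaluation point
#'
#' Composes [build_local_design()], [ols_init()] and [newton_raphson()],
#' and records the per-predictor validity window `(x0_j - h_j, x0_j + h_j)`
#' of the local Taylor approximation. Because the OLS start operates on the
#' raw count scale it can sit far above the log-scale optimum; it is used
#' only when its weighted log-likelihood beats the log-mean fallback start
#' `(log(max(weighted mean y, 1)), 0, ..., 0)`.
#'
#' @param data A [count_dataset()].
#' @param x0 Evaluation point.
#' @param spec A [kernel_spec()].
#' @param opts A [fit_options()].
#' @return A `local_fit` (see [newton_raphson()]), with `window` set.
#' @export
fit_local <- function(data, x0, spec, opts = fit_options()) {
  design <- build_local_design(data, x0, spec)
  n <- length(design$w)
  if (sum(design$w) < 1e-2 * max(design$w) * n) {
    stop(sprintf("degenerate neighbourhood at x0 = (%s): effective sample too small",
                 paste(format(x0), collapse = ", ")), call. = FALSE)
  }
  ols <- tryCatch(ols_init(data, x0), error = function(e) NULL)
  fit <- newton_raphson(design, choose_init(design, ols), opts)
  h <- spec$bandwidths
  fit$window <- cbind(lower = as.numeric(x0) - h, upper = as.numeric(x0) + h)
  rownames(fit$window) <- data$names
  fit
}

#' Fit local models at every observation point
#'
#' Applies [fit_local()] with `x0` set to each observation row in turn, the
#' estimation scheme in which one local model is attached to each
#' observation. Per-point failures are collected, not fatal.
#'
#' @inheritParams fit_local
#' @return List of `n` elements, each a `local_fit` or (on failure) a
#'   `local_fit_error` holding the condition message.
#' @seealso [llp_model()] for the assembled model object,
#'   [coef_table()] for a tabular summary.
#' @export
fit_at_observations <- function(data, spec, opts = fit_options()) {
  lapply(seq_along(data$y), function(i) {
    tryCatch(fit_local(data, data$X[i, ], spec, opts),
             error = function(e) {
               structure(list(index = i, message = conditionMessage(e)),
                         class = "local_fit_error")
             })
  })
}

#' Coefficient table of per-point local fits
#'
#' One row per evaluation point with the point coordinates, coefficients
#' and convergence diagnostics; failed points carry `NA` coefficients.
#'
#' @param fits List of fits from [fit_at_observations()] (or an
#'   [llp_model()]).
#' @return Data frame with columns `point_id`, `x0_*`, `beta0`, `beta1`,
#'   ..., `converged`, `n_iter`, `loglik`.
#' @export
coef_table <- function(fits) {
  if (inherits(fits, "llp_model")) fits <- fits$fits
  ok <- vapply(fits, inherits, logical(1), "local_fit")
  k <- length(fits[[which(ok)[1]]]$beta)
  p <- k - 1L
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "local_fit")) {
      c(i, f$x0, f$beta, as.numeric(f$converged), f$n_iter, f$loglik)
    } else {
      c(i, rep(NA_real_, p), rep(NA_real_, k), 0, NA_real_, NA_real_)
    }
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("point_id", paste0("x0_", seq_len(p)),
                  paste0("beta", 0:p), "converged", "n_iter", "loglik")
  out$converged <- out$converged == 1
  out
}

#' Global Poisson GLM baseline
#'
#' Newton-Raphson maximum likelihood on the uncentered design with unit
#' weights: the ordinary log-linear Poisson regression
#' `m(x) = exp(b0 + b1 x1 + ... + bp xp)` used as the comparison baseline
#' for the local model.
#'
#' @param data A [count_dataset()].
#' @param opts A [fit_options()].
#' @return Object of class `global_fit`: `beta` (named, intercept first),
#'   `loglik`, `fitted` (means at the observations), `fisher`, `converged`,
#'   `n_iter`.
#' @export
fit_global <- function(data, opts = fit_options()) {
  n <- length(data$y)
  Xc <- cbind(1, data$X)
  colnames(Xc) <- c("(intercept)", data$names)
  design <- structure(list(Xc = Xc, w = rep(1, n), y = data$y,
                           x0 = rep(0, ncol(data$X))),
                      class = "local_design")
  ols <- tryCatch(ols_init(data, rep(0, ncol(data$X))),
                  error = function(e) NULL)
  fit <- newton_raphson(design, choose_init(design, ols), opts)
  structure(list(
    beta = stats::setNames(fit$beta, colnames(Xc)),
    loglik = fit$loglik,
    fitted = exp(drop(Xc %*% fit$beta)),
    fisher = fit$fisher,
    converged = fit$converged,
    n_iter = fit$n_iter
  ), class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat("Global Poisson regression (log link)\n")
  print(x$beta)
  cat(sprintf("loglik %.6g, converged %s in %d iterations\n",
              x$loglik, x$converged, x$n_iter))
  invisible(x)
}

#' Equidispersion diagnostic
#'
#' Ratio of the sample variance to the sample mean of the counts; values
#' near 1 are consistent with the Poisson equidispersion assumption.
#'
#' @param data A [count_dataset()].
#' @return List with `ratio` and the [describe_dataset()] `table`.
#' @export
dispersion_check <- function(data) {
  stopifnot(inherits(data, "count_dataset"), length(data$y) >= 2)
  m <- mean(data$y)
  list(ratio = if (m > 0) stats::var(data$y) / m else 0,
       table = describe_dataset(data))
}
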