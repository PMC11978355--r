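#' Build the centered local design at an evaluation point
#'
#' Constructs the local linear design: an `n x (p+1)` matrix whose first
#' column is all ones and whose remaining columns are the centered offsets
#' `x_ij - x0_j`, together with the product-kernel weights at `x0`. The
#' centered parameterization makes the intercept equal to the log-mean at
#' `x0` and the slopes equal to the partial derivatives of the log-mean
#' there (the first-order Taylor expansion of the unknown regression
#' function).
#'
#' @param data A [count_dataset()].
#' @param x0 Numeric length-`p` evaluation point.
#' @param spec A [kernel_spec()].
#' @return An object of class `local_design`: list with `Xc` (centered
#'   design), `w` (kernel weights), `y`, `x0`.
#' @export
build_local_design <- function(data, x0, spec) {
  stopifnot(inherits(data, "count_dataset"))
  p <- ncol(data$X)
  if (length(x0) != p) {
    stop(sprintf("x0 must have length %d", p), call. = FALSE)
  }
  w <- product_kernel_weights(data$X, x0, spec)
  if (all(w <= 0) || !any(is.finite(w) & w > 0)) {
    stop(sprintf("degenerate neighbourhood at x0 = (%s): all kernel weights are zero",
                 paste(format(x0), collapse = ", ")), call. = FALSE)
  }
  Xc <- cbind(1, sweep(data$X, 2, as.numeric(x0)))
  colnames(Xc) <- c("(intercept)", data$names)
  structure(list(Xc = Xc, w = w, y = data$y, x0 = as.numeric(x0)),
            class = "local_design")
}

#' Linear predictor of a local fit
#'
#' `eta_i = Xc_i . beta` on the centered design. Because the centered row at
#' `x0` itself is `(1, 0, ..., 0)`, the local mean estimate at `x0` is
#' `exp(beta[1])`.
#'
#' @param design A `local_design`.
#' @param beta Length-`(p+1)` coefficient vector (intercept first).
#' @return Length-`n` vector of linear predictors.
#' @export
linear_predictor <- function(design, beta) {
  beta <- as.numeric(beta)
  if (length(beta) != ncol(design$Xc)) {
    stop("beta length must match the design columns", call. = FALSE)
  }
  drop(design$Xc %*% beta)
}

#' Kernel-weighted Poisson log-likelihood
#'
#' The local log-likelihood
#' `l(beta) = sum_i w_i ( y_i eta_i - exp(eta_i) - ln(y_i!) )`,
#' with `ln(y!)` computed through `lgamma(y + 1)` so large counts do not
#' overflow. Overflow of `exp(eta)` yields `-Inf`, which the fitting
#' safeguard treats as a diverged step.
#'
#' @param design A `local_design`.
#' @param beta Coefficient vector.
#' @return The weighted log-likelihood (scalar; `-Inf` on mean overflow).
#' @export
local_loglik <- function(design, beta) {
  eta <- linear_predictor(design, beta)
  mu <- exp(eta)
  ll <- sum(design$w * (design$y * eta - mu - lgamma(design$y + 1)))
  if (is.nan(ll)) ll <- -Inf
  ll
}

#' Score (gradient) of the local log-likelihood
#'
#' `g = Xc' diag(w) (y - exp(eta))`; zero exactly at the local maximum
#' likelihood estimate.
#'
#' @inheritParams local_loglik
#' @return Length-`(p+1)` gradient vector.
#' @export
local_score <- function(design, beta) {
  eta <- linear_predictor(design, beta)
  drop(crossprod(design$Xc, design$w * (design$y - exp(eta))))
}

#' Hessian of the local log-likelihood
#'
#' `H = -Xc' V Xc` with `V = diag(w_i exp(eta_i))`: the kernel weights enter
#' the curvature alongside the Poisson means. `H` is symmetric negative
#' semidefinite, and negative definite whenever the weighted design has full
#' column rank.
#'
#' @inheritParams local_loglik
#' @return `(p+1) x (p+1)` Hessian matrix.
#' @export
local_hessian <- function(design, beta) {
  eta <- linear_predictor(design, beta)
  v <- design$w * exp(eta)
  -crossprod(design$Xc, design$Xc * v)
}

#' Fisher information of the local fit
#'
#' The observed information `I = -H = Xc' V Xc`, positive semidefinite.
#'
#' @inheritParams local_loglik
#' @return `(p+1) x (p+1)` information matrix.
#' @export
fisher_information <- function(design, beta) {
  -local_hessian(design, beta)
}
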