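#' Kernel specification
#'
#' Bundles a kernel family with a vector of per-predictor bandwidths.
#' Observation weights around an evaluation point are formed as the product
#' over predictors of the scaled kernel evaluated at the per-coordinate
#' offsets, each coordinate with its own bandwidth.
#'
#' @param family Kernel family, one of `"gaussian"` (default) or
#'   `"epanechnikov"`. The Gaussian kernel gives strictly positive weights
#'   everywhere, so the local likelihood is well defined at any evaluation
#'   point; the Epanechnikov kernel has compact support `|u| <= 1` and can
#'   produce empty neighbourhoods at small bandwidths.
#' @param bandwidths Numeric vector of positive bandwidths, one per
#'   predictor, in the units of that predictor.
#'
#' @return An object of class `kernel_spec` with elements `family` and
#'   `bandwidths`.
#' @seealso [product_kernel_weights()], [fit_local()]
#' @export
#' @examples
#' kernel_spec("gaussian", c(0.56, 0.35))
kernel_spec <- function(family = c("gaussian", "epanechnikov"), bandwidths) {
  family <- match.arg(family)
  bandwidths <- as.numeric(bandwidths)
  if (length(bandwidths) < 1L || anyNA(bandwidths) || any(bandwidths <= 0)) {
    stop("all bandwidths must be positive reals", call. = FALSE)
  }
  structure(list(family = family, bandwidths = bandwidths),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("Kernel spec: %s, bandwidths (%s)\n",
              x$family, paste(format(x$bandwidths), collapse = ", ")))
  invisible(x)
}

#' Kernel density functions
#'
#' Evaluates a symmetric probability-density kernel `K(u)`. Supported
#' families are the standard Gaussian density and the Epanechnikov kernel
#' `0.75 (1 - u^2)` on `|u| <= 1` (zero outside).
#'
#' @param family Kernel family name.
#' @param u Numeric vector of evaluation points.
#' @return `K(u)`, non-negative, symmetric about zero, integrating to one.
#' @export
#' @examples
#' kernel_density("gaussian", 0)      # 1/sqrt(2*pi)
#' kernel_density("epanechnikov", 1.5) # 0: outside the support
kernel_density <- function(family, u) {
  switch(family,
    gaussian = stats::dnorm(u),
    epanechnikov = ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0),
    stop(sprintf("unknown kernel family '%s'", family), call. = FALSE)
  )
}

#' Bandwidth-scaled kernel
#'
#' Evaluates `K_h(t) = K(t / h) / h`, the density-scaled kernel. The `1/h`
#' factor cancels from the local score equations, so parameter estimates do
#' not depend on this convention; it only sets the scale of reported weight
#' and MLCV magnitudes.
#'
#' @param family Kernel family name.
#' @param h Positive bandwidth.
#' @param t Numeric vector of offsets.
#' @return `K(t/h)/h`.
#' @export
scaled_kernel <- function(family, h, t) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h <= 0) {
    stop("bandwidth h must be a single positive number", call. = FALSE)
  }
  kernel_density(family, t / h) / h
}

#' Product-kernel observation weights
#'
#' Computes, for each observation, the product over predictors of the scaled
#' kernel evaluated at the offset from the evaluation point:
#' `w_i = prod_j K_hj(x_ij - x0_j)`. Weights are largest for observations
#' closest to `x0` and are not renormalized; only weight ratios matter for
#' the locally weighted likelihood.
#'
#' @param X Numeric matrix (`n x p`) of predictors.
#' @param x0 Numeric length-`p` evaluation point.
#' @param spec A [kernel_spec()] whose bandwidth vector has length `p`.
#' @return Length-`n` non-negative weight vector.
#' @export
#' @examples
#' X <- cbind(c(1, 2, 3), c(4, 5, 6))
#' product_kernel_weights(X, c(2, 5), kernel_spec("gaussian", c(1, 1)))
product_kernel_weights <- function(X, x0, spec) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (length(x0) != p || length(spec$bandwidths) != p) {
    stop(sprintf(
      "dimension mismatch: X has %d columns, x0 length %d, bandwidths length %d",
      p, length(x0), length(spec$bandwidths)), call. = FALSE)
  }
  w <- rep(1, nrow(X))
  for (j in seq_len(p)) {
    w <- w * scaled_kernel(spec$family, spec$bandwidths[j], X[, j] - x0[j])
  }
  w
}
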