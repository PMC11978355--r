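#' Leave-one-out local estimate at an observation
#'
#' Deletes row `i`, fits the local model at `x0 = x_i` on the remaining
#' rows, and returns the estimated log-mean there: the centered intercept
#' of the leave-one-out fit, which is the only value the local
#' parameterization defines at the evaluation point itself.
#'
#' @param data A [count_dataset()].
#' @param i Row index to leave out.
#' @param spec A [kernel_spec()].
#' @param opts A [fit_options()].
#' @return The leave-one-out log-mean estimate at `x_i` (scalar). Errors
#'   from degenerate neighbourhoods or non-convergence propagate so callers
#'   can record the failure.
#' @export
loo_estimate <- function(data, i, spec, opts = fit_options()) {
  n <- length(data$y)
  stopifnot(i >= 1, i <= n)
  if (n - 1L < ncol(data$X) + 2L) {
    stop("too few rows after deletion for a local fit", call. = FALSE)
  }
  keep <- setdiff(seq_len(n), i)
  d <- count_dataset(data$y[keep], data$X[keep, , drop = FALSE],
                     names = data$names)
  fit <- fit_local(d, data$X[i, ], spec, opts)
  if (!fit$converged) {
    stop(sprintf("leave-one-out fit at row %d did not converge", i),
         call. = FALSE)
  }
  fit$beta[1]
}

#' Leave-one-out maximum-likelihood cross-validation score
#'
#' `MLCV(h) = sum_i ( m_{-i}(x_i) y_i - exp(m_{-i}(x_i)) - ln(y_i!) )`,
#' the sum of leave-one-out predictive Poisson log-densities. Larger is
#' better; the bandwidth maximizing it is selected.
#'
#' Leave-one-out fits that fail (degenerate neighbourhood under a compact
#' kernel, non-convergence) are dropped from the sum with their count
#' recorded; if more than 20% fail the score is returned as `NA` (grid
#' point invalid).
#'
#' @inheritParams loo_estimate
#' @return The MLCV score with attribute `n_failed`.
#' @export
mlcv <- function(data, spec, opts = fit_options()) {
  n <- length(data$y)
  terms <- vapply(seq_len(n), function(i) {
    m_i <- tryCatch(loo_estimate(data, i, spec, opts),
                    error = function(e) NA_real_)
    if (is.na(m_i)) return(NA_real_)
    m_i * data$y[i] - exp(m_i) - lgamma(data$y[i] + 1)
  }, numeric(1))
  n_failed <- sum(is.na(terms))
  score <- if (n_failed > 0.2 * n) NA_real_ else sum(terms, na.rm = TRUE)
  structure(score, n_failed = n_failed)
}

#' Bandwidth selection by MLCV grid search
#'
#' Evaluates the MLCV score over a bandwidth grid and returns the argmax.
#' In `joint` mode the grid is a list of full bandwidth vectors (or a
#' matrix with one vector per row) scanned exhaustively. In
#' `per_predictor` mode the grid is a list of `p` one-dimensional grids,
#' scanned coordinate-wise: each `h_j` is scanned over its own grid holding
#' the other bandwidths at their current best, in one pass over the
#' coordinates.
#'
#' Ties break deterministically to the earliest grid point; grid points
#' whose score is `NA` (too many leave-one-out failures) are excluded from
#' the argmax.
#'
#' @param data A [count_dataset()].
#' @param grid Bandwidth grid (see Details above).
#' @param opts A [fit_options()].
#' @param mode `"per_predictor"` (default) or `"joint"`.
#' @param family Kernel family passed to [kernel_spec()].
#' @return Object of class `mlcv_result`: data frame `grid` (columns
#'   `h_1..h_p`, `mlcv`, `n_failed`), `best` bandwidth vector, `best_mlcv`.
#' @export
select_bandwidth <- function(data, grid, opts = fit_options(),
                             mode = c("per_predictor", "joint"),
                             family = "gaussian") {
  mode <- match.arg(mode)
  p <- ncol(data$X)
  eval_point <- function(h) {
    s <- mlcv(data, kernel_spec(family, h), opts)
    c(h, as.numeric(s), attr(s, "n_failed"))
  }
  if (mode == "joint") {
    if (is.matrix(grid)) grid <- lapply(seq_len(nrow(grid)), function(r) grid[r, ])
    if (!length(grid)) stop("empty bandwidth grid", call. = FALSE)
    rows <- t(vapply(grid, eval_point, numeric(p + 2L)))
  } else {
    if (!is.list(grid) || length(grid) != p) {
      stop(sprintf("per_predictor mode needs a list of %d one-dimensional grids", p),
           call. = FALSE)
    }
    # start from each coordinate's median grid value, then one coordinate pass
    current <- vapply(grid, function(g) g[ceiling(length(g) / 2)], numeric(1))
    rows <- NULL
    for (j in seq_len(p)) {
      res_j <- t(vapply(grid[[j]], function(hj) {
        h <- current
        h[j] <- hj
        eval_point(h)
      }, numeric(p + 2L)))
      rows <- rbind(rows, res_j)
      valid <- !is.na(res_j[, p + 1L])
      if (!any(valid)) next
      best_j <- which(valid)[which.max(res_j[valid, p + 1L])]
      current[j] <- grid[[j]][best_j]
    }
  }
  out <- as.data.frame(rows)
  names(out) <- c(paste0("h_", seq_len(p)), "mlcv", "n_failed")
  valid <- !is.na(out$mlcv)
  if (!any(valid)) stop("all bandwidth grid points were invalid", call. = FALSE)
  best_row <- which(valid)[which.max(out$mlcv[valid])]
  structure(list(
    grid = out,
    best = as.numeric(out[best_row, seq_len(p)]),
    best_mlcv = out$mlcv[best_row]
  ), class = "mlcv_result")
}

#' @export
print.mlcv_result <- function(x, ...) {
  cat(sprintf("MLCV bandwidth selection over %d grid points\n", nrow(x$grid)))
  cat(sprintf("  best bandwidths: (%s), MLCV = %.6f\n",
              paste(format(x$best), collapse = ", "), x$best_mlcv))
  invisible(x)
}
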