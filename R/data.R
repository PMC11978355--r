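#' Count dataset container
#'
#' Validates and bundles a count response with a matrix of numeric
#' predictors. The response must be non-negative integers (Poisson counts);
#' missing values are rejected, and there must be more rows than fitted
#' parameters (`n > p + 1`).
#'
#' @param y Numeric vector of non-negative integer counts.
#' @param X Numeric matrix or data frame of predictors (`n x p`, `p >= 1`).
#' @param names Optional character vector of `p` predictor labels; defaults
#'   to the column names of `X` or `x1..xp`.
#' @return An object of class `count_dataset` with elements `y` (integer
#'   vector), `X` (numeric matrix) and `names`.
#' @export
#' @examples
#' d <- count_dataset(c(3, 0, 7), cbind(a = 1:3, b = c(2, 2, 5)))
#' d$names
count_dataset <- function(y, X, names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("y and X must have the same number of rows", call. = FALSE)
  if (anyNA(y) || anyNA(X)) {
    bad <- which(is.na(y) | rowSums(is.na(X)) > 0)
    stop(sprintf("missing values in rows: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(y < 0 | y != round(y))
  if (length(bad)) {
    stop(sprintf("response must be non-negative integers; offending row %d (value %s)",
                 bad[1], format(y[bad[1]])), call. = FALSE)
  }
  if (n <= p + 1L) {
    stop(sprintf("need n > p + 1 rows (got n = %d, p = %d)", n, p), call. = FALSE)
  }
  if (is.null(names)) {
    names <- colnames(X)
    if (is.null(names)) names <- paste0("x", seq_len(p))
  }
  if (length(names) != p) stop("names must have one label per predictor", call. = FALSE)
  colnames(X) <- names
  structure(list(y = as.integer(round(y)), X = X, names = names),
            class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("Count dataset: n = %d, predictors: %s\n",
              length(x$y), paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Read a count dataset from delimited text
#'
#' Reads a CSV (or TSV) file with a header, validates the named columns and
#' returns a [count_dataset()]. Validation failures cite the offending row.
#'
#' @param path File path.
#' @param response Name of the count response column.
#' @param predictors Character vector of predictor column names.
#' @param sep Field separator, `","` by default; use `"\t"` for TSV.
#' @return A [count_dataset()].
#' @export
read_count_dataset <- function(path, response, predictors, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("column(s) not found in '%s': %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (response %in% predictors) {
    stop("response column must be distinct from the predictor columns",
         call. = FALSE)
  }
  y <- suppressWarnings(as.numeric(df[[response]]))
  if (anyNA(y)) {
    stop(sprintf("response column '%s' has non-numeric value at row %d",
                 response, which(is.na(y))[1]), call. = FALSE)
  }
  X <- as.matrix(df[predictors])
  storage.mode(X) <- "double"
  count_dataset(y, X, names = predictors)
}

#' Write a count dataset to CSV
#'
#' Values are written at full precision so a write/read round trip is
#' lossless.
#'
#' @param data A [count_dataset()].
#' @param path Output file path.
#' @param response Name for the response column.
#' @export
write_count_dataset <- function(data, path, response = "y") {
  df <- data.frame(data$y, data$X, check.names = FALSE)
  names(df) <- c(response, data$names)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive statistics table
#'
#' Per-column mean, minimum, maximum and sample standard deviation
#' (n - 1 denominator) for the response and every predictor.
#'
#' @param data A [count_dataset()].
#' @return Data frame with one row per column.
#' @export
describe_dataset <- function(data) {
  stopifnot(inherits(data, "count_dataset"))
  cols <- cbind(y = data$y, data$X)
  data.frame(
    variable = colnames(cols),
    mean = colMeans(cols),
    min = apply(cols, 2, min),
    max = apply(cols, 2, max),
    sd = apply(cols, 2, stats::sd),
    row.names = NULL
  )
}
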