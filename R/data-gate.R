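# Input validation and cleaning shared by every user-facing entry point.
# Enforces: numeric inputs, equal lengths, pairwise-complete removal of
# missing values, at least two remaining observations, and at least two
# distinct values per column (zero variance is not testable by a rank
# method).  Infinite values pass through: a rank-based statistic only needs
# order.  Idempotent on already-clean data.
check_data <- function(x, y) {
  if (is.matrix(x) && is.matrix(y)) {
    if (!all(dim(x) == dim(y))) {
      stop("'x' and 'y' must have the same dimensions", call. = FALSE)
    }
    x <- as.vector(x)
    y <- as.vector(y)
  }
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("'x' and 'y' must be numeric", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have the same dimensions (lengths ",
         length(x), " and ", length(y), ")", call. = FALSE)
  }
  keep <- !(is.na(x) | is.na(y))
  x <- as.numeric(x[keep])
  y <- as.numeric(y[keep])
  if (length(x) < 2L) {
    stop("insufficient data: fewer than two complete observations",
         call. = FALSE)
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("zero variance: 'x' or 'y' is constant after removing missing values",
         call. = FALSE)
  }
  list(x = x, y = y, n = length(x))
}

#' Pairwise Kendall correlation matrix
#'
#' Computes Kendall's tau-b between every pair of columns, using
#' pairwise-complete observations for each pair (rows are dropped only where
#' one of the two columns involved is missing).  A column pair that fails
#' validation — fewer than two complete rows, or a constant column — yields
#' `NA` with a warning rather than an error.
#'
#' @param data numeric matrix or data frame with at least two columns.
#' @return Symmetric matrix of tau values with unit diagonal, with dimnames
#'   taken from the columns of `data`.
#' @examples
#' arcade <- arcade_data()
#' tau_matrix(arcade[, c("doctorates", "revenue")])
#' @export
tau_matrix <- function(data) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("'data' must be numeric", call. = FALSE)
  p <- ncol(data)
  if (p < 2L) stop("'data' must have at least two columns", call. = FALSE)
  out <- diag(1, p)
  nm <- colnames(data)
  dimnames(out) <- list(nm, nm)
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      tau <- tryCatch(
        kendall_cor(data[, i], data[, j]),
        error = function(e) {
          warning("columns ", i, " and ", j, ": ", conditionMessage(e),
                  call. = FALSE)
          NA_real_
        }
      )
      out[i, j] <- out[j, i] <- tau
    }
  }
  out
}
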