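#' Fast Kendall rank correlation (tau-b)
#'
#' Computes Kendall's tau-b between two numeric vectors in O(n log n) time
#' using Knight's sort-and-count-inversions algorithm: the data are sorted by
#' x (breaking x-ties by y), tie pairs in x, in y and jointly are counted,
#' and the discordant pairs are obtained as the number of inversions of the
#' reordered y counted during a merge sort.  Ties are handled with the tau-b
#' correction
#' \deqn{\tau_b = \frac{c - d}{\sqrt{(m - T_x)(m - T_y)}},}
#' where \eqn{c} and \eqn{d} are the concordant and discordant pair counts,
#' \eqn{m = n(n-1)/2}, and \eqn{T_x}, \eqn{T_y} are the numbers of pairs tied
#' in x and in y.
#'
#' Missing values are removed pairwise; after removal at least two
#' observations must remain and both vectors must have at least two distinct
#' values.  Infinite values are valid (only order matters); ties are defined
#' by exact floating-point equality.
#'
#' If `x` is a matrix or data frame and `y` is omitted, the full pairwise
#' correlation matrix is returned (see [tau_matrix()]).
#'
#' @param x numeric vector, or a numeric matrix/data frame whose columns are
#'   variables.
#' @param y numeric vector of the same length as `x`; omit when `x` is a
#'   matrix.
#' @return A single correlation in `[-1, 1]`, or a symmetric matrix when `x`
#'   is a matrix and `y` is omitted.
#' @examples
#' arcade <- arcade_data()
#' kendall_cor(arcade$doctorates, arcade$revenue)
#' @seealso [kendall_cor_test()] for hypothesis tests and confidence
#'   intervals, [kendall_cor_ref()] for the definitional O(n^2) reference.
#' @export
kendall_cor <- function(x, y = NULL) {
  if (is.null(y)) {
    if (!(is.matrix(x) || is.data.frame(x))) {
      stop("'y' is missing: supply two vectors or a matrix 'x'", call. = FALSE)
    }
    return(tau_matrix(x))
  }
  sample <- check_data(x, y)
  knight_tau(sample)$tau
}

# Full Knight computation on a validated sample; returns tau plus the tie
# summary (m, tie pairs in x / y / jointly, merge-sort swap count) and the
# numerator S = c - d used by the approximate test.
knight_tau <- function(sample, threshold = 10L) {
  res <- knight_tau_cpp(sample$x, sample$y, threshold)
  if (is.na(res$tau)) {
    stop("zero variance: all x values or all y values are tied", call. = FALSE)
  }
  res
}

# Sorting primitives, exposed for verification: both return the input sorted
# nondecreasingly together with its inversion count (pairs i < j with
# v[i] > v[j]; ties not counted).
insertion_sort_count <- function(values) {
  insertion_sort_count_cpp(as.numeric(values))
}

merge_sort_count <- function(values, threshold = 10L) {
  merge_sort_count_cpp(as.numeric(values), as.integer(threshold))
}

# Tied pairs in a nondecreasing vector: sum over runs of equal values of
# L(L-1)/2.  Unsorted input is a contract violation.
count_tie_pairs <- function(sorted_values) {
  count_tie_pairs_cpp(as.numeric(sorted_values))
}
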