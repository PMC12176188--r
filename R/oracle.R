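#' Definitional pair classification for Kendall's tau
#'
#' Classifies every unordered pair of observations by a direct O(n^2) scan:
#' concordant (`(x_i - x_j)(y_i - y_j) > 0`), discordant (`< 0`), tied in x
#' only, tied in y only, or tied in both.  The counts always partition the
#' \eqn{m = n(n-1)/2} pairs.  This is the definitional reference
#' implementation used to verify the O(n log n) engine; it is deliberately
#' independent of the fast code path.
#'
#' @param x,y numeric vectors of equal length (validated and cleaned the same
#'   way as in [kendall_cor()]).
#' @return A list with components `c` (concordant), `d` (discordant), `e`
#'   (tied in x only), `f` (tied in y only), `joint` (tied in both) and `m`.
#' @examples
#' arcade <- arcade_data()
#' concordance_counts(arcade$doctorates, arcade$revenue)
#' @export
concordance_counts <- function(x, y) {
  sample <- check_data(x, y)
  x <- sample$x
  y <- sample$y
  n <- length(x)
  ut <- upper.tri(matrix(0, n, n))
  # order comparisons, not sign of differences, so +/-Inf pairs classify
  # correctly (Inf - Inf is NaN)
  sx <- (outer(x, x, "<") - outer(x, x, ">"))[ut]
  sy <- (outer(y, y, "<") - outer(y, y, ">"))[ut]
  prod <- sx * sy
  list(
    c = sum(prod > 0),
    d = sum(prod < 0),
    e = sum(sx == 0 & sy != 0),
    f = sum(sx != 0 & sy == 0),
    joint = sum(sx == 0 & sy == 0),
    m = n * (n - 1) / 2
  )
}

#' Definitional O(n^2) Kendall tau-b
#'
#' Computes tau-b straight from the pair classification of
#' [concordance_counts()]:
#' \eqn{(c - d)/\sqrt{(c + d + e)(c + d + f)}}.  With no ties this reduces to
#' \eqn{(c - d)/m = 4c/(n(n-1)) - 1}.  Quadratic in n; intended as a
#' cross-check of [kendall_cor()] on small inputs, which implements the same
#' quantity in O(n log n).
#'
#' @inheritParams concordance_counts
#' @return Kendall's tau-b.
#' @examples
#' kendall_cor_ref(c(1, 2, 3), c(3, 2, 1))
#' @export
kendall_cor_ref <- function(x, y) {
  counts <- concordance_counts(x, y)
  denom <- sqrt(counts$c + counts$d + counts$e) *
    sqrt(counts$c + counts$d + counts$f)
  if (denom == 0) {
    stop("zero variance: all x values or all y values are tied", call. = FALSE)
  }
  (counts$c - counts$d) / denom
}
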