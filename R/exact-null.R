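#' Exact null distribution of the Kendall statistic
#'
#' `ckendall(k, n)` returns the number of permutations of `n` items whose
#' inversion statistic equals `k` — the counts underlying the exact null
#' distribution of the concordant-pair statistic `T` for untied data.  They
#' satisfy the recursion \eqn{w(n, k) = \sum_{i=0}^{n-1} w(n-1, k-i)} with
#' \eqn{w(1, 0) = 1}, computed with memoization; `k` outside
#' \eqn{[0, n(n-1)/2]} yields 0.
#'
#' `pkendall(q, n)` is the CDF \eqn{P(T \le \lfloor q \rfloor)}, the counts
#' summed and normalized by \eqn{\Gamma(n + 1) = n!}.  Values below 0 map to
#' 0 and values at or above the maximum \eqn{u = n(n-1)/2} map to 1.
#'
#' Counts are stored as doubles: they are exact integers up to `n = 18`
#' (`n! < 2^53`) and remain accurate relative approximations well beyond the
#' `n < 50` range where the exact test is used.
#'
#' @param k integer vector of statistic values.
#' @param q numeric vector of quantiles.
#' @param n number of observations (a single integer, `n >= 1`).
#' @return For `ckendall`, permutation counts; for `pkendall`, probabilities
#'   in `[0, 1]`, vectorized over the first argument.
#' @examples
#' ckendall(0:3, 3)           # 1 2 2 1 over the 6 permutations
#' pkendall(1, 3)             # (1 + 2) / 6
#' sum(ckendall(0:45, 10))    # 10!
#' @export
ckendall <- function(k, n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  ckendall_cpp(as.integer(k), n)
}

#' @rdname ckendall
#' @export
pkendall <- function(q, n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 1L)
  pkendall_cpp(as.numeric(q), n)
}

# Gamma function used to normalize the exact-null counts (Gamma(n+1) = n!).
# Delegates to R's implementation, which covers the reflection formula for
# negative non-integer arguments; nonpositive-integer poles return NaN.
gammafn <- function(x) {
  suppressWarnings(base::gamma(x))
}
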