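#' Test of association based on Kendall's tau
#'
#' Tests the null hypothesis that Kendall's correlation between `x` and `y`
#' is zero, with tau computed by the O(n log n) engine of [kendall_cor()].
#'
#' Two inference paths are available.  The *exact* path (valid only without
#' ties) takes the number of concordant pairs `T` as the statistic and
#' evaluates tail probabilities from the exact permutation null distribution
#' via [pkendall()]; the one-sided p-values are
#' \eqn{P(T \ge T_{obs}) = 1 - pkendall(T_{obs} - 1, n)} and
#' \eqn{P(T \le T_{obs}) = pkendall(T_{obs}, n)}, and the two-sided p-value
#' is twice the smaller tail, capped at 1.  The *approximate* path
#' standardizes the numerator \eqn{S = c - d} by the tie-corrected null
#' variance
#' \deqn{v = \frac{v_0 - v_t - v_u}{18} + v_1 + v_2,}
#' with \eqn{v_0 = n(n-1)(2n+5)}, \eqn{v_t = \sum_t t(t-1)(2t+5)} over tie
#' run lengths in x (and \eqn{v_u} over y), and the usual pairwise and triple
#' products \eqn{v_1, v_2}; with no ties this reduces to
#' \eqn{n(n-1)(2n+5)/18}.  With `continuity = TRUE`, 1 is subtracted from
#' `|S|` before standardizing.
#'
#' By default (`exact = NULL`) the exact path is used when there are no ties
#' and `n < 50`, otherwise the normal approximation.  Requesting
#' `exact = TRUE` with tied data is an error: the permutation null assumes
#' untied ranks.
#'
#' The confidence interval is the normal-approximation interval of
#' [kendall_ci()] at level `conf.level`.
#'
#' @param x,y numeric vectors of equal length; missing values are removed
#'   pairwise.
#' @param alternative direction of the alternative hypothesis:
#'   `"two.sided"`, `"greater"` (tau > 0) or `"less"`.
#' @param conf.level confidence level for the reported interval, in (0, 1).
#' @param exact `NULL` to decide automatically, or `TRUE`/`FALSE` to force
#'   the exact/approximate path.
#' @param continuity if `TRUE`, apply the continuity correction on the
#'   approximate path.
#' @return An object of class `"htest"` with components `estimate` (tau),
#'   `statistic` (`T`, concordant pairs, on the exact path; `z` otherwise),
#'   `p.value`, `conf.int`, `alternative` and `method`.
#' @examples
#' arcade <- arcade_data()
#' kendall_cor_test(arcade$doctorates, arcade$revenue,
#'                  alternative = "greater", conf.level = 0.80)
#' @export
kendall_cor_test <- function(x, y,
                             alternative = c("two.sided", "greater", "less"),
                             conf.level = 0.95,
                             exact = NULL,
                             continuity = FALSE) {
  alternative <- match.arg(alternative)
  if (!is.numeric(conf.level) || length(conf.level) != 1L ||
      conf.level <= 0 || conf.level >= 1) {
    stop("'conf.level' must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)))
  sample <- check_data(x, y)
  kt <- knight_tau(sample)
  n <- sample$n
  has_ties <- kt$tie_x > 0 || kt$tie_y > 0

  if (is.null(exact)) {
    do_exact <- !has_ties && n < 50L
  } else {
    do_exact <- isTRUE(exact)
    if (do_exact && has_ties) {
      stop("exact test requested but ties are present; ",
           "the exact null distribution assumes untied data", call. = FALSE)
    }
  }

  if (do_exact) {
    # no ties: d = swaps, c = m - swaps, so T = (S + m) / 2
    T_stat <- round((kt$S + kt$m) / 2)
    p_greater <- 1 - pkendall(T_stat - 1, n)
    p_less <- pkendall(T_stat, n)
    p.value <- switch(alternative,
      two.sided = min(2 * min(p_greater, p_less), 1),
      greater = p_greater,
      less = p_less
    )
    statistic <- c(T = T_stat)
    method <- "Kendall's rank correlation tau"
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    tl <- tie_run_lengths(sample$x)
    ul <- tie_run_lengths(sample$y)
    vt <- sum(tl * (tl - 1) * (2 * tl + 5))
    vu <- sum(ul * (ul - 1) * (2 * ul + 5))
    v1 <- sum(tl * (tl - 1)) * sum(ul * (ul - 1)) / (2 * n * (n - 1))
    v2 <- sum(tl * (tl - 1) * (tl - 2)) * sum(ul * (ul - 1) * (ul - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_S <- (v0 - vt - vu) / 18 + v1 + v2
    shift <- if (continuity) sign(kt$S) else 0
    z <- (kt$S - shift) / sqrt(var_S)
    p.value <- switch(alternative,
      two.sided = min(2 * pnorm(-abs(z)), 1),
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z)
    )
    statistic <- c(z = z)
    method <- paste0("Kendall's rank correlation tau (normal approximation",
                     if (continuity) ", continuity corrected", ")")
  }

  ci <- kendall_ci(kt$tau, n, conf.level = conf.level,
                   alternative = alternative)
  cint <- c(ci$low, ci$high)
  attr(cint, "conf.level") <- conf.level

  structure(
    list(
      statistic = statistic,
      p.value = as.numeric(p.value),
      estimate = c(tau = kt$tau),
      conf.int = cint,
      null.value = c(tau = 0),
      alternative = alternative,
      method = method,
      data.name = dname,
      n = n
    ),
    class = "htest"
  )
}

# run lengths of tied values (only runs of length > 1 matter downstream)
tie_run_lengths <- function(v) {
  r <- rle(sort(v))$lengths
  as.numeric(r)
}

#' Normal-approximation confidence interval for Kendall's tau
#'
#' Builds the interval around an estimated tau from the large-sample null
#' standard error \eqn{se = \sqrt{2(2n+5)/(9n(n-1))}}.  The two-sided
#' interval is \eqn{\tau \pm z_{1-\alpha/2}\, se}; one-sided alternatives
#' keep the same \eqn{z_{1-\alpha/2}} quantile and open the unbounded side to
#' \eqn{\pm 1}.  Bounds are clamped to `[-1, 1]`.
#'
#' @param tau estimated correlation in `[-1, 1]`.
#' @param n sample size, at least 3.
#' @param conf.level confidence level in (0, 1).
#' @param alternative `"two.sided"`, `"greater"` (lower bound only) or
#'   `"less"` (upper bound only).
#' @return List with `low` and `high`.
#' @examples
#' kendall_ci(0.8222222, 10, conf.level = 0.80, alternative = "greater")
#' @export
kendall_ci <- function(tau, n,
                       conf.level = 0.95,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n < 3) stop("'n' must be at least 3 for the interval", call. = FALSE)
  if (conf.level <= 0 || conf.level >= 1) {
    stop("'conf.level' must be strictly between 0 and 1", call. = FALSE)
  }
  se <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  zq <- qnorm(1 - (1 - conf.level) / 2)
  clamp <- function(v) pmin(1, pmax(-1, v))
  switch(alternative,
    two.sided = list(low = clamp(tau - zq * se), high = clamp(tau + zq * se)),
    greater = list(low = clamp(tau - zq * se), high = 1),
    less = list(low = -1, high = clamp(tau + zq * se))
  )
}

#' Pseudo-R-squared from Kendall's correlation
#'
#' The squared Kendall correlation between observed and fitted values, a
#' goodness-of-fit summary used for count-data regressions (e.g. Poisson or
#' quasi-Poisson models with fixed effects) where a conventional R-squared is
#' unavailable.
#'
#' @param observed,fitted numeric vectors of equal length.
#' @return A value in `[0, 1]`.
#' @examples
#' fit <- c(1.1, 1.9, 3.2, 4.1)
#' pseudo_r2(c(1, 2, 3, 4), fit)
#' @export
pseudo_r2 <- function(observed, fitted) {
  kendall_cor(observed, fitted)^2
}
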