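---
title: "Methods: fast Kendall correlation and its inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fast Kendall correlation and its inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taufast)
```

## The statistic

For paired observations $(x_i, y_i)$, $i = 1, \dots, n$, every unordered
pair $(i, j)$ is *concordant* when $(x_i - x_j)(y_i - y_j) > 0$,
*discordant* when the product is negative, and tied otherwise (in $x$, in
$y$, or in both). With $c$ concordant pairs, $d$ discordant pairs,
$m = n(n-1)/2$ total pairs, and $T_x$, $T_y$ the numbers of pairs tied in
$x$ and in $y$ (joint ties counted in both), the tie-corrected coefficient
is

$$\tau_b = \frac{c - d}{\sqrt{(m - T_x)(m - T_y)}},$$

which reduces to $(c - d)/m = 4c/(n(n-1)) - 1$ without ties. Only the
orderings of $x$ and of $y$ enter, so $\tau_b$ is invariant under strictly
increasing transformations of either margin, robust to outliers, and
meaningful for ordinal data. No distributional assumption is needed for the
coefficient itself; the inference below assumes exchangeability under the
null of no association.

## The O(n log n) engine

Classifying all pairs directly is $O(n^2)$. Knight's observation is that
after sorting the data by $x$, the discordant pairs are exactly the
*inversions* of the permuted $y$ sequence, and inversions can be counted as
a side effect of a merge sort in $O(n \log n)$:

1. sort the pairs by $x$, breaking $x$-ties by $y$, and carry $y$ along;
2. count tie pairs in $x$, in $y$, and jointly in $(x, y)$ (sum of
   $L(L-1)/2$ over runs of equal values);
3. merge-sort the reordered $y$, accumulating the number of swaps $s$
   (each time a right-block element overtakes $k$ left-block elements it
   contributes $k$);
4. the numerator is $S = c - d = m - T_x - T_y + T_{xy} - 2s$, and
   $\tau_b = S / \sqrt{(m - T_x)(m - T_y)}$.

The $(x, y)$ tie-break in step 1 matters: it guarantees that pairs tied in
$x$ are already in $y$-order and therefore never register as inversions, so
$s$ counts only pairs discordant among those untied in $x$. Subarrays
shorter than 10 elements are handled by an insertion sort (also counting
swaps); the threshold is a configurable constant of the internal sorting
routines, and the result is independent of it.

The engine is written in C++. Swap and tie counters are stored as doubles
because pair counts reach $n(n-1)/2 \approx 5 \times 10^9$ at $n = 10^5$,
beyond 32-bit range but exactly representable in a double (integers up to
$2^{53}$).

**Verification.** The package also ships the definitional $O(n^2)$ scan
(`concordance_counts()`, `kendall_cor_ref()`), written in plain R on a
deliberately separate code path. The test suite asserts equality of the two
routes to $10^{-12}$ on hundreds of randomized instances ($n$ from 2 to
200, tie-heavy alphabets included), plus the partition identity
$c + d + e + f + \text{joint} = m$ and the symmetry, antisymmetry and
monotone-invariance properties of $\tau$.

## Exact small-sample inference

With no ties, under the null all $n!$ orderings of $y$ relative to $x$ are
equally likely, and the number of concordant pairs $T$ has the classical
inversion distribution: the number of permutations with statistic $k$
satisfies

$$w(n, k) = \sum_{i=0}^{n-1} w(n-1,\, k-i), \qquad w(1, 0) = 1,$$

for $k \in [0, u]$, $u = n(n-1)/2$, and 0 outside. `ckendall()` implements
this recursion with a per-call memoization table of size
$(n+1) \times (u+1)$ (no global state, so results are identical regardless
of call order); `pkendall(q, n)` sums the counts up to $\lfloor q \rfloor$
and normalizes by $\Gamma(n+1) = n!$. The gamma normalizer delegates to R's
own gamma implementation, which satisfies the integer factorial identities
to double precision and handles negative non-integer arguments by the
reflection formula; nonpositive-integer poles return `NaN`.

The exact test reports $T$ as its statistic, with

- $p_\text{greater} = P(T \ge T_\text{obs}) = 1 - \text{pkendall}(T_\text{obs} - 1, n)$,
- $p_\text{less} = P(T \le T_\text{obs}) = \text{pkendall}(T_\text{obs}, n)$,
- two-sided $p = \min(2 \min(p_\text{greater}, p_\text{less}),\, 1)$.

Both one-sided tails include the observed point mass, so
$p_\text{greater} + p_\text{less} \ge 1$ always. Counts are doubles, exact
up to $n = 18$ ($n! < 2^{53}$) and accurate in relative terms far beyond
the range where the exact path is used.

**When the exact path runs.** Under the default `exact = NULL` the exact
test is used when the data have no ties and $n < 50$; this mirrors the
convention users know from `stats::cor.test` and keeps the table fill
negligible. `exact = TRUE` forces it (an error with ties, where the
permutation null is invalid); `exact = FALSE` forces the approximation. The
tests verify that the enumerated distribution matches brute-force
enumeration of all permutations at $n \le 5$, conserves total mass $n!$
and is symmetric for $n \le 12$, and that exact p-values match
`stats::cor.test` (used strictly as an independent cross-check).

## Normal approximation with tie correction

For tied data or large $n$, $S = c - d$ is standardized by the null
variance

$$v = \frac{v_0 - v_t - v_u}{18} + v_1 + v_2,$$

with $v_0 = n(n-1)(2n+5)$, $v_t = \sum_t t(t-1)(2t+5)$ over tie run
lengths $t$ in $x$ (and $v_u$ over $y$),
$v_1 = \sum_t t(t-1) \sum_u u(u-1) / (2n(n-1))$ and
$v_2 = \sum_t t(t-1)(t-2) \sum_u u(u-1)(u-2) / (9 n(n-1)(n-2))$; with no
ties, $v = n(n-1)(2n+5)/18$. With `continuity = TRUE`, 1 is subtracted
from $|S|$ before standardizing, the usual correction for approximating a
discrete statistic by a continuous one. The default is `continuity =
FALSE`, matching the most common convention; the worked example's
comparison value 0.0012822 requires it on, and both settings are tested.
At $n$ between 30 and 49 the continuity-corrected approximation stays
within 0.01 of the exact two-sided p-value (property-tested); without the
correction the gap can reach about 0.016 at mid-range p-values.

## Confidence intervals

The interval uses the large-sample null standard error
$\mathrm{se} = \sqrt{2(2n+5) / (9n(n-1))}$: two-sided
$\tau \pm z_{1-\alpha/2}\,\mathrm{se}$, and for one-sided alternatives the
same $z_{1-\alpha/2}$ quantile with the unbounded side opened to $\pm 1$;
bounds are clamped to $[-1, 1]$. Keeping $z_{1-\alpha/2}$ (rather than
$z_{1-\alpha}$) for one-sided intervals is a deliberate design choice: it
reproduces the worked example's published 80% one-sided lower bound
0.5038182 exactly, and treats the interval as the one-sided projection of
the two-sided interval at the same level. This null-variance interval is
anti-conservative in principle for $|\tau|$ near 1 (the sampling variance
of $\hat\tau$ shrinks there), but in the tested regime it is conservative:
on bivariate-normal data with $\rho = 0.5$ ($\tau = 1/3$) at $n = 200$ the
95% interval covered the truth in well over 90% of 1,000 replicates.
`kendall_ci()` requires $n \ge 3$.

## Validation semantics

All entry points share one gate: inputs must be numeric and of equal
length; rows with a missing value (`NA`/`NaN`) in either member are dropped
pairwise; at least two complete observations must remain; and each margin
must have at least two distinct values — a constant margin has zero
variance and $\tau$ is undefined (error, not `NA`). Infinite values are
accepted: a rank method only needs order. Ties are defined by exact
floating-point equality, with no epsilon; callers who consider nearly-equal
values tied should round before calling. The gate is idempotent.
`tau_matrix()` applies the gate per column pair (pairwise-complete rows); a
pair that fails validation yields `NA` with a warning so one bad column
does not poison the matrix.

## The synthetic generator

`simulate_kendall_sample(n, rho, tie_granularity, seed)` draws from a
bivariate normal with latent Pearson correlation $\rho$, for which
Greiner's relation gives the population value
$\tau = (2/\pi) \arcsin(\rho)$ — the device used throughout the tests to
produce samples with *known* $\tau$. `tie_granularity` rounds both margins
to a grid, inducing ties for tie-handling tests (the rounding perturbs the
effective $\tau$ slightly, so tie-heavy tests assert oracle equality, not a
target value). Seeded draws are reproducible and restore the caller's RNG
state.

What the generator does *not* emulate: heavy-tailed or skewed margins,
ordinal scales with few levels and strong marginal imbalance, monotone but
non-Gaussian dependence structures, and missingness mechanisms. Because
$\tau$ depends only on ranks, the engine's correctness (checked against the
definitional oracle on arbitrary inputs, including small discrete
alphabets) transfers to such data; the *calibration* statements — type-I
error, CI coverage, exact-vs-approximate agreement — are demonstrated under
the Gaussian design and exchangeable nulls only.

## Problem sizes used in the checks

The shipped verification uses: 500 randomized oracle-equivalence instances
at $n \le 200$; exact-null conservation up to $n = 12$ and enumeration up
to $n = 5$; 2,000 null replicates at $n = 20$ for test size (rejection
rate at $\alpha = 0.05$ required within $[0.03, 0.07]$); 1,000 replicates
at $n = 200$ for CI coverage; and $n = 20{,}000$ for parameter recovery
within $\pm 0.02$ of $(2/\pi)\arcsin(0.7)$. A qualitative scaling check
confirms that quadrupling $n$ increases runtime far less than
sixteen-fold; absolute timings are hardware-dependent and not asserted.

## Known limitations

- The exact null distribution is valid only for untied data; there is no
  exact tie-permutation test (the tie-corrected normal approximation is
  used instead), and no Edgeworth-type tail refinement.
- The confidence interval is a normal approximation built from the null
  standard error; it is not a variance-stabilized or bootstrap interval,
  and its coverage is demonstrated, not proven, in the Gaussian regime
  tested.
- Pearson and Spearman coefficients, weighted $\tau$, $\tau_c$ and partial
  $\tau$ are out of scope; base R and dedicated packages already serve
  those needs.
- Null-distribution counts lose integer exactness above $n = 18$, well
  inside the regime where the normal approximation is preferable anyway.
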