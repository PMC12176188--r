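# taufast

Fast Kendall rank correlation (tau-b) with exact and approximate inference.

Kendall's tau is the standard nonparametric measure of monotone association:
it depends only on the ordering of the data, so it is robust to outliers and
appropriate for ordinal scales. The textbook computation classifies all
m = n(n−1)/2 pairs of observations, which is O(n²) and becomes a real
bottleneck at the sample sizes common in genomics, finance and trade
econometrics. `taufast` computes the tie-corrected coefficient

τ_b = (c − d) / √((m − T_x)(m − T_y))

— c and d the concordant and discordant pair counts, T_x and T_y the pairs
tied in x and in y — in O(n log n) with Knight's algorithm: sort by x
(breaking x-ties by y), then count the inversions of the reordered y with a
merge sort; the inversion count is exactly d among the pairs not tied in x.
The core is C++.

Around the coefficient the package provides:

- **Exact small-sample test** (untied data): the null distribution of the
  concordant-pair statistic T is built by the recursion
  w(n, k) = Σᵢ w(n−1, k−i), memoized and normalized by Γ(n+1) = n!
  (`ckendall()`, `pkendall()`).
- **Tie-corrected normal approximation** with optional continuity
  correction, for tied data or large n.
- **Confidence intervals** at any level from the large-sample standard
  error √(2(2n+5)/(9n(n−1))), two-sided or one-sided
  (`kendall_ci()`).
- **Pairwise correlation matrix** with pairwise-complete missing-data
  handling (`tau_matrix()`), a squared-tau **pseudo-R²** for count-data
  regressions (`pseudo_r2()`), a **definitional O(n²) reference**
  implementation used for verification (`kendall_cor_ref()`,
  `concordance_counts()`), and a seeded **bivariate-normal sample
  generator** with controllable ties (`simulate_kendall_sample()`).
- A **command-line interface** for CSV/TSV files (`run_cli()`, plus the
  installed `exec/taufast` script).

## Worked example

The packaged dataset pairs US computer-science doctorates with arcade
revenue, 2000–2009 (n = 10, a strong monotone association with no causal
story — a classic spurious correlation):

```r
library(taufast)
arcade <- arcade_data()

kendall_cor(arcade$doctorates, arcade$revenue)
#> [1] 0.8222222

kendall_cor_test(arcade$doctorates, arcade$revenue,
                 alternative = "greater", conf.level = 0.80)
#>
#> 	Kendall's rank correlation tau
#>
#> data:  arcade$doctorates and arcade$revenue
#> T = 41, p-value = 0.0001788
#> alternative hypothesis: true tau is greater than 0
#> 80 percent confidence interval:
#>  0.5038182 1.0000000
#> sample estimates:
#>       tau
#> 0.8222222
```

Of the 45 pairs, 41 are concordant and 4 discordant, giving
τ = (41 − 4)/45 = 0.822. With no ties and n = 10 the test is exact: T = 41
concordant pairs has upper-tail probability 0.0001788 under the permutation
null, so the one-sided null (no positive association) is firmly rejected;
the 80% one-sided interval for τ is [0.504, 1]. The squared coefficient,
`pseudo_r2(arcade$revenue, arcade$doctorates)`, is 0.6760494.

The same analysis from a shell:

```sh
$ taufast test --fixture arcade --alternative greater --conf-level 0.80
$ taufast cor my_data.csv --x-col dose --y-col response
$ taufast test my_data.csv --format json
```

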