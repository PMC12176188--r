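# Brute-force reference computations, independent of the package's code paths.

# inversion count by direct pair scan: pairs i < j with v[i] > v[j]
brute_inversions <- function(v) {
  n <- length(v)
  if (n < 2) return(0)
  gt <- outer(v, v, ">")
  sum(gt[upper.tri(gt)])
}

# all permutations of 1..n (recursive; only used for tiny n)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- all_perms(n - 1L)
  out <- list()
  for (p in smaller) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# exact distribution of the inversion statistic by enumeration
enum_inversion_counts <- function(n) {
  inv <- vapply(all_perms(n), brute_inversions, numeric(1))
  tabulate(inv + 1L, nbins = n * (n - 1) / 2 + 1L)
}

# random paired sample, optionally tie-heavy (values drawn from a small
# alphabet so long equal runs occur); never returns a constant column
rand_paired <- function(n, ties = FALSE) {
  repeat {
    if (ties) {
      k <- sample(2:max(3, n %/% 4), 1)
      x <- sample(seq_len(k), n, replace = TRUE) + 0
      y <- sample(seq_len(k), n, replace = TRUE) + 0
    } else {
      x <- rnorm(n)
      y <- rnorm(n)
    }
    if (length(unique(x)) > 1 && length(unique(y)) > 1) {
      return(list(x = x, y = y))
    }
  }
}

arcade <- taufast::arcade_data()
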