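test_that("worked example reproduces the published test output", {
  gt <- kendall_cor_test(arcade$doctorates, arcade$revenue,
                         alternative = "greater", conf.level = 0.80)
  expect_equal(unname(gt$statistic), 41)
  expect_equal(signif(gt$p.value, 4), 0.0001788)
  expect_equal(gt$conf.int[1], 0.5038182, tolerance = 1e-3)
  expect_equal(gt$conf.int[2], 1)
  expect_equal(unname(gt$estimate), 0.8222222, tolerance = 1e-7)

  ts <- kendall_cor_test(arcade$doctorates, arcade$revenue)
  expect_equal(unname(ts$statistic), 41)
  expect_equal(signif(ts$p.value, 4), 0.0003577)

  cc <- kendall_cor_test(arcade$doctorates, arcade$revenue,
                         exact = FALSE, continuity = TRUE)
  expect_equal(signif(cc$p.value, 5), 0.0012822)

  # without the continuity correction the z-based p is smaller
  nc <- kendall_cor_test(arcade$doctorates, arcade$revenue, exact = FALSE)
  expect_lt(nc$p.value, cc$p.value)

  lt <- kendall_cor_test(arcade$doctorates, arcade$revenue,
                         alternative = "less")
  expect_gt(lt$p.value, 0.99)
})

test_that("exact path matches stats::cor.test on untied data", {
  set.seed(404)
  for (rep in 1:15) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    for (alt in c("two.sided", "greater", "less")) {
      ours <- kendall_cor_test(x, y, alternative = alt)
      ref <- cor.test(x, y, method = "kendall", alternative = alt)
      expect_match(ours$method, "rank correlation")
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
      expect_equal(unname(ours$estimate), unname(ref$estimate),
                   tolerance = 1e-12)
    }
  }
})

test_that("approximate path matches stats::cor.test on tied data", {
  set.seed(505)
  for (rep in 1:15) {
    n <- sample(10:120, 1)
    s <- rand_paired(n, ties = TRUE)
    for (cont in c(FALSE, TRUE)) {
      ours <- kendall_cor_test(s$x, s$y, exact = FALSE, continuity = cont)
      ref <- suppressWarnings(
        cor.test(s$x, s$y, method = "kendall", exact = FALSE,
                 continuity = cont)
      )
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
      expect_equal(unname(ours$statistic), unname(ref$statistic),
                   tolerance = 1e-10)
    }
  }
})

test_that("exact and approximate p-values agree closely for moderate n", {
  set.seed(606)
  for (rep in 1:20) {
    n <- sample(30:49, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    pe <- kendall_cor_test(x, y, exact = TRUE)$p.value
    # the continuity correction is the appropriate normal approximation to a
    # discrete statistic, and the one comparable to the exact tail
    pa <- kendall_cor_test(x, y, exact = FALSE, continuity = TRUE)$p.value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("the two exact one-sided tails overlap at the observed point", {
  set.seed(707)
  for (rep in 1:10) {
    n <- sample(4:30, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    pg <- kendall_cor_test(x, y, alternative = "greater")$p.value
    pl <- kendall_cor_test(x, y, alternative = "less")$p.value
    expect_gte(pg + pl, 1)
  }
})

test_that("exact-path selection and its guard rails", {
  # ties force the approximation under auto
  withties <- kendall_cor_test(c(1, 1, 2, 3, 4), c(2, 3, 1, 5, 4))
  expect_equal(names(withties$statistic), "z")
  # and requesting exact with ties is an error
  expect_error(
    kendall_cor_test(c(1, 1, 2, 3, 4), c(2, 3, 1, 5, 4), exact = TRUE),
    "ties"
  )
  # large untied n switches to the approximation automatically
  set.seed(808)
  x <- rnorm(60)
  y <- rnorm(60)
  expect_equal(names(kendall_cor_test(x, y)$statistic), "z")
  expect_equal(names(kendall_cor_test(x, y, exact = TRUE)$statistic), "T")
})

test_that("confidence intervals follow the normal construction", {
  ci <- kendall_ci(0.8222222, 10, conf.level = 0.80, alternative = "greater")
  expect_equal(ci$low, 0.5038182, tolerance = 1e-3)
  expect_equal(ci$high, 1)

  # symmetric about 0 when tau = 0
  ci0 <- kendall_ci(0, 25, conf.level = 0.95)
  expect_equal(ci0$low, -ci0$high)

  # conf.level -> 1 widens to the whole range
  ciw <- kendall_ci(0.3, 12, conf.level = 1 - 1e-12)
  expect_equal(ciw$low, -1)
  expect_equal(ciw$high, 1)

  # bounds are clamped
  cih <- kendall_ci(0.95, 10, conf.level = 0.99)
  expect_lte(cih$high, 1)

  expect_error(kendall_ci(0.5, 2), "at least 3")
  expect_error(kendall_cor_test(arcade$doctorates, arcade$revenue,
                                conf.level = 1.2), "conf.level")
})

test_that("95% confidence intervals cover the known population tau", {
  # bivariate normal with rho = 0.5, so true tau = (2/pi) asin(0.5) = 1/3
  true_tau <- 1 / 3
  set.seed(515)
  covered <- 0L
  reps <- 1000
  for (i in seq_len(reps)) {
    s <- simulate_kendall_sample(200, rho = 0.5)
    ci <- kendall_ci(kendall_cor(s$x, s$y), 200, conf.level = 0.95)
    if (ci$low <= true_tau && true_tau <= ci$high) covered <- covered + 1L
  }
  expect_gte(covered / reps, 0.90)
})

test_that("pseudo-R2 is the squared tau", {
  x <- c(2, 4, 6, 9)
  expect_equal(pseudo_r2(x, x), 1)
  expect_equal(pseudo_r2(arcade$doctorates, arcade$revenue),
               0.8222222^2, tolerance = 1e-6)
  # anti-monotone fits score the same as monotone ones
  expect_equal(pseudo_r2(x, rev(x)), 1)
  set.seed(909)
  obs <- rpois(40, 5)
  fit <- obs + rnorm(40, sd = 2)
  r2 <- pseudo_r2(obs, fit)
  expect_true(r2 >= 0 && r2 <= 1)
})
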