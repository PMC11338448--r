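test_that("the shift algorithm reproduces the enumerated distribution", {
  d <- rank_sum_distribution(c(1, 2), c(3, 4))
  expect_equal(d$support, c(6, 8, 10, 12, 14))
  expect_equal(d$counts, c(1, 1, 2, 1, 1))
  expect_equal(d$total, 6)

  # all pooled values tied: a single support point at the doubled mean
  d <- rank_sum_distribution(c(5, 5), 5)
  expect_equal(d$support, 8)       # n1 * (N + 1) on the doubled scale
  expect_equal(d$counts, 3)        # choose(3, 2)
})

test_that("counts always sum to choose(N, n1)", {
  set.seed(19)
  for (i in 1:30) {
    dat <- random_dataset(sample(1:8, 1), sample(1:8, 1), tied = i %% 2 == 0)
    d <- rank_sum_distribution(dat$x, dat$y)
    expect_identical(sum(d$counts), choose(d$N, d$n1))
  }
})

test_that("without ties the distribution matches the classical WMW null", {
  set.seed(23)
  dat <- random_dataset(6, 5, tied = FALSE)
  d <- rank_sum_distribution(dat$x, dat$y)
  # doubled support 2W maps to the Mann-Whitney U = W - n1(n1+1)/2
  u <- d$support / 2 - d$n1 * (d$n1 + 1) / 2
  expect_equal(d$counts / d$total, stats::dwilcox(u, d$n1, d$n2))
  # and the untied distribution is symmetric about its doubled mean
  e2 <- d$n1 * (d$N + 1)
  expect_equal(d$support - e2, rev(e2 - d$support))
  expect_equal(d$counts, rev(d$counts))
})

test_that("exact p-values match their enumerated values on small cases", {
  expect_equal(exact_pvalue(c(1, 2), c(3, 4), "less")$p.value, 1 / 6)
  expect_equal(exact_pvalue(c(1, 2), c(3, 4), "two.sided")$p.value, 2 / 6)
  # degenerate: every assignment gives the same statistic
  for (alt in c("two.sided", "less", "greater"))
    expect_equal(exact_pvalue(c(2, 2, 2), c(2, 2), alt)$p.value, 1)
})

test_that("without ties exact p-values agree with stats::wilcox.test", {
  set.seed(31)
  for (i in 1:20) {
    dat <- random_dataset(sample(2:7, 1), sample(2:7, 1), tied = FALSE)
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(exact_pvalue(dat$x, dat$y, alt)$p.value,
                   stats::wilcox.test(dat$x, dat$y, alternative = alt,
                                      exact = TRUE)$p.value)
    }
  }
})

test_that("shift algorithm and brute-force enumeration agree everywhere", {
  set.seed(37)
  for (i in 1:60) {
    dat <- random_dataset(sample(1:7, 1), sample(1:7, 1), tied = i %% 3 != 0)
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(exact_pvalue(dat$x, dat$y, alt)$p.value,
                   brute_force_pvalue(dat$x, dat$y, alt)$p.value)
    }
  }
})

test_that("brute force refuses oversized problems", {
  expect_error(brute_force_pvalue(rnorm(15), rnorm(15)), "refused")
})

test_that("exact p-values are invariant under group exchange and shifts", {
  set.seed(41)
  for (i in 1:20) {
    dat <- random_dataset(sample(2:7, 1), sample(2:7, 1), tied = TRUE)
    p2 <- exact_pvalue(dat$x, dat$y, "two.sided")$p.value
    expect_equal(exact_pvalue(dat$y, dat$x, "two.sided")$p.value, p2)
    expect_equal(exact_pvalue(dat$x, dat$y, "less")$p.value,
                 exact_pvalue(dat$y, dat$x, "greater")$p.value)
    expect_equal(exact_pvalue(dat$x + 17.3, dat$y + 17.3, "two.sided")$p.value,
                 p2)
  }
})

test_that("the exact test keeps its level: P(p <= a) <= a analytically", {
  set.seed(43)
  for (i in 1:15) {
    dat <- random_dataset(sample(2:7, 1), sample(2:7, 1), tied = TRUE)
    d <- rank_sum_distribution(dat$x, dat$y)
    e2 <- d$n1 * (d$N + 1)
    # two-sided p-value of every achievable statistic, then its exact CDF
    p_all <- vapply(d$support, function(v)
      sum(d$counts[abs(d$support - e2) >= abs(v - e2)]) / d$total, numeric(1))
    for (a in c(0.01, 0.05, 0.1, 0.25, 0.5, 1))
      expect_lte(sum(d$counts[p_all <= a]) / d$total, a + 1e-12)
  }
})

test_that("binary data reduce to Fisher's exact test", {
  # the example table {{2,0},{1,3}}: all two-sided conventions coincide
  p <- exact_pvalue(c(0, 0, 1), c(1, 1, 1), "two.sided")$p.value
  expect_equal(p, 0.4)
  expect_equal(p, stats::fisher.test(matrix(c(2, 0, 1, 3), 2,
                                            byrow = TRUE))$p.value)
})

test_that("permutation counts overflow guard triggers beyond 2^53", {
  expect_error(rank_sum_distribution(rnorm(30), rnorm(30)), "Monte-Carlo")
})
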