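han_adrb2 <- function() list(
  case = as_genotype_counts(c(29, 60, 12), "rs1042713"),
  ctrl = as_genotype_counts(c(16, 48, 28), "rs1042713"))

test_that("genotype and allele contingency tables are assembled correctly", {
  h <- han_adrb2()
  gt <- genotype_table(h$case, h$ctrl)
  expect_identical(dim(gt), c(2L, 3L))
  expect_identical(unname(rowSums(gt)), c(101, 92))
  expect_identical(colnames(gt), c("AA", "AG", "GG"))

  kz <- genotype_table(as_genotype_counts(c(18, 44, 18), "rs2243250"),
                       as_genotype_counts(c(29, 48, 16), "rs2243250"))
  expect_identical(unname(rowSums(kz)), c(80, 93))

  expect_error(genotype_table(h$case,
                              as_genotype_counts(c(1, 1, 1), "rs20541")),
               "different loci")

  expect_identical(unname(allele_table(h$case, h$ctrl, "paper_n")),
                   rbind(c(59, 42), c(40, 52)))
  expect_identical(unname(allele_table(h$case, h$ctrl, "two_n")),
                   rbind(c(118, 84), c(80, 104)))

  mono <- allele_table(as_genotype_counts(c(5, 0, 0), "rs20541"),
                       as_genotype_counts(c(9, 0, 0), "rs20541"))
  expect_match(attr(mono, "untestable"), "monomorphic")
})

test_that("Pearson chi-square reproduces the bundled table statistics", {
  h <- han_adrb2()
  res <- pearson_chi2(genotype_table(h$case, h$ctrl))
  expect_equal(round(res$statistic, 2), 11.09)
  expect_identical(res$df, 2L)
  expect_equal(res$p_value, 0.004, tolerance = 0.1)

  al <- pearson_chi2(allele_table(h$case, h$ctrl, "paper_n"))
  expect_equal(round(al$statistic, 2), 4.30)
  expect_identical(al$df, 1L)

  # independence: proportional rows give a zero statistic
  null <- pearson_chi2(rbind(c(10, 20, 30), c(20, 40, 60)))
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)

  kaz5 <- pearson_chi2(rbind(c(15, 65), c(16, 77)))
  expect_equal(round(kaz5$p_value, 2), 0.79)

  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "degenerate")
  expect_error(pearson_chi2(rbind(c(1, 2, 3), c(4, 5, 6)), yates = TRUE),
               "2 x 2")
})

test_that("Pearson statistic is permutation-invariant and scales linearly", {
  set.seed(7)
  for (i in 1:25) {
    tab <- matrix(sample(1:60, 6, replace = TRUE), 2, 3)
    s0 <- pearson_chi2(tab)$statistic
    expect_equal(pearson_chi2(tab[2:1, ])$statistic, s0)
    expect_equal(pearson_chi2(tab[, c(3, 1, 2)])$statistic, s0)
    k <- sample(2:6, 1)
    expect_equal(pearson_chi2(tab * k)$statistic, k * s0)
  }
  # which is exactly why paper_n allele statistics are half of two_n
  h <- han_adrb2()
  expect_equal(pearson_chi2(allele_table(h$case, h$ctrl, "paper_n"))$statistic,
               pearson_chi2(allele_table(h$case, h$ctrl, "two_n"))$statistic / 2)
})

test_that("Fisher exact matches brute-force hypergeometric enumeration", {
  tab <- rbind(c(2, 8), c(8, 2))
  res <- fisher_exact(tab)
  expect_equal(res$p_value, fisher_enumerate(tab))
  expect_equal(round(res$p_value, 3), 0.023)
  expect_equal(res$statistic, dhyper(2, 10, 10, 10))

  expect_equal(fisher_exact(rbind(c(5, 5), c(5, 5)))$p_value, 1)
  expect_lt(fisher_exact(rbind(c(0, 10), c(10, 0)))$p_value, 1e-4)

  set.seed(11)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6) + 1, 2, 2)
    expect_equal(fisher_exact(tab)$p_value, fisher_enumerate(tab))
  }

  expect_error(fisher_exact(rbind(c(1.5, 2), c(3, 4))), "two_n")
  expect_error(fisher_exact(rbind(c(1, 2, 3), c(4, 5, 6))), "2 x 2")
})

test_that("Fisher and Pearson agree within 0.05 when expected counts are large", {
  # agreement is asymptotic: near the expected-count-5 boundary the exact and
  # chi-square p-values still differ by up to ~0.1, so the sanity bound is
  # checked on comfortably large random tables
  set.seed(23)
  tried <- 0
  while (tried < 30) {
    tab <- matrix(sample(150:750, 4, replace = TRUE), 2, 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) next
    tried <- tried + 1
    expect_lt(abs(fisher_exact(tab)$p_value - pearson_chi2(tab)$p_value), 0.05)
  }
})

test_that("automatic test selection uses Fisher only for sparse 2x2 tables", {
  expect_identical(association_test(rbind(c(1, 30), c(9, 28)))$method, "fisher")
  expect_identical(association_test(rbind(c(20, 30), c(25, 28)))$method,
                   "pearson")
  expect_identical(association_test(rbind(c(2, 3, 40), c(5, 4, 38)))$method,
                   "pearson")  # 2x3 always Pearson
})

test_that("odds ratios and Woolf intervals reproduce the bundled risk rows", {
  h <- odds_ratio_ci(rbind(c(45, 56), c(22, 70)))
  expect_equal(round(h$odds_ratio, 2), 2.56)
  expect_equal(round(c(h$ci_low, h$ci_high), 2), c(1.38, 4.75))

  k <- odds_ratio_ci(rbind(c(15, 65), c(16, 77)))
  expect_equal(round(k$odds_ratio, 2), 1.11)
  expect_equal(round(c(k$ci_low, k$ci_high), 2), c(0.51, 2.42))

  # balanced table: OR 1 with a log-symmetric interval
  b <- odds_ratio_ci(rbind(c(7, 7), c(7, 7)))
  expect_equal(b$odds_ratio, 1)
  expect_equal(b$ci_low * b$ci_high, 1)

  expect_error(odds_ratio_ci(rbind(c(0, 5), c(5, 5))), "haldane")
  hald <- odds_ratio_ci(rbind(c(0, 5), c(5, 5)), haldane = TRUE)
  expect_gt(hald$odds_ratio, 0)
})

test_that("inverting exposure labels maps OR to 1/OR and swaps the interval", {
  set.seed(3)
  for (i in 1:20) {
    tab <- matrix(sample(1:50, 4, replace = TRUE), 2, 2)
    a <- odds_ratio_ci(tab)
    b <- odds_ratio_ci(tab[, 2:1])
    expect_equal(b$odds_ratio, 1 / a$odds_ratio)
    expect_equal(b$ci_low, 1 / a$ci_high)
    expect_equal(b$ci_high, 1 / a$ci_low)
  }
})

test_that("summary t test reproduces the bundled age comparisons", {
  han <- t_test_from_summary(summary_stats(6.48, 2.38, 101),
                             summary_stats(5.74, 3.70, 92))
  expect_equal(round(han$p_value, 3), 0.097)
  expect_equal(han$df, 191)

  kaz <- t_test_from_summary(summary_stats(4.89, 3.63, 80),
                             summary_stats(4.98, 3.37, 93))
  expect_gte(kaz$p_value, 0.85)
  expect_lte(kaz$p_value, 0.87)

  same <- t_test_from_summary(summary_stats(5, 2, 30), summary_stats(5, 2, 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("summary t test agrees with t.test on raw data (pooled and Welch)", {
  set.seed(5)
  x <- rnorm(40, 6, 2); y <- rnorm(55, 5, 3)
  sx <- summary_stats(mean(x), sd(x), length(x))
  sy <- summary_stats(mean(y), sd(y), length(y))
  pooled <- t_test_from_summary(sx, sy, "pooled")
  ref_p <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$statistic, unname(ref_p$statistic))
  expect_equal(pooled$p_value, ref_p$p.value)
  welch <- t_test_from_summary(sx, sy, "welch")
  ref_w <- t.test(x, y)
  expect_equal(welch$statistic, unname(ref_w$statistic))
  expect_equal(welch$df, unname(ref_w$parameter))
  expect_equal(welch$p_value, ref_w$p.value)
})
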