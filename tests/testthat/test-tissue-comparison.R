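test_that("BLQ imputation replaces censored values by the LLOQ", {
  # 8 censored at LLOQ 5.0 plus one quantifiable value reconstructed from
  # the reported mean: 9 * 5.70 - 8 * 5.0 = 11.3
  v <- impute_blq(c(rep(NA, 8), 11.3), c(rep(TRUE, 8), FALSE), lloq = 5.0)
  expect_equal(mean(v), 5.70)
  expect_equal(attr(v, "n_blq"), 8L)
  # no BLQ: identity
  x <- c(1.2, 3.4)
  expect_equal(as.numeric(impute_blq(x, c(FALSE, FALSE), 0.5)), x)
  # all BLQ: degenerate group at the LLOQ
  allb <- impute_blq(rep(NA_real_, 5), rep(TRUE, 5), 5)
  expect_equal(mean(allb), 5)
  expect_equal(sd(allb), 0)
  expect_error(impute_blq(x, c(TRUE, FALSE), lloq = NULL), "LLOQ")
})

test_that("LLOQ imputation is bracketed by zero- and minimum-imputation", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    blq <- runif(n) < 0.4
    val <- ifelse(blq, NA, runif(n, 1, 10))
    if (all(blq) || !any(blq)) next
    lloq <- 0.9   # below the smallest quantifiable value by construction
    m_lloq <- mean(impute_blq(val, blq, lloq))
    m_zero <- mean(ifelse(blq, 0, val))
    m_min <- mean(ifelse(blq, min(val, na.rm = TRUE), val))
    expect_gte(m_lloq, m_zero)
    expect_lte(m_lloq, m_min)
  }
})

test_that("group summaries reproduce printed t-based intervals", {
  fp <- group_summary(n = 9, mean = 5.82, sd = 1.64)
  expect_equal(round(fp$ci, 2), c(4.56, 7.08))
  st <- group_summary(n = 10, mean = 84.5, sd = 56.0)
  expect_equal(st$ci, c(44.4, 124.6), tolerance = 0.002)
  # and the interval is symmetric with the textbook half-width
  expect_equal(diff(st$ci) / 2, qt(0.975, 9) * 56 / sqrt(10))
  # constant group: zero-width interval
  cc <- group_summary(rep(7, 4))
  expect_equal(cc$ci, c(7, 7))
  # raw-data path agrees with the summary path
  set.seed(5)
  x <- rnorm(12, 50, 8)
  expect_equal(group_summary(x)$ci,
               group_summary(n = 12, mean = mean(x), sd = sd(x))$ci)
  expect_error(group_summary(numeric(0)), "empty")
})

test_that("the CI is suppressed for groups containing imputed values", {
  v <- impute_blq(c(rep(NA, 8), 11.3), c(rep(TRUE, 8), FALSE), 5.0)
  gs <- group_summary(v)
  expect_equal(gs$n_blq, 8L)
  expect_true(all(is.na(gs$ci)))
  expect_equal(gs$mean, 5.70)
})

test_that("Welch's test from summaries matches the published table", {
  tb <- table5_summaries()
  w <- welch_test(do.call(group_summary, tb$synovial_tissue$test),
                  do.call(group_summary, tb$synovial_tissue$ref))
  expect_equal(w$statistic, 4.446, tolerance = 1e-3)
  expect_equal(w$df, 9.03, tolerance = 0.01)
  expect_equal(round(w$p.value, 3), 0.002)
  expect_true(w$significant)
  # Welch-Satterthwaite df always lies between min(n)-1 and n1+n2-2
  expect_gte(w$df, 8)
  expect_lte(w$df, 17)
})

test_that("raw-data Welch agrees with t.test and is antisymmetric", {
  set.seed(8)
  for (i in 1:20) {
    x <- rlnorm(10, 3, 0.5)
    y <- rlnorm(9, 2.5, 0.8)
    mine <- welch_test(x, y)
    ref <- t.test(x, y)     # Welch by default
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    flip <- welch_test(y, x)
    expect_equal(flip$statistic, -mine$statistic)
    expect_equal(flip$p.value, mine$p.value)
  }
})

test_that("with equal n and variance Welch reduces to the pooled t", {
  set.seed(9)
  x <- rnorm(8, 10, 2)
  y <- x[sample(8)] + 1          # same sample variance, shifted
  mine <- welch_test(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$statistic, unname(pooled$statistic), tolerance = 1e-10)
  expect_equal(mine$df, unname(pooled$parameter), tolerance = 1e-10)
})

test_that("degenerate Welch inputs behave as specified", {
  x <- c(1, 2, 3, 4)
  ident <- welch_test(x, x)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)
  expect_error(welch_test(rep(3, 4), rep(5, 4)), "zero variance")
  expect_error(welch_test(3, c(1, 2)), "n >= 2")
})

test_that("confidence intervals achieve nominal coverage", {
  set.seed(15)
  hits <- replicate(2000, {
    g <- group_summary(rnorm(10, 50, 12))
    g$ci[1] <= 50 && 50 <= g$ci[2]
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.02)
})

test_that("fold ratios report the test-over-reference mean quotient", {
  expect_equal(fold_ratio(list(mean = 84.5), list(mean = 5.70)), 14.8)
  expect_equal(fold_ratio(list(mean = 149), list(mean = 4.55)), 32.7)
  expect_equal(fold_ratio(list(mean = 3), list(mean = 3)), 1.0)
  expect_error(fold_ratio(list(mean = 1), list(mean = 0)), "positive")
})

test_that("racemate halving is exact and vectorized", {
  expect_equal(sfp_from_racemate(10), 5)
  expect_equal(sfp_from_racemate(0), 0)
  v <- c(0.5, 3, 12)
  expect_equal(sfp_from_racemate(v), v / 2)
  expect_length(sfp_from_racemate(v), 3)
  expect_error(sfp_from_racemate(-1), "non-negative")
})

test_that("the two-group comparison report has the published shape", {
  dat <- simulate_study2(seed = 31)
  cmp <- compare_groups(dat, lloq = study2_targets()$lloq,
                        test = "SFPP", ref = "FP")
  expect_equal(nrow(cmp), 4)
  expect_setequal(cmp$tissue, c("synovial_tissue", "synovial_fluid",
                                "plasma", "absorption_ratio"))
  expect_equal(cmp$n_test, rep(10L, 4))
  expect_equal(cmp$n_ref, rep(9L, 4))
  # imputed reference synovial tissue: CI suppressed, flagged
  i <- cmp$tissue == "synovial_tissue"
  expect_gt(cmp$n_blq_ref[i], 0)
  expect_true(is.na(cmp$ci_lower_ref[i]))
  # significance verdicts match the p-values
  expect_identical(cmp$significant, cmp$p < 0.05)
  # a censorable matrix without an LLOQ is an error
  expect_error(compare_groups(dat, lloq = list(plasma = 0.5),
                              test = "SFPP", ref = "FP"), "missing LLOQ")
})

test_that("p-values format to three decimals with a floor", {
  expect_equal(format_p(0.0016), "0.002")
  expect_equal(format_p(0.04951), "0.050")
  expect_equal(format_p(0.0004), "<0.001")
  expect_equal(format_p(1), "1.000")
})
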