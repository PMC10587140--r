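test_that("median_iqr matches hand values and a sort-based oracle", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)), c(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  expect_error(median_iqr(numeric(0)), "nonempty")
  set.seed(61)
  x <- runif(1000)
  m <- median_iqr(x)
  s <- sort(x)
  # type-7 quantile: linear interpolation at h = (n-1)p + 1
  q7 <- function(p) { h <- (999) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)]) }
  expect_equal(unname(m), c(q7(0.5), q7(0.25), q7(0.75)))
})

test_that("kruskal_wallis reproduces the hand-ranked statistic", {
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kw$df, 1)
  same <- kruskal_wallis(list(a = rep(2, 4), b = rep(2, 5)))
  expect_equal(same$H, 0); expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(list(a = 1:3)), ">= 2")
})

test_that("two-group kruskal-wallis equals the squared rank-sum z (no ties)", {
  set.seed(62)
  x <- sample(1:100, 12); y <- sample(101:200, 9) - runif(9)
  kw <- kruskal_wallis(list(x = x, y = y))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  W <- sum(rank(c(x, y))[seq_len(n1)])
  z <- (W - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(kw$H, z^2, tolerance = 1e-10)
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_error(bonferroni(c(0.1, 0.2), 1), ">=")
})

test_that("fisher_exact matches enumeration on small tables", {
  set.seed(63)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 3), 2, 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab),
                 oracle_fisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("roc_auc obeys the Mann-Whitney identity and its extremes", {
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2, 3))$auc, 1)
  expect_equal(roc_auc(rep(4, 5), rep(4, 8))$auc, 0.5)
  set.seed(64)
  pos <- rnorm(105, 1); neg <- rnorm(30)
  r <- roc_auc(pos, neg)
  pairs <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  expect_equal(r$auc, mean(pairs), tolerance = 1e-12)
  # trapezoid area under the swept curve equals the pair count
  roc <- r$roc[order(r$roc$fpr, r$roc$tpr), ]
  trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
  # independent reference implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(
      c(rep(1, 105), rep(0, 30)), c(pos, neg), quiet = TRUE, direction = "<")))
    expect_equal(r$auc, ref, tolerance = 1e-12)
  }
})

test_that("DME classification uses strict sex-specific CST thresholds", {
  expect_true(classify_dme(321, "male"))
  expect_false(classify_dme(320, "male"))
  expect_true(classify_dme(306, "female"))
  expect_false(classify_dme(305, "female"))
  expect_error(classify_dme(300, "unknown"), "sex")
  expect_error(classify_dme(-1, "male"), "positive")
})

test_that("decimal VA converts to logMAR", {
  expect_equal(decimal_to_logmar(1.0), 0)
  expect_equal(decimal_to_logmar(0.1), 1)
  expect_equal(round(decimal_to_logmar(0.5), 5), 0.30103)
  expect_error(decimal_to_logmar(0), "> 0")
})

test_that("cohort_report emits the standard sector-by-group layout", {
  set.seed(65)
  df <- data.frame(group = rep(c("ctl", "dr"), each = 10),
                   all_sectors = c(runif(10, 0, 0.05), runif(10, 0.1, 0.3)),
                   center = runif(20), nasal = runif(20), superior = runif(20),
                   temporal = runif(20), inferior = runif(20))
  rep1 <- cohort_report(df, "group", auc_sector = "all_sectors",
                        positive_group = "dr")
  expect_equal(rep1$summary$sector,
               c("all_sectors", "center", "nasal", "superior", "temporal",
                 "inferior"))
  expect_true(all(c("ctl", "dr", "p_value") %in% names(rep1$summary)))
  expect_gte(rep1$auc$auc, 0.95)   # constructed separation
  expect_null(rep1$pairwise)

  # identical observations in all groups: p-values of 1 throughout
  df2 <- df; for (s in names(df)[-1]) df2[[s]] <- 1
  rep2 <- cohort_report(df2, "group")
  expect_true(all(rep2$summary$p_value == 1))

  # three groups: Bonferroni-adjusted pairwise table appears
  df3 <- rbind(df, transform(df[1:5, ], group = "x"))
  rep3 <- cohort_report(df3, "group")
  expect_equal(nrow(rep3$pairwise), 6 * 3)
  expect_true(all(rep3$pairwise$p_adj <= 1))
})
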