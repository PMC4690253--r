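test_that("Welch t matches the textbook formula on a worked example", {
  w <- welchT(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(w$t, -1)
  expect_equal(w$df, 8)
  expect_equal(w$p, 2 * pt(-1, 8), tolerance = 1e-12)
})

test_that("Welch t is antisymmetric and null on identical samples", {
  a <- rnorm(12); b <- rnorm(15, 1)
  w1 <- welchT(a, b); w2 <- welchT(b, a)
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$p, w2$p)
  wi <- welchT(a, a)
  expect_equal(wi$t, 0)
  expect_equal(wi$p, 1)
  # degenerate constant samples with equal means
  wc <- welchT(rep(3, 5), rep(3, 4))
  expect_equal(c(wc$t, wc$p), c(0, 1))
  expect_error(welchT(1, 1:5), "n >= 2")
})

test_that("rank-sum exact p matches full enumeration on the 2x2 case", {
  # a = (1,2) is the most extreme of the 6 equally likely assignments
  w <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_true(w$exact)
  expect_equal(w$p, 1 / 3)
})

test_that("identical samples give Z = 0 and p = 1", {
  w <- wilcoxonRankSum(rep(4, 3), rep(4, 3))
  expect_equal(w$Z, 0)
  expect_equal(w$p, 1)
})

test_that("exact and normal-approximation p agree at n = 6 per group", {
  set.seed(17)
  for (i in 1:40) {
    a <- rnorm(6); b <- rnorm(6, 0.5)
    pe <- wilcoxonRankSum(a, b, exact = TRUE)$p
    pn <- wilcoxonRankSum(a, b, exact = FALSE)$p
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("rank-sum p agrees with stats::wilcox.test", {
  set.seed(23)
  for (i in 1:25) {
    a <- rnorm(8); b <- rnorm(9, 0.8)          # no ties: exact on both sides
    ours <- wilcoxonRankSum(a, b, exact = TRUE)$p
    ref <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  # large-sample normal path against wilcox.test's corrected approximation
  a <- rnorm(40); b <- rnorm(45, 0.3)
  expect_equal(wilcoxonRankSum(a, b)$p,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("effect size r follows Z / sqrt(N) and stays within [-1, 1]", {
  w <- structure(list(W = 1, Z = 3.05, p = 0.01, nA = 30, nB = 31),
                 class = "rankSumTest")
  expect_equal(effectSizeR(w, nTotal = 61), 3.05 / sqrt(61))
  expect_equal(round(effectSizeR(w, nTotal = 61), 2), 0.39)
  w$Z <- 0
  expect_equal(effectSizeR(w), 0)
  w$Z <- 1e6
  expect_lte(effectSizeR(w), 1)
  t <- welchT(1:5, 3:7)
  expect_equal(effectSizeR(t, method = "t"),
               sqrt(t$t^2 / (t$t^2 + t$df)))
})

test_that("both tests hold their nominal size under the null", {
  set.seed(99)
  nrep <- 4000
  pw <- numeric(nrep); pr <- numeric(nrep)
  for (i in seq_len(nrep)) {
    a <- rnorm(30, 60, 4); b <- rnorm(31, 60, 4)
    pw[i] <- welchT(a, b)$p
    pr[i] <- wilcoxonRankSum(a, b)$p
  }
  expect_gt(mean(pw < 0.05), 0.04); expect_lt(mean(pw < 0.05), 0.06)
  expect_gt(mean(pr < 0.05), 0.04); expect_lt(mean(pr < 0.05), 0.06)
})

test_that("madSD separates the classes more strongly than madT2", {
  set.seed(7)
  rs <- replicate(300, {
    f <- generateCohortFeatures(30, 31, seed = sample.int(1e6, 1))
    hv <- f[f$label == "HV", ]; acm <- f[f$label == "ACM", ]
    c(abs(effectSizeR(wilcoxonRankSum(hv$madSD, acm$madSD))),
      abs(effectSizeR(wilcoxonRankSum(hv$madT2, acm$madT2))))
  })
  expect_gt(median(rs[1, ]), median(rs[2, ]))
})

test_that("compareGroups reproduces the cohort-table shape", {
  f <- generateCohortFeatures(25, 25, seed = 31)
  cmp <- compareGroups(f)
  expect_setequal(cmp$feature, referenceFeatureMoments()$feature)
  expect_true(all(cmp$p_welch >= 0 & cmp$p_welch <= 1))
  expect_true(all(cmp$p_wilcoxon >= 0 & cmp$p_wilcoxon <= 1))
  expect_true(all(abs(cmp$effect_size_r) <= 1))
})
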