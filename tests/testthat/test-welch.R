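test_that("welchTest handles identical and degenerate inputs", {
  r <- welchTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_true(r$indistinguishable)
  # zero-variance convention: constant groups with different means
  r0 <- welchTest(c(0, 0, 0), c(5, 5, 5), 99)
  expect_equal(r0$p, 0)
  expect_false(r0$indistinguishable)
  expect_equal(welchTest(c(2, 2), c(2, 2))$p, 1)
  expect_error(welchTest(1, c(1, 2)))
})

test_that("welchTest p-values match a numerical t-CDF oracle", {
  cases <- list(list(a = c(1, 2, 3), b = c(2, 3, 4)),
                list(a = c(0.1, 0.5, 0.9, 1.3), b = c(2, 2.2, 2.1)),
                list(a = rnorm(5), b = rnorm(6, 1, 2)))
  for (cs in cases) {
    r <- welchTest(cs$a, cs$b)
    expect_equal(r$p, tCdfTailOracle(r$t, r$df), tolerance = 1e-6)
  }
  # and the Welch statistic itself agrees with the standard formula
  r <- welchTest(c(1, 2, 3), c(2, 3, 4))
  se2 <- var(c(1, 2, 3)) / 3 + var(c(2, 3, 4)) / 3
  expect_equal(r$t, (2 - 3) / sqrt(se2))
})

test_that("welchTest is symmetric and monotone in confidence", {
  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5, 0.5)
    ra <- welchTest(a, b); rb <- welchTest(b, a)
    expect_equal(ra$t, -rb$t)
    expect_equal(ra$p, rb$p)
    expect_equal(ra$df, rb$df)
  }
  test <- matrix(rnorm(30), 3)
  train <- matrix(rnorm(60, 0.8), 6)
  counts <- vapply(c(90, 95, 99, 99.9, 99.999), function(cf)
    countIndistinguishable(test, train, cf)$count, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("indistinguishable counts hit their extremes", {
  p <- 8
  base <- matrix(rep(seq_len(p), each = 6), nrow = 6)
  expect_equal(countIndistinguishable(base[1:3, ], base, 95)$count, p)
  shifted <- base[1:3, ] + 1000
  shifted <- shifted + matrix(rnorm(3 * p, 0, 1e-3), 3)
  noisy <- base + matrix(rnorm(6 * p, 0, 1e-3), 6)
  expect_equal(countIndistinguishable(shifted, noisy, 99.999)$count, 0)
})

test_that("the true isomer wins the count in most cards", {
  hits <- vapply(1:10, function(s) {
    nt <- toyNormalized(seed = 700 + s)
    cmp <- welchCardComparisons(nt, 95)
    ok <- 0; tot <- 0
    for (cd in unique(cmp$card)) for (cl in unique(cmp$test_class)) {
      sub <- cmp[cmp$card == cd & cmp$test_class == cl, ]
      if (!nrow(sub)) next
      tot <- tot + 1
      best <- sub$compare_class[which.max(sub$count)]
      ok <- ok + (best == cl)
    }
    ok / tot
  }, numeric(1))
  expect_gt(mean(hits), 0.5)
})

test_that("ROC construction matches its analytic extremes", {
  sep <- data.frame(count = c(9, 10, 8, 1, 2, 0),
                    positive = rep(c(TRUE, FALSE), each = 3), total = 10)
  r <- rocFromCounts(sep)
  expect_equal(r$auc, 1)
  flat <- data.frame(count = rep(5, 6),
                     positive = rep(c(TRUE, FALSE), 3), total = 10)
  expect_equal(rocFromCounts(flat)$auc, 0.5)
  expect_error(rocFromCounts(data.frame(count = 1:3, positive = TRUE,
                                        total = 5)),
               "positive and one negative")
})

test_that("permuted labels give AUC near 0.5 and monotone transforms
           leave AUC unchanged", {
  set.seed(99)
  counts <- rpois(60, 20)
  labels <- rep(c(TRUE, FALSE), 30)
  aucs <- vapply(1:120, function(i) {
    rocFromCounts(data.frame(count = counts,
                             positive = sample(labels),
                             total = 60))$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
  df <- data.frame(count = counts, positive = labels, total = 60)
  df2 <- data.frame(count = 2 * counts + 3, positive = labels,
                    total = 2 * 60 + 3)
  expect_equal(rocFromCounts(df2)$auc, rocFromCounts(df)$auc)
})

test_that("max-count decision rule applies margin and tie conventions", {
  expect_equal(classifyByMaxCount(c(a = 40, b = 10, c = 8), 5)$assigned,
               "a")
  expect_true(is.na(classifyByMaxCount(c(a = 40, b = 38, c = 8),
                                       5)$assigned))
  expect_true(is.na(classifyByMaxCount(c(a = 40, b = 40, c = 8),
                                       0)$assigned))
})

test_that("replicated Welch runs are reproducible and perfect on
           noiseless separable data", {
  tab <- toyTable(seed = 3, design = smallDesign(1, 2))
  w1 <- runWelchReplicates(tab, NULL, n_replicates = 1, seed = 5)
  w2 <- runWelchReplicates(tab, NULL, n_replicates = 1, seed = 5)
  expect_identical(w1$summary, w2$summary)
  expect_identical(w1$roc, w2$roc)
  # zero-noise generator with class effects: every comparison resolves
  model0 <- toyModel(noise_sd = 1e-6, week_effect_sd = 0,
                     week_shared_sd = 0)
  tab0 <- toyTable(seed = 4, model = model0)
  w0 <- runWelchReplicates(tab0, NULL, n_replicates = 3, seed = 6)
  expect_equal(w0$averaged_auc, 1)
})

test_that("same-day training does not fall behind the full data set on
           average", {
  diffs <- vapply(1:10, function(s) {
    tab <- toyTable(seed = 800 + s, model = toyModel(noise_sd = 0.25,
                                                     week_effect_sd = 0.4,
                                                     week_shared_sd = 0.3))
    full <- runWelchReplicates(tab, NULL, n_replicates = 2,
                               seed = s)$averaged_auc
    day <- runWelchReplicates(tab, NULL, n_replicates = 2, seed = s,
                              scope = "same_day")$averaged_auc
    day - full
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("same-day scope skips single-card days with a warning", {
  tab <- toyTable(seed = 6, design = smallDesign(2, 1))
  nt <- normalizeSpectra(tab, NULL, "ion_current")
  w <- capture_warnings(cmp <- welchCardComparisons(nt, 95, "same_day"))
  expect_match(w, "single card", all = TRUE)
  expect_gt(length(w), 0)
  expect_null(cmp)
})

test_that("per-bin accuracy counts TP and TN as documented", {
  cmp <- data.frame(card = "c", day = 1, test_class = "a",
                    compare_class = c("a", "b", "a", "b"),
                    positive = c(TRUE, FALSE, TRUE, FALSE),
                    count = 0, total = 1)
  # one variable: TP, TN, FN, FP -> accuracy 0.5
  attr(cmp, "indistinguishable") <-
    matrix(c(TRUE, FALSE, FALSE, TRUE), ncol = 1,
           dimnames = list(NULL, "v1"))
  expect_equal(unname(perBinAccuracy(cmp)), 0.5)
  attr(cmp, "indistinguishable") <-
    matrix(c(TRUE, FALSE, TRUE, FALSE), ncol = 1)
  expect_equal(unname(perBinAccuracy(cmp)), 1)
  attr(cmp, "indistinguishable") <-
    matrix(c(FALSE, TRUE, FALSE, TRUE), ncol = 1)
  expect_equal(unname(perBinAccuracy(cmp)), 0)
})
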