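# Small separable data set: one decisive variable plus noise columns.
separableData <- function(n_per = 12, p_noise = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b", "c"), each = n_per)
  x <- matrix(rep(c(0, 10, 20), each = n_per), ncol = 1,
              dimnames = list(NULL, "sep"))
  if (p_noise > 0)
    x <- cbind(x, matrix(rnorm(3 * n_per * p_noise), ncol = p_noise,
                         dimnames = list(NULL,
                                         paste0("n", seq_len(p_noise)))))
  rownames(x) <- paste0("s", seq_along(y))
  list(x = x, y = y)
}

test_that("a perfectly separating variable gives zero OOB error and
           identical refits under one seed", {
  d <- separableData()
  f1 <- fitForest(d$x, d$y, n_trees = 100, seed = 3)
  prof <- oobVoteProfiles(f1)
  expect_equal(errorRate(prof$top_class, d$y), 0)
  f2 <- fitForest(d$x, d$y, n_trees = 100, seed = 3)
  expect_equal(oobVoteProfiles(f2), prof)
})

test_that("OOB vote proportions sum to one and agree with the fitted
           forest's own tally", {
  nt <- toyNormalized(seed = 17)
  f <- fitForest(nt, n_trees = 150, seed = 5)
  prof <- oobVoteProfiles(f)
  pm <- as.matrix(prof[, f$classes])
  expect_lt(max(abs(rowSums(pm) - 1)), 1e-12)
  expect_true(all(pm >= 0 & pm <= 1))
  # contract check: my per-tree tally reproduces randomForest's votes
  expect_equal(unname(pm), unname(as.matrix(f$fit$votes[, f$classes])),
               tolerance = 1e-12)
})

test_that("per-tree OOB fraction matches the bootstrap expectation", {
  d <- separableData(n_per = 20)
  f <- fitForest(d$x, d$y, n_trees = 200, seed = 9)
  oob_frac <- mean(f$fit$inbag == 0)
  n <- nrow(d$x)
  expect_equal(oob_frac, (1 - 1 / n)^n, tolerance = 0.02)
  expect_equal((1 - 1 / n)^n, exp(-1), tolerance = 0.01)
})

test_that("with shuffled labels the forest errs at the 2/3 chance level
           of exchangeable labels", {
  # oracle: any classifier on exchangeable labels has expected hold-out
  # error (K-1)/K = 2/3; OOB error additionally carries the known
  # small-sample pessimistic bias, so it must not dip below chance
  res <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    x <- matrix(rnorm(72 * 5), 72,
                dimnames = list(NULL, paste0("v", 1:5)))
    y <- sample(rep(c("a", "b", "c"), each = 24))
    tr <- seq_len(36)
    f <- fitForest(x[tr, ], y[tr], n_trees = 100, seed = s)
    holdout <- errorRate(as.character(predict(f$fit, x[-tr, ])), y[-tr])
    oob <- errorRate(oobVoteProfiles(f)$top_class, y[tr])
    c(holdout, oob)
  }, numeric(2))
  expect_equal(mean(res[1, ]), 2 / 3, tolerance = 0.05)
  expect_gt(mean(res[2, ]), 2 / 3 - 0.05)
})

test_that("a single-tree forest leaves each sample either OOB or
           profileless", {
  d <- separableData(n_per = 4)
  f <- fitForest(d$x, d$y, n_trees = 1, seed = 2)
  prof <- oobVoteProfiles(f)
  oob <- f$fit$inbag[, 1] == 0
  expect_equal(prof$n_voting_trees, as.integer(oob))
  expect_true(all(is.na(prof$top_class[!oob])))
})

test_that("permutation importance collapses a sole separating variable
           to chance and leaves null variables in the noise band", {
  d <- separableData(n_per = 12, p_noise = 0)
  mdas <- vapply(1:3, function(s) {
    f <- fitForest(d$x, d$y, n_trees = 100, seed = s)
    expect_equal(isomerMS:::.oobAccuracy(f), 1)
    # unpermuted data reproduces the baseline exactly (identity case)
    expect_equal(isomerMS:::.oobAccuracy(f, f$x), 1)
    permutationImportance(f, repeats = 5, seed = s + 8)$mda
  }, numeric(1))
  # oracle: accuracy falls to the 1/K chance level, so MDA ~ 1 - 1/3
  expect_lt(abs(mean(mdas) - 2 / 3), 0.1)

  nt <- toyNormalized(seed = 23)
  fr <- fitForest(nt, seed = 6)
  imp2 <- permutationImportance(fr, repeats = 5, seed = 7)
  # the zero-effect base-peak variable at 30 V carries no class signal
  null_var <- "150.075_30V"
  strong <- imp2$mda[imp2$variable != null_var]
  expect_lt(abs(imp2$mda[imp2$variable == null_var]),
            max(0.02, min(sort(strong, decreasing = TRUE)[1:3])))
  expect_true(all(imp2$rank %in% seq_len(nrow(imp2))))
  expect_equal(sort(imp2$rank), seq_len(nrow(imp2)))
})

test_that("elimination curve halves correctly and stays below chance on
           separable data", {
  d <- separableData(n_per = 12, p_noise = 7)   # p = 8
  curve <- eliminationCurve(d$x, d$y, folds = 6, n_trees = 60, seed = 2)
  expect_equal(curve$n_variables, c(8, 4, 2, 1))
  expect_true(all(curve$cv_error < 2 / 3))
  expect_equal(attr(curve, "variables")[[4]], "sep")
  one <- eliminationCurve(d$x[, "sep", drop = FALSE], d$y, folds = 6,
                          n_trees = 30, seed = 2)
  expect_equal(nrow(one), 1)
  expect_error(eliminationCurve(d$x, d$y, folds = 1000, n_trees = 10),
               "folds")
})

test_that("multiple informative variables keep the halving curve below
           chance at every step", {
  below <- vapply(1:5, function(s) {
    set.seed(4000 + s)
    n <- 36
    y <- rep(c("a", "b", "c"), each = n / 3)
    x <- matrix(rnorm(n * 8), n)
    for (j in 1:4) x[, j] <- x[, j] + rep(c(0, 2.5, -2.5), each = n / 3)
    colnames(x) <- paste0("v", 1:8)
    curve <- eliminationCurve(x, y, folds = 6, n_trees = 60, seed = s)
    all(curve$cv_error < 2 / 3)
  }, logical(1))
  expect_true(all(below))
})

test_that("triplicate rules follow their worked examples", {
  prop <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("A", "B", "C")
    m
  }
  p1 <- prop(c(0.9, 0.05, 0.05), c(0.8, 0.1, 0.1), c(0.7, 0.2, 0.1))
  r <- triplicateConclusion(p1, "all_match", 0.75)
  expect_equal(r$assigned, "A")
  expect_equal(r$score, 0.8)
  p2 <- prop(c(0.9, 0.05, 0.05), c(0.8, 0.1, 0.1), c(0.2, 0.7, 0.1))
  expect_true(is.na(triplicateConclusion(p2, "all_match", 0.5)$assigned))
  r2 <- triplicateConclusion(p2, "majority", 0.8)
  expect_equal(r2$assigned, "A")
  expect_equal(r2$score, 0.85)
  p3 <- prop(c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3), c(0.25, 0.25, 0.5))
  expect_true(is.na(triplicateConclusion(p3, "majority", 0)$assigned))
  r3 <- triplicateConclusion(p3, "highest", 0.55)
  expect_equal(r3$assigned, "B")
  # samples tied on the top proportion but voting different classes
  p4 <- prop(c(0.6, 0.3, 0.1), c(0.1, 0.3, 0.6), c(0.3, 0.4, 0.3))
  expect_true(is.na(triplicateConclusion(p4, "highest", 0.5)$assigned))
  expect_error(triplicateConclusion(p3[1:2, ], "majority", 0.5),
               "exactly 3")
})

test_that("all-match conclusive calls are a subset of majority calls at
           the same threshold", {
  set.seed(77)
  n_conclusive <- 0
  for (i in 1:80) {
    raw <- matrix(rexp(9), 3)
    if (i %% 2 == 0) raw[, 1] <- raw[, 1] + 4   # force agreement often
    prop <- raw / rowSums(raw)
    colnames(prop) <- c("A", "B", "C")
    th <- runif(1, 0.3, 0.9)
    am <- triplicateConclusion(prop, "all_match", th)
    mj <- triplicateConclusion(prop, "majority", th)
    if (!is.na(am$assigned)) {
      n_conclusive <- n_conclusive + 1
      expect_false(is.na(mj$assigned))
      expect_equal(mj$assigned, am$assigned)
    }
  }
  expect_gt(n_conclusive, 0)
})

test_that("external prediction uses all trees and inherits scale
           invariance", {
  nt <- toyNormalized(seed = 31)
  f <- fitForest(nt, n_trees = 150, seed = 3)
  mat <- t(abundanceMatrix(nt))
  prof <- predictExternal(f, mat)
  expect_true(all(prof$n_voting_trees == 150))
  expect_false(any(prof$oob))
  # training rows re-presented: near-unanimous correct votes
  expect_gt(mean(prof$top_class == sampleData(nt)$class), 0.97)
  expect_gt(mean(prof$top_proportion), 0.9)
  expect_error(predictExternal(f, mat[, -1, drop = FALSE]),
               "missing model variable")
  # a x10 rescaled external batch normalises to identical profiles
  ext <- generateExternalBatch(toyModel(), n_cards = 2,
                               shift = list(intensity_scale = 1,
                                            drift_scale = 1), seed = 44)
  ext10 <- generateExternalBatch(toyModel(), n_cards = 2,
                                 shift = list(intensity_scale = 10,
                                              drift_scale = 1), seed = 44)
  vars <- variableKeys(nt)
  n1 <- normalizeSpectra(assembleTable(ext), vars, "ion_current")
  n2 <- normalizeSpectra(assembleTable(ext10), vars, "ion_current")
  expect_equal(predictExternal(f, n1), predictExternal(f, n2))
})
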