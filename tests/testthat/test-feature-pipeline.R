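# Bare table builder for hand-crafted matrices (one class unless given).
makeTable <- function(mat, voltage, bin_upper = NULL, class = "a",
                      week = 1L) {
  n <- ncol(mat)
  if (is.null(bin_upper)) bin_upper <- seq_len(nrow(mat)) * 0.025 + 100
  md <- data.frame(sample_id = paste0("s", seq_len(n)),
                   class = rep_len(class, n), week = rep_len(week, n),
                   card = paste0("c", seq_len(n)),
                   replicate = 1L, volume = 3, batch = "main",
                   day = rep_len(week, n))
  BinnedSpectra(mat, bin_upper, voltage, md)
}

test_that("percent-abundance selection counts qualifying spectra", {
  # bin 1 is the base peak everywhere; bin 2 reaches 50% in only two
  # spectra of six
  mat <- rbind(rep(1000, 6), c(500, 500, 0, 0, 0, 0))
  tab <- makeTable(mat, voltage = c(30, 30))
  expect_equal(selectBins(tab, pct_threshold = 10, min_spectra = 2),
               sort(SummarizedExperiment::rowData(tab)$bin_upper))
  # boundary: qualifying in min_spectra - 1 spectra -> discarded
  expect_equal(selectBins(tab, pct_threshold = 10, min_spectra = 3),
               SummarizedExperiment::rowData(tab)$bin_upper[1])
  # retained in every spectrum -> retained at any sane min_spectra
  expect_true(SummarizedExperiment::rowData(tab)$bin_upper[1] %in%
                selectBins(tab, pct_threshold = 10, min_spectra = 6))
})

test_that("raising the percent threshold never adds a bin", {
  for (s in 1:5) {
    tab <- toyTable(seed = 40 + s)
    prev <- selectBins(tab, 0.3, min_spectra = 30)
    for (th in c(1, 5, 10, 30)) {
      cur <- selectBins(tab, th, min_spectra = 30)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("selection recovers exactly the generator's catalog support", {
  tab <- toyTable(seed = 7)
  model <- toyModel()
  truth <- unique(data.frame(
    bin_upper = binPeak(model$catalog$mz[1:6]),
    voltage = model$catalog$voltage[1:6]))
  bins <- selectBins(tab, 1, min_spectra = 30)
  expect_setequal(bins, unique(truth$bin_upper))  # t7 is sub-threshold
  keys <- refinePerVoltage(tab, bins, 1, min_spectra = 30)
  expect_equal(nrow(keys), nrow(truth))
  expect_setequal(paste(keys$bin_upper, keys$voltage),
                  paste(truth$bin_upper, truth$voltage))
  # a fragment present only at 30 V is kept there and dropped elsewhere
  b2 <- binPeak(model$catalog$mz[2])
  expect_equal(keys$voltage[keys$bin_upper == b2], 30)
})

test_that("selection never mutates the raw table", {
  tab <- toyTable(seed = 9)
  before <- abundanceMatrix(tab)
  invisible(selectBins(tab, 10, 5))
  invisible(selectVariables(tab, 10, 5))
  expect_identical(abundanceMatrix(tab), before)
})

test_that("normalisation schemes match their worked examples", {
  tab <- makeTable(matrix(c(10, 30, 60), ncol = 1), voltage = c(30, 30, 30))
  expect_equal(unname(abundanceMatrix(
    normalizeSpectra(tab, NULL, "ion_current"))[, 1]),
    c(0.1, 0.3, 0.6))
  tab2 <- makeTable(matrix(c(3, 4), ncol = 1), voltage = c(60, 60))
  expect_equal(unname(abundanceMatrix(
    normalizeSpectra(tab2, NULL, "vector_length"))[, 1]),
    c(0.6, 0.8))
})

test_that("normalised rows satisfy their per-voltage invariants and are
           scale invariant", {
  tab <- toyTable(seed = 13)
  vars <- selectVariables(tab, 1, 30)
  for (scheme in c("ion_current", "vector_length")) {
    nt <- normalizeSpectra(tab, vars, scheme)
    m <- abundanceMatrix(nt)
    vlt <- SummarizedExperiment::rowData(nt)$voltage
    for (v in unique(vlt)) {
      seg <- m[vlt == v, , drop = FALSE]
      stat <- if (scheme == "ion_current") colSums(seg)
              else sqrt(colSums(seg^2))
      expect_lt(max(abs(stat - 1)), 1e-12)
    }
    # homogeneity: a rescaled table normalises identically
    sc <- BinnedSpectra(abundanceMatrix(tab) * 7.3,
                        SummarizedExperiment::rowData(tab)$bin_upper,
                        vlt <- SummarizedExperiment::rowData(tab)$voltage,
                        sampleData(tab))
    expect_equal(abundanceMatrix(normalizeSpectra(sc, vars, scheme)), m)
  }
})

test_that("an all-zero voltage segment stays zero with a warning", {
  mat <- rbind(c(5, 0), c(3, 0), c(2, 9))
  tab <- makeTable(mat, voltage = c(30, 30, 60))
  expect_warning(nt <- normalizeSpectra(tab, NULL, "ion_current"),
                 "all-zero")
  expect_equal(unname(abundanceMatrix(nt)[, 2]), c(0, 0, 1))
})

test_that("multiway ANOVA: equal group means give F = 0, p = 1", {
  mat <- matrix(c(1, 2, 3, 2, 1, 3), nrow = 1)   # identical class means
  tab <- makeTable(mat, voltage = 30, class = rep(c("a", "b"), each = 3))
  res <- multiwayAnova(tab, factors = "class")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("one-factor ANOVA F equals the squared pooled t on a toy", {
  a <- c(1, 2, 4); b <- c(2, 3, 6)
  # textbook pooled two-sample t computed from first principles
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  tab <- makeTable(matrix(c(a, b), nrow = 1), voltage = 30,
                   class = rep(c("a", "b"), each = 3))
  res <- multiwayAnova(tab, factors = "class")
  expect_equal(res$statistic, t^2, tolerance = 1e-12)
})

test_that("single-level factors are skipped with a warning", {
  tab <- toyTable(seed = 2, design = smallDesign(1, 2))
  nt <- normalizeSpectra(tab, NULL, "ion_current")
  expect_warning(res <- multiwayAnova(nt, factors = c("class", "volume",
                                                      "week")),
                 "single level")
  expect_false(any(grepl("week", res$term)))
  expect_true(all(c("class", "volume", "class:volume") %in% res$term))
})

test_that("full three-factor ANOVA reports all interactions with
           balanced degrees of freedom", {
  nt <- toyNormalized(seed = 3)
  res <- multiwayAnova(nt)
  one <- res[res$variable == res$variable[1], ]
  expect_setequal(one$term,
                  c("class", "week", "volume", "class:week",
                    "class:volume", "week:volume", "class:week:volume"))
  expect_equal(one$df[one$term == "class"], 2)
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("weekly profiles: modes agree on one week, accumulate to the
           grand mean", {
  nt1 <- toyNormalized(seed = 5, design = smallDesign(1, 2),
                       min_spectra = 10)
  expect_equal(weeklyProfiles(nt1, "per_week"),
               weeklyProfiles(nt1, "accumulating"))
  nt <- toyNormalized(seed = 5)
  acc <- weeklyProfiles(nt, "accumulating")
  md <- sampleData(nt)
  last <- acc[acc$week == max(md$week), ]
  m <- abundanceMatrix(nt)
  for (cl in unique(md$class)) {
    grand <- rowMeans(m[, md$class == cl, drop = FALSE])
    got <- last$mean[last$class == cl][match(rownames(m),
                                             last$variable[last$class == cl])]
    expect_equal(got, unname(grand))
  }
  # constant data has zero dispersion everywhere
  cst <- makeTable(matrix(5, 2, 4), voltage = c(30, 30),
                   week = c(1, 1, 2, 2))
  expect_true(all(weeklyProfiles(cst, "per_week")$sd == 0))
})

test_that("correlation matrix is symmetric with unit diagonal and flags
           degenerate variables", {
  mat <- rbind(x = c(1, 2, 3, 4), y = -c(1, 2, 3, 4), z = rep(2, 4))
  tab <- makeTable(mat, voltage = c(30, 30, 30))
  expect_warning(cm <- correlationMatrix(tab), "zero-variance")
  expect_equal(diag(cm), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm[1, 2], -1)
  expect_true(all(is.na(cm[3, -3])))
  expect_error(correlationMatrix(makeTable(mat[, 1:2], c(30, 30, 30))),
               "3 samples")
})

test_that("shared week drift induces positive between-variable
           correlations", {
  mean_off <- vapply(1:10, function(s) {
    tab <- toyTable(seed = 900 + s,
                    model = toyModel(noise_sd = 0.1,
                                     week_shared_sd = 0.4,
                                     week_effect_sd = 0.1))
    cm <- correlationMatrix(tab)
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_gt(mean(mean_off), 0)
  expect_gt(mean(mean_off > 0), 0.8)
})
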