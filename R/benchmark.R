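#' Study-style benchmark of the three classifier families
#'
#' Runs the full evaluation protocol once, on synthetic data generated
#' under the reference study conditions: simulate the design, bin with
#' the centroid abundance floor, select variables, normalise, then score
#' the three classifier families on comparable validation harnesses —
#' the random forest by out-of-bag argmax error, LDA by
#' leave-one-card-out argmax error, and the Welch counting classifier by
#' its max-count decision error over leave-one-card-out triplicates. A
#' tied top score counts as a miss everywhere. Also returns the
#' permutation importance table of the forest.
#'
#' @param seed master seed for the simulation and every fit.
#' @param model a [spectrumModel()].
#' @param config a [designConfig()].
#' @param n_trees forest size.
#' @param scheme normalisation scheme for the classifiers.
#' @param pct_threshold,min_spectra variable-selection settings.
#' @param floor centroid abundance floor.
#' @param importance_repeats permutation repeats (0 skips importance).
#' @param confidence Welch confidence level (percent).
#' @return list with `ntable`, `variables`, `forest`, `oob_profiles`,
#'   `rf_oob_error`, `lda_locso_error`, `welch_decision_error`,
#'   `welch_comparisons` and `importance`.
#' @export
studyBenchmark <- function(seed, model = spectrumModel(),
                           config = designConfig(), n_trees = 500,
                           scheme = "ion_current", pct_threshold = 1,
                           min_spectra = 50, floor = 120,
                           importance_repeats = 5, confidence = 95) {
  design <- generateDesign(config)
  spectra <- simulateSpectra(design, model, seed = seed)
  tab <- assembleTable(applyAbundanceFloor(spectra, floor))
  vars <- selectVariables(tab, pct_threshold, min_spectra)
  ntab <- normalizeSpectra(tab, vars, scheme)
  md <- sampleData(ntab)
  mat <- t(abundanceMatrix(ntab))

  forest <- fitForest(ntab, n_trees = n_trees, seed = .subSeed(seed, 1))
  prof <- oobVoteProfiles(forest)
  rf_err <- .missRate(prof$top_class, md$class)

  wrong <- 0
  for (f in locsoSplits(md)) {
    tr <- match(f$train_ids, md$sample_id)
    te <- match(f$test_ids, md$sample_id)
    fit <- fitLda(mat[tr, , drop = FALSE], md$class[tr])
    pred <- ldaPosterior(fit, mat[te, , drop = FALSE])$top_class
    wrong <- wrong + sum(is.na(pred) | pred != md$class[te])
  }
  lda_err <- wrong / nrow(mat)

  cmp <- welchCardComparisons(ntab, confidence)
  wtot <- 0; wwrong <- 0
  for (cd in unique(cmp$card)) {
    for (cl in unique(cmp$test_class[cmp$card == cd])) {
      sub <- cmp[cmp$card == cd & cmp$test_class == cl, ]
      dec <- classifyByMaxCount(stats::setNames(sub$count,
                                                sub$compare_class), 0)
      wtot <- wtot + 1
      if (is.na(dec$assigned) || dec$assigned != cl)
        wwrong <- wwrong + 1
    }
  }

  imp <- if (importance_repeats > 0)
    permutationImportance(forest, repeats = importance_repeats,
                          seed = .subSeed(seed, 2))
  else NULL

  list(ntable = ntab, variables = vars, forest = forest,
       oob_profiles = prof, rf_oob_error = rf_err,
       lda_locso_error = lda_err,
       welch_decision_error = wwrong / wtot,
       welch_comparisons = cmp, importance = imp)
}

.missRate <- function(predicted, truth) {
  mean(is.na(predicted) | predicted != as.character(truth))
}
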