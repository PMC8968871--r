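#' Turn class scores into a conclusive / inconclusive call
#'
#' The shared decision rule of all three classifier families: assign the
#' top-scoring class when its score reaches the acceptance threshold,
#' otherwise report inconclusive. A tie for the top score is always
#' inconclusive. Thresholds are applied after the classifiers run, so
#' raising a threshold can only turn a conclusion inconclusive — never
#' flip it to another class.
#'
#' @param scores named numeric vector of per-class scores (vote
#'   proportions, posteriors, ...), >= 2 classes.
#' @param threshold acceptance threshold.
#' @param strict if `TRUE`, the score must strictly exceed the
#'   threshold; the default treats a score equal to the threshold as
#'   conclusive.
#' @return list with `assigned` (class label or `NA`), `score`,
#'   `threshold`.
#' @export
thresholdConclusion <- function(scores, threshold, strict = FALSE) {
  stopifnot(length(scores) >= 2)
  i <- .argmaxNoTies(scores)
  top <- max(scores)
  ok <- !is.na(i) && (if (strict) top > threshold else top >= threshold)
  list(assigned = if (ok) names(scores)[i] else NA_character_,
       score = unname(top), threshold = threshold)
}

#' Success / inconclusive / error rates over a threshold sweep
#'
#' For each acceptance threshold, classifies every item by
#' [thresholdConclusion()] and reports the fraction of correct
#' conclusive calls (success), wrong conclusive calls (error), and
#' withheld calls (inconclusive). The three fractions sum to 1 at every
#' threshold.
#'
#' @param scores numeric matrix or `data.frame`, items x classes (named
#'   columns).
#' @param truth true class label per item.
#' @param thresholds acceptance thresholds; default the 0.50-0.95 sweep
#'   in steps of 0.05.
#' @param strict see [thresholdConclusion()].
#' @return `data.frame`: `threshold`, `success`, `inconclusive`,
#'   `error`, `n`.
#' @export
rateTable <- function(scores, truth,
                      thresholds = seq(0.5, 0.95, by = 0.05),
                      strict = FALSE) {
  scores <- as.matrix(scores)
  if (!nrow(scores)) stop("empty input")
  stopifnot(length(truth) == nrow(scores))
  top <- apply(scores, 1, max)
  top_i <- apply(scores, 1, .argmaxNoTies)
  assigned <- colnames(scores)[ifelse(is.na(top_i), 1L, top_i)]
  assigned[is.na(top_i)] <- NA_character_
  out <- lapply(thresholds, function(th) {
    conclusive <- !is.na(assigned) &
      (if (strict) top > th else top >= th)
    success <- mean(conclusive & assigned == as.character(truth),
                    na.rm = TRUE)
    error <- mean(conclusive & assigned != as.character(truth),
                  na.rm = TRUE)
    data.frame(threshold = th, success = success,
               inconclusive = 1 - success - error, error = error,
               n = nrow(scores))
  })
  do.call(rbind, out)
}

#' Stratified 80/20 train/test split
#'
#' Randomly splits the samples into training and test sets, stratified
#' by class: the total test size is `round(N * (1 - train_fraction))`
#' and is distributed as evenly as possible over the classes (remainder
#' classes chosen at random under the seed). A class with fewer than 5
#' samples triggers a warning and best-effort stratification.
#'
#' @param metadata sample metadata `data.frame` (needs `sample_id`,
#'   `class`), or a [BinnedSpectra-class] object.
#' @param seed RNG seed.
#' @param train_fraction fraction assigned to training.
#' @return list with `train_ids` and `test_ids` (disjoint, covering all
#'   samples).
#' @export
split8020 <- function(metadata, seed = 1, train_fraction = 0.8) {
  md <- if (is(metadata, "BinnedSpectra")) sampleData(metadata)
        else as.data.frame(metadata)
  if (!nrow(md)) stop("empty input")
  classes <- sort(unique(md$class))
  sizes <- table(factor(md$class, levels = classes))
  if (any(sizes < 5))
    warning("class(es) with fewer than 5 samples; stratification is ",
            "best-effort", call. = FALSE)
  n_test <- round(nrow(md) * (1 - train_fraction))
  base <- n_test %/% length(classes)
  rem <- n_test %% length(classes)
  .withSeed(seed, {
    extra <- sample(classes, rem)
    test_ids <- unlist(lapply(classes, function(cl) {
      ids <- md$sample_id[md$class == cl]
      k <- min(length(ids), base + (cl %in% extra))
      sample(ids, k)
    }), use.names = FALSE)
  })
  list(train_ids = setdiff(md$sample_id, test_ids),
       test_ids = test_ids)
}

#' Leave-one-card-out folds
#'
#' One cross-validation fold per QuickStrip card: the fold's test set is
#' every sample on that card, the training set everything else. Since a
#' card carries all isomers in triplicate, each fold tests one
#' triplicate per class.
#'
#' @param metadata sample metadata `data.frame` (needs `card`), or a
#'   [BinnedSpectra-class] object.
#' @return list of folds: each `list(card, test_ids, train_ids)`.
#' @export
locsoSplits <- function(metadata) {
  md <- if (is(metadata, "BinnedSpectra")) sampleData(metadata)
        else as.data.frame(metadata)
  lapply(unique(md$card), function(cd) {
    list(card = cd,
         test_ids = md$sample_id[md$card == cd],
         train_ids = md$sample_id[md$card != cd])
  })
}

#' Same-day leave-one-card-out folds
#'
#' Per acquisition day, each card in turn is the test set and only the
#' remaining cards of the same day train the model. Days with a single
#' card yield no fold (warning).
#'
#' @inheritParams locsoSplits
#' @return list of folds: each `list(day, card, test_ids, train_ids)`.
#' @export
sameDaySplits <- function(metadata) {
  md <- if (is(metadata, "BinnedSpectra")) sampleData(metadata)
        else as.data.frame(metadata)
  folds <- list()
  for (d in unique(md$day)) {
    cards <- unique(md$card[md$day == d])
    if (length(cards) < 2L) {
      warning("day ", d, " has a single card; no same-day fold",
              call. = FALSE)
      next
    }
    for (cd in cards) {
      folds[[length(folds) + 1L]] <- list(
        day = d, card = cd,
        test_ids = md$sample_id[md$card == cd],
        train_ids = md$sample_id[md$day == d & md$card != cd])
    }
  }
  folds
}
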