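#' Fit the random-forest isomer classifier
#'
#' An ensemble of CART-style trees grown on bootstrap resamples of the
#' training data (each resample the size of the data set), with a random
#' subset of `mtry` candidate variables at every node and no pruning —
#' the canonical Breiman defaults: 500 trees and `mtry = floor(sqrt(p))`.
#' Tree induction is delegated to the randomForest package with in-bag
#' bookkeeping retained, so out-of-bag votes can be recomputed (and
#' verified) from the per-tree predictions.
#'
#' @param object a normalised [BinnedSpectra-class] table, or numeric
#'   matrix (samples x variables).
#' @param labels class labels; defaults to the table's `class` metadata.
#' @param n_trees number of trees.
#' @param mtry candidate variables per node; default
#'   `max(1, floor(sqrt(p)))`.
#' @param seed RNG seed; the fit is deterministic given it.
#' @return An object of class `"IsomerForest"`: list with the
#'   randomForest `fit`, the training matrix `x` and `labels`,
#'   `variables`, `classes` and `config`.
#' @export
fitForest <- function(object, labels = NULL, n_trees = 500, mtry = NULL,
                      seed = 1) {
  mat <- if (is(object, "BinnedSpectra")) t(abundanceMatrix(object))
         else as.matrix(object)
  if (is.null(labels) && is(object, "BinnedSpectra"))
    labels <- sampleData(object)$class
  y <- factor(labels)
  if (ncol(mat) == 0L) stop("no variables to train on")
  if (nlevels(y) < 2L || any(table(y) < 2L))
    stop("need >= 2 classes with >= 2 samples each")
  n_trees <- .assertCount(n_trees, "n_trees")
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("s", seq_len(nrow(mat)))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(mat))))
  if (mtry < 1 || mtry > ncol(mat)) stop("mtry must be in [1, p]")
  fit <- .withSeed(seed, randomForest::randomForest(
    x = mat, y = y, ntree = n_trees, mtry = mtry,
    keep.forest = TRUE, keep.inbag = TRUE))
  structure(list(fit = fit, x = mat, labels = y,
                 variables = colnames(mat), classes = levels(y),
                 config = list(n_trees = n_trees, mtry = mtry,
                               seed = as.integer(seed))),
            class = "IsomerForest")
}

#' @export
print.IsomerForest <- function(x, ...) {
  cat("IsomerForest:", x$config$n_trees, "trees, mtry =",
      x$config$mtry, ",", length(x$variables), "variables,",
      nrow(x$x), "samples\n")
  prof <- oobVoteProfiles(x)
  cat("  OOB error:",
      format(mean(prof$top_class != x$labels, na.rm = FALSE), digits = 4),
      "\n")
  invisible(x)
}

# Per-tree class predictions for a sample matrix (n x ntree character
# matrix).
.treePredictions <- function(forest, mat) {
  stats::predict(forest$fit, mat, predict.all = TRUE)$individual
}

# Tally votes over a tree mask (n x ntree logical; TRUE = tree votes).
.tallyVotes <- function(ind, mask, classes) {
  votes <- sapply(classes, function(k) rowSums((ind == k) & mask))
  votes <- matrix(votes, nrow = nrow(ind),
                  dimnames = list(rownames(ind), classes))
  n <- rowSums(mask)
  prop <- votes / ifelse(n == 0, NA_real_, n)
  list(prop = prop, n = n)
}

.profileFrame <- function(prop, n, ids, classes, oob) {
  top_i <- apply(prop, 1, function(p)
    if (anyNA(p)) NA_integer_ else .argmaxNoTies(p))
  out <- data.frame(sample_id = ids, prop, row.names = NULL,
                    check.names = FALSE)
  out$n_voting_trees <- n
  out$top_class <- ifelse(is.na(top_i), NA_character_, classes[top_i])
  out$top_proportion <- prop[cbind(seq_len(nrow(prop)),
                                   ifelse(is.na(top_i), 1L, top_i))]
  out$top_proportion[is.na(top_i)] <- apply(prop, 1, max)[is.na(top_i)]
  out$oob <- oob
  attr(out, "classes") <- classes
  out
}

#' Out-of-bag vote profiles for the training samples
#'
#' For every training sample, tallies the votes of only those trees
#' whose bootstrap resample excluded it, giving an unbiased vote
#' proportion per isomer. Recomputed from the per-tree predictions and
#' the stored in-bag counts (not read off the fit), so the bootstrap /
#' OOB contract is verifiable. A sample that appeared in every bootstrap
#' (probability (1 - e^-1)^T, negligible) gets `NA` proportions.
#'
#' @param forest an `"IsomerForest"`.
#' @return `data.frame`: `sample_id`, one vote-proportion column per
#'   class (summing to 1 over voting trees), `n_voting_trees`,
#'   `top_class` (`NA` on a tied vote), `top_proportion`, `oob = TRUE`.
#' @export
oobVoteProfiles <- function(forest) {
  stopifnot(inherits(forest, "IsomerForest"))
  ind <- .treePredictions(forest, forest$x)
  tal <- .tallyVotes(ind, forest$fit$inbag == 0, forest$classes)
  .profileFrame(tal$prop, tal$n, rownames(forest$x), forest$classes,
                oob = TRUE)
}

# OOB accuracy with plain argmax conclusions; a tied vote counts as a
# miss. Optionally with one variable's values permuted.
.oobAccuracy <- function(forest, mat = forest$x) {
  ind <- .treePredictions(forest, mat)
  tal <- .tallyVotes(ind, forest$fit$inbag == 0, forest$classes)
  top_i <- apply(tal$prop, 1, function(p)
    if (anyNA(p)) NA_integer_ else .argmaxNoTies(p))
  pred <- forest$classes[top_i]
  mean(!is.na(pred) & pred == as.character(forest$labels))
}

#' Permutation variable importance (mean decrease in accuracy)
#'
#' Establishes the out-of-bag accuracy of the fitted forest, then, for
#' each variable in turn, shuffles its values among samples, re-runs the
#' out-of-bag samples through the trees, and records how much the
#' accuracy drops. MDA = baseline accuracy minus the mean accuracy over
#' `repeats` independent permutations (repeats average out shuffling
#' noise; set `repeats = 1` for a single-pass literal mode).
#'
#' @param forest an `"IsomerForest"`.
#' @param repeats permutations averaged per variable.
#' @param seed RNG seed for the shuffles.
#' @return `data.frame`: `variable`, `mda`, `rank` (1 = most important;
#'   ranks are a permutation of 1..p).
#' @export
permutationImportance <- function(forest, repeats = 5, seed = 1) {
  stopifnot(inherits(forest, "IsomerForest"))
  repeats <- .assertCount(repeats, "repeats")
  baseline <- .oobAccuracy(forest)
  n <- nrow(forest$x)
  p <- length(forest$variables)
  mda <- numeric(p)
  for (v in seq_len(p)) {
    acc <- numeric(repeats)
    for (r in seq_len(repeats)) {
      perm <- .withSeed(.subSeed(seed, (v - 1L) * repeats + r),
                        sample.int(n))
      pmat <- forest$x
      pmat[, v] <- pmat[perm, v]
      acc[r] <- .oobAccuracy(forest, pmat)
    }
    mda[v] <- baseline - mean(acc)
  }
  data.frame(variable = forest$variables, mda = mda,
             rank = rank(-mda, ties.method = "first"))
}

#' Recursive variable-halving elimination curve
#'
#' Assesses robustness to the removal of low-impact variables: starting
#' from all p variables, records a stratified k-fold cross-validation
#' error, ranks the variables by permutation importance, removes the
#' least important half (`floor(p/2)` removed, `ceiling(p/2)` kept), and
#' repeats until one variable remains — giving the sequence
#' p, ceil(p/2), ..., 1.
#'
#' @param object normalised [BinnedSpectra-class] table or matrix.
#' @param labels class labels (default: table `class` metadata).
#' @param folds number of CV folds (error if more than samples).
#' @param n_trees trees per forest.
#' @param seed RNG seed (folds, fits, permutations).
#' @param rerank re-rank importance after each halving (default); if
#'   `FALSE`, the initial full-variable ranking is reused throughout.
#' @param importance_repeats permutation repeats used for ranking.
#' @return `data.frame` with one row per step: `n_variables`,
#'   `cv_error`; the variable set at each step is attached as
#'   `attr(, "variables")` (a list).
#' @export
eliminationCurve <- function(object, labels = NULL, folds = 12,
                             n_trees = 500, seed = 1, rerank = TRUE,
                             importance_repeats = 1) {
  mat <- if (is(object, "BinnedSpectra")) t(abundanceMatrix(object))
         else as.matrix(object)
  if (is.null(labels) && is(object, "BinnedSpectra"))
    labels <- sampleData(object)$class
  y <- factor(labels)
  folds <- .assertCount(folds, "folds")
  if (folds > nrow(mat)) stop("more folds than samples")
  fold_id <- .stratifiedFolds(y, folds, .subSeed(seed, 0))
  vars <- colnames(mat)
  ranking <- NULL
  steps <- list(); var_sets <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    sub <- mat[, vars, drop = FALSE]
    err <- 0
    for (f in seq_len(folds)) {
      te <- fold_id == f
      fit <- fitForest(sub[!te, , drop = FALSE], y[!te],
                       n_trees = n_trees,
                       seed = .subSeed(seed, step * 1000L + f))
      pred <- stats::predict(fit$fit, sub[te, , drop = FALSE])
      err <- err + sum(pred != y[te])
    }
    steps[[step]] <- data.frame(n_variables = length(vars),
                                cv_error = err / nrow(mat))
    var_sets[[step]] <- vars
    if (length(vars) == 1L) break
    if (rerank || is.null(ranking)) {
      full <- fitForest(sub, y, n_trees = n_trees,
                        seed = .subSeed(seed, step * 1000L))
      imp <- permutationImportance(full, repeats = importance_repeats,
                                   seed = .subSeed(seed, step))
      ranking <- imp$variable[order(imp$rank)]
    }
    ranked <- ranking[ranking %in% vars]
    vars <- ranked[seq_len(ceiling(length(vars) / 2))]
  }
  out <- do.call(rbind, steps)
  attr(out, "variables") <- var_sets
  out
}

# Stratified fold assignment (balanced within class), seeded.
.stratifiedFolds <- function(y, k, seed) {
  id <- integer(length(y))
  .withSeed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      id[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  id
}

#' Combine a card triplicate's vote profiles into one conclusion
#'
#' Three rules for reporting one conclusion per triplicate instead of
#' one per sample. `"all_match"`: all three samples must share the same
#' top isomer, and the mean of their three top vote proportions must
#' reach the threshold. `"majority"`: at least two must agree; the mean
#' top proportion of the agreeing samples is compared to the threshold.
#' `"highest"`: only the sample with the highest top proportion is
#' scored against the threshold. Any failure (disagreement, a tied vote
#' within a sample, or a score below threshold) is inconclusive.
#'
#' @param profiles vote-profile rows for the three triplicate samples
#'   (a 3-row `data.frame` from [oobVoteProfiles()] /
#'   [predictExternal()], or a 3 x K proportion matrix).
#' @param rule `"all_match"`, `"majority"` or `"highest"`.
#' @param threshold vote-proportion acceptance threshold; conclusive
#'   when the rule's score is >= threshold.
#' @param classes class labels (needed only for a bare matrix without
#'   the `"classes"` attribute).
#' @return list with `assigned` (class or `NA`), `score`, `rule`,
#'   `threshold`.
#' @export
triplicateConclusion <- function(profiles,
                                 rule = c("all_match", "majority",
                                          "highest"),
                                 threshold = 0.5, classes = NULL) {
  rule <- match.arg(rule)
  if (is.null(classes)) classes <- attr(profiles, "classes")
  if (is.data.frame(profiles)) {
    prop <- as.matrix(profiles[, classes, drop = FALSE])
  } else {
    prop <- as.matrix(profiles)
    if (is.null(classes)) classes <- colnames(prop)
  }
  if (nrow(prop) != 3L) stop("a triplicate needs exactly 3 profiles")
  top_i <- apply(prop, 1, .argmaxNoTies)
  top_p <- apply(prop, 1, max)
  inconclusive <- list(assigned = NA_character_, score = NA_real_,
                       rule = rule, threshold = threshold)
  if (rule == "all_match") {
    if (anyNA(top_i) || length(unique(top_i)) != 1L) return(inconclusive)
    score <- mean(top_p)
    cls <- classes[top_i[1]]
  } else if (rule == "majority") {
    tab <- table(factor(top_i[!is.na(top_i)], levels = seq_along(classes)))
    win <- which(tab >= 2L)
    if (length(win) != 1L) return(inconclusive)
    agree <- !is.na(top_i) & top_i == win
    score <- mean(top_p[agree])
    cls <- classes[win]
  } else {
    best <- which(top_p == max(top_p))
    cls_i <- unique(top_i[best])
    # samples tied on the top proportion must also agree on the class
    if (anyNA(cls_i) || length(cls_i) != 1L) return(inconclusive)
    score <- top_p[best[1]]
    cls <- classes[cls_i]
  }
  if (score >= threshold)
    list(assigned = cls, score = score, rule = rule,
         threshold = threshold)
  else
    list(assigned = NA_character_, score = score, rule = rule,
         threshold = threshold)
}

#' Apply a trained forest to an external batch
#'
#' Classifies externally acquired samples with every tree of the
#' main-batch forest (no out-of-bag restriction). The external table
#' must have been binned with the main batch's variables and normalised
#' with one of the per-voltage schemes, which also makes the profiles
#' invariant to a global intensity rescaling of the external batch.
#'
#' @param forest an `"IsomerForest"` trained on the main batch.
#' @param newdata normalised external [BinnedSpectra-class] table or
#'   matrix; missing any model variable is an error naming it.
#' @return Vote-profile `data.frame` as [oobVoteProfiles()], with
#'   `oob = FALSE` and all trees voting.
#' @export
predictExternal <- function(forest, newdata) {
  stopifnot(inherits(forest, "IsomerForest"))
  mat <- if (is(newdata, "BinnedSpectra")) t(abundanceMatrix(newdata))
         else as.matrix(newdata)
  miss <- setdiff(forest$variables, colnames(mat))
  if (length(miss))
    stop("external table is missing model variable(s): ",
         paste(miss, collapse = ", "))
  mat <- mat[, forest$variables, drop = FALSE]
  ind <- .treePredictions(forest, mat)
  mask <- matrix(TRUE, nrow(ind), ncol(ind))
  tal <- .tallyVotes(ind, mask, forest$classes)
  ids <- if (is.null(rownames(mat))) as.character(seq_len(nrow(mat)))
         else rownames(mat)
  .profileFrame(tal$prop, tal$n, ids, forest$classes, oob = FALSE)
}
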