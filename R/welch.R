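# Column-wise Welch tests between two sample matrices (rows = samples).
# Zero-variance convention (reachable with noiseless triplicates): both
# groups constant -> p = 1 when the means agree, p = 0 when they differ.
.welchColumns <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  both0 <- se2 == 0
  if (any(both0)) {
    eq <- both0 & (ma == mb)
    t[eq] <- 0; p[eq] <- 1
    ne <- both0 & (ma != mb)
    t[ne] <- sign(ma[ne] - mb[ne]) * Inf
    p[ne] <- 0
    df[both0] <- NA_real_
  }
  list(t = t, df = df, p = p)
}

#' Welch's unequal-variance t test with an indistinguishability call
#'
#' The atomic comparison of the univariate classifier: are the abundances
#' of one m/z variable distinguishable between a test triplicate and a
#' known isomer's training data? Standard Welch t with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value; the
#' comparison is *indistinguishable* when the test fails to reject at
#' the stated confidence, i.e. `p > 1 - confidence/100` (p equal to the
#' significance level counts as distinguishable). When both groups have
#' zero variance, p is 1 if the means agree and 0 otherwise.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param confidence confidence level as a percent in (0, 100).
#' @return list with `t`, `df`, `p`, `confidence`, `indistinguishable`.
#' @examples
#' welchTest(c(1, 2, 3), c(2, 3, 4), 95)
#' @export
welchTest <- function(a, b, confidence = 95) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            confidence > 0, confidence < 100)
  r <- .welchColumns(matrix(a, ncol = 1), matrix(b, ncol = 1))
  list(t = unname(r$t), df = unname(r$df), p = unname(r$p),
       confidence = confidence,
       indistinguishable = unname(r$p > 1 - confidence / 100))
}

#' Count indistinguishable variables between a triplicate and a class
#'
#' Applies [welchTest()] at every variable between a test triplicate and
#' the training rows of one candidate isomer, and counts the variables
#' the test cannot distinguish. A test triplicate compared to its true
#' isomer should leave more variables indistinguishable than a
#' comparison to a wrong isomer.
#'
#' @param test numeric matrix of the test triplicate, samples x
#'   variables (3 rows in the reference design).
#' @param train numeric matrix of the candidate class's training rows
#'   (the test card excluded), samples x variables.
#' @param confidence percent confidence level.
#' @return list with `count`, `total` and the per-variable logical
#'   `indistinguishable`.
#' @export
countIndistinguishable <- function(test, train, confidence = 95) {
  test <- as.matrix(test); train <- as.matrix(train)
  stopifnot(ncol(test) == ncol(train), nrow(test) >= 2, nrow(train) >= 2)
  r <- .welchColumns(test, train)
  ind <- r$p > 1 - confidence / 100
  list(count = sum(ind), total = length(ind), indistinguishable = ind)
}

#' Leave-one-card-out Welch comparisons over a normalised table
#'
#' For every QuickStrip card, compares each of its class triplicates to
#' the training data of every candidate isomer (the test card excluded)
#' and records the indistinguishable-bin count. `scope = "same_day"`
#' restricts the training data to cards acquired the same day as the
#' test card; a day with a single card is skipped with a warning.
#'
#' @param object a normalised [BinnedSpectra-class] table.
#' @param confidence percent confidence level for [welchTest()].
#' @param scope `"full"` or `"same_day"`.
#' @return `data.frame` with one row per (test card, test class,
#'   compared class): `card`, `day`, `test_class`, `compare_class`,
#'   `positive`, `count`, `total`; the per-variable indistinguishability
#'   indicator matrix is attached as `attr(, "indistinguishable")`.
#' @export
welchCardComparisons <- function(object, confidence = 95,
                                 scope = c("full", "same_day")) {
  scope <- match.arg(scope)
  md <- sampleData(object)
  mat <- t(abundanceMatrix(object))
  classes <- sort(unique(md$class))
  if (length(classes) < 2L) stop("need at least 2 classes")
  rows <- list(); indist <- list()
  for (cd in unique(md$card)) {
    in_card <- md$card == cd
    day <- md$day[in_card][1]
    pool <- if (scope == "full") !in_card else (!in_card & md$day == day)
    if (scope == "same_day" && !any(pool)) {
      warning("day ", day, " has a single card; card ", cd, " skipped",
              call. = FALSE)
      next
    }
    for (cl in intersect(classes, md$class[in_card])) {
      test <- mat[in_card & md$class == cl, , drop = FALSE]
      if (nrow(test) < 2L) next
      for (cmp in classes) {
        train <- mat[pool & md$class == cmp, , drop = FALSE]
        if (nrow(train) < 2L) next
        cc <- countIndistinguishable(test, train, confidence)
        rows[[length(rows) + 1L]] <- data.frame(
          card = cd, day = day, test_class = cl, compare_class = cmp,
          positive = cl == cmp, count = cc$count, total = cc$total,
          stringsAsFactors = FALSE)
        indist[[length(indist) + 1L]] <- cc$indistinguishable
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "indistinguishable") <- do.call(rbind, indist)
  out
}

#' ROC curve and AUC from indistinguishable-bin counts
#'
#' Sweeps an increasing count threshold: a comparison is *called* (the
#' test triplicate deemed to match the compared isomer) when its
#' indistinguishable-bin count reaches the threshold. True positive rate
#' is computed over comparisons against the true isomer, false positive
#' rate over comparisons against wrong isomers. The sweep runs from 0 to
#' one past the largest variable count so the curve spans (1,1) to
#' (0,0); AUC is the trapezoid area.
#'
#' @param profiles `data.frame` with columns `count` (integer),
#'   `positive` (logical) and `total`, e.g. from
#'   `welchCardComparisons()`.
#' @return list with `roc` (`data.frame`: `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
rocFromCounts <- function(profiles) {
  if (!any(profiles$positive) || all(profiles$positive))
    stop("need at least one positive and one negative comparison")
  thr <- 0:(max(profiles$total) + 1L)
  tpr <- vapply(thr, function(k) mean(profiles$count[profiles$positive] >= k),
                numeric(1))
  fpr <- vapply(thr, function(k) mean(profiles$count[!profiles$positive] >= k),
                numeric(1))
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = .trapezoidAuc(fpr, tpr))
}

# Trapezoid area under a ROC traced from (1,1) down to (0,0).
.trapezoidAuc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  x <- fpr[o]; y <- tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Classify a triplicate by its maximum indistinguishable-bin count
#'
#' The decision-rule form of the univariate classifier: assign the
#' isomer with the highest indistinguishable-bin count, provided its
#' lead over the runner-up exceeds `min_difference`; otherwise (or on a
#' tie for the maximum) the result is inconclusive.
#'
#' @param counts named numeric vector, one count per candidate isomer
#'   (>= 2 classes).
#' @param min_difference required margin (counts) over the second-best
#'   class; the margin must strictly exceed it.
#' @return list with `assigned` (class label or `NA` for inconclusive)
#'   and `margin`.
#' @export
classifyByMaxCount <- function(counts, min_difference = 0) {
  stopifnot(length(counts) >= 2)
  o <- order(counts, decreasing = TRUE)
  margin <- counts[o[1]] - counts[o[2]]
  assigned <- if (margin > min_difference) names(counts)[o[1]]
              else NA_character_
  list(assigned = assigned, margin = unname(margin))
}

#' Replicated Welch-test analysis with randomised settings
#'
#' Runs the full leave-one-card-out Welch analysis `n_replicates` times,
#' each replicate drawing a confidence level uniformly between 90 and
#' 99.999% and a normalisation scheme uniformly from ion-current /
#' vector-length, and returns per-replicate ROC curves plus the
#' replicate-averaged curve (pointwise mean FPR and TPR per count
#' threshold). `scope = "same_day"` restricts training data to cards
#' analysed the same day as the test card.
#'
#' @param object a *raw* [BinnedSpectra-class] table.
#' @param variables retained VariableKeys (see [normalizeSpectra()]).
#' @param n_replicates number of randomised replicates.
#' @param scope `"full"` or `"same_day"`.
#' @param seed master seed; replicate r uses a derived substream seed.
#' @param confidence_range percent range the confidence is drawn from.
#' @return list with `summary` (`replicate`, `confidence`, `scheme`,
#'   `auc`), `roc` (per-replicate curves, long), `averaged_roc`,
#'   `averaged_auc`, and `comparisons` (per-replicate comparison tables).
#' @export
runWelchReplicates <- function(object, variables = NULL,
                               n_replicates = 20,
                               scope = c("full", "same_day"),
                               seed = 1,
                               confidence_range = c(90, 99.999)) {
  scope <- match.arg(scope)
  n_replicates <- .assertCount(n_replicates, "n_replicates")
  schemes <- c("ion_current", "vector_length")
  summ <- list(); rocs <- list(); comps <- list()
  for (r in seq_len(n_replicates)) {
    sr <- .subSeed(seed, r)
    draw <- .withSeed(sr, list(
      confidence = stats::runif(1, confidence_range[1],
                                confidence_range[2]),
      scheme = sample(schemes, 1)))
    ntab <- normalizeSpectra(object, variables, draw$scheme)
    cmp <- welchCardComparisons(ntab, draw$confidence, scope)
    roc <- rocFromCounts(cmp)
    summ[[r]] <- data.frame(replicate = r, confidence = draw$confidence,
                            scheme = draw$scheme, auc = roc$auc,
                            seed = sr)
    rocs[[r]] <- cbind(replicate = r, roc$roc)
    comps[[r]] <- cmp
  }
  roc_long <- do.call(rbind, rocs)
  avg <- stats::aggregate(cbind(fpr, tpr) ~ threshold, roc_long, mean)
  avg <- avg[order(avg$threshold), ]
  list(summary = do.call(rbind, summ), roc = roc_long,
       averaged_roc = avg,
       averaged_auc = .trapezoidAuc(avg$fpr, avg$tpr),
       comparisons = comps)
}

#' Per-variable classification accuracy of the Welch comparisons
#'
#' For each variable, accuracy = (true positives + true negatives) /
#' comparisons, where *indistinguishable on the true isomer* is a true
#' positive and *distinguishable on a wrong isomer* a true negative.
#'
#' @param comparisons a comparison table from `welchCardComparisons()`
#'   (with its per-variable indicator attribute).
#' @return named numeric vector of per-variable accuracies in \[0, 1\].
#' @export
perBinAccuracy <- function(comparisons) {
  ind <- attr(comparisons, "indistinguishable")
  if (is.null(ind)) stop("comparisons lack the per-variable indicator")
  pos <- comparisons$positive
  (colSums(ind[pos, , drop = FALSE]) +
     colSums(!ind[!pos, , drop = FALSE])) / nrow(ind)
}
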