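#' Fit a linear discriminant classifier with equal priors
#'
#' Linear discriminant analysis on the full retained variable set (no
#' further variable reduction), assuming multivariate normal classes
#' with a common covariance and equal prior probabilities. Variables
#' whose pooled within-class variance falls below `tolerance` carry no
#' usable information and destabilise the fit; they are removed and
#' recorded before fitting. A pooled covariance that is still singular
#' after the guard (typically many highly correlated variables and too
#' few samples) raises an error suggesting the higher percent-abundance
#' threshold variable set rather than silently regularising.
#'
#' Fitting is delegated to [MASS::lda()]; the variance guard, equal
#' priors and the conclusion machinery are applied around it.
#'
#' @param object a normalised [BinnedSpectra-class] table, or a numeric
#'   matrix (samples x variables).
#' @param labels class labels; defaults to the table's `class` metadata.
#' @param tolerance pooled within-class variance below which a variable
#'   is dropped.
#' @return An object of class `"IsomerLDA"`: list with the `MASS` fit,
#'   `variables`, `dropped_variables`, `classes`, class `means`, and the
#'   pooled covariance `pooled_cov` (denominator N - K).
#' @export
fitLda <- function(object, labels = NULL, tolerance = 1.0e-8) {
  mat <- if (is(object, "BinnedSpectra")) t(abundanceMatrix(object))
         else as.matrix(object)
  if (is.null(labels) && is(object, "BinnedSpectra"))
    labels <- sampleData(object)$class
  y <- factor(labels)
  if (length(y) != nrow(mat)) stop("labels must match samples")
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (any(table(y) < 2L)) stop("every class needs at least 2 samples")
  wvar <- .pooledWithinVariance(mat, y)
  drop <- colnames(mat)[wvar < tolerance]
  if (length(drop))
    message("removed ", length(drop),
            " variable(s) with within-class variance below ",
            format(tolerance), ": ", paste(drop, collapse = ", "))
  keep <- setdiff(colnames(mat), drop)
  if (!length(keep)) stop("no variable survives the variance guard")
  x <- mat[, keep, drop = FALSE]
  prior <- rep(1 / nlevels(y), nlevels(y))
  fit <- withCallingHandlers(
    tryCatch(MASS::lda(x, grouping = y, prior = prior),
             error = function(e)
               stop("LDA fit failed (", conditionMessage(e),
                    "); the pooled covariance is likely singular - ",
                    "consider the higher percent-abundance threshold ",
                    "variable set", call. = FALSE)),
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  mu <- rowsum(x, y) / as.vector(table(y))
  structure(list(fit = fit, variables = keep, dropped_variables = drop,
                 classes = levels(y), tolerance = tolerance,
                 means = mu,
                 pooled_cov = .pooledCovariance(x, y)),
            class = "IsomerLDA")
}

.pooledWithinVariance <- function(mat, y) {
  n <- tabulate(y)
  ss <- 0
  for (k in seq_len(nlevels(y))) {
    sub <- mat[y == levels(y)[k], , drop = FALSE]
    ss <- ss + colSums(sweep(sub, 2, colMeans(sub))^2)
  }
  ss / (length(y) - nlevels(y))
}

.pooledCovariance <- function(mat, y) {
  S <- 0
  for (k in seq_len(nlevels(y))) {
    sub <- mat[y == levels(y)[k], , drop = FALSE]
    cen <- sweep(sub, 2, colMeans(sub))
    S <- S + crossprod(cen)
  }
  S / (length(y) - nlevels(y))
}

#' @export
print.IsomerLDA <- function(x, ...) {
  cat("IsomerLDA:", length(x$classes), "classes,",
      length(x$variables), "variables")
  if (length(x$dropped_variables))
    cat(" (", length(x$dropped_variables), " dropped by variance guard)",
        sep = "")
  cat("\n  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior class probabilities, conclusions and likelihood ratios
#'
#' Posterior probability that each sample belongs to each isomer under
#' the equal-prior, equal-covariance Gaussian model, together with the
#' likelihood ratio formed as highest / second-highest posterior. The LR
#' is indicative only: it has not been calibrated against
#' ground-truth-known case data and should not be reported as evidential
#' weight.
#'
#' @param model an `"IsomerLDA"` fit.
#' @param newdata a [BinnedSpectra-class] table or samples-x-variables
#'   matrix containing every model variable (a missing variable is an
#'   error naming it).
#' @return `data.frame`: `sample_id`, one posterior column per class,
#'   `top_class`, `top_posterior`, `lr`.
#' @export
ldaPosterior <- function(model, newdata) {
  stopifnot(inherits(model, "IsomerLDA"))
  mat <- if (is(newdata, "BinnedSpectra")) t(abundanceMatrix(newdata))
         else as.matrix(newdata)
  miss <- setdiff(model$variables, colnames(mat))
  if (length(miss))
    stop("missing model variable(s): ", paste(miss, collapse = ", "))
  post <- stats::predict(model$fit,
                         mat[, model$variables, drop = FALSE])$posterior
  top2 <- t(apply(post, 1, function(p) sort(p, decreasing = TRUE)[1:2]))
  top_i <- apply(post, 1, .argmaxNoTies)
  out <- data.frame(sample_id = if (is.null(rownames(mat)))
                                  as.character(seq_len(nrow(mat)))
                                else rownames(mat),
                    post, row.names = NULL, check.names = FALSE)
  out$top_class <- ifelse(is.na(top_i), NA_character_,
                          colnames(post)[top_i])
  out$top_posterior <- top2[, 1]
  out$lr <- top2[, 1] / top2[, 2]
  out
}

#' Per-variable influence on the discriminant axes
#'
#' The absolute scaling coefficient of each variable on each linear
#' discriminant axis; a high absolute coefficient means the variable has
#' a high impact on the transformation onto that axis. Ranked within
#' each axis (rank 1 = largest influence).
#'
#' @param model an `"IsomerLDA"` fit.
#' @return `data.frame`: `variable`, `axis`, `coefficient`,
#'   `abs_coefficient`, `rank`.
#' @export
scalingInfluence <- function(model) {
  stopifnot(inherits(model, "IsomerLDA"))
  sc <- model$fit$scaling
  out <- do.call(rbind, lapply(seq_len(ncol(sc)), function(j) {
    a <- abs(sc[, j])
    data.frame(variable = rownames(sc), axis = colnames(sc)[j],
               coefficient = sc[, j], abs_coefficient = a,
               rank = rank(-a, ties.method = "first"),
               row.names = NULL)
  }))
  out[order(out$axis, out$rank), ]
}
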