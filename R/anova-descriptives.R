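#' Multiway ANOVA screening of every variable
#'
#' Fits, for each (bin, voltage) variable, a factorial analysis of
#' variance of its normalised abundance on isomer identity, analysis
#' week, and deposition volume, with all interactions, and reports raw
#' per-term p-values (no multiplicity correction — the screen is
#' descriptive). Sums of squares are sequential (Type I); the reference
#' design is balanced so the ANOVA types coincide, and a warning is
#' emitted for unbalanced input. A factor with fewer than two levels is
#' skipped with a warning.
#'
#' @param object a [BinnedSpectra-class] table (normalised, typically).
#' @param factors metadata columns to use as crossed factors.
#' @return `data.frame` with one row per variable per model term:
#'   `variable`, `term`, `df`, `statistic` (F), `p`.
#' @export
multiwayAnova <- function(object, factors = c("class", "week", "volume")) {
  md <- sampleData(object)
  use <- character()
  for (f in factors) {
    if (!f %in% names(md)) stop("metadata column not found: ", f)
    if (length(unique(md[[f]])) < 2L)
      warning("factor '", f, "' has a single level and was skipped",
              call. = FALSE)
    else use <- c(use, f)
  }
  if (!length(use)) stop("no factor has two or more levels")
  fdf <- as.data.frame(lapply(md[use], factor))
  if (length(unique(table(interaction(fdf)))) > 1L)
    warning("unbalanced design: sequential (Type I) sums of squares ",
            "depend on factor order", call. = FALSE)
  form <- stats::as.formula(
    paste("y ~", paste(use, collapse = " * ")))
  mat <- abundanceMatrix(object)
  res <- vector("list", nrow(mat))
  for (i in seq_len(nrow(mat))) {
    dat <- cbind(y = mat[i, ], fdf)
    tab <- summary(stats::aov(form, data = dat))[[1]]
    terms <- trimws(rownames(tab))
    keep <- terms != "Residuals"
    res[[i]] <- data.frame(variable = rownames(mat)[i],
                           term = terms[keep],
                           df = tab$Df[keep],
                           statistic = tab$`F value`[keep],
                           p = tab$`Pr(>F)`[keep],
                           row.names = NULL)
  }
  do.call(rbind, res)
}

#' Weekly mean/SD profiles per variable and class
#'
#' Summarises each variable per class over acquisition weeks, either week
#' by week (`"per_week"`) or over an accumulating data set
#' (`"accumulating"`: weeks 1..k), the view used to judge whether
#' between-session drift stabilises as data accumulate.
#'
#' @param object a [BinnedSpectra-class] table.
#' @param mode `"per_week"` or `"accumulating"`.
#' @return `data.frame`: `variable`, `class`, `week`, `mean`, `sd`, `n`.
#' @export
weeklyProfiles <- function(object, mode = c("per_week", "accumulating")) {
  mode <- match.arg(mode)
  md <- sampleData(object)
  mat <- abundanceMatrix(object)
  weeks <- sort(unique(md$week))
  classes <- sort(unique(md$class))
  out <- list()
  for (cl in classes) {
    for (k in seq_along(weeks)) {
      cols <- if (mode == "per_week") {
        md$class == cl & md$week == weeks[k]
      } else {
        md$class == cl & md$week %in% weeks[seq_len(k)]
      }
      sub <- mat[, cols, drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        variable = rownames(mat), class = cl, week = weeks[k],
        mean = rowMeans(sub),
        sd = apply(sub, 1, stats::sd),
        n = sum(cols), row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Pearson correlation matrix between variables
#'
#' The between-variable correlation structure (the heat-map view): batch
#' drift shared across fragments and per-voltage normalisation both
#' induce strong correlations, which is why classifiers that tolerate
#' correlated predictors are preferred here. Zero-variance variables get
#' `NA` rows/columns, with a warning.
#'
#' @param object a [BinnedSpectra-class] table with at least 3 samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(object) {
  if (ncol(object) < 3L) stop("need at least 3 samples")
  mat <- t(abundanceMatrix(object))
  sds <- apply(mat, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(mat))
  if (any(sds == 0)) {
    warning("zero-variance variable(s): ",
            paste(colnames(mat)[sds == 0], collapse = ", "),
            "; correlations recorded as NA", call. = FALSE)
    cm[sds == 0, ] <- NA_real_
    cm[, sds == 0] <- NA_real_
  }
  diag(cm) <- 1
  cm
}
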