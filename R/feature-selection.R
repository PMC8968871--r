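# Percent-of-base-peak matrix per spectrum (one spectrum = one sample at
# one voltage). Base-peak normalisation is used only during variable
# selection; raw abundances pass through to every later stage.
.percentOfBase <- function(object) {
  mat <- abundanceMatrix(object)
  vlt <- rowData(object)$voltage
  pct <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  zero <- character()
  for (v in unique(vlt)) {
    rows <- vlt == v
    base <- apply(mat[rows, , drop = FALSE], 2, max)
    z <- base == 0
    if (any(z)) {
      zero <- c(zero, paste0(colnames(mat)[z], "@", v, "V"))
      base[z] <- NA_real_
    }
    pct[rows, ] <- 100 * sweep(mat[rows, , drop = FALSE], 2, base, "/")
  }
  if (length(zero))
    warning("all-zero spectra excluded from selection counting: ",
            paste(utils::head(zero, 5), collapse = ", "),
            if (length(zero) > 5) " ...", call. = FALSE)
  pct
}

#' Select candidate m/z bins by a percent-abundance threshold
#'
#' Each spectrum (one sample at one voltage) is temporarily normalised to
#' a base-peak value of 100%. A bin is a candidate when the number of
#' spectra — pooled across voltages and classes — in which its percent
#' abundance reaches `pct_threshold` is at least `min_spectra`. Bins are
#' voltage-agnostic at this stage; [refinePerVoltage()] then restricts
#' them to the voltages where they matter.
#'
#' @param object a raw [BinnedSpectra-class] table.
#' @param pct_threshold percent-of-base-peak threshold (e.g. 0.3, 1, 10).
#' @param min_spectra minimum number of qualifying spectra.
#' @param rule `"count_meeting"` retains a bin when at least `min_spectra`
#'   spectra meet the threshold (default); `"count_failing"` is the
#'   literal inverse reading, discarding a bin when at least `min_spectra`
#'   spectra fail it.
#' @return Sorted numeric vector of candidate bin upper limits (Da).
#' @export
selectBins <- function(object, pct_threshold = 1, min_spectra = 50,
                       rule = c("count_meeting", "count_failing")) {
  rule <- match.arg(rule)
  stopifnot(pct_threshold > 0, pct_threshold <= 100, min_spectra >= 1)
  if (!ncol(object)) stop("empty table")
  pct <- .percentOfBase(object)
  meets <- pct >= pct_threshold            # NA for all-zero spectra
  bins <- rowData(object)$bin_upper
  n_meet <- tapply(rowSums(meets, na.rm = TRUE), bins, sum)
  keep <- if (rule == "count_meeting") {
    n_meet >= min_spectra
  } else {
    # spectra counted per bin = spectra x voltages where the bin exists
    n_counted <- tapply(rowSums(!is.na(meets)), bins, sum)
    (n_counted - n_meet) < min_spectra
  }
  sort(as.numeric(names(n_meet))[keep])
}

#' Refine candidate bins per voltage into the final variable set
#'
#' A (bin, voltage) variable is retained when, restricted to that
#' voltage's spectra, at least `min_spectra` spectra reach the percent
#' abundance threshold — the same counting rule as [selectBins()] applied
#' within each voltage channel. The rule is pluggable via `refine_fun`.
#'
#' @param object a raw [BinnedSpectra-class] table.
#' @param bins candidate bin upper limits from [selectBins()].
#' @param pct_threshold,min_spectra as in [selectBins()].
#' @param refine_fun optional replacement rule: a
#'   `function(pct_matrix_voltage, bins_in_rows)` returning a logical
#'   vector over the rows it is given.
#' @return `data.frame` of VariableKeys: `variable`, `bin_upper`,
#'   `voltage`.
#' @export
refinePerVoltage <- function(object, bins, pct_threshold = 1,
                             min_spectra = 50, refine_fun = NULL) {
  pct <- .percentOfBase(object)
  rd <- rowData(object)
  cand <- rd$bin_upper %in% bins
  keep <- logical(nrow(object))
  for (v in unique(rd$voltage)) {
    rows <- which(rd$voltage == v & cand)
    if (!length(rows)) next
    sub <- pct[rows, , drop = FALSE]
    keep[rows] <- if (is.null(refine_fun)) {
      rowSums(sub >= pct_threshold, na.rm = TRUE) >= min_spectra
    } else {
      refine_fun(sub, rd$bin_upper[rows])
    }
  }
  out <- data.frame(variable = rownames(object)[keep],
                    bin_upper = rd$bin_upper[keep],
                    voltage = rd$voltage[keep])
  out[order(out$voltage, out$bin_upper), , drop = FALSE]
}

#' Select the final variable set in one step
#'
#' Convenience wrapper running [selectBins()] then [refinePerVoltage()].
#'
#' @inheritParams selectBins
#' @return As [refinePerVoltage()].
#' @export
selectVariables <- function(object, pct_threshold = 1, min_spectra = 50,
                            rule = "count_meeting") {
  bins <- selectBins(object, pct_threshold, min_spectra, rule)
  refinePerVoltage(object, bins, pct_threshold, min_spectra)
}

#' Normalise the binned table per sample and voltage
#'
#' Two schemes, both applied within each voltage channel and using only
#' the retained variables in the denominator: `"ion_current"` divides
#' each abundance by the summed abundance of the retained bins at the
#' same voltage (rows then sum to 1 per voltage), and `"vector_length"`
#' divides by the Euclidean length of that abundance vector (unit norm
#' per voltage). Both are invariant to rescaling a sample's raw
#' intensities. A voltage segment that is all zero stays all zero, with a
#' warning, so degraded samples still flow through to the classifiers.
#'
#' @param object a raw [BinnedSpectra-class] table.
#' @param variables the retained variables: a VariableKey `data.frame`
#'   from [refinePerVoltage()], a character vector of variable names, or
#'   `NULL` for all variables in `object`.
#' @param scheme `"ion_current"` or `"vector_length"`.
#' @return A [BinnedSpectra-class] restricted to `variables`, with
#'   `normalization(x)` set to the scheme.
#' @examples
#' # ion current: (10, 30, 60) -> (0.1, 0.3, 0.6)
#' @export
normalizeSpectra <- function(object, variables = NULL,
                             scheme = c("ion_current", "vector_length")) {
  scheme <- match.arg(scheme)
  vn <- if (is.null(variables)) rownames(object)
        else if (is.data.frame(variables)) variables$variable
        else as.character(variables)
  miss <- setdiff(vn, rownames(object))
  if (length(miss))
    stop("variables not in table: ", paste(miss, collapse = ", "))
  if (!length(vn)) stop("no variables to normalize")
  x <- object[vn, ]
  mat <- abundanceMatrix(x)
  vlt <- rowData(x)$voltage
  for (v in unique(vlt)) {
    rows <- vlt == v
    seg <- mat[rows, , drop = FALSE]
    denom <- if (scheme == "ion_current") colSums(seg)
             else sqrt(colSums(seg^2))
    z <- denom == 0
    if (any(z)) {
      warning(sprintf("%d all-zero %g V segment(s) left as zero",
                      sum(z), v), call. = FALSE)
      denom[z] <- 1
    }
    mat[rows, ] <- sweep(seg, 2, denom, "/")
  }
  out <- BinnedSpectra(mat, rowData(x)$bin_upper, rowData(x)$voltage,
                       sampleData(x),
                       bin_width = metadata(x)$bin_width,
                       normalization = scheme)
  metadata(out)$selection <- vn
  out
}
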