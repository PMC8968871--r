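#' Assign a centroid m/z to its named bin
#'
#' Bins are fixed-width, left-open/right-closed intervals named for their
#' upper limit: with the default 0.025 Da width the 109.050 bin covers
#' m/z (109.025, 109.050], so 109.031 maps to 109.050 and 109.050 itself
#' belongs to its named bin.
#'
#' @param mz centroid m/z value(s), Da; must be positive.
#' @param width bin width, Da.
#' @return The smallest multiple of `width` that is >= `mz`, for each
#'   input value.
#' @examples
#' binPeak(109.031)  # 109.050
#' @export
binPeak <- function(mz, width = 0.025) {
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("m/z values must be positive and finite")
  # the small slack absorbs floating-point error when mz sits on a
  # bin boundary (e.g. 109.050 / 0.025)
  k <- ceiling(mz / width - 1e-9)
  round(k * width, 9)
}

# Aggregate a long peak table to (sample, voltage, bin) with summed
# abundance. Summation treats ion current as additive when several
# centroids fall in one bin; "max" keeps the largest centroid instead.
.binPeaksLong <- function(peaks, width, aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  bin <- binPeak(peaks$mz, width)
  key <- paste(peaks$sample_id, peaks$voltage, format(bin, nsmall = 9),
               sep = "\r")
  fun <- if (aggregate == "sum") sum else max
  ab <- tapply(peaks$abundance, key, fun)
  first <- !duplicated(key)
  out <- data.frame(sample_id = peaks$sample_id[first],
                    voltage = peaks$voltage[first],
                    bin_upper = bin[first],
                    stringsAsFactors = FALSE)
  out$abundance <- as.numeric(ab[key[first]])
  out[order(out$sample_id, out$voltage, out$bin_upper), , drop = FALSE]
}

#' @rdname backgroundSubtract
#' @details Centroid m/z values of a sample and a solvent blank never
#'   match exactly, so both are first aggregated to bins of `bin_width`;
#'   the blank's per-bin abundance is then subtracted from the sample's
#'   per-bin abundance at the same voltage, clamping at zero (a blank
#'   larger than the sample yields 0, never a negative abundance).
#'   Output peaks sit at their bin upper limits; bins whose corrected
#'   abundance is zero are dropped. Every voltage present in the sample
#'   spectra must be present in the blank.
#' @export
setMethod("backgroundSubtract", "CentroidSpectra",
          function(object, blank, bin_width = 0.025) {
  if (is(blank, "CentroidSpectra")) {
    if (nrow(sampleData(blank)) != 1L)
      stop("blank must contain exactly one sample")
    blank <- peaksTable(blank)[, c("voltage", "mz", "abundance")]
  }
  blank <- as.data.frame(blank)
  stopifnot(all(c("voltage", "mz", "abundance") %in% names(blank)))
  missing_v <- setdiff(voltages(object), unique(blank$voltage))
  if (length(missing_v))
    stop("voltage mismatch: blank has no spectrum at ",
         paste(missing_v, collapse = ", "), " V")
  pk <- peaksTable(object)
  if (!nrow(pk)) return(object)
  sb <- .binPeaksLong(pk, bin_width)
  blank$sample_id <- "blank"
  bb <- .binPeaksLong(blank, bin_width)
  bkey <- paste(bb$voltage, format(bb$bin_upper, nsmall = 9))
  bab <- stats::setNames(bb$abundance, bkey)
  skey <- paste(sb$voltage, format(sb$bin_upper, nsmall = 9))
  corr <- pmax(0, sb$abundance - ifelse(skey %in% bkey, bab[skey], 0))
  keep <- corr > 0
  out <- data.frame(sample_id = sb$sample_id[keep],
                    voltage = sb$voltage[keep],
                    mz = sb$bin_upper[keep],
                    abundance = corr[keep],
                    stringsAsFactors = FALSE)
  CentroidSpectra(out, sampleData(object), object@runInfo)
})

#' @rdname applyAbundanceFloor
#' @details The floor is inclusive: a centroid exactly at the floor is
#'   the minimum reportable value and is kept.
#' @export
setMethod("applyAbundanceFloor", "CentroidSpectra",
          function(object, floor = 120) {
  stopifnot(length(floor) == 1L, floor >= 0)
  pk <- peaksTable(object)
  CentroidSpectra(pk[pk$abundance >= floor, , drop = FALSE],
                  sampleData(object), object@runInfo)
})

#' Assemble centroided spectra into the wide binned-abundance table
#'
#' Bins every peak to its (bin upper limit, voltage) variable, sums
#' multiple centroids falling in one bin, and lays the result out as one
#' row per sample and one column per variable, with absent bins stored as
#' zero. This is the single wide table on which all variable selection,
#' normalisation and classification operate.
#'
#' @param spectra a [CentroidSpectra-class] object.
#' @param bin_width bin width, Da.
#' @param voltages voltages every sample must provide; defaults to all
#'   voltages present in `spectra`. A sample lacking any required voltage
#'   raises an error naming it.
#' @param aggregate how multiple centroids in one bin combine: `"sum"`
#'   (ion current is additive; default) or `"max"`.
#' @return A [BinnedSpectra-class] object with raw abundances.
#' @export
assembleTable <- function(spectra, bin_width = 0.025, voltages = NULL,
                          aggregate = c("sum", "max")) {
  stopifnot(is(spectra, "CentroidSpectra"))
  pk <- peaksTable(spectra)
  md <- sampleData(spectra)
  if (is.null(voltages)) voltages <- sort(unique(pk$voltage))
  have <- unique(pk[, c("sample_id", "voltage")])
  for (v in voltages) {
    miss <- setdiff(md$sample_id, have$sample_id[have$voltage == v])
    if (length(miss))
      stop(sprintf("sample '%s' is missing a spectrum at %g V",
                   miss[1], v))
  }
  long <- .binPeaksLong(pk[pk$voltage %in% voltages, , drop = FALSE],
                        bin_width, aggregate)
  vars <- unique(long[, c("bin_upper", "voltage")])
  vars <- vars[order(vars$voltage, vars$bin_upper), , drop = FALSE]
  vname <- variableName(vars$bin_upper, vars$voltage)
  mat <- matrix(0, nrow = nrow(vars), ncol = nrow(md),
                dimnames = list(vname, md$sample_id))
  ri <- match(variableName(long$bin_upper, long$voltage), vname)
  ci <- match(long$sample_id, md$sample_id)
  mat[cbind(ri, ci)] <- long$abundance
  BinnedSpectra(mat, vars$bin_upper, vars$voltage, md,
                bin_width = bin_width, normalization = "raw")
}

#' Write / read the wide binned table as CSV
#'
#' The layout mirrors the assembled study table: sample metadata columns
#' first, then one column per (bin, voltage) variable named like
#' `109.050_30V`. Numbers are written with full precision so the
#' write-read round trip reproduces the table exactly.
#'
#' @param object a [BinnedSpectra-class] object.
#' @param file CSV path.
#' @return `writeBinnedTable()` the path invisibly; `readBinnedTable()` a
#'   [BinnedSpectra-class] object.
#' @export
writeBinnedTable <- function(object, file) {
  stopifnot(is(object, "BinnedSpectra"))
  md <- sampleData(object)
  mat <- t(abundanceMatrix(object))
  num <- as.data.frame(apply(mat, 2, function(x) sprintf("%.17g", x)),
                       optional = TRUE)
  if (nrow(mat) == 1L) {  # apply() drops to a vector for one row
    num <- as.data.frame(as.list(sprintf("%.17g", mat[1, ])),
                         optional = TRUE)
    names(num) <- colnames(mat)
  }
  out <- cbind(md, num)
  attr(out, "normalization") <- NULL
  header <- sprintf("# normalization=%s bin_width=%.17g",
                    normalization(object), metadata(object)$bin_width)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(file)
}

#' @rdname writeBinnedTable
#' @export
readBinnedTable <- function(file) {
  header <- readLines(file, n = 1L)
  norm <- sub(".*normalization=(\\S+).*", "\\1", header)
  bw <- as.numeric(sub(".*bin_width=(\\S+).*", "\\1", header))
  df <- utils::read.csv(file, skip = 1L, check.names = FALSE,
                        stringsAsFactors = FALSE)
  meta_cols <- .SAMPLE_COLS
  var_cols <- setdiff(names(df), meta_cols)
  parsed <- regmatches(var_cols,
                       regexec("^([0-9.]+)_([0-9.]+)V$", var_cols))
  bin_upper <- vapply(parsed, function(p) as.numeric(p[2]), numeric(1))
  voltage <- vapply(parsed, function(p) as.numeric(p[3]), numeric(1))
  mat <- t(as.matrix(df[, var_cols, drop = FALSE]))
  md <- df[, meta_cols, drop = FALSE]
  md$sample_id <- as.character(md$sample_id)
  BinnedSpectra(mat, bin_upper, voltage, md, bin_width = bw,
                normalization = norm)
}
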