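#' @include AllGenerics.R
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.SAMPLE_COLS <- c("sample_id", "class", "week", "card", "replicate",
                  "volume", "batch", "day")
.PEAK_COLS <- c("sample_id", "voltage", "mz", "abundance")
.NORM_SCHEMES <- c("raw", "ion_current", "vector_length")

#' CentroidSpectra: centroided multi-voltage spectra in long form
#'
#' Holds one centroided spectrum per sample per Orifice-1 voltage, as a long
#' peak table, together with the per-sample study metadata (isomer class,
#' analysis week/day, QuickStrip card, replicate within triplicate,
#' deposition volume, batch label). Peaks are kept sorted by sample,
#' voltage and m/z.
#'
#' @slot peaks `data.frame` with columns `sample_id`, `voltage`, `mz` (Da),
#'   `abundance` (counts, non-negative).
#' @slot sampleData `data.frame` with one row per sample: `sample_id`,
#'   `class`, `week`, `card`, `replicate`, `volume`, `batch`, `day`.
#' @slot runInfo `list` recording provenance (generator config, seed).
#'
#' @seealso [simulateSpectra()], [assembleTable()]
#' @export
setClass("CentroidSpectra",
         slots = c(peaks = "data.frame",
                   sampleData = "data.frame",
                   runInfo = "list"))

setValidity("CentroidSpectra", function(object) {
  msg <- character()
  if (!all(.PEAK_COLS %in% names(object@peaks)))
    msg <- c(msg, sprintf("peaks must have columns %s",
                          paste(.PEAK_COLS, collapse = ", ")))
  if (!all(.SAMPLE_COLS %in% names(object@sampleData)))
    msg <- c(msg, sprintf("sampleData must have columns %s",
                          paste(.SAMPLE_COLS, collapse = ", ")))
  if (length(msg)) return(msg)
  if (nrow(object@peaks)) {
    if (any(object@peaks$abundance < 0))
      msg <- c(msg, "peak abundances must be non-negative")
    if (any(object@peaks$mz <= 0))
      msg <- c(msg, "peak m/z values must be positive")
    if (!all(object@peaks$sample_id %in% object@sampleData$sample_id))
      msg <- c(msg, "every peak must belong to a sample in sampleData")
    o <- order(object@peaks$sample_id, object@peaks$voltage, object@peaks$mz)
    if (!identical(o, seq_len(nrow(object@peaks))))
      msg <- c(msg, "peaks must be sorted by sample_id, voltage, mz")
  }
  if (anyDuplicated(object@sampleData$sample_id))
    msg <- c(msg, "sample_id must be unique in sampleData")
  if (length(msg)) msg else TRUE
})

#' Construct a CentroidSpectra object
#'
#' @param peaks `data.frame` of peaks (`sample_id`, `voltage`, `mz`,
#'   `abundance`); sorted internally.
#' @param sampleData per-sample metadata `data.frame` (see
#'   [CentroidSpectra-class]).
#' @param runInfo optional provenance list.
#' @return A [CentroidSpectra-class] object.
#' @export
CentroidSpectra <- function(peaks, sampleData, runInfo = list()) {
  peaks <- as.data.frame(peaks)[, .PEAK_COLS]
  peaks <- peaks[order(peaks$sample_id, peaks$voltage, peaks$mz), ,
                 drop = FALSE]
  rownames(peaks) <- NULL
  sampleData <- as.data.frame(sampleData)
  rownames(sampleData) <- NULL
  new("CentroidSpectra", peaks = peaks, sampleData = sampleData,
      runInfo = runInfo)
}

#' @rdname peaksTable
#' @export
setMethod("peaksTable", "CentroidSpectra", function(object) object@peaks)

#' @rdname sampleData
#' @export
setMethod("sampleData", "CentroidSpectra", function(object) object@sampleData)

#' @rdname voltages
#' @export
setMethod("voltages", "CentroidSpectra", function(object)
  sort(unique(object@peaks$voltage)))

setMethod("show", "CentroidSpectra", function(object) {
  cat("CentroidSpectra with", nrow(object@sampleData), "samples,",
      length(voltages(object)), "voltage channels,",
      nrow(object@peaks), "peaks\n")
  cat("  voltages:", paste(voltages(object), collapse = ", "), "V\n")
  cat("  classes: ",
      paste(sort(unique(object@sampleData$class)), collapse = ", "), "\n",
      sep = "")
  if (!is.null(object@runInfo$seed))
    cat("  generator seed:", object@runInfo$seed, "\n")
  invisible(NULL)
})

#' BinnedSpectra: the wide sample-by-variable abundance table
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single assay `"abundance"` holds one row per (m/z bin, voltage)
#' variable and one column per sample. `rowData` carries `bin_upper` (Da;
#' bins are named for their upper limit) and `voltage`; `colData` carries
#' the study metadata. The `normalization` slot records whether the values
#' are raw abundances or have been ion-current or vector-length normalised.
#'
#' @slot normalization `"raw"`, `"ion_current"` or `"vector_length"`.
#' @seealso [assembleTable()], [normalizeSpectra()]
#' @export
setClass("BinnedSpectra",
         contains = "SummarizedExperiment",
         slots = c(normalization = "character"),
         prototype = prototype(normalization = "raw"))

setValidity("BinnedSpectra", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  rd <- rowData(object)
  if (!all(c("bin_upper", "voltage") %in% names(rd)))
    msg <- c(msg, "rowData must have columns bin_upper and voltage")
  if (!(length(object@normalization) == 1L &&
        object@normalization %in% .NORM_SCHEMES))
    msg <- c(msg, sprintf("normalization must be one of %s",
                          paste(.NORM_SCHEMES, collapse = ", ")))
  if (length(msg)) return(msg)
  bw <- metadata(object)$bin_width
  if (!is.null(bw) && nrow(object)) {
    off <- abs(rd$bin_upper / bw - round(rd$bin_upper / bw))
    if (any(off > 1e-6))
      msg <- c(msg, "bin_upper values must be multiples of the bin width")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BinnedSpectra object
#'
#' Most users obtain these from [assembleTable()]; this constructor is for
#' assembling one directly from a matrix.
#'
#' @param abundance numeric matrix, variables (rows) by samples (columns).
#' @param bin_upper numeric vector of bin upper limits (Da), one per row.
#' @param voltage numeric vector of voltage labels, one per row.
#' @param sampleData per-sample metadata `data.frame`; row order must match
#'   the matrix columns.
#' @param bin_width bin width in Da (default 0.025).
#' @param normalization normalisation scheme of the values.
#' @return A [BinnedSpectra-class] object.
#' @export
BinnedSpectra <- function(abundance, bin_upper, voltage, sampleData,
                          bin_width = 0.025, normalization = "raw") {
  abundance <- as.matrix(abundance)
  stopifnot(length(bin_upper) == nrow(abundance),
            length(voltage) == nrow(abundance),
            nrow(sampleData) == ncol(abundance))
  rownames(abundance) <- variableName(bin_upper, voltage)
  colnames(abundance) <- as.character(sampleData$sample_id)
  se <- SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = DataFrame(bin_upper = bin_upper, voltage = voltage),
    colData = DataFrame(sampleData, row.names = colnames(abundance)))
  metadata(se)$bin_width <- bin_width
  new("BinnedSpectra", se, normalization = normalization)
}

#' Canonical variable name for a (bin, voltage) pair
#'
#' @param bin_upper bin upper limit(s), Da.
#' @param voltage voltage label(s), V.
#' @return character vector like `"109.050_30V"`.
#' @export
variableName <- function(bin_upper, voltage) {
  sprintf("%.3f_%gV", bin_upper, voltage)
}

#' @rdname variableKeys
#' @export
setMethod("variableKeys", "BinnedSpectra", function(object) {
  rd <- rowData(object)
  data.frame(variable = rownames(object),
             bin_upper = rd$bin_upper,
             voltage = rd$voltage)
})

#' @rdname normalization
#' @export
setMethod("normalization", "BinnedSpectra",
          function(object) object@normalization)

#' @rdname sampleData
#' @export
setMethod("sampleData", "BinnedSpectra", function(object) {
  df <- as.data.frame(colData(object))
  rownames(df) <- NULL
  df
})

#' @rdname voltages
#' @export
setMethod("voltages", "BinnedSpectra", function(object)
  sort(unique(rowData(object)$voltage)))

setMethod("show", "BinnedSpectra", function(object) {
  cat("BinnedSpectra:", nrow(object), "variables x", ncol(object),
      "samples\n")
  cat("  voltages:", paste(voltages(object), collapse = ", "), "V;",
      "bin width:", metadata(object)$bin_width, "Da\n")
  cat("  normalization:", object@normalization, "\n")
  invisible(NULL)
})

#' Abundance matrix of a binned table
#'
#' @param object A [BinnedSpectra-class] object.
#' @return Numeric matrix, variables by samples.
#' @export
abundanceMatrix <- function(object) {
  stopifnot(is(object, "BinnedSpectra"))
  assay(object, "abundance")
}
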