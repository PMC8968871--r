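#' @import methods
NULL

#' Peak table of a centroided spectrum collection
#'
#' @param object A [CentroidSpectra-class] object.
#' @return A `data.frame` with columns `sample_id`, `voltage`, `mz`,
#'   `abundance`, one row per centroided peak.
#' @export
setGeneric("peaksTable", function(object) standardGeneric("peaksTable"))

#' Per-sample metadata
#'
#' @param object A [CentroidSpectra-class] or [BinnedSpectra-class] object.
#' @return A `data.frame` with one row per sample (columns `sample_id`,
#'   `class`, `week`, `card`, `replicate`, `volume`, `batch`, `day`).
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' Voltage labels present in an object
#'
#' @param object A [CentroidSpectra-class] or [BinnedSpectra-class] object.
#' @return Sorted numeric vector of Orifice-1 voltage labels (V).
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))

#' Variable keys (bin upper limit, voltage) of a binned table
#'
#' Each variable of the analysis is one (m/z bin, voltage) pair; bins are
#' named for their upper limit, so the key `109.050` at 30 V covers
#' m/z (109.025, 109.050].
#'
#' @param object A [BinnedSpectra-class] object.
#' @return A `data.frame` with columns `variable`, `bin_upper`, `voltage`.
#' @export
setGeneric("variableKeys", function(object) standardGeneric("variableKeys"))

#' Normalisation scheme of a binned table
#'
#' @param object A [BinnedSpectra-class] object.
#' @return One of `"raw"`, `"ion_current"`, `"vector_length"`.
#' @export
setGeneric("normalization", function(object) standardGeneric("normalization"))

#' Background-subtract a solvent blank from sample spectra
#'
#' @param object A [CentroidSpectra-class] object holding sample spectra.
#' @param blank A blank spectrum: either a [CentroidSpectra-class] object
#'   containing a single sample, or a `data.frame` with columns `voltage`,
#'   `mz`, `abundance`.
#' @param bin_width Bin width (Da) used to match blank and sample peaks;
#'   centroid m/z values never match exactly, so both are binned first.
#' @return A [CentroidSpectra-class] object with blank-corrected abundances,
#'   clamped at zero.
#' @export
setGeneric("backgroundSubtract",
           function(object, blank, bin_width = 0.025)
             standardGeneric("backgroundSubtract"))

#' Drop centroided peaks below an abundance floor
#'
#' @param object A [CentroidSpectra-class] object.
#' @param floor Minimum reportable centroid abundance (counts); peaks with
#'   abundance below the floor are removed, the floor itself is kept.
#' @return A [CentroidSpectra-class] object.
#' @export
setGeneric("applyAbundanceFloor",
           function(object, floor = 120) standardGeneric("applyAbundanceFloor"))
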