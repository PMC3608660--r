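#' @import methods
NULL

#' Spectrum: a centroided peak list
#'
#' Container for an observed or simulated peak list — either a MALDI peptide
#' mass fingerprint (no precursor) or a tandem MS/MS spectrum (precursor MH+
#' annotated). Peaks are kept sorted by m/z.
#'
#' @slot mz Numeric, peak m/z values (Da), sorted ascending, all > 0.
#' @slot intensity Numeric, same length as \code{mz}, all >= 0.
#' @slot precursorMz Numeric scalar; MH+ of the selected precursor, or
#'   \code{NA_real_} for PMFs.
#' @slot label Character scalar identifying the spectrum.
#' @export
setClass("Spectrum",
  representation(mz = "numeric", intensity = "numeric",
                 precursorMz = "numeric", label = "character"),
  prototype(precursorMz = NA_real_, label = ""))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity lengths differ")
  if (length(object@mz) && any(object@mz <= 0))
    msg <- c(msg, "all m/z values must be > 0")
  if (is.unsorted(object@mz))
    msg <- c(msg, "peaks must be sorted by m/z")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (length(object@precursorMz) != 1L)
    msg <- c(msg, "precursorMz must be a scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param mz Numeric vector of peak m/z values (Da); sorted internally.
#' @param intensity Numeric vector of intensities (default all 1).
#' @param precursorMz Optional precursor MH+ (Da).
#' @param label Spectrum identifier.
#' @return A \linkS4class{Spectrum}.
#' @export
#' @examples
#' Spectrum(c(1453.7, 876.4), label = "pmf1")
Spectrum <- function(mz, intensity = rep(1, length(mz)),
                     precursorMz = NA_real_, label = "") {
  o <- order(mz)
  new("Spectrum", mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
      precursorMz = as.numeric(precursorMz), label = as.character(label))
}

#' @describeIn Spectrum-class Peak m/z values.
#' @param object,x A \code{Spectrum}.
#' @export
setGeneric("peakMz", function(object) standardGeneric("peakMz"))
#' @rdname Spectrum-class
#' @export
setMethod("peakMz", "Spectrum", function(object) object@mz)

#' @describeIn Spectrum-class Peak intensities.
#' @export
setGeneric("peakIntensity", function(object) standardGeneric("peakIntensity"))
#' @rdname Spectrum-class
#' @export
setMethod("peakIntensity", "Spectrum", function(object) object@intensity)

#' @describeIn Spectrum-class Precursor MH+ (NA for PMFs).
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))
#' @rdname Spectrum-class
#' @export
setMethod("precursorMz", "Spectrum", function(object) object@precursorMz)

#' @describeIn Spectrum-class Spectrum label.
#' @export
setGeneric("spectrumLabel", function(object) standardGeneric("spectrumLabel"))
#' @rdname Spectrum-class
#' @export
setMethod("spectrumLabel", "Spectrum", function(object) object@label)

#' @rdname Spectrum-class
#' @export
setMethod("length", "Spectrum", function(x) length(x@mz))

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum \"", object@label, "\": ", length(object@mz), " peaks",
      sep = "")
  if (length(object@mz))
    cat(sprintf(", m/z %.2f-%.2f", min(object@mz), max(object@mz)))
  if (!is.na(object@precursorMz))
    cat(sprintf(", precursor MH+ %.4f", object@precursorMz))
  cat("\n")
  invisible(NULL)
})

#' ConcatAlignment: concatenated alpha1/alpha2 site matrix
#'
#' A rectangular amino-acid site matrix over the taxa, formed by pasting the
#' alpha1(I) columns before the alpha2(I) columns of a master alignment.
#' Characters are the 20 amino-acid letters, '-' (gap) and '?' (unobserved).
#'
#' @slot seqs Character matrix, rows = taxa (rownames), single characters.
#' @slot boundary Integer, index of the last alpha1 column.
#' @export
setClass("ConcatAlignment",
  representation(seqs = "matrix", boundary = "integer"))

setValidity("ConcatAlignment", function(object) {
  msg <- character()
  if (!is.character(object@seqs)) msg <- c(msg, "seqs must be character")
  if (is.null(rownames(object@seqs))) msg <- c(msg, "taxa rownames required")
  if (anyDuplicated(rownames(object@seqs)))
    msg <- c(msg, "duplicate taxon labels")
  if (length(object@boundary) != 1L || is.na(object@boundary) ||
      object@boundary < 1L || object@boundary > ncol(object@seqs))
    msg <- c(msg, "boundary must lie within [1, n sites]")
  bad <- setdiff(unique(as.vector(object@seqs)), c(.AA_ORDER, "-", "?"))
  if (length(bad))
    msg <- c(msg, paste("invalid residue letters:", paste(bad, collapse = " ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn ConcatAlignment-class Taxon labels.
#' @param object A \code{ConcatAlignment}.
#' @export
setGeneric("alignmentTaxa", function(object) standardGeneric("alignmentTaxa"))
#' @rdname ConcatAlignment-class
#' @export
setMethod("alignmentTaxa", "ConcatAlignment",
          function(object) rownames(object@seqs))

#' @describeIn ConcatAlignment-class The character site matrix.
#' @export
setGeneric("siteMatrix", function(object) standardGeneric("siteMatrix"))
#' @rdname ConcatAlignment-class
#' @export
setMethod("siteMatrix", "ConcatAlignment", function(object) object@seqs)

#' @describeIn ConcatAlignment-class Index of the last alpha1 column.
#' @export
setGeneric("chainBoundary", function(object) standardGeneric("chainBoundary"))
#' @rdname ConcatAlignment-class
#' @export
setMethod("chainBoundary", "ConcatAlignment", function(object) object@boundary)

#' @describeIn ConcatAlignment-class Per-taxon fraction of non-'?' sites.
#' @export
setGeneric("coverageFraction", function(object)
  standardGeneric("coverageFraction"))
#' @rdname ConcatAlignment-class
#' @export
setMethod("coverageFraction", "ConcatAlignment", function(object)
  rowMeans(object@seqs != "?"))

setMethod("show", "ConcatAlignment", function(object) {
  cat("ConcatAlignment: ", nrow(object@seqs), " taxa x ", ncol(object@seqs),
      " sites (alpha1 1-", object@boundary, ", alpha2 ",
      object@boundary + 1L, "-", ncol(object@seqs), ")\n", sep = "")
  cv <- round(100 * coverageFraction(object))
  cat("  coverage%: ", paste0(rownames(object@seqs), "=", cv,
                              collapse = " "), "\n", sep = "")
  invisible(NULL)
})

#' SplitSystem: weighted circular split system
#'
#' The result of a NeighborNet decomposition of a distance matrix: a set of
#' weighted bipartitions (splits) of the taxa, compatible with a circular
#' ordering. Incompatible splits with positive weight visualise conflicting
#' phylogenetic signal as boxes in the network.
#'
#' @slot splits List of integer vectors (one side of each split, as indices
#'   into \code{taxa}), carrying phangorn "splits" semantics.
#' @slot weights Numeric split weights, >= 0.
#' @slot cycle Integer circular ordering of the taxa.
#' @slot taxa Character taxon labels.
#' @export
setClass("SplitSystem",
  representation(splits = "list", weights = "numeric",
                 cycle = "integer", taxa = "character"))

setValidity("SplitSystem", function(object) {
  msg <- character()
  if (length(object@splits) != length(object@weights))
    msg <- c(msg, "splits and weights lengths differ")
  if (length(object@weights) && any(object@weights < 0))
    msg <- c(msg, "split weights must be >= 0")
  if (length(object@cycle) != length(object@taxa))
    msg <- c(msg, "cycle must be a permutation of the taxa")
  if (length(msg)) msg else TRUE
})

#' @describeIn SplitSystem-class Split weights.
#' @param object A \code{SplitSystem}.
#' @export
setGeneric("splitWeights", function(object) standardGeneric("splitWeights"))
#' @rdname SplitSystem-class
#' @export
setMethod("splitWeights", "SplitSystem", function(object) object@weights)

#' @describeIn SplitSystem-class Splits as lists of taxon labels.
#' @export
setGeneric("splitList", function(object) standardGeneric("splitList"))
#' @rdname SplitSystem-class
#' @export
setMethod("splitList", "SplitSystem", function(object)
  lapply(object@splits, function(i) object@taxa[i]))

#' @describeIn SplitSystem-class Circular taxon ordering.
#' @export
setGeneric("circularOrder", function(object) standardGeneric("circularOrder"))
#' @rdname SplitSystem-class
#' @export
setMethod("circularOrder", "SplitSystem", function(object)
  object@taxa[object@cycle])

setMethod("show", "SplitSystem", function(object) {
  cat("SplitSystem: ", length(object@splits), " weighted splits on ",
      length(object@taxa), " taxa\n", sep = "")
  cat("  cycle:", paste(circularOrder(object), collapse = " "), "\n")
  invisible(NULL)
})
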