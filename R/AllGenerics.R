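#' Accessors for occumap classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `geneIds` and `geneLengths` for [GeneSet-class]; `sampleId`,
#' `experimentReads` and `spikeinReads` for [ReadSet-class]; `trackSignal`,
#' `trackUnits` and `scaleFactor` for [CoverageTrack-class];
#' `signalValues`, `anchorType` and `binOffsets` for [SignalMatrix-class].
#'
#' @param x An occumap object.
#' @return The corresponding slot value (see Details of each class).
#' @name accessors
#' @examples
#' gs <- exampleGeneSet()
#' geneIds(gs)
#' geneLengths(gs)
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))
#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("experimentReads", function(x) standardGeneric("experimentReads"))
#' @rdname accessors
#' @export
setGeneric("spikeinReads", function(x) standardGeneric("spikeinReads"))
#' @rdname accessors
#' @export
setGeneric("readRanges", function(x) standardGeneric("readRanges"))
#' @rdname accessors
#' @export
setGeneric("trackSignal", function(x) standardGeneric("trackSignal"))
#' @rdname accessors
#' @export
setGeneric("trackUnits", function(x) standardGeneric("trackUnits"))
#' @rdname accessors
#' @export
setGeneric("scaleFactor", function(x) standardGeneric("scaleFactor"))
#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setGeneric("anchorType", function(x) standardGeneric("anchorType"))
#' @rdname accessors
#' @export
setGeneric("binOffsets", function(x) standardGeneric("binOffsets"))

#' @rdname accessors
setMethod("geneIds", "GeneSet", function(x) names(x@genes))
#' @rdname accessors
setMethod("geneLengths", "GeneSet", function(x) {
  w <- width(x@genes); names(w) <- names(x@genes); w
})
#' @rdname accessors
setMethod("geneRanges", "GeneSet", function(x) x@genes)
#' @rdname accessors
setMethod("sampleId", "ReadSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "CoverageTrack", function(x) x@sampleId)
#' @rdname accessors
setMethod("experimentReads", "ReadSet", function(x) x@experimentReads)
#' @rdname accessors
setMethod("spikeinReads", "ReadSet", function(x) x@spikeinReads)
#' @rdname accessors
setMethod("readRanges", "ReadSet", function(x) x@reads)
#' @rdname accessors
setMethod("trackSignal", "CoverageTrack", function(x) x@signal)
#' @rdname accessors
setMethod("trackUnits", "CoverageTrack", function(x) x@units)
#' @rdname accessors
setMethod("scaleFactor", "CoverageTrack", function(x) x@scaleFactor)
#' @rdname accessors
setMethod("signalValues", "SignalMatrix", function(x) x@values)
#' @rdname accessors
setMethod("anchorType", "SignalMatrix", function(x) x@anchor)
#' @rdname accessors
setMethod("binOffsets", "SignalMatrix", function(x)
  as.numeric(colnames(x@values)))

#' Total signal mass of a coverage track
#'
#' Sum of the per-base signal over all chromosomes; for a raw track this is
#' the total number of covered base pairs (read count times read length,
#' minus truncation), and it scales linearly under normalization.
#'
#' @param x A [CoverageTrack-class].
#' @return A single numeric value.
#' @export
#' @examples
#' sim <- exampleTrack()
#' trackMass(sim)
setGeneric("trackMass", function(x) standardGeneric("trackMass"))

#' @rdname trackMass
setMethod("trackMass", "CoverageTrack", function(x)
  sum(vapply(x@signal, function(v) sum(as.numeric(v)), numeric(1))))
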