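#' @import methods
#' @importFrom S4Vectors Rle RleList runValue runValue<-
#' @importFrom IRanges IRanges Views
#' @importFrom GenomicRanges GRanges granges seqnames strand start end width
#'   coverage resize trim
#' @importFrom BiocGenerics unlist
NULL

VALID_UNITS <- c("raw", "RPM")
VALID_ANCHORS <- c("TSS", "TTS")
VALID_SHAPES <- c("uniform_gene_body", "tss_peak", "tts_peak", "mixture",
                  "background_only")

#' GeneSet: strand-aware gene intervals with derived anchors
#'
#' Holds protein-coding gene intervals as a [GenomicRanges::GRanges] (1-based,
#' closed, the Bioconductor convention; BED input is shifted on import) whose
#' names are unique gene identifiers.  Transcription start sites (TSS) and
#' termination sites (TTS) are derived strand-aware: on the plus strand the
#' TSS is the lowest coordinate, on the minus strand the highest.
#'
#' @slot genes A named `GRanges`; names are unique gene ids, strand is
#'   `+` or `-` for every record.
#' @slot provenance Character scalar describing origin (file and filters).
#'
#' @seealso [loadGenes()], [classifyByLength()], [classifyByExpression()],
#'   [anchorPositions()]
#' @exportClass GeneSet
setClass("GeneSet",
  representation(genes = "GRanges", provenance = "character"))

setValidity("GeneSet", function(object) {
  gr <- object@genes
  msgs <- character()
  if (length(gr)) {
    ids <- names(gr)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      msgs <- c(msgs, "every gene must have a non-empty id (names of 'genes')")
    else if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicate gene ids: %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    st <- as.character(strand(gr))
    if (any(!st %in% c("+", "-")))
      msgs <- c(msgs, "all genes must be stranded ('+' or '-')")
    if (any(width(gr) < 1))
      msgs <- c(msgs, "gene widths must be >= 1")
  }
  if (length(object@provenance) != 1)
    msgs <- c(msgs, "provenance must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' ReadSet: aligned single-end reads partitioned by genome of origin
#'
#' Reads mapped to the experiment genome are kept as intervals; reads mapped
#' to the spike-in genome (recognized by a chromosome-name prefix) are only
#' counted, since their sole use is the normalization denominator.
#'
#' @slot sampleId,condition Character scalars identifying the sample.
#' @slot replicate Integer replicate number.
#' @slot reads `GRanges` of experiment-genome read intervals (start <= end).
#' @slot spikeinReads Count of reads mapped to the spike-in genome.
#' @slot experimentReads Count of reads mapped to the experiment genome
#'   (equals `length(reads)`).
#'
#' @seealso [loadReads()], [spikeinScaleFactor()], [buildCoverage()]
#' @exportClass ReadSet
setClass("ReadSet",
  representation(sampleId = "character", condition = "character",
                 replicate = "integer", reads = "GRanges",
                 spikeinReads = "integer", experimentReads = "integer"))

setValidity("ReadSet", function(object) {
  msgs <- character()
  if (length(object@sampleId) != 1 || length(object@condition) != 1 ||
      length(object@replicate) != 1)
    msgs <- c(msgs, "sampleId, condition and replicate must be scalars")
  if (length(object@spikeinReads) != 1 || object@spikeinReads < 0)
    msgs <- c(msgs, "spikeinReads must be a single nonnegative count")
  if (length(object@experimentReads) != 1 ||
      object@experimentReads != length(object@reads))
    msgs <- c(msgs, "experimentReads must equal length(reads)")
  if (length(msgs)) msgs else TRUE
})

#' CoverageTrack: per-base signal along each chromosome
#'
#' Per-chromosome, per-base signal stored as a run-length encoded list
#' ([IRanges::RleList]).  A track is either `raw` (read pileup counts) or
#' `RPM` (scaled once by a spike-in factor); applying a scale factor twice
#' is rejected, which guards the core spike-in normalization invariant.
#'
#' @slot sampleId Character scalar.
#' @slot signal `RleList`, one run-length vector per chromosome, whose
#'   lengths equal the declared chromosome sizes.
#' @slot units `"raw"` or `"RPM"`.
#' @slot scaleFactor Factor applied to reach RPM (1 for raw tracks).
#'
#' @seealso [buildCoverage()], [normalizeTrack()], [subtractBackground()]
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(sampleId = "character", signal = "RleList",
                 units = "character", scaleFactor = "numeric"))

setValidity("CoverageTrack", function(object) {
  msgs <- character()
  if (!(length(object@units) == 1 && object@units %in% VALID_UNITS))
    msgs <- c(msgs, "units must be 'raw' or 'RPM'")
  if (length(object@scaleFactor) != 1 || !is.finite(object@scaleFactor))
    msgs <- c(msgs, "scaleFactor must be a single finite number")
  if (identical(object@units, "raw")) {
    if (any(vapply(object@signal, function(x) any(runValue(x) < 0), logical(1))))
      msgs <- c(msgs, "raw tracks must be nonnegative")
    if (object@scaleFactor != 1)
      msgs <- c(msgs, "raw tracks must have scaleFactor 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' CorrectedTrack: background-subtracted coverage
#'
#' A [CoverageTrack-class] produced by subtracting a control track (no-tag
#' strain, or a deletion strain lacking the immunoprecipitated protein) from
#' a signal track, both in RPM.  When `clamped`, negative residuals were set
#' to zero (the default for visualization tracks).
#'
#' @slot controlId Sample id of the subtracted control track.
#' @slot clamped Logical; `TRUE` if negatives were zeroed.
#' @seealso [subtractBackground()], [averageReplicates()]
#' @exportClass CorrectedTrack
setClass("CorrectedTrack", contains = "CoverageTrack",
  representation(controlId = "character", clamped = "logical"))

setValidity("CorrectedTrack", function(object) {
  msgs <- character()
  if (length(object@controlId) != 1 || length(object@clamped) != 1)
    msgs <- c(msgs, "controlId and clamped must be scalars")
  if (isTRUE(object@clamped) &&
      any(vapply(object@signal, function(x) any(runValue(x) < 0), logical(1))))
    msgs <- c(msgs, "clamped tracks must be everywhere >= 0")
  if (length(msgs)) msgs else TRUE
})

#' SignalMatrix: genes-by-bins anchored signal
#'
#' Signal around the TSS or TTS of each gene, strand-flipped so that every
#' row reads upstream-to-downstream left to right.  Cells are mean per-base
#' RPM within a bin; window bases falling outside the chromosome are masked
#' (`NA`) rather than zero-filled, so short chromosomes do not fabricate
#' depletion.  Column names give bin-center offsets relative to the anchor
#' (offset 0 is the anchor base, downstream positive).
#'
#' @slot anchor `"TSS"` or `"TTS"`.
#' @slot flankUp,flankDown Window extent in bp, each divisible by `binSize`.
#' @slot binSize Bin width in bp.
#' @slot values Numeric matrix, rownames gene ids, `NA` = masked.
#' @slot rowOrder `"input"` or `"length_desc"`.
#' @slot groups Optional named character vector mapping gene id to group label
#'   (zero-length when absent).
#'
#' @seealso [anchorMatrix()], [sortRowsByLength()], [metagene()]
#' @exportClass SignalMatrix
setClass("SignalMatrix",
  representation(anchor = "character", flankUp = "integer",
                 flankDown = "integer", binSize = "integer",
                 values = "matrix", rowOrder = "character",
                 groups = "character"))

setValidity("SignalMatrix", function(object) {
  msgs <- character()
  if (!(length(object@anchor) == 1 && object@anchor %in% VALID_ANCHORS))
    msgs <- c(msgs, "anchor must be 'TSS' or 'TTS'")
  span <- object@flankUp + object@flankDown
  if (span <= 0 || span %% object@binSize != 0)
    msgs <- c(msgs, "flankUp + flankDown must be a positive multiple of binSize")
  else if (ncol(object@values) != span %/% object@binSize)
    msgs <- c(msgs, "column count must equal (flankUp + flankDown) / binSize")
  if (is.null(rownames(object@values)))
    msgs <- c(msgs, "rows must be named by gene id")
  if (length(msgs)) msgs else TRUE
})

#' OccupancyModel: parametric per-gene occupancy landscape
#'
#' Generative description of where immunoprecipitated protein sits on genes,
#' used by the read simulator.  Shapes mirror the occupancy archetypes seen
#' for the H2B-ubiquitination / H3K4-methylation machinery in budding yeast:
#' `uniform_gene_body` (Rad6/H2Bub-like, reads spread evenly over the gene
#' body, per-gene mass proportional to length), `tss_peak` (H3K4me3/Set1-like
#' Gaussian peak downstream of the TSS), `tts_peak` (CPF-like peak at the
#' TTS), `mixture` (weighted combination of component models, e.g. the
#' two-peak Swd2 landscape), and `background_only` (no-tag control or a
#' strain in which chromatin binding is lost).
#'
#' @slot shape One of `uniform_gene_body`, `tss_peak`, `tts_peak`,
#'   `mixture`, `background_only`.
#' @slot amplitude Expected relative reads per gene (per kb of gene body for
#'   the uniform shape); must be 0 for `background_only`.
#' @slot peakOffset Peak center in bp relative to the anchor (downstream
#'   positive, strand-aware).
#' @slot peakWidth Standard deviation (bp) of the Gaussian placement kernel.
#' @slot backgroundRate Relative reads per kb of genome, added genome-wide.
#' @slot tierMultipliers Named numeric `(high, medium, low)` scaling
#'   amplitude per expression tier (all 1 disables tier structure).
#' @slot components List of component `OccupancyModel`s (mixture only).
#' @slot weights Mixture weights, summing to 1 (mixture only).
#'
#' @seealso [occupancyModel()], [simulateReads()], [conditionSuite()]
#' @exportClass OccupancyModel
setClass("OccupancyModel",
  representation(shape = "character", amplitude = "numeric",
                 peakOffset = "numeric", peakWidth = "numeric",
                 backgroundRate = "numeric", tierMultipliers = "numeric",
                 components = "list", weights = "numeric"))

setValidity("OccupancyModel", function(object) {
  msgs <- character()
  if (!(length(object@shape) == 1 && object@shape %in% VALID_SHAPES))
    msgs <- c(msgs, sprintf("shape must be one of %s",
                            paste(VALID_SHAPES, collapse = ", ")))
  if (object@amplitude < 0)
    msgs <- c(msgs, "amplitude must be >= 0")
  if (identical(object@shape, "background_only") && object@amplitude != 0)
    msgs <- c(msgs, "background_only models must have amplitude 0")
  if (object@backgroundRate < 0)
    msgs <- c(msgs, "backgroundRate must be >= 0")
  if (!all(c("high", "medium", "low") %in% names(object@tierMultipliers)))
    msgs <- c(msgs, "tierMultipliers must be named high, medium, low")
  if (identical(object@shape, "mixture")) {
    if (length(object@components) < 2 ||
        !all(vapply(object@components, is, logical(1), "OccupancyModel")))
      msgs <- c(msgs, "mixture requires >= 2 OccupancyModel components")
    if (length(object@weights) != length(object@components) ||
        abs(sum(object@weights) - 1) > 1e-8 || any(object@weights < 0))
      msgs <- c(msgs, "mixture weights must be nonnegative and sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' WindowSpec: an anchor-relative quantification window
#'
#' @slot anchor `"TSS"` or `"TTS"`.
#' @slot upstream,downstream Extent in bp on either side of the anchor;
#'   their sum (the window length) must be positive.
#' @seealso [windowSpec()], [windowRpkm()]
#' @exportClass WindowSpec
setClass("WindowSpec",
  representation(anchor = "character", upstream = "integer",
                 downstream = "integer"))

setValidity("WindowSpec", function(object) {
  msgs <- character()
  if (!(length(object@anchor) == 1 && object@anchor %in% VALID_ANCHORS))
    msgs <- c(msgs, "anchor must be 'TSS' or 'TTS'")
  if (object@upstream + object@downstream <= 0)
    msgs <- c(msgs, "window length upstream + downstream must be > 0")
  if (length(msgs)) msgs else TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "GeneSet", function(object) {
  gr <- object@genes
  cat("GeneSet with", length(gr), "genes on",
      length(unique(as.character(seqnames(gr)))), "chromosome(s)\n")
  if (length(gr))
    cat("  length range:", min(width(gr)), "-", max(width(gr)), "bp\n")
  cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet", object@sampleId,
      sprintf("(condition %s, replicate %d)\n", object@condition,
              object@replicate))
  cat("  experiment reads:", object@experimentReads,
      " spike-in reads:", object@spikeinReads, "\n")
})

setMethod("show", "CoverageTrack", function(object) {
  cat(class(object), object@sampleId, "in", object@units, "units\n")
  cat("  chromosomes:", paste(names(object@signal), collapse = ", "), "\n")
  cat("  scale factor:", format(object@scaleFactor), "\n")
  if (is(object, "CorrectedTrack"))
    cat("  control:", object@controlId,
        if (object@clamped) "(clamped at 0)" else "(unclamped)", "\n")
})

setMethod("show", "SignalMatrix", function(object) {
  cat("SignalMatrix:", nrow(object@values), "genes x",
      ncol(object@values), "bins,", object@anchor, "anchored\n")
  cat(sprintf("  window -%d..+%d bp, %d-bp bins, row order: %s\n",
              object@flankUp, object@flankDown, object@binSize,
              object@rowOrder))
  if (length(object@groups))
    cat("  groups:", paste(names(table(object@groups)), collapse = ", "), "\n")
})

setMethod("show", "OccupancyModel", function(object) {
  cat("OccupancyModel:", object@shape, "\n")
  if (object@shape %in% c("tss_peak", "tts_peak"))
    cat(sprintf("  peak offset %+d bp, width (sd) %d bp\n",
                as.integer(object@peakOffset), as.integer(object@peakWidth)))
  cat("  amplitude:", object@amplitude,
      " background rate:", object@backgroundRate, "reads/kb\n")
  if (identical(object@shape, "mixture"))
    cat("  mixture of", length(object@components), "components, weights",
        paste(format(object@weights), collapse = "/"), "\n")
})
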