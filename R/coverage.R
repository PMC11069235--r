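#' Load aligned single-end reads and split off the spike-in
#'
#' Ingests aligned reads from SAM/BAM or from a 6-column BED of read
#' intervals.  Reads are partitioned by chromosome name: names starting
#' with `spikeinPrefix` belong to the foreign spike-in genome and are only
#' counted (they exist solely as a normalization denominator); the rest are
#' experiment-genome reads and are kept as intervals.  Unmapped SAM/BAM
#' records are skipped.
#'
#' @param path Path to the alignment file.
#' @param format `"BAM"` (also accepts headered SAM) or `"BED"`.
#' @param spikeinPrefix Chromosome-name prefix marking the spike-in genome.
#' @param chromSizes Optional named vector of chromosome lengths covering
#'   both genomes; when given, reads on undeclared chromosomes raise an
#'   error naming them.
#' @param sampleId,condition,replicate Sample metadata recorded on the
#'   returned object.
#' @return A [ReadSet-class].
#' @export
loadReads <- function(path, format = c("BAM", "BED"),
                      spikeinPrefix = "spikein_", chromSizes = NULL,
                      sampleId = basename(path), condition = "NA",
                      replicate = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  gr <- if (format == "BED") {
    .parseBed6(path)
  } else {
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    granges(GenomicAlignments::readGAlignments(bam))
  }
  chroms <- as.character(seqnames(gr))
  if (!is.null(chromSizes)) {
    unknown <- setdiff(unique(chroms), names(chromSizes))
    if (length(unknown))
      stop("read(s) on undeclared chromosome(s): ",
           paste(unknown, collapse = ", "))
  }
  isSpike <- startsWith(chroms, spikeinPrefix)
  expReads <- gr[!isSpike]
  if (!length(expReads))
    stop("no reads mapped to the experiment genome in ", path)
  names(expReads) <- NULL
  if (!is.null(chromSizes)) {
    expSizes <- chromSizes[!startsWith(names(chromSizes), spikeinPrefix)]
    GenomeInfoDb::seqlevels(expReads) <- names(expSizes)
    GenomeInfoDb::seqlengths(expReads) <- unname(expSizes)
  }
  new("ReadSet", sampleId = sampleId, condition = condition,
      replicate = as.integer(replicate), reads = expReads,
      spikeinReads = sum(isSpike), experimentReads = length(expReads))
}

#' Spike-in normalization factor
#'
#' Each sample is scaled so that its spike-in genome receives exactly one
#' million reads: the factor is `1e6 / spikeinReads`.  Because experiment
#' and spike-in chromatin are mixed before immunoprecipitation, this makes
#' occupancy comparable across samples and conditions regardless of IP
#' efficiency or sequencing depth.
#'
#' @param rs A [ReadSet-class] with at least one spike-in read.
#' @return A single numeric scale factor.
#' @export
#' @examples
#' \dontrun{spikeinScaleFactor(rs)  # 1e6 / spikeinReads(rs)}
spikeinScaleFactor <- function(rs) {
  stopifnot(is(rs, "ReadSet"))
  if (spikeinReads(rs) == 0)
    stop("no spike-in reads in sample '", sampleId(rs),
         "'; spike-in normalization is impossible -- build an unscaled ",
         "track and normalize by depth instead")
  1e6 / spikeinReads(rs)
}

#' Build a raw per-base coverage track
#'
#' Each experiment-genome read adds +1 to every base of its interval,
#' optionally after extending it to `extendTo` bp from its 5' end
#' (strand-aware).  Intervals are truncated at chromosome bounds.  The 51-bp
#' single-end reads this pipeline is designed around are counted over their
#' mapped span by default — no fragment-extension smoothing is assumed.
#'
#' @param rs A [ReadSet-class].
#' @param chromSizes Named vector of experiment-genome chromosome lengths;
#'   must cover every chromosome with reads.
#' @param extendTo Optional fragment length in bp (>= the longest read) to
#'   extend each read to from its 5' end.
#' @return A raw-unit [CoverageTrack-class].
#' @export
buildCoverage <- function(rs, chromSizes, extendTo = NULL) {
  stopifnot(is(rs, "ReadSet"))
  gr <- readRanges(rs)
  chroms <- unique(as.character(seqnames(gr)))
  missing <- setdiff(chroms, names(chromSizes))
  if (length(missing))
    stop("chromSizes missing chromosome(s): ", paste(missing, collapse = ", "))
  if (!is.null(extendTo)) {
    if (extendTo < max(width(gr)))
      stop("extendTo (", extendTo, ") is shorter than the longest read (",
           max(width(gr)), ")")
    gr <- resize(gr, extendTo, fix = "start")
  }
  gr <- GRanges(seqnames(gr), ranges(gr), strand = strand(gr))
  GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
  # ranges running past a chromosome end are expected here; trim() is the fix
  suppressWarnings(GenomeInfoDb::seqlengths(gr) <- unname(chromSizes))
  gr <- trim(gr)
  sig <- coverage(gr, width = as.list(chromSizes))
  new("CoverageTrack", sampleId = sampleId(rs), signal = sig,
      units = "raw", scaleFactor = 1)
}

#' Apply a normalization factor to a raw track
#'
#' Multiplies every per-base value by `factor` and marks the track RPM.
#' Normalizing an already-RPM track is an error: the factor must be applied
#' exactly once.
#'
#' @param cov A raw [CoverageTrack-class].
#' @param factor Positive scale factor, typically [spikeinScaleFactor()].
#' @return An RPM [CoverageTrack-class].
#' @export
normalizeTrack <- function(cov, factor) {
  stopifnot(is(cov, "CoverageTrack"))
  if (trackUnits(cov) != "raw")
    stop("track '", sampleId(cov),
         "' is already in RPM units; refusing to normalize twice")
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("factor must be a single positive number")
  new("CoverageTrack", sampleId = cov@sampleId, signal = cov@signal * factor,
      units = "RPM", scaleFactor = factor)
}

#' Read-to-track convenience wrapper
#'
#' Pipeline shorthand: builds raw coverage and spike-in normalizes it in one
#' step (`normalizeTrack(buildCoverage(rs, ...), spikeinScaleFactor(rs))`).
#'
#' @inheritParams buildCoverage
#' @return An RPM [CoverageTrack-class].
#' @export
spikeinNormalizedTrack <- function(rs, chromSizes, extendTo = NULL) {
  normalizeTrack(buildCoverage(rs, chromSizes, extendTo = extendTo),
                 spikeinScaleFactor(rs))
}
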