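#' Read / write a chrom.sizes declaration
#'
#' Two-column TSV (chromosome name, length) declaring experiment and
#' spike-in chromosomes together.
#'
#' @param path File path.
#' @return `readChromSizes`: named integer vector.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$size), df$chrom)
}

#' @rdname readChromSizes
#' @param chromSizes Named integer vector of chromosome lengths.
#' @export
writeChromSizes <- function(chromSizes, path) {
  utils::write.table(data.frame(names(chromSizes), unname(chromSizes)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Four-column bedGraph (0-based half-open), zero runs omitted.
#'
#' @param track A [CoverageTrack-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeBedGraph <- function(track, path) {
  gr <- as(trackSignal(track), "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Read a bedGraph file back into a coverage track
#'
#' @param path bedGraph path.
#' @param chromSizes Named lengths of the track's chromosomes.
#' @param units Units to stamp on the track (bedGraph does not record
#'   them); defaults to `"RPM"`, the common on-disk currency here.
#' @param sampleId Sample id for the track.
#' @return A [CoverageTrack-class].
#' @export
readBedGraph <- function(path, chromSizes, units = "RPM",
                         sampleId = basename(path)) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
  GenomeInfoDb::seqlengths(gr) <- unname(chromSizes)
  sig <- coverage(gr, weight = gr$score, width = as.list(chromSizes))
  new("CoverageTrack", sampleId = sampleId, signal = sig, units = units,
      scaleFactor = 1)
}

.combineReads <- function(parts) {
  # experiment and spike-in genomes share no seqlevels by design
  suppressWarnings(c(GRanges(seqnames(parts$exp), ranges(parts$exp),
                             strand = strand(parts$exp)),
                     GRanges(seqnames(parts$spike), ranges(parts$spike),
                             strand = strand(parts$spike))))
}

.readsToGRanges <- function(sim) {
  if (is(sim, "ReadSet")) return(list(exp = readRanges(sim),
                                      spike = GRanges()))
  list(exp = readRanges(sim$reads), spike = sim$spikeinRanges)
}

#' Write simulated reads as a headered SAM file
#'
#' Minimal single-end SAM: one `@SQ` line per declared chromosome, reads
#' with flag 0/16 by strand, CIGAR `<width>M`, placeholder `*` sequence and
#' quality.  Experiment and spike-in reads are written together, so the
#' file round-trips through [loadReads()].
#'
#' @param sim A [simulateReads()] result (or a bare [ReadSet-class]).
#' @param chromSizes Both-genome chromosome declaration.
#' @param path Output `.sam` path.
#' @return Invisibly, `path`.
#' @export
writeReadsSAM <- function(sim, chromSizes, path) {
  parts <- .readsToGRanges(sim)
  gr <- .combineReads(parts)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chromSizes),
                   unname(chromSizes)))
  flag <- ifelse(as.character(strand(gr)) == "-", 16L, 0L)
  body <- sprintf("read%07d\t%d\t%s\t%d\t42\t%dM\t*\t0\t0\t*\t*",
                  seq_along(gr), flag, as.character(seqnames(gr)),
                  start(gr), width(gr))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulated reads as 6-column BED
#'
#' @inheritParams writeReadsSAM
#' @param path Output `.bed` path.
#' @return Invisibly, `path`.
#' @export
writeReadsBED <- function(sim, path) {
  parts <- .readsToGRanges(sim)
  gr <- .combineReads(parts)
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   sprintf("read%07d", seq_along(gr)), 0L,
                   as.character(strand(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write planted simulation truth as JSON
#'
#' @param truth The `truth` element of a [simulateReads()] result.
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
writeSimTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tiny built-in example objects
#'
#' Deterministic miniature objects used in documentation examples:
#' `exampleGeneSet()` returns six genes on two chromosomes spanning the
#' length classes; `exampleTrack()` a small raw coverage track over them.
#'
#' @return A [GeneSet-class] or [CoverageTrack-class].
#' @export
#' @examples
#' exampleGeneSet()
exampleGeneSet <- function() {
  gr <- GRanges(c("chrI", "chrI", "chrI", "chrII", "chrII", "chrII"),
                IRanges(start = c(1001, 3001, 6001, 501, 4001, 9001),
                        width = c(500, 1200, 1900, 2500, 3200, 600)),
                strand = c("+", "-", "+", "-", "+", "-"))
  names(gr) <- paste0("gene", 1:6)
  GenomeInfoDb::seqlevels(gr) <- c("chrI", "chrII")
  GenomeInfoDb::seqlengths(gr) <- c(chrI = 10000L, chrII = 15000L)
  new("GeneSet", genes = gr, provenance = "built-in example")
}

#' @rdname exampleGeneSet
#' @export
exampleTrack <- function() {
  gs <- exampleGeneSet()
  reads <- unlist(GenomicRanges::tile(geneRanges(gs), width = 50))
  names(reads) <- NULL
  rs <- new("ReadSet", sampleId = "example", condition = "example",
            replicate = 1L, reads = reads, spikeinReads = 1000L,
            experimentReads = length(reads))
  buildCoverage(rs, c(chrI = 10000L, chrII = 15000L))
}
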