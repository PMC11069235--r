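#' Construct a quantification window
#'
#' @param anchor `"TSS"` or `"TTS"`.
#' @param upstream,downstream Extent in bp either side of the anchor; the
#'   default (-100 / +300 of the TSS) is the promoter-proximal window used
#'   for per-gene occupancy scatters.
#' @return A [WindowSpec-class].
#' @export
#' @examples
#' windowSpec("TSS", 100, 300)
windowSpec <- function(anchor = c("TSS", "TTS"), upstream = 100L,
                       downstream = 300L) {
  anchor <- match.arg(anchor)
  new("WindowSpec", anchor = anchor, upstream = as.integer(upstream),
      downstream = as.integer(downstream))
}

.windowRanges <- function(genes, w) {
  anchors <- anchorPositions(genes, w@anchor)
  pos <- start(anchors)
  plus <- as.character(strand(anchors)) == "+"
  # offsets [-upstream, +downstream) on the gene's own strand
  lo <- ifelse(plus, pos - w@upstream, pos - w@downstream + 1L)
  hi <- ifelse(plus, pos + w@downstream - 1L, pos + w@upstream)
  out <- GRanges(seqnames(anchors), IRanges(lo, hi), strand = strand(anchors))
  names(out) <- names(anchors)
  out
}

#' Windowed per-gene RPKM
#'
#' Counts reads overlapping (by at least one bp) a strand-aware window
#' around each gene's anchor and converts to RPKM: count divided by window
#' length in kb and by experiment-genome mapped reads in millions.  RPKM is
#' depth-relative by definition, so spike-in scaling is deliberately not
#' applied here.
#'
#' @param rs A [ReadSet-class] with at least one experiment read.
#' @param genes A [GeneSet-class].
#' @param w A [WindowSpec-class].
#' @return Named numeric vector gene id -> RPKM.
#' @export
windowRpkm <- function(rs, genes, w) {
  stopifnot(is(rs, "ReadSet"), is(genes, "GeneSet"), is(w, "WindowSpec"))
  len <- w@upstream + w@downstream
  if (len <= 0) stop("zero-length quantification window")
  if (experimentReads(rs) == 0) stop("ReadSet has no experiment reads")
  windows <- .windowRanges(genes, w)
  counts <- GenomicRanges::countOverlaps(windows, readRanges(rs),
                                         ignore.strand = TRUE)
  rpkm <- counts / (len / 1000) / (experimentReads(rs) / 1e6)
  stats::setNames(as.numeric(rpkm), names(windows))
}

#' Null-strain corrected occupancy table
#'
#' Per-gene windowed occupancy for several conditions, with the occupancy
#' measured in a null strain (one lacking the immunoprecipitated protein,
#' e.g. a deletion mutant) subtracted, unclamped, from every other
#' condition.  Values near zero may therefore go slightly negative.
#'
#' @param tables Named list (condition -> named RPKM vector as returned by
#'   [windowRpkm()]); all conditions must cover the same genes.
#' @param nullCondition Name of the null condition within `tables`.
#' @return A data.frame with `gene_id`, one `raw_<condition>` column per
#'   condition and one `corrected_<condition>` column per non-null
#'   condition; the null condition used is recorded in
#'   `attr(, "nullCondition")`.
#' @export
nullCorrectedOccupancy <- function(tables, nullCondition) {
  if (!is.list(tables) || is.null(names(tables)))
    stop("tables must be a named list of per-condition RPKM vectors")
  if (!nullCondition %in% names(tables))
    stop("null condition '", nullCondition, "' not among: ",
         paste(names(tables), collapse = ", "))
  ids <- names(tables[[1]])
  for (cond in names(tables)) {
    if (!setequal(names(tables[[cond]]), ids))
      stop("gene sets differ between conditions ('", cond,
           "' vs '", names(tables)[1], "')")
    tables[[cond]] <- tables[[cond]][ids]
  }
  out <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (cond in names(tables))
    out[[paste0("raw_", cond)]] <- unname(tables[[cond]])
  null <- tables[[nullCondition]]
  for (cond in setdiff(names(tables), nullCondition))
    out[[paste0("corrected_", cond)]] <- unname(tables[[cond]] - null)
  attr(out, "nullCondition") <- nullCondition
  out
}

#' Two-condition scatter table
#'
#' Extracts the corrected occupancy of two conditions as (x, y) pairs for
#' all genes — points near the y = x diagonal indicate unchanged occupancy.
#' No genes are filtered.
#'
#' @param occ Data frame from [nullCorrectedOccupancy()].
#' @param xCondition,yCondition Condition names.
#' @return A data.frame with columns `gene_id`, `x`, `y`.
#' @export
scatterTable <- function(occ, xCondition, yCondition) {
  xc <- paste0("corrected_", xCondition)
  yc <- paste0("corrected_", yCondition)
  for (col in c(xc, yc))
    if (!col %in% names(occ))
      stop("condition column missing from occupancy table: ", col)
  data.frame(gene_id = occ$gene_id, x = occ[[xc]], y = occ[[yc]],
             stringsAsFactors = FALSE)
}
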