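## Offset convention shared by anchorMatrix and windowRpkm: offset 0 is the
## anchor base itself, downstream positive along the gene's own strand.  A
## window [-up, +down) covers up + down bases; on the minus strand offset o
## maps to genomic position anchor - o, so every row reads
## upstream -> downstream left to right.

.windowPositions <- function(anchorPos, plusStrand, from, to) {
  off <- seq.int(from, to)
  if (plusStrand) anchorPos + off else anchorPos - off
}

#' Anchored genes-by-bins signal matrix
#'
#' Extracts per-base RPM signal in a strand-flipped window around the TSS or
#' TTS of every gene and averages it within fixed-width bins — the matrix
#' behind occupancy heatmaps.  Window bases beyond chromosome ends are
#' masked (`NA`) and excluded from bin means rather than counted as zero.
#'
#' @param track An RPM [CoverageTrack-class] (corrected or not).
#' @param genes A [GeneSet-class]; every gene's chromosome must be present
#'   in the track.
#' @param anchor `"TSS"` (default) or `"TTS"`.
#' @param flankUp,flankDown Window extent in bp (defaults 1500/1500, the
#'   standard +/- 1.5-kb view); each side must be divisible by `binSize`.
#' @param binSize Bin width in bp; 10 suits heatmaps, 25 metagenes.
#' @return A [SignalMatrix-class] in the gene order of `genes`.
#' @export
anchorMatrix <- function(track, genes, anchor = c("TSS", "TTS"),
                         flankUp = 1500L, flankDown = 1500L, binSize = 10L) {
  anchor <- match.arg(anchor)
  stopifnot(is(track, "CoverageTrack"), is(genes, "GeneSet"))
  if (trackUnits(track) != "RPM")
    stop("anchorMatrix expects a spike-in normalized (RPM) track")
  flankUp <- as.integer(flankUp); flankDown <- as.integer(flankDown)
  binSize <- as.integer(binSize)
  if (flankUp %% binSize != 0 || flankDown %% binSize != 0)
    stop("flankUp and flankDown must each be divisible by binSize")
  sig <- trackSignal(track)
  gr <- geneRanges(genes)
  chroms <- unique(as.character(seqnames(gr)))
  missing <- setdiff(chroms, names(sig))
  if (length(missing))
    stop("gene(s) on chromosome(s) absent from track: ",
         paste(missing, collapse = ", "))
  anchors <- anchorPositions(genes, anchor)
  pos <- start(anchors)
  plus <- as.character(strand(anchors)) == "+"
  chrom <- as.character(seqnames(anchors))
  span <- flankUp + flankDown
  vals <- matrix(NA_real_, nrow = length(gr), ncol = span,
                 dimnames = list(names(gr), NULL))
  decoded <- lapply(sig[chroms], as.numeric)
  for (i in seq_along(gr)) {
    p <- .windowPositions(pos[i], plus[i], -flankUp, flankDown - 1L)
    v <- decoded[[chrom[i]]]
    ok <- p >= 1L & p <= length(v)
    row <- rep(NA_real_, span)
    row[ok] <- v[p[ok]]
    vals[i, ] <- row
  }
  binned <- .binMeans(vals, binSize)
  colnames(binned) <- -flankUp + (seq_len(ncol(binned)) - 0.5) * binSize
  new("SignalMatrix", anchor = anchor, flankUp = flankUp,
      flankDown = flankDown, binSize = binSize, values = binned,
      rowOrder = "input", groups = character())
}

## bin means over columns, NA-masked bases excluded; all-NA bins stay NA
.binMeans <- function(m, binSize) {
  nb <- ncol(m) %/% binSize
  idx <- rep(seq_len(nb), each = binSize)
  sums <- t(rowsum(t(ifelse(is.na(m), 0, m)), idx))
  cnts <- t(rowsum(t(!is.na(m)) + 0, idx))
  out <- sums / cnts          # 0/0 -> NaN for fully masked bins
  out[cnts == 0] <- NA_real_
  rownames(out) <- rownames(m)
  out
}

#' Sort matrix rows by descending gene length
#'
#' Reorders rows the way length-sorted occupancy heatmaps are drawn: longest
#' gene on top, ties broken by gene id.  Idempotent.
#'
#' @param m A [SignalMatrix-class].
#' @param genes The [GeneSet-class] the matrix was built from.
#' @return The reordered [SignalMatrix-class] (`rowOrder` = "length_desc").
#' @export
sortRowsByLength <- function(m, genes) {
  stopifnot(is(m, "SignalMatrix"), is(genes, "GeneSet"))
  ids <- rownames(signalValues(m))
  w <- geneLengths(genes)
  missing <- setdiff(ids, names(w))
  if (length(missing))
    stop("matrix row(s) absent from GeneSet: ", paste(missing, collapse = ", "))
  ord <- order(-w[ids], ids)
  out <- m
  out@values <- m@values[ord, , drop = FALSE]
  out@rowOrder <- "length_desc"
  out
}

#' Group-averaged metagene profiles
#'
#' Per-bin arithmetic mean of matrix rows within each group — the metagene
#' curve.  Masked cells are excluded from the means.
#'
#' @param m A [SignalMatrix-class].
#' @param groups Optional named vector gene id -> group label; `NULL`
#'   averages all rows as one group `"all"`.  Genes labelled but absent
#'   from the matrix are an error; empty groups are an error.
#' @return A data.frame with columns `label`, `offset` (bin center, bp
#'   relative to the anchor) and `mean` (RPM).
#' @export
metagene <- function(m, groups = NULL) {
  stopifnot(is(m, "SignalMatrix"))
  vals <- signalValues(m)
  if (is.null(groups))
    groups <- stats::setNames(rep("all", nrow(vals)), rownames(vals))
  labs <- unique(groups)
  missing <- setdiff(names(groups), rownames(vals))
  if (length(missing))
    stop("grouped gene(s) without a matrix row: ",
         paste(missing, collapse = ", "))
  off <- binOffsets(m)
  out <- lapply(labs, function(lb) {
    rows <- names(groups)[groups == lb]
    if (!length(rows)) stop("empty metagene group: '", lb, "'")
    data.frame(label = lb, offset = off,
               mean = colMeans(vals[rows, , drop = FALSE], na.rm = TRUE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expression-tier heatmaps
#'
#' Builds one anchored [SignalMatrix-class] per expression tier
#' (high / medium / low), the occupancy-vs-transcription view.
#'
#' @param track,genes,anchor,flankUp,flankDown,binSize As [anchorMatrix()].
#' @param tiers Named vector gene id -> tier from [classifyByExpression()].
#' @return Named list of three [SignalMatrix-class] objects.
#' @export
tieredHeatmaps <- function(track, genes, tiers, anchor = "TSS",
                           flankUp = 1500L, flankDown = 1500L,
                           binSize = 10L) {
  stopifnot(is(genes, "GeneSet"))
  full <- anchorMatrix(track, genes, anchor = anchor, flankUp = flankUp,
                       flankDown = flankDown, binSize = binSize)
  vals <- signalValues(full)
  out <- lapply(c(high = "high", medium = "medium", low = "low"),
                function(tier) {
    ids <- names(tiers)[tiers == tier]
    ids <- intersect(rownames(vals), ids)
    if (!length(ids)) stop("no genes in expression tier '", tier, "'")
    sub <- full
    sub@values <- vals[ids, , drop = FALSE]
    sub@groups <- stats::setNames(rep(tier, length(ids)), ids)
    sub
  })
  out
}

#' Write a SignalMatrix as TSV plus JSON sidecar
#'
#' The TSV has a `gene_id` column followed by one column per bin (header:
#' bin-center offsets); the sidecar records anchor, flanks, bin size, row
#' order and groups so the matrix is self-describing.
#'
#' @param m A [SignalMatrix-class].
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
writeSignalMatrix <- function(m, path) {
  vals <- signalValues(m)
  df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(anchor = m@anchor, flank_up = m@flankUp,
               flank_down = m@flankDown, bin_size = m@binSize,
               row_order = m@rowOrder,
               groups = if (length(m@groups)) as.list(m@groups) else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Write metagene profiles as TSV
#'
#' @param profiles Data frame from [metagene()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMetagene <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
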