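#' Load a gene annotation into a GeneSet
#'
#' Reads gene intervals from BED6 or GFF3.  BED coordinates (0-based,
#' half-open) are converted to the internal 1-based closed convention on
#' import; GFF3 coordinates are used as-is.  Only `gene`-type features are
#' taken from GFF3.  Every record must carry a `+`/`-` strand and a unique
#' identifier (BED name field; GFF3 `ID` or `Name` attribute).
#'
#' @param path Path to the annotation file.
#' @param format `"BED6"` or `"GFF3"`.
#' @return A [GeneSet-class].
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chrI\t1000\t2000\tgeneA\t0\t+",
#'              "chrI\t5000\t6500\tgeneB\t0\t-"), bed)
#' gs <- loadGenes(bed, format = "BED6")
#' geneLengths(gs)
loadGenes <- function(path, format = c("BED6", "GFF3")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("annotation file not found: ", path)
  gr <- if (format == "BED6") .parseBed6(path) else .parseGff3Genes(path)
  ids <- names(gr)
  if (anyDuplicated(ids))
    stop("duplicate gene_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  st <- as.character(strand(gr))
  bad <- which(!st %in% c("+", "-"))
  if (length(bad))
    stop("gene(s) without '+'/'-' strand: ",
         paste(ids[bad], collapse = ", "))
  new("GeneSet", genes = gr,
      provenance = sprintf("%s (%s, %d genes)", basename(path), format,
                           length(gr)))
}

## BED parsed line by line so malformed input can be reported with its line
## number; rtracklayer's importer aborts without one.
.parseBed6 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)|^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("malformed BED6 line ", lineno[which(nf < 6)[1]],
         ": fewer than 6 fields")
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start0 <- suppressWarnings(as.integer(m[, 2]))
  end0 <- suppressWarnings(as.integer(m[, 3]))
  badnum <- which(is.na(start0) | is.na(end0))
  if (length(badnum))
    stop("malformed BED6 line ", lineno[badnum[1]],
         ": non-numeric coordinates")
  badint <- which(start0 >= end0)
  if (length(badint))
    stop("malformed BED6 line ", lineno[badint[1]], ": start >= end")
  gr <- GRanges(m[, 1], IRanges(start0 + 1L, end0), strand = m[, 6])
  names(gr) <- m[, 4]
  gr
}

.parseGff3Genes <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  gff <- gff[!is.na(gff$type) & as.character(gff$type) == "gene"]
  if (!length(gff)) stop("no 'gene' features in ", path)
  ids <- as.character(gff$ID)
  if (all(is.na(ids)) && !is.null(gff$Name)) ids <- as.character(gff$Name)
  if (anyNA(ids)) stop("GFF3 gene feature(s) without ID attribute")
  gr <- granges(gff)
  names(gr) <- ids
  gr
}

#' Classify genes into length classes
#'
#' Assigns each gene to a length class using half-open `[lower, upper)`
#' boundaries: with the default boundaries a 749-bp gene is `XS`, a 750-bp
#' gene is `S`, and genes of 3750 bp or more get the `OVER` label.  `OVER`
#' genes stay in the gene set (whole-genome heatmaps use all genes) but are
#' conventionally excluded from five-class metagene averages.
#'
#' @param gs A [GeneSet-class] (must be non-empty).
#' @param boundaries Strictly increasing class boundaries in bp.  The
#'   default `c(750, 1500, 2250, 3000, 3750)` reproduces the five standard
#'   yeast gene-length classes XS/S/M/L/XL.
#' @param labels Class labels, one per boundary.
#' @return Named character vector gene id -> class label (factor levels
#'   `labels` then `"OVER"`).
#' @export
#' @examples
#' gs <- exampleGeneSet()
#' table(classifyByLength(gs))
classifyByLength <- function(gs,
                             boundaries = c(750, 1500, 2250, 3000, 3750),
                             labels = c("XS", "S", "M", "L", "XL")) {
  stopifnot(is(gs, "GeneSet"))
  if (!length(gs@genes)) stop("empty GeneSet")
  if (any(diff(boundaries) <= 0) || any(boundaries <= 0))
    stop("boundaries must be positive and strictly increasing")
  if (length(labels) != length(boundaries))
    stop("need exactly one label per boundary")
  w <- geneLengths(gs)
  idx <- findInterval(w, boundaries) + 1L  # length < b[1] -> 1
  lab <- c(labels, "OVER")[idx]
  names(lab) <- names(w)
  lab
}

#' Classify genes into expression tertiles
#'
#' Ranks genes by expression (RPKM, descending) and splits them into
#' `high`, `medium` and `low` tiers of sizes `floor(n/3)`, `floor(n/3)` and
#' the remainder — for the standard 6020 yeast protein-coding genes this
#' yields 2006 / 2006 / 2008.  Ties in RPKM are broken by gene id
#' (lexicographic), so the assignment is deterministic.
#'
#' @param gs A [GeneSet-class].
#' @param rpkm Named numeric vector of per-gene expression values; every
#'   gene in `gs` must be present.
#' @return Named character vector gene id -> tier (`high`/`medium`/`low`),
#'   in the gene order of `gs`.
#' @export
#' @examples
#' gs <- exampleGeneSet()
#' rpkm <- setNames(seq_along(geneIds(gs)), geneIds(gs))
#' table(classifyByExpression(gs, rpkm))
classifyByExpression <- function(gs, rpkm) {
  stopifnot(is(gs, "GeneSet"))
  ids <- geneIds(gs)
  if (!length(ids)) stop("empty GeneSet")
  missing <- setdiff(ids, names(rpkm))
  if (length(missing))
    stop("missing rpkm for gene(s): ", paste(missing, collapse = ", "))
  vals <- rpkm[ids]
  if (any(vals < 0, na.rm = TRUE) || anyNA(vals))
    stop("rpkm values must be nonnegative and non-missing")
  ord <- order(-vals, ids)
  n <- length(ids)
  k <- n %/% 3L
  tier <- rep(c("high", "medium", "low"), c(k, k, n - 2L * k))
  out <- character(n)
  out[ord] <- tier
  names(out) <- ids
  out
}

#' Strand-aware anchor coordinates
#'
#' The TSS of a plus-strand gene is its lowest coordinate and its TTS the
#' highest; on the minus strand the two are swapped.  Flipping a gene's
#' strand therefore exchanges its anchors exactly.
#'
#' @param gs A [GeneSet-class].
#' @param anchor `"TSS"` or `"TTS"`.
#' @return A width-1 `GRanges`, named by gene id, at the anchor base.
#' @export
#' @examples
#' anchorPositions(exampleGeneSet(), "TSS")
anchorPositions <- function(gs, anchor = c("TSS", "TTS")) {
  anchor <- match.arg(anchor)
  stopifnot(is(gs, "GeneSet"))
  gr <- gs@genes
  plus <- as.character(strand(gr)) == "+"
  pos <- if (anchor == "TSS") ifelse(plus, start(gr), end(gr))
         else ifelse(plus, end(gr), start(gr))
  out <- GRanges(seqnames(gr), IRanges(pos, pos), strand = strand(gr),
                 seqinfo = seqinfo(gr))
  names(out) <- names(gr)
  out
}

#' Write a gene classification table
#'
#' Emits a TSV with columns gene_id, chrom, start, end, strand, length,
#' length_class and (when supplied) expression_tier.  Coordinates are
#' written in the BED convention (0-based half-open), matching the input
#' most annotation files arrive in.
#'
#' @param gs A [GeneSet-class].
#' @param path Output file path.
#' @param lengthClass,expressionTier Optional named vectors as returned by
#'   [classifyByLength()] / [classifyByExpression()].
#' @return Invisibly, the written data.frame.
#' @export
writeGeneTable <- function(gs, path, lengthClass = NULL,
                           expressionTier = NULL) {
  gr <- gs@genes
  df <- data.frame(gene_id = names(gr),
                   chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   strand = as.character(strand(gr)),
                   length = width(gr), stringsAsFactors = FALSE)
  if (!is.null(lengthClass)) df$length_class <- unname(lengthClass[df$gene_id])
  if (!is.null(expressionTier))
    df$expression_tier <- unname(expressionTier[df$gene_id])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
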