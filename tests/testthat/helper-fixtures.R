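# In-code fixture builders shared across test files.

library(GenomicRanges)

make_gene_set <- function(df, chromSizes = NULL) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  names(gr) <- df$gene_id
  if (!is.null(chromSizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
    GenomeInfoDb::seqlengths(gr) <- unname(chromSizes)
  }
  new("GeneSet", genes = gr, provenance = "test fixture")
}

make_read_set <- function(df, spikein = 0L, sampleId = "test",
                          condition = "test", replicate = 1L) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                strand = if ("strand" %in% names(df)) df$strand else "+")
  new("ReadSet", sampleId = sampleId, condition = condition,
      replicate = as.integer(replicate), reads = gr,
      spikeinReads = as.integer(spikein), experimentReads = length(gr))
}

make_track <- function(vecs, units = "RPM", sampleId = "track") {
  new("CoverageTrack", sampleId = sampleId,
      signal = as(lapply(vecs, S4Vectors::Rle), "RleList"),
      units = units, scaleFactor = 1)
}

random_reads <- function(n, chromSizes, readLen = 51, seed = 1) {
  set.seed(seed)
  chrom <- sample(names(chromSizes), n, replace = TRUE)
  start <- sapply(chromSizes[chrom], function(L)
    sample.int(max(L - readLen + 1, 1), 1))
  data.frame(chrom = chrom, start = start, end = start + readLen - 1,
             stringsAsFactors = FALSE)
}

track_vectors <- function(track)
  lapply(as.list(trackSignal(track)), as.numeric)

# cached simulated study design; built once per test run
suite_cache <- new.env()
get_suite <- function() {
  if (is.null(suite_cache$suite))
    suite_cache$suite <- conditionSuite(seed = 1)
  suite_cache$suite
}
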