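# Independent brute-force oracles: plain loops over base vectors and read
# tables, sharing no code with the package internals.

# reads: data.frame(chrom, start, end) 1-based closed
oracle_coverage <- function(reads, chromSizes) {
  out <- lapply(chromSizes, function(n) numeric(n))
  for (i in seq_len(nrow(reads))) {
    n <- chromSizes[[reads$chrom[i]]]
    for (p in seq(reads$start[i], reads$end[i]))
      if (p >= 1 && p <= n) out[[reads$chrom[i]]][p] <-
          out[[reads$chrom[i]]][p] + 1
  }
  out
}

# genes: data.frame(gene_id, chrom, start, end, strand) 1-based closed
oracle_anchor_pos <- function(g, anchor) {
  if (anchor == "TSS") { if (g$strand == "+") g$start else g$end }
  else { if (g$strand == "+") g$end else g$start }
}

# per-base window values, NA outside chromosome; offsets -fu .. fd-1
oracle_window_values <- function(trackVecs, g, anchor, fu, fd) {
  a <- oracle_anchor_pos(g, anchor)
  v <- trackVecs[[g$chrom]]
  vals <- numeric(0)
  for (off in seq(-fu, fd - 1)) {
    p <- if (g$strand == "+") a + off else a - off
    vals <- c(vals, if (p >= 1 && p <= length(v)) v[p] else NA_real_)
  }
  vals
}

oracle_anchor_matrix <- function(trackVecs, genes, anchor, fu, fd, bin) {
  nb <- (fu + fd) / bin
  m <- matrix(NA_real_, nrow(genes), nb, dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    vals <- oracle_window_values(trackVecs, genes[i, ], anchor, fu, fd)
    for (j in seq_len(nb)) {
      chunk <- vals[((j - 1) * bin + 1):(j * bin)]
      m[i, j] <- if (all(is.na(chunk))) NA_real_ else mean(chunk, na.rm = TRUE)
    }
  }
  m
}

oracle_metagene <- function(mat, ids) {
  apply(mat[ids, , drop = FALSE], 2, function(col)
    mean(col, na.rm = TRUE))
}

# count reads with >= 1 bp overlap of [wlo, whi]
oracle_window_count <- function(reads, chrom, wlo, whi) {
  n <- 0L
  for (i in seq_len(nrow(reads)))
    if (reads$chrom[i] == chrom && reads$start[i] <= whi &&
        reads$end[i] >= wlo) n <- n + 1L
  n
}
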