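#' Construct an occupancy model
#'
#' Convenience constructor for [OccupancyModel-class].  For `mixture`,
#' supply component models (their own `backgroundRate` is ignored; only the
#' top-level rate adds genome-wide background) and `weights` summing to 1.
#'
#' @param shape One of `"uniform_gene_body"`, `"tss_peak"`, `"tts_peak"`,
#'   `"mixture"`, `"background_only"`.
#' @param amplitude Expected relative reads per gene (per kb of gene body
#'   for the uniform shape); forced to 0 for `background_only`.
#' @param peakOffset Gaussian peak center, bp downstream of the anchor
#'   (strand-aware).
#' @param peakWidth Gaussian placement-kernel standard deviation in bp.
#' @param backgroundRate Relative reads per kb of experiment genome.
#' @param tierMultipliers Named `(high, medium, low)` amplitude multipliers.
#' @param components,weights Mixture components and their weights.
#' @return An [OccupancyModel-class].
#' @export
#' @examples
#' occupancyModel("tss_peak", peakOffset = 100, peakWidth = 150)
occupancyModel <- function(shape, amplitude = 1, peakOffset = 100,
                           peakWidth = 150, backgroundRate = 0.02,
                           tierMultipliers = c(high = 1, medium = 1, low = 1),
                           components = list(), weights = numeric()) {
  if (identical(shape, "background_only")) amplitude <- 0
  new("OccupancyModel", shape = shape, amplitude = amplitude,
      peakOffset = peakOffset, peakWidth = peakWidth,
      backgroundRate = backgroundRate, tierMultipliers = tierMultipliers,
      components = components, weights = weights)
}

#' Declare a synthetic two-genome chromosome set
#'
#' Experiment chromosomes are named `chrS1, chrS2, ...`; spike-in
#' chromosomes carry the configured prefix, keeping the two genomes
#' disjoint by name (the same convention used when mapping reads against a
#' concatenated experiment + spike-in reference).
#'
#' @param nChroms,chromLength Experiment chromosomes and their length (bp).
#' @param spikeinChroms,spikeinLength Spike-in chromosomes and length.
#' @param spikeinPrefix Name prefix for spike-in chromosomes.
#' @return Named integer vector of chromosome lengths (both genomes).
#' @export
#' @examples
#' makeGenome(2, 200000, 1)
makeGenome <- function(nChroms = 2L, chromLength = 200000L,
                       spikeinChroms = 1L, spikeinLength = chromLength,
                       spikeinPrefix = "spikein_") {
  if (nChroms < 1 || chromLength < 1 || spikeinChroms < 0)
    stop("chromosome counts and lengths must be positive")
  sizes <- c(rep(as.integer(chromLength), nChroms),
             rep(as.integer(spikeinLength), spikeinChroms))
  names(sizes) <- c(paste0("chrS", seq_len(nChroms)),
                    if (spikeinChroms > 0)
                      paste0(spikeinPrefix, seq_len(spikeinChroms)))
  sizes
}

#' Simulate a strand-mixed gene annotation
#'
#' Places `n` non-overlapping genes on the experiment chromosomes with at
#' least `minGap` bp between neighbours.  Gene lengths are drawn uniformly
#' within length classes cycled over all five standard classes (XS..XL, with
#' a 300-bp minimum), so every class is populated whenever `n >= 5`.
#' Strands are independent coin flips.
#'
#' @param chromSizes Chromosome declaration from [makeGenome()] (spike-in
#'   chromosomes, recognized by `spikeinPrefix`, are skipped).
#' @param n Number of genes.
#' @param minGap Minimum intergenic gap in bp.
#' @param strandProb Probability of the `+` strand.
#' @param spikeinPrefix Spike-in chromosome name prefix.
#' @param seed Integer seed; identical inputs regenerate identical genes.
#' @return A [GeneSet-class].
#' @export
makeGenes <- function(chromSizes, n = 120L, minGap = 100L,
                      strandProb = 0.5, spikeinPrefix = "spikein_",
                      seed = 1L) {
  set.seed(seed)
  expSizes <- chromSizes[!startsWith(names(chromSizes), spikeinPrefix)]
  if (!length(expSizes)) stop("no experiment chromosomes declared")
  classLo <- c(300L, 750L, 1500L, 2250L, 3000L)
  classHi <- c(749L, 1499L, 2249L, 2999L, 3749L)
  cls <- sample(rep_len(seq_len(5L), n))
  lens <- classLo[cls] + floor(stats::runif(n) * (classHi[cls] - classLo[cls] + 1))
  # greedy chromosome assignment by remaining free space
  free <- as.numeric(expSizes) - minGap
  chromOf <- integer(n)
  for (i in order(-lens)) {
    need <- lens[i] + minGap
    fits <- which(free >= need)
    if (!length(fits))
      stop("genome too small for ", n, " genes with minGap ", minGap)
    pick <- fits[sample.int(length(fits), 1, prob = free[fits])]
    chromOf[i] <- pick
    free[pick] <- free[pick] - need
  }
  chromNames <- names(expSizes)
  out <- vector("list", length(expSizes))
  for (ci in seq_along(expSizes)) {
    idx <- which(chromOf == ci)
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    k <- length(idx)
    slack <- as.numeric(expSizes[ci]) - sum(lens[idx]) - minGap * (k + 1)
    parts <- floor(diff(c(0, sort(stats::runif(k)), 1)) * slack)
    starts <- minGap + 1L + parts[1] +
      c(0, cumsum(lens[idx[-k]] + minGap + parts[-c(1, k + 1)]))[seq_len(k)]
    out[[ci]] <- GRanges(chromNames[ci],
                         IRanges(as.integer(starts),
                                 width = lens[idx]),
                         strand = ifelse(stats::runif(k) < strandProb,
                                         "+", "-"))
    names(out[[ci]]) <- sprintf("gene%04d", idx)
  }
  gr <- suppressWarnings(do.call(c, out[!vapply(out, is.null, logical(1))]))
  gr <- gr[order(names(gr))]
  GenomeInfoDb::seqlevels(gr) <- names(expSizes)
  GenomeInfoDb::seqlengths(gr) <- unname(expSizes)
  new("GeneSet", genes = gr,
      provenance = sprintf("simulated (n=%d, seed=%d)", n, seed))
}

## Relative per-gene read mass under a model component.
.geneWeights <- function(model, genes, tiers = NULL) {
  w <- geneLengths(genes)
  mult <- rep(1, length(w))
  if (!is.null(tiers)) {
    tm <- model@tierMultipliers
    mult <- unname(tm[tiers[names(w)]])
  }
  switch(model@shape,
    uniform_gene_body = model@amplitude * mult * as.numeric(w) / 1000,
    tss_peak = ,
    tts_peak = model@amplitude * mult + 0 * as.numeric(w),
    background_only = rep(0, length(w)),
    mixture = stop(".geneWeights is per-component"))
}

.drawPositions <- function(model, genes, geneIdx) {
  gr <- geneRanges(genes)[geneIdx]
  n <- length(geneIdx)
  if (model@shape == "uniform_gene_body")
    return(start(gr) + floor(stats::runif(n) * width(gr)))
  anchor <- if (model@shape == "tss_peak") "TSS" else "TTS"
  plus <- as.character(strand(gr)) == "+"
  apos <- if (anchor == "TSS") ifelse(plus, start(gr), end(gr))
          else ifelse(plus, end(gr), start(gr))
  off <- round(stats::rnorm(n, model@peakOffset, model@peakWidth))
  ifelse(plus, apos + off, apos - off)
}

#' Simulate aligned single-end reads under an occupancy landscape
#'
#' Draws each read's 5' position from the model landscape — uniform over
#' the gene body, a Gaussian kernel at the anchor for peak shapes, uniform
#' genome-wide for background — then extends it `readLen` bp downstream on
#' a randomly assigned strand (ChIP signal is strand-symmetric).  A
#' binomial fraction of reads is placed uniformly on the spike-in
#' chromosomes instead, emulating the foreign-chromatin spike.  Everything
#' is determined by `(arguments, seed)`.
#'
#' @param genes A [GeneSet-class] (typically from [makeGenes()]).
#' @param model An [OccupancyModel-class].
#' @param chromSizes Both-genome declaration from [makeGenome()].
#' @param nReads Total reads to emit (experiment + spike-in).
#' @param readLen Read length in bp (default 51, typical short single-end
#'   sequencing).
#' @param spikeinFraction Probability a read derives from spike-in
#'   chromatin; in `[0, 1)`.
#' @param tiers Optional expression tiers (gene id -> tier) activating the
#'   model's `tierMultipliers`.
#' @param sampleId,condition,replicate Metadata for the resulting
#'   [ReadSet-class].
#' @param spikeinPrefix Spike-in chromosome name prefix.
#' @param seed Integer seed.
#' @return A list: `reads` (a [ReadSet-class] of experiment reads plus the
#'   spike-in count), `spikeinRanges` (`GRanges` of the simulated spike-in
#'   reads, for writing complete SAM/BED files), and `truth` (planted
#'   parameters: per-gene expected read counts, component weights, counts,
#'   seed).
#' @export
simulateReads <- function(genes, model, chromSizes, nReads = 200000L,
                          readLen = 51L, spikeinFraction = 0.1,
                          tiers = NULL, sampleId = "sim",
                          condition = sampleId, replicate = 1L,
                          spikeinPrefix = "spikein_", seed = 1L) {
  stopifnot(is(genes, "GeneSet"), is(model, "OccupancyModel"))
  if (spikeinFraction < 0 || spikeinFraction >= 1)
    stop("spikeinFraction must be in [0, 1)")
  set.seed(seed)
  spikeSizes <- chromSizes[startsWith(names(chromSizes), spikeinPrefix)]
  expSizes <- chromSizes[!startsWith(names(chromSizes), spikeinPrefix)]
  if (spikeinFraction > 0 && !length(spikeSizes))
    stop("spikeinFraction > 0 but no spike-in chromosomes declared")

  nSpike <- if (spikeinFraction > 0)
    stats::rbinom(1, nReads, spikeinFraction) else 0L
  nExp <- nReads - nSpike

  comps <- if (model@shape == "mixture") model@components else list(model)
  compW <- if (model@shape == "mixture") model@weights else 1
  gw <- lapply(comps, function(cm) {
    cm@tierMultipliers <- model@tierMultipliers  # tiers act at top level
    .geneWeights(cm, genes, tiers)
  })
  compMass <- compW * vapply(gw, sum, numeric(1))
  bgMass <- model@backgroundRate * sum(as.numeric(expSizes)) / 1000
  total <- sum(compMass) + bgMass
  if (total <= 0) stop("occupancy landscape has zero total mass")

  origin <- sample.int(length(comps) + 1L, nExp, replace = TRUE,
                       prob = c(compMass, bgMass))
  chrom <- character(nExp)
  pos <- integer(nExp)
  expected <- rep(0, length(geneIds(genes)))
  names(expected) <- geneIds(genes)
  for (k in seq_along(comps)) {
    take <- which(origin == k)
    expected <- expected + nExp * compW[k] * gw[[k]] / total
    if (!length(take)) next
    gi <- sample.int(length(gw[[k]]), length(take), replace = TRUE,
                     prob = gw[[k]])
    chrom[take] <- as.character(seqnames(geneRanges(genes)))[gi]
    pos[take] <- .drawPositions(comps[[k]], genes, gi)
  }
  bg <- which(origin == length(comps) + 1L)
  if (length(bg)) {
    ci <- sample.int(length(expSizes), length(bg), replace = TRUE,
                     prob = as.numeric(expSizes))
    chrom[bg] <- names(expSizes)[ci]
    pos[bg] <- 1L + floor(stats::runif(length(bg)) * expSizes[ci])
  }
  pos <- pmin(pmax(pos, 1L), unname(expSizes[chrom]))
  st <- ifelse(stats::runif(nExp) < 0.5, "+", "-")
  lo <- ifelse(st == "+", pos, pos - readLen + 1L)
  hi <- ifelse(st == "+", pos + readLen - 1L, pos)
  lo <- pmax(lo, 1L)
  hi <- pmin(hi, unname(expSizes[chrom]))
  gr <- GRanges(chrom, IRanges(as.integer(lo), as.integer(hi)), strand = st)
  GenomeInfoDb::seqlevels(gr) <- names(expSizes)
  GenomeInfoDb::seqlengths(gr) <- unname(expSizes)

  spikeGr <- GRanges()
  if (nSpike > 0) {
    ci <- sample.int(length(spikeSizes), nSpike, replace = TRUE,
                     prob = as.numeric(spikeSizes))
    sp <- 1L + floor(stats::runif(nSpike) * (spikeSizes[ci] - readLen))
    spikeGr <- GRanges(names(spikeSizes)[ci],
                       IRanges(as.integer(sp), width = readLen),
                       strand = ifelse(stats::runif(nSpike) < 0.5, "+", "-"))
  }
  rs <- new("ReadSet", sampleId = sampleId, condition = condition,
            replicate = as.integer(replicate), reads = gr,
            spikeinReads = as.integer(nSpike),
            experimentReads = length(gr))
  truth <- list(seed = seed, shape = model@shape,
                n_reads = nReads, n_spikein = nSpike,
                spikein_fraction = spikeinFraction,
                background_mass = bgMass,
                component_weights = as.numeric(compW),
                peak_offset = model@peakOffset,
                peak_width = model@peakWidth,
                expected_gene_reads = as.list(expected))
  list(reads = rs, spikeinRanges = spikeGr, truth = truth)
}

#' Simulate the full multi-condition study design
#'
#' Generates one shared genome, gene annotation and expression tiering, then
#' simulates the occupancy landscapes of a Rad6/Set1/Swd2-style ChIP-seq
#' design: a uniformly gene-body-bound ubiquitin ligase, a TSS-peaked
#' methylation mark with expression-tier-ordered amplitude, a wild-type
#' Swd2-like factor with both TSS and TTS peaks, a `set1`-deletion Swd2
#' landscape in which the 5' peak is lost and the 3' (TTS) peak intensified,
#' a `rad6`-deletion Swd2 landscape with chromatin binding lost entirely
#' (background only), and a single no-tag control.  Signal IPs carry a 10%
#' spike-in read fraction; in background-only IPs nothing is enriched, so
#' spike-in reads make up a far larger share of the library (45% here).
#'
#' @param seed Integer master seed; per-sample seeds are derived from it.
#' @param nReads Reads per sample.
#' @param nGenes,nChroms,chromLength Annotation/genome scale.
#' @param readLen Read length in bp.
#' @return A list with `chromSizes`, `genes` ([GeneSet-class]), `rpkm`
#'   (synthetic expression values), `tiers`, `samples` (named list of
#'   [simulateReads()] results; replicated conditions get `_rep1`/`_rep2`
#'   entries) and `design` (data.frame of planted per-sample parameters).
#' @export
conditionSuite <- function(seed = 1L, nReads = 200000L, nGenes = 120L,
                           nChroms = 2L, chromLength = 200000L,
                           readLen = 51L) {
  seed <- as.integer(seed)
  chromSizes <- makeGenome(nChroms, chromLength, spikeinChroms = 1L)
  genes <- makeGenes(chromSizes, n = nGenes, seed = seed)
  set.seed(seed + 1L)
  rpkm <- stats::setNames(stats::rlnorm(nGenes, meanlog = 3, sdlog = 1),
                          geneIds(genes))
  tiers <- classifyByExpression(genes, rpkm)

  tss <- occupancyModel("tss_peak", peakOffset = 100, peakWidth = 150,
                        backgroundRate = 0)
  tts <- occupancyModel("tts_peak", peakOffset = 0, peakWidth = 150,
                        backgroundRate = 0)
  models <- list(
    rad6_uniform = occupancyModel("uniform_gene_body",
                                  backgroundRate = 0.012),
    h3k4me3_tss = occupancyModel("tss_peak", peakOffset = 100,
                                 peakWidth = 150, backgroundRate = 0.006,
                                 tierMultipliers = c(high = 3, medium = 1,
                                                     low = 0.3)),
    wt_swd2 = occupancyModel("mixture", backgroundRate = 0.006,
                             components = list(tss, tts),
                             weights = c(0.6, 0.4)),
    dset1_swd2 = occupancyModel("tts_peak", peakOffset = 0,
                                peakWidth = 150, backgroundRate = 0.006),
    drad6_swd2 = occupancyModel("background_only", backgroundRate = 1),
    notag = occupancyModel("background_only", backgroundRate = 1))
  spikeFrac <- c(rad6_uniform = 0.10, h3k4me3_tss = 0.10, wt_swd2 = 0.10,
                 dset1_swd2 = 0.10, drad6_swd2 = 0.45, notag = 0.45)
  nRep <- c(rad6_uniform = 2L, h3k4me3_tss = 2L, wt_swd2 = 2L,
            dset1_swd2 = 2L, drad6_swd2 = 2L, notag = 1L)

  samples <- list()
  design <- list()
  k <- 0L
  for (cond in names(models)) {
    useTiers <- if (cond == "h3k4me3_tss") tiers else NULL
    for (rep in seq_len(nRep[[cond]])) {
      k <- k + 1L
      id <- if (nRep[[cond]] > 1) sprintf("%s_rep%d", cond, rep) else cond
      samples[[id]] <- simulateReads(genes, models[[cond]], chromSizes,
                                     nReads = nReads, readLen = readLen,
                                     spikeinFraction = spikeFrac[[cond]],
                                     tiers = useTiers, sampleId = id,
                                     condition = cond, replicate = rep,
                                     seed = seed + 100L + k)
      design[[id]] <- data.frame(sample = id, condition = cond,
                                 replicate = rep,
                                 shape = models[[cond]]@shape,
                                 spikein_fraction = spikeFrac[[cond]],
                                 stringsAsFactors = FALSE)
    }
  }
  list(chromSizes = chromSizes, genes = genes, rpkm = rpkm, tiers = tiers,
       samples = samples, design = do.call(rbind, design))
}
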