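test_that("genome declarations name both genomes and validate inputs", {
  cs <- makeGenome(2, 200000, 1)
  expect_equal(length(cs), 3)
  expect_named(cs, c("chrS1", "chrS2", "spikein_1"))
  expect_true(all(cs == 200000))
  expect_identical(makeGenome(2, 200000, 1), cs)
  expect_error(makeGenome(0, 200000, 1), "positive")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeChromSizes(cs, path)
  expect_identical(readChromSizes(path), cs)
})

test_that("simulated genes are non-overlapping, gapped, class-complete", {
  cs <- makeGenome(2, 200000, 1)
  gs <- makeGenes(cs, n = 100, minGap = 100, seed = 3)
  expect_equal(length(geneIds(gs)), 100)
  cls <- classifyByLength(gs)
  expect_setequal(unique(cls), c("XS", "S", "M", "L", "XL"))
  gr <- geneRanges(gs)
  for (chr in c("chrS1", "chrS2")) {
    g <- gr[as.character(seqnames(gr)) == chr]
    g <- g[order(start(g))]
    if (length(g) > 1)
      expect_true(all(start(g)[-1] - end(g)[-length(g)] - 1 >= 100))
    expect_true(all(start(g) >= 1 & end(g) <= cs[[chr]]))
  }
  # seed-fixed regeneration is identical
  gs2 <- makeGenes(cs, n = 100, minGap = 100, seed = 3)
  expect_identical(geneRanges(gs2), geneRanges(gs))
  expect_error(makeGenes(makeGenome(1, 5000, 0), n = 100), "too small")
})

test_that("read simulation is deterministic and conserves counts", {
  cs <- makeGenome(1, 50000, 1, 20000)
  gs <- makeGenes(cs, n = 20, seed = 5)
  model <- occupancyModel("uniform_gene_body", backgroundRate = 0.01)
  sim1 <- simulateReads(gs, model, cs, nReads = 5000, seed = 9)
  sim2 <- simulateReads(gs, model, cs, nReads = 5000, seed = 9)
  expect_identical(readRanges(sim1$reads), readRanges(sim2$reads))
  expect_identical(sim1$truth, sim2$truth)
  expect_equal(experimentReads(sim1$reads) + spikeinReads(sim1$reads), 5000)
  expect_equal(length(sim1$spikeinRanges), spikeinReads(sim1$reads))
})

test_that("spike-in read counts are binomial at the configured fraction", {
  cs <- makeGenome(1, 50000, 1, 20000)
  gs <- makeGenes(cs, n = 20, seed = 5)
  model <- occupancyModel("uniform_gene_body", backgroundRate = 0.01)
  sim <- simulateReads(gs, model, cs, nReads = 100000,
                       spikeinFraction = 0.1, seed = 13)
  sd4 <- 4 * sqrt(100000 * 0.1 * 0.9)
  expect_lt(abs(spikeinReads(sim$reads) - 10000), sd4)
  noSpike <- simulateReads(gs, model, cs, nReads = 1000,
                           spikeinFraction = 0, seed = 13)
  expect_equal(spikeinReads(noSpike$reads), 0)
  expect_error(simulateReads(gs, model, cs, spikeinFraction = 1),
               "spikeinFraction")
})

test_that("uniform landscapes give counts proportional to gene length", {
  cs <- makeGenome(2, 100000, 1, 20000)
  gs <- makeGenes(cs, n = 40, seed = 7)
  model <- occupancyModel("uniform_gene_body", backgroundRate = 0)
  sim <- simulateReads(gs, model, cs, nReads = 60000,
                       spikeinFraction = 0, seed = 17)
  # assign each read to the gene containing its 5' end
  gr <- readRanges(sim$reads)
  fivep <- GRanges(seqnames(gr),
                   IRanges(ifelse(as.character(strand(gr)) == "+",
                                  start(gr), end(gr)), width = 1))
  counts <- GenomicRanges::countOverlaps(geneRanges(gs), fivep)
  expected <- 60000 * geneLengths(gs) / sum(geneLengths(gs))
  chi <- sum((counts - expected)^2 / expected)
  # df = 39; far tail only under a broken generator
  expect_lt(chi, qchisq(1 - 1e-6, df = 39))
  expect_equal(unname(unlist(sim$truth$expected_gene_reads)),
               unname(expected), tolerance = 1e-9)
})

test_that("zero-mass landscapes are rejected", {
  cs <- makeGenome(1, 50000, 1, 20000)
  gs <- makeGenes(cs, n = 10, seed = 5)
  model <- occupancyModel("background_only", backgroundRate = 0)
  expect_error(simulateReads(gs, model, cs, nReads = 100, seed = 1),
               "zero total mass")
})

test_that("planted TSS peaks are recovered through the full pipeline", {
  cs <- makeGenome(2, 100000, 1, 50000)
  expCS <- cs[c("chrS1", "chrS2")]
  gs <- makeGenes(cs, n = 40, seed = 19)
  model <- occupancyModel("tss_peak", peakOffset = 100, peakWidth = 100,
                          backgroundRate = 0.005)
  sim <- simulateReads(gs, model, cs, nReads = 80000,
                       spikeinFraction = 0.1, seed = 23)
  track <- spikeinNormalizedTrack(sim$reads, expCS)
  # bin grid aligned so +100 is a bin center (see vignette)
  m <- anchorMatrix(track, gs, "TSS", 1480, 1520, 40)
  prof <- metagene(m)
  best <- prof$offset[which.max(prof$mean)]
  expect_lte(abs(best - 100), 40)
})

test_that("mixture models are validated and built as configured", {
  tss <- occupancyModel("tss_peak", backgroundRate = 0)
  tts <- occupancyModel("tts_peak", backgroundRate = 0)
  mix <- occupancyModel("mixture", components = list(tss, tts),
                        weights = c(0.6, 0.4))
  expect_s4_class(mix, "OccupancyModel")
  expect_error(occupancyModel("mixture", components = list(tss),
                              weights = 1), "components")
  expect_error(occupancyModel("mixture", components = list(tss, tts),
                              weights = c(0.9, 0.4)), "sum to 1")
  expect_error(occupancyModel("sideways_peak"), "shape")
  # background_only forces amplitude zero
  expect_equal(occupancyModel("background_only", amplitude = 5)@amplitude, 0)
})

test_that("simulated reads round-trip through SAM and BED", {
  cs <- makeGenome(1, 50000, 1, 20000)
  gs <- makeGenes(cs, n = 15, seed = 5)
  model <- occupancyModel("uniform_gene_body", backgroundRate = 0.01)
  sim <- simulateReads(gs, model, cs, nReads = 2000,
                       spikeinFraction = 0.2, seed = 29)

  sam <- withr::local_tempfile(fileext = ".sam")
  writeReadsSAM(sim, cs, sam)
  rsSam <- loadReads(sam, format = "BAM", chromSizes = cs)
  expect_equal(experimentReads(rsSam), experimentReads(sim$reads))
  expect_equal(spikeinReads(rsSam), spikeinReads(sim$reads))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeReadsBED(sim, bed)
  rsBed <- loadReads(bed, format = "BED", chromSizes = cs)
  expect_equal(experimentReads(rsBed), experimentReads(sim$reads))
  expect_equal(spikeinReads(rsBed), spikeinReads(sim$reads))
  # identical pileups from both on-disk representations
  expCS <- cs["chrS1"]
  expect_equal(track_vectors(buildCoverage(rsSam, expCS)),
               track_vectors(buildCoverage(rsBed, expCS)))

  truthPath <- withr::local_tempfile(fileext = ".json")
  writeSimTruth(sim$truth, truthPath)
  truth <- jsonlite::read_json(truthPath)
  expect_equal(truth$n_reads, 2000)
  expect_equal(truth$shape, "uniform_gene_body")
})

test_that("bedGraph round-trips an RPM track", {
  cs <- makeGenome(1, 60000, 1, 10000)
  gs <- makeGenes(cs, n = 10, seed = 5)
  model <- occupancyModel("uniform_gene_body", backgroundRate = 0.01)
  sim <- simulateReads(gs, model, cs, nReads = 3000, spikeinFraction = 0.2,
                       seed = 37)
  track <- spikeinNormalizedTrack(sim$reads, cs["chrS1"])
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeBedGraph(track, path)
  back <- readBedGraph(path, cs["chrS1"])
  expect_equal(track_vectors(back), track_vectors(track), tolerance = 1e-6)
})

test_that("the condition suite encodes the planted study design", {
  suite <- get_suite()
  expect_equal(nrow(suite$design), 11)
  expect_setequal(unique(suite$design$condition),
                  c("rad6_uniform", "h3k4me3_tss", "wt_swd2", "dset1_swd2",
                    "drad6_swd2", "notag"))
  wt <- suite$samples$wt_swd2_rep1
  expect_equal(wt$truth$shape, "mixture")
  expect_equal(wt$truth$component_weights, c(0.6, 0.4))
  expect_equal(suite$samples$drad6_swd2_rep1$truth$shape, "background_only")
  expect_equal(sum(suite$tiers == "high"), 40)
})
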