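toy_genes <- function(sizes = c(chrA = 10000L, chrB = 8000L), seed = 4,
                      n = 10) {
  set.seed(seed)
  df <- data.frame(gene_id = sprintf("g%02d", 1:n),
                   chrom = sample(names(sizes), n, replace = TRUE),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  df$start <- sapply(sizes[df$chrom], function(L) sample.int(L - 3000, 1)) +
    1500
  df$end <- df$start + sample(500:1500, n, replace = TRUE)
  df
}

random_track <- function(sizes, seed = 2) {
  set.seed(seed)
  make_track(lapply(sizes, function(L) round(runif(L) * 10)), units = "RPM")
}

test_that("a constant track yields a constant matrix in unmasked cells", {
  sizes <- c(chrA = 6000L)
  track <- make_track(list(chrA = rep(2, 6000)), units = "RPM")
  gs <- make_gene_set(data.frame(gene_id = c("p", "m"), chrom = "chrA",
                                 start = c(2500, 2600), end = c(3500, 3900),
                                 strand = c("+", "-"),
                                 stringsAsFactors = FALSE))
  m <- anchorMatrix(track, gs, "TSS", 1500, 1500, 50)
  expect_true(all(signalValues(m) == 2))
  expect_equal(dim(signalValues(m)), c(2, 60))
})

test_that("anchorMatrix requires RPM units and known chromosomes", {
  gs <- make_gene_set(data.frame(gene_id = "p", chrom = "chrZ", start = 2500,
                                 end = 3500, strand = "+",
                                 stringsAsFactors = FALSE))
  raw <- make_track(list(chrA = rep(1, 6000)), units = "raw")
  expect_error(anchorMatrix(raw, gs, "TSS", 100, 100, 10), "RPM")
  rpm <- make_track(list(chrA = rep(1, 6000)), units = "RPM")
  expect_error(anchorMatrix(rpm, gs, "TSS", 100, 100, 10), "chrZ")
  gs2 <- make_gene_set(data.frame(gene_id = "p", chrom = "chrA",
                                  start = 2500, end = 3500, strand = "+",
                                  stringsAsFactors = FALSE))
  expect_error(anchorMatrix(rpm, gs2, "TSS", 105, 100, 10), "divisible")
})

test_that("minus-strand rows are flipped so downstream reads rightward", {
  sizes <- c(chrA = 6000L)
  v <- rep(0, 6000)
  tssMinus <- 4000
  v[tssMinus - 100] <- 9   # 100 bp downstream of a minus-strand TSS
  track <- make_track(list(chrA = v), units = "RPM")
  gs <- make_gene_set(data.frame(gene_id = "m", chrom = "chrA", start = 3000,
                                 end = tssMinus, strand = "-",
                                 stringsAsFactors = FALSE))
  m <- anchorMatrix(track, gs, "TSS", 500, 500, 1)
  hit <- which(signalValues(m)["m", ] > 0)
  expect_equal(binOffsets(m)[hit], 100.5)  # bin center of offset +100
})

test_that("windows beyond chromosome ends are masked, not zero", {
  sizes <- c(chrA = 2000L)
  track <- make_track(list(chrA = rep(3, 2000)), units = "RPM")
  gs <- make_gene_set(data.frame(gene_id = "edge", chrom = "chrA",
                                 start = 100, end = 900, strand = "+",
                                 stringsAsFactors = FALSE))
  m <- anchorMatrix(track, gs, "TSS", 500, 500, 100)
  vals <- signalValues(m)["edge", ]
  expect_true(is.na(vals[1]))            # fully out-of-bounds bin
  expect_equal(unname(vals[5]), 3)       # partially masked bin keeps mean 3
  expect_true(all(vals[6:10] == 3))
})

test_that("anchored matrices match the brute-force window oracle", {
  sizes <- c(chrA = 10000L, chrB = 8000L)
  genes <- toy_genes(sizes)
  track <- random_track(sizes)
  gs <- make_gene_set(genes, sizes)
  for (anchor in c("TSS", "TTS")) {
    m <- anchorMatrix(track, gs, anchor, 1000, 1000, 50)
    oracle <- oracle_anchor_matrix(track_vectors(track), genes, anchor,
                                   1000, 1000, 50)
    expect_equal(unname(signalValues(m)), unname(oracle[genes$gene_id, ]),
                 tolerance = 1e-12)
  }
})

test_that("strand mirroring with a reflected track reproduces the matrix", {
  L <- 5000L
  set.seed(8)
  v <- round(runif(L) * 10)
  track <- make_track(list(chrA = v), units = "RPM")
  mirror <- make_track(list(chrA = rev(v)), units = "RPM")
  df <- data.frame(gene_id = "g", chrom = "chrA", start = 2000, end = 3200,
                   strand = "+", stringsAsFactors = FALSE)
  dfM <- data.frame(gene_id = "g", chrom = "chrA", start = L + 1 - 3200,
                    end = L + 1 - 2000, strand = "-",
                    stringsAsFactors = FALSE)
  m <- anchorMatrix(track, make_gene_set(df), "TSS", 800, 800, 40)
  mM <- anchorMatrix(mirror, make_gene_set(dfM), "TSS", 800, 800, 40)
  expect_equal(signalValues(m), signalValues(mM))
})

test_that("row sorting is by descending length with id tie-break", {
  sizes <- c(chrA = 10000L)
  df <- data.frame(gene_id = c("b", "a", "c"), chrom = "chrA",
                   start = c(3000, 5000, 7000), end = c(3500, 6500, 7500),
                   strand = "+", stringsAsFactors = FALSE)
  gs <- make_gene_set(df)
  track <- make_track(list(chrA = rep(1, 10000)), units = "RPM")
  m <- anchorMatrix(track, gs, "TSS", 200, 200, 100)
  s <- sortRowsByLength(m, gs)
  expect_identical(rownames(signalValues(s)), c("a", "b", "c"))
  expect_identical(s@rowOrder, "length_desc")
  expect_identical(signalValues(sortRowsByLength(s, gs)), signalValues(s))
})

test_that("metagene equals the per-group row-mean oracle", {
  sizes <- c(chrA = 10000L, chrB = 8000L)
  genes <- toy_genes(sizes)
  track <- random_track(sizes)
  gs <- make_gene_set(genes, sizes)
  m <- anchorMatrix(track, gs, "TSS", 1000, 1000, 50)
  groups <- setNames(rep(c("odd", "even"), 5), genes$gene_id)
  prof <- metagene(m, groups)
  for (lb in c("odd", "even")) {
    ids <- names(groups)[groups == lb]
    expect_equal(prof$mean[prof$label == lb],
                 unname(oracle_metagene(signalValues(m), ids)))
  }
  one <- metagene(m, setNames("solo", genes$gene_id[1]))
  expect_equal(one$mean, unname(signalValues(m)[genes$gene_id[1], ]))
  expect_error(metagene(m, setNames("x", "ghost")), "ghost")
})

test_that("metagene of constant rows is their midpoint", {
  vals <- rbind(g1 = rep(1, 10), g2 = rep(3, 10))
  colnames(vals) <- seq(-95, by = 10, length.out = 10)
  m <- new("SignalMatrix", anchor = "TSS", flankUp = 50L, flankDown = 50L,
           binSize = 10L, values = vals, rowOrder = "input",
           groups = character())
  prof <- metagene(m)
  expect_true(all(prof$mean == 2))
})

test_that("tiered heatmaps partition genes and preserve the matrix", {
  sizes <- c(chrA = 10000L, chrB = 8000L)
  genes <- toy_genes(sizes)
  gs <- make_gene_set(genes, sizes)
  track <- random_track(sizes)
  tiers <- classifyByExpression(gs, setNames(seq_len(10), genes$gene_id))
  th <- tieredHeatmaps(track, gs, tiers, flankUp = 1000, flankDown = 1000,
                       binSize = 100)
  expect_named(th, c("high", "medium", "low"))
  got <- sum(sapply(th, function(x) nrow(signalValues(x))))
  expect_equal(got, 10)
  full <- anchorMatrix(track, gs, "TSS", 1000, 1000, 100)
  for (tier in names(th)) {
    ids <- rownames(signalValues(th[[tier]]))
    expect_equal(signalValues(th[[tier]]),
                 signalValues(full)[ids, , drop = FALSE])
  }
  oneTier <- setNames(rep("high", 10), genes$gene_id)
  expect_error(tieredHeatmaps(track, gs, oneTier), "medium")
})

test_that("matrix TSV and JSON sidecar round-trip the metadata", {
  sizes <- c(chrA = 10000L)
  df <- toy_genes(c(chrA = 10000L), n = 4)
  df$chrom <- "chrA"
  gs <- make_gene_set(df)
  m <- anchorMatrix(random_track(sizes), gs, "TTS", 500, 500, 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSignalMatrix(m, path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(back$gene_id, rownames(signalValues(m)))
  expect_equal(as.numeric(names(back)[-1]), binOffsets(m))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$anchor, "TTS")
  expect_equal(meta$bin_size, 100)
})
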