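---
title: "Methods: spike-in normalized occupancy profiling with occumap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in normalized occupancy profiling with occumap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occumap)
```

# Scope and model

`occumap` quantifies protein occupancy along genes from single-end ChIP-seq
style read alignments. Its central difficulty is that immunoprecipitation
efficiency varies between samples and conditions, so read depth alone cannot
be compared across libraries. The package adopts the *spike-in* solution: a
fixed fraction of chromatin from a foreign genome is mixed into every sample
before immunoprecipitation, and every sample is rescaled so that its foreign
genome receives exactly one million reads. Global occupancy changes — which
depth normalization silently erases — then survive into the final tracks.

The pipeline, in order:

1. **Annotation** — load genes (BED6 or GFF3), classify by length and by
   ranked expression tertile, derive strand-aware TSS/TTS anchors.
2. **Coverage** — partition reads into experiment vs. spike-in chromosomes
   by name prefix, pile up the experiment reads per base, and multiply by
   the spike-in factor `1e6 / spikeinReads`.
3. **Correction** — subtract a no-tag (mock IP) track from each replicate
   track, clamping negatives to zero by default, then average replicates.
4. **Profiles** — anchor a matrix of binned signal at each gene's TSS or
   TTS, flip minus-strand rows so downstream is always to the right, and
   average columns into metagenes, optionally per group.
5. **Quantification** — count reads overlapping a fixed window around the
   anchor (default −100..+300 of the TSS), convert to RPKM, and subtract a
   null-strain baseline per gene (unclamped, so compensating errors stay
   visible in scatter plots).
6. **Simulation** — generate genomes, gene sets, and reads from parametric
   occupancy landscapes so every step can be validated against planted
   truth.

# Conventions

* **Coordinates.** All in-memory ranges are 1-based and closed, the native
  convention of `GRanges`. BED input/output is converted at the boundary
  (BED `[1000, 2000)` becomes bases 1001..2000).
* **Anchors.** The TSS of a plus-strand gene is its lowest coordinate; for
  a minus-strand gene it is the highest. TTS is the opposite end. A window
  offset of 0 is the anchor base itself and positive offsets run downstream
  *along the gene's strand*, so minus-strand windows extend toward lower
  genomic coordinates.
* **Units.** Tracks carry a `units` tag (`raw` or `RPM`). Normalization is
  applied exactly once: re-normalizing an RPM track, or subtracting tracks
  of unequal units, is an error rather than a silent double scaling.
* **Out-of-bounds bins.** Where an anchored window runs off a chromosome
  end, the affected bins are `NA` rather than zero, and metagene column
  means exclude them. Zero-filling would bias flank averages downward.

# Parameter defaults and rationale

| Parameter | Default | Rationale |
|---|---|---|
| length class boundaries | 750/1500/2250/3000/3750 | five equal 750-bp classes XS..XL; genes ≥ 3750 bp get `OVER` and are typically excluded from length-resolved plots |
| tertile split | floor(n/3), floor(n/3), remainder | deterministic; for 6020 genes gives 2006/2006/2008 (high/medium/low); ties in RPKM break by gene id |
| heatmap flanks | ±1500 bp | covers the full body of most yeast-scale genes plus flanking context |
| heatmap bin | 10 bp (profiles), 25 bp (metagenes) | fine enough to localize a ~150-bp-wide peak, coarse enough to smooth shot noise |
| quantification window | −100..+300 of TSS | captures the 5′ occupancy peak while excluding most of the body |
| read extension | none | 51-bp single-end reads are counted over their mapped span; fragment extension is available via `extendTo` but off by default |
| background subtraction | clamp at 0 | corrected tracks are occupancy estimates and negative occupancy is not interpretable; per-gene null correction is *unclamped* so systematic over-subtraction remains visible |
| order of operations | subtract, then average | each replicate is corrected against the shared no-tag control before averaging; with clamping off the two orders are identical (the tests assert this algebra), with clamping on subtract-first is the stated convention |

RPKM in the quantification module is deliberately *depth-relative*
(`count / (len/1000) / (libSize/1e6)`) and does not fold in the spike-in
factor; spike-in scaling lives in the track pipeline. Mixing the two would
apply cross-sample calibration twice.

# The simulator

`simulateReads()` draws read 5′ positions from a mixture over genes plus a
uniform background:

* Each gene gets a weight `amplitude × tierMultiplier × (shape term)`.
  For `uniform_gene_body` the shape term is `width/1000`, so counts are
  proportional to gene length; for `tss_peak`/`tts_peak` it is 1, so every
  gene receives the same expected mass at its anchor.
* Within a gene, `uniform_gene_body` draws positions uniformly over the
  body; peak shapes draw a Gaussian offset (`peakOffset`, `peakWidth`)
  around the anchor, strand-aware. `mixture` composes components with
  fixed weights; `background_only` has zero gene mass.
* Background mass is `backgroundRate` per kb of genome, drawn uniformly.
* Each read is assigned to the spike-in genome with probability
  `spikeinFraction` (binomial split), reflecting that spike-in recovery
  depends on IP efficiency: an antibody that enriches nothing returns
  mostly spike-in and background.

`conditionSuite()` wires these into an 11-sample study: a uniform-body
factor (two replicates), a 5′-peaked mark with expression-tier-scaled
amplitudes (high 3×, medium 1×, low 0.3×), a wild-type factor mixing TSS
(60%) and TTS (40%) peaks, a deletion that shifts it entirely to the TTS,
a deletion that abolishes binding (`background_only`), and a no-tag
control. Signal-bearing samples use `spikeinFraction = 0.10`; the
background-only IP and the no-tag control use 0.45, because without real
enrichment the foreign chromatin dominates what little is recovered. This
asymmetry is what makes spike-in normalization informative: after scaling,
the abolished-binding condition collapses to a few percent of wild-type
mass, which pure depth normalization could never show.

Scale choices (two 200-kb chromosomes, 120 genes, 200k reads per sample)
keep the full suite under ~10 s while leaving every planted effect several
standard deviations above noise.

# One deliberate grid choice

The suite plants its 5′ peak at +100 with a symmetric kernel. On a bin grid
whose boundaries fall at multiples of the bin size, +100 sits *on* a
boundary, so the two adjacent bins receive equal mass in expectation and
the metagene argmax is a coin flip. Peak-recovery checks therefore use
`flankUp = 1480, flankDown = 1520, bin = 40`, which centers a bin on +100
(`[80, 120)`). This is a property of discretization, not of the signal;
any analysis that compares a peak location to a fixed coordinate should
align its grid the same way.

# Worked example

```{r example, eval = FALSE}
suite <- conditionSuite(seed = 1)
expCS <- suite$chromSizes[!startsWith(names(suite$chromSizes), "spikein_")]
wt <- correctedConditionTrack(
  list(suite$samples$wt_swd2_rep1$reads, suite$samples$wt_swd2_rep2$reads),
  suite$samples$notag$reads, expCS)
m <- anchorMatrix(wt, suite$genes, "TSS", 1500, 1500, 25)
head(metagene(m, classifyByLength(suite$genes)))
```

# Limitations

* Single-end reads only; no paired-end fragment reconstruction.
* No duplicate marking or mapping-quality filtering — inputs are assumed
  pre-filtered.
* Overlapping genes are not disambiguated: a read in an overlap counts for
  both windows.
* The simulator plants occupancy landscapes, not sequences; it cannot model
  mappability or GC artifacts.
* bigWig export is omitted (binary format); bedGraph is the on-disk track
  format.
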