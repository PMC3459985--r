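# chromParticles

Size-class chromatin particle mapping and centromere chromatin profiling
from paired-end MNase-seq and ChIP-seq, with a fully ground-truthed
synthetic mini-genome.

## What it does, and for whom

MNase digestion of chromatin leaves particle-protected DNA fragments whose
length identifies the particle: ~150 bp for a mono-nucleosome, ~300/450 bp
for di-/tri-nucleosomes, ~125 bp for the budding-yeast point-centromere
core particle. Sequenced in paired-end mode, each fragment's template
length (SAM `ISIZE`) selects a size class and its center estimates the
particle **dyad**:

```
keep pairs with isize in [target*(1-f), target*(1+f)]   (150 bp ± 20%)
dyad = left5 + floor(isize / 2)
bin dyads at 15 bp, smooth with a 3-bin moving average
```

Peaks of the smoothed dyad frequency are translationally positioned
nucleosomes; the centromeric core particle appears as a small peak over
the centromere. For chromatin biologists studying nucleosome organisation
— especially around point centromeres — the package provides, as plain R
functions over Bioconductor containers:

* `sizeClassFilter()`, `dyadPositions()`, `binDyads()`, `smooth3()`,
  `mapParticles()`, `isizeSpectrum()`, `callPeaks()` — the particle
  mapping core;
* `binTags()`, `normalizeTrack()`, `log2Enrichment()`,
  `linearOccupancy()`, `differenceTrack()`, `featureBoxStats()` —
  input-normalized ChIP tracks (reads per million per kilobase of probe)
  and per-feature-class enrichment summaries;
* `geneTable()`, `assignIgrs()`, `classifyOrientation()`,
  `expressionCategories()` — gene context: TSS/TTS anchors, intergenic
  regions (UTR + 150 b extension), divergent/convergent/tandem classes,
  expression tertiles;
* `anchoredProfile()`, `scaledProfile()`, `normalizeOccupancy()`,
  `movingAverageRatio()` — metagene profiles with 95% confidence
  intervals;
* `cenReport()` — per-centromere genotype comparison: core-particle
  detection, flanking-nucleosome peak matching, shift and
  accessibility-change calls;
* `quantifyExpression()`, `foldChangeLists()`, `coverageReport()`,
  `hypergeomOverlap()` — expression fold-change lists at a 1.5-fold
  cutoff and hypergeometric list-overlap probabilities;
* `simConfig()`, `makeGenome()`, `simulateMnasePairs()`,
  `simulateChipTags()`, `simulateExpression()` — the synthetic study with
  ground truth (`TruthSet`) for recovery scoring;
* `runPipeline()` — all stages end to end into a directory of
  .sgr/.bedgraph/.bedpe/.bed/.gff3/.tsv text outputs plus a JSON
  manifest.

## Worked example

```r
library(chromParticles)

cfg <- simConfig(seed = 7)          # two 60 kb chromosomes, 195 pairs/nucleosome
g   <- makeGenome(cfg)
g$truth
#> TruthSet: 2 chromosome(s), 2 CEN(s), 40 gene(s)
#>   dyads: mutant=679, wt=679
#>   planted expression changes: 4 gene(s)

pairs <- simulateMnasePairs(g$truth, cfg, "wt")
track <- mapParticles(pairs, seqlengths = g$seqlengths)   # 150 bp class
track
#> BinnedTrack: 2 chromosome(s), 8000 bins of 15 bp [frequency]

## how well do smoothed-track peaks recover the true dyads?
pk <- callPeaks(track)
td <- truthDyads(g$truth, "wt")
rec <- mean(vapply(seq_len(nrow(td)), function(i) {
  p <- pk[pk$chrom == td$chrom[i], ]
  any(abs(p$bin - td$pos[i] %/% 15L) <= 1L)
}, logical(1)))
rec
#> [1] 1
```

All 679 ground-truth dyads sit within one 15 bp bin of a called peak.
The centromere comparison between genotypes:

```r
mut <- mapParticles(simulateMnasePairs(g$truth, cfg, "mutant"),
                    seqlengths = g$seqlengths)
rep <- cenReport(track, mut, truthCens(g$truth))
cenReportTable(rep)[, c("cen_id", "core_height_ratio", "max_abs_shift", "call")]
#>   cen_id core_height_ratio max_abs_shift call
#> 1   CEN1         0.5566038            30 both
#> 2   CEN2         0.4594595            30 both
```

Both simulated centromeres are called changed: their flanking nucleosome
peaks moved by the planted 30 bp and the core-particle height dropped by
the planted factor ~0.5.

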