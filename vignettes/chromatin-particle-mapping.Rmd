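---
title: "Size-class chromatin particle mapping and centromere profiling"
author: "chromParticles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-class chromatin particle mapping and centromere profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromParticles)
```

## The analysis this package implements

Micrococcal nuclease (MNase) digests the linker DNA between nucleosomes and
leaves particle-protected fragments behind: roughly 150 bp for a
mono-nucleosome, 300 bp for a di-nucleosome, 450 bp for a tri-nucleosome,
and about 125 bp for the budding-yeast point-centromere core particle.
When such a digest is sequenced in paired-end mode, the template length of
each pair (the SAM `ISIZE`) reports which particle protected the fragment,
and the *center* of the pair estimates the particle dyad.  The package
implements this size-class logic end to end:

1. **Size-class selection.** Pairs are kept when their insert size falls in
   the inclusive window `target x (1 +/- windowFraction)`; the nucleosome
   class is 150 bp +/- 20%, i.e. 120-180 bp.
2. **Dyad mapping.** Each retained pair contributes its center,
   `left5 + floor(isize / 2)`, as a putative nucleosome dyad.  The floor is
   a fixed, documented choice for odd insert sizes.
3. **Binning and smoothing.** Dyads are counted into 15 bp bins anchored at
   coordinate 0 and smoothed with a 3-bin moving average.  Peaks of the
   smoothed frequency distribution correspond to translationally
   positioned nucleosomes; the centromeric core particle appears as a
   smaller peak centered on the centromere.

Around this core the package provides input-normalized ChIP enrichment and
difference tracks, gene-context annotation (transcript anchors, intergenic
regions, orientation classes, expression categories), anchored and
length-scaled metagene profiles, per-centromere genotype comparison,
fold-change calling, and hypergeometric list-overlap statistics, plus the
text formats (.sgr, bedGraph, BEDPE, minimal SAM, BED6, GFF3, TSV) that
connect the stages.

## The synthetic study and what it does (not) emulate

No external data are required: `makeGenome()` builds a mini-genome whose
chromatin matches the statistical structure the analysis assumes, with a
full ground truth (`TruthSet`) for recovery scoring.  The defaults define
the study conditions used throughout the tests:

* two chromosomes of 60 kb, nucleosome arrays at a 165 bp repeat --
  roughly 360 positioned nucleosomes per chromosome;
* a promoter nucleosome-depleted region of 140 bp upstream of each TSS;
* one 125 bp centromere per chromosome carrying a single core particle at
  half the bulk occupancy, flanked by well-positioned nucleosomes;
* an insert-size mixture with mono/di/tri peaks at 150/300/450 bp
  (weights 0.60/0.25/0.15, within-class SD 10 bp) -- di- and
  tri-nucleosome pairs center on the midpoint of the spanned dyads, so the
  300 bp class peaks *between* adjacent nucleosomes;
* 195 sequenced pairs per unit-occupancy nucleosome, the coverage scale of
  a typical yeast nucleosome-sequencing experiment, with uniform +/- 10 bp
  jitter on observed centers;
* ChIP enrichment folds per feature class, strongest over centromeres
  (fold 8), and an H2A.Z-like target whose mutant genotype redistributes
  signal from promoters (fold 6 to 1.5) into gene bodies (0.7 to 2.2);
* a mutant genotype whose centromere-flanking nucleosomes shift by 30 bp
  and whose core-particle occupancy is halved, on a configurable subset of
  centromeres;
* per-gene negative-binomial expression counts around log-normal means,
  with 10% of genes planted at or beyond a 1.5-fold change.

The simulator is deliberately idealized: it emits no base qualities or
sequencing errors, no MNase AT-cleavage bias, no fuzzy or delocalized
nucleosomes, and no copy-number structure.  Passing tests therefore show
that the *computation* is correct under its stated model -- they do not
certify performance on real chromatin, where positioning is less regular
and digestion bias is substantial.

Determinism is part of the contract: one master seed drives per-module,
per-genotype sub-streams, so identical configurations give byte-identical
outputs and adding one simulation never perturbs another.

## Numerical and design choices

* **Smoothing edges.** The 3-bin moving average shrinks to the two
  available bins at track ends, so constant tracks are exact fixed
  points.
* **.sgr serialization.** Three tab-separated columns (chromosome,
  zero-referenced bin start, value), values at 10 significant digits so a
  write-read cycle reproduces a track to numerical test tolerance.
* **Normalization.** Count tracks are scaled to reads per million per
  kilobase of probe; ratio tracks add a pseudocount of 0.5 normalized
  units to both sides (needed for zero-input bins; zero pseudocount turns
  those bins into NA with a count message).
* **Per-feature summaries** use the mean of bin values over the feature;
  box statistics use linear-interpolation quartiles (R type 7).
* **Intergenic regions.** The 5'/3' IGR is the UTR plus a 150-base
  outward extension; genes lacking UTR annotation fall back to the bare
  extension from the ORF boundary.  IGRs truncate at the nearest
  neighbouring feature boundary (not the midpoint), keeping them disjoint
  from every ORF, and clip at chromosome ends.
* **Metagene windows.** Probes of 25 bp from -1000 to +2000 around the
  TSS (mirrored around the TTS); 95% confidence intervals use the normal
  approximation `mean +/- 1.96 SE`.  For length-scaled profiles the gene
  body is resampled to 40 bins by overlap-weighted means and each 1250 bp
  flank is split into 50 fragments of 25 bp -- the fragment width is
  chosen as `flank / 50` so the fragment count and flank extent are
  arithmetically consistent; both are parameters.
* **Expression.** Quantification is reads per kilobase per million
  (`count x 1e9 / (total x length)`); categories are tertiles of ranked
  log2 intensity with ties broken by gene identifier; fold-change ratios
  add a pseudocount of 1 normalized unit.
* **Overlap statistics.** The upper-tail probability `P(X >= k)` is the
  default (the point probability is an option), evaluated through the
  hypergeometric distribution in log space; tests verify it against
  exhaustive enumeration of all draws for universes up to 12 genes.
* **Peak calling.** A local maximum is a bin strictly greater than both
  neighbouring runs; plateaus report their leftmost bin; track ends are
  never peaks.

## Centromere comparison: thresholds and statistical power

`cenReport()` compares two genotypes per centromere: the core particle is
the highest local maximum within the centromere +/- one bin; flanking
peaks (at least 20% of the window maximum, suppressing noise maxima) are
matched greedily by nearest position within 150 bp, about one nucleosome
footprint.  A flank-shift is called when a matched peak moved by at least
2 bins; a core-accessibility change when the core height ratio deviates
from 1 by at least a factor 1.25 (or the core is detected in only one
genotype).  Both thresholds make qualitative by-eye calls reproducible
and are configurable.

A power consideration fixes the problem sizes used in the call-accuracy
tests: at 195 pairs per nucleosome the half-occupancy core particle
collects on the order of 100 mono-class pairs, so the mutant/wild-type
core height ratio carries 15-20% sampling noise and an unperturbed
centromere can graze the 1.25 threshold.  Discriminating a true factor
0.5 from no change at that threshold therefore needs deeper sampling, and
the centromere call-accuracy analyses use 1000 pairs per nucleosome on
16 chromosomes of 20 kb, where the ratio noise drops to about 6% and the
perturbed/unperturbed separation is essentially deterministic.  Dyad
*position* recovery is already reliable at 195 pairs per nucleosome and
is tested at that coverage on the default two-chromosome genome.

## Problem sizes used by tests and the acceptance script

Unit tests run on a one-chromosome 20 kb genome; recovery analyses use
the default two 60 kb chromosomes (about 675 truth dyads, 130k pairs);
fold-change recovery uses about 500 genes at deep counts (mean 20000,
dispersion 5e-4), where a plain 1.5-fold cutoff should recover planted
changes almost perfectly; the centromere study uses 16 x 20 kb
chromosomes with 10 of 16 centromeres perturbed.  All are the package's
own choices of desk-scale problem sizes that keep every property
measurable.

## Known limitations

* The simulator's regular arrays make peak calling easier than on real
  chromatin; recovery rates here are upper bounds.
* Insert-size truncation at +/- 3 SD makes extreme insert sizes
  impossible, which real libraries do produce.
* The centromere report's fixed thresholds are not significance tests; no
  multiple-testing control is applied (none is needed for 16 calls, but
  genome-wide use would want one).
* BAM/CRAM input is out of scope; alignments enter as BEDPE or minimal
  SAM text.
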