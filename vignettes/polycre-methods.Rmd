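---
title: "Identifying candidate Polycomb response elements from PhoRC co-occupancy: models and methods"
author: "polycre package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polycre methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

In *Drosophila*, Polycomb response elements (PREs) are cis-regulatory DNA
elements that recruit Polycomb group (PcG) silencing complexes.  The
pleiohomeotic repressive complex (PhoRC) — the sequence-specific DNA
binder Pho together with dSfmbt — marks candidate PREs: genomic regions
bound by **both** subunits.  `polycre` implements the downstream desk
analysis of such a study: it derives high-confidence per-factor peak
sets from replicate ChIP-seq peak calls, intersects them into co-bound
(PhoRC) regions, annotates each region against promoters and two tiers
of developmental enhancers, tests overlap enrichment against matched
background regions with Fisher's exact test, characterises the
H3K27me3 chromatin state around bound promoters and enhancers
(meta-profiles with bootstrap bands, a focused-versus-broad promoter
classifier, nucleosome-depleted-region detection), discovers the Pho
recruitment motif de novo, and compares nearest-gene expression (RPKM)
between regulatory classes.  Because real ChIP-seq inputs are
genome-scale and the upstream processing is laboratory-specific, the
package pairs every step with a synthetic-data generator that plants
known ground truth, so the whole pipeline is validated by parameter
recovery rather than by re-processing archived reads.

## Coordinate and container conventions

All files use BED conventions: 0-based, half-open intervals.  In
memory the package uses `GRanges` (1-based, closed), converting at the
I/O boundary; the TSS of a minus-strand gene is `end - 1` in 0-based
coordinates.  A single convention at each layer eliminates off-by-one
drift; every reported midpoint or TSS position in output tables is
0-based.  Signal is carried by the `SignalTrack` class: one numeric
vector per chromosome at a fixed bin width (default 25 bp), the
in-memory form of a bedGraph.  Binning a bedGraph maps each record onto
bins by coverage-weighted mean (bedGraph values are per-base), so mass
is conserved exactly; region sums and meta-profile rebinning integrate
the piecewise-constant signal analytically, making partial bins exact
rather than approximated.

## Co-occupancy model

Replicate reconciliation keeps a peak iff it has at least 25%
reciprocal overlap with a peak in the other replicate, merging partners
by interval union.  The threshold is a deliberate simplification —
irreproducible-discovery-rate modelling is out of scope — and is a
tunable argument.  Co-occupancy uses the most permissive rule
consistent with the term: one shared base pair (`minOverlap = 1`), on
half-open intervals, so abutting peaks do not qualify.  A co-bound
region is the union of its transitively overlapping peak group rather
than the intersection: the union preserves the full footprint, whose
midpoint later centers meta-profiles.  Counts are kept in *source-peak
units* as well, because the headline percentages (co-bound share of
each factor's peaks) are ratios of peak counts, not of merged regions.

## Annotation rules

Each region's category is decided by its midpoint, which guarantees a
partition without fractional assignments.  Precedence is promoter
(unsigned midpoint-to-TSS distance ≤ 500 bp, inclusive, either side)
over characterized enhancer, over ChIP-defined enhancer, over
intragenic, over intergenic.  The promoter-first order reflects that
the promoter class is defined by an explicit distance rule while the
others are catalog memberships; both the window and the precedence are
arguments.  Nearest-TSS ties break to the lexicographically smaller
gene identifier so results never depend on input order.  Median
distances are computed on unsigned distances; signed (strand-aware)
distances are retained for plotting.

## Enrichment statistics

`fisherExact()` computes the two-sided p-value as the sum of
hypergeometric probabilities of all tables, with the observed margins,
that are no more probable than the observed table (relative tolerance
1e-7 on the comparison — the common "sum of small p's" convention;
alternatives such as doubling one tail differ and are not used).  The
effect size is the sample odds ratio (a·d)/(b·c), with the
Haldane–Anscombe +0.5 added to every cell iff any cell is zero (the
p-value is unaffected; the `correctionApplied` slot records it).  A
zero margin is an error, not a silent 1.  `mannWhitneyU()` reports U
for the first sample (ties counted 1/2).  Exact mode enumerates all
C(n+m, n) group assignments and returns
P(|U − nm/2| ≥ |U~obs~ − nm/2|); it is intended for small samples and
for oracle testing.  Normal mode applies the tie-corrected variance
with a 0.5 continuity correction.  Both are implemented in the package
because their exact semantics are part of the analysis contract;
`stats::fisher.test` and `stats::wilcox.test` serve as independent
cross-checks in the test suite only.

Matched background sampling controls what "enrichment" means: for each
peak, 10 intervals (configurable) with identical length, the same
chromosome, and a nearest-TSS distance inside the same decile of the
peak set's distance distribution, never overlapping any input peak.
Distance matching matters because enhancer catalogs are themselves
TSS-distance structured; without it the enrichment test partly measures
distance geometry.  Placement is targeted (an offset drawn within the
decile bounds around a random TSS) with bounded retries and a hard
failure naming the offending peak.  No multiple-testing correction is
applied by default (single raw p-values are reported);
`adjustEnrichmentBatch()` offers Benjamini–Hochberg for batch use.

## Chromatin profiles and the promoter-state classifier

Meta-profiles are regions × position-bins matrices over
±10 kb (default) of each region midpoint at 100-bp bins.  Windows that
cross a chromosome edge are padded with `NA`, not zeros — zeros would
bias mean curves downward — and `NA` bins are excluded from the summary
curve and bootstrap.  Confidence bands are percentile bootstrap over
regions (rows), deterministic under a seed.

The focused/broad promoter split is this package's operationalisation;
the underlying study describes the two classes (a focused H3K27me3 peak
within ±500 bp versus an approximately three-fold higher level
spreading to about ±10 kb) but not a classification procedure, so no
claim is made of reproducing any published fractions on real data.
Features per promoter: mean H3-subtracted H3K27me3 in ±500 bp and in
±10 kb of the bound-peak midpoint, and *breadth*, the fraction of
±10 kb bins above τ, where τ is the genome-wide median of positive
track values (scale-free and robust to sequencing depth).  A 2-means
split (best of 10 seeded restarts) on (log1p(broad level), breadth)
assigns labels; the cluster with the higher mean breadth is "broad" —
the Polycomb-repressed state.  Degenerate feature matrices yield a
single class with a warning.

NDR (nucleosome-depleted region) detection is rule-based: a dip is
called iff the center bin is below half (default ratio) of the mean of
the two flank maxima within ±1 kb; depth is 1 − center/flank-max mean.
Zero flanks are "not callable" rather than negative calls.

## Motif discovery

Discovery is seeded ZOOPS expectation–maximization.  Seeds are the five
most enriched 6-mers ((width − 2)-mers) against a dinucleotide-style
shuffled background; the shuffle is a first-order Markov resample
fitted per sequence, which preserves expected dinucleotide composition
and is used only for seeding.  Each seed initialises a PWM (0.8 point
mass on the seed positions, background elsewhere) refined under a
zero-or-one-occurrence-per-sequence model on both strands with a
per-column pseudocount of 0.01 split by background frequency, until the
log-likelihood improves by less than 1e-4 or 100 iterations; the
log-likelihood is asserted non-decreasing every iteration, and the
highest-likelihood refined model wins.  ZOOPS rather than
one-occurrence-per-sequence because not every bound region need contain
the motif.  Scanning reports log2-odds scores against the 0-order
background on both strands, skipping windows with non-ACGT characters.
One practical property worth knowing: on planted data the EM may
converge registered one position left or right of the planted 8-mer, so
recovery checks align the discovered consensus to the planted one
rather than requiring a literal substring.

## Expression

RPKM is counts / (length/1000 × library/10^6), with the library size
taken from the counts table when it declares one (the synthetic
generator declares its 2M-read library, since mapped reads are not
confined to gene models) and the column sum otherwise.  Regions map to
the gene with the nearest TSS (ties lexicographic, optional distance
cap, off by default).  When a gene is reached by both a repressed
promoter and a bound enhancer, the promoter label wins — promoter
evidence is direct.  Medians use the mean-of-central-order-statistics
convention (median of {1,2,3,4} is 2.5).

## The synthetic generator: what it emulates, and what it does not

The generator defines the package's reference study conditions; the
defaults are fixed once and are not tuning knobs:

* **Genome** — one 10-Mb chromosome, 200 non-overlapping genes on both
  strands (log-normal lengths 2–20 kb, gaps ≥ 3 kb, 60-kb margins so
  ±10-kb windows never truncate).
* **Peaks** — 100 Pho and 200 dSfmbt true peaks (the 2:1 ratio echoes
  the relative sizes of the two factors' high-confidence sets), with a
  co-binding fraction of 0.8 (the study's co-bound share of Pho peaks
  is ~80%).  Planted counts are exact (`round(fraction × n)`, largest
  remainder across categories) so recovery error measures the pipeline,
  not generator sampling noise.  Peak widths are 1000–2000 bp
  (truncated normal, mean 1400): with ±25-bp uniform end jitter between
  factors and between replicates, the narrowest peak still guarantees
  ≥ 90% reciprocal replicate overlap, which the replicate rule relies
  on.  Each replicate additionally gets 10% replicate-specific decoy
  peaks that reconciliation must discard.
* **Categories** — co-bound peaks are spread over
  promoter/characterized-enhancer/ChIP-enhancer/intergenic/intragenic
  at 47/5.2/17.4/16.2/14.2% — the published annotation mix — subject to
  placement rules that make the planted truth unambiguous under the
  package's own precedence rules (enhancers ≥ 1.5 kb from any TSS,
  peaks mutually separated).
* **Chromatin** — focused promoters carry a rectangular H3K27me3 peak
  of amplitude 2 over ±500 bp; broad (repressed) promoters and bound
  enhancers carry a plateau at 3× that amplitude over ±10 kb.  The 3×
  is an amplitude (level) ratio: comparing each class's mean over its
  own planted support recovers it, whereas comparing both classes over
  ±10 kb would conflate level with spread.  Promoter hosts are kept
  ≥ 21 kb from each other and from bound-enhancer domains so a focused
  promoter is never shadowed by a neighbour's ±10-kb domain.  Bound
  elements (except focused promoters, which model stalled rather than
  repressed promoters) carry a multiplicative nucleosome-depleted dip
  of relative depth 0.6 over ±150 bp in H3 and H3K27me3, producing the
  bimodal profile NDR detection looks for.  H3K27ac marks TF-bound
  (PhoRC-nonbound) enhancers, H3K4me1 all enhancers, input is flat.
  Noise is additive Gaussian on log-signal (sd 0.2) applied to signal
  plus a 0.05 baseline — multiplicative log-normal keeps tracks
  non-negative without read-level simulation.
* **Sequences and motif** — element sequences are i.i.d. uniform ACGT
  with the consensus GCCATTGT (GCCAT core) embedded once, random
  position and strand, in 80% of bound elements; uniform background
  makes motif enrichment analytically predictable.
* **Expression** — gene classes follow the regulatory truth (repressed
  promoter, bound enhancer, TF-bound enhancer, nonbound enhancer, and
  ubiquitous/meso/non-meso reference thirds for the rest) with RPKM
  medians 1.5/2/25/8/60/40/2 and log-normal spread (sd 0.4) around
  them — free parameters shaped to the qualitative ordering of the
  published comparison (PhoRC classes at inactive-gene levels, TF-bound
  classes high).
* **PRE catalog** — 30 elements, 28 planted on co-bound regions, so the
  catalog-overlap report reproduces 93% when the pipeline recovers the
  planting.

What the generator does **not** emulate: read-level sampling noise and
mappability artifacts, fragment-size effects, peak-width and
signal-to-noise distributions of real ChIP (the originals live in
unavailable supplemental processing rules), correlated occupancy beyond
the planted structure, and realistic sequence composition.  Passing the
recovery suite therefore demonstrates that the pipeline's logic is
correct and internally calibrated — not that its thresholds are tuned
for any particular real dataset.

## Null calibration of the enrichment test

The type-I property (p-values uniform when features are planted
independently of the query) is checked on a design where it holds
exactly: the genome is partitioned into disjoint 2-kb blocks; 1500
query and 4500 background unit intervals occupy distinct blocks and
features are planted per block independently (rate 0.4).  This makes
the overlap indicators i.i.d., so conditioned on the margins the table
is exactly hypergeometric, and the table is large enough that the
discrete exact p is close to continuous.  Naive designs with random
intervals on a continuous genome fail this check for a different
reason than test error: nearby intervals share feature coverage, the
indicators become positively correlated, and the hypergeometric null
is genuinely wrong there.  At 500 simulations the
Kolmogorov–Smirnov uniformity p ranged over 0.12–0.84 across six RNG
streams under this design.

## Problem sizes

The validation suite runs the full reference genome (10 Mb, 200 genes,
100 + 200 peaks) for parameter-recovery sweeps, 50 × 200-bp sequence
sets for motif recovery with 20 null repetitions, 500 simulations for
null calibration, and two complete pipeline runs for the determinism
check — sizes chosen so that every property is measured on the same
conditions the generator defines while the whole suite stays
desk-scale.

## Known limitations

* The replicate rule and the co-occupancy threshold are simplifications
  of laboratory-specific processing; both are exposed as arguments.
* The focused/broad classifier is unsupervised; on real data with a
  continuum of domain widths the 2-means split can be unstable near the
  boundary, and its fractions should be read as descriptive.
* Matched background sampling requires genes on every peak's
  chromosome and can fail loudly on exotic geometries (by design).
* The motif module discovers a single ungapped motif; multiple motifs,
  gapped models and database comparison are out of scope.
* `fisherExact()` enumerates the hypergeometric support, which is
  exact but not meant for tables with totals in the millions; overlap
  tables at desk scale are far below that.
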