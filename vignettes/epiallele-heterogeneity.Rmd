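---
title: "Epiallele-level methylation heterogeneity: model, thresholds and design"
author: "epishift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epiallele-level methylation heterogeneity: model, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epishift)
```

## The measurement model

Bisulfite sequencing reads report the methylation state of every CpG they
cover, so a single read is a direct observation of one DNA molecule's
local methylation pattern. `epishift` works at the level of **loci of four
adjacent CpGs covered by the same read**: each covering read carries one
of $2^4 = 16$ patterns (epialleles), encoded as an index $0\dots15$ with
the first CpG in genomic order as the most significant bit
(`UUUU` $\to$ 0, `MUUU` $\to$ 8, `MMMM` $\to$ 15). The locus in one sample
is summarized by the pattern proportions $p_1,\dots,p_{16}$.

Three views of heterogeneity are computed from one distribution:

* **Epipolymorphism** $Epi = 1 - \sum_i p_i^2$, the probability that two
  random reads carry different epialleles. It is 0 iff one pattern has all
  the mass, and maximal, $1 - 16\cdot(1/16)^2 = 0.9375$, at the uniform
  distribution.
* **PDR**, the proportion of reads that are *discordant* (neither pattern
  0 nor pattern 15). Epi and PDR answer different questions: a 50/50
  mixture of fully methylated and fully unmethylated molecules — two
  clean subpopulations — has $Epi = 0.5$ but $PDR = 0$, while stochastic
  per-molecule methylation drives PDR up.
* **Combinatorial entropy**
  $S = s \cdot \sum_i p_i \log_2 p_i$, with scale $s = 25$ per bit so that
  $S \in [-100, 0]$ for 4-CpG loci. Descriptions of this family of methods
  sometimes quote a maximal shift of magnitude 144; no scaling of
  $\sum p_i \log_2 p_i$ over 16 patterns produces that bound (the entropy
  range is 4 bits), so we keep the $[-100,0]$ convention of the entropy
  scale 25 and expose `entropy_scale` rather than calibrating to any other
  printed bound. All downstream thresholds here assume the
  $[-100, 0]$ scale.

Mean methylation of a locus is $\sum_i p_i\,\mathrm{popcount}(i)/4$. The
attainable $(m, Epi)$ region is bounded by two envelopes
(`epipolymorphism_envelope()`): the bimodal curve $2m(1-m)$ (mass only on
patterns 0 and 15) and the maximal curve, computed exactly by convex
quadratic programming over the five *weight classes* (patterns grouped by
methylated-CpG count, multiplicities 1, 4, 6, 4, 1). Within a class, an
equal split over its patterns minimizes $\sum p^2$ at fixed class mass
(Cauchy–Schwarz), so the optimization reduces to 5 variables; the
KKT active sets (31 of them) are enumerated, which is exact and is checked
in the tests against a grid search.

## Locus construction and filters

The CpG map is data-derived: all positions observed in the reads, with
CpGs below 10 valid calls removed (`min_cpg_coverage`), matching the usual
per-CpG coverage filter of methylation callers. Every window of 4
*consecutive map CpGs* (sliding, stride 1) is a candidate locus; a read
contributes iff it has non-missing calls at all four positions, and loci
with fewer than 60 such reads (`min_locus_depth`) are dropped. Stride-1
windows maximize locus discovery; since neither a stride nor a
disjointness rule is standard, this choice is configuration-free and its
equivalence to a brute-force window enumeration is property-tested.
Reads with a missing call at any of the four CpGs are excluded from that
locus only — they still count toward other windows they fully cover.

Coordinates: per-CpG positions are 1-based positions of the C on the
+ strand (the producer is expected to collapse G-strand calls onto the C
and to emit one row per read *pair*, so a fragment is never counted
twice); interval files are 0-based half-open BED. Base-quality filtering
(PHRED ≥ 20) is assumed done upstream; an optional per-CpG quality column
in the epiread dialect is honored with the same threshold.

## Entropy shifts, eloci, EPM

For a locus covered (at depth ≥ 60) in both samples of a pair,
$\Delta S = S_2 - S_1$. The locus is an **elocus** when
$\Delta S < -70$, a strict inequality. Two calling modes exist because
the signed rule only detects entropy *gains* (toward disorder):

* signed (default): $\Delta S < -70$ — compatible with the original
  methclone convention;
* absolute: $-|\Delta S| < -70$ — symmetric, also catching *selection*
  events where a minor pattern sweeps to dominance (an entropy loss).
  These are exactly the events expected under treatment pressure, and the
  classifier (below) can only observe them among eloci in this mode.

Both modes are first-class; the mode travels in the report manifest.

$EPM = 10^6 E / C$ normalizes the elocus count $E$ by the number of loci
$C$ covered in both samples; when $C = 0$ EPM is reported as missing, not
zero. Against controls, a locus must be an elocus versus **all**
`n_npc = 3` control samples (consensus intersection); the consensus
section reports $C$ as the loci covered in the tumor sample and every
control. Direction calls use the locus mean methylation difference with
an inclusive $\geq 25\%$ threshold (hyper) / $\leq -25\%$ (hypo); the
locus, not the single CpG, is the unit throughout. For consensus eloci the
direction uses the diagnosis methylation minus the mean control
methylation, and the pattern-change category uses the pooled control
counts as stage 1.

Pattern changes between stages are classified with strict 30%/70% rules:
`disorder_maintenance` (no pattern reaches 30% at either stage),
`selection` (disordered, then one pattern above 70%), `disorder` (the
reverse), `switch` (different dominant patterns above 70% at both
stages), else `unclassified` — e.g. the same dominant pattern twice, or
any stage with a maximum between 30% and 70%. Category fractions are
reported over eloci.

## Genomic context

Promoters are TSS ± 2 kb; shores are the 2 kb flanks of merged CpG
islands minus the islands; shelves the next 2 kb; promoter CGIs the
promoter/island intersection. Loci are annotated by the **midpoint** of
their 4-CpG span (`floor((first + last)/2)`; even spans floor down), with
fixed precedence promoter > TTS window (TTS ± 2 kb, a documented choice —
annotation tools differ here) > exon > intron > intergenic, and
CGI > shore > shelf > open sea. Region-set statistics (base-overlap
fraction, Jaccard, merged genome coverage, median interval length, TSS
distance to the nearest containing-region boundary) are plain interval
algebra on `GRanges`. The boundary-distance quantile convention is
configurable (`quantile_type`, default linear interpolation, nearest-rank
available) because third-quartile summaries of such distances depend on
it.

## Expression association

Per gene, promoter methylation and promoter PDR are unweighted means over
the loci whose center falls in the promoter. Genes are split at the
cohort mean promoter PDR into low/high strata; within each stratum a 2×2
table of expressed (FPM > 1) by methylated (> 75%) / unmethylated (< 25%)
promoters is formed — genes with intermediate methylation are excluded —
and summarized by the odds ratio with the Haldane–Anscombe +0.5
correction when a cell is zero and Woolf's 95% log-scale interval. With
rows = expressed and columns = methylated/unmethylated, OR < 1 is the
canonical repressive coupling and OR ≈ 1 its loss. Estimator and interval
are standard choices for sparse 2×2 tables; nothing in the analysis
depends on their exact flavor. Coefficients of variation use the sample
(n−1) standard deviation over samples and exclude genes with mean FPM at
or below 1.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the analysis assumes: three
control replicates sharing a per-locus baseline distribution (Dirichlet
jitter, concentration 1500 — tight enough that the consensus rule is
exercised but null loci rarely break it; control-to-control variability
has no published quantitative model, so this is a free, documented
parameter), one diagnosis and one relapse sample, with reads drawn
multinomially at Poisson depth (mean 80) clamped at the 60-read floor so
coverage dropout never interacts with metric behavior (a `dropout_rate`
mode reintroduces missing calls when wanted).

Background loci draw from three archetypes (55% bimodal concordant, 25%
single-dominant, 20% Dirichlet-disordered — a caricature of the bimodal
methylome with a disordered fraction). Planted events between baseline
and diagnosis realize each category's defining distributions with a 0.05
margin (disordered stages rejection-sampled to max ≤ 0.25; dominant
stages ≥ 0.78): `selection`, `disorder`, `switch`, `disorder_maintenance`,
plus `hyper_shift`/`hypo_shift` (single-pattern baseline to a
near-uniform distribution tilted toward methylated/unmethylated patterns,
giving $|\Delta S_{true}| \gtrsim 90$ *and* a ≥ 25% methylation change).
Default planted fractions total 12% of loci — deliberately shift-enriched
so that small test cohorts contain all event types; the remaining loci
are null (identical truth in both stages). Relapse events are planted
only at loci whose diagnosis distribution satisfies the category's
stage-1 requirement. Locus anchors are spaced 5 kb apart so that exactly
one locus falls in each synthetic promoter.

Genes sit with their TSS at the center of a dedicated promoter locus
whose archetype is cycled over four promoter types: concordant
(low-PDR) or discordant (high-PDR), each in an unmethylated (< 25%) or
methylated (> 75%) version — the discordant types place mass on patterns
with at most one discordant CpG so that methylation stays extreme while
PDR is high. Genes with low-PDR promoters are *coupled*:
$\log_2 FPM = 4 - 6\,m + \mathcal N(0,1)$ against their promoter
methylation $m$; high-PDR genes are *decoupled*, drawing expression
around the mid-methylation expectation with SD 1.5, independent of $m$.
These values put expressed/unexpressed on either side of FPM = 1 for
extreme methylation and reproduce the qualitative odds-ratio contrast.

PMD-like regions alternate lognormal segments to cover ≈ 65% of the
synthetic genome. What the generator does **not** emulate: real CpG
density and RRBS fragment structure, coverage gradients, bisulfite
conversion errors, copy-number effects, and correlated methylation along
chromosomes — passing tests therefore validate the estimators and the
pipeline plumbing on distributionally faithful input, not robustness to
every artifact of real libraries.

## Numerical choices and degenerate inputs

* $0 \log_2 0 = 0$ throughout; distributions are validated to sum to 1
  within $10^{-9}$.
* Zero-depth loci, empty metric tables, zero eloci, $C = 0$, empty region
  sets and all-zero 2×2 tables raise errors or return missing values
  explicitly rather than silently producing 0.
* Strictness: elocus ($<$), dominant ($>0.70$), minor ($<0.30$) and
  expressed ($>1$) are strict; the direction threshold ($\geq 25\%$) is
  inclusive, following the respective printed rules.
* Reports contain no timestamps; reruns on identical inputs are
  byte-identical (tested), and the manifest carries the configuration,
  input digests and package version.

## Problem sizes used in the test-suite

Oracle-equivalence suites run 1000 randomized pattern vectors and 10–30
randomized read sets against brute-force re-implementations. The
simulation-recovery checks use a 1000-locus cohort at depth 100 (planted
shifts with $|\Delta S_{true}| \ge 90$ recovered at sensitivity ≥ 0.9,
null loci called below 2%), truth recovery at depth 10\,000 (total
variation ≤ 0.02 per locus), and the expression contrast over 20 seeded
replicates of a 130-locus / 120-gene cohort. These sizes make the whole
suite run in a few minutes while keeping every estimate comfortably away
from its acceptance margin.

## Known limitations

* Locus size is fixed at 4 CpGs; no variable-k or phased-haplotype mode.
* Entropy shifts are pairwise; no joint model across more than two
  samples beyond the consensus intersection.
* The signed/absolute elocus ambiguity is real: the signed rule cannot
  call selection events, the absolute rule doubles the null tail. Both
  are exposed; neither is silently preferred in output.
* Promoter-level methylation uses locus means, not per-CpG means; with
  sparse promoter coverage the two can differ.
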