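---
title: "Methods: population analysis of segmental duplications from pangenome assemblies"
author: "SDPopGen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population analysis of segmental duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SDPopGen)
```

## The problem

Segmental duplications (SDs) are blocks of homologous DNA longer than 1 kb
with more than 90% sequence identity. They are hotspots of copy-number
polymorphism (through non-allelic homologous recombination) and harbour on
the order of a thousand protein-coding genes, yet they are the hardest part
of the genome to genotype: short reads map ambiguously across near-identical
paralogs, and a single reference genome cannot represent presence/absence
variation. Haplotype-resolved long-read assemblies change this: with a
cohort of phased assemblies, each SD can be located, its haplotype frequency
estimated, and gene copy number counted directly.

`SDPopGen` implements that analysis as a reusable pipeline: projection of
per-haplotype SD calls onto a common reference frame, a flattened region
catalog with frequency classes, sequence-property and dispersion statistics
of SD pairs, gene-family copy number by two independent routes, population
differentiation tests, and a reference-divergence filter for novel gene
discovery from full-length cDNA alignments. Because the real cohorts are
hundreds of gigabases, the package ships a synthetic cohort generator that
reproduces the statistical structure of such a study at desk scale and
records ground truth, so that every stage can be validated end to end.

## Coordinate conventions and projection

All on-disk formats are 0-based half-open (BED convention); chromosome names
are taken verbatim so mixed naming dialects fail loudly. Internally,
interval arithmetic is delegated to `GenomicRanges`/`IRanges`.

Haplotype-to-reference alignments are modelled as *gap-free 1-to-1 blocks*:
equal-length interval pairs with a strand. Within a forward block, offsets
map directly; within a reverse block they mirror. Indels appear as block
boundaries, and any part of a query interval covered by no block is returned
as "unplaced" and excluded from the catalog (population statistics are
restricted to 1-to-1 syntenic sequence). This is deliberately simpler than
CIGAR algebra but exact for the contract it states; projection is
length-preserving per block and invertible on forward blocks, which the test
suite checks against a per-base brute-force oracle.

## The region catalog and frequency classes

Projected SD intervals from both mates of every pair are flattened into
nonoverlapping regions (`flattenUnion`, a set-theoretic union). A haplotype
is *present* in a region when its SD bases cover at least 50% of the
region's length. The frequency classification is then:

* **fixed** — present in every haplotype of the cohort;
* **polymorphic (known)** — in the reference SD annotation, not fixed;
* **polymorphic (novel)** — absent from the reference, seen in two or more
  samples;
* **private** — absent from the reference, confined to a single sample
  (one or both of its haplotypes).

Two thresholds are genuine design choices, since no presence rule is
printed for the original analysis: the 50% presence threshold and the 50%
reference-overlap rule for "known". Both are reciprocal-overlap-style
guards: they tolerate boundary jitter between assemblies while preventing a
trivial 1-bp overlap from counting as presence. A region found in one
sample *and* in the reference is classified polymorphic (known), not
private — the reference counts as evidence of recurrence.

The accumulation curve adds haplotypes in a stated order (by default the
non-African block, then the African block) and reports the distinct bp
gained per genome by class and by intra-/interchromosomal kind. The shape
depends on the ordering; the final total always equals the catalog union.
Both the mean per-genome increment and the least-squares slope of the
cumulative curve are reported, because "bp added per additional genome" can
reasonably mean either.

## Pair properties

Each SD pair is classified by orientation (direct/inverted) and dispersion.
The gap between same-chromosome mates is the *inner* distance (end of the
left mate to start of the right; 0 if they touch or overlap) — the
conservative reading of "apart". Classes are mutually exclusive: clustered
(gap ≤ 1 Mb), interspersed (1 Mb < gap ≤ 50 Mb), distant (> 50 Mb),
interchromosomal. Carrier-count bands follow the published convention:
rare = at most 5 of 170 haplotypes (< 3% frequency), common = 6–20.

Inversion enrichment among interspersed versus clustered pairs is a 2×2
contingency analysis: the point estimate is the sample odds ratio *ad/bc*
(with a Haldane–Anscombe 0.5 correction, flagged, when a cell is zero) and
the P value is Fisher's exact two-sided (minimum-likelihood) test, which the
suite cross-checks against a full hypergeometric enumeration.

Two permutation tests are provided. `permutationCompare` permutes group
labels and uses the add-one estimator
$P = (1 + \#\{T^\ast \ge T\}) / (1 + n_\mathrm{perm})$, one-sided. By
default the tested direction is the observed one, which is the right tool
for a directional *screen* but — like any post-hoc-signed test — has twice
the nominal selective type-I error; for a calibrated test the direction is
fixed in advance via `alternative=`, and the calibration suite verifies
nominal size in that mode. `proximityPermutation` asks whether novel
regions sit closer to known SDs than random placement: the statistic is the
median distance to the nearest known SD, and the null re-places each region
uniformly on its own chromosome, length-preserving, avoiding excluded
intervals.

## Gene copy number by two routes

**Assembly route.** Paralog alignment hits are filtered with the printed
cutoffs, all strict where printed as strict: coverage > 60%, identity >
90%, coding sequence at least 200 bp, hits wholly contained in repeat
annotation removed (`repeat_overlap = 1` to machine precision; partial
overlap is retained), and optionally no assembly break within 30 kb (the
flank filter is off for cohort totals and on for paralog-resolved
reporting, since it exists to protect per-paralog claims). Diploid copy
number is the hit count summed over a sample's two haplotypes. Genes whose
extra copies appear in only one haplotype across the whole cohort are
flagged as putative assembly artefacts; their exclusion is a switch because
the same analysis that motivates it also reports per-haplotype paralog
copy numbers.

**Read-depth route.** Depth is summarised in 1-kb non-overlapping windows
(the window size is configurable; 1 kb keeps ~15–25 usable windows inside a
typical gene at desk scale). Windows overlapping tandem-repeat or
low-complexity annotation by strictly more than 10% are excluded. GC bias
is corrected by *self-recalibration*: a uniform-depth self sample — the
stand-in for decomposing the reference into fixed-length fragments and
processing them as a perfectly matched sample — is binned by GC (0.01-wide
bins pooled to at least 100 windows each, for stable factors at toy genome
sizes), and each bin's factor is its mean depth over the global mean.
Dividing by these factors makes the unbiased sample flat by construction;
the fixed-point property (refitting on corrected data gives unit factors)
is tested. Window copy number is `2 × corrected depth / baseline`, the
baseline being the mean corrected depth over caller-supplied diploid
("unique") regions; gene copy number is the median over windows fully
contained in the gene span.

Read depth underestimates copy number where paralogs diverge (reads fail to
align). A per-gene adjustment factor is therefore calibrated on one sample
with assembly copy number as ground truth, `a_g = CN_asm / CN_depth`; genes
needing more than a 50% adjustment are excluded, and retained factors make
the calibration sample exact by construction. Concordance between routes is
summarised as the R² of regressing read-depth on assembly copy number over
all gene × sample pairs.

## Population differentiation

Families are eligible for testing when, within the African or within the
non-African samples, the dispersion index (sample variance over mean, n−1
denominator — unbiased at cohort sizes of tens of samples) is at least 0.1
and mean copy number exceeds 2. Eligible families are compared between
groups with a Mann–Whitney test (exact by enumeration up to 12 total
observations, tie-corrected normal approximation with continuity correction
above) and BH-adjusted across eligible families. Directions of significant
families are summarised with a one-sided exact binomial test toward the
majority direction — the one-sided form is used because it is the version
consistent with both worked values the analysis is designed to reproduce
(13/16 → 0.01; 164/263 → 0.00004), where the two-sided test is not
(13/16 → 0.021). A family significant in the primary cohort is *replicated*
when the replication cohort shows the same direction at (strictly) adjusted
P < 0.05. Family ranking for reporting uses the dispersion index with a
mean-CN > 3 eligibility bound and lexicographic tie-breaks.

## The Iso-Seq novel-gene filter

A full-length cDNA read supports a reference-divergent duplication when it
aligns to a haplotype assembly at identity strictly above 99.9% and to the
reference at *gap-compressed* identity strictly below 99.7% (below typical
allelic divergence for coding sequence). Gap-compressed identity is the
conventional `matches / (matches + mismatches + gap openings)` — the source
analysis names but does not define it, and this is the standard definition;
a multi-base indel counts once. The haplotype side uses plain identity, as
printed; a switch could make it gap-compressed, but the printed asymmetry is
kept as the default. A missing reference alignment counts as identity 0
(maximally divergent). An optional pre-filter restricts candidates to rare
duplications (regions carried by at most 10 haplotypes, on by default).
Novel genes are counted per family from the haplotype carrying the most
predictions for that family, and each prediction locus is classified as
reference-SD, haplotype-SD-only, or unique sequence.

## The synthetic cohort generator

The generator's defaults are the study conditions the pipeline targets:
85 samples — 38 African and 47 non-African, i.e. 170 haplotypes — on a toy
layout of three chromosomes totalling 30 Mb. SD pair *templates* (two
disjoint loci each) are placed on a 10-kb slot grid so regions never
collide; each template draws a carrier set from a frequency spectrum mixing
fixed (25%), polymorphic known (35%), polymorphic novel (25%) and private
(15%) classes, with the truth class always re-derived from the carrier set
by the same published rules the classifier implements. Rare templates
(≤ 5 carriers) draw longer, higher-identity loci than common ones
(shifted log-normal lengths, median ≈ 6 kb vs ≈ 2.5 kb; identity
≈ 0.985–0.999 vs ≈ 0.925–0.98), making the rare-vs-common contrast
detectable by the permutation tests. African-only intrachromosomal
templates are added until the expected extra intrachromosomal SD content
reaches 120 kb per African haplotype — a small, clearly detectable effect
at these cohort sizes, analogous in kind (not in magnitude) to the
African excess the analysis is designed to measure.

Orientation is drawn per pair *record* (per carrier), with inversion odds
among interspersed records set to 2.0 times the clustered odds. Modelling
orientation at the record level mirrors the pooled contingency analysis the
enrichment statistic performs over all pairwise alignments and provides the
thousands of independent records that make the odds ratio recoverable
within ±25% on a 30-Mb layout; a per-template draw would leave too few
independent units at this scale. On a 30-Mb toy layout no pair can be
"distant" (> 50 Mb); that class is exercised on synthetic coordinates in
the unit tests instead.

Gene copy number truth is drawn per haplotype (capped at 6 copies per
haplotype so diploid values stay in the 0–12 range where read depth is
informative); ten of fifty families receive a population shift of two
diploid copies on average, 80% toward African samples. Paralog hits
consistent with the truth are emitted with filter-passing attributes, so
assembly counting recovers truth exactly. Window depth is negative
binomial (size 1500 — mild overdispersion with Poisson as the limit) with
mean `coverage × CN/2 × gc_bias(gc) × attenuation(gene)` at 30×; the GC
bias curve is a smooth Gaussian-bump dampening (range ≈ 0.6–1.0), and
~15% of genes get a 0.75–0.9 divergence attenuation plus ~3% a 0.5–0.62
attenuation strong enough to trip the 50% adjustment exclusion. A
noise-free self sample and the complement of gene spans (the diploid
baseline) are emitted alongside. Iso-Seq tables plant a perfectly
separable divergent read set in rare novel regions plus background reads
violating at least one threshold.

What the generator does *not* emulate: sequence-level realism (no reads or
FASTA), NAHR mechanism, boundary jitter between assemblies, reference
bias, or correlated assembly error. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct under its stated
contracts — not that real assemblies meet those contracts.

## Problem sizes and numerical choices

The validation suite runs the full default cohort (170 haplotypes, ~1,100
templates, ~2,200 regions, 50 families, 20 sequenced samples at 30×) once
for recovery checks, 100 seeded cohorts for odds-ratio recovery, and 200
null replicates per calibration check at 199 permutations each; these sizes
give Monte-Carlo error comfortably inside the asserted bands while keeping
a full run in minutes on one core. Permutation P values always use the
add-one estimator and a recorded seed; RNG state is saved and restored
around every seeded routine so library calls never perturb a caller's
stream. Ties in ranks use midranks with tie-corrected variance; degenerate
inputs (zero margins, empty groups, zero mean copy number, constant
predictors) are errors rather than silent NAs.

## Known limitations

* Alignment blocks are gap-free by contract; true CIGAR-level projection is
  out of scope, and unplaced fragments are reported, not rescued.
* The catalog assigns intra/inter kind from the generating pairs; a region
  touched by both kinds is tagged `both` and counted once in union totals.
* The read-depth route assumes the caller can supply diploid baseline
  regions and a reference-matched calibration sample.
* The auto-direction permutation P is a screen, not a calibrated two-sided
  test (see above).
* `runPipeline` orchestrates the synthetic study end to end; applying the
  stages to real data means producing the documented TSV/BED contracts from
  an aligner and SD caller upstream.
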