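---
title: "Methods: detecting and dating nuclear insertions of mitochondrial DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and dating nuclear insertions of mitochondrial DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `numtatlas`, the parameters that
matter, the numerical and design choices made where reasonable
alternatives existed, and what validation on synthetic data does and does
not establish about real data.

## 1. The biological model

A NUMT is born when an mtDNA fragment integrates into a nuclear
chromosome. From that moment the nuclear copy evolves at the nuclear
substitution rate (order 1e-9 substitutions/site/year) while the
mitochondrial lineage keeps evolving at its own, roughly tenfold faster
rate. Two consequences carry all the information the package exploits:

1. **Degradation clocks.** The divergence between a NUMT and the modern
   mtDNA grows at `V_mt + V_numt`; among sites where the ancestral and the
   modern mtDNA differ, the probability that the NUMT carries the modern
   allele decreases linearly with insertion age along the branch.
2. **Phylogenetic presence.** A region shared by two species was inserted
   before their divergence; a region private to one lineage was inserted
   after it. With the *Sus* split at ~3.5 Mya, the warthog split at
   ~10 Mya and the Suidae/Ruminantia split at ~55 Mya, presence patterns
   bracket the insertion age.

## 2. Detection in assembled genomes

The mtDNA query is doubled (`circularize()`) so local alignments can cross
the circular origin; hit query coordinates are normalised back to `[0, L)`
and circular-copy shadows (hits whose nuclear interval lies inside a
higher-scoring same-strand hit) are removed.

The aligner (`local_align()`) seeds with exact k-mers (default k = 11),
clusters seeds by diagonal (band 64, gap 500), triages weak clusters with
an ungapped X-drop extension (X-drop 20, promotion score 20), and extends
promoted clusters with affine-gap local dynamic programming on a window
around the cluster. Old NUMT have sparse seeds, so the window re-expands
(margin 150 → ×3, capped at 4 kb) whenever the optimal alignment touches
its boundary. For small problems (≤ 2.5e5 cells) the exact full-matrix
alignment is always computed as well, so the reported optimum equals the
Smith–Waterman optimum regardless of seeding; mid-size problems fall back
to exact alignment when seeding finds nothing. Scoring is +1/−1 with
gap-open 7 and gap-extend 1 — parameters suited to distant homology, where
a long degraded match should outscore short perfect noise. `N` bases never
seed and always score as mismatches. Identity is computed over all aligned
columns, counting gap columns as non-identity.

The reporting threshold is calibrated per genome by aligning the
*reversed, not complemented* mtDNA: reversal preserves base composition
and repeat structure but no homology, so the best such score is the noise
ceiling of that search space. The calibrated value (max spurious score
+ 1) is capped at the configured default 30, which is deliberately permissive
so that heavily degraded ancient copies (the most informative ones) are
not lost; the cost, about 0.02 expected spurious alignments per search
under the Karlin–Altschul model with λ = ln 3, is absorbed by the
downstream filters. On 1-Mb synthetic genomes the calibrated values fall
around 19–25, below the cap, as expected for a search space orders of
magnitude smaller than a full mammalian genome.

Post-filters: hits more than half covered by DUST-like low-complexity
sequence or tandem repeats of period ≤ 6 are masked; hits shorter than
30 bp or within 1000 bp of contig ends are dropped (assembly quality near
ends is unreliable and cross-genome orthology cannot be validated there).
Hits < 20 kb apart merge into regions by single linkage (a gap of exactly
20 kb starts a new region); region ids follow the
`<CONTIG>_REGION_<ordinal>` convention in coordinate order. A region is
*complex* when member hits overlap by > 50 bp on mtDNA coordinates
(duplication) or mix strands with overlapping mtDNA intervals; mixed
strands alone set the inversion flag. This rule is a deterministic
approximation of what is otherwise a dot-plot judgement call.

## 3. Detection in short-read data

Breakpoints are read positions where soft-clips pile up (≥ 3 clips of
≥ 7 nt). Clipped sequences are aligned to the circularised mtDNA — all
clips at one breakpoint share a junction, so the mtDNA neighbourhood is
located once with the longest clip and the rest are aligned within it,
with full-length rescue for failures — and kept at identity strictly
above 0.75 and E-value strictly below 1e-4. Surviving mtDNA intervals are
union-merged and concatenated into the putative inserted sequence.

Numerical/semantic choices the literature leaves open, fixed here and
tested: depth bounds are inclusive (`6 ≤ depth ≤ d + 4√d`, window
± 200 bp ≈ one insert size; `d` is a 10%-trimmed mean over 1-kb tiling
windows); R1 rejection is strict (`< 0.75` at every breakpoint in every
sample); R2 genotype bounds are hom `> 0.80`, het `[0.30, 0.80]` (closed),
absent `< 0.30`; reads are deduplicated by (name, flag) before any count;
both junction sides of a blunt insertion fall on the same reference
coordinate, so a clip on either side at that coordinate counts as
insertion-allele evidence in R2. For pooled samples (dozens of animals,
mixed genotypes) R2 genotyping is meaningless and only carrier status is
called; the R2 rejection is waived for pool-only loci. Accepted novel loci
must be ≥ 30 bp (the smallest assembly-detected NUMT) and present in ≥ 2
datasets, and must not fall within ± 100 bp of a known region.

Insertion contigs are assembled by greedy overlap-layout-consensus
(suffix–prefix overlaps ≥ 20 bp at ≥ 90% identity, containment absorbed);
disconnected reads yield separate contigs and single reads are flagged
fragmentary. Reads are assumed insertion-forward; reverse-orientation
handling is left to the caller.

## 4. Orthology

One-to-one whole-genome alignment blocks (MAF) are consumed, not computed
— the contribution is the decision logic, not the aligner. Blocks with
mismap probability > 1e-5 are ignored. A region projects through the
covering blocks column by column: overlap with a called region in the
other genome ⇒ `CORRESPONDING`; projection entirely onto gaps ⇒ `PRIVATE`
(a polymorphic insertion); projection onto sequence where no region was
called ⇒ `COMPATIBLE_SEQUENCE`, which is promoted to a region — the
false-negative correction — making the mapping idempotent; no coverage ⇒
`UNALIGNED`. Mixed projections use the aligned-base fraction with a 0.5
cut; in the synthetic fixtures projections are exact so the cut never
decides, and on real alignments borderline cases should be reviewed.

For distant species, where sequence alignment is unreliable, two regions
are orthologous when (i) ≥ 50% of the comparable flanking genes (up to
five per side) are syntenic — mapped orthologs in a consistent relative
order, assessed by the longest monotone subsequence, so a jointly inverted
segment still counts — and (ii) the reciprocal overlap of their source
mtDNA intervals exceeds 40% (strict), measured against the smaller
interval. Fewer than four comparable genes returns `NA` rather than a
guess.

## 5. Dating

**Age classes.** The full 16-pattern rule table is exhaustive: bovid +
any Suinae ⇒ > 55 Mya; warthog + any *Sus* ⇒ 10–55; both *Sus* species
(or warthog-private) ⇒ 3.5–10; single-*Sus*-lineage ⇒ ≤ 3.5; no presence
or bovid-only ⇒ undetermined (the latter contradicts a single insertion
event on this tree).

**Allele matching ratio** (classes ≤ 10 Mya, summed fragments > 150 bp,
mean identity > 80%, non-D-loop). The ancestral mtDNA is reconstructed by
Fitch parsimony at the relevant node; re-rooting the tree at the node
makes the single bottom-up pass exact, and ambiguous sites are excluded
from the counts (as are gap/N columns). Counts are summed across a
region's fragments before forming the ratio, so long and short fragments
are weighted by their information content. The identity gate exists
because a low-identity region that merely went undetected in the warthog
assembly would otherwise masquerade as recent. Reconstruction accuracy —
and with it the small downward bias of this method — depends on taxon
sampling: with only one in-clade lineage the host branch cannot be
polarised, which is why the validation panels (and the original multi-
genome mtDNA panels this mirrors) include several *Sus* lineages. On
2-kb fragments with a six-taxon panel the mean absolute error over ages
0.5–3 Mya is about 0.2–0.3 Mya (recomputed by the acceptance script).

**Kimura distances** (older or low-identity regions, longest fragment
> 150 bp, non-D-loop). `kimura_k80()` implements the closed form with
pairwise deletion of gap/N columns and reports saturation (non-positive
log argument) as undatable rather than a number. The closest species by
distance approximates the insertion point; K averages the NUMT's
distances to all species whose divergence from the host does not exceed
the closest species' divergence (an alternative strictly-lower reading is
available behind `strictly_lower`). The printed form of the rate formula
is ambiguous between `avg(K/2·T)` and `avg(K/(2T))`; only the latter has
the units of a per-site-per-year rate (pairwise distance ≈ 2 × rate ×
time), so `V_mt = mean(K_pair / (2 T_pair))` is implemented. Ages are
reported under all three nuclear rates; the mammalian average 2.2e-9 is
the default for classes above 10 Mya. Because detection recovers only the
best-conserved parts of very old copies, their distance-based ages are
biased downward on partially recovered regions — visible in the worked
README example and inherent to any alignment-based ascertainment.

**D-loop rule.** Fragments whose mtDNA interval overlaps the annotated
control region (default `[15400, 16600)`) by more than half their span are
excluded from both methods: ancestral D-loop states are unreliable and
its rate is atypical.

## 6. Population summaries and annotation

Carrier fractions are computed per breed/group with undetermined calls
removed from denominators; groups under 10 datasets are flagged ineligible
for clustering. Regions of the > 55 Mya class are necessarily fixed, so
their mean non-detection rate across datasets estimates the pipeline's
false-negative rate; a region is polymorphic when its species-wide
carrier fraction is strictly below `1 − fn_rate` (fallback threshold 0.97
when no ancient control exists). Group profiles cluster by UPGMA on
Euclidean distances (`hclust(method = "average")`), with columns sorted
for deterministic tie-breaking. Annotation classifies each region by
overlap precedence exon > UTR > intron > intergenic (exonic overlap is the
strongest, rarest claim, and UTRs are exon subsets in most annotations),
reports the closest gene with signed distance, collects repeat classes
within 1 kb (repeats inside the region itself are the NUMT, not its
context), and computes flank GC over ± 1 kb. Repeat enrichment is a
two-sided Fisher exact test on nucleotide counts, reported per class with
raw p-values — no multiplicity correction, matching how such scans are
conventionally reported; adjust downstream if desired.

## 7. The synthetic-data generator

`simulate_mtdna_set()` evolves a uniform-random root sequence along an
ultrametric species tree under K80 (default transition/transversion rate
ratio κ = 4, mammalian-mtDNA-like; mitochondrial rate default 2e-8
subs/site/year; mt length 16,600 bp), recording true ancestors at every
internal node and true lineage states at arbitrary ages — those lineage
states are the sequences that get inserted. `plant_numts()` evolves each
inserted copy at the nuclear rate (default 2.2e-9) for its age, applies
optional fragmentation (deletions, inversions), realises genotypes per
haplotype, and emits an exact truth table including directly counted
allele matching ratios. `simulate_reads()` places uniform paired-end
fragments (fixed insert size 300, read length 100, per-base error rate
1%) and constructs their SAM records analytically against the
insertion-free reference: a read is aligned on the reference segment it
overlaps most and the remainder is soft-clipped, which reproduces the
clip signal of a real mapper at an insertion junction without one.
Mapping quality is fixed at 60.

What the generator does *not* emulate — and therefore what green tests do
not establish about real data: indels and rate heterogeneity in mtDNA
evolution (the D-loop's repeat turnover in particular, though the D-loop
is excluded from dating anyway), realistic repeat landscapes beyond
planted cassettes, mapper-specific artefacts (multi-mapping, indel-aware
CIGARs, target-site duplications at insertion points), sequencing-quality
profiles, and structural variation other than the planted insertions.
Shared insertions are planted as identical copies across carriers rather
than re-evolved per lineage, which makes cross-genome truth exact but
slightly optimistic for orthology projection.

## 8. Validation problem sizes

The shipped validation (test suite plus `scripts/acceptance.R`) uses:
200 random pairs up to 300 bp against a brute-force affine DP oracle; a
hand-constructed two-sample SAM fixture with eight loci exercising every
rejection rule; 20 replicate cohorts of 20 planted insertions
(100–2000 bp) in 300-kb genomes at 20× and 1% error; 20 replicates per
true age for both dating methods (2-kb fragments; ages 0.5/1.75/3 Mya
against the 3.5-My horizon, 15/30/60 Mya for the distance method on a
deep-outgroup panel); exhaustive plus randomised Fisher tables up to
n = 200; and a full pipeline demo on 1-Mb genomes with three samples run
twice to confirm byte-identical outputs. These sizes were chosen so every
stage is exercised at a few hundred thousand bases — large enough for the
asymptotic behaviour of the filters and small enough to be a routine
desk-scale run.

## 9. Known limitations

* Heuristic seeding can miss spurious (and, in principle, genuine)
  alignments an exhaustive search would find; the calibrated threshold is
  therefore self-consistent with this aligner rather than universal.
* Hom/het genotyping degrades below ~15×; the caller reports what R2
  supports and leaves low-coverage interpretation to the user.
* The orthology logic assumes one-to-one alignment blocks; paralogous
  NUMT clusters that defeat the upstream aligner will surface as
  conflicting duplicate calls (resolved conservatively to CORRESPONDING,
  with the conflict retained in the status table).
* Ages of partially recovered ancient regions are underestimated
  (ascertainment toward conserved fragments), and the allele-matching
  method inherits a small downward bias from parsimony reconstruction
  error that shrinks with denser taxon panels.
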