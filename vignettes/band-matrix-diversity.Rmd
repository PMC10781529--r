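---
title: "Dominant-marker band matrices: models, indices and clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-marker band matrices: models, indices and clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandiv)
```

## The data model

Dominant markers — SCoT, RAPD and ISSR amplicons, SDS-PAGE protein bands,
isozyme bands on native gels — are scored per genotype only as band
present (1) or absent (0); heterozygotes are indistinguishable from
dominant homozygotes. Everything in this package therefore starts from a
`band_matrix`: a loci × genotypes 0/1 grid plus per-locus metadata (assay,
group, band size). "Group" is the unit over which informativeness indices
are computed: a PCR primer for SCoT, an enzyme system (POD, PPO) for
isozymes, the gel system for proteins. Band size is the field's usual
identifier for a band: molecular weight in kDa for proteins, fragment
length in bp for amplicons, relative mobility Rm ∈ [0, 1] for isozymes.

Two structural rules are enforced at construction rather than downstream:

* **No all-zero locus rows.** A band that was never observed on any gel is
  not a locus; band lists in practice contain only observed bands, so an
  all-zero row can only be a scoring or transcription error.
* **Intensity is metadata.** Staining-density grades (+/++/+++, coded
  1–3) are carried alongside presence where recorded, with the invariant
  grade > 0 ⇔ presence = 1, but every statistic is defined on presence
  only; `collapse_intensity()` (idempotent) makes that explicit. Optical
  density differences between gels are not comparable enough to support
  quantitative use.

Pooling multiple assays (`pool_bands()`) concatenates loci and aligns
genotypes *by label*, not by column position, so independently prepared
files with different column orders pool correctly; a genotype-set mismatch
is an error, never a silent intersection.

## Polymorphism classes and marker indices

For a band with presence count *c* among *n* genotypes, the frequency is
p = c/n, kept as an exact rational until the reporting boundary. Classes:

* monomorphic — p = 1;
* polymorphic — everything else, with two flagged subclasses:
  **unique positive** (c = 1; the band fingerprints its single carrier,
  an M⁺ marker) and **unique negative** (c = n − 1; the *absence*
  fingerprints the single non-carrier, M⁻). A band absent from two or
  more (but not all) genotypes is polymorphic yet fingerprints nobody.

Per primer (group), with tbn total and pbn polymorphic bands:

* **PIC** (dominant form) = mean over bands of 2p(1 − p). The per-band
  term is the probability that two random genotypes differ at the band;
  its maximum 0.5 is attained at p = 0.5, and a fully monomorphic primer
  scores exactly 0.
* **EMR** = pbn · (pbn/tbn) = pbn²/tbn, the effective multiplex ratio.
* **MI** = PIC · EMR, maintained as an exact identity (tested to machine
  precision).
* **Rp** (resolving power) = Σ over bands of 1 − 2|0.5 − p|. Rp = 0
  exactly when every band has p ∈ {0, 1}.

These are the standard dominant-marker formulas. They are stated here
explicitly because published tables in this literature not infrequently
print EMR/Rp values that no standard formula reproduces (see *Errata*
below); the package's contract is the formula, not any particular printed
value.

Percentages are rounded half-up to 2 decimals and similarities to 3
decimals **only at the reporting boundary**; internal arithmetic is never
rounded. Half-up (rather than R's default half-to-even) matches how such
tables are conventionally printed.

## Similarity

For a genotype pair let a = shared presences, b and c = one-sided
presences, d = shared absences. The primary coefficient is **Jaccard**
s = a/(a + b + c): shared absence of a dominant band carries no
information about relatedness, so d is ignored. Dice 2a/(2a + b + c) and
simple matching (a + d)/(a + b + c + d) are provided for comparison; Dice
dominates Jaccard off-diagonal, a property the tests check. A pair with
an empty union is given s = 0 with a warning — it cannot arise from a
valid single matrix (no all-zero rows) but can in principle after
subsetting, and 0 (maximal dissimilarity, no shared band) is the only
defensible convention under a coefficient that ignores d.

Pooled similarity is Jaccard on the concatenated matrix, i.e.
(Σ a)/(Σ union) over assays — not the mean of per-assay similarities.

## UPGMA

Clustering operates on distances d = 1 − s. At each step the two clusters
with the smallest **arithmetic average of all leaf-pair distances** are
merged (size-weighted Lance–Williams update — UPGMA proper, not WPGMA).
The merge height recorded is that average distance; in the ultrametric
Newick export a node merged at height h sits at depth h/2, so every
root-to-leaf path has equal length. MVSP and similar legacy programs
cluster the similarity matrix directly; since d = 1 − s is strictly
monotone, the topology is identical either way.

Printed similarity matrices are rounded to 3 decimals, so exact ties in
average distance are common. The tie-break is deterministic and
documented: among tied cluster pairs, the pair whose lexicographically
smallest leaf label is first wins, then the smaller partner label. Newick
child order is likewise deterministic (subtree containing the smallest
leaf first). Height monotonicity is asserted on every construction (UPGMA
cannot produce inversions; the assertion guards the implementation).

The implementation is validated two independent ways: against a
brute-force clusterer that re-averages all leaf pairs from the original
matrix at every step (500 seeded random matrices up to 7 leaves), and
against `stats::hclust(method = "average")` merge heights.

## The packaged bottle gourd study

The fixtures under `inst/extdata/` transcribe the printed band data of a
diversity study of ten Egyptian bottle gourd cultivars: the 17-band
SDS-PAGE protein matrix, the two 5-band isozyme matrices with intensity
grades, the 8-primer SCoT count table and the printed protein, pooled and
SCoT similarity matrices. `reproduce_paper()` recomputes every
desk-reproducible number; the analysis drivers under `analysis/` narrate
the same computations. Reproduced exactly: 29.41% protein polymorphism,
the four M⁻ markers (S8 at 126 and 100 kDa, S6 at 23 kDa, S2 at 11 kDa),
the complete protein similarity matrix, 26 of the 27-locus pooled
matrix's 45 printed cells plus the extremes (0.778 for S2–S8; 1.000 among
S3, S4, S5, S7, S10), the isozyme 20% polymorphism with the Rm 0.6 band
confined to S1 and S2, the SCoT 44/22/50% counts, and the first merge of
the SCoT tree (S5–S7 at d = 0.111).

### Errata in the printed tables

Reproducing a paper from its own printed data is also an audit of that
data. Three internal inconsistencies surfaced; the package documents them
instead of reproducing them:

1. **Pooled similarity cell (S2, S7).** The printed band matrices give
   a = 23 shared bands over a union of 27, so Jaccard = 0.852. The pooled
   table prints 0.825 — the same digits transposed. All other 44 cells
   reproduce to every printed decimal, so the band matrices and the
   computed 0.852 are taken as authoritative.
2. **The SCoT dendrogram prose.** The narrative describes a first split
   {S1, S2, S3} vs {S4…S10} with sister pairs {S4, S5} and {S6, S7}. No
   standard linkage (UPGMA, WPGMA, complete, single) produces that tree
   from the printed SCoT similarity matrix: the matrix yields first merge
   (S5, S7) — which the same narrative *also* states, via the 0.889
   maximum — then (S8, S9), with k = 2 split {S2, S3} vs the rest. The
   matrix-derived topology is asserted in the regular tests; the
   acceptance test records the prose claims and their failure. (The
   protein dendrogram prose has the same defect: S1 is Jaccard-identical
   to five other cultivars and so cannot be sister to S2.)
3. **The isozyme-only similarity table** prints S1 at similarity 0
   against every other cultivar although S1 shares 4 of 5 bands per
   enzyme with most of them; it is not derivable from the printed isozyme
   matrices under any binary coefficient and is excluded from
   reproduction entirely.

Two further printed quantities are non-reproducible by construction
rather than error: the per-primer EMR/Rp/MI values (no standard formula
matches, e.g. EMR 2.5 and Rp 5 for a primer with zero polymorphic bands),
for which the index engine is instead accepted by its algebraic
properties; and the "45.15%" mean polymorphism, which is the mean of
per-primer percentages *truncated* to two decimals (unrounded: 45.157) —
the tests accept it within 0.01.

## The synthetic generator

`synth_spec()`/`generate_bands()` emulate scored dominant-marker data:
bands grouped under primers, per-band presence frequencies (fixed or
uniform on [lo, hi]), optional planted genotype clusters, and optional
planted unique bands. With a cluster plan, each block receives a
Bernoulli template score per band and members flip it independently with
probability δ — a minimal model of gel scoring error (dropout and ghost
bands). Independence across bands and genotypes is the simplest
defensible choice; real scoring errors correlate within lanes and gels,
and the generator makes no attempt to model electrophoretic physics or
primer-binding chemistry. Passing the recovery tests therefore shows the
*pipeline* is correct and noise-tolerant, not that any particular real
data set will cluster cleanly.

All randomness flows from one integer seed with a documented stream
order (planted carriers, band frequencies, templates/flips, all-zero-row
resampling), so matrices are reproducible across sessions and releases.
All-zero rows are redrawn (a never-observed band is not a locus); after
100 failed redraws a single random carrier is forced — reachable only at
extreme frequencies.

Validation problem sizes, chosen to make the checks sharp at negligible
cost: frequency calibration on a 600-band, 20-genotype matrix (within 3
binomial standard errors); cluster recovery on 10 genotypes in two
planted blocks of 5 with 40 bands, 200 replicates per noise level
(recovery is 100% at δ ≤ 0.05 and degrades only beyond δ ≈ 0.2 — run
`analysis/04_synthetic_validation.R` for the curve); planted unique-band
detection in every noiseless replicate.

## Known limitations

* PIC uses the dominant-marker form throughout; no Hardy–Weinberg allele
  frequency estimation, and no codominant PIC.
* Similarity is descriptive: no bootstrap support on similarity values or
  tree nodes, and no ordination (PCoA).
* UPGMA inherits its usual caveats — it assumes rate constancy
  (ultrametricity); for strongly non-ultrametric distances the tree is a
  summary, not an estimate of phylogeny.
* Ties broken by the documented label rule can differ from legacy
  software whose tie rule is undocumented; topologies are identical
  whenever the input has no exact ties.
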