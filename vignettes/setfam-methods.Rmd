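---
title: "Classifying SET-domain proteins from domain architectures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying SET-domain proteins from domain architectures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setfam)
```

## The problem

SET domains (~130–150 aa, named after Su(var)3–9, Enhancer of zeste and
Trithorax) catalyse histone lysine methylation. Across the plant lineage
(Archaeplastida) the proteins carrying them fall into four canonical
families — E(z), Ash, Trx and Su(var)3–9 — plus a heterogeneous fifth group
(Orphan, SETD, TPR) of low sequence similarity. Family membership is
largely determined by the *ordered domain architecture* of a protein: which
reader/binding domains (AWS, PHD, PWWP, FYR, SRA, WIYLD, PreSET, PostSET,
…) flank the SET domain, in which order, and how many times.

`setfam` turns this inventory analysis into a reusable pipeline over a
16-species Archaeplastida panel (glaucophyta → chlorophyta → charophyta →
marchantiophyta → bryophyta → pteridophyta → gymnosperm → angiosperms):
candidate identification from proteomes and transcriptomes, rule-catalog
classification, nearest-homolog naming, per-species counts and phyletic
presence/absence matrices, first-appearance dating of domains, and a
distance-based phylogeny of the classifiable SET domains.

## The rule catalog

The classification rules live in a human-editable text file
(`inst/extdata/set_catalog.txt`): one row per protein type, with a
hierarchical id (`II-2C` = class II, subclass 2, subdivision C), a
hyphen-joined backbone (the signature N→C domain sequence), the recorded
co-occurring "extra" domains, and a 16-character `+/-` phyletic string.
Keeping the catalog as reviewable text was deliberate: the transcription of
the source tables must be auditable line by line, and the catalog-fidelity
test compares it string-for-string against an independent in-test copy.

Three design points deserve explanation:

* **Per-family Orphan rows.** The Ash, Trx and Su(var) tables each contain
  an Orphan row whose printed architecture is just `SET`. Three entries
  cannot share one backbone for exact matching, so these rows are flagged
  `orphan`: they are exempt from backbone uniqueness and are never
  exact-matched — a bare-SET protein is routed to the homology fallback,
  which decides *which* family's Orphan it is.
* **One genuinely duplicated backbone.** `PHD-PreSET-SET` is printed both
  as a Trx type (III-3D) and as a Su(var) type (IV-2B). The catalog keeps
  both rows (the later one flagged `ambig`); an exact match returns the
  first in table order together with the full candidate list, and
  `classify_all()` resolves the tie by SET-domain homology to the family
  references. Undeclared duplicates in a user catalog remain a hard error.
* **E(z) variants.** The E(z) class has no printed table, only a figure of
  seven representative domain organisations (SANT, TCR, Vn, CSR, MSL,
  ALDH-SF, PreSET combinations). The seven backbones are encoded as
  entries `I-1` … `I-7`; the ids are this package's own, since the source
  prints none, and the per-species assignments follow the narrative
  descriptions (SANT only in rice, Vn in the bryophyte/liverwort pair, CSR
  and MSL in *Ostreococcus*, E(z) absent from *Cyanophora* and *Volvox*).

Domain names are canonicalized case-insensitively through an alias table
(`Post-SET` → `PostSET`, `zf-C2H2` → `ZnF_C2H2`, …); unknown names pass
through flagged as extras rather than erroring, because the tables'
"Extra Domains" columns are full of one-off domains (TUDOR, LIM,
PLN03081, …) that must not derail classification.

## Classification procedure

For each protein, hits are sorted by start coordinate; hits with more than
50% reciprocal overlap are resolved by score, then length, then position.
The classifier then:

1. **strips extras** — every domain outside the class I–IV backbone
   vocabulary — to obtain the signature architecture;
2. **exact-matches** the signature against the catalog backbones. Repeat
   counts matter: `PHD-AWS-SET` (II-2B) and `PHD-PHD-PHD-AWS-SET` (II-2A)
   are different types, and an extended backbone never falls back to its
   prefix;
3. failing that, checks the **Class V signatures**: a Rubisco-LSMT
   substrate-binding domain ⇒ SETD; TPR repeats with no canonical family
   domain ⇒ TPR;
4. otherwise defers to the **homology fallback**: the SET subsequence (cut
   by hit coordinates) is globally aligned against the At/Os reference set;
   the nearest family at ≥30% identity with ≥80% coverage claims the
   protein as its Orphan (families II–IV only — E(z) has no Orphan
   subgroup). If homology is inconclusive, a family-diagnostic bigram
   (AWS⇒Ash; SRA/WIYLD or PreSET-before-SET without SRA⇒Su(var);
   PWWP/PHD/FYR before SET⇒Trx) decides; failing that the protein is a
   Class V Orphan.

An architecture with neither SET nor TPR is rejected as "not a SET-pathway
protein". Classification is total otherwise: every SET-bearing input gets
exactly one label.

The 30% identity / 80% coverage defaults operationalize "significant
homology", which the source analysis never quantifies; 30% over a ~140 aa
domain is the usual twilight-zone floor for confident family assignment,
and both knobs are exposed (`threshold`, `min_coverage`).

**Interrupted SET domains.** Some Class V Orphans carry a SET domain split
into two hits. Two SET hits separated by ≥10 residues, spanning ≤400
residues in union, *and summing to ≤200 aa of hit length* are merged into
one hit flagged `interrupted`. The third condition is this package's
refinement: without it, genuine tandem-SET architectures (IV-1C,
`SRA-PreSET-SET-SET`, two full ~140 aa domains) would be swallowed by the
merge.

## Identification and redundancy

Transcripts are six-frame translated; an ORF runs from an ATG (or from the
frame start in stop-to-stop mode) to the first in-frame stop, ties broken
by frame order (+1, +2, +3, −1, −2, −3) then 5′-most start; the longest
translation ≥100 aa (the usual transdecoding floor) becomes the predicted
protein. Candidates must carry a SET hit; the observed 200–3500 aa length
range of SET proteins is treated as a sanity window that warns rather than
drops (a strict mode drops), since it is an observation about real SET
proteins, not a defining criterion. Redundancy removal keeps the longest
sequence per locus, then collapses same-species proteins with byte-identical
SET subsequences to the longest — within species only, since cross-species
identity is biological signal, not redundancy.

## Naming

Proteins are named after their nearest At/Os homolog: capitalized homolog
name + lowercase species code (`SDG8cr`). When several proteins of one
species share a nearest homolog, all receive hyphenated letter suffixes in
input order (`SDG8cr-a`, `SDG8cr-b`, …, `-aa` after `-z`). The hyphen is a
readability choice — bare letter suffixes are ambiguous after names that
end in letters.

## Comparative summaries

`count_by_class_species()` tallies a 16×5 species-by-family matrix whose
grand total equals the input size. `presence_matrix()` rebuilds, from a
classified protein set, the same row/column layout as the transcribed
tables, which gives the round-trip test its sharpest form: generate a
synthetic proteome *from* the transcribed matrices, push it through the
whole pipeline, and require the re-summarised matrices to be identical.
`earliest_appearance()` reports the minimum-lineage-rank species in which a
domain occurs within a family, either from a classified set or directly
from the catalog's phyletic strings. One inconsistency in the source is
worth noting: *Micromonas* RCC299 is called a charophyte once in the text
but a chlorophyte in every species key; the lineage config follows the
species key.

## Phylogeny

The tree is built from SET-domain p-distances
(`d = 1 − identity` of a Needleman–Wunsch global alignment, BLOSUM62,
affine gaps 10/0.5, identity measured over aligned columns excluding
terminal gaps) and classic Saitou–Nei neighbor joining, which is exact on
additive matrices — the property the oracle tests exploit. Negative NJ
branch estimates are clamped to zero with a warning. Class V and the
family Orphans are excluded from the tree input (an
`include_family_orphans` flag restores the latter): their low similarity is
precisely why they are orphans, and they destabilise distance estimates.

Because no multiple alignment is built, bootstrap resampling uses a
*reference-anchored column set*: every sequence is aligned once to the
longest one, projecting all residues into the anchor's coordinates, and
replicates resample those columns with replacement. This is a documented
approximation — columns absent from the anchor are invisible to the
resampling — chosen over reimplementing progressive MSA. The pipeline's
tree distances use the same anchor-projected columns so that supports and
topology share one distance definition; `pdistance_matrix()` remains the
exact all-pairs alternative.

`class_purity()` scores how cleanly the four families separate on the
tree: for each family, the best Jaccard overlap between the family's leaf
set and the leaf set on one side of any edge (the full leaf set counts as
a side, so a single-family tree is trivially pure). A family forming a
clade scores 1; the acceptance condition asks for a mean ≥0.9 on simulated
four-family data.

## The synthetic-data generator

The generator emulates the study's inputs so every stage is testable
without downloads: for each `+` cell of each family's transcribed presence
matrix it emits a protein embedding the entry's backbone as fixed random
60–150 aa blocks joined by random linkers (with exactly matching hit
coordinates), plus SET-free decoys, truncated same-locus isoforms, and a
fraction of proteins realised only as transcripts whose longest ORF is the
protein (UTRs are built without adenine so they cannot spawn competing
ATGs; codon choice is rejection-sampled until the longest ORF is exactly
the protein). Defaults mirror the study conditions: all four family
matrices, one protein per cell, five decoys per species, 10% isoform and
transcript load, 5% block mutation.

Two deliberate departures from "one fixed block per domain name":

* the SET block has one divergent variant per family (~35% mutated from a
  common base) — homology is the only signal that can classify bare-SET
  Orphan rows, so family information must reside in the SET sequence, as
  it does in reality;
* each locus's SET block carries a unique 3-residue tag (positions 5–7
  encode the locus counter). Distinct paralogs are never byte-identical in
  real proteomes, and without the tag the redundancy filter would
  (correctly, per its definition) collapse same-family paralogs generated
  at mutation rate 0.

What the generator does *not* emulate: realistic amino-acid composition,
indels, domain gain/loss along a lineage tree, genuine PFAM/CD-search
score distributions, or assembly/annotation noise. Passing round-trip
tests therefore demonstrates the internal consistency of the pipeline —
classifier, summaries and filters invert the generator exactly — not
performance on real proteomes, where domain-calling errors dominate.

## Problem sizes and numerical choices

The default synthetic run (all four family tables, one protein per cell)
yields ≈160 primary proteins plus decoys and isoforms across 16 species —
the same order as the real inventory's per-species counts — and completes,
with its NJ tree, in well under a minute; the test suite and the
acceptance script size their simulations accordingly (200 random
transcripts for the ORF oracle, 8 additive matrices of 4–8 taxa for the NJ
oracle, 100 bootstrap replicates where supports are asserted). Ties are
deterministic everywhere: lexicographic ids break dedup ties, frame order
breaks ORF ties, reference name order breaks homology ties, and all
randomness flows from explicit seeds (generator configs require one; the
bootstrap takes one; RNG state is restored afterwards).

## Known limitations

* Exact-match classification is only as good as the hit table; no de novo
  domain detection is attempted beyond the SET-region homology fallback.
* The NJ tree is a stand-in for likelihood-based inference at full scale;
  its role here is the family-separation statistic, not publishable
  topology.
* The Su(var) catalog follows the 11 printed table rows even though the
  accompanying figure legend claims 17 domain combinations; the extra
  combinations are not enumerated anywhere in the source tables.
* Class V phyletic presence is narrative in the source and therefore not
  tabulated in the catalog; `presence_matrix()` is defined for the four
  canonical families.
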