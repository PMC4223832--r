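---
title: "Methods: detecting and comparing CRISPR-Cas systems across strains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and comparing CRISPR-Cas systems across strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `spacerscape`, and what its synthetic-data tests do and
do not demonstrate about real data.

## Coordinates and containers

All internal coordinates are 0-based half-open on the forward strand;
GFF3 output converts to 1-based closed, BED input is taken as 0-based
half-open. Contig boundaries are hard: no feature spans contigs (assembly
gaps inside one pseudochromosome are N-runs within a single sequence and
are handled by the locus-merging rule instead). The strain is the unit of
aggregation; species, phylotype, location and biome groupings come only
from the metadata table, never from sequence.

## Array detection

A CRISPR locus is modelled as `n >= 2` occurrences of one repeat unit of
length 21–48 nt, separated by spacers of 0.6–2.5 times the repeat length.
Detection proceeds in four steps:

1. **Seeding.** Exact 16-mers that recur at a spacing compatible with one
   repeat–spacer period (about 33–168 nt under the defaults) anchor
   candidate regions. Nearby anchors are clustered, and a handful of seeds
   per cluster (most frequent periods first) are tried.
2. **Candidate repeat.** A seed pair is extended by exact matching into a
   candidate repeat, capped at the maximum repeat length and at one period.
3. **Chaining.** All occurrences of the candidate within the identity
   threshold (80% against the candidate, via mismatch-tolerant pattern
   matching) are collected; the longest run of consecutive occurrences
   whose gaps are admissible spacer lengths becomes the array. Near-
   duplicate occurrence starts are collapsed to the best-matching one.
4. **Boundary refinement.** With occurrence starts fixed, repeat
   boundaries are refined by per-column conservation across occurrences.
   The conservation threshold is `max(0.8, 1 - 1/n)`: full agreement for
   small arrays, at most one deviating occurrence for larger ones.
   Trimming removes boundary columns below the threshold with a
   three-column lookahead, because a single chance-conserved column at the
   boundary must not shield unconserved columns just inside it. Extension,
   by contrast, only proceeds through *unanimous* columns: a column in
   which one occurrence deviates is statistically indistinguishable from a
   chance-conserved spacer-edge column, so extension demands more evidence
   than retention. This asymmetry keeps noiseless boundaries exact while
   staying tolerant of mutated repeats.

Overlapping candidates are resolved deterministically: more repeat
occurrences, then longer span, then leftmost. Loci are always reported on
the forward strand; leader/trailer orientation is metadata, never a
coordinate flip.

The **confirmed** filter mirrors the behaviour of the CRISPRFinder-style
"confirmed" call that multi-strain surveys restrict themselves to, and is
an explicit approximation since those criteria are not published in full:
at least 3 repeat occurrences, every occurrence within 80% identity of the
consensus, and mean pairwise spacer self-identity at most 0.8 (this last
rule rejects tandem repeats, whose "spacers" are all alike). Spacer
self-identity is a cheap left-anchored positional identity, not an
alignment; it only needs to separate near-identical from unrelated
spacers. Locus size is measured from the first repeat start to the last
repeat end, without flanking leader sequence.

`brute_force_scan()` is the reference implementation: it enumerates every
(start, period) pair with an exactly repeated unit, chains exhaustively,
and applies the same refinement and acceptance rules. The test suite
asserts agreement with the seeded detector on kilobase-scale sequences.

**Merging.** Adjacent loci are combined only when the gap between them is
an N-run (up to 10 non-N bp tolerated at each flank, at most 2 kb long)
and the consensus repeats are identical or exact reverse complements. The
gap is retained as a spacer interval so that repeats and spacers still
tile the locus; gap pseudo-spacers contain N and are excluded from the
spacer catalog.

**Orientation.** The leader end is placed adjacent to an associated cas
cluster when one exists; otherwise a degenerate terminal repeat (terminal
consensus identity lower than the opposite terminal by more than 0.05)
marks the trailer; otherwise the orientation is `unknown`, and
leader-relative spacer indices are undefined.

## Cas subtypes

Clusters are maximal runs of cas-vocabulary genes with intergenic gaps of
at most 500 nt; an interleaved non-cas gene splits a run. Classification is
set-based and order-invariant: the highest-priority signature whose
required genes are present and forbidden genes absent wins, and a cluster
without *cas3* — the type I signature gene — is never labelled. The shipped
signature table encodes I-E (`cas3, cse1, cse2`), I-C (`cas3, cas8c`), I-B
(`cas3` plus the larger cst1-related replacement of cas8b), I-U_csb3
(`cas3, csb3`), I-U_csx17 (`cas3, csx17`, cas1 forbidden) and I-U_Sa
(`cas3, csb1, csb2`, cas1/csb3/csx17 forbidden). The exact gene orders of
the three I-U designations are not published as text, so this table is a
reconstruction meant to be edited via YAML (`signatures_from_yaml()`)
against a reference figure when one is available. Completeness requires
cas1 and cas2 except for subtypes that forbid cas1, which are complete by
their own definition. Gene names are normalized case-insensitively through
an alias table (cse1 = cas8e, cas8c = csd1, cst1-like variants).

A locus associates with the nearest cluster on the same contig within
1 kb edge-to-edge; paired loci — two confirmed arrays whose consensus
repeats are exact reverse complements, each within the association
distance of one internal cluster — both associate with it.

## Matching rules

Perfect hits are exact full-length substring matches of the spacer or its
reverse complement (100% identity, 100% coverage). Partial hits are
maximal exact common substrings of at least 18 nt — two thirds of the
average repeat length, a suggested minimum for a functional spacer —
excluding spans covered by a perfect hit, so a partial hit always has
`18 <= length < spacer length`. Because only ungapped 100%-identity spans
survive these filters, exact substring search returns the same hit set as
short-query BLAST with word size 7 followed by the identity/coverage
filter: every exact span of length at least 7 contains an exact word of
length 7, so seeding loses nothing. This equivalence is why no aligner is
involved. The implementation seeds an 18-mer dictionary (`matchPDict`) and
extends seeds to maximal spans along their diagonal; the test suite checks
it against a brute-force sliding comparator on hundreds of seeded random
pairs, including reverse-complement and fragment plantings.

The self-targeting scan matches a strain's spacers against its own contigs
and discards hits overlapping any detected locus interval expanded by
100 nt (the margin is a package choice; a spacer trivially matches its own
array). Hits inside annotated prophage regions are flagged.

In summaries, a spacer counts once per target class regardless of how many
targets it hits, and fractions are over distinct canonical spacers within
the group. One published worked example is treated deliberately: the
CNX-481 cytochrome P450 spacer is described in survey text as a perfect
self-match, but the printed spacer and chromosomal sequences diverge after
32 nt. The printed sequences are taken as authoritative, so the pair is
reported as a 32-nt partial hit.

## Spacer catalog and array comparison

Spacers are deduplicated on their canonical form, the lexicographic
minimum of the sequence and its reverse complement, because array strand
is not always known and strand ambiguity must not split identical
spacers; raw-strand counts are reported alongside for comparison with
surveys that compared extracted strings directly. Sharing means presence
in at least two distinct strains; same-strain copies count once.

Homologous loci across strains are operationalized as: identical (or
exactly reverse-complementary) consensus repeats *and* at least one shared
canonical spacer, transitively. Alignment operates on spacer tokens, not
concatenated nucleotides: the longest common subsequence over tokens
aligns identical spacers in single columns and inserts gaps elsewhere,
which is exact for the identical-spacer columns that the comparison
interprets, and avoids nucleotide-aligner heuristics. Progressive order
for more than two arrays is descending array length (ties by strain then
locus id). Group-specific blocks are maximal runs of columns occupied by
every member of exactly one declared strain group and nobody else; they
are reported as insertions *or* deletions, never directionally.

Variant groups collect equal-length spacers at single-linkage Hamming
distance ≤ 3 (matching the at-most-three polymorphic sites seen in
conserved 41-nt spacer variants). The distance is strand-aware — the
minimum over the two orientations — because canonical folding is
lexicographic and a single substitution near a sequence end can flip which
strand is canonical.

## Statistics

Counts are normalized per Mb of genome or per annotated gene. The battery
follows the omnibus-then-pairwise scheme: Kruskal-Wallis (ties-corrected
H, chi-square reference) across species, location, biome and
within-species phylotypes; pairwise Wilcoxon rank-sum tests only when the
omnibus p < 0.05. The rank-sum test enumerates the exact null when the
combined sample size is at most 10 and there are no ties, and uses the
normal approximation with continuity correction otherwise — exactness at
small n keeps the gated pairwise comparisons reproducible. Student's
t-test (pooled variance) compares prophage-matching spacer fractions
between prophage-harbouring and prophage-free strains, and ordinary least
squares provides R² for content-vs-prophage correlations. All tests are
two-sided; no multiple-testing correction is applied, matching the survey
practice this pipeline mirrors — both decisions are deliberate and
documented rather than configurable. Degenerate inputs are defined away:
all-tied groups give H = 0 with p = 1, and a constant response gives
R² = 0.

The location/biome restriction of a shared spacer uses the inclusive OR —
confined to one location *or* one biome — with both component fractions
also reported.

## The synthetic study

`simulation_config()` defaults define the study conditions: 10 strains of
1 Mb at 70% GC split 5/4/1 across three *Salinispora*-like species over
seven collection sites; Poisson(4.4) arrays per strain; 8–25 spacers of
35–44 nt per array; subtype-specific repeats of 29 nt (I-E, I-B) and
37 nt (I-C, I-U); 60% of arrays cas-associated and 60% of cas-associated
I-E arrays paired; Poisson(1.5) prophages of 10 kb per strain; a 20-record
known-MGE database; 11% of distinct spacers given a perfect prophage
protospacer, 1.1% a known-MGE protospacer, 5% a planted central 24-nt
partial span, 2% a self-target copy inside a housekeeping gene; 68% of
distinct spacers unique; 40% of shared spacers location/biome-restricted;
one four-strain clade sharing a homologous locus with three
subclade-specific blocks (lengths 4/3/3 around a 10-token backbone); and
one conserved 41-nt spacer with five SNP variants across three sites
(3 + 1 + 1). Planting is deterministic given the seed (counts are rounded,
not drawn), so recovered fractions equal planted fractions exactly.

Two generator conventions matter for interpretation. First, planted
features never overlap and are separated by background, and the single
background bases flanking each array are chosen so that the spacer-edge
columns are not unanimous; within a strain, spacers are also arranged so
that no array has unanimous first or last spacer characters. This makes
planted boundaries *identifiable*: without it, a column in which every
spacer coincidentally ends with the same base is mathematically
indistinguishable from a repeat column, and no detector could place the
boundary. Real data contains such ambiguities, plus degenerate repeats,
nested arrays and mobile-element insertions that the generator does not
model; passing recovery tests therefore demonstrates correctness of the
machinery under the stated model, not detector performance on arbitrary
genomes. Second, background is i.i.d. at the configured GC, so the
genomes lack the repetitive structure (rRNA operons, transposons) that
produces candidate-array noise in real assemblies; the negative controls
only show the false-positive rate under that background model.

Scoring matches loci by at least 50% reciprocal overlap, spacers by
(strain, canonical sequence), subtype labels through interval-overlapping
clusters, hits by (canonical, target, class, category), blocks by exact
token runs, and the variant group by membership.

## Problem sizes

The shipped analysis and the acceptance checks run the default 10-strain,
1-Mb study (plus a 2%-repeat-mutation variant for detection robustness),
chosen as the smallest configuration that exercises every feature class
with realistic per-strain content; unit tests use 3-strain, 120-kb
configurations and kilobase-scale fixtures. The worked-example
computations are instantaneous.

## Known limitations

* The confirmed filter approximates an unpublished external tool's
  criteria; borderline loci (2 occurrences, near-identical spacers) may be
  classified differently than by that tool.
* Repeat secondary structure, repeat-family classification, PAM analysis
  and leader-motif discovery are out of scope, as are prophage prediction
  (regions are consumed as input) and phylogeny construction (trees are
  consumed as newick).
* Partial-hit planting records the planted span; flanking coincidences can
  lengthen the detected maximal span, so planted-hit scoring matches on
  identity of spacer/target/category, not span length.
* Insertion-versus-deletion polarity of clade blocks and acquisition
  dating are deliberately not inferred.
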