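---
title: "Detecting clade-specific signature indels, operons and CXXC motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting clade-specific signature indels, operons and CXXC motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csidetect)
```

## The screen and its assumptions

A conserved signature indel (CSI) is a clade-restricted insertion or
deletion embedded in conserved sequence. The screen implemented here
assumes its inputs are *trusted alignments*: the package consumes gapped
protein multiple sequence alignments (it does not build them) and treats
alignment columns as homology statements. Everything downstream is then a
deterministic function of three explicit criteria.

**1. Group-differential gap blocks.** Given an in-group / out-group
partition, each column is classified from two fractions: the fraction of
in-group records holding a residue, and the fraction of out-group records
holding one. A column supports an *insertion* (relative to the in-group)
when the first fraction is at least `1 - max_ingroup_missing` and the
second at most `max_outgroup_sharing`; a *deletion* column is the mirror
image. Candidates are the maximal runs of same-type columns — greedy
extension, so two runs separated by even one non-qualifying column are
distinct candidates. With both tolerances at their default of 0 this is
the strict reading of "uniquely shared by all members": every in-group
sequence must hold residues in every column of the run and no out-group
sequence may.

The defaults deliberately encode "all". Real clade indels are sometimes
*ragged* — member lineages carry 5, 6 or 7 residues of the same insert —
and the trailing columns of a ragged insert are gapped in part of the
in-group. Detecting such an indel at its full width requires opening
`max_ingroup_missing` to roughly the fraction of members lacking the
longest variant; the reported size range (`size_min`–`size_max`) then
comes from the per-sequence residue counts of the *carrier* group within
the run. For insertions the carriers are the in-group; for deletions the
in-group holds nothing in the run, so sizes are taken from the out-group
— the material the in-group lacks, which is what a "2 aa deletion" means.

**2. Flank conservation.** A column is *conserved* when a single residue
reaches a majority of `conservation_threshold` across records, with gaps
and `X` counted in the denominator (a mostly-gap column can never be
conserved) and ties broken alphabetically. The screen counts conserved
columns within `flank_window` columns on each side of the candidate,
excluding the candidate itself and truncating at the alignment edges, and
requires `min_conserved_flank` on *both* sides. Conservation is scored
across both groups by default — the flanks are evidence that in-group and
out-group sequences are genuinely alignable around the indel — with
`conservation_scope = "ingroup"` available when the out-group is too
diverged for that to be a reasonable demand.

**3. Specificity.** Independently of the column-wise pattern, each
sequence either carries the indel as a unit (any residue in the interval,
for an insertion; an all-gap interval, for a deletion) or does not. The
verdict is `strict` when carriage coincides exactly with the partition,
`tolerant` when violations stay within the configured fractions (or a
single out-group sharer under `allow_isolated_exception`, the "isolated
exception" case), and `rejected` otherwise. Real screens also check
specificity against large public databases by sequence search; that step
is out of process here — the package exports the 60–100 aa validation
segment around each hit precisely so that such a search can be run
externally, and computes specificity only within the supplied panel.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `conservation_threshold` | 0.8 | fraction | reproducible surrogate for by-eye conservation; no published numeric cutoff exists, so it is exposed |
| `flank_window` | 35 | columns | centre of the conventional 30–40 residue neighbourhood |
| `min_conserved_flank` | 5 | columns | lower end of the conventional 5–6 conserved residues |
| `max_ingroup_missing` | 0 | fraction | "all members"; raise for "most", or for ragged indels |
| `max_outgroup_sharing` | 0 | fraction | strict specificity |
| `validation_segment_length` | 80 | residues | middle of the 60–100 window; clamped to that range |
| `linkage_bp` | 200 | bp | same-strand genes closer than this are likely co-transcribed; strict `<` |
| `merge_bp` | 100 | bp | boundary gap under which adjacent external operon calls are joined; strict `<` |

## Coordinates and report conventions

All user-facing coordinates are 1-based and inclusive: column indices,
reference-protein positions, and genomic base pairs. (Interval
arithmetic is easier half-open and 0-based, but R's indexing and the
field's file formats — GFF3, GenBank — are 1-based, and mixing
conventions at the API surface is the classic source of off-by-one
bugs.) `map_column_to_reference()` converts alignment columns to ungapped
reference positions by cumulative residue count; a column where the
reference is gapped maps to the nearest preceding reference residue, 0 if
none, which makes the mapping total and monotone.

The reported region of a CSI (`region_start`–`region_end`) runs from the
leftmost conserved column of the passing left flank to the rightmost of
the right flank. Published signature tables chose their excerpt bounds by
hand; flank-to-flank is a reproducible surrogate, so when comparing to a
published region the honest check is containment of the indel, not
equality of endpoints. The signature block itself is lossless by
construction: dash = identity with the top (reference) line, letter =
difference, `.` = gap against a reference residue; `parse_signature()`
inverts it exactly, and that round-trip is asserted for every emitted
record in the test suite.

Intergenic distance is `start(b) − end(a) − 1` on 1-based inclusive
coordinates: abutting genes give 0, overlapping coding regions give
negative values, and an overlap always links its pair regardless of
thresholds. Both distance thresholds are strict inequalities, matching
their verbal definitions ("< 200 bp", "< 100 bp"). `predict_operons()`
partitions the gene set — every gene lands in exactly one call — and
never merges across a run boundary created by a ≥ `linkage_bp` gap;
`merge_operons()` applies the sub-`merge_bp` join rule to an operon
table, flagging joined calls, which is how externally predicted operons
that split a cluster are reconciled.

Arrangement comparison is exact equality of the ordered (family, strand)
tuple over the anchor-anchored window of the reference's length;
orientation is normalised so a minus-strand anchor reads left-to-right,
making "downstream" mean 3′ of the anchor in every genome. A zero-length
reference matches every genome vacuously (documented degenerate case).

For CXXC scanning, `X` means any residue *including* cysteine by default
(`CCCC` contains overlapping motifs); the strict reading — "any other
amino acid" — is available as `strict_x = TRUE`. Both a full overlapping
scan and a greedy left-to-right non-overlapping selection are provided;
in real zinc-finger proteins motifs are disjoint, so the policies agree
there, and non-overlapping counts can never exceed overlapping ones.

## What the generator emulates — and what it does not

`sim_family_alignment()` uses an i.i.d. column model: a fixed fraction of
columns invariant across *all* sequences (both groups share the conserved
backbone, as real signature alignments do), the rest mutated
independently per sequence at a constant substitution probability, and
the indel planted as a contiguous block of residues-vs-gaps. Defaults are
the study conditions used throughout the package's verification: 24
in-group vs 12 out-group sequences, a 600-residue reference, half the
columns invariant, substitution probability 0.3, and planted sizes
spanning 1–65 residues. A null mode plants a *shared* gap block (random
subset of both groups) to confirm that non-differential alignment gaps
are never called.

This is deliberately not a phylogenetic simulator: there is no tree, no
rate heterogeneity, no indel drift, and truth is exact by construction.
Passing the recovery study therefore shows that the detector implements
its stated criteria correctly, not that those criteria are optimal on
real alignments — real families have correlated substitutions, alignment
errors near gaps, and partial homologs, all of which the tolerance
parameters exist to absorb and none of which the generator produces.
Likewise `sim_genome_set()` lays coordinates out left-to-right so planted
intergenic gaps are exact, and `sim_proteome_with_motifs()` excludes
background cysteines and spaces planted motifs ≥ 8 residues apart so the
planted count is the true count under every scanning policy.

## Problem sizes and numerical choices in the test suite

The recovery study runs 100 planted and 100 null families (about half a
minute); oracle equivalence checks run 500 random alignments of at most
8 × 40 against a brute-force interval enumeration and 500 random
sequences against an all-positions motif oracle; the neighborhood survey
uses the 26-genome / 24-cluster configuration. These sizes make the suite
complete in about a minute while keeping every check exhaustive at its
scale. Degenerate inputs are pinned by tests: candidates at alignment
edges fail their truncated flank, an all-gap column has no majority
residue, a missing anchor is a reported miss rather than an error, and
empty proteomes yield empty (typed) tables.

## Known limitations

* Specificity is judged only within the supplied out-group panel; the
  package intentionally has no networked search step.
* Region endpoints are a surrogate (flank-to-flank) and will not
  reproduce hand-chosen published excerpt bounds exactly.
* Ragged indels require the user to open `max_ingroup_missing`; the
  strict default reports only their shared core.
* Zinc-finger *pairing* of CXXC motifs is structural knowledge and is not
  inferred from sequence.
* Operon calls rest on distance/strand heuristics; no promoter or
  terminator evidence is used.
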