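---
title: "Tracing exon-intron structural changes in gene subfamilies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing exon-intron structural changes in gene subfamilies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonEvo)
```

## The problem

Plant MADS-box genes (and many other gene families) evolve not only by
point substitution but by changes to their exon-intron architecture:
intraexonic insertions and deletions, recruitment of noncoding sequence
into exons (exonization) and the reverse (pseudoexonization), intron gain
and loss, and gain or loss of whole exons.  These structural changes
create alignment columns that are not homologous — a frameshifting indel
destroys the homology of everything downstream, and independent changes at
the same position in different lineages can be forced into the same
columns — so treating a CDS alignment as if every column were homologous
distorts both the alignment and any phylogeny built from it.

`exonEvo` implements a structure-aware comparative workflow: build a
codon alignment with exon boundaries mapped into alignment coordinates,
refine gap placement exon by exon, classify every gap (and every exon
count difference) into a structural-change mechanism, place each event on
a rooted phylogeny by maximum parsimony, and reconstruct the exon-intron
structure of ancestral genes at the internal nodes.  A simulator with a
fully recorded event history makes every stage testable without external
data.

## The data model

A `GeneModel` holds one gene's CDS, its exon lengths in transcript order,
and (when genomic sequence is available) intron and flanking noncoding
sequences.  The invariant is strict: the concatenation of the exon
sequences equals the CDS byte for byte.  The CDS length need not be a
multiple of three — frameshifted descendants are legal inputs, because
frameshifts are among the events being studied.  A `FamilySet` collects
the models plus a provenance log of every filtering decision, and a
`CodonAlignment` stores the alignment matrix with a per-row map from
alignment column to CDS position, per-row exon boundary columns, and a
per-column homology mask.  Terminal exon lengths include the stop codon;
that convention makes published per-exon lengths sum to the CDS length,
and it is only a reporting convention (a flag at model construction
decides nothing downstream).

Coordinates are 1-based inclusive in GFF3 files and half-open inside
`IRanges`, the standard Bioconductor convention, so there is no
off-by-one ambiguity at the I/O boundary.

## Filtering rules

Two quantitative retention rules are applied by `filterModels()`: coding
sequences shorter than 400 bp are excluded as uninformative, and among
same-species sequences whose pairwise CDS identity exceeds 0.95 —
operationally alleles of one gene — exactly one survives (the longest
CDS, ties broken by identifier).  Identity is computed on a global
alignment with match 1 / mismatch 0 and affine gaps (open 10, extend
0.5), counting matches over non-terminal-gap columns; the choice of
scheme matters little at a 0.95 threshold but is fixed and documented so
the rule is reproducible.  For loci with alternative transcripts,
`selectTranscript()` keeps the isoform with the fewest detected
structural events against its nearest reference, breaking ties by total
event length and then by transcript id.

## Alignment

Real analyses normally start from a curated protein alignment:
`projectProteinAlignment()` expands each aligned residue into its source
codon (gaps become `---`), verifies every row against its CDS under the
standard genetic code, and appends a terminal stop codon ungapped when
present.  For synthetic data the package carries its own progressive
aligner (`progressiveAlign()`): profile-profile dynamic programming along
the input tree as guide tree, so no external aligner is ever required by
the test suite.  It is deliberately minimal and is not a replacement for
a curated alignment on real data.

All pairwise steps share one affine-gap DP engine with match +2,
mismatch −3, gap open −5, gap extend −2 (a gap of length L scores
`open + L·extend`) and a fixed tie-break order — diagonal, then up, then
left — so every alignment is reproducible to the byte.  The scheme is
exposed everywhere via an explicit `scheme` argument.

`refineExonByExon()` then relocates gap runs without changing any row's
sequence.  Rows sharing a byte-identical gap run move as one group
(otherwise a clade-wide gap could never relocate, because any single row's
move would transiently split the shared gap).  Placements are ranked by
sum-of-pairs score; among score ties the refinement prefers placements
that do not straddle another row's exon boundary, then placements flush
against a boundary, then the leftmost placement.  A straddling placement
is kept only when it strictly outscores every alternative, and is flagged.
The sum-of-pairs score never decreases.  The boundary-aware preferences
codify, as a deterministic rule, the kind of manual exon-by-exon
adjustment a careful annotator performs; they make no claim of
reproducing any particular manual alignment.

## Event classification

`detectEvents()` walks the consensus exon blocks (boundary columns
supported by at least half of the annotated rows, clustered with a 12-bp
tolerance so event-shifted boundaries do not fragment the consensus) and
attributes every gap column to an event or to the mask:

* **Whole-exon changes.**  An exon bracketed by one row's own boundaries
  in which the other rows are predominantly gapped is a whole-exon
  event.  If the missing sequence aligns to the partner's noncoding
  sequence it is exonization-class; if it aligns nowhere (coding or
  noncoding) it is an indeterminate exon gain/loss refined by parsimony.
  Anchoring the call on the annotation makes both the call and the event
  length robust to gap fragmentation, which is otherwise common when a
  unique exon has no homologous counterpart to align against.
* **Boundary gaps.**  A gap run abutting a consensus boundary is tested
  against the gapless rows' flanking intron (or UTR at the termini):
  alignable means exonization/pseudoexonization class, with polarity left
  to parsimony.  Segments shorter than the alignability span stay
  indeterminate indels — a 3-bp boundary gap simply cannot carry evidence
  of noncoding homology.
* **Interior gaps.**  Gap columns are partitioned by their gap signature
  (the set of rows gapped there); each maximal run of one signature is
  one intraexonic indel candidate, so rows sharing an identical run form
  one event's carrier group and nested events (as in the stacked 33 + 66
  bp insertions of the packaged `capsella_nested_insertions` fixture)
  resolve into separate stacked events.  When more than two distinct
  signatures interleave in one gapped region the region is flagged as an
  indel hotspot and handed to masking instead of being force-classified.
* **Intron gain/loss.**  An annotated row lacking a consensus boundary
  whose exon aligns perfectly (identity at least 0.9 on each side of the
  junction, junction within 3 bp) to two neighbouring exons of a
  boundary-bearing row is an intron change; the symmetric case — a
  minority clade carrying an extra boundary inside a consensus block — is
  detected the same way with the roles swapped.  No gaps are involved;
  only the exon numbers differ.
* **Stop-codon events.**  At the 3' terminus, `detectStopCodonEvents()`
  distinguishes readthrough exonization (the partner's stop codon columns
  are substituted, not gapped, and the coding extension aligns into the
  partner's UTR) from frameshift-driven pseudoexonization (a non-triplet
  indel upstream creates a premature in-frame stop; the emitted
  pseudoexonization is linked to its causal indel).

Alignability is operationalised as: the segment spans at least 15 bp and
at least half of its positions are matched in the best local alignment to
the partner.  Anchoring the fraction on the query keeps 15-bp segments
robust to end trimming while preventing short spurious local hits in
unrelated sequence from qualifying.  "Perfect" alignment for intron
changes is 0.9 per sub-segment.  Both thresholds are configurable.

Single matched characters occasionally split one biological event into a
long run and a sliver; runs with identical signatures separated by at
most two columns are coalesced back into one event and re-classified.

## Parsimony mapping and ancestral structures

Each event defines a binary presence/absence character.  `mapEvent()`
minimises the number of state changes (Sankoff recursion with missing
data allowed for rows that carry no information in the event's block);
among equally parsimonious scenarios it prefers the single-origin
(Dollo-like) scenario, then the scenario whose gains sit closest to the
root, and it lists — rather than discards — the remaining alternatives.
The ancestral state at the root is fixed by designated outgroup rows when
present; otherwise the cheaper root state wins, with ties resolved toward
the agreement of the two root-adjacent subtrees and flagged when they
disagree.  Polarisation happens at this point: an indeterminate indel
whose ancestral state is "sequence present" becomes a deletion carried by
the gap rows, an exonization-class event whose ancestral state is long
becomes a pseudoexonization, and so on.  Every event costs one step
regardless of length, matching the convention of counting structural
change events rather than weighting them.

`reconstructAncestralStructure()` turns the placements into per-node
exon-intron structures.  For every root-to-leaf path and every reference
exon block, the leaf length equals the node length plus the signed event
lengths on the path below the node — exactly, not approximately; a leaf
that cannot be decomposed this way makes the exon ambiguous (or raises an
error naming the offending path in strict mode).  Root lengths are
anchored on the outgroup when one is designated, because the outgroup is
the lineage most likely to carry the ancestral state.  Exon counts adjust
on whichever side of an intron-change or whole-exon placement holds the
split or exon-bearing state, and block lengths are re-partitioned at
exon-bearing nodes when the consensus blocks reflect the derived state
(for example, when the majority of rows lost an exon and the reference
partition no longer shows it).

`rankStructuralDivergence()` scores each gene by the events on its
root-to-leaf path, weighting frame-violating events threefold (1 + a
non-triplet penalty of 2), and emits nested retention subsets — the
analytic device of progressively excluding structurally diverged
lineages to stabilise downstream phylogenetics.

## The simulator

`simulateFamily()` generates families with known histories.  The
defaults are the package's study conditions and are not tuned per run:

* **Ancestral gene**: 8 exons of 185, 79, 62, 100, 42, 42, 137, 85 bp
  (the inferred ancestral SEP1-like architecture: conserved MADS/K core,
  variable terminal exons), 200-bp introns, 300-bp flanks, stop-free
  random codons with an ATG start and a TGA terminal stop.
* **Tree**: a random 5-leaf ingroup topology plus one outgroup leaf;
  branch lengths uniform on 0.005–0.02 substitutions/site.  This models
  within-family, shallow divergence — the regime in which published
  intron-loss calls ("aligned perfectly") are actually made.  Deep
  divergence is deliberately out of scope for the simulator.
* **Substitutions**: Jukes–Cantor; never creating a premature in-frame
  stop and never touching the terminal stop codon (only structural events
  may deliberately break these).
* **Events**: Poisson per branch with mean rate × branch length; rates
  (per unit branch length) 20 intraexonic indels, 4 + 4 exonization /
  pseudoexonization, 3 intron losses, 1.5 intron gains, 1 + 1 exon
  gain/loss — roughly four events per family, indel-dominated with rarer
  boundary and exon-level events, mirroring the observed mechanism mix.
  Indel lengths are geometric in codons (mean 2) with probability 0.9 of
  being a codon multiple; boundary recruitments draw at least 15 bp
  (15 + 3·Geom), since shorter segments are undetectable against
  noncoding sequence by construction of the alignability threshold.
  Boundary events target intron-adjacent edges; stop-codon-driven
  terminal scenarios are exercised by the deterministic fixtures instead.
* **Non-overlap bookkeeping**: every event claims its ancestral-coordinate
  footprint plus a 12-bp buffer, and one junction token per intron —
  two recruitments from opposite ends of the same intron are disjoint in
  the genome but collide in alignment space, so a junction is claimable
  once.  Rejected placements are redrawn; if more than half of all drawn
  events cannot be placed, the run aborts and advises lower rates.  The
  outgroup branch stays event-free so it anchors ancestral states.

Every simulation returns a `TrueHistory`: an operation ledger
(substitutions included) and per-node snapshots such that
`replayHistory()` reproduces every leaf byte for byte.

What passing the recovery suite does **not** show: performance on deeply
diverged families, on alternative splicing, on selection- or
hotspot-driven indel processes, or on genes whose annotations are wrong.
The simulator emulates clean annotations and neutral sequence evolution;
real data add all four complications.

## Fixtures

`emitFixture()` replays six classic structural-change scenarios as
deterministic desk-scale families (an internal fixed-constant generator
keeps them seedless and independent of R's RNG; the sequences are
synthetic stand-ins, with stop-free {A,C,G} coding bodies except where a
stop codon is the point):
`brassicaceae_intron_loss` (a 84-bp exon matching 42 + 42 bp of its
homolog), `paleoAP1_stop_loss` (two point substitutions break the stop;
15 bp of UTR become coding), `euAP1_frameshift` (a 1-bp deletion
pseudoexonizes the last 8 reference-coding nucleotides),
`capsella_nested_insertions` (33 bp on a three-taxon stem, 66 bp private
and adjacent), `flc_exon3` (62 → 68 bp via two 3-bp changes on one stem)
and `flc_exon_loss` (terminal exon lost on a stem; seven exons remain).

## Numerical and degenerate-input choices

* DP tie-breaks are fixed (diagonal, up, left); profile columns score by
  residue-frequency products; existing gaps in a profile are neutral.
* `N` scores zero against everything.
* Empty queries/targets are errors in pairwise alignment, `NULL`/`FALSE`
  in scans and alignability tests.
* An unterminated ORF (no stop in any frame within the terminal exon plus
  200 bp of flank) is a hard error in stop-codon classification.
* Noncoding scans truncate at 200 kb with a warning.
* Refinement relocates runs at most 30 columns per pass (three passes);
  gap placement virtually always stabilises after one.
* The simulation-scale choices (5 + 1 leaves, ~4 events/family, 200
  families in the recovery suite) keep a full run on one CPU in minutes
  while leaving enough events (~750) for tight recovery estimates.

## Known limitations

* Perfectly compensated double frameshifts and events invisible to
  alignment are not detectable (by design).
* When noncoding sequence is unavailable for all partners, exonization
  cannot be distinguished from intraexonic insertion; such events stay
  indeterminate indels.
* Under the default scoring scheme a random character pair scores −1.75
  while a gap extension costs −2, so an aligner will smear sequence that
  has no true homolog across chance matches; the annotation-bracketed
  whole-exon pass exists precisely to stay robust to this, but residual
  fragmentation can still split or shift a small fraction of events in
  simulated families.
* The refinement is a codified, deterministic stand-in for manual
  exon-by-exon curation; on real data an expert may still do better.

## A worked run

```{r}
res <- runPipeline(pipelineConfig(fixture = "flc_exon3"))
eventTable(res$events)
placementTable(res$placements)
ancestralTable(res$ancestral)
```

The two 3-bp changes are placed on the `MRCA_FLC` stem branch; exon 3 is
62 bp at the root and 68 bp in the FLC-clade ancestor, with every other
exon untouched.
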