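# exonEvo

Tracing exon-intron structural changes in gene subfamilies.

Gene families such as the plant MADS-box genes evolve by point
substitution *and* by structural change: intraexonic insertions and
deletions, exonization of intronic/UTR/intergenic sequence,
pseudoexonization of formerly coding sequence, intron gain and loss, and
gain or loss of whole exons.  These events create non-homologous
alignment columns — a frameshift destroys downstream homology, and
independent changes at one position get forced together — so ignoring
them distorts alignments and the phylogenies built from them.  `exonEvo`
is for molecular evolutionists who want to make gene structure a
first-class observable: it classifies every gap and every exon-count
difference into a mechanism, places the events on a phylogeny, and
reconstructs ancestral exon-intron structures.

## What it computes

Given gene models (CDS + exon annotation + genomic context), a rooted
tree, and optionally a protein guide alignment:

1. **Exon-boundary-aware codon alignment** — protein-to-codon projection
   (or a built-in progressive aligner for synthetic data), exon
   boundaries mapped into alignment coordinates, gap placement refined
   exon by exon under a deterministic affine-gap scheme
   (match +2 / mismatch −3 / gap open −5 / extend −2).
2. **Event classification** — for homologous exon blocks: gaps interior
   to an exon are intraexonic indels; gaps at exon boundaries whose
   missing sequence aligns to the partner's noncoding sequence (local
   identity ≥ 0.5 over ≥ 15 bp) are exonization/pseudoexonization; whole
   exons alignable nowhere are exon gain/loss; one exon matching two
   neighbouring exons of a partner at ≥ 0.9 identity per segment, with no
   gaps, is an intron gain/loss; stop-codon readthrough and
   frameshift-induced premature stops are classified at the 3' terminus.
3. **Maximum-parsimony placement** — each event is a binary
   presence/absence character minimised over branch assignments
   (single-origin, Dollo-like scenarios preferred at ties; root state
   anchored by outgroups), which also polarises insertion-vs-deletion and
   gain-vs-loss calls.
4. **Ancestral structures** — per-node exon counts and lengths such that
   every leaf's exon lengths equal the root lengths plus the signed event
   lengths along its path, exactly; plus a per-gene structural-divergence
   ranking with nested retention subsets.
5. **Simulation** — `simulateFamily()` evolves a MADS-box-like 8-exon
   ancestor (185, 79, 62, 100, 42, 42, 137, 85 bp) along a random tree
   with a fully recorded event ledger (`TrueHistory`), so detection and
   placement can be scored against a known truth; `emitFixture()` replays
   six classic worked scenarios deterministically.

## A worked example

```r
library(exonEvo)

res <- runPipeline(pipelineConfig(fixture = "flc_exon3"))
placementTable(res$placements)
#>    event_id             mechanism exon_index signed_length branches loss_branches cost n_alternatives
#> 1   bnd_001 intraexonic_insertion          3             3 MRCA_FLC                  1              0
#> 2 indel_002 intraexonic_insertion          3             3 MRCA_FLC                  1              0
ancestralTable(res$ancestral)[, 1:3]
#>           node_id exon_count               exon_lengths
#> root         root          8 185,79,62,100,42,42,137,85
#> MRCA_FLC MRCA_FLC          8 185,79,68,100,42,42,137,85
#> outgrp     outgrp          8 185,79,62,100,42,42,137,85
```

Two 3-bp changes land on the FLC-clade stem branch: exon 3 is 62 bp in
the family's ancestor and 68 bp in the FLC-clade ancestor.  With
`outDir` set, `runPipeline()` writes the full report bundle (event table,
placements, ancestral structures, divergence ranking, boundary map,
masked alignment, NHX-annotated tree, summary) deterministically —
identical config and seed give byte-identical files.

```r
sim <- simulateFamily(simConfig(seed = 7))
structuralLedger(ledger(sim$history))[, c("branch", "mechanism", "exon_index", "length_bp")]
#>     branch             mechanism exon_index length_bp
#> 159     g3  intraexonic_deletion          3         3
#> 227     g2           intron_loss          1         0
#> 364     g5 intraexonic_insertion          2         2
```

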