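#' @include AllClasses.R simulate.R
NULL

FIXTURE_NAMES <- c("brassicaceae_intron_loss", "paleoAP1_stop_loss",
                   "euAP1_frameshift", "capsella_nested_insertions",
                   "flc_exon3", "flc_exon_loss")

# deterministic ancestral state for fixtures: CDS body over {A,C,G} (which
# cannot contain a stop codon in any reading frame), ATG start, TGA
# terminal stop; introns and flanks over the full alphabet.  All sequences
# are synthetic stand-ins generated by a fixed LCG, so fixtures are
# byte-identical across calls and never touch R's RNG.
fixtureAncestralState <- function(exonLengths, rng, intronLength = 200L,
                                  flankLength = 300L) {
    total <- sum(exonLengths)
    stopifnot(total %% 3L == 0L)
    cds <- lcgSeq(rng, total, c("A", "C", "G"))
    substr(cds, 1L, 3L) <- "ATG"
    substr(cds, total - 2L, total) <- "TGA"
    off <- exonOffsets(exonLengths)
    exonSeqs <- vapply(seq_along(exonLengths), function(i)
        substr(cds, off[i, "start"], off[i, "end"]), character(1))
    intronSeqs <- vapply(seq_len(length(exonLengths) - 1L), function(i)
        lcgSeq(rng, intronLength, c("A", "C", "G", "T")), character(1))
    newStateFromSeqs(exonSeqs, intronSeqs,
                     lcgSeq(rng, flankLength, c("A", "C", "G", "T")),
                     lcgSeq(rng, flankLength, c("A", "C", "G", "T")))
}

# assemble a fixture: evolve the ancestor along the tree applying the
# per-branch ledger operations, recording snapshots at every node
buildFixture <- function(ancState, treeText, ledger, outgroup = character(),
                         speciesOf = NULL) {
    tree <- ensureNodeLabels(ape::read.tree(text = treeText))
    n <- ape::Ntip(tree)
    rootLab <- nodeLabel(tree, rootNode(tree))
    snapshots <- list()
    snapshots[[rootLab]] <- stateToModel(rootLab, ancState,
                                         annotationSource = "fixture")
    walk <- function(node, state) {
        for (child in childrenOf(tree, node)) {
            lab <- nodeLabel(tree, child)
            ops <- ledger[ledger$branch == lab, , drop = FALSE]
            st <- applyOps(state, ops)
            sp <- if (!is.null(speciesOf) && lab %in% names(speciesOf))
                      speciesOf[[lab]] else lab
            snapshots[[lab]] <<- stateToModel(lab, st, speciesId = sp,
                                              annotationSource = "fixture")
            if (child > n) walk(child, st)
        }
    }
    walk(rootNode(tree), ancState)
    leaves <- lapply(tree$tip.label, function(t) snapshots[[t]])
    fam <- FamilySet(leaves, outgroup = outgroup)
    history <- new("TrueHistory", ledger = ledger, snapshots = snapshots,
                   tree = tree, ancestorId = rootLab)
    list(family = fam, tree = tree, history = history)
}

fixtureOp <- function(event_id, branch, mechanism, seg_type, seg_index,
                      exon_index, side = NA_integer_,
                      position = NA_integer_, length_bp = 0L,
                      payload = NA_character_) {
    ledgerRow(event_id, branch, mechanism, seg_type, seg_index, exon_index,
              side, position, length_bp, payload)
}

#' Deterministic fixtures replaying classic structural-change scenarios
#'
#' Each fixture is a small gene family with a known, fully recorded event
#' history, reproducing a textbook MADS-box structural-change scenario:
#' \describe{
#'   \item{brassicaceae_intron_loss}{two genes with identical CDS; one has
#'     lost the intron between its fifth and sixth exons, so its fifth exon
#'     (84 bp) aligns end-to-end to the partner's fifth (42 bp) plus sixth
#'     (42 bp) exons.}
#'   \item{paleoAP1_stop_loss}{two point substitutions (T-C and A-C)
#'     disrupt the ancestral stop codon; translation reads through to the
#'     next in-frame stop, exonizing 15 bp of former 3' UTR.}
#'   \item{euAP1_frameshift}{a 1-bp deletion in the terminal exon shifts
#'     the frame onto a premature stop, pseudoexonizing the last 8
#'     reference-coding nucleotides.}
#'   \item{capsella_nested_insertions}{a 33-bp exon-7 insertion shared by a
#'     three-taxon ingroup, with an adjacent private 66-bp insertion in
#'     one of them.}
#'   \item{flc_exon3}{a 3-bp insertion plus an independent 3-bp boundary
#'     recruitment on one stem branch lengthen exon 3 from the ancestral
#'     62 bp to 68 bp in that clade.}
#'   \item{flc_exon_loss}{loss of the terminal (eighth) exon on a stem
#'     branch, leaving a seven-exon gene.}
#' }
#'
#' @param name one of the fixture names above.
#' @return list with \code{family} (\code{FamilySet}), \code{tree}
#'   (labelled rooted \code{phylo}) and \code{history}
#'   (\code{TrueHistory}).
#' @examples
#' fx <- emitFixture("brassicaceae_intron_loss")
#' exonLengths(models(fx$family)[[2]])
#' @export
emitFixture <- function(name) {
    if (!name %in% FIXTURE_NAMES)
        stop("unknown fixture '", name, "'; valid fixtures: ",
             paste(FIXTURE_NAMES, collapse = ", "))
    switch(name,
           brassicaceae_intron_loss = fixtureBrassicaceae(),
           paleoAP1_stop_loss = fixturePaleoAP1(),
           euAP1_frameshift = fixtureEuAP1(),
           capsella_nested_insertions = fixtureCapsella(),
           flc_exon3 = fixtureFlcExon3(),
           flc_exon_loss = fixtureFlcExonLoss())
}

# ancestral SEP1-like template inferred for crown angiosperms
SEP1_TEMPLATE <- c(185L, 79L, 62L, 100L, 42L, 42L, 137L, 85L)
# ancestral AP1/FUL-like template
AP1FUL_TEMPLATE <- c(185L, 79L, 65L, 100L, 42L, 42L, 113L, 106L)

fixtureBrassicaceae <- function() {
    anc <- fixtureAncestralState(SEP1_TEMPLATE, lcgNew(11))
    ledger <- fixtureOp("V0001", "SEP12_brassicaceae", "intron_loss",
                        "intron", 5L, 5L)
    buildFixture(anc, "(SEP1_other:0.02,SEP12_brassicaceae:0.02)root;",
                 ledger, outgroup = "SEP1_other")
}

fixturePaleoAP1 <- function() {
    anc <- fixtureAncestralState(AP1FUL_TEMPLATE, lcgNew(23))
    # 3' UTR: 12 stop-free bases then the next in-frame stop (TAA); the
    # terminal exon starts at CDS offset 626, so exon-local codons start at
    # positions 2 mod 3 and the appended 15 bp stay in frame
    f3 <- anc$flank3
    substr(f3, 13L, 15L) <- "TAA"
    anc$flank3 <- f3
    ops <- rbind(
        fixtureOp("S0001", "paleoAP1_gene", "substitution", "exon", 8L, 8L,
                  position = 104L, length_bp = 1L, payload = "C"),
        fixtureOp("S0002", "paleoAP1_gene", "substitution", "exon", 8L, 8L,
                  position = 106L, length_bp = 1L, payload = "C"),
        fixtureOp("V0001", "paleoAP1_gene", "exonization", "exon", 8L, 8L,
                  side = 3L, length_bp = 15L))
    buildFixture(anc, "(paleoAP1_gene:0.02,ancestral_like:0.02)root;",
                 ops, outgroup = "ancestral_like")
}

fixtureEuAP1 <- function() {
    anc <- fixtureAncestralState(AP1FUL_TEMPLATE, lcgNew(37))
    # plant the premature stop met by the shifted frame: after a 1-bp
    # deletion at position 30, the new frame reads the triplet at
    # reference positions 96-98
    ex8 <- anc$exonSeqs[8]
    substr(ex8, 96L, 98L) <- "TAA"
    anc$exonSeqs[8] <- ex8
    ops <- rbind(
        fixtureOp("V0001", "euAP1_gene", "intraexonic_deletion", "exon", 8L,
                  8L, position = 30L, length_bp = 1L),
        fixtureOp("V0002", "euAP1_gene", "pseudoexonization", "exon", 8L,
                  8L, side = 3L, length_bp = 8L))
    buildFixture(anc, "(euAP1_gene:0.02,ancestral_like:0.02)root;",
                 ops, outgroup = "ancestral_like")
}

fixtureCapsella <- function() {
    rng <- lcgNew(41)
    anc <- fixtureAncestralState(SEP1_TEMPLATE, rng)
    p33 <- lcgSeq(rng, 33L, c("A", "C", "G"))
    p66 <- lcgSeq(rng, 66L, c("A", "C", "G"))
    ops <- rbind(
        fixtureOp("V0001", "ingroup", "intraexonic_insertion", "exon", 7L,
                  7L, position = 60L, length_bp = 33L, payload = p33),
        fixtureOp("V0002", "Capsella", "intraexonic_insertion", "exon", 7L,
                  7L, position = 93L, length_bp = 66L, payload = p66))
    buildFixture(anc,
        "(outgroup:0.02,(Capsella:0.02,(Brassica:0.01,Arabidopsis:0.01)BA:0.01)ingroup:0.01)root;",
        ops, outgroup = "outgroup")
}

fixtureFlcExon3 <- function() {
    rng <- lcgNew(53)
    anc <- fixtureAncestralState(SEP1_TEMPLATE, rng)
    p3 <- lcgSeq(rng, 3L, c("A", "C", "G"))
    ops <- rbind(
        fixtureOp("V0001", "MRCA_FLC", "intraexonic_insertion", "exon", 3L,
                  3L, position = 30L, length_bp = 3L, payload = p3),
        fixtureOp("V0002", "MRCA_FLC", "exonization", "exon", 3L, 3L,
                  side = 5L, length_bp = 3L))
    buildFixture(anc,
        "((FLC_A:0.01,FLC_B:0.01)MRCA_FLC:0.02,(SEP_A:0.01,AGL6_A:0.01)outgrp:0.02)root;",
        ops, outgroup = c("SEP_A", "AGL6_A"))
}

fixtureFlcExonLoss <- function() {
    # template variant whose seventh exon ends on a codon boundary, so the
    # stem lineage can terminate cleanly once the eighth exon is lost
    lengths <- c(185L, 79L, 68L, 100L, 42L, 42L, 105L, 87L)
    anc <- fixtureAncestralState(lengths, lcgNew(67))
    # the ancestral exon 7 ends CAA; a single C-T substitution on the stem
    # turns it into a TAA stop once the terminal exon is gone
    ex7 <- anc$exonSeqs[7]
    substr(ex7, 103L, 105L) <- "CAA"
    anc$exonSeqs[7] <- ex7
    ops <- rbind(
        fixtureOp("V0001", "MRCA_FLC", "exon_loss", "exon", 8L, 8L,
                  length_bp = 87L),
        fixtureOp("S0001", "MRCA_FLC", "substitution", "exon", 7L, 7L,
                  position = 103L, length_bp = 1L, payload = "T"))
    buildFixture(anc,
        "((FLC_A:0.01,FLC_B:0.01)MRCA_FLC:0.02,(SEP_A:0.01,AGL6_A:0.01)outgrp:0.02)root;",
        ops, outgroup = c("SEP_A", "AGL6_A"))
}
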