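---
title: "Profiling gene-family history from intron positions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling gene-family history from intron positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introtrace)
```

## The model

`introtrace` treats the position of a spliceosomal intron in a coding
sequence as a heritable, near-irreversible character. The coordinate
object is the *coding offset*: the number of coding nucleotides strictly
upstream of the intron. Everything else is a derived view — the phase is
`offset mod 3`, and the codon index is `offset / 3` for a phase-0 intron
(reported as "between codon i and i+1", anchored to the upstream codon) or
`floor(offset / 3) + 1` when the intron interrupts a codon. Carrying one
canonical integer key avoids the boundary ambiguities that arise when
phase-0 introns are described by either neighbouring codon.

Two introns in different genes are *the same character* exactly when they
occupy the same protein-alignment column in the same phase. Matching is
exact: no sliding window, because empirical work across deeply diverged
eukaryotes shows intron positions essentially never migrate, and the rare
near-coincidences across phases (one codon apart) are precisely the cases
the phase comparison is there to separate. A consequence the package
enforces as an invariant is that a shared-position class can never contain
two phases.

Given a per-species presence/absence pattern of such a character, the
history is reconstructed under Dollo parsimony: the character arises once
and can only be lost. The origin is the most recent common ancestor (MRCA)
of the carriers — any deeper origin only adds losses, so the MRCA is the
unique optimum — and the losses are the maximal clades inside the origin
clade with no carrier, one loss each. Species where the family could not
be assessed at all ("unknown") are excluded from the loss count but
reported separately, and a second count treats them as losses, yielding
the lower/upper bound pair ("some k" / "up to m") that honest reporting of
patchy annotation requires.

## Assumptions and their limits

- *Single gain.* A shared column+phase position is assumed to arise once.
  Parallel insertion at a protosplice hotspot would violate this; the
  protosplice scorer exists partly to flag such candidate sites.
- *Loss is irreversible.* Regained introns at the same offset would be
  misread as retention.
- *The alignment is right.* Projection is only as good as the protein
  alignment; the `validate_alignment()` gate refuses stale alignments
  (degapped rows must equal the annotated proteins exactly), and gapped
  columns make a position "unmappable" rather than guessed.
- *The species tree is known.* The tree is consumed as Newick input and
  never inferred from the family itself.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `max_aa` (length filter) | 200 aa | core and variant histones are short; longer hits are chimeric or spurious annotations, removed rather than repaired (strictly greater than the cutoff is removed; 200 is kept) |
| `max_evalue` | 1e-10 | conventional stringent homology cutoff for short, highly conserved proteins; inclusive at the boundary |
| protosplice window | 2+2 nt | the consensus AG\|GT is a four-mer; the signal call is a full match of either flanking dinucleotide, which reproduces the qualitative calls on CA\|GT and AG\|GC (signal) versus CT\|GG (none) |
| collapse keys | protein+offsets, or CDS | two genes are redundant only if both the protein and the intron positions agree; at nucleotide level only exact CDS duplicates collapse |

Representatives of collapsed groups are the lexicographically smallest
gene id, so all outputs are independent of input order.

## The simulator

The generator embodies the scenario the inference is designed for: an
intronless canonical gene evolves along a species tree; at a chosen birth
node a variant copy appears carrying a novel intron at a chosen coding
offset (inserted at a planted AG|GT site when `protosplice_bias` is on);
every branch below the birth node loses the variant with a fixed
probability; the variant lineage evolves faster by a configurable
multiplier. Defaults — 32 species, loss probability 0.1 per branch,
0.02 substitutions/site on an average-length branch, rate multiplier 3,
no annotation dropouts — describe a deep origin retained in most species
with a handful of independent losses, the regime the method's qualitative
conclusions live in; the 130-codon gene length matches a core histone.

Sequence evolution is nucleotide-level Jukes–Cantor with stop-codon
avoidance (offending substitutions are resampled; the terminal stop is
frozen). This is deliberately not a codon model: the tests need controlled
divergence and exact truth records, not realism. The default mode has no
indels, so families simulated by it align trivially; the package's
progressive Needleman–Wunsch (BLOSUM62, affine gaps, deterministic
tie-break toward the diagonal) and external-alignment ingestion exist for
real, indel-bearing data and are exercised on small fixtures. Passing
simulation-based tests therefore demonstrates the correctness of the
coordinate arithmetic, projection, classification and reconstruction
machinery — not robustness to alignment error, annotation noise beyond
dropouts, or intron sliding, which real data can contain.

Random trees come from a Yule (pure birth) process, with branch lengths
rescaled to mean 1 so that per-branch divergence is directly the
substitution rate. All randomness flows from a single integer seed; a
fixed seed reproduces output files byte for byte.

### What "truth" means for the origin

With per-branch loss, the birth node itself is not always identifiable:
if an entire child lineage of the birth node loses the variant, every
surviving carrier descends from a shallower ancestor, and no
presence-based method can see deeper than the MRCA of the carriers. The
truth record therefore stores both the birth node and the
*pattern-implied* origin (the MRCA of the species that actually retain
the variant). Recovery is assessed against the pattern-implied origin —
the quantity the method can in principle recover — and the two coincide
whenever both child lineages of the birth node retain at least one
carrier. Likewise, two sister clades that lose the variant independently
collapse into one maximal absent clade; loss-count recovery is assessed
on replicates where the simulated loss events are themselves maximal
clades.

## Numerical and degenerate-case choices

- GFF3 is 1-based inclusive; all internal intervals are 0-based
  half-open; reports use the 1-based codon convention.
- Genes whose CDS length is not divisible by 3, or that contain internal
  stop codons, are excluded with warnings — dubious annotations are
  dropped, never repaired, since silent repair fabricates data.
- Multiple transcripts per gene reduce to the longest CDS (ties:
  lexicographically smallest transcript id).
- Introns at the extreme ends of a CDS (offset < 1 or > length−1) are
  invalid; an all-absent presence pattern is an error, not an empty
  result.
- Fitch reconstruction uses Hartigan's generalization on multifurcating
  nodes (keep states of maximal child support; `k − max(support)` changes
  at the node), which reduces to classic Fitch on binary trees; unknown
  tips carry the full observed alphabet.
- Neighbor joining validates symmetry and a zero diagonal, then delegates
  to `ape::nj()`; it is an internal utility for small per-exon trees, not
  a substitute for model-based phylogenetics.
- The Welch test wraps `stats::t.test(var.equal = FALSE)`; identical
  groups give t = 0 and one-tailed p = 0.5 exactly, and both-constant
  groups are an error.
- The six-frame rescue scan is ungapped BLOSUM62 window scoring — a
  qualitative re-search for annotation dropouts with no e-value
  statistics, used on single-gene contigs, and callers should pass the
  longest exon's peptide so introns do not split the match.

## Problem sizes used by the test suite

The suite validates the Dollo reconstruction against exhaustive
single-gain enumeration over all presence patterns on seeded random
topologies of 4–8 leaves (over two thousand cases), Fitch counts against
full labeling enumeration on 4–6-leaf trees with up to 4 states,
projection equivariance on 1000 randomized alignments, and parameter
recovery on 50 seeded 32-leaf simulations at loss probability 0.1 and
rate 0.02/site run through the full file-level pipeline. These sizes give
exhaustive or near-exhaustive coverage of the small-tree space while
keeping the default run of the suite comfortably reproducible on a
laptop.

## Known limitations

- No probabilistic gain/loss model: counts are parsimony counts, with
  bounds rather than posterior uncertainty.
- No modelling of intron sliding or alignment uncertainty; a
  systematically misaligned region will mis-classify its introns.
- The e-value filter consumes an external search's table; the package
  does not reimplement BLAST statistics, and fixture e-values are
  synthetic.
- The concerted-evolution call is purely topological (cherry or not);
  it ignores branch support.
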