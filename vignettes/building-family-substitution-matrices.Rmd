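---
title: "Building family-specific substitution matrices from alignment blocks"
author: "famsubmat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building family-specific substitution matrices from alignment blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famsubmat)
```

## The problem

General-purpose substitution matrices (the BLOSUM and PAM series) are
averages over large, compositionally mixed protein sets. Protein families
with a strong compositional bias — the membrane-spanning helices of class A
(rhodopsin-like) G protein-coupled receptors are the canonical example, with
leucine near 14 % and charged/polar residues at roughly twice the level of
average membrane proteins — are poorly served by those averages, especially
in the twilight zone (~20–35 % identity) where most GPCR alignments live.
famsubmat implements the block-counting log-odds construction for a *single*
family: given a curated multiple alignment split into short segment blocks
(here, the seven transmembrane helices TM1–TM7), it derives the family's own
scoring matrix, the statistics that characterise it, and a matrix-driven
pairwise aligner to use it.

## The construction

Let the alignment blocks be the columns of the annotated segments after
redundancy filtering. Every column contributes all unordered pairs of its
rows whose residues are both standard amino acids; a column with $n$
countable residues yields $n(n-1)/2$ pairs, of which $n_a n_b$ are $\{a,b\}$
pairs ($a \ne b$) and $\binom{n_a}{2}$ are $\{a,a\}$ pairs. Gap and
ambiguity characters (X, B, Z, U, O) contribute nothing. From the raw
tallies $f_{ij}$:

$$O_{ij} = f_{ij} \Big/ \sum_{i=1}^{20}\sum_{j=1}^{i} f_{ij}, \qquad
  p_i = O_{ii} + \sum_{j \ne i} O_{ij}/2,$$

$$e_{ij} = 2\,p_i p_j \;(i \ne j), \qquad e_{ii} = p_i^2, \qquad
  S_{ij} = 2 \log_2 (O_{ij}/e_{ij}).$$

The scale factor 2 gives half-bit scores, as in the BLOSUM construction;
the published matrix rounds $S$ to the nearest integer. The relative entropy

$$H = \sum_{i \ge j} O_{ij} \log_2 (O_{ij}/e_{ij})$$

summarises how strongly the matrix separates family alignments from chance.

### Conventions the literature leaves open

Several details are under-determined by the defining equations; famsubmat
fixes each one explicitly and exposes the alternative where one is in use:

* **Relative-entropy scale.** The defining sum is sometimes written with the
  2×-scaled scores inside the expectation, yet the H values conventionally
  reported for matrices of this family (e.g. BLOSUM62's 0.6979) follow the
  unscaled-bits convention. `relativeEntropy()` defaults to
  `unscaled_bits` and exposes `paper_scaled`, which is exactly twice it.
  H is always computed from the unrounded scores: rounding before the
  expectation cannot reproduce four-decimal H values.
* **Zero-count cells.** $f_{ij} = 0$ leaves $S_{ij}$ undefined. The default
  keeps the equations exact wherever counts exist and assigns unobserved
  cells the *floor* — the minimum over defined scores, i.e. the
  most-penalised observed exchange — so the matrix remains usable for
  alignment. A Laplace `pseudocount` on the counts is available instead;
  it perturbs every cell slightly but leaves none undefined.
* **Rounding.** "Nearest integer" is implemented as round-half-away-from-zero,
  which treats positive and negative scores symmetrically and is
  deterministic (banker's rounding is not what any published matrix uses).
* **Identity denominator.** The >90 %-identity redundancy screen needs a
  definition of identity for gapped rows: positions with a gap in either
  sequence are excluded from numerator and denominator. The screen itself is
  a greedy keep-first pass in input order — deterministic, idempotent, and
  order-documented — rather than a clustering, which the construction does
  not require.
* **No sequence weighting.** The construction removes near-identical
  sequences instead of down-weighting clusters (the BLOSUM alternative); the
  two mechanisms are not combined.
* **Coordinates.** Segment ranges are stored as 1-based inclusive
  `IRanges` — the native R/Bioconductor convention — and the TSV interface
  uses the same 1-based inclusive columns a bioinformatician expects, so no
  conversion ever happens at the boundary.

## Matrix analyses

`differenceMatrix()` subtracts integer scores elementwise (the published form
of a matrix is the integer one). For residue clustering the score-to-distance
transform is not canonical; the default `diagonal_deficit`,
$d_{ij} = S_{ii} + S_{jj} - 2S_{ij}$ floored at zero, is monotone decreasing
in the log-odds and zero on self; `correlation` distance
($1 - r$ of matrix rows) is exposed because published matrix-clustering work
often uses it. Cluster *topologies* are the comparable output; exact merge
heights depend on the transform and should not be over-interpreted.

`upgma()` is the textbook unweighted pair-group method: merge heights are
half the merged distance (so cophenetic distances are ultrametric), and ties
are broken by the lexicographically smallest pair of cluster labels, which
makes the output deterministic on degenerate inputs. `classicalMDS()` is
Torgerson double-centering with an explicit sign convention (each axis's
largest-magnitude coordinate is positive) so embeddings are reproducible;
when fewer positive eigenvalues exist than requested dimensions the output
is truncated and flagged rather than padded.

## The aligner

`alignPair()` implements Needleman–Wunsch–Gotoh (global) and
Smith–Waterman–Gotoh (local) dynamic programming in C++ under an affine gap
model. The default gap convention is BLAST's: a gap of length $L$ costs
$\mathrm{existence} + \mathrm{extension}\,(L-1)$, with existence 15 and
extension 2 as the published evaluation settings for half-bit family
matrices; the `open_plus_extend` alternative is a flag. Traceback ties are
resolved diagonal-first, then gap-in-b, then gap-in-a, so outputs are
deterministic. Integer scores are the default (published matrices are
consumed as integers); real-valued scoring is available. Ambiguity letters
are scored with the matrix floor. `segmentOverlap()` quantifies whether
same-named segments (e.g. TM3 of both receptors) end up opposite each other,
the testable surrogate for "the helices are aligned correctly".

Optimality is verified against an exhaustive enumeration of all gapped
alignments (a separate recursive routine with no memoisation) for sequences
up to length 8 — long enough that every gap-run interaction of the affine
model is exercised.

## The synthetic generator

`generateAlignment()` uses a column-anchor model: each column draws an
anchor residue from a target composition; each row keeps the anchor with the
column's conservation probability, otherwise draws a replacement in
proportion to the anchor's row of a symmetric exchangeability table. This
reproduces the two features the construction's statistics depend on —
compositional bias and per-column conservation — with minimal machinery.

Defaults emulate the study conditions of the family alignment: 1019
sequences, seven blocks of 25 columns (short, like the real helices), the
published transmembrane composition as anchor distribution, one
highly conserved column per block (0.98, the level of the most conserved
motif residues such as the TM1 asparagine) and 0.30 elsewhere, which places
typical pairwise identities in the twilight zone. The default
exchangeability is the chance-level table $\mathrm{outer}(p, p)$, which
preserves the target composition in expectation, so composition round-trips
are exact up to sampling error.

What the generator does **not** emulate: phylogenetic correlation between
rows (rows are exchangeable draws, not tree tips), rate variation across
lineages, insertion/deletion processes (gaps appear only if present in
input), and covariation between columns. Tests passing on generated data
therefore validate the *equations and their implementation*, not the
biological claims about any particular family; reproducing a real family's
published H exactly requires that family's own curated alignment and segment
ranges.

`recoveryExperiment()` plants a smoothly graded exchangeability
(`gradedExchangeability()`: residue $i$ carries trait $\sqrt i$, propensity
$e^{-|t_i - t_j|/\tau}$, $\tau = 1$) and checks that the ranking of the
recovered off-diagonal scores matches the generating propensities. The
default setting — 500 sequences × 200 columns, uniform composition,
conservation 0.5 — was chosen so that anchor–replacement pairs dominate the
counts and the planted propensities span a wide dynamic range; at that size
the Spearman correlation is reliably above 0.9.

## Numerical choices and test scales

Probability-mass invariants are asserted to 1e-9; brute-force equivalence of
the probability pipeline to 1e-12; MDS recovery of planted geometry to 1e-8
(Procrustes). The test suite runs the pipeline oracle on 1000 random blocks
(≤ 6 rows × ≤ 5 columns), aligner optimality on 10,000 random pairs of
length ≤ 8, and one study-scale generator run (1019 × 175); these sizes keep
the whole suite comfortably within a few minutes on one CPU while exercising
every code path the larger real inputs would.

## Limitations

* The construction is only as good as the input alignment and its segment
  annotation; column ranges shift scores.
* The zero-cell floor is a pragmatic default, not a statistical model of
  unobserved exchanges; use a pseudocount when downstream work needs finite
  log-odds with defined uncertainty.
* The redundancy screen is greedy in input order; a different input order
  can keep a different (equally valid) non-redundant subset.
* UPGMA and classical MDS are descriptive tools; they inherit every known
  limitation of ultrametric clustering and linear embeddings.
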