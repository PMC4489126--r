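## The core construction: pair counting over block columns, observed/expected
## pair probabilities, half-bit log-odds scores and relative entropy, plus the
## composition and conservation statistics that characterise the family.

#' Count residue pairs in alignment block columns
#'
#' Every column of every block contributes one count to f_\{a,b\} for each
#' unordered pair of rows whose residues are both standard amino acids: a
#' column with n countable residues yields n(n-1)/2 pairs (so n copies of the
#' same residue a add n(n-1)/2 to the diagonal cell f_\{a,a\}). Gaps and
#' ambiguity letters contribute nothing.
#'
#' @param blocks a list of [AlignmentBlock-class] objects (or one block).
#' @param pseudocount non-negative Laplace count added to every cell of the
#'   20x20 table after counting (default 0: the raw tallies).
#' @return A [PairCountTable-class].
#' @examples
#' b <- new("AlignmentBlock", segmentName = "toy",
#'          mat = matrix(c("A","A","C", "L","L","L"), nrow = 3,
#'                       dimnames = list(c("s1","s2","s3"), NULL)))
#' pairCounts(countPairs(list(b)))["A", "C"]   # 2
#' @export
countPairs <- function(blocks, pseudocount = 0) {
  if (is(blocks, "AlignmentBlock")) blocks <- list(blocks)
  if (length(blocks) == 0L) stop("no blocks to count")
  stopifnot(pseudocount >= 0)
  f <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  for (b in blocks) {
    m <- b@mat
    for (col in seq_len(ncol(m))) {
      n <- tabulate(match(m[, col], AA_ORDER), nbins = 20L)
      if (sum(n) < 2L) next
      cp <- outer(n, n)            # n_a * n_b unordered pairs for a != b
      diag(cp) <- n * (n - 1) / 2  # C(n_a, 2) on the diagonal
      f <- f + cp
    }
  }
  f <- f + pseudocount
  new("PairCountTable", counts = f,
      totalPairs = sum(f[upper.tri(f, diag = TRUE)]))
}

#' Observed, background and expected pair probabilities
#'
#' `probabilityTables()` converts raw pair counts into the three probability
#' tables of the log-odds construction: observed pair probabilities
#' O_ij = f_ij / total pairs, single-residue background frequencies
#' p_i = O_ii + sum over j != i of O_ij / 2, and chance expectations
#' e_ij = 2 p_i p_j for i != j, p_i^2 on the diagonal.
#'
#' @param counts a [PairCountTable-class] with at least one pair.
#' @return A [ProbabilityTables-class].
#' @export
probabilityTables <- function(counts) {
  if (totalPairs(counts) <= 0) stop("no observed pairs: cannot normalize")
  O <- pairCounts(counts) / totalPairs(counts)
  p <- backgroundFrequencies(O)
  new("ProbabilityTables", observed = O, background = p,
      expected = expectedProbabilities(p))
}

#' @rdname probabilityTables
#' @return `observedProbabilities`: the symmetric 20x20 matrix O_ij alone.
#' @export
observedProbabilities <- function(counts) {
  if (totalPairs(counts) <= 0) stop("no observed pairs: cannot normalize")
  pairCounts(counts) / totalPairs(counts)
}

#' @rdname probabilityTables
#' @param observed symmetric 20x20 observed-probability matrix (the unordered
#'   pair mass O_ij stored in both triangles).
#' @return `backgroundFrequencies`: named length-20 vector p_i summing to 1.
#' @export
backgroundFrequencies <- function(observed) {
  if (is(observed, "ProbabilityTables")) observed <- observedProbs(observed)
  # p_i = O_ii + sum_{j != i} O_ij / 2; off-diagonal mass is shared equally
  diag(observed) + (rowSums(observed) - diag(observed)) / 2
}

#' @rdname probabilityTables
#' @param p length-20 background frequency vector summing to 1.
#' @return `expectedProbabilities`: symmetric 20x20 matrix e_ij.
#' @export
expectedProbabilities <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  e <- 2 * outer(p, p)
  diag(e) <- p^2
  e
}

#' Log-odds substitution scores
#'
#' S_ij = scale * log2(O_ij / e_ij), the Henikoff block construction with the
#' default scale factor 2 (half-bit scores). Cells never observed (O_ij = 0,
#' where the log is undefined) are assigned a floor score: by default the
#' minimum over defined cells, mirroring the most-penalised observed exchange;
#' alternatively an explicit numeric floor. Integer scores round half away
#' from zero. Relative entropy is attached in both conventions (see
#' [relativeEntropy()]).
#'
#' @param p a [ProbabilityTables-class].
#' @param scale scaling factor applied to the base-2 log-odds (default 2).
#' @param zeroScore policy for unobserved cells: `"floor"` (default) or a
#'   single number to use directly.
#' @param provenance optional list merged into the result's provenance.
#' @return A [SubstitutionMatrix-class].
#' @export
logOdds <- function(p, scale = 2, zeroScore = "floor", provenance = list()) {
  O <- observedProbs(p); e <- expectedProbs(p)
  if (any(O > 0 & e == 0))
    stop("numeric domain error: observed pair with zero expectation")
  S <- matrix(NA_real_, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  pos <- O > 0
  S[pos] <- scale * log2(O[pos] / e[pos])
  if (identical(zeroScore, "floor")) {
    floorVal <- if (any(pos)) min(S[pos]) else 0
  } else {
    stopifnot(is.numeric(zeroScore), length(zeroScore) == 1L)
    floorVal <- zeroScore
  }
  S[!pos] <- floorVal
  H <- relativeEntropy(p, "unscaled_bits")
  new("SubstitutionMatrix", scoresReal = S, scoresInt = roundHalfAway(S),
      scaleFactor = scale, background = backgroundFreqs(p),
      relativeEntropy = c(unscaled_bits = H, paper_scaled = 2 * H),
      provenance = c(list(zero_cells = sum(!pos), floor_score = floorVal,
                          scale = scale), provenance))
}

setMethod("relativeEntropy", "ProbabilityTables",
  function(x, convention = c("unscaled_bits", "paper_scaled")) {
    convention <- match.arg(convention)
    O <- observedProbs(x); e <- expectedProbs(x)
    ut <- upper.tri(O, diag = TRUE)
    keep <- ut & O > 0
    h <- sum(O[keep] * log2(O[keep] / e[keep]))
    if (convention == "paper_scaled") 2 * h else h
  })

#' Residue composition of alignment blocks
#'
#' Fraction of each standard residue among all non-gap, non-ambiguous
#' characters of the blocks.
#'
#' @param blocks list of [AlignmentBlock-class] objects (or one block).
#' @return Named length-20 numeric vector summing to 1.
#' @export
composition <- function(blocks) {
  if (is(blocks, "AlignmentBlock")) blocks <- list(blocks)
  stopifnot(length(blocks) > 0L)
  n <- rowSums(vapply(blocks, function(b)
    tabulate(match(b@mat, AA_ORDER), nbins = 20L), numeric(20)))
  names(n) <- AA_ORDER
  if (sum(n) == 0) stop("no countable residues in the blocks")
  n / sum(n)
}

#' Accumulated fraction of a residue group
#'
#' @param profile composition vector from [composition()].
#' @param residues subset of the 20 standard one-letter codes, e.g.
#'   [chargedPolarResidues()].
#' @return Sum of the group's fractions.
#' @export
groupedFraction <- function(profile, residues) {
  residues <- toupper(residues)
  if (length(residues) == 0L) return(0)
  bad <- setdiff(residues, AA_ORDER)
  if (length(bad)) stop("unknown residue letter: ", paste(bad, collapse = ", "))
  sum(profile[residues])
}

#' Per-column conservation of a block
#'
#' For every column, the frequency of each residue among non-gap rows (the
#' denominator excludes gaps, so a conserved motif residue present in 98 % of
#' the sequences scores 0.98). All-gap columns are flagged and excluded from
#' maximum queries.
#'
#' @param block an [AlignmentBlock-class].
#' @return A list with `freq` (20 x n-columns matrix of per-column residue
#'   frequencies), `maxResidue` / `maxFraction` (per column), and `allGap`
#'   (logical per column).
#' @export
columnConservation <- function(block) {
  m <- block@mat
  freq <- vapply(seq_len(ncol(m)), function(col) {
    n <- tabulate(match(m[, col], AA_ORDER), nbins = 20L)
    ng <- sum(m[, col] != GAP_CHAR)
    if (ng == 0) rep(NA_real_, 20) else n / ng
  }, numeric(20))
  rownames(freq) <- AA_ORDER
  allGap <- apply(is.na(freq), 2, all)
  maxFraction <- vapply(seq_len(ncol(m)), function(k)
    if (allGap[k]) NA_real_ else max(freq[, k]), numeric(1))
  maxResidue <- vapply(seq_len(ncol(m)), function(k)
    if (allGap[k]) NA_character_ else AA_ORDER[which.max(freq[, k])],
    character(1))
  list(freq = freq, maxResidue = maxResidue,
       maxFraction = maxFraction, allGap = allGap,
       segmentName = block@segmentName)
}

#' Maximum per-column frequency of one residue in a block
#'
#' The natural quantitative reading of statements like "N in TM1, present in
#' 98 % of the sequences": the largest per-column frequency of the residue
#' within the block, gap-excluded denominators.
#'
#' @param block an [AlignmentBlock-class] (or the result of
#'   [columnConservation()]).
#' @param residue single standard one-letter code.
#' @return Fraction in \[0, 1\].
#' @export
maxConservation <- function(block, residue) {
  residue <- toupper(residue)
  stopifnot(residue %in% AA_ORDER)
  cons <- if (is(block, "AlignmentBlock")) columnConservation(block) else block
  ok <- !cons$allGap
  if (!any(ok)) stop("block has no non-gap columns")
  max(cons$freq[residue, ok])
}

#' Build a substitution matrix from an annotated alignment
#'
#' The full construction pipeline: redundancy filtering, block extraction,
#' pair counting, observed/background/expected probabilities, and log-odds
#' scoring with relative entropy. Options and intermediate totals are recorded
#' in the result's provenance.
#'
#' @param aln a [MultiBlockAlignment-class] with segment annotations.
#' @param redundancy identity ceiling for [filterRedundant()]; NULL skips the
#'   filter. Default 0.90.
#' @param scale log-odds scale factor (default 2, half-bits).
#' @param pseudocount Laplace count added to every pair cell (default 0).
#' @param zeroScore policy for unobserved cells (see [logOdds()]).
#' @return A [SubstitutionMatrix-class].
#' @export
buildMatrix <- function(aln, redundancy = 0.90, scale = 2, pseudocount = 0,
                        zeroScore = "floor") {
  nIn <- length(records(aln))
  if (!is.null(redundancy)) aln <- filterRedundant(aln, redundancy)
  blocks <- extractBlocks(aln)
  counts <- countPairs(blocks, pseudocount = pseudocount)
  p <- probabilityTables(counts)
  logOdds(p, scale = scale, zeroScore = zeroScore,
          provenance = list(
            sequences_input = nIn,
            sequences_kept = length(records(aln)),
            redundancy_threshold = if (is.null(redundancy)) NA else redundancy,
            n_blocks = length(blocks),
            total_pairs = totalPairs(counts),
            pseudocount = pseudocount))
}
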