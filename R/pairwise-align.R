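## Matrix-driven pairwise alignment with affine gap penalties, plus rescoring
## of fixed alignments and the per-segment overlap statistic used to judge
## whether transmembrane helices are aligned against each other.

encodeResidues <- function(x, what = "sequence") {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  if (length(v) == 0L) stop("empty ", what)
  if (any(v == GAP_CHAR)) stop(what, " must be ungapped")
  bad <- setdiff(v, c(AA_ORDER, AMBIGUITY_LETTERS))
  if (length(bad)) stop("residue '", bad[1], "' absent from the matrix")
  idx <- match(v, AA_ORDER)
  idx[is.na(idx)] <- 0L   # ambiguity letters: scored via the floor score
  list(idx = as.integer(idx), letters = v)
}

gapCharges <- function(g) {
  # first-column charge of a gap run, and per-extra-column charge
  if (g@convention == "blast") c(first = g@open, ext = g@extend)
  else c(first = g@open + g@extend, ext = g@extend)
}

#' Align two protein sequences under a substitution matrix
#'
#' Optimal global (Needleman-Wunsch-Gotoh) or local (Smith-Waterman-Gotoh)
#' alignment under an affine gap model. With the default `"blast"` convention
#' a gap of length L costs open + extend*(L-1) (gap "existence" and
#' "extension"); the published evaluation settings are existence 15,
#' extension 2. Traceback ties are broken deterministically: diagonal first,
#' then gap-in-b, then gap-in-a. Ambiguity letters are scored with the
#' matrix's floor (minimum) score.
#'
#' @param a,b ungapped residue strings.
#' @param m a [SubstitutionMatrix-class].
#' @param gap a [GapModel-class]; default `gapModel()` (open 15, extend 2).
#' @param mode `"global"` or `"local"`.
#' @param scores `"int"` (default; published matrices are consumed in integer
#'   form) or `"real"`.
#' @return A [PairAlignment-class].
#' @examples
#' \dontrun{
#' alignPair("NVFVIALAV", "NVFILNLAV", builtMatrix, gapModel())
#' }
#' @export
alignPair <- function(a, b, m, gap = gapModel(),
                      mode = c("global", "local"), scores = c("int", "real")) {
  mode <- match.arg(mode)
  S <- switch(match.arg(scores), int = scoresInt(m), real = scoresReal(m))
  ea <- encodeResidues(a, "sequence a"); eb <- encodeResidues(b, "sequence b")
  gc <- gapCharges(gap)
  res <- .gotohAlign(ea$idx, eb$idx, S, min(S), gc["first"], gc["ext"],
                     mode == "local")
  la <- rep(GAP_CHAR, length(res$pathA))
  la[res$pathA > 0L] <- ea$letters[res$pathA[res$pathA > 0L]]
  lb <- rep(GAP_CHAR, length(res$pathB))
  lb[res$pathB > 0L] <- eb$letters[res$pathB[res$pathB > 0L]]
  comparable <- la != GAP_CHAR & lb != GAP_CHAR
  ident <- if (any(comparable)) sum(la[comparable] == lb[comparable]) /
    sum(comparable) else 0
  new("PairAlignment",
      alignedA = paste(la, collapse = ""), alignedB = paste(lb, collapse = ""),
      score = unname(res$score), mode = mode, identity = ident,
      offsetA = as.integer(res$startA), offsetB = as.integer(res$startB))
}

#' Score a fixed pairwise alignment
#'
#' Sum of substitution scores over residue columns minus the affine cost of
#' each maximal gap run (first column of a run charged the opening penalty,
#' later columns the extension penalty, under the gap model's convention).
#' Columns with gaps in both rows are rejected.
#'
#' @param alignedA,alignedB equal-length gapped strings.
#' @param m a [SubstitutionMatrix-class].
#' @param gap a [GapModel-class].
#' @param scores `"int"` or `"real"`.
#' @return The alignment score (a single number).
#' @export
scoreAlignment <- function(alignedA, alignedB, m, gap = gapModel(),
                           scores = c("int", "real")) {
  S <- switch(match.arg(scores), int = scoresInt(m), real = scoresReal(m))
  va <- strsplit(toupper(alignedA), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(alignedB), "", fixed = TRUE)[[1]]
  if (length(va) != length(vb)) stop("aligned strings must have equal length")
  if (any(va == GAP_CHAR & vb == GAP_CHAR))
    stop("column with gaps in both rows")
  gc <- gapCharges(gap)
  floorScore <- min(S)
  lookup <- function(x, y) {
    ix <- match(x, AA_ORDER); iy <- match(y, AA_ORDER)
    ifelse(is.na(ix) | is.na(iy), floorScore, S[cbind(ix, iy)])
  }
  total <- 0
  inGapA <- FALSE; inGapB <- FALSE
  for (k in seq_along(va)) {
    if (va[k] == GAP_CHAR) {
      total <- total - if (inGapA) gc["ext"] else gc["first"]
      inGapA <- TRUE; inGapB <- FALSE
    } else if (vb[k] == GAP_CHAR) {
      total <- total - if (inGapB) gc["ext"] else gc["first"]
      inGapB <- TRUE; inGapA <- FALSE
    } else {
      total <- total + lookup(va[k], vb[k])
      inGapA <- FALSE; inGapB <- FALSE
    }
  }
  unname(total)
}

#' Per-segment overlap of a pairwise alignment
#'
#' For each segment name present in both annotation sets (segments are given
#' in ungapped 1-based residue coordinates of each input sequence), the
#' fraction of sequence-a segment residues that are aligned opposite
#' residues of the same-named segment of sequence b — the quantitative
#' surrogate for "the helices are aligned against each other". A
#' self-alignment scores 1 everywhere; a helix placed entirely opposite loops
#' scores 0.
#'
#' @param aln a [PairAlignment-class].
#' @param segmentsA,segmentsB named [IRanges::IRanges] (or data.frames with
#'   `name`/`start`/`end`) in ungapped residue coordinates of a and b.
#' @return Named numeric vector of overlap fractions, one per shared segment
#'   name; an error if a name in `segmentsA` is missing from `segmentsB`.
#' @export
segmentOverlap <- function(aln, segmentsA, segmentsB) {
  segA <- asSegmentRanges(segmentsA); segB <- asSegmentRanges(segmentsB)
  missing <- setdiff(names(segA), names(segB))
  if (length(missing))
    stop("unknown segment name in b: ", paste(missing, collapse = ", "))
  va <- strsplit(aln@alignedA, "", fixed = TRUE)[[1]]
  vb <- strsplit(aln@alignedB, "", fixed = TRUE)[[1]]
  posA <- ifelse(va != GAP_CHAR, cumsum(va != GAP_CHAR) + aln@offsetA, NA)
  posB <- ifelse(vb != GAP_CHAR, cumsum(vb != GAP_CHAR) + aln@offsetB, NA)
  out <- vapply(names(segA), function(nm) {
    ra <- IRanges::start(segA)[names(segA) == nm]:IRanges::end(segA)[names(segA) == nm]
    sb <- IRanges::start(segB)[names(segB) == nm]
    eb <- IRanges::end(segB)[names(segB) == nm]
    cols <- which(posA %in% ra)
    sum(!is.na(posB[cols]) & posB[cols] >= sb & posB[cols] <= eb) / length(ra)
  }, numeric(1))
  out
}

# R-side oracle wrapper: exhaustive global score for short sequences
bruteForceScore <- function(a, b, m, gap = gapModel(), scores = c("int", "real")) {
  S <- switch(match.arg(scores), int = scoresInt(m), real = scoresReal(m))
  ea <- encodeResidues(a); eb <- encodeResidues(b)
  gc <- gapCharges(gap)
  .bruteForceGlobalScore(ea$idx, eb$idx, S, min(S), gc["first"], gc["ext"])
}
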