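#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom IRanges IRanges
#' @importFrom IRanges IRanges start end width
#' @importFrom Biostrings AAStringSet readBStringSet readAAMultipleAlignment
#' @importFrom stats cor sd setNames
#' @importFrom utils read.table write.table packageVersion
#' @useDynLib famsubmat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

validResidueString <- function(x) {
  # returns NULL if ok, else c(offending letter, position) of first violation
  bad <- regexpr(sprintf("[^%s]", paste(ALLOWED_CHARS, collapse = "")), x)
  if (bad == -1L) return(NULL)
  c(substr(x, bad, bad), bad)
}

#' MultiBlockAlignment: an aligned protein family with segment annotations
#'
#' Holds a gapped multiple sequence alignment (all records the same width,
#' stored uppercase as an [Biostrings::AAStringSet]) together with the column
#' ranges of the segment blocks (e.g. the seven transmembrane helices TM1-TM7
#' of a class A GPCR alignment) as a named [IRanges::IRanges] in 1-based
#' inclusive alignment coordinates.
#'
#' @slot records AAStringSet of equal-width gapped sequences, unique names.
#' @slot segments named IRanges of block column ranges, non-overlapping,
#'   within the alignment width.
#' @aliases MultiBlockAlignment
#' @exportClass MultiBlockAlignment
setClass("MultiBlockAlignment",
  representation(records = "AAStringSet", segments = "IRanges"))

setValidity("MultiBlockAlignment", function(object) {
  rec <- object@records
  if (length(rec) == 0L) return("alignment has no records")
  ids <- names(rec)
  if (is.null(ids) || any(!nzchar(ids))) return("every record needs a nonempty id")
  if (anyDuplicated(ids)) return("record ids must be unique")
  w <- unique(Biostrings::width(rec))
  if (length(w) != 1L)
    return(sprintf("alignment shape error: records have unequal lengths (%s)",
                   paste(w, collapse = ", ")))
  chars <- as.character(rec)
  for (k in seq_along(chars)) {
    bad <- validResidueString(chars[[k]])
    if (!is.null(bad))
      return(sprintf("illegal character '%s' at position %s of record '%s'",
                     bad[1], bad[2], ids[k]))
  }
  seg <- object@segments
  if (length(seg) > 0L) {
    if (is.null(names(seg)) || any(!nzchar(names(seg))))
      return("segments must be named")
    if (anyDuplicated(names(seg))) return("segment names must be unique")
    if (any(IRanges::start(seg) < 1L) || any(IRanges::end(seg) > w))
      return(sprintf("configuration error: segment outside alignment width %d", w))
    if (length(seg) > 1L) {
      o <- order(IRanges::start(seg))
      s <- IRanges::start(seg)[o]; e <- IRanges::end(seg)[o]
      if (any(s[-1L] <= e[-length(e)])) return("segments overlap")
    }
  }
  TRUE
})

#' AlignmentBlock: one segment's columns of an alignment
#'
#' The counting substrate of the matrix construction: the rows of a
#' [MultiBlockAlignment] restricted to one segment's column range, stored as a
#' character matrix (rows = sequences, one uppercase letter per cell).
#'
#' @slot segmentName name of the originating segment (e.g. "TM1").
#' @slot mat character matrix of single letters; rownames are sequence ids.
#' @exportClass AlignmentBlock
setClass("AlignmentBlock",
  representation(segmentName = "character", mat = "matrix"))

setValidity("AlignmentBlock", function(object) {
  m <- object@mat
  if (nrow(m) < 2L) return("a block needs at least 2 rows")
  if (ncol(m) < 1L) return("a block needs at least 1 column")
  if (is.null(rownames(m))) return("block rows must carry sequence ids")
  if (!all(m %in% ALLOWED_CHARS)) {
    off <- setdiff(unique(as.vector(m)), ALLOWED_CHARS)
    return(sprintf("illegal character '%s' in block", off[1]))
  }
  TRUE
})

#' PairCountTable: raw residue-pair tallies from block columns
#'
#' Symmetric 20x20 table of pair frequencies f_ij: each alignment column with
#' n standard residues contributes every unordered pair of its rows once
#' (n(n-1)/2 pairs). Gap and ambiguity characters contribute nothing.
#'
#' @slot counts symmetric 20x20 numeric matrix; `counts[a, b]` is the number
#'   of unordered \{a,b\} pairs (stored in both triangles).
#' @slot totalPairs sum of the upper triangle including the diagonal.
#' @exportClass PairCountTable
setClass("PairCountTable",
  representation(counts = "matrix", totalPairs = "numeric"))

setValidity("PairCountTable", function(object) {
  m <- object@counts
  if (!identical(dim(m), c(20L, 20L))) return("counts must be 20x20")
  if (!identical(rownames(m), AA_ORDER) || !identical(colnames(m), AA_ORDER))
    return("counts must be labelled by the 20 residues in canonical order")
  if (any(m < 0)) return("counts must be non-negative")
  if (max(abs(m - t(m))) > 0) return("counts must be symmetric")
  tri <- sum(m[upper.tri(m, diag = TRUE)])
  if (abs(tri - object@totalPairs) > 1e-9 * max(1, tri))
    return("totalPairs must equal the triangle sum of counts")
  TRUE
})

#' ProbabilityTables: observed, background and expected pair probabilities
#'
#' Observed pair probabilities O_ij = f_ij / sum f_ij (unordered mass, so the
#' triangle i >= j sums to 1), single-residue background frequencies
#' p_i = O_ii + sum_\{j != i\} O_ij / 2, and chance expectations
#' e_ij = 2 p_i p_j (i != j), e_ii = p_i^2.
#'
#' @slot observed symmetric 20x20 matrix of O_ij.
#' @slot background length-20 named vector p_i summing to 1.
#' @slot expected symmetric 20x20 matrix of e_ij.
#' @exportClass ProbabilityTables
setClass("ProbabilityTables",
  representation(observed = "matrix", background = "numeric",
                 expected = "matrix"))

triSum <- function(m) sum(m[upper.tri(m, diag = TRUE)])

setValidity("ProbabilityTables", function(object) {
  O <- object@observed; p <- object@background; e <- object@expected
  if (abs(triSum(O) - 1) > 1e-9) return("observed triangle must sum to 1")
  if (abs(sum(p) - 1) > 1e-9) return("background must sum to 1")
  if (abs(triSum(e) - 1) > 1e-9) return("expected triangle must sum to 1")
  if (max(abs(O - t(O))) > 1e-12 || max(abs(e - t(e))) > 1e-12)
    return("probability tables must be symmetric")
  TRUE
})

#' SubstitutionMatrix: log-odds scores with background and relative entropy
#'
#' Scores S_ij = scale * log2(O_ij / e_ij) in real-valued and
#' nearest-integer-rounded form (default scale 2, i.e. half-bits), plus the
#' background frequencies and the relative entropy H of the observed versus
#' expected pair distribution. `provenance` records how the matrix was built
#' (pair totals, pseudocount, zero-cell policy, options).
#'
#' @slot scoresReal symmetric 20x20 numeric matrix of unrounded scores.
#' @slot scoresInt symmetric 20x20 integer-valued matrix (half away from zero).
#' @slot scaleFactor numeric scaling applied to the base-2 log-odds.
#' @slot background length-20 p_i, or NA when unknown (e.g. a parsed file).
#' @slot relativeEntropy named numeric: `unscaled_bits` and `paper_scaled`
#'   conventions (NA when unknown).
#' @slot provenance list of free-form metadata.
#' @exportClass SubstitutionMatrix
setClass("SubstitutionMatrix",
  representation(scoresReal = "matrix", scoresInt = "matrix",
                 scaleFactor = "numeric", background = "numeric",
                 relativeEntropy = "numeric", provenance = "list"))

setValidity("SubstitutionMatrix", function(object) {
  sR <- object@scoresReal; sI <- object@scoresInt
  if (!identical(dim(sR), c(20L, 20L)) || !identical(dim(sI), c(20L, 20L)))
    return("score matrices must be 20x20")
  if (max(abs(sR - t(sR))) > 1e-9 || max(abs(sI - t(sI))) > 0)
    return("score matrices must be symmetric")
  if (any(sI != roundHalfAway(sR)))
    return("scoresInt must be scoresReal rounded half away from zero")
  TRUE
})

#' GapModel: affine gap penalties in the BLAST convention
#'
#' A gap of length L costs `open + extend * (L - 1)` under the default
#' `"blast"` convention (gap "existence" and "extension" as used for the
#' published evaluation: existence 15, extension 2), or
#' `open + extend * L` under `"open_plus_extend"`.
#'
#' @slot open non-negative gap opening (existence) penalty.
#' @slot extend non-negative gap extension penalty, `extend <= open`.
#' @slot convention `"blast"` or `"open_plus_extend"`.
#' @exportClass GapModel
setClass("GapModel",
  representation(open = "numeric", extend = "numeric", convention = "character"))

setValidity("GapModel", function(object) {
  if (object@extend < 0 || object@open < object@extend)
    return("need open >= extend >= 0")
  if (!object@convention %in% c("blast", "open_plus_extend"))
    return("convention must be 'blast' or 'open_plus_extend'")
  TRUE
})

#' Construct a GapModel
#'
#' @param open gap opening (existence) penalty, default 15.
#' @param extend gap extension penalty, default 2.
#' @param convention `"blast"` (gap of length L costs open + extend*(L-1),
#'   the BLASTP existence/extension semantics) or `"open_plus_extend"`.
#' @return A [GapModel-class] object.
#' @examples
#' gapModel()           # the published evaluation settings
#' gapModel(11, 1)      # BLOSUM62 defaults
#' @export
gapModel <- function(open = 15, extend = 2, convention = "blast") {
  new("GapModel", open = open, extend = extend,
      convention = match.arg(convention, c("blast", "open_plus_extend")))
}

#' PairAlignment: a scored pairwise alignment
#'
#' @slot alignedA,alignedB gapped strings of equal length; removing gaps
#'   recovers the input sequences (or substrings in local mode).
#' @slot score optimal score under the matrix and gap model used.
#' @slot mode `"global"` or `"local"`.
#' @slot identity fraction of identical residues over aligned non-gap columns.
#' @slot offsetA,offsetB 0-based ungapped start offsets of the aligned region
#'   within the original sequences (nonzero only in local mode).
#' @exportClass PairAlignment
setClass("PairAlignment",
  representation(alignedA = "character", alignedB = "character",
                 score = "numeric", mode = "character", identity = "numeric",
                 offsetA = "integer", offsetB = "integer"))

setValidity("PairAlignment", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings must have equal length")
  if (!object@mode %in% c("global", "local")) return("bad mode")
  TRUE
})
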