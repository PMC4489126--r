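#' @rdname MultiBlockAlignment-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname MultiBlockAlignment-class
#' @export
setGeneric("segmentRanges", function(x) standardGeneric("segmentRanges"))

#' @rdname PairCountTable-class
#' @param x a `PairCountTable`.
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' @rdname PairCountTable-class
#' @export
setGeneric("totalPairs", function(x) standardGeneric("totalPairs"))

#' @rdname ProbabilityTables-class
#' @param x a `ProbabilityTables` (or, for `backgroundFreqs`, a
#'   `SubstitutionMatrix`).
#' @export
setGeneric("observedProbs", function(x) standardGeneric("observedProbs"))

#' @rdname ProbabilityTables-class
#' @export
setGeneric("backgroundFreqs", function(x) standardGeneric("backgroundFreqs"))

#' @rdname ProbabilityTables-class
#' @export
setGeneric("expectedProbs", function(x) standardGeneric("expectedProbs"))

#' @rdname SubstitutionMatrix-class
#' @param x a `SubstitutionMatrix`.
#' @export
setGeneric("scoresInt", function(x) standardGeneric("scoresInt"))

#' @rdname SubstitutionMatrix-class
#' @export
setGeneric("scoresReal", function(x) standardGeneric("scoresReal"))

#' Relative entropy of a scoring system
#'
#' H = sum over residue pairs (i >= j) of O_ij * log2(O_ij / e_ij) in the
#' default `unscaled_bits` convention (cells with O_ij = 0 are skipped), or
#' exactly twice that (`paper_scaled`, using the half-bit scores
#' S_ij = 2 log2(O_ij / e_ij) inside the expectation). H measures how strongly
#' a matrix discriminates family alignments from chance and is always >= 0.
#' Computed from the unrounded log-odds, never the integer matrix.
#'
#' @param x a [ProbabilityTables-class] (computed on the fly) or a
#'   [SubstitutionMatrix-class] (stored at build time).
#' @param convention `"unscaled_bits"` (default) or `"paper_scaled"`.
#' @return A single non-negative number (bits per aligned pair).
#' @export
setGeneric("relativeEntropy",
  function(x, convention = c("unscaled_bits", "paper_scaled"))
    standardGeneric("relativeEntropy"))

setMethod("records", "MultiBlockAlignment", function(x) x@records)
setMethod("segmentRanges", "MultiBlockAlignment", function(x) x@segments)
setMethod("pairCounts", "PairCountTable", function(x) x@counts)
setMethod("totalPairs", "PairCountTable", function(x) x@totalPairs)
setMethod("observedProbs", "ProbabilityTables", function(x) x@observed)
setMethod("backgroundFreqs", "ProbabilityTables", function(x) x@background)
setMethod("expectedProbs", "ProbabilityTables", function(x) x@expected)
setMethod("backgroundFreqs", "SubstitutionMatrix", function(x) x@background)
setMethod("scoresInt", "SubstitutionMatrix", function(x) x@scoresInt)
setMethod("scoresReal", "SubstitutionMatrix", function(x) x@scoresReal)

setMethod("relativeEntropy", "SubstitutionMatrix",
  function(x, convention = c("unscaled_bits", "paper_scaled")) {
    convention <- match.arg(convention)
    unname(x@relativeEntropy[convention])
  })

#' @rdname PairAlignment-class
#' @param x a `PairAlignment`.
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))

#' @rdname PairAlignment-class
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname PairAlignment-class
#' @export
setGeneric("alignmentIdentity", function(x) standardGeneric("alignmentIdentity"))

setMethod("alignedSeqs", "PairAlignment",
  function(x) c(a = x@alignedA, b = x@alignedB))
setMethod("alignmentScore", "PairAlignment", function(x) x@score)
setMethod("alignmentIdentity", "PairAlignment", function(x) x@identity)

setMethod("show", "MultiBlockAlignment", function(object) {
  cat(sprintf("MultiBlockAlignment: %d sequences x %d columns, %d segment(s)\n",
              length(object@records), Biostrings::width(object@records)[1],
              length(object@segments)))
  if (length(object@segments))
    cat("  segments:", paste(sprintf("%s[%d-%d]", names(object@segments),
        IRanges::start(object@segments), IRanges::end(object@segments)),
        collapse = " "), "\n")
})

setMethod("show", "AlignmentBlock", function(object) {
  cat(sprintf("AlignmentBlock '%s': %d sequences x %d columns\n",
              object@segmentName, nrow(object@mat), ncol(object@mat)))
})

setMethod("show", "PairCountTable", function(object) {
  cat(sprintf("PairCountTable: %s residue pairs over %d residue types observed\n",
              format(object@totalPairs, big.mark = ","),
              sum(diag(object@counts) > 0 | rowSums(object@counts) > 0)))
})

setMethod("show", "ProbabilityTables", function(object) {
  top <- names(sort(object@background, decreasing = TRUE))[1:3]
  cat(sprintf("ProbabilityTables: most frequent residues %s\n",
              paste(sprintf("%s (%.1f%%)", top, 100 * object@background[top]),
                    collapse = ", ")))
})

setMethod("show", "SubstitutionMatrix", function(object) {
  cat(sprintf("SubstitutionMatrix (scale %g): integer scores in [%d, %d]",
              object@scaleFactor, min(object@scoresInt), max(object@scoresInt)))
  if (!is.na(object@relativeEntropy["unscaled_bits"]))
    cat(sprintf(", H = %.4f bits", object@relativeEntropy["unscaled_bits"]))
  cat("\n")
})

setMethod("show", "GapModel", function(object) {
  cat(sprintf("GapModel: open %g, extend %g (%s convention)\n",
              object@open, object@extend, object@convention))
})

setMethod("show", "PairAlignment", function(object) {
  cat(sprintf("PairAlignment (%s): score %g, identity %.1f%%, length %d\n",
              object@mode, object@score, 100 * object@identity,
              nchar(object@alignedA)))
  w <- nchar(object@alignedA)
  chunk <- 60L
  for (s in seq(1L, w, by = chunk)) {
    e <- min(w, s + chunk - 1L)
    cat("  ", substr(object@alignedA, s, e), "\n",
        "  ", substr(object@alignedB, s, e), "\n", sep = "")
  }
})
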