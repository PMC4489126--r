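## Reading, validating and slicing aligned protein sequences. Parsing of the
## FASTA and Clustal dialects is delegated to Biostrings; everything after the
## raw parse (alphabet checks, segment bookkeeping, redundancy screening) is
## implemented here.

#' Construct a MultiBlockAlignment
#'
#' @param sequences named character vector (or AAStringSet) of equal-length
#'   gapped sequences; stored uppercase.
#' @param segments segment definitions: a named [IRanges::IRanges], or a
#'   data.frame with columns `name`, `start`, `end` (1-based inclusive
#'   alignment columns), or NULL for none.
#' @return A [MultiBlockAlignment-class].
#' @examples
#' multiBlockAlignment(c(s1 = "ALVI", s2 = "GLVI"),
#'                     data.frame(name = "TM1", start = 1, end = 4))
#' @export
multiBlockAlignment <- function(sequences, segments = NULL) {
  raw <- toupper(if (is.character(sequences)) sequences
                 else as.character(sequences))
  ids <- if (is.null(names(raw))) as.character(seq_along(raw)) else names(raw)
  # validate before handing to the AA container so the offender is named
  for (k in seq_along(raw)) {
    bad <- validResidueString(raw[[k]])
    if (!is.null(bad))
      stop(sprintf("illegal character '%s' at position %s of record '%s'",
                   bad[1], bad[2], ids[k]))
  }
  if (length(unique(nchar(raw))) > 1L)
    stop(sprintf("alignment shape error: records have unequal lengths (%s)",
                 paste(sort(unique(nchar(raw))), collapse = ", ")))
  seqs <- Biostrings::AAStringSet(stats::setNames(raw, names(raw)))
  new("MultiBlockAlignment", records = seqs, segments = asSegmentRanges(segments))
}

asSegmentRanges <- function(segments) {
  if (is.null(segments)) return(IRanges::IRanges())
  if (is(segments, "IRanges")) return(segments)
  stopifnot(is.data.frame(segments),
            all(c("name", "start", "end") %in% names(segments)))
  IRanges::IRanges(start = as.integer(segments$start),
                   end = as.integer(segments$end),
                   names = as.character(segments$name))
}

#' Read an aligned protein file
#'
#' Reads a gapped protein multiple alignment in FASTA or Clustal format,
#' uppercases it and validates that every character is one of the 20 standard
#' residues, an ambiguity letter (X, B, Z, U, O) or the gap character `-`.
#' Records are returned in file order.
#'
#' @param path file path.
#' @param format `"fasta"` or `"clustal"`.
#' @param segments optional segment definitions (see [multiBlockAlignment()]),
#'   e.g. from [readSegments()].
#' @return A [MultiBlockAlignment-class].
#' @export
readAlignment <- function(path, format = c("fasta", "clustal"), segments = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "fasta") {
    raw <- Biostrings::readBStringSet(path)
    seqs <- stats::setNames(toupper(as.character(raw)), names(raw))
  } else {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    raw <- as(msa, "AAStringSet")
    seqs <- stats::setNames(toupper(as.character(raw)), names(raw))
  }
  multiBlockAlignment(seqs, segments)
}

#' Read segment definitions from a TSV file
#'
#' One row per segment: `name`, `start`, `end` in 1-based inclusive alignment
#' columns (the usual bioinformatics coordinate convention). A header row and
#' `#` comment lines are permitted.
#'
#' @param path TSV file path.
#' @return Named [IRanges::IRanges].
#' @export
readSegments <- function(path) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("name", "start", "end"))
  if (tolower(tab$name[1]) == "name") tab <- tab[-1L, , drop = FALSE]
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  if (any(is.na(tab$start)) || any(is.na(tab$end)))
    stop("segment file has non-numeric start/end")
  asSegmentRanges(tab)
}

#' Write an alignment
#'
#' `writeAlignmentFasta` writes aligned FASTA; `writeAlignmentClustal` writes
#' an interleaved CLUSTAL-format file readable by standard tools (and by
#' [readAlignment()] with `format = "clustal"`).
#'
#' @param aln a [MultiBlockAlignment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAlignmentFasta <- function(aln, path) {
  Biostrings::writeXStringSet(records(aln), path)
  invisible(path)
}

#' @rdname writeAlignmentFasta
#' @export
writeAlignmentClustal <- function(aln, path) {
  seqs <- as.character(records(aln))
  ids <- names(seqs)
  wid <- max(nchar(ids)) + 3L
  con <- file(path, "w")
  on.exit(close(con))
  # header followed by two blank lines, as the standard readers expect
  writeLines(c("CLUSTAL W multiple sequence alignment", "", ""), con)
  len <- nchar(seqs[[1]])
  for (s in seq(1L, len, by = 60L)) {
    e <- min(len, s + 59L)
    for (k in seq_along(seqs))
      writeLines(sprintf("%-*s%s", wid, ids[k], substr(seqs[[k]], s, e)), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Slice an alignment into its segment blocks
#'
#' Returns one [AlignmentBlock-class] per annotated segment, preserving row
#' order; alignment columns outside every segment (loops, termini) are
#' discarded.
#'
#' @param aln a [MultiBlockAlignment-class] with at least one segment.
#' @return Named list of [AlignmentBlock-class] objects.
#' @export
extractBlocks <- function(aln) {
  seg <- segmentRanges(aln)
  if (length(seg) == 0L)
    stop("configuration error: alignment has no segment definitions")
  chars <- as.character(records(aln))
  full <- do.call(rbind, strsplit(chars, "", fixed = TRUE))
  rownames(full) <- names(chars)
  out <- lapply(seq_along(seg), function(k) {
    cols <- IRanges::start(seg)[k]:IRanges::end(seg)[k]
    new("AlignmentBlock", segmentName = names(seg)[k],
        mat = full[, cols, drop = FALSE])
  })
  stats::setNames(out, names(seg))
}

#' Pairwise percent identity of two aligned rows
#'
#' Identity = matches / compared positions, where any position with a gap in
#' either sequence is excluded from both numerator and denominator. Returns 0
#' when no comparable positions exist.
#'
#' @param a,b equal-length residue strings (gaps allowed).
#' @return Fraction in \[0, 1\].
#' @examples
#' percentIdentity("ACDE", "ACDF")  # 0.75
#' percentIdentity("AC-E", "ACDE")  # 1 over the 3 comparable positions
#' @export
percentIdentity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal aligned length")
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  keep <- va != GAP_CHAR & vb != GAP_CHAR
  if (!any(keep)) return(0)
  sum(va[keep] == vb[keep]) / sum(keep)
}

#' Remove near-identical sequences from an alignment
#'
#' Greedy screen in input order: a record is kept iff its identity to every
#' previously kept record is at most `threshold`; records strictly above the
#' threshold to any kept record are excluded (the "> 90 % identity excluded"
#' rule, with the default threshold 0.90). Kept records preserve input order,
#' so the pass is idempotent and deterministic.
#'
#' @param aln a [MultiBlockAlignment-class].
#' @param threshold identity ceiling in (0, 1\]; default 0.90.
#' @return A [MultiBlockAlignment-class] with the kept records.
#' @export
filterRedundant <- function(aln, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  chars <- as.character(records(aln))
  # residues as small integers, gaps as NA, for vectorised row comparisons
  mat <- do.call(rbind, strsplit(chars, "", fixed = TRUE))
  code <- matrix(match(mat, ALLOWED_CHARS), nrow = nrow(mat))
  code[mat == GAP_CHAR] <- NA_integer_
  kept <- integer(0)
  for (k in seq_along(chars)) {
    if (length(kept)) {
      keptMat <- code[kept, , drop = FALSE]
      cand <- rep(code[k, ], each = length(kept))
      comparable <- !is.na(keptMat) & !is.na(cand)
      matches <- rowSums(comparable & keptMat == cand, na.rm = TRUE)
      nComp <- rowSums(comparable)
      ident <- ifelse(nComp == 0, 0, matches / nComp)
      if (any(ident > threshold)) next
    }
    kept <- c(kept, k)
  }
  new("MultiBlockAlignment", records = records(aln)[kept],
      segments = segmentRanges(aln))
}
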