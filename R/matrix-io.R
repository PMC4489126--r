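## Scoring-matrix file I/O in the NCBI/EMBOSS text format: '#' comment lines,
## a column-label row, then one labelled row of scores per residue. Files
## written here are readable by common alignment tools and round-trip through
## readMatrix().

#' Write a substitution matrix in NCBI/EMBOSS text format
#'
#' Writes the integer scores with `#` header comments carrying provenance,
#' the background frequencies and the relative entropy, so a written file can
#' be read back (by [readMatrix()] or by standard alignment tools).
#' `writeMatrixReal` writes a TSV with the unrounded scores instead (p_i and
#' H in the header; observed and expected probabilities too when a
#' [ProbabilityTables-class] is supplied).
#'
#' @param m a [SubstitutionMatrix-class].
#' @param path output file path.
#' @param comment extra character lines to include in the header.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(m, path, comment = character(0)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# famsubmat %s substitution matrix (scale %g)",
                       as.character(utils::packageVersion("famsubmat")),
                       m@scaleFactor),
               paste0("# ", comment)[seq_along(comment)]), con)
  if (!anyNA(m@background))
    writeLines(sprintf("# p: %s", paste(sprintf("%s=%.6f", AA_ORDER,
                                                m@background), collapse = " ")), con)
  if (!is.na(m@relativeEntropy["unscaled_bits"]))
    writeLines(sprintf("# H: unscaled_bits=%.6f paper_scaled=%.6f",
                       m@relativeEntropy["unscaled_bits"],
                       m@relativeEntropy["paper_scaled"]), con)
  writeLines(paste(" ", paste(sprintf("%3s", AA_ORDER), collapse = " ")), con)
  for (a in AA_ORDER)
    writeLines(paste(a, paste(sprintf("%3d", as.integer(m@scoresInt[a, ])),
                              collapse = " ")), con)
  invisible(path)
}

#' @rdname writeMatrix
#' @param probs optional [ProbabilityTables-class]; if given, O_ij and e_ij
#'   are appended as additional TSV sections.
#' @export
writeMatrixReal <- function(m, path, probs = NULL, comment = character(0)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# famsubmat real-valued scores",
               paste0("# ", comment)[seq_along(comment)]), con)
  if (!anyNA(m@background))
    writeLines(sprintf("# p: %s", paste(sprintf("%s=%.6f", AA_ORDER,
                                                m@background), collapse = " ")), con)
  if (!is.na(m@relativeEntropy["unscaled_bits"]))
    writeLines(sprintf("# H: unscaled_bits=%.6f paper_scaled=%.6f",
                       m@relativeEntropy["unscaled_bits"],
                       m@relativeEntropy["paper_scaled"]), con)
  writeSection <- function(tag, mat) {
    writeLines(sprintf("# section: %s", tag), con)
    writeLines(paste(c("", AA_ORDER), collapse = "\t"), con)
    for (a in AA_ORDER)
      writeLines(paste(c(a, format(mat[a, ], digits = 10)), collapse = "\t"), con)
  }
  writeSection("scores_real", m@scoresReal)
  if (!is.null(probs)) {
    writeSection("observed", observedProbs(probs))
    writeSection("expected", expectedProbs(probs))
  }
  invisible(path)
}

#' Read a scoring matrix from an NCBI/EMBOSS text file
#'
#' Parses the standard text format used to distribute published matrices
#' (BLOSUM, PAM and relatives). Lowercase labels are uppercased; files with
#' extra columns (B, Z, X, *) are accepted and restricted to the 20 standard
#' residues; asymmetric or non-square tables are rejected. Background
#' frequencies and relative entropy are recovered from header comments when
#' present (as written by [writeMatrix()]), otherwise left NA.
#'
#' @param path matrix file path.
#' @return A [SubstitutionMatrix-class] (scoresReal equal to the parsed
#'   integer scores; scale recorded from the header when available).
#' @export
readMatrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  comments <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("matrix format error: no score rows found")
  labels <- toupper(strsplit(trimws(body[1]), "\\s+")[[1]])
  rows <- body[-1L]
  if (length(rows) != length(labels))
    stop(sprintf("matrix format error: %d column labels but %d rows",
                 length(labels), length(rows)))
  sc <- matrix(NA_real_, length(labels), length(labels),
               dimnames = list(labels, labels))
  for (r in rows) {
    parts <- strsplit(trimws(r), "\\s+")[[1]]
    lab <- toupper(parts[1])
    if (!lab %in% labels) stop("matrix format error: unknown row label ", lab)
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (length(vals) != length(labels) || anyNA(vals))
      stop("matrix format error: row ", lab, " does not have ",
           length(labels), " numeric entries")
    sc[lab, ] <- vals
  }
  if (!all(AA_ORDER %in% labels))
    stop("matrix format error: missing residues ",
         paste(setdiff(AA_ORDER, labels), collapse = ", "))
  sc <- sc[AA_ORDER, AA_ORDER]
  if (max(abs(sc - t(sc))) > 0)
    stop("matrix format error: table is not symmetric")
  bg <- rep(NA_real_, 20); names(bg) <- AA_ORDER
  pLine <- grep("^#\\s*p:", comments, value = TRUE)
  if (length(pLine)) {
    kv <- regmatches(pLine[1], gregexpr("[A-Z]=[0-9.eE+-]+", pLine[1]))[[1]]
    for (item in kv) {
      a <- sub("=.*", "", item)
      if (a %in% AA_ORDER) bg[a] <- as.numeric(sub(".*=", "", item))
    }
  }
  H <- c(unscaled_bits = NA_real_, paper_scaled = NA_real_)
  hLine <- grep("^#\\s*H:", comments, value = TRUE)
  if (length(hLine)) {
    u <- regmatches(hLine[1], regexpr("unscaled_bits=[0-9.eE+-]+", hLine[1]))
    s <- regmatches(hLine[1], regexpr("paper_scaled=[0-9.eE+-]+", hLine[1]))
    if (length(u)) H["unscaled_bits"] <- as.numeric(sub(".*=", "", u))
    if (length(s)) H["paper_scaled"] <- as.numeric(sub(".*=", "", s))
  }
  scale <- 2
  sLine <- regmatches(comments, regexpr("scale [0-9.]+", comments))
  if (length(sLine)) scale <- as.numeric(sub("scale ", "", sLine[1]))
  new("SubstitutionMatrix", scoresReal = sc, scoresInt = roundHalfAway(sc),
      scaleFactor = scale, background = bg, relativeEntropy = H,
      provenance = list(source = path))
}

#' Wrap a plain score matrix as a SubstitutionMatrix
#'
#' Convenience for consuming matrices already in R (e.g. `Biostrings`'s
#' BLOSUM62 data) in the comparison and alignment operations.
#'
#' @param scores square numeric matrix labelled by residue letters; extra
#'   rows/columns beyond the 20 standard residues are dropped.
#' @param scale scale factor to record (default 2).
#' @return A [SubstitutionMatrix-class] with NA background and entropy.
#' @export
asSubstitutionMatrix <- function(scores, scale = 2) {
  rownames(scores) <- toupper(rownames(scores))
  colnames(scores) <- toupper(colnames(scores))
  if (!all(AA_ORDER %in% rownames(scores)) || !all(AA_ORDER %in% colnames(scores)))
    stop("score matrix must cover the 20 standard residues")
  sc <- scores[AA_ORDER, AA_ORDER]
  bg <- rep(NA_real_, 20); names(bg) <- AA_ORDER
  new("SubstitutionMatrix", scoresReal = sc, scoresInt = roundHalfAway(sc),
      scaleFactor = scale, background = bg,
      relativeEntropy = c(unscaled_bits = NA_real_, paper_scaled = NA_real_),
      provenance = list(source = "matrix"))
}
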