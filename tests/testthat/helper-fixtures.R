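# Fixtures and independent oracles used across the suite. Oracles are written
# as plain loops, independent of the vectorised implementation they check.

AAs <- aminoAcids()

# the hand-worked 3-sequence, 2-column toy: columns [A,A,C] and [L,L,L]
toyAlignment <- function() {
  multiBlockAlignment(c(s1 = "AL", s2 = "AL", s3 = "CL"),
                      data.frame(name = "TM1", start = 1, end = 2))
}

toyBlock <- function() extractBlocks(toyAlignment())[[1]]

blockFromColumns <- function(..., name = "blk") {
  cols <- list(...)
  m <- do.call(cbind, cols)
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  new("AlignmentBlock", segmentName = name, mat = m)
}

randomBlock <- function(nrow, ncol, gapProb = 0.1, ambigProb = 0.05) {
  letters20 <- c(AAs, "X", "B", "-")
  probs <- c(rep((1 - gapProb - ambigProb) / 20, 20),
             ambigProb / 2, ambigProb / 2, gapProb)
  m <- matrix(sample(letters20, nrow * ncol, TRUE, prob = probs), nrow, ncol)
  rownames(m) <- paste0("s", seq_len(nrow))
  new("AlignmentBlock", segmentName = "rnd", mat = m)
}

# brute-force pair counting: enumerate every pair of rows in every column
bruteCountPairs <- function(blocks) {
  f <- matrix(0, 20, 20, dimnames = list(AAs, AAs))
  for (b in blocks) {
    m <- b@mat
    for (col in seq_len(ncol(m))) {
      for (r1 in seq_len(nrow(m) - 1)) for (r2 in (r1 + 1):nrow(m)) {
        a <- m[r1, col]; bb <- m[r2, col]
        if (a %in% AAs && bb %in% AAs) {
          f[a, bb] <- f[a, bb] + 1
          if (a != bb) f[bb, a] <- f[bb, a] + 1
        }
      }
    }
  }
  f
}

# brute-force probability pipeline from a raw symmetric count table
bruteProbabilities <- function(f) {
  tot <- 0
  for (i in 1:20) for (j in 1:i) tot <- tot + f[i, j]
  O <- f / tot
  p <- numeric(20); names(p) <- AAs
  for (i in 1:20) {
    p[i] <- O[i, i]
    for (j in seq_len(20)[-i]) p[i] <- p[i] + O[i, j] / 2
  }
  e <- matrix(0, 20, 20, dimnames = list(AAs, AAs))
  for (i in 1:20) for (j in 1:20)
    e[i, j] <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
  list(total = tot, O = O, p = p, e = e)
}

randomSequence <- function(len) paste(sample(AAs, len, TRUE), collapse = "")

blosum62Matrix <- function() {
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  asSubstitutionMatrix(e$BLOSUM62)
}

# least-squares superposition error after centering and an orthogonal map
# (rotation/reflection, no scaling)
procrustesError <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Xc) %*% Yc)
  Q <- s$u %*% t(s$v)
  sqrt(sum((Xc %*% Q - Yc)^2))
}
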