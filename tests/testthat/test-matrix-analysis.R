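test_that("difference matrices subtract integer scores elementwise", {
  b62 <- blosum62Matrix()
  toy <- buildMatrix(toyAlignment(), redundancy = NULL)
  expect_true(all(differenceMatrix(b62, b62) == 0))
  ab <- differenceMatrix(toy, b62)
  ba <- differenceMatrix(b62, toy)
  expect_true(all(ab + ba == 0))
  expect_equal(ab["A", "C"], scoresInt(toy)["A", "C"] - scoresInt(b62)["A", "C"])
  expect_equal(ab["A", "A"], scoresInt(toy)["A", "A"] - 4)  # hand subtraction
})

test_that("score-to-distance transforms give zero self-distance and the stated formulas", {
  b62 <- blosum62Matrix()
  d <- scoreToDistance(b62)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  expect_equal(d["A", "C"], 4 + 9 - 2 * 0)  # S_AA + S_CC - 2 S_AC
  expect_equal(d, t(d))

  # identity-like matrix: off-diagonal distances all 2c
  idLike <- asSubstitutionMatrix(
    matrix(diag(5, 20), 20, dimnames = list(AAs, AAs)))
  dId <- scoreToDistance(idLike)
  expect_true(all(dId[upper.tri(dId)] == 10))

  dc <- scoreToDistance(b62, method = "correlation")
  expect_true(all(diag(dc) == 0))
  expect_true(all(abs(dc - t(dc)) < 1e-12))
  expect_error(scoreToDistance(idLike, method = "correlation"), NA)

  flat <- asSubstitutionMatrix(matrix(1, 20, 20, dimnames = list(AAs, AAs)))
  expect_error(scoreToDistance(flat, method = "correlation"), "constant")
})

test_that("UPGMA reproduces the hand-worked 3-leaf case and the tie-break contract", {
  lab <- c("A", "B", "C")
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, dimnames = list(lab, lab))
  tr <- upgma(d)
  expect_equal(tr$height, c(1, 3))
  expect_identical(sort(tr$labels), lab)
  # cophenetic() reports merge heights; tree (path) distance is twice that
  cc <- as.matrix(stats::cophenetic(tr))
  expect_equal(2 * cc["A", "B"], 2)
  expect_equal(2 * cc["A", "C"], 6)
  expect_equal(2 * cc["B", "C"], 6)

  # equal distances: merges all at the same height, joined in label order
  lab4 <- c("D", "B", "C", "A")
  dEq <- matrix(4, 4, 4, dimnames = list(lab4, lab4)); diag(dEq) <- 0
  trEq <- upgma(dEq)
  expect_true(all(trEq$height == 2))
  first <- sort(trEq$labels[-trEq$merge[1, ]])
  expect_identical(first, c("A", "B"))  # lexicographically smallest pair first

  expect_error(upgma(matrix(c(0, NA, NA, 0), 2)), "NA")
})

test_that("UPGMA agrees with average-linkage hclust heights on random distances", {
  set.seed(3)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- paste0("L", seq_len(n))
    d <- as.matrix(dist(x))
    tr <- upgma(d)
    hc <- stats::hclust(as.dist(d), method = "average")
    # same merge heights (ours are half the merged distance)
    expect_equal(sort(tr$height), sort(hc$height / 2), tolerance = 1e-12)
    # cophenetic distances are ultrametric and bounded by the largest input
    cc <- as.matrix(stats::cophenetic(tr))
    expect_equal(cc, as.matrix(stats::cophenetic(hc)) / 2, tolerance = 1e-12)
    expect_lte(max(cc), max(d))
    for (i in 1:n) for (j in 1:n) for (l in 1:n)
      expect_lte(cc[i, j], max(cc[i, l], cc[j, l]) + 1e-9)
  }
})

test_that("UPGMA output converts to an ultrametric phylo and Newick", {
  d <- scoreToDistance(blosum62Matrix())
  tr <- upgma(d)
  expect_identical(sort(tr$labels), sort(AAs))
  ph <- ape::as.phylo(tr)
  expect_identical(sort(ph$tip.label), sort(AAs))
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, nwk)
  back <- ape::read.tree(nwk)
  expect_identical(sort(back$tip.label), sort(AAs))
  # root-to-tip depths all equal (ultrametric)
  depths <- ape::node.depth.edgelength(back)[seq_along(back$tip.label)]
  expect_lt(diff(range(depths)), 1e-8)
})

test_that("classical MDS recovers planted configurations and fixes signs", {
  # two points at distance 4 -> 1-D coordinates +/- 2
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  pr <- classicalMDS(d2, k = 1)
  expect_equal(sort(as.vector(pr$points)), c(-2, 2))

  set.seed(9)
  X <- matrix(rnorm(20 * 2), 20)
  rownames(X) <- AAs
  d <- as.matrix(dist(X))
  pr <- classicalMDS(d, k = 2)
  expect_false(pr$truncated)
  expect_lt(procrustesError(pr$points, X), 1e-8)
  # pairwise distances reproduced
  expect_equal(as.matrix(dist(pr$points)), d, ignore_attr = TRUE,
               tolerance = 1e-8)
  # centroid at origin, spectrum non-increasing, axis signs fixed
  expect_true(all(abs(colMeans(pr$points)) < 1e-10))
  expect_true(all(diff(pr$eigenvalues) < 1e-8))
  for (ax in 1:2) expect_gt(pr$points[which.max(abs(pr$points[, ax])), ax], 0)
  # deterministic output agrees with the stats oracle up to sign
  cmd <- stats::cmdscale(d, k = 2)
  expect_lt(procrustesError(pr$points, cmd), 1e-8)

  # rank-deficient input: more requested dimensions than positive eigenvalues
  expect_warning(pr1 <- classicalMDS(d2, k = 1 + 0), NA)
  dLine <- as.matrix(dist(matrix(1:5, 5)))
  expect_warning(prT <- classicalMDS(dLine, k = 3), "positive eigenvalue")
  expect_true(prT$truncated)
  expect_equal(ncol(prT$points), 1L)
})

test_that("matrix files round-trip and malformed files are rejected", {
  b62 <- blosum62Matrix()
  f <- withr::local_tempfile(fileext = ".txt")
  writeMatrix(b62, f)
  back <- readMatrix(f)
  expect_equal(scoresInt(back), scoresInt(b62))

  # a built matrix keeps background and entropy through the round trip
  m <- buildMatrix(toyAlignment(), redundancy = NULL)
  writeMatrix(m, f)
  back <- readMatrix(f)
  expect_equal(scoresInt(back), scoresInt(m))
  expect_equal(backgroundFreqs(back), backgroundFreqs(m), tolerance = 1e-5)
  expect_equal(relativeEntropy(back), relativeEntropy(m), tolerance = 1e-6)

  lines <- readLines(f)
  labelRow <- grep("^\\s+A", lines)[1]
  writeLines(lines[-(labelRow + 3)], f)  # drop one score row
  expect_error(readMatrix(f), "format error")

  # lowercase labels accepted, asymmetric tables rejected
  writeLines(c(paste(" ", paste(tolower(AAs), collapse = " ")),
               vapply(seq_along(AAs), function(i)
                 paste(c(tolower(AAs)[i], rep("0", 20)), collapse = " "),
                 character(1))), f)
  expect_equal(unname(scoresInt(readMatrix(f))), matrix(0, 20, 20))
  bad <- readLines(f)
  bad[2] <- paste(c("a", "0", "1", rep("0", 18)), collapse = " ")
  writeLines(bad, f)
  expect_error(readMatrix(f), "not symmetric")
})
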