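test_that("the worked toy block reproduces every hand-derived quantity", {
  cnt <- countPairs(list(toyBlock()))
  f <- pairCounts(cnt)
  expect_equal(f["A", "A"], 1)
  expect_equal(f["A", "C"], 2)
  expect_equal(f["C", "A"], 2)
  expect_equal(f["L", "L"], 3)
  expect_equal(totalPairs(cnt), 6)

  p <- probabilityTables(cnt)
  O <- observedProbs(p)
  expect_equal(O["A", "A"], 1 / 6)
  expect_equal(O["A", "C"], 1 / 3)
  expect_equal(O["L", "L"], 1 / 2)

  bg <- backgroundFreqs(p)
  expect_equal(unname(bg["A"]), 1 / 3)
  expect_equal(unname(bg["C"]), 1 / 6)
  expect_equal(unname(bg["L"]), 1 / 2)

  e <- expectedProbs(p)
  expect_equal(e["A", "A"], 1 / 9)
  expect_equal(e["A", "C"], 1 / 9)
  expect_equal(e["L", "L"], 1 / 4)

  m <- logOdds(p)
  expect_equal(scoresReal(m)["A", "A"], 2 * log2(1.5))
  expect_equal(scoresReal(m)["A", "C"], 2 * log2(3))
  expect_equal(scoresReal(m)["L", "L"], 2)
  expect_equal(scoresInt(m)["A", "A"], 1)
  expect_equal(scoresInt(m)["A", "C"], 3)
  expect_equal(scoresInt(m)["L", "L"], 2)

  expect_equal(relativeEntropy(p),
               (1 / 6) * log2(1.5) + (1 / 3) * log2(3) + (1 / 2) * 1)
  expect_equal(relativeEntropy(p), 1.1258, tolerance = 1e-4)
  expect_equal(relativeEntropy(p, "paper_scaled"), 2 * relativeEntropy(p))
  expect_equal(relativeEntropy(m), relativeEntropy(p))
})

test_that("pair counting obeys the gap/ambiguity exclusion and additivity", {
  b <- blockFromColumns(c("A", "-", "C"))
  f <- pairCounts(countPairs(list(b)))
  expect_equal(f["A", "C"], 1)
  expect_equal(sum(f), 2)  # the symmetric pair stored twice, nothing else

  bx <- blockFromColumns(c("A", "X", "C", "B"))
  expect_equal(pairCounts(countPairs(list(bx)))["A", "C"], 1)
  expect_equal(totalPairs(countPairs(list(bx))), 1)

  one <- countPairs(list(toyBlock()))
  two <- countPairs(list(toyBlock(), toyBlock()))
  expect_equal(pairCounts(two), 2 * pairCounts(one))
})

test_that("pipeline matches the brute-force oracle on random small blocks", {
  set.seed(101)
  for (k in 1:200) {
    blocks <- list(randomBlock(sample(2:6, 1), sample(1:5, 1)))
    cnt <- countPairs(blocks)
    fOracle <- bruteCountPairs(blocks)
    expect_identical(unname(pairCounts(cnt)), unname(fOracle))
    if (totalPairs(cnt) == 0) {
      expect_error(probabilityTables(cnt), "no observed pairs")
      next
    }
    ref <- bruteProbabilities(fOracle)
    p <- probabilityTables(cnt)
    expect_equal(totalPairs(cnt), ref$total)
    expect_equal(observedProbs(p), ref$O, tolerance = 1e-12)
    expect_equal(backgroundFreqs(p), ref$p, tolerance = 1e-12)
    expect_equal(expectedProbs(p), ref$e, tolerance = 1e-12)
  }
})

test_that("probability mass, symmetry and non-negative entropy hold on random inputs", {
  set.seed(7)
  for (k in 1:50) {
    blocks <- list(randomBlock(5, 6, gapProb = 0.15))
    cnt <- countPairs(blocks)
    if (totalPairs(cnt) == 0) next
    p <- probabilityTables(cnt)
    O <- observedProbs(p); e <- expectedProbs(p)
    expect_equal(sum(O[upper.tri(O, diag = TRUE)]), 1, tolerance = 1e-9)
    expect_equal(sum(backgroundFreqs(p)), 1, tolerance = 1e-9)
    expect_equal(sum(e[upper.tri(e, diag = TRUE)]), 1, tolerance = 1e-9)
    expect_equal(O, t(O))
    expect_equal(e, t(e))
    m <- logOdds(p)
    expect_equal(scoresReal(m), t(scoresReal(m)))
    expect_gte(relativeEntropy(p), 0)
  }
})

test_that("uniform observed probabilities give uniform backgrounds", {
  f <- matrix(1, 20, 20, dimnames = list(AAs, AAs))
  cnt <- new("PairCountTable", counts = f,
             totalPairs = sum(f[upper.tri(f, diag = TRUE)]))
  # O is uniform over the 210 triangle cells up to the shared off-diagonal mass
  bg <- backgroundFreqs(probabilityTables(cnt))
  expect_equal(unname(bg), rep(1 / 20, 20), tolerance = 1e-12)
})

test_that("log-odds scaling is linear and O = e gives zero scores", {
  p <- probabilityTables(countPairs(list(toyBlock())))
  m1 <- logOdds(p, scale = 2)
  m2 <- logOdds(p, scale = 4)
  expect_equal(scoresReal(m2), 2 * scoresReal(m1))

  # background-consistent observed table: O = e exactly
  bg <- rep(1 / 20, 20); names(bg) <- AAs
  e <- expectedProbabilities(bg)
  pe <- new("ProbabilityTables", observed = e, background = bg, expected = e)
  expect_true(all(abs(scoresReal(logOdds(pe))) < 1e-12))
  expect_equal(relativeEntropy(pe), 0)
})

test_that("unobserved cells take the floor of the defined scores", {
  m <- logOdds(probabilityTables(countPairs(list(toyBlock()))))
  defined <- c(scoresReal(m)["A", "A"], scoresReal(m)["A", "C"],
               scoresReal(m)["L", "L"])
  expect_equal(scoresReal(m)["W", "W"], min(defined))
  expect_equal(scoresReal(m)["A", "V"], min(defined))
  mFixed <- logOdds(probabilityTables(countPairs(list(toyBlock()))),
                    zeroScore = -9)
  expect_equal(scoresReal(mFixed)["W", "W"], -9)
  expect_equal(scoresInt(mFixed)["W", "W"], -9)
})

test_that("permuting rows or blocks and relabeling residues behave equivariantly", {
  set.seed(11)
  blocks <- list(randomBlock(5, 4), randomBlock(4, 3))
  base <- pairCounts(countPairs(blocks))
  shuffledRows <- lapply(blocks, function(b) {
    m <- b@mat[sample(nrow(b@mat)), , drop = FALSE]
    new("AlignmentBlock", segmentName = b@segmentName, mat = m)
  })
  expect_equal(pairCounts(countPairs(rev(shuffledRows))), base)

  # relabeling amino acids permutes the count table accordingly
  perm <- setNames(sample(AAs), AAs)
  relabeled <- lapply(blocks, function(b) {
    m <- b@mat
    std <- m %in% AAs
    m[std] <- perm[m[std]]
    new("AlignmentBlock", segmentName = b@segmentName, mat = m)
  })
  fRel <- pairCounts(countPairs(relabeled))
  expect_equal(fRel[perm[AAs], perm[AAs]], base[AAs, AAs],
               ignore_attr = TRUE)
})

test_that("composition counts non-gap, non-ambiguous characters only", {
  b <- blockFromColumns(c("L", "L", "L", "V"))
  comp <- composition(list(b))
  expect_equal(unname(comp["L"]), 0.75)
  expect_equal(unname(comp["V"]), 0.25)
  expect_equal(sum(comp), 1)

  bg <- blockFromColumns(c("L", "-", "L"), c("X", "L", "-"))
  expect_equal(unname(composition(list(bg))["L"]), 1)

  allGap <- blockFromColumns(c("-", "-"))
  expect_error(composition(list(allGap)), "no countable residues")
})

test_that("grouped fractions sum the named residues and reject unknown letters", {
  comp <- composition(list(toyBlock()))
  expect_equal(groupedFraction(comp, AAs), 1)
  expect_equal(groupedFraction(comp, character(0)), 0)
  expect_equal(groupedFraction(comp, c("A", "C")),
               unname(comp["A"] + comp["C"]))
  expect_error(groupedFraction(comp, c("A", "J")), "unknown residue")
})

test_that("column conservation uses gap-excluded denominators and flags all-gap columns", {
  b <- blockFromColumns(c("N", "N", "N", "N"), c("N", "N", "D", "-"),
                        c("-", "-", "-", "-"))
  cons <- columnConservation(b)
  expect_equal(unname(cons$freq["N", 1]), 1)
  expect_equal(unname(cons$freq["N", 2]), 2 / 3)
  expect_equal(unname(cons$freq["D", 2]), 1 / 3)
  expect_true(cons$allGap[3])
  expect_equal(maxConservation(b, "N"), 1)
  expect_equal(maxConservation(b, "D"), 1 / 3)
})

test_that("buildMatrix composes the pipeline end to end", {
  m <- buildMatrix(toyAlignment(), redundancy = NULL)
  expect_equal(scoresInt(m)["A", "A"], 1)
  expect_equal(scoresInt(m)["A", "C"], 3)
  expect_equal(scoresInt(m)["L", "L"], 2)
  expect_equal(relativeEntropy(m), 1.1258, tolerance = 1e-4)
  expect_equal(m@provenance$total_pairs, 6)

  # duplicating rows changes nothing once the redundancy filter runs
  aln <- generateAlignment(generatorConfig(nSequences = 12, nColumns = 8,
                                           nSegments = 2, seed = 5))
  dup <- multiBlockAlignment(
    setNames(rep(as.character(records(aln)), 2),
             c(names(records(aln)), paste0(names(records(aln)), "_dup"))),
    data.frame(name = names(segmentRanges(aln)),
               start = IRanges::start(segmentRanges(aln)),
               end = IRanges::end(segmentRanges(aln))))
  expect_equal(scoresReal(buildMatrix(dup, redundancy = 0.90)),
               scoresReal(buildMatrix(aln, redundancy = 0.90)))

  # Laplace pseudocount leaves no unobserved cell
  mp <- buildMatrix(toyAlignment(), redundancy = NULL, pseudocount = 1)
  expect_equal(mp@provenance$zero_cells, 0)
})
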