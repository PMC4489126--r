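## Matrix comparison and residue clustering: difference matrices, a
## score-to-dissimilarity transform, UPGMA with a fixed deterministic
## tie-break, and classical (Torgerson) multidimensional scaling with a fixed
## axis-sign convention.

#' Elementwise difference of two substitution matrices
#'
#' A - B on the integer scores (the published form of the matrices), with
#' shared residue ordering; used to visualise where one matrix rewards or
#' penalises an exchange more than another (e.g. a family matrix versus
#' BLOSUM62).
#'
#' @param a,b [SubstitutionMatrix-class] objects.
#' @param labels length-2 character naming A and B in the result attributes.
#' @return 20x20 numeric matrix of a - b with attribute `labels`.
#' @export
differenceMatrix <- function(a, b, labels = c("A", "B")) {
  sa <- scoresInt(a); sb <- scoresInt(b)
  if (!identical(dimnames(sa), dimnames(sb)))
    stop("matrices must share the same residue ordering")
  structure(sa - sb, labels = labels)
}

#' Dissimilarity between residues implied by a scoring matrix
#'
#' `"diagonal_deficit"` (default): d_ij = S_ii + S_jj - 2 S_ij, floored at 0 —
#' monotone decreasing in the log-odds and zero on self. `"correlation"`:
#' d_ij = 1 - Pearson correlation of matrix rows i and j, a common choice in
#' published matrix-clustering work. Both give d_ii = 0.
#'
#' @param m a [SubstitutionMatrix-class].
#' @param method `"diagonal_deficit"` or `"correlation"`.
#' @param scores `"int"` (default; the published integer form) or `"real"`.
#' @return Symmetric non-negative 20x20 matrix with zero diagonal.
#' @export
scoreToDistance <- function(m, method = c("diagonal_deficit", "correlation"),
                            scores = c("int", "real")) {
  method <- match.arg(method)
  S <- switch(match.arg(scores), int = scoresInt(m), real = scoresReal(m))
  if (method == "diagonal_deficit") {
    d <- outer(diag(S), diag(S), "+") - 2 * S
    d[d < 0] <- 0
  } else {
    if (any(apply(S, 1, stats::sd) == 0))
      stop("correlation distance undefined: constant matrix row")
    d <- 1 - stats::cor(t(S))
    d[d < 0] <- 0
  }
  diag(d) <- 0
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair-group method with arithmetic mean: repeatedly merge the
#' closest pair of clusters, the distance between clusters being the
#' unweighted mean of all member pairwise distances; a merge is placed at
#' height = half the merged distance, so the result is ultrametric. Ties are
#' broken by the lexicographically smallest pair of cluster labels (a cluster
#' is labelled by its lexicographically smallest member), making the output
#' deterministic.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   labelled dimnames.
#' @return An object of class `hclust` (usable with [stats::cophenetic()],
#'   [ape::as.phylo()], `plot()`, ...) with `$height` the merge heights.
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$height   # 1 then 3
#' @export
upgma <- function(d) {
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  stopifnot(nrow(d) == ncol(d), max(abs(d - t(d))) < 1e-9, all(diag(d) == 0))
  labels <- rownames(d)
  n <- nrow(d)
  # active clusters: list of member leaf indices; id: negative leaf index or
  # positive merge index (hclust convention); tag: smallest member label
  clusters <- lapply(seq_len(n), function(i) i)
  ids <- -seq_len(n)
  tags <- labels
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      ti <- tags[i]; tj <- tags[j]
      key <- if (ti < tj) c(ti, tj) else c(tj, ti)
      if (is.null(best) || D[i, j] < best$d - 1e-12 ||
          (abs(D[i, j] - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = D[i, j], key = key)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- c(ids[i], ids[j])
    height[step] <- best$d / 2
    newMembers <- c(clusters[[i]], clusters[[j]])
    # unweighted mean over all member leaf pairs
    newRow <- vapply(seq_len(m), function(k) {
      if (k == i || k == j) return(NA_real_)
      mean(d[newMembers, clusters[[k]], drop = FALSE])
    }, numeric(1))
    keep <- setdiff(seq_len(m), c(i, j))
    clusters <- c(clusters[keep], list(newMembers))
    tags <- c(tags[keep], min(tags[c(i, j)]))
    ids <- c(ids[keep], step)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newRow[keep]),
               c(newRow[keep], 0))
  }
  structure(list(merge = merge, height = height,
                 order = upgmaLeafOrder(merge, n), labels = labels,
                 method = "upgma", call = match.call(),
                 dist.method = "user-supplied"),
            class = "hclust")
}

upgmaLeafOrder <- function(merge, n) {
  walk <- function(id) {
    if (id < 0) return(-id)
    c(walk(merge[id, 1]), walk(merge[id, 2]))
  }
  walk(nrow(merge))
}

#' Write a dendrogram as Newick
#'
#' Converts the UPGMA tree to an [ape::phylo] and writes Newick with branch
#' lengths (differences of merge heights).
#'
#' @param tree `hclust` object from [upgma()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers -d^2/2, eigendecomposes, and uses the top `k` non-negative
#' eigenpairs as coordinates. The embedding is centred at the origin and
#' deterministic: each axis's sign is fixed so that its largest-magnitude
#' coordinate is positive. If fewer than `k` positive eigenvalues exist the
#' output is truncated and flagged.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k number of output dimensions (default 2, at most n - 1).
#' @return A list with `points` (n x k' coordinate matrix, labelled rows),
#'   `eigenvalues` (full non-increasing spectrum) and `truncated` (TRUE if
#'   k' < k for lack of positive eigenvalues).
#' @export
classicalMDS <- function(d, k = 2) {
  stopifnot(nrow(d) == ncol(d), k >= 1, k <= nrow(d) - 1)
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  pos <- which(eg$values > max(eg$values[1], 0) * 1e-12 & eg$values > 0)
  kEff <- min(k, length(pos))
  truncated <- kEff < k
  if (truncated)
    warning(sprintf("only %d positive eigenvalue(s); returning %d dimension(s)",
                    length(pos), kEff))
  pts <- eg$vectors[, seq_len(kEff), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(kEff)]), kEff)
  for (ax in seq_len(kEff)) {
    big <- which.max(abs(pts[, ax]))
    if (pts[big, ax] < 0) pts[, ax] <- -pts[, ax]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("dim", seq_len(kEff))
  list(points = pts, eigenvalues = eg$values, truncated = truncated)
}

#' Write an MDS projection as TSV
#'
#' @param proj result of [classicalMDS()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeProjection <- function(proj, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# eigenvalues: %s",
                     paste(format(proj$eigenvalues, digits = 8), collapse = " ")),
             con)
  tab <- data.frame(residue = rownames(proj$points), proj$points,
                    check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
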