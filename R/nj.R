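# Neighbour-Joining tree inference (Saitou-Nei agglomeration).

#' Neighbour-Joining tree from a distance matrix
#'
#' Classic Saitou-Nei Neighbour-Joining: repeatedly join the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` (ties broken by smallest index pair),
#' with the standard branch-length formulas. A negative branch length is
#' clamped to zero and its deficit moved to the sibling edge, preserving the
#' joined pair's path length. Additive matrices are recovered exactly.
#'
#' @param D Symmetric distance matrix with zero diagonal and unique id
#'   dimnames; at least 2 taxa (2 taxa give a single split edge).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) abort("distance matrix must be symmetric")
  ids <- rownames(D)
  if (is.null(ids) || anyDuplicated(ids)) abort("distance matrix needs unique id dimnames")
  n <- nrow(D)
  if (n < 2) abort("need at least 2 taxa")
  if (n == 2) {
    d <- D[1, 2]
    return(ape::read.tree(text = sprintf("(%s:%.17g,%s:%.17g);",
                                         ids[1], d / 2, ids[2], d / 2)))
  }
  labels <- ids                      # Newick fragment per active node
  while (n > 3) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (i, j) index pair among the minima
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    d_ij <- D[i, j]
    li <- d_ij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d_ij - li
    if (li < 0) { li <- 0; lj <- d_ij }
    if (lj < 0) { lj <- 0; li <- d_ij }
    new_lab <- sprintf("(%s:%.17g,%s:%.17g)", labels[i], li, labels[j], lj)
    d_new <- (D[i, ] + D[j, ] - d_ij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    labels <- c(labels[keep], new_lab)
    n <- n - 1
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  len <- pmax(c(la, lb, lc), 0)
  txt <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 labels[1], len[1], labels[2], len[2], labels[3], len[3])
  ape::read.tree(text = txt)
}
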