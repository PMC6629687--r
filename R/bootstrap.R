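# Column-resampling bootstrap over Poisson-corrected Neighbour-Joining.

#' Bootstrap replicate trees
#'
#' Resamples alignment columns with replacement (same length), recomputes
#' Poisson-corrected distances and a Neighbour-Joining tree per replicate.
#' Replicates in which some pair saturates (`p >= cap`) or has no comparable
#' sites are dropped with a warning; the count of dropped replicates is
#' attached as attribute `dropped`.
#'
#' @param aln Alignment tibble.
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed; the replicate list is reproducible from it.
#' @param deletion Gap handling, see [p_distance_matrix()].
#' @param cap Saturation guard, see [poisson_correct()].
#' @return List of `ape::phylo` trees (length `<= n_reps`).
#' @export
bootstrap_trees <- function(aln, n_reps = 1000, seed = 1,
                            deletion = c("pairwise", "complete"), cap = 0.95) {
  deletion <- match.arg(deletion)
  if (n_reps == 0) return(list())
  m <- alignment_matrix(aln)
  valid <- m != "-" & m != "X"
  n <- nrow(m); nc <- ncol(m)
  ids <- rownames(m)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  # per-pair, per-column difference and comparability indicators
  diff_m <- matrix(FALSE, nrow(pairs), nc)
  comp_m <- matrix(FALSE, nrow(pairs), nc)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    comp_m[k, ] <- valid[i, ] & valid[j, ]
    diff_m[k, ] <- comp_m[k, ] & (m[i, ] != m[j, ])
  }
  set.seed(seed)
  trees <- vector("list", n_reps)
  dropped <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    nd <- rowSums(diff_m[, idx, drop = FALSE])
    ns <- rowSums(comp_m[, idx, drop = FALSE])
    if (any(ns == 0)) { dropped <- dropped + 1L; next }
    p <- nd / ns
    if (any(p >= cap)) { dropped <- dropped + 1L; next }
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    D[pairs] <- -log(1 - p)
    D <- D + t(D)
    trees[[r]] <- nj_tree(D)
  }
  trees <- trees[!purrr::map_lgl(trees, is.null)]
  if (dropped > 0) {
    warn(sprintf("%d bootstrap replicate(s) dropped (saturated or empty pairs)", dropped))
  }
  attr(trees, "dropped") <- dropped
  trees
}
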