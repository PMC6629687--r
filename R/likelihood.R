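# Felsenstein pruning likelihood under an equal-rates 20-state amino-acid
# model (uniform stationary frequencies; every exchange equally likely).
# Branch lengths are in expected substitutions per site, so
# P(same after t) = 1/20 + (19/20) exp(-(20/19) t).

#' Transition probability matrix of the equal-rates amino-acid model
#'
#' @param t Branch length (expected substitutions per site).
#' @return A 20 x 20 stochastic matrix over the canonical residues.
#' @export
aa_transition_matrix <- function(t) {
  e <- exp(-(20 / 19) * t)
  same <- 1 / 20 + (19 / 20) * e
  diffp <- 1 / 20 - (1 / 20) * e
  m <- matrix(diffp, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(m) <- same
  m
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Sums, over alignment columns, the log of the pruned likelihood under the
#' equal-rates amino-acid model with uniform root frequencies. Gaps and `X`
#' are treated as missing data (all-ones partial likelihood). The likelihood
#' is invariant under re-rooting because the model is time-reversible with a
#' uniform stationary distribution.
#'
#' @param tree `ape::phylo` with branch lengths; tip labels must match the
#'   alignment ids.
#' @param aln Alignment tibble.
#' @return Total log-likelihood (natural log).
#' @export
#' @examples
#' aln <- progressive_align(aa_sequences(c("a", "b"), c("DRWYAI", "DRWYAI")))
#' tr <- ape::read.tree(text = "(a:0,b:0);")
#' pruning_log_likelihood(tr, aln)  # 6 * log(1/20)
pruning_log_likelihood <- function(tree, aln) {
  if (!setequal(tree$tip.label, aln$id)) abort("tree leaves do not match alignment ids")
  m <- alignment_matrix(aln)[tree$tip.label, , drop = FALSE]
  nc <- ncol(m)
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(tree$edge)
  partial <- vector("list", nnode)
  idx <- matrix(match(m, AA_ALPHABET), nrow(m), nc)   # NA for gap/X
  for (i in seq_len(ntip)) {
    L <- matrix(0, 20, nc)
    known <- !is.na(idx[i, ])
    L[cbind(idx[i, known], which(known))] <- 1
    L[, !known] <- 1
    partial[[i]] <- L
  }
  for (n in (ntip + 1):nnode) partial[[n]] <- matrix(1, 20, nc)
  scale_log <- 0
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    P <- aa_transition_matrix(tree$edge.length[k])
    partial[[p]] <- partial[[p]] * (P %*% partial[[ch]])
    if (k %% 8 == 0) {                 # rescale to avoid underflow
      mx <- apply(partial[[p]], 2, max)
      mx[mx == 0] <- 1
      partial[[p]] <- sweep(partial[[p]], 2, mx, "/")
      scale_log <- scale_log + sum(log(mx))
    }
  }
  root <- tree$edge[nrow(tree$edge), 1]
  sum(log(colSums(partial[[root]] / 20))) + scale_log
}
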