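# Independent oracles and shared fixtures, built in code.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(len, pool = AA20) {
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

# Exhaustive global-alignment oracle: enumerates every monotone alignment of
# a and b and scores it directly (affine gaps: open + (L-1) * extend per run).
brute_force_align_score <- function(a, b, scoring = scoring_scheme()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  M <- scoring$matrix
  go <- scoring$gap_open
  ge <- scoring$gap_extend
  best <- -Inf
  score_cols <- function(cols) {
    s <- 0
    run <- ""
    for (c in cols) {
      if (c[1] != "-" && c[2] != "-") {
        s <- s + M[c[1], c[2]]
        run <- ""
      } else {
        g <- if (c[1] == "-") "a" else "b"
        s <- s + if (identical(run, g)) ge else go
        run <- g
      }
    }
    s
  }
  rec <- function(i, j, cols) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_cols(cols))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, c(cols, list(c(av[i], bv[j]))))
    }
    if (i <= length(av)) rec(i + 1, j, c(cols, list(c(av[i], "-"))))
    if (j <= length(bv)) rec(i, j + 1, c(cols, list(c("-", bv[j]))))
  }
  rec(1, 1, list())
  best
}

# Exhaustive likelihood oracle: sums the column likelihood over every
# assignment of internal-node states (uniform root frequencies).
brute_force_log_likelihood <- function(tree, aln) {
  m <- alignment_matrix(aln)
  ntip <- length(tree$tip.label)
  P <- lapply(tree$edge.length, aa_transition_matrix)
  idx <- matrix(match(m, AA20), nrow(m), dimnames = dimnames(m))
  internals <- (ntip + 1):max(tree$edge)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
  total <- 0
  for (col in seq_len(ncol(m))) {
    lik <- 0
    tipstate <- idx[tree$tip.label, col]
    for (g in seq_len(nrow(grid))) {
      st <- integer(max(tree$edge))
      st[internals] <- grid[g, ]
      st[seq_len(ntip)] <- tipstate
      pr <- 1 / 20
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
      }
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}

# Brute-force signature oracle: every substring (within length bounds) of the
# first in-group sequence that is carried by all members, absent from every
# outsider, and maximal under single-residue extension in that sequence.
brute_force_signatures <- function(seqs, labels, group, len_bounds = c(6, 25)) {
  members <- group_members(labels, group)
  ins <- seqs$residues[seqs$id %in% members]
  outs <- seqs$residues[!seqs$id %in% members]
  s1 <- ins[1]
  n <- nchar(s1)
  valid <- function(motif) {
    all(vapply(ins, function(x) grepl(motif, x, fixed = TRUE), logical(1))) &&
      !any(vapply(outs, function(x) grepl(motif, x, fixed = TRUE), logical(1)))
  }
  found <- character(0)
  for (start in seq_len(n)) {
    for (len in seq(len_bounds[1], len_bounds[2])) {
      if (start + len - 1 > n) break
      motif <- substr(s1, start, start + len - 1)
      if (!valid(motif)) next
      left_ok <- start == 1 || !valid(substr(s1, start - 1, start + len - 1))
      right_ok <- start + len - 1 == n ||
        !valid(substr(s1, start, start + len))
      if (left_ok && right_ok) found <- c(found, motif)
    }
  }
  sort(unique(found))
}

# Memoized shared datasets (regenerating them per test would dominate runtime).
.fixtures <- new.env(parent = emptyenv())

shallow_dataset <- function() {
  if (is.null(.fixtures$shallow)) {
    .fixtures$shallow <- generate_dataset(sim_config(seed = 7))
  }
  .fixtures$shallow
}

deep_dataset <- function() {
  if (is.null(.fixtures$deep)) {
    .fixtures$deep <- generate_dataset(
      sim_config(tree = sim_tree_deep(), tm_flank_rate = 1, seed = 42))
  }
  .fixtures$deep
}

deep_alignment <- function() {
  if (is.null(.fixtures$deep_aln)) {
    .fixtures$deep_aln <- progressive_align(deep_dataset()$seqs)
  }
  .fixtures$deep_aln
}
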