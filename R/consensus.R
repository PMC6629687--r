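# Bipartitions, majority-rule consensus, Robinson-Foulds distance and
# Newick round-tripping.

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the split is keyed
#' canonically by the side not containing the alphabetically first leaf,
#' with sorted labels joined by `|`.
#'
#' @param tree An `ape::phylo`.
#' @return Character vector of bipartition keys (possibly empty).
#' @export
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(character(0))
  ref <- sort(tree$tip.label)[1]
  clades <- clade_tip_sets(tree)
  keys <- purrr::map_chr(clades, function(tips) {
    if (ref %in% tips) tips <- setdiff(tree$tip.label, tips)
    paste(sort(tips), collapse = "|")
  })
  sizes <- purrr::map_int(clades, length)
  keep <- sizes >= 2 & sizes <= ntip - 2
  unique(keys[keep])
}

# Tip label sets below each internal edge (child is an internal node).
clade_tip_sets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  sets <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  internal_children <- tree$edge[tree$edge[, 2] > ntip, 2]
  sets[internal_children]
}

#' Majority-rule consensus with support values
#'
#' Keeps exactly the non-trivial bipartitions occurring in strictly more than
#' `cutoff` percent of the input trees and annotates each with its percentage
#' as node support. For `cutoff >= 50` the kept splits are mutually
#' compatible by construction.
#'
#' @param trees List of `ape::phylo` on the same leaf set.
#' @param cutoff Percentage cutoff (default 50).
#' @return An `ape::phylo` consensus tree; internal node labels carry the
#'   support percentages.
#' @export
majority_consensus <- function(trees, cutoff = 50) {
  if (length(trees) == 0) abort("need at least one tree")
  tips <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), tips)) abort("trees have differing leaf sets")
  }
  if (cutoff < 50) {
    warn("cutoff below 50 can select incompatible splits; proceeding greedily")
  }
  counts <- table(unlist(purrr::map(trees, bipartitions)))
  pct <- 100 * as.numeric(counts) / length(trees)
  keys <- names(counts)[pct > cutoff]
  pct <- pct[pct > cutoff]
  clades <- purrr::map(keys, ~ strsplit(.x, "|", fixed = TRUE)[[1]])
  ord <- order(lengths(clades), decreasing = TRUE)
  clades <- clades[ord]; pct <- pct[ord]
  # drop any split incompatible with those already kept (no-op for cutoff >= 50)
  kept <- list(); kept_pct <- numeric(0)
  for (k in seq_along(clades)) {
    ok <- all(purrr::map_lgl(kept, function(other) {
      a <- clades[[k]]; b <- other
      length(intersect(a, b)) == 0 || all(a %in% b) || all(b %in% a)
    }))
    if (ok) { kept <- c(kept, list(clades[[k]])); kept_pct <- c(kept_pct, pct[k]) }
  }
  build_consensus_tree(tips, kept, kept_pct)
}

# Assemble a rooted-display Newick from a laminar family of clades (none of
# which contains the reference first tip) and parse it back.
build_consensus_tree <- function(tips, clades, pct) {
  nodes <- c(as.list(tips), clades)
  n_tip <- length(tips)
  n <- length(nodes)
  size <- lengths(nodes)
  parent <- rep(0L, n)                      # 0 = root
  for (k in seq_len(n)) {
    strict_sup <- which(size > size[k] &
                          purrr::map_lgl(nodes, ~ all(nodes[[k]] %in% .x)))
    strict_sup <- strict_sup[strict_sup > n_tip & strict_sup != k]
    if (length(strict_sup) > 0) {
      parent[k] <- strict_sup[which.min(size[strict_sup])]
    }
  }
  lab <- function(k) {
    if (k <= n_tip) return(nodes[[k]])
    inner <- paste(vapply(which(parent == k), lab, character(1)), collapse = ",")
    sprintf("(%s)%s", inner, format_support(pct[k - n_tip]))
  }
  top <- which(parent == 0L)
  txt <- paste0("(", paste(vapply(top, lab, character(1)), collapse = ","), ");")
  ape::read.tree(text = txt)
}

format_support <- function(x) {
  if (abs(x - round(x)) < 1e-9) sprintf("%d", as.integer(round(x))) else sprintf("%.4g", x)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the non-trivial bipartition sets
#' of two unrooted trees on the same leaves.
#'
#' @param t1,t2 `ape::phylo` trees with identical leaf sets.
#' @return Integer distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!identical(sort(t1$tip.label), sort(t2$tip.label))) {
    abort("trees have differing leaf sets")
  }
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Read / write Newick trees
#'
#' Thin wrappers over `ape` that preserve branch lengths and internal-node
#' support labels.
#'
#' @param tree An `ape::phylo`.
#' @param path File path; for `write_newick()` omit to get the string.
#' @return `read_newick()` returns an `ape::phylo`; `write_newick()` returns
#'   the path (or the Newick string when `path` is `NULL`).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_newick
#' @param text Newick string, as an alternative to `path`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)),
    error = function(e) abort(paste0("malformed Newick: ", conditionMessage(e))))
  if (is.null(tr)) abort("malformed Newick: no tree parsed")
  tr
}

#' Bootstrap support values mapped onto a reference tree
#'
#' @param tree Reference `ape::phylo`.
#' @param trees List of replicate trees.
#' @return Tibble `bipartition`, `support` (percent) for each internal edge of
#'   `tree`.
#' @export
edge_support <- function(tree, trees) {
  counts <- table(unlist(purrr::map(trees, bipartitions)))
  b <- bipartitions(tree)
  tibble(bipartition = b,
         support = 100 * as.numeric(counts[b]) / length(trees)) |>
    dplyr::mutate(support = ifelse(is.na(.data$support), 0, .data$support))
}
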