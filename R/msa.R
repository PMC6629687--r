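# Progressive multiple sequence alignment along a Neighbour-Joining guide
# tree, plus conserved-block/consensus reporting.
#
# An alignment is a tibble (id, aligned) of equal-length gapped rows;
# removing the gaps from a row recovers the input residues exactly, and no
# column is all-gap.

new_alignment <- function(id, aligned) {
  stopifnot(length(unique(nchar(aligned))) <= 1)
  structure(tibble(id = id, aligned = aligned),
            class = c("aa_alignment", class(tibble())))
}

#' Construct an alignment from gapped rows
#'
#' Validates that all rows have equal length and that removing gaps leaves a
#' valid residue string.
#'
#' @param id Sequence ids.
#' @param aligned Equal-length gapped residue strings.
#' @return Alignment tibble of class `aa_alignment`.
#' @export
as_alignment <- function(id, aligned) {
  if (length(unique(nchar(aligned))) > 1) abort("rows must have equal length")
  validate_sequences(tibble(id = id, residues = gsub("-", "", aligned)))
  new_alignment(as.character(id), as.character(aligned))
}

#' Number of columns of an alignment
#' @param aln Alignment tibble.
#' @return Integer column count.
#' @export
alignment_ncol <- function(aln) {
  if (nrow(aln) == 0) return(0L)
  nchar(aln$aligned[1])
}

#' Alignment as a character matrix
#' @param aln Alignment tibble.
#' @return Character matrix (rows = sequences, named by id).
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$aligned, ""))
  rownames(m) <- aln$id
  m
}

#' Strip gaps from alignment rows
#' @param aln Alignment tibble.
#' @return Sequence tibble (id, description, residues).
#' @export
ungap <- function(aln) {
  tibble(id = aln$id, description = "",
         residues = stringr::str_remove_all(aln$aligned, "-"))
}

#' Build a Neighbour-Joining guide tree from pairwise alignments
#'
#' Aligns every pair globally, computes p-distances over the gap-free aligned
#' positions, and runs Neighbour-Joining on the resulting matrix.
#'
#' @param seqs Sequence tibble (>= 2 rows).
#' @param scoring A [scoring_scheme()].
#' @return An `ape::phylo` guide tree.
#' @export
build_guide_tree <- function(seqs, scoring = scoring_scheme()) {
  seqs <- validate_sequences(seqs)
  n <- nrow(seqs)
  if (n < 2) abort("guide tree needs at least 2 sequences")
  D <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      al <- pairwise_align(seqs$residues[i], seqs$residues[j], scoring)
      x <- strsplit(al$a, "")[[1]]; y <- strsplit(al$b, "")[[1]]
      ok <- x != "-" & y != "-" & x != "X" & y != "X"
      p <- if (any(ok)) sum(x[ok] != y[ok]) / sum(ok) else 0
      D[i, j] <- D[j, i] <- p
    }
  }
  nj_tree(D)
}

#' Progressive multiple sequence alignment
#'
#' Merges sequence profiles bottom-up along a guide tree with affine-gap
#' profile-profile alignment under a mean sum-of-pairs column score. Children
#' at each node are visited in a canonical order (smallest leaf label first)
#' so the result does not depend on input order.
#'
#' @param seqs Sequence tibble.
#' @param guide Optional `ape::phylo` guide tree whose tip labels equal the
#'   sequence ids; defaults to [build_guide_tree()].
#' @param scoring A [scoring_scheme()].
#' @return Alignment tibble (class `aa_alignment`) with columns `id`,
#'   `aligned`.
#' @export
progressive_align <- function(seqs, guide = NULL, scoring = scoring_scheme()) {
  seqs <- validate_sequences(seqs)
  if (nrow(seqs) == 1) return(new_alignment(seqs$id, seqs$residues))
  if (is.null(guide)) guide <- build_guide_tree(seqs, scoring)
  if (!setequal(guide$tip.label, seqs$id)) {
    abort("guide tree leaves do not match sequence ids")
  }
  tree <- rooted_binary(guide)
  res <- align_node(tree$root, tree, seqs, scoring)
  ord <- match(seqs$id, res$ids)
  new_alignment(seqs$id, res$rows[ord])
}

# Root an (unrooted) guide tree deterministically and return child lists.
rooted_binary <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  children <- split(phy$edge[, 2], phy$edge[, 1])
  list(root = root, children = children, tip = phy$tip.label, ntip = ntip)
}

smallest_leaf <- function(node, tree) {
  if (node <= tree$ntip) return(tree$tip[node])
  min(vapply(tree$children[[as.character(node)]], smallest_leaf, character(1),
             tree = tree))
}

align_node <- function(node, tree, seqs, scoring) {
  if (node <= tree$ntip) {
    id <- tree$tip[node]
    return(list(ids = id, rows = seqs$residues[seqs$id == id]))
  }
  kids <- tree$children[[as.character(node)]]
  kids <- kids[order(vapply(kids, smallest_leaf, character(1), tree = tree))]
  acc <- align_node(kids[1], tree, seqs, scoring)
  for (k in kids[-1]) {
    nxt <- align_node(k, tree, seqs, scoring)
    merged <- align_profiles(acc$rows, nxt$rows, scoring)
    acc <- list(ids = c(acc$ids, nxt$ids), rows = merged$rows)
  }
  acc
}

#' Sum-of-pairs score of a multiple alignment
#'
#' Scores every induced pairwise alignment (substitution scores plus affine
#' gap costs, columns gapped in both rows skipped) and sums over pairs.
#'
#' @param aln Alignment tibble.
#' @param scoring A [scoring_scheme()].
#' @return Numeric score.
#' @export
sp_score <- function(aln, scoring = scoring_scheme()) {
  m <- alignment_matrix(aln)
  n <- nrow(m)
  M <- scoring$matrix
  total <- 0
  for (i in seq_len(max(n - 1, 0))) {
    for (j in seq.int(i + 1, n)) {
      x <- m[i, ]; y <- m[j, ]
      keep <- !(x == "-" & y == "-")
      x <- x[keep]; y <- y[keep]
      res <- x != "-" & y != "-"
      total <- total + sum(M[cbind(x[res], y[res])])
      gaps <- rle(ifelse(x == "-", "a", ifelse(y == "-", "b", "r")))
      glen <- gaps$lengths[gaps$values != "r"]
      total <- total + sum(scoring$gap_open + (glen - 1) * scoring$gap_extend)
    }
  }
  total
}

#' Conserved blocks and consensus of an alignment
#'
#' Maximal runs of gap-free columns whose majority-residue frequency is at
#' least `min_identity`, reported with the per-column majority consensus.
#'
#' @param aln Alignment tibble.
#' @param min_identity Minimum majority-residue frequency per column
#'   (default 0.9).
#' @param min_len Minimum block length in columns (default 6).
#' @return Tibble with columns `start`, `end` (0-based, half-open alignment
#'   columns) and `consensus`.
#' @export
conserved_blocks <- function(aln, min_identity = 0.9, min_len = 6) {
  m <- alignment_matrix(aln)
  nc <- ncol(m)
  empty <- tibble(start = integer(), end = integer(), consensus = character())
  if (nc == 0 || min_len > nc) return(empty)
  maj <- apply(m, 2, function(col) {
    if (any(col == "-")) return(c(NA, NA))
    tab <- sort(table(col), decreasing = TRUE)
    c(names(tab)[1], unname(tab)[1] / length(col))
  })
  good <- !is.na(maj[1, ]) & as.numeric(maj[2, ]) >= min_identity
  r <- rle(good)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(empty)
  tibble(start = as.integer(starts[keep] - 1L), end = as.integer(ends[keep]),
         consensus = purrr::map2_chr(starts[keep], ends[keep],
                                     ~ paste(maj[1, .x:.y], collapse = "")))
}

#' Write an alignment as aligned FASTA
#' @param aln Alignment tibble.
#' @param path Output path.
#' @param width Columns per line.
#' @export
write_alignment <- function(aln, path, width = 60) {
  lines <- purrr::map2(aln$id, aln$aligned, function(h, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read an aligned FASTA file
#' @param path Input path.
#' @return Alignment tibble.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  id <- stringr::str_extract(names(set), "^\\S+")
  new_alignment(id, unname(toupper(as.character(set))))
}
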