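# The AT/Ox family motif at the TMIII / IC Loop 2 interface, and the
# codon-change calculator behind the D<->E and Y->N substitution arguments.

# Degenerate family pattern: the union of the observed per-phylum variants
# (D/E at slot 1, Y/N at slot 4, I/V at slot 6).
FAMILY_MOTIF_PATTERN <- "[DE]RW[YN]A[IV]"

#' Locate the family motif anchored at the TMIII/IC Loop 2 interface
#'
#' Searches for the degenerate six-residue family motif `[DE]RW[YN]A[IV]`
#' whose start lies in the anchor window from six residues before the end of
#' TMIII to the end of IC Loop 2 (the motif may begin inside the helix and
#' finish in the loop). The first such match wins.
#'
#' @param residues Residue string (or one-row sequence tibble).
#' @param topology A `gpcr_topology` from a passing seven-TM screen.
#' @param pattern Regular expression for the motif (default the family
#'   pattern; widen only deliberately).
#' @return A one-row tibble with columns `variant`, `start` (0-based),
#'   `region` (labels spanned, joined with " - "), or a zero-row tibble when
#'   no anchored match exists.
#' @export
find_family_motif <- function(residues, topology, pattern = FAMILY_MOTIF_PATTERN) {
  residues <- as_residue_string(residues)
  empty <- tibble(variant = character(), start = integer(), region = character())
  if (is.null(topology)) return(empty)
  m <- gregexpr(pattern, residues, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  tm3_end <- topology$tm$end[3]
  icl2_end <- topology$regions$end[topology$regions$region == "IC Loop 2"]
  in_window <- starts >= (tm3_end - 6L) & starts < icl2_end
  if (!any(in_window)) return(empty)
  k <- which(in_window)[1]
  span <- seq.int(starts[k], starts[k] + lens[k] - 1L)
  regs <- unique(region_at(topology, span))
  tibble(variant = substr(residues, starts[k] + 1L, starts[k] + lens[k]),
         start = starts[k],
         region = paste(regs, collapse = " - "))
}

#' Family-motif table for a screened dataset
#'
#' @param seqs Sequence tibble.
#' @param screen Result of [screen_dataset()] on `seqs`.
#' @param pattern Motif pattern, see [find_family_motif()].
#' @return Tibble with one row per passing sequence that carries the anchored
#'   motif: `id`, `variant`, `start`, `region`.
#' @export
family_motif_table <- function(seqs, screen, pattern = FAMILY_MOTIF_PATTERN) {
  topo <- attr(screen, "topologies")
  rows <- purrr::map2(seqs$id, seqs$residues, function(id, res) {
    t <- topo[[id]]
    if (is.null(t)) return(NULL)
    hit <- find_family_motif(res, t, pattern)
    if (nrow(hit) == 0) return(NULL)
    dplyr::bind_cols(tibble(id = id), hit)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(id = character(), variant = character(),
                  start = integer(), region = character())
  }
  out
}

#' Count family-motif variants
#'
#' Summarises a motif table into per-variant counts (the shape of a
#' per-phylum signature table when `labels`/`group_level` are given).
#'
#' @param motifs Result of [family_motif_table()].
#' @param labels Optional group labelling tibble.
#' @param group_level Optional 1-based index into the taxonomy path used as
#'   the grouping unit (e.g. 1 for the phylum-like top level).
#' @return Tibble of counts, most frequent variant first.
#' @export
classify_variants <- function(motifs, labels = NULL, group_level = NULL) {
  if (is.null(labels)) {
    return(dplyr::arrange(dplyr::count(motifs, .data$variant), dplyr::desc(.data$n)))
  }
  lv <- tibble(id = labels$id,
               group = purrr::map_chr(labels$path, ~ .x[min(group_level, length(.x))]))
  joined <- dplyr::inner_join(motifs, lv, by = "id")
  dplyr::arrange(dplyr::count(joined, .data$group, .data$variant), .data$group)
}

# ---- codon-change analysis ---------------------------------------------------

standard_genetic_code <- function() {
  if (is.null(the$genetic_code)) {
    gc <- Biostrings::GENETIC_CODE
    the$genetic_code <- tibble(codon = names(gc), aa = unname(gc))
  }
  the$genetic_code
}

.onLoad <- function(libname, pkgname) {
  # force Biostrings' lazy-loaded code table once, at load time
  try(standard_genetic_code(), silent = TRUE)
}

#' Minimum codon changes between two amino acids
#'
#' Exhaustively searches the standard genetic code for the codon pairs that
#' interconvert two amino acids with the fewest nucleotide substitutions.
#'
#' @param aa_from,aa_to Single amino-acid letters (sense codons only).
#' @return List with `min_changes` (integer) and `witnesses`, a tibble of all
#'   minimising codon pairs with their differing codon positions (1-based,
#'   comma-joined in column `positions`).
#' @export
#' @examples
#' codon_min_changes("D", "E")$min_changes  # 1, always at codon position 3
codon_min_changes <- function(aa_from, aa_to) {
  code <- standard_genetic_code()
  code <- code[code$aa != "*", ]
  for (a in c(aa_from, aa_to)) {
    if (!a %in% code$aa) abort(sprintf("'%s' is not a coded amino acid", a))
  }
  from <- code$codon[code$aa == aa_from]
  to <- code$codon[code$aa == aa_to]
  fm <- matrix(unlist(strsplit(from, "")), ncol = 3, byrow = TRUE)
  tm <- matrix(unlist(strsplit(to, "")), ncol = 3, byrow = TRUE)
  idx <- expand.grid(f = seq_along(from), t = seq_along(to))
  neq <- fm[idx$f, , drop = FALSE] != tm[idx$t, , drop = FALSE]
  ndiff <- rowSums(neq)
  m <- min(ndiff)
  keep <- which(ndiff == m)
  pos <- vapply(keep, function(k) paste(which(neq[k, ]), collapse = ","),
                character(1))
  list(min_changes = as.integer(m),
       witnesses = tibble(codon_from = from[idx$f[keep]],
                          codon_to = to[idx$t[keep]],
                          positions = pos))
}

#' Codon-change table for a set of amino-acid replacements
#'
#' @param pairs Data frame with columns `from`, `to`.
#' @return Tidy tibble: `from`, `to`, `min_changes`, `positions` (the union of
#'   differing codon positions over all minimising pairs, comma-joined).
#' @export
codon_change_table <- function(pairs) {
  rows <- purrr::map2(pairs$from, pairs$to, function(f, t) {
    r <- codon_min_changes(f, t)
    pos <- sort(unique(unlist(strsplit(r$witnesses$positions, ","))))
    tibble(from = f, to = t, min_changes = r$min_changes,
           positions = paste(pos, collapse = ","))
  })
  dplyr::bind_rows(rows)
}
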