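# Clade-specific signature-motif mining.
#
# A signature of a group is a contiguous, gap-free stretch of alignment
# columns at which every member of the group carries the identical residue
# string (100% identity), while no sequence outside the group contains that
# string anywhere as an exact full-length substring (the in-dataset
# replacement for verifying candidates against an external database).

#' Exact-substring specificity check
#'
#' `TRUE` iff no sequence outside `group` contains `motif` as an exact,
#' full-length substring.
#'
#' @param motif Candidate motif string.
#' @param seqs Sequence tibble (ungapped).
#' @param labels Group labelling tibble.
#' @param group Group name.
#' @return Logical flag.
#' @export
check_specificity <- function(motif, seqs, labels, group) {
  if (!nzchar(motif)) abort("motif must be non-empty")
  members <- group_members(labels, group)
  out <- seqs$residues[!seqs$id %in% members]
  !any(stringr::str_detect(out, stringr::fixed(motif)))
}

#' Mine signature motifs for one group
#'
#' Scans the alignment for maximal runs of gap-free columns that are 100%
#' conserved within the group, keeps those whose length falls within
#' `len_bounds` and whose residue string passes [check_specificity()], and
#' reports them sorted by alignment position. A column gapped in every group
#' member records an insertion elsewhere in the alignment, not a break in the
#' group's own peptide, so such columns are skipped rather than ending a run;
#' a gap in only some members still breaks it.
#'
#' @param aln Alignment tibble.
#' @param labels Group labelling tibble (ids must cover the alignment rows).
#' @param group Group name.
#' @param len_bounds Length bounds `(min, max)` in residues (default
#'   `c(6, 25)`, bracketing the observed family and group signatures).
#' @param min_group_size Minimum member count (default 2); smaller groups
#'   return an empty result with a warning, since every substring of a single
#'   sequence is trivially "conserved".
#' @return Tibble with columns `group`, `motif`, `aln_start`, `aln_end`
#'   (0-based, half-open columns), `n_in_group`.
#' @export
mine_signatures <- function(aln, labels, group, len_bounds = c(6, 25),
                            min_group_size = 2) {
  members <- group_members(labels, group)
  if (length(members) == 0) abort(sprintf("unknown or empty group '%s'", group))
  in_rows <- aln$id %in% members
  empty <- tibble(group = character(), motif = character(),
                  aln_start = integer(), aln_end = integer(),
                  n_in_group = integer())
  if (sum(in_rows) < min_group_size) {
    warn(sprintf("group '%s' has fewer than %d aligned members; no signatures mined",
                 group, min_group_size))
    return(empty)
  }
  m <- alignment_matrix(aln[in_rows, ])
  # a column gapped in every member does not interrupt the group's contiguous
  # peptide (it only reflects an insertion elsewhere in the alignment); drop it
  keep_cols <- which(colSums(m != "-") > 0)
  m <- m[, keep_cols, drop = FALSE]
  conserved <- apply(m, 2, function(col) {
    col[1] != "-" && col[1] != "X" && all(col == col[1])
  })
  r <- rle(conserved)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  seqs <- ungap(aln)
  rows <- list()
  for (k in seq_len(nrow(runs))) {
    len <- runs[k, 2] - runs[k, 1] + 1
    if (len < len_bounds[1] || len > len_bounds[2]) next
    motif <- paste(m[1, runs[k, 1]:runs[k, 2]], collapse = "")
    if (!check_specificity(motif, seqs, labels, group)) next
    rows[[length(rows) + 1]] <- tibble(group = group, motif = motif,
                                       aln_start = as.integer(keep_cols[runs[k, 1]] - 1L),
                                       aln_end = as.integer(keep_cols[runs[k, 2]]),
                                       n_in_group = sum(in_rows))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else dplyr::arrange(out, .data$aln_start)
}

#' Structural region annotation of a mined signature
#'
#' Maps the motif's alignment columns back to residue coordinates in each
#' in-group sequence and reads the per-sequence region labels from its
#' topology; the majority label is reported, with a disagreement flag.
#'
#' @param motif One row of a [mine_signatures()] result.
#' @param aln Alignment tibble.
#' @param labels Group labelling tibble.
#' @param topologies Named list of `gpcr_topology` (e.g. the `topologies`
#'   attribute of [screen_dataset()]).
#' @return Tibble with `location` (majority region label, e.g.
#'   `"TMIII - IC Loop 2"`) and `agreement` (fraction of members agreeing).
#' @export
annotate_motif_region <- function(motif, aln, labels, topologies) {
  members <- intersect(group_members(labels, motif$group), aln$id)
  per_seq <- purrr::map_chr(members, function(id) {
    topo <- topologies[[id]]
    if (is.null(topo)) abort(sprintf("missing topology for '%s'", id))
    row <- strsplit(aln$aligned[aln$id == id], "")[[1]]
    res_pos <- cumsum(row != "-") - 1L            # 0-based residue index per column
    span <- seq.int(motif$aln_start + 1L, motif$aln_end)
    regs <- unique(region_at(topo, res_pos[span]))
    paste(regs, collapse = " - ")
  })
  tab <- sort(table(per_seq), decreasing = TRUE)
  tibble(location = names(tab)[1],
         agreement = as.numeric(tab[1]) / length(per_seq))
}

#' Signature report over several groups
#'
#' Mines every requested group and assembles the publication-shaped table
#' (group, location, motif), deterministically ordered by group then
#' alignment position.
#'
#' @param aln Alignment tibble.
#' @param labels Group labelling tibble.
#' @param groups Character vector of group names (default: every named group
#'   with at least `min_group_size` members, excluding groups that cover the
#'   whole dataset).
#' @param topologies Optional named list of topologies for location
#'   annotation.
#' @inheritParams mine_signatures
#' @return Tibble with columns `group`, `location`, `motif`, `n_in_group`,
#'   `aln_start`, `aln_end`.
#' @export
signature_report <- function(aln, labels, groups = NULL, topologies = NULL,
                             len_bounds = c(6, 25), min_group_size = 2) {
  if (is.null(groups)) {
    groups <- group_names(labels)
    sizes <- purrr::map_int(groups, ~ length(group_members(labels, .x)))
    groups <- groups[sizes >= min_group_size & sizes < nrow(aln)]
  }
  res <- purrr::map(groups, function(g) {
    mine_signatures(aln, labels, g, len_bounds, min_group_size)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(group = character(), location = character(),
                  motif = character(), n_in_group = integer(),
                  aln_start = integer(), aln_end = integer()))
  }
  loc <- purrr::map_chr(seq_len(nrow(out)), function(k) {
    if (is.null(topologies)) return(NA_character_)
    annotate_motif_region(out[k, ], aln, labels, topologies)$location
  })
  out$location <- loc
  dplyr::arrange(out[, c("group", "location", "motif", "n_in_group",
                         "aln_start", "aln_end")],
                 .data$group, .data$aln_start)
}

#' Write a signature report to TSV
#' @param report Result of [signature_report()].
#' @param path Output path.
#' @export
write_signature_report <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
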