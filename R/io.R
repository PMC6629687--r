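# Reading, writing and validating protein sequence sets and group labellings.
#
# A sequence set is a tibble with columns id, description, residues; ids are
# the FASTA header token up to the first whitespace and must be unique. The
# residue alphabet is strict: the 20 canonical amino acids plus X. All
# coordinates exposed by the package are 0-based, half-open.

#' Build a validated protein sequence table
#'
#' @param id Character vector of unique sequence identifiers.
#' @param residues Character vector of uppercase residue strings.
#' @param description Optional free-text descriptions (default "").
#' @return A tibble with columns `id`, `description`, `residues`.
#' @export
aa_sequences <- function(id, residues, description = "") {
  seqs <- tibble(id = as.character(id),
                 description = rep_len(as.character(description), length(id)),
                 residues = toupper(as.character(residues)))
  validate_sequences(seqs)
}

validate_sequences <- function(seqs) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  if (!"description" %in% names(seqs)) seqs$description <- ""
  dup <- unique(seqs$id[duplicated(seqs$id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s): ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(seqs$residues))) {
    abort(paste0("empty sequence record: ",
                 paste(seqs$id[!nzchar(seqs$residues)], collapse = ", ")))
  }
  bad <- stringr::str_locate(seqs$residues, paste0("[^", paste(AA_WITH_X, collapse = ""), "]"))[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    chr <- substr(seqs$residues[i], bad[i], bad[i])
    abort(sprintf("illegal residue character '%s' in sequence '%s' at position %d (0-based)",
                  chr, seqs$id[i], bad[i] - 1L))
  }
  as_tibble(seqs[, c("id", "description", "residues")])
}

#' Read protein sequences from FASTA
#'
#' Parses a FASTA file into a tibble of sequences. Residues are uppercased and
#' a single terminal `*` (stop) is stripped; the id is the header token up to
#' the first whitespace, the remainder becomes the description.
#'
#' @param path Path to a FASTA file (or connection readable by Biostrings).
#' @return A tibble with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  if (is.null(headers)) headers <- character(0)
  id <- stringr::str_extract(headers, "^\\S+")
  description <- stringr::str_trim(stringr::str_remove(headers, "^\\S+\\s*"))
  residues <- toupper(as.character(set))
  residues <- stringr::str_remove(residues, "\\*$")
  seqs <- tibble(id = id, description = description, residues = unname(residues))
  validate_sequences(seqs)
}

#' Write protein sequences to FASTA
#'
#' @param seqs Sequence tibble (see [read_fasta()]).
#' @param path Output file path.
#' @param width Residues per sequence line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  seqs <- validate_sequences(seqs)
  header <- ifelse(nzchar(seqs$description),
                   paste(seqs$id, seqs$description), seqs$id)
  lines <- purrr::map2(header, seqs$residues, function(h, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a taxonomic group table
#'
#' Reads a two-column TSV (`id`, `taxonomy`) where `taxonomy` is a
#' semicolon-separated path of group names, most inclusive first
#' (e.g. `Chordata;Sauropsida;Testudines`). A sequence belongs to every group
#' named on its path, so membership is transitive along the path.
#'
#' @param path Path to the TSV file. A header line `id<TAB>taxonomy` is
#'   expected.
#' @return A tibble with columns `id`, `taxonomy` and list-column `path`.
#' @export
read_group_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("id", "taxonomy") %in% names(tab))) {
    abort("group table must have columns 'id' and 'taxonomy'")
  }
  group_labels(tab$id, tab$taxonomy)
}

#' Build a group labelling from ids and taxonomy paths
#'
#' @param id Sequence ids.
#' @param taxonomy Semicolon-separated taxonomy paths.
#' @return A tibble with columns `id`, `taxonomy`, `path` (list of character).
#' @export
group_labels <- function(id, taxonomy) {
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate id(s) in group table: ", paste(dup, collapse = ", ")))
  }
  path <- stringr::str_split(taxonomy, ";")
  path <- purrr::map(path, ~ stringr::str_trim(.x[nzchar(stringr::str_trim(.x))]))
  if (any(lengths(path) == 0) && length(id) > 0) {
    abort(paste0("empty taxonomy path for id(s): ",
                 paste(id[lengths(path) == 0], collapse = ", ")))
  }
  tibble(id = as.character(id), taxonomy = as.character(taxonomy), path = path)
}

#' Write a group table to TSV
#'
#' @param labels Group labelling tibble (see [read_group_table()]).
#' @param path Output path.
#' @export
write_group_table <- function(labels, path) {
  readr::write_tsv(labels[, c("id", "taxonomy")], path, progress = FALSE)
  invisible(path)
}

#' Cross-validate a labelling against a sequence set
#'
#' Errors if the labelling mentions ids absent from the sequence set.
#'
#' @param labels Group labelling tibble.
#' @param seqs Sequence tibble.
#' @return `labels`, invisibly, when consistent.
#' @export
validate_labels <- function(labels, seqs) {
  orphans <- setdiff(labels$id, seqs$id)
  if (length(orphans) > 0) {
    abort(paste0("labelled id(s) absent from sequence set: ",
                 paste(orphans, collapse = ", ")))
  }
  invisible(labels)
}

#' Members of a taxonomic group
#'
#' @param labels Group labelling tibble.
#' @param group Group name.
#' @return Character vector of ids whose taxonomy path contains `group`.
#' @export
group_members <- function(labels, group) {
  labels$id[purrr::map_lgl(labels$path, ~ group %in% .x)]
}

#' All group names present in a labelling
#'
#' @param labels Group labelling tibble.
#' @return Character vector of distinct group names, in order of first
#'   appearance.
#' @export
group_names <- function(labels) {
  unique(unlist(labels$path))
}
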