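# End-to-end orchestration: screen -> family filter -> align -> distances ->
# NJ -> bootstrap -> consensus -> signatures, with artifacts on disk.

#' Run the full analysis pipeline
#'
#' Applies the family's inclusion rule (seven TM helices and the anchored
#' E/DRWYAI motif), aligns the retained sequences, infers the
#' Neighbour-Joining tree on Poisson-corrected distances, runs the
#' column-resampling bootstrap with majority-rule consensus, and mines
#' group signatures. All artifacts are written under `outdir`.
#'
#' @param seqs Sequence tibble (see [read_fasta()]).
#' @param labels Group labelling tibble (see [read_group_table()]).
#' @param outdir Output directory (created if needed).
#' @param screen_params Named list overriding [screen_seven_tm()] defaults.
#' @param scoring A [scoring_scheme()].
#' @param bootstrap_reps Bootstrap replicates (default 1000).
#' @param bootstrap_seed Seed for the bootstrap resampling.
#' @param consensus_cutoff Majority-rule cutoff percentage (default 50).
#' @param len_bounds,min_group_size Signature mining parameters.
#' @param deletion Gap handling for distances.
#' @return Invisibly, a list with the screen report, motif table, alignment,
#'   distance matrix, NJ tree, consensus tree, signature report and artifact
#'   paths.
#' @export
run_pipeline <- function(seqs, labels, outdir,
                         screen_params = list(), scoring = scoring_scheme(),
                         bootstrap_reps = 1000, bootstrap_seed = 1,
                         consensus_cutoff = 50,
                         len_bounds = c(6, 25), min_group_size = 2,
                         deletion = "pairwise") {
  seqs <- validate_sequences(seqs)
  validate_labels(labels, seqs)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run_log.txt")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logline("pipeline start: %d sequences, bootstrap_reps=%d seed=%d cutoff=%g",
          nrow(seqs), bootstrap_reps, bootstrap_seed, consensus_cutoff)
  logline("screen params: %s",
          paste(names(screen_params), unlist(screen_params),
                sep = "=", collapse = " ") %||% "defaults")

  screen <- do.call(screen_dataset, c(list(seqs), screen_params))
  write_screen_report(screen, file.path(outdir, "screen_report.tsv"))
  motifs <- family_motif_table(seqs, screen)
  readr::write_tsv(motifs, file.path(outdir, "family_motifs.tsv"), progress = FALSE)
  keep <- seqs$id %in% motifs$id
  logline("screen: %d/%d pass 7-TM; %d carry the anchored family motif",
          sum(screen$pass), nrow(seqs), nrow(motifs))
  if (!any(keep)) abort("no sequences passed family screen")
  kept <- seqs[keep, ]
  write_fasta(kept, file.path(outdir, "filtered.fasta"))

  aln <- progressive_align(kept, scoring = scoring)
  write_alignment(aln, file.path(outdir, "aligned.fasta"))
  logline("alignment: %d sequences x %d columns", nrow(aln), alignment_ncol(aln))

  D <- poisson_distance_matrix(aln, deletion = deletion)
  write_distance_tsv(D, file.path(outdir, "distances.tsv"))
  nj <- nj_tree(D)
  write_newick(nj, file.path(outdir, "nj_tree.nwk"))

  boots <- bootstrap_trees(aln, n_reps = bootstrap_reps, seed = bootstrap_seed,
                           deletion = deletion)
  if (attr(boots, "dropped") > 0) {
    logline("WARN: %d bootstrap replicates dropped", attr(boots, "dropped"))
  }
  cons <- majority_consensus(boots, cutoff = consensus_cutoff)
  write_newick(cons, file.path(outdir, "consensus_tree.nwk"))
  logline("bootstrap: %d replicates retained; consensus has %d internal splits",
          length(boots), length(bipartitions(cons)))

  labs_kept <- labels[labels$id %in% kept$id, ]
  sig <- signature_report(aln, labs_kept, topologies = attr(screen, "topologies"),
                          len_bounds = len_bounds, min_group_size = min_group_size)
  write_signature_report(sig, file.path(outdir, "signatures.tsv"))
  logline("signatures: %d motifs across %d groups",
          nrow(sig), length(unique(sig$group)))
  logline("pipeline done")

  invisible(list(screen = screen, motifs = motifs, alignment = aln,
                 distances = D, nj = nj, bootstrap = boots, consensus = cons,
                 signatures = sig, outdir = outdir,
                 artifacts = list.files(outdir, full.names = TRUE)))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || !nzchar(a[1])) b else a
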