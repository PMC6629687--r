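toy_alignment <- function() {
  # three Protacanthopterygii rows share KFRAEFKA near the C-terminus; the
  # two outsiders carry unrelated residues there
  rows <- c(p1 = "MNTDLKVQKFRAEFKAGSD",
            p2 = "MNTDLRIAKFRAEFKATTD",
            p3 = "MNTELKVQKFRAEFKAGSD",
            o1 = "MNTDLKVQWIRTEYHAGSD",
            o2 = "MNTDLKVQWLRTEYQAGSD")
  atoxfam:::new_alignment(names(rows), unname(rows))
}

toy_labels <- function() {
  group_labels(c("p1", "p2", "p3", "o1", "o2"),
               c(rep("Teleostei;Protacanthopterygii", 3),
                 rep("Teleostei;Other", 2)))
}

test_that("a shared, group-exclusive block is mined as a signature", {
  sig <- mine_signatures(toy_alignment(), toy_labels(), "Protacanthopterygii",
                         len_bounds = c(6, 25))
  expect_equal(nrow(sig), 1)
  expect_equal(sig$motif, "KFRAEFKA")
  expect_equal(sig$n_in_group, 3L)
  expect_equal(c(sig$aln_start, sig$aln_end), c(8L, 16L))
})

test_that("an in-group mismatch splits the candidate run", {
  aln <- toy_alignment()
  # break conservation inside the motif for one member
  aln$aligned[2] <- sub("KFRAEFKA", "KFRAQFKA", aln$aligned[2])
  sig <- mine_signatures(aln, toy_labels(), "Protacanthopterygii",
                         len_bounds = c(3, 25))
  expect_false(any(grepl("KFRAEFKA", sig$motif)))
  expect_true(all(nchar(sig$motif) >= 3))
})

test_that("a motif carried by any outsider is rejected", {
  aln <- toy_alignment()
  aln$aligned[4] <- sub("WIRTEYHA", "KFRAEFKA", aln$aligned[4])
  sig <- mine_signatures(aln, toy_labels(), "Protacanthopterygii",
                         len_bounds = c(6, 25))
  expect_equal(nrow(sig), 0)
})

test_that("specificity follows the exact full-length substring rule", {
  ds <- shallow_dataset()
  seqs <- ds$seqs
  # the family motif is carried by every leaf, so it cannot be group-specific
  expect_false(check_specificity("DRWYAI", seqs, ds$labels, "GroupA"))
  # planted GroupA signature is absent outside GroupA
  expect_true(check_specificity("KFRAEFKA", seqs, ds$labels, "GroupA"))
  # when the group is the whole dataset the check is vacuously true
  expect_true(check_specificity("DRWYAI", seqs, ds$labels, "Root"))
  expect_error(check_specificity("", seqs, ds$labels, "GroupA"), "non-empty")
})

test_that("single-member groups warn and mine nothing by default", {
  labels <- group_labels(c("p1", "p2", "p3", "o1", "o2"),
                         c("T;P;Solo", "T;P", "T;P", "T;O", "T;O"))
  expect_warning(sig <- mine_signatures(toy_alignment(), labels, "Solo"),
                 "fewer than")
  expect_equal(nrow(sig), 0)
  expect_error(mine_signatures(toy_alignment(), labels, "Nowhere"), "unknown")
})

test_that("mined motifs are annotated with their structural region", {
  ds <- shallow_dataset()
  aln <- progressive_align(ds$seqs)
  scr <- screen_dataset(ds$seqs)
  topo <- attr(scr, "topologies")
  # family anchor block spans the TMIII end and IC Loop 2
  fam <- tibble::tibble(group = "Root", aln_start = 161L, aln_end = 173L)
  ann <- annotate_motif_region(fam, aln, ds$labels, topo)
  expect_equal(ann$location, "TMIII - IC Loop 2")
  # planted GroupA signature sits in the C-terminal tail
  sigA <- mine_signatures(aln, ds$labels, "GroupA", len_bounds = c(8, 25))
  sigA <- sigA[grepl("KFRAEFKA", sigA$motif), ]
  annA <- annotate_motif_region(sigA[1, ], aln, ds$labels, topo)
  expect_equal(annA$location, "C-terminal")
  # planted GroupC signature sits in the N-terminal region
  sigC <- mine_signatures(aln, ds$labels, "GroupC", len_bounds = c(8, 25))
  sigC <- sigC[grepl("ASTESRKSL", sigC$motif), ]
  annC <- annotate_motif_region(sigC[1, ], aln, ds$labels, topo)
  expect_equal(annC$location, "N-terminal")
  expect_error(annotate_motif_region(fam, aln, ds$labels, list()), "missing topology")
})

test_that("signature reports are deterministic tables of the expected shape", {
  empty <- signature_report(toy_alignment(), toy_labels(), groups = character(0))
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("group", "location", "motif", "n_in_group",
                        "aln_start", "aln_end"))
  rep1 <- signature_report(toy_alignment(), toy_labels(),
                           groups = c("Protacanthopterygii"))
  expect_equal(rep1$motif, "KFRAEFKA")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signature_report(rep1, f)
  expect_equal(nrow(readr::read_tsv(f, show_col_types = FALSE)), 1)
})

test_that("mining is sound and equals the brute-force substring oracle", {
  ds <- deep_dataset()
  aln <- deep_alignment()
  seqs <- ds$seqs
  for (g in c("GroupA", "GroupB", "GroupC")) {
    mined <- mine_signatures(aln, ds$labels, g, len_bounds = c(8, 25))
    members <- group_members(ds$labels, g)
    for (k in seq_len(nrow(mined))) {
      motif <- mined$motif[k]
      ins <- seqs$residues[seqs$id %in% members]
      outs <- seqs$residues[!seqs$id %in% members]
      expect_true(all(grepl(motif, ins, fixed = TRUE)))
      expect_false(any(grepl(motif, outs, fixed = TRUE)))
    }
    oracle <- brute_force_signatures(seqs, ds$labels, g, len_bounds = c(8, 25))
    expect_setequal(mined$motif, oracle)
  }
})

test_that("planted signatures are recovered with perfect precision and recall", {
  ds <- deep_dataset()
  aln <- deep_alignment()
  mined <- dplyr::bind_rows(purrr::map(c("GroupA", "GroupB", "GroupC"),
                                       ~ mine_signatures(aln, ds$labels, .x,
                                                         len_bounds = c(8, 25))))
  ev <- evaluate_signature_recovery(mined, ds$truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})
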