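test_that("the template has the advertised architecture", {
  tmpl <- make_template(sim_config())
  expect_equal(nchar(tmpl$sequence), tmpl$layout$seq_len)
  expect_equal(nrow(tmpl$layout$tm), 7)
  # exactly one DRWYAI occurrence, at the TMIII-end junction
  hits <- gregexpr("DRWYAI", tmpl$sequence, fixed = TRUE)[[1]]
  expect_equal(length(hits), 1)
  expect_equal(as.integer(hits) - 1L, tmpl$layout$tm$end[3])
  # ground-truth topology labels the junction as entering IC Loop 2
  expect_equal(region_at(tmpl$topology, tmpl$layout$tm$end[3]), "IC Loop 2")
})

test_that("simulation respects branch lengths, masks and seeds", {
  tmpl <- random_peptide(200)
  tr <- ape::read.tree(text = "(x:0,(y:0,z:0):0);")
  leaves <- simulate_on_tree(tmpl, tr, seed = 3)
  expect_true(all(leaves == tmpl))

  tr2 <- ape::read.tree(text = "(x:0.4,y:0.4);")
  rates <- rep(1, 200); rates[51:60] <- 0
  l1 <- simulate_on_tree(tmpl, tr2, site_rates = rates, seed = 5)
  expect_equal(substr(l1[["x"]], 51, 60), substr(tmpl, 51, 60))
  expect_equal(substr(l1[["y"]], 51, 60), substr(tmpl, 51, 60))
  l2 <- simulate_on_tree(tmpl, tr2, site_rates = rates, seed = 5)
  expect_identical(l1, l2)
  l3 <- simulate_on_tree(tmpl, tr2, site_rates = rates, seed = 6)
  expect_false(identical(l1, l3))
})

test_that("pairwise divergence follows the equal-rates closed form", {
  tr <- ape::read.tree(text = "(x:0.05,y:0.05);")
  withr::local_seed(55)
  tmpl <- random_peptide(10000)
  q <- (19 / 20) * (1 - exp(-(20 / 19) * 0.1))
  ps <- vapply(1:30, function(r) {
    lv <- simulate_on_tree(tmpl, tr, seed = 600 + r)
    mean(strsplit(lv[["x"]], "")[[1]] != strsplit(lv[["y"]], "")[[1]])
  }, numeric(1))
  se <- sqrt(q * (1 - q) / 10000) / sqrt(30)
  expect_lt(abs(mean(ps) - q), 3 * se + 1e-12)
})

test_that("per-branch substitution counts are Poisson-distributed", {
  # short branch, multiple hits negligible: differing sites ~ Poisson(b * L)
  tr <- ape::read.tree(text = "(x:0.01,y:0);")
  withr::local_seed(66)
  tmpl <- random_peptide(2000)
  counts <- vapply(1:300, function(r) {
    lv <- simulate_on_tree(tmpl, tr, seed = 9000 + r)
    sum(strsplit(lv[["x"]], "")[[1]] != strsplit(lv[["y"]], "")[[1]])
  }, numeric(1))
  lambda <- 0.01 * 2000
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 300) + 0.5)
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.75)
  expect_lt(disp, 1.3)
  breaks <- c(-Inf, 14, 17, 20, 23, Inf)
  obs <- table(cut(counts, breaks))
  pr <- diff(ppois(c(-1, 14, 17, 20, 23, Inf), lambda))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.001)
})

test_that("generated datasets are reproducible and ground-truthed", {
  cfg <- sim_config(seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$seqs, d2$seqs)
  expect_equal(nrow(d1$truth$signatures), 3)
  expect_setequal(d1$truth$signatures$group, c("GroupA", "GroupB", "GroupC"))
  expect_equal(nrow(d1$truth$family_blocks), 2)
  # planted motifs are present in every clade member and absent elsewhere
  for (k in 1:3) {
    g <- d1$truth$signatures$group[k]
    motif <- d1$truth$signatures$motif[k]
    ins <- d1$seqs$residues[d1$seqs$id %in% group_members(d1$labels, g)]
    outs <- d1$seqs$residues[!d1$seqs$id %in% group_members(d1$labels, g)]
    expect_true(all(grepl(motif, ins, fixed = TRUE)))
    expect_false(any(grepl(motif, outs, fixed = TRUE)))
  }
  # files written when an output directory is given
  out <- withr::local_tempdir()
  generate_dataset(cfg, outdir = out)
  expect_true(all(file.exists(file.path(out,
    c("sequences.fasta", "groups.tsv", "true_tree.nwk",
      "truth_signatures.tsv", "truth_tm_segments.tsv")))))
})

test_that("every generated leaf passes the screen and carries the family motif", {
  for (ds in list(shallow_dataset(),
                  generate_dataset(sim_config(seed = 13)))) {
    scr <- screen_dataset(ds$seqs)
    expect_true(all(scr$pass))
    motifs <- family_motif_table(ds$seqs, scr)
    expect_equal(sort(motifs$id), sort(ds$seqs$id))
    expect_true(all(motifs$variant == "DRWYAI"))
  }
})

test_that("tree-derived labels give nested taxonomy paths", {
  labels <- shallow_dataset()$labels
  expect_equal(nrow(labels), 12)
  expect_true(all(purrr::map_lgl(labels$path, ~ .x[1] == "Root")))
  expect_setequal(group_members(labels, "A12"), c("A1", "A2"))
  expect_true(all(group_members(labels, "A12") %in% group_members(labels, "GroupA")))
})

test_that("planted motifs that do not fit their region are rejected", {
  expect_error(sim_config(planted = tibble::tibble(
    group = "GroupA", motif = strrep("K", 40), region = "C-terminal")),
    "does not fit")
  expect_error(sim_config(planted = tibble::tibble(
    group = "NoSuchClade", motif = "KFRAEFKA", region = "C-terminal")),
    "named internal nodes")
  expect_error(sim_config(planted = tibble::tibble(
    group = c("GroupA", "GroupB"), motif = c("KFRAEFKA", "MNDPLKWQ"),
    region = c("C-terminal", "C-terminal"))),
    "collide")
})
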