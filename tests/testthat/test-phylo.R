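aln_of <- function(ids, rows) atoxfam:::new_alignment(ids, rows)

test_that("p-distances count differing sites with the right deletion policy", {
  aln <- aln_of(c("a", "b"), c("AAAA", "AATT"))
  expect_equal(p_distance_matrix(aln)["a", "b"], 0.5)
  aln <- aln_of(c("a", "b"), c("AA-A", "AATA"))
  expect_equal(p_distance_matrix(aln, "pairwise")["a", "b"], 0)
  aln <- aln_of(c("a", "b", "c"), c("AA-A", "AATA", "CATA"))
  P <- p_distance_matrix(aln, "complete")     # gap column dropped for all
  expect_equal(P["a", "b"], 0)
  expect_equal(P["a", "c"], 1 / 3)
})

test_that("pairs with no comparable sites are an error naming the pair", {
  aln <- aln_of(c("a", "b"), c("AA--", "--TT"))
  expect_error(p_distance_matrix(aln), "no comparable sites.*'a'.*'b'")
})

test_that("the Poisson correction matches its closed form and guards saturation", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), 0.693147, tolerance = 1e-6)
  expect_error(poisson_correct(0.99), "saturated")
  expect_error(poisson_correct(-0.1), "non-negative")
})

test_that("Neighbour-Joining solves the three-taxon case exactly", {
  D <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], 0.05)
  expect_equal(len[["B"]], 0.15)
  expect_equal(len[["C"]], 0.25)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("Neighbour-Joining recovers additive five-leaf trees exactly", {
  skip_if_not_installed("phangorn")
  withr::local_seed(31)
  trees <- phangorn::allTrees(5, tip.label = letters[1:5])
  for (ti in seq_along(trees)) {
    t <- trees[[ti]]
    t$edge.length <- stats::runif(nrow(t$edge), 0.05, 0.4)
    D <- stats::cophenetic(t)[letters[1:5], letters[1:5]]
    nj <- nj_tree(D)
    expect_equal(robinson_foulds(nj, t), 0)
    expect_lt(max(abs(stats::cophenetic(nj)[letters[1:5], letters[1:5]] - D)), 1e-9)
  }
})

test_that("an equidistant matrix yields the minimum-evolution tree length", {
  ids <- letters[1:5]
  D <- matrix(1, 5, 5, dimnames = list(ids, ids)); diag(D) <- 0
  nj <- nj_tree(D)
  expect_equal(sum(nj$edge.length), 2.5, tolerance = 1e-9)
  # oracle: least-squares branch lengths on every topology, minimal total length
  skip_if_not_installed("phangorn")
  trees <- phangorn::allTrees(5, tip.label = ids)
  totals <- vapply(seq_along(trees), function(ti) {
    t <- trees[[ti]]
    paths <- matrix(0, 10, nrow(t$edge))
    pairs <- which(upper.tri(D), arr.ind = TRUE)
    for (k in seq_len(10)) {
      nodepath <- ape::nodepath(t, pairs[k, 1], pairs[k, 2])
      on_path <- t$edge[, 1] %in% nodepath & t$edge[, 2] %in% nodepath
      paths[k, ] <- as.numeric(on_path)
    }
    fit <- stats::lm.fit(paths, D[pairs])
    sum(pmax(fit$coefficients, 0))
  }, numeric(1))
  expect_equal(sum(nj$edge.length), min(totals), tolerance = 1e-9)
})

test_that("bootstrap replicates are seed-reproducible and column-resampled", {
  ds <- shallow_dataset()
  aln <- progressive_align(ds$seqs)
  expect_equal(bootstrap_trees(aln, n_reps = 0), list(), ignore_attr = TRUE)
  b1 <- bootstrap_trees(aln, n_reps = 20, seed = 5)
  b2 <- bootstrap_trees(aln, n_reps = 20, seed = 5)
  expect_identical(purrr::map_chr(b1, write_newick),
                   purrr::map_chr(b2, write_newick))
  expect_equal(attr(b1, "dropped"), 0L)
})

test_that("a saturated alignment drops bootstrap replicates with a warning", {
  withr::local_seed(8)
  aln <- aln_of(c("a", "b", "c"),
                c(random_peptide(50), random_peptide(50), random_peptide(50)))
  expect_warning(bt <- bootstrap_trees(aln, n_reps = 10, seed = 2, cap = 0.5),
                 "dropped")
  expect_lt(length(bt), 10)
})

test_that("majority consensus keeps splits above the cutoff with exact supports", {
  t1 <- ape::read.tree(text = "((A,B),C,(D,E));")
  t2 <- ape::read.tree(text = "((A,C),B,(D,E));")
  cons <- majority_consensus(c(rep(list(t1), 6), rep(list(t2), 4)), cutoff = 50)
  keys <- bipartitions(cons)
  expect_true("C|D|E" %in% keys)            # the AB|CDE split, at 60%
  expect_false("B|D|E" %in% keys)           # the minority AC split
  expect_setequal(cons$node.label[nzchar(cons$node.label)], c("60", "100"))

  same <- rep(list(t1), 10)
  cons2 <- majority_consensus(same, cutoff = 50)
  expect_equal(robinson_foulds(cons2, t1), 0)
  expect_true(all(cons2$node.label[nzchar(cons2$node.label)] == "100"))

  star <- majority_consensus(c(rep(list(t1), 6), rep(list(t2), 4)), cutoff = 100)
  expect_equal(length(bipartitions(star)), 0)
  t3 <- ape::read.tree(text = "((A,B),C,(D,F));")
  expect_error(majority_consensus(list(t1, t3)), "leaf sets")
})

test_that("Robinson-Foulds distance equals the bipartition symmetric difference", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  bin <- ape::read.tree(text = "((A,B),C,(D,E));")
  expect_equal(robinson_foulds(bin, star), length(bipartitions(bin)))
  skip_if_not_installed("phangorn")
  withr::local_seed(17)
  for (k in 1:8) {
    ta <- ape::unroot(ape::rtree(7)); tb <- ape::unroot(ape::rtree(7))
    expect_equal(robinson_foulds(ta, tb), phangorn::RF.dist(ta, tb))
  }
})

test_that("Newick output round-trips topology, lengths and supports", {
  tr <- read_newick(text = "(A:0.1,B:0.1);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_identical(write_newick(tr), "(A:0.1,B:0.1);")
  tr2 <- read_newick(text = "((A,B)75:0.1,C,D);")
  expect_equal(tr2$node.label[2], "75")
  expect_error(read_newick(text = "((A,B,;"), "malformed|Newick")
  withr::local_seed(23)
  for (k in 1:5) {
    t <- ape::rtree(8)
    back <- read_newick(text = write_newick(t))
    expect_equal(robinson_foulds(back, t), 0)
    expect_equal(sort(back$edge.length), sort(t$edge.length), tolerance = 1e-9)
  }
})

test_that("the pruning likelihood matches trivial and exhaustive references", {
  aln <- aln_of(c("a", "b"), c("DRWYAI", "DRWYAI"))
  tr <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(pruning_log_likelihood(tr, aln), 6 * log(1 / 20), tolerance = 1e-9)
  withr::local_seed(41)
  for (k in 1:5) {
    bl <- stats::runif(6, 0.05, 0.6)
    tr <- ape::read.tree(text = sprintf(
      "((A:%g,B:%g):%g,(C:%g,D:%g):%g);", bl[1], bl[2], bl[3], bl[4], bl[5], bl[6]))
    aln4 <- aln_of(c("A", "B", "C", "D"),
                   vapply(1:4, function(i) random_peptide(6), character(1)))
    expect_equal(pruning_log_likelihood(tr, aln4),
                 brute_force_log_likelihood(tr, aln4), tolerance = 1e-8)
  }
  expect_error(pruning_log_likelihood(tr, aln), "match")
})

test_that("the likelihood is invariant under re-rooting (pulley principle)", {
  withr::local_seed(43)
  tr <- ape::unroot(ape::rtree(6))
  aln <- aln_of(tr$tip.label,
                vapply(1:6, function(i) random_peptide(30), character(1)))
  base <- pruning_log_likelihood(tr, aln)
  for (tip in tr$tip.label[1:4]) {
    rerooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(pruning_log_likelihood(rerooted, aln), base, tolerance = 1e-8)
  }
})

test_that("gaps and X act as missing data in the likelihood", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.2);")
  full <- pruning_log_likelihood(tr, aln_of(c("a", "b"), c("DR", "DR")))
  with_missing <- pruning_log_likelihood(tr, aln_of(c("a", "b"), c("DR-X", "DRWY")))
  expect_equal(with_missing, full + 2 * log(1 / 20), tolerance = 1e-9)
})
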