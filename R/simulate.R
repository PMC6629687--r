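# Ground-truthed synthetic GPCR-like families.
#
# A template receptor is built from hydrophobic TM stretches and hydrophilic
# loops, with the DRWYAI family motif written at the TMIII-end / IC Loop 2
# junction. The template is then evolved along a known tree under the
# equal-rates 20-state model; selected positions are held invariant
# (structural anchors, family motif) or evolve at a reduced rate (TM flank
# residues), and clade-specific signature motifs are planted on the stem
# branch of named clades and held invariant inside them only.

TM_RESIDUES <- c("I", "L", "V", "F", "A")
LOOP_RESIDUES <- c("R", "K", "D", "E", "N", "Q", "S", "G")

#' Default 12-leaf study tree
#'
#' Three labelled clades of four leaves each; every branch has the given
#' length. Internal nodes are named (`GroupA`, `A12`, ...) so group
#' labellings can be read off the tree.
#'
#' @param branch Branch length for every edge (default 0.05, the shallow
#'   study condition).
#' @param tips,internals,stems Optional per-tier branch lengths overriding
#'   `branch` (tip edges, within-clade internal edges, clade stem edges).
#' @return An `ape::phylo` with node labels.
#' @export
sim_tree_default <- function(branch = 0.05, tips = branch, internals = branch,
                             stems = branch) {
  grp <- function(g) {
    sprintf("((%s1:%g,%s2:%g)%s12:%g,(%s3:%g,%s4:%g)%s34:%g)Group%s:%g",
            g, tips, g, tips, g, internals, g, tips, g, tips, g, internals,
            g, stems)
  }
  txt <- paste0("(", grp("A"), ",", grp("B"), ",", grp("C"), ")Root;")
  ape::read.tree(text = txt)
}

#' Deep study tree for signature mining
#'
#' Same shape as [sim_tree_default()] but with tip branches 0.3 and internal
#' branches 0.2, giving between-clade divergence well above 0.2 so that
#' within-clade conservation of unplanted background is improbable.
#'
#' @return An `ape::phylo` with node labels.
#' @export
sim_tree_deep <- function() {
  sim_tree_default(tips = 0.3, internals = 0.2, stems = 0.2)
}

default_planted <- function() {
  tibble(group = c("GroupA", "GroupB", "GroupC"),
         motif = c("KFRAEFKA", "QRNWRTIQCS", "ASTESRKSLTTQISNFDN"),
         region = c("C-terminal", "IC Loop 3", "N-terminal"))
}

#' Simulation configuration
#'
#' Assembles and validates the generator's study conditions. Defaults define
#' the shallow 12-leaf dataset: branch length 0.05 everywhere, a 413-residue
#' template (N-terminal 30, seven 29-residue TM helices, 25-residue loops,
#' C-terminal 30), the DRWYAI family motif at the TMIII/IC Loop 2 junction,
#' two family-wide invariant anchor blocks (TMIII end + motif; TMVII core)
#' and one planted signature per clade, placed in loop/terminal regions.
#'
#' @param tree `ape::phylo` with branch lengths and named internal nodes
#'   (the names define the taxonomic groups).
#' @param tm_len,loop_len,nterm_len,cterm_len Segment lengths (residues).
#' @param tm_core Number of freely evolving residues at each helix centre.
#' @param tm_flank_rate Relative substitution rate of the remaining TM
#'   residues (0 = invariant, 1 = background; default 0.25).
#' @param rate Global rate multiplier (expected substitutions per site per
#'   unit branch length; default 1).
#' @param planted Tibble with columns `group`, `motif`, `region`: one
#'   signature per labelled clade, planted on the clade's stem branch and
#'   invariant inside the clade.
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(tree = sim_tree_default(), tm_len = 31, loop_len = 25,
                       nterm_len = 30, cterm_len = 30, tm_core = 7,
                       tm_flank_rate = 0.25, rate = 1,
                       planted = default_planted(), seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (tm_len < tm_core + 2) abort("tm_len too short for the evolving core")
  groups <- tree$node.label
  if (nrow(planted) > 0) {
    if (!all(planted$group %in% groups)) {
      abort("planted groups must be named internal nodes of the tree")
    }
    bad <- !stringr::str_detect(planted$motif, "^[ARNDCQEGHILKMFPSTWYV]+$")
    if (any(bad)) abort("planted motifs must be canonical residue strings")
  }
  cfg <- structure(list(tree = tree, tm_len = tm_len, loop_len = loop_len,
                        nterm_len = nterm_len, cterm_len = cterm_len,
                        tm_core = tm_core, tm_flank_rate = tm_flank_rate,
                        rate = rate, planted = planted, seed = as.integer(seed)),
                   class = "sim_config")
  cfg$layout <- template_layout(cfg)
  validate_planted(cfg)
  cfg
}

# Segment coordinate layout (0-based, half-open) of the template.
template_layout <- function(cfg) {
  lens <- c(cfg$nterm_len,
            rep(c(cfg$tm_len, cfg$loop_len), 6), cfg$tm_len, cfg$cterm_len)
  bounds <- cumsum(c(0L, lens))
  regions <- tibble(start = as.integer(bounds[-length(bounds)]),
                    end = as.integer(bounds[-1]), region = REGION_LABELS)
  tm <- regions[grepl("^TM", regions$region), c("start", "end")]
  seq_len_ <- bounds[length(bounds)]
  motif_start <- tm$end[3]                       # DRWYAI enters IC Loop 2
  # family-wide invariant anchors: TMIII end + motif, and a TMVII core block
  anchor1 <- seq.int(tm$end[3] - 6L, motif_start + 5L)
  tm7_mid <- floor((tm$start[7] + tm$end[7]) / 2)
  anchor2 <- seq.int(tm7_mid - 2L, tm7_mid + 9L)
  # freely evolving helix cores (TMVII core shifted off its invariant block)
  cores <- unlist(purrr::map(1:7, function(k) {
    mid <- floor((tm$start[k] + tm$end[k]) / 2)
    if (k == 7) seq.int(tm$start[k] + 1L, tm$start[k] + cfg$tm_core) else
      seq.int(mid - floor(cfg$tm_core / 2), mid + floor((cfg$tm_core - 1) / 2))
  }))
  cores <- setdiff(cores, c(anchor1, anchor2))
  tm_all <- unlist(purrr::map2(tm$start, tm$end, ~ seq.int(.x, .y - 1L)))
  flanks <- setdiff(tm_all, c(cores, anchor1, anchor2))
  list(regions = regions, tm = tm, seq_len = as.integer(seq_len_),
       motif_start = as.integer(motif_start),
       invariant = sort(unique(c(anchor1, anchor2))),
       cores = sort(cores), flanks = sort(flanks))
}

region_lookup <- function(layout, position) {
  layout$regions$region[findInterval(position, layout$regions$start)]
}

# Planted motifs must fit their stated region and stay off the family-wide
# anchors and off each other.
validate_planted <- function(cfg) {
  lay <- cfg$layout
  if (nrow(cfg$planted) == 0) return(invisible(cfg))
  spans <- purrr::pmap(cfg$planted, function(group, motif, region) {
    reg <- lay$regions[lay$regions$region == region, ]
    if (nrow(reg) == 0) abort(sprintf("unknown region '%s'", region))
    if (nchar(motif) > reg$end - reg$start - 4) {
      abort(sprintf("planted motif for %s does not fit region %s", group, region))
    }
    start <- reg$start + 2L                      # small offset inside region
    seq.int(start, start + nchar(motif) - 1L)
  })
  all_pos <- unlist(spans)
  if (anyDuplicated(all_pos) || length(intersect(all_pos, lay$invariant)) > 0) {
    abort("planted motifs collide with each other or with invariant anchors")
  }
  cfg$planted$start <- purrr::map_int(spans, ~ as.integer(.x[1]))
  invisible(cfg)
}

planted_spans <- function(cfg) {
  lay <- cfg$layout
  if (nrow(cfg$planted) == 0) {
    return(tibble(group = character(), motif = character(),
                  region = character(), start = integer()))
  }
  starts <- purrr::pmap_int(cfg$planted[, c("group", "motif", "region")],
                            function(group, motif, region) {
    reg <- lay$regions[lay$regions$region == region, ]
    as.integer(reg$start + 2L)
  })
  dplyr::mutate(cfg$planted, start = starts)
}

#' Build the template receptor sequence
#'
#' Draws hydrophobic TM stretches and hydrophilic loops, writes the DRWYAI
#' family motif at the TMIII-end/IC Loop 2 junction, and returns the true
#' topology alongside.
#'
#' @param cfg A [sim_config()].
#' @return List with `sequence` (residue string), `topology`
#'   (`gpcr_topology` ground truth) and `layout` (coordinate list).
#' @export
make_template <- function(cfg = sim_config()) {
  lay <- cfg$layout
  set.seed(cfg$seed)
  res <- character(lay$seq_len)
  for (k in seq_len(nrow(lay$regions))) {
    span <- seq.int(lay$regions$start[k] + 1L, lay$regions$end[k])
    pool <- if (grepl("^TM", lay$regions$region[k])) TM_RESIDUES else LOOP_RESIDUES
    res[span] <- sample(pool, length(span), replace = TRUE)
  }
  motif <- strsplit("DRWYAI", "")[[1]]
  res[lay$motif_start + seq_along(motif)] <- motif
  res <- harden_template_helices(res, lay)
  list(sequence = paste(res, collapse = ""),
       topology = assign_regions(lay$tm, lay$seq_len),
       layout = lay)
}

# Redraw helices whose called hydropathy run has no safety margin. A uniform
# draw over the hydrophobic set occasionally lands an Ala-heavy stretch whose
# above-threshold run barely reaches the detector's minimum length; a genuine
# TM helix is robustly detectable, so such stretches are resampled until every
# helix is called with margin (run length >= min_run in context).
harden_template_helices <- function(res, lay, min_run = 22, max_rounds = 300) {
  for (round in seq_len(max_rounds)) {
    seg <- find_tm_segments(hydropathy_profile(paste(res, collapse = "")))
    weak <- integer(0)
    for (k in 1:7) {
      ov <- seg[seg$start < lay$tm$end[k] & seg$end > lay$tm$start[k], ]
      run <- if (nrow(ov) == 0) 0 else max(ov$end - ov$start)
      if (run < min_run) weak <- c(weak, k)
    }
    if (nrow(seg) == 7 && length(weak) == 0) return(res)
    if (length(weak) == 0) weak <- 1:7    # spurious extra segment: redraw all
    for (k in weak) {
      span <- seq.int(lay$tm$start[k] + 1L, lay$tm$end[k])
      res[span] <- sample(TM_RESIDUES, length(span), replace = TRUE)
    }
  }
  res
}

#' Evolve a sequence along a tree
#'
#' Each site substitutes along every branch as a 20-state equal-rates Markov
#' process: the number of events is Poisson with mean `branch length x site
#' rate`, and each event replaces the residue with one of the other 19
#' uniformly. Sites with rate 0 are copied unchanged.
#'
#' @param template Residue string at the root.
#' @param tree `ape::phylo` with branch lengths.
#' @param rate Global rate multiplier.
#' @param site_rates Optional per-site relative rates (default all 1).
#' @param seed Integer seed (deterministic output).
#' @param plant Optional tibble (`group`, `motif`, `start`) of motifs written
#'   onto the sequence entering the named clade and held invariant below it.
#' @return Named character vector of leaf sequences.
#' @export
simulate_on_tree <- function(template, tree, rate = 1, site_rates = NULL,
                             seed = 1, plant = NULL) {
  n <- nchar(template)
  if (is.null(site_rates)) site_rates <- rep(1, n)
  stopifnot(length(site_rates) == n)
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_names <- c(tree$tip.label, tree$node.label)
  seqs <- vector("list", max(tree$edge))
  rates_at <- vector("list", max(tree$edge))
  seqs[[root]] <- strsplit(template, "")[[1]]
  rates_at[[root]] <- site_rates
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    b <- tree$edge.length[k]
    s <- seqs[[p]]
    r <- rates_at[[p]]
    lambda <- b * rate * r
    nev <- stats::rpois(n, lambda)
    hit <- which(nev > 0)
    for (i in hit) {
      cur <- s[i]
      for (e in seq_len(nev[i])) cur <- sample(setdiff(AA_ALPHABET, cur), 1)
      s[i] <- cur
    }
    # plant clade signatures on the stem entering the named node
    if (!is.null(plant) && nrow(plant) > 0 && !is.na(node_names[ch]) &&
        node_names[ch] %in% plant$group) {
      rows <- plant[plant$group == node_names[ch], ]
      for (q in seq_len(nrow(rows))) {
        span <- rows$start[q] + seq_len(nchar(rows$motif[q]))
        s[span] <- strsplit(rows$motif[q], "")[[1]]
        r[span] <- 0
      }
    }
    seqs[[ch]] <- s
    rates_at[[ch]] <- r
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  setNames(out, tree$tip.label)
}

#' Generate a complete ground-truthed dataset
#'
#' Builds the template, evolves it along the configured tree with the
#' configured rate tiers, plants the clade signatures, and returns sequences,
#' group labelling, the true tree and truth tables. With `outdir` set, also
#' writes FASTA, labels TSV, true Newick and truth TSVs.
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional output directory.
#' @return List with `seqs` (tibble), `labels` (tibble), `tree`
#'   (`ape::phylo`), `template` (list from [make_template()]) and `truth`
#'   (list: `signatures`, `segments`, `family_motif`).
#' @export
generate_dataset <- function(cfg = sim_config(), outdir = NULL) {
  tmpl <- make_template(cfg)
  lay <- tmpl$layout
  site_rates <- rep(1, lay$seq_len)
  site_rates[lay$flanks + 1L] <- cfg$tm_flank_rate
  site_rates[lay$invariant + 1L] <- 0
  plant <- planted_spans(cfg)
  leaves <- simulate_on_tree(tmpl$sequence, cfg$tree, rate = cfg$rate,
                             site_rates = site_rates,
                             seed = cfg$seed + 1L, plant = plant)
  seqs <- aa_sequences(names(leaves), unname(leaves),
                       description = "synthetic AT/Ox-like receptor")
  labels <- labels_from_tree(cfg$tree)
  anchor_blocks <- family_anchor_blocks(tmpl)
  truth <- list(
    signatures = plant,
    family_blocks = anchor_blocks,
    segments = lay$tm,
    family_motif = tibble(motif = "DRWYAI", start = lay$motif_start,
                          region = "TMIII - IC Loop 2"))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(seqs, file.path(outdir, "sequences.fasta"))
    write_group_table(labels, file.path(outdir, "groups.tsv"))
    write_newick(cfg$tree, file.path(outdir, "true_tree.nwk"))
    readr::write_tsv(plant, file.path(outdir, "truth_signatures.tsv"),
                     progress = FALSE)
    readr::write_tsv(lay$tm, file.path(outdir, "truth_tm_segments.tsv"),
                     progress = FALSE)
  }
  list(seqs = seqs, labels = labels, tree = cfg$tree, template = tmpl,
       truth = truth)
}

# Residue strings of the family-wide invariant anchor blocks (the TMIII-end +
# DRWYAI block and the TMVII block), read off the template.
family_anchor_blocks <- function(tmpl) {
  lay <- tmpl$layout
  runs <- split(lay$invariant, cumsum(c(1, diff(lay$invariant) != 1)))
  tibble(start = purrr::map_int(runs, ~ as.integer(.x[1])),
         end = purrr::map_int(runs, ~ as.integer(.x[length(.x)] + 1L)),
         motif = purrr::map_chr(runs, function(r) {
           substr(tmpl$sequence, r[1] + 1L, r[length(r)] + 1L)
         }))
}

#' Score mined signatures against the planted truth
#'
#' A mined motif counts as a planted discovery when it contains (or is
#' contained in) a planted clade signature of the same group, or when it
#' contains a family-wide invariant anchor block (family blocks are planted
#' features too: within a clade they are always conserved, and a single
#' chance-conserved neighbouring column can make the extended run
#' clade-specific). Recall is the fraction of planted clade signatures
#' recovered by a mined motif of the right group.
#'
#' @param mined Tibble from [mine_signatures()]/[signature_report()].
#' @param truth Truth list from [generate_dataset()] (uses `signatures` and
#'   `family_blocks`).
#' @return Tibble with `precision`, `recall`, `n_mined`, `n_planted`.
#' @export
evaluate_signature_recovery <- function(mined, truth) {
  planted <- truth$signatures
  blocks <- truth$family_blocks$motif
  hit <- function(motif, group) {
    own <- planted$motif[planted$group == group]
    any(purrr::map_lgl(own, ~ grepl(.x, motif, fixed = TRUE) ||
                         grepl(motif, .x, fixed = TRUE))) ||
      any(purrr::map_lgl(blocks, ~ grepl(.x, motif, fixed = TRUE)))
  }
  prec <- if (nrow(mined) == 0) NA_real_ else {
    mean(purrr::map2_lgl(mined$motif, mined$group, hit))
  }
  rec <- mean(purrr::map_lgl(seq_len(nrow(planted)), function(k) {
    any(mined$group == planted$group[k] &
          grepl(planted$motif[k], mined$motif, fixed = TRUE))
  }))
  tibble(precision = prec, recall = rec,
         n_mined = nrow(mined), n_planted = nrow(planted))
}

#' Group labelling implied by a tree's named internal nodes
#'
#' Each leaf's taxonomy path is the sequence of named ancestors from the root
#' down (root label first).
#'
#' @param tree `ape::phylo` with (possibly partial) node labels.
#' @return Group labelling tibble.
#' @export
labels_from_tree <- function(tree) {
  ntip <- length(tree$tip.label)
  node_names <- c(tree$tip.label, tree$node.label)
  parent <- rep(NA_integer_, max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  paths <- vapply(seq_len(ntip), function(i) {
    anc <- character(0)
    p <- parent[i]
    while (!is.na(p)) {
      if (!is.na(node_names[p]) && nzchar(node_names[p])) {
        anc <- c(node_names[p], anc)
      }
      p <- parent[p]
    }
    paste(anc, collapse = ";")
  }, character(1))
  group_labels(tree$tip.label, paths)
}
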