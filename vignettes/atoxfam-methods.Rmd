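---
title: "Methods: screening, alignment, phylogenetics and signature mining for AT/Ox-like GPCRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, alignment, phylogenetics and signature mining for AT/Ox-like GPCRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atoxfam)
```

## The analysis

Allatotropin/Orexin (AT/Ox) receptors are rhodopsin-family G-protein coupled
receptors: seven transmembrane (TM) helices, an extracellular N-terminus, an
intracellular C-terminus, and three loops on each side of the membrane. The
family is distinguished from the broader rhodopsin E/DR(Y/F) pattern by a
tryptophan in the third slot and, more specifically, by a six-residue motif —
`[D/E]RWYA[I/V]`, most commonly `DRWYAI` — at the interface between the third
helix (TMIII) and the second intracellular loop (IC Loop 2).

`atoxfam` implements the complete analysis chain around that observation:

1. **Topology screening** — call the seven TM helices from Kyte–Doolittle
   hydropathy and derive the structural region map (N-terminal, TMI–TMVII,
   EC/IC Loops 1–3, C-terminal).
2. **Family filtering** — keep sequences whose anchored `[DE]RW[YN]A[IV]`
   motif starts between six residues before the called TMIII end and the end
   of IC Loop 2.
3. **Alignment** — progressive multiple alignment along a Neighbour-Joining
   guide tree, with affine-gap Gotoh alignment at every step.
4. **Phylogenetics** — Poisson-corrected distances, Neighbour-Joining,
   column-resampling bootstrap, majority-rule consensus, and a Felsenstein
   pruning log-likelihood scorer under an equal-rates amino-acid model.
5. **Signature mining** — clade-specific motifs: 100% conserved inside a
   labelled group and absent, as an exact substring, from every sequence
   outside it.
6. **Simulation** — a generator that builds GPCR-like template sequences and
   evolves them along a known tree, so that every stage above can be tested
   against planted ground truth.

Because the original receptor collection was assembled from a public
database without a deposited accession list, the package's validation rests
entirely on simulated families with known truth, plus closed-form and
brute-force oracles. Two analytic results are reproduced exactly from the
genetic code: interconverting aspartate and glutamate (the `D/E` slot of the
family motif) requires a single nucleotide substitution, always at codon
position 3, and the tyrosine-to-asparagine variant of the fourth slot
requires a single substitution at codon position 1.

## Topology screening

Hydropathy is the classic sliding-window statistic: the windowed mean of the
Kyte–Doolittle index, window 19, with edge windows truncated so that the
profile has one value per residue (`X` contributes 0). TM segments are
maximal runs of windowed values at or above a threshold of 1.6; runs
separated by at most 3 positions are merged, and runs shorter than 15
residues are discarded. These are standard hydropathy-plot settings; all
four are arguments of `screen_seven_tm()`. A sequence passes when exactly
seven segments are called. Orientation is not inferred: the family fixes an
extracellular N-terminus, so regions alternate deterministically and the
loops after TMI, TMIII and TMV are intracellular.

Window means are rounded to nine decimals before thresholding. The
Kyte–Doolittle scale is a 0.1-grained table, so a window mean can equal the
threshold exactly; rounding removes floating-point accumulation-order noise
that could otherwise flip such a boundary position when, say, a flank is
prepended to a sequence.

Hidden-Markov-model topology prediction is deliberately out of scope; the
hydropathy detector is a transparent stand-in whose behaviour the tests can
reason about. It has the known limitations of hydropathy plots: at high
divergence an evolving helix interior can drag the windowed mean below the
calling threshold (see *Simulator* below for how the study conditions handle
this).

## Family motif and codon analysis

The filter pattern `[DE]RW[YN]A[IV]` is exactly the union of the variants
observed across phyla (including the Y→N variant seen in *Hydra*); wider
degeneracy is possible via the `pattern` argument but is not the default.
The anchor window starts six residues (one motif length) before the called
TMIII end, allowing the motif to begin inside the helix and finish in the
loop, and ends with IC Loop 2. The first match in the window wins; no
partial or scored matching is attempted.

`codon_min_changes()` brute-forces all sense-codon pairs of the standard
genetic code and reports the minimum Hamming distance together with every
minimising codon pair and its differing positions. The exhaustive check over
all 190 amino-acid pairs (1 ≤ minimum ≤ 3) is part of the test suite.

## Alignment

Pairwise alignment is global Gotoh with affine gaps: BLOSUM62, gap open −10,
gap extend −1, a gap of length $L$ costing $\mathrm{open} + (L-1)\,
\mathrm{ext}$, end gaps penalised. Traceback ties are broken in a fixed
order (pair, then gap in the second sequence, then gap in the first) so
results are deterministic. On sequence pairs short enough to enumerate every
global alignment, the implementation is tested to equal the enumeration
maximum exactly.

The multiple alignment is progressive: a guide tree from Neighbour-Joining
on pairwise p-distances, then profile–profile Gotoh merges bottom-up, with
column pairs scored by the mean sum-of-pairs substitution score (gap symbols
score zero). Children are merged in a canonical order (smallest leaf label
first), which makes the result independent of input order for a fixed guide
tree. Iterative refinement and HMM alignment are out of scope; the aligner
is not intended to reproduce any particular external tool column-for-column.

`conserved_blocks()` reports maximal runs of gap-free columns whose majority
residue reaches a frequency cutoff, with the per-column majority consensus —
the family-level view in which the two strongly conserved regions (TMIII +
IC Loop 2, and TMVII) stand out.

## Distances, trees, support

The observed difference fraction $p$ (gaps and `X` excluded, per pair by
default, or by complete deletion) is corrected as $d = -\ln(1-p)$, the
Poisson correction for repeated substitution. $p \ge 0.95$ is treated as
saturation and raises an error rather than returning an unstable distance —
the user is expected to prune rogue sequences.

Neighbour-Joining follows Saitou–Nei: join the pair minimising
$Q(i,j) = (n-2)d_{ij} - r_i - r_j$, ties broken by the smallest index pair;
standard branch-length formulas; a negative branch length is clamped to zero
with the deficit moved to the sibling edge so the joined path length is
preserved. On additive matrices the algorithm is exact, and the tests verify
exact topology and branch-length recovery on all 15 five-leaf topologies.

The bootstrap resamples alignment columns with replacement, recomputes
Poisson-corrected distances and the NJ tree per replicate (1000 replicates
and a 50% consensus cutoff by default), and is reproducible from its seed.
Replicates that saturate are dropped and counted. The majority-rule
consensus keeps exactly the bipartitions occurring in strictly more than the
cutoff percentage of replicates, annotated with their exact frequencies;
above 50% these are compatible by construction. Robinson–Foulds distance
(symmetric difference of non-trivial bipartition sets) is the topology
metric used throughout, cross-checked against an independent implementation
in the tests.

The likelihood scorer implements Felsenstein pruning under the equal-rates
20-state model implied by the Poisson correction: uniform stationary
frequencies and $P(\text{same}) = \tfrac1{20} + \tfrac{19}{20}
e^{-20t/19}$. Gaps and `X` are missing data. The model is reversible with a
uniform root, so the likelihood is invariant under re-rooting; the tests
check this and the exact agreement with exhaustive summation over internal
states on four-leaf trees. A heuristic maximum-likelihood tree search is
deliberately not implemented: topology comes from NJ, and the scorer ranks
candidate topologies under a reproducible criterion.

## Signature mining

A signature of group $G$ is a maximal run of gap-free alignment columns at
which all members of $G$ are identical, whose residue string lies within the
length bounds (default 6–25, bracketing the observed family motif and group
signatures) and is absent as an exact full-length substring from every
sequence outside $G$. Specificity is checked against the dataset only — an
explicit semantic difference from verifying candidates against an external
database, which is neither reproducible nor version-stable.

One subtlety: a column in which *every* member of $G$ has a gap records an
insertion elsewhere in the alignment, not a break in $G$'s own peptide, so
such columns are skipped rather than terminating a run (the mined motif is
still a contiguous ungapped peptide in each member). A gap in only some
members does break the run. This keeps column-based mining equivalent to
the natural sequence-space definition, and the tests verify exact agreement
with a brute-force oracle that enumerates substrings directly.

Groups with a single member are refused by default (`min_group_size = 2`)
because every substring of a single sequence is trivially "conserved".
Degenerate positions (e.g. a two-way `L/Q` slot) are not mined: the default
stays strict about 100% identity.

The structural annotation maps a motif's columns back to residue
coordinates per member and reads the region labels off each member's
topology; the majority label is reported together with the agreement
fraction.

## The simulator

`generate_dataset()` builds a template receptor — hydrophilic N-terminal
(30 residues), seven hydrophobic stretches of 31 residues drawn from
{I, L, V, F, A} separated by 25-residue loops drawn from
{R, K, D, E, N, Q, S, G}, hydrophilic C-terminal (30 residues), `DRWYAI`
written at the TMIII-end/IC Loop 2 junction — and evolves it along a named
tree under the same equal-rates model the phylogenetics assumes:
substitutions per site per branch are Poisson with mean (branch length ×
site rate), each event replacing the residue with one of the other 19
uniformly. Everything is deterministic given the seed.

Site rates come in three tiers:

* **invariant anchors** (rate 0): the last six TMIII residues plus the
  family motif, and a 12-residue block in TMVII — the two family-wide
  conserved regions; planted clade signatures are likewise invariant, but
  only inside their clade;
* **helix flanks** (default relative rate 0.25): TM residues outside the
  core, evolving slowly the way strongly constrained helix positions do;
* **free sites** (rate 1): loops, termini and a 7-residue core in each
  helix.

The helix cores ensure that TM residues genuinely evolve, which is what
makes the screening stage worth testing; the slow flanks keep the helices
detectable at the study divergences. Two further design choices deserve
note. First, a uniform draw over the hydrophobic set occasionally produces
an Ala-heavy stretch whose above-threshold run barely reaches the
detector's minimum length; no real helix sits at the detection limit, so
template helices are redrawn until each is called with a margin (run ≥ 22
positions). Even so, at the shallow study condition roughly one leaf in
thirty datasets can lose a helix call to an unlucky run of core
substitutions; the pipeline simply drops such a sequence, as it would a
genuinely divergent receptor. Second, clade signatures are planted by
overwriting the sequence entering the clade's stem branch, so members carry
the motif exactly while outsiders carry evolving background at the same
positions.

Two preset study conditions are used:

* **shallow** (`sim_tree_default()`, every branch 0.05 substitutions/site):
  the end-to-end condition. All 12 leaves pass the screen and carry
  `DRWYAI`; the bootstrap consensus recovers the generating topology with
  Robinson–Foulds distance 0.
* **deep** (`sim_tree_deep()`, tips 0.3, internals/stems 0.2, helices fully
  evolving): the signature-mining condition, chosen so that between-clade
  divergence is well above 0.2 and chance within-clade conservation of an
  8-residue run is improbable (per-site conservation within a clade ≈
  $e^{-1.6} \approx 0.2$, so an unplanted conserved 8-run has probability
  ≈ $2.6\times10^{-6}$ per position). Under this condition mining recovers
  exactly the planted signatures: precision and recall are 1.0 against the
  truth tables, where a mined run is matched to the planted feature it
  contains — either a clade signature or one of the two family-invariant
  anchor blocks, which are planted features too and can acquire a
  clade-specific single-column extension by chance.

At shallow divergence, by contrast, many short runs are clade-conserved by
luck and genuinely specific within a 12-sequence dataset; the miner reports
them faithfully. Precision against planted truth is therefore only a
meaningful benchmark at the deep condition — a limitation of small
shallow datasets, not of the miner.

What the simulator does **not** emulate: insertions and deletions (columns
stay homologous by construction, so alignment quality is exercised only
through substitution noise), rate heterogeneity across free sites, amino
acid exchangeabilities (no BLOSUM/JTT-like bias), codon-level evolution, and
database contamination. Passing tests on these data show the machinery is
correct under its own model assumptions; they do not show that the
hydropathy stand-in matches HMM topology predictions on real receptors,
nor that signature specificity would survive a search of a full protein
database.

## Parameter summary

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `window` | 19 | screen | hydropathy window (residues) |
| `threshold` | 1.6 | screen | minimum windowed hydropathy |
| `min_len` / `merge_gap` | 15 / 3 | screen | segment calling |
| `pattern` | `[DE]RW[YN]A[IV]` | filter | family motif |
| `gap_open` / `gap_extend` | −10 / −1 | aligner | affine gap costs (BLOSUM62) |
| `deletion` | pairwise | distances | gap handling |
| `cap` | 0.95 | distances | saturation guard on `p` |
| `n_reps` / `cutoff` | 1000 / 50 | bootstrap/consensus | replicates, % cutoff |
| `len_bounds` | (6, 25) | mining | signature length bounds |
| `min_group_size` | 2 | mining | smallest minable group |
| `tm_len` / `loop_len` | 31 / 25 | simulator | template geometry |
| `tm_core` / `tm_flank_rate` | 7 / 0.25 | simulator | helix rate tiers |

## Notes on the published tables

The published group-signature table contains one location given as
"EC Loop 4"; a seven-helix receptor has exactly three extracellular loops,
so the package's region vocabulary treats that row as EC Loop 3 and no
such label exists at runtime. Similarly, the family motif once appears in
the source literature in a five-residue spelling; the six-residue form used
in its tables is the one implemented.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: 12-leaf
families of ~430-residue sequences, 1000 bootstrap replicates in the
end-to-end run (200 where support values are compared exactly), 200
random pairs for the alignment oracle, 50 four-leaf trees for the
likelihood oracle, and 100 replicates of length-10,000 two-leaf
simulations for the divergence closed form. These sizes were chosen so the
full validation completes in a few minutes on one CPU while keeping every
Monte-Carlo tolerance comfortably below the assertion thresholds.
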