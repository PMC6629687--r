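# Pairwise and profile-profile global alignment (Gotoh affine gaps).

seq_to_idx <- function(residues) {
  match(strsplit(residues, "")[[1]], AA_WITH_X)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment maximising the substitution score
#' minus affine gap costs (a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`). End gaps are penalised. Traceback ties
#' are broken deterministically: residue pairing, then a gap in `b`, then a
#' gap in `a`.
#'
#' @param a,b Residue strings (or one-row sequence tibbles).
#' @param scoring A [scoring_scheme()].
#' @return List with `a`, `b` (gapped strings) and `score`.
#' @export
#' @examples
#' pairwise_align("DRWYAI", "DRWYAI")$score  # 37
pairwise_align <- function(a, b, scoring = scoring_scheme()) {
  a <- as_residue_string(a); b <- as_residue_string(b)
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  ia <- seq_to_idx(a); ib <- seq_to_idx(b)
  M <- scoring$matrix[AA_WITH_X, AA_WITH_X]
  S <- M[ia, ib, drop = FALSE]
  res <- gotoh_align_cpp(S, scoring$gap_open, scoring$gap_extend)
  ach <- strsplit(a, "")[[1]]; bch <- strsplit(b, "")[[1]]
  out_a <- character(length(res$moves)); out_b <- character(length(res$moves))
  i <- 0; j <- 0
  for (k in seq_along(res$moves)) {
    mv <- res$moves[k]
    if (mv == 1L) { i <- i + 1; j <- j + 1; out_a[k] <- ach[i]; out_b[k] <- bch[j] }
    else if (mv == 2L) { i <- i + 1; out_a[k] <- ach[i]; out_b[k] <- "-" }
    else { j <- j + 1; out_a[k] <- "-"; out_b[k] <- bch[j] }
  }
  list(a = paste(out_a, collapse = ""), b = paste(out_b, collapse = ""),
       score = res$score)
}

# Column count matrix of a profile: 22 x ncol (21 residue symbols + gap row,
# the gap row scores 0 against everything).
profile_counts <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  symbols <- c(AA_WITH_X, "-")
  counts <- matrix(0L, nrow = length(symbols), ncol = ncol(mat),
                   dimnames = list(symbols, NULL))
  for (s in symbols) counts[s, ] <- colSums(mat == s)
  counts
}

# Mean sum-of-pairs score between every column of profile A and B.
profile_column_scores <- function(countsA, countsB, scoring) {
  M <- rbind(cbind(scoring$matrix[AA_WITH_X, AA_WITH_X], 0), 0)
  nA <- sum(countsA[, 1]); nB <- sum(countsB[, 1])
  (t(countsA) %*% M %*% countsB) / (nA * nB)
}

align_profiles <- function(rowsA, rowsB, scoring) {
  cA <- profile_counts(rowsA); cB <- profile_counts(rowsB)
  S <- profile_column_scores(cA, cB, scoring)
  res <- gotoh_align_cpp(S, scoring$gap_open, scoring$gap_extend)
  mvs <- res$moves
  nc <- length(mvs)
  idxA <- integer(nc); idxB <- integer(nc)
  i <- 0; j <- 0
  for (k in seq_len(nc)) {
    if (mvs[k] != 3L) { i <- i + 1; idxA[k] <- i }
    if (mvs[k] != 2L) { j <- j + 1; idxB[k] <- j }
  }
  gapA <- strrep("-", 1)
  splice <- function(rows, idx) {
    ch <- strsplit(rows, "")
    vapply(ch, function(v) {
      out <- rep("-", nc)
      out[idx > 0] <- v[idx[idx > 0]]
      paste(out, collapse = "")
    }, character(1))
  }
  list(rows = c(splice(rowsA, idxA), splice(rowsB, idxB)), score = res$score)
}
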