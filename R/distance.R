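# Observed proportion distances and the Poisson correction.

#' Pairwise p-distance matrix of an alignment
#'
#' Proportion of differing sites per pair. Sites with a gap or `X` are
#' excluded per pair (`pairwise` deletion) or globally (`complete` deletion).
#'
#' @param aln Alignment tibble.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return Symmetric numeric matrix with id dimnames.
#' @export
p_distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (nrow(aln) < 2) abort("need at least 2 rows for a distance matrix")
  m <- alignment_matrix(aln)
  valid <- m != "-" & m != "X"
  if (deletion == "complete") {
    keep <- apply(valid, 2, all)
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- valid[i, ] & valid[j, ]
      nc <- sum(ok)
      if (nc == 0) {
        abort(sprintf("no comparable sites between '%s' and '%s'",
                      rownames(m)[i], rownames(m)[j]))
      }
      D[i, j] <- D[j, i] <- sum(m[i, ok] != m[j, ok]) / nc
    }
  }
  D
}

#' Poisson correction of a protein p-distance
#'
#' `d = -log(1 - p)`: the expected substitutions per site under a Poisson
#' model of repeated substitution, given an observed difference fraction `p`.
#'
#' @param p Observed difference fraction(s), in `[0, cap)`.
#' @param cap Saturation guard (default 0.95); `p >= cap` is an error rather
#'   than an unstable huge distance.
#' @return Corrected distance(s).
#' @export
#' @examples
#' poisson_correct(0.5)  # 0.6931
poisson_correct <- function(p, cap = 0.95) {
  if (any(p < 0)) abort("p-distance must be non-negative")
  if (any(p >= cap)) {
    abort(sprintf("saturated distance: p = %.3f >= cap %.2f", max(p), cap))
  }
  -log(1 - p)
}

#' Poisson-corrected distance matrix
#'
#' @inheritParams p_distance_matrix
#' @param cap Saturation guard passed to [poisson_correct()].
#' @return Symmetric matrix of corrected distances.
#' @export
poisson_distance_matrix <- function(aln, deletion = c("pairwise", "complete"),
                                    cap = 0.95) {
  P <- p_distance_matrix(aln, deletion)
  D <- P
  D[] <- poisson_correct(as.vector(P), cap)
  D
}

#' Write a distance matrix as TSV
#' @param D Distance matrix with id dimnames.
#' @param path Output path.
#' @export
write_distance_tsv <- function(D, path) {
  tab <- as_tibble(D)
  tab <- dplyr::bind_cols(tibble(id = rownames(D)), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
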