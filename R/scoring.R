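# Substitution matrix and gap parameters used by the aligners.

# Frozen copy of the standard BLOSUM62 substitution matrix (half-bit units,
# 20 canonical residues).
.blosum62_values <- c(
  4L, -1L, -2L, -2L, 0L, -1L, -1L, 0L, -2L, -1L, -1L, -1L, -1L, -2L, -1L, 1L, 0L, -3L, -2L, 0L,
  -1L, 5L, 0L, -2L, -3L, 1L, 0L, -2L, 0L, -3L, -2L, 2L, -1L, -3L, -2L, -1L, -1L, -3L, -2L, -3L,
  -2L, 0L, 6L, 1L, -3L, 0L, 0L, 0L, 1L, -3L, -3L, 0L, -2L, -3L, -2L, 1L, 0L, -4L, -2L, -3L,
  -2L, -2L, 1L, 6L, -3L, 0L, 2L, -1L, -1L, -3L, -4L, -1L, -3L, -3L, -1L, 0L, -1L, -4L, -3L, -3L,
  0L, -3L, -3L, -3L, 9L, -3L, -4L, -3L, -3L, -1L, -1L, -3L, -1L, -2L, -3L, -1L, -1L, -2L, -2L, -1L,
  -1L, 1L, 0L, 0L, -3L, 5L, 2L, -2L, 0L, -3L, -2L, 1L, 0L, -3L, -1L, 0L, -1L, -2L, -1L, -2L,
  -1L, 0L, 0L, 2L, -4L, 2L, 5L, -2L, 0L, -3L, -3L, 1L, -2L, -3L, -1L, 0L, -1L, -3L, -2L, -2L,
  0L, -2L, 0L, -1L, -3L, -2L, -2L, 6L, -2L, -4L, -4L, -2L, -3L, -3L, -2L, 0L, -2L, -2L, -3L, -3L,
  -2L, 0L, 1L, -1L, -3L, 0L, 0L, -2L, 8L, -3L, -3L, -1L, -2L, -1L, -2L, -1L, -2L, -2L, 2L, -3L,
  -1L, -3L, -3L, -3L, -1L, -3L, -3L, -4L, -3L, 4L, 2L, -3L, 1L, 0L, -3L, -2L, -1L, -3L, -1L, 3L,
  -1L, -2L, -3L, -4L, -1L, -2L, -3L, -4L, -3L, 2L, 4L, -2L, 2L, 0L, -3L, -2L, -1L, -2L, -1L, 1L,
  -1L, 2L, 0L, -1L, -3L, 1L, 1L, -2L, -1L, -3L, -2L, 5L, -1L, -3L, -1L, 0L, -1L, -3L, -2L, -2L,
  -1L, -1L, -2L, -3L, -1L, 0L, -2L, -3L, -2L, 1L, 2L, -1L, 5L, 0L, -2L, -1L, -1L, -1L, -1L, 1L,
  -2L, -3L, -3L, -3L, -2L, -3L, -3L, -3L, -1L, 0L, 0L, -3L, 0L, 6L, -4L, -2L, -2L, 1L, 3L, -1L,
  -1L, -2L, -2L, -1L, -3L, -1L, -1L, -2L, -2L, -3L, -3L, -1L, -2L, -4L, 7L, -1L, -1L, -4L, -3L, -2L,
  1L, -1L, 1L, 0L, -1L, 0L, 0L, 0L, -1L, -2L, -2L, 0L, -1L, -2L, -1L, 4L, 1L, -3L, -2L, -2L,
  0L, -1L, 0L, -1L, -1L, -1L, -1L, -2L, -2L, -1L, -1L, -1L, -1L, -2L, -1L, 1L, 5L, -2L, -2L, 0L,
  -3L, -3L, -4L, -4L, -2L, -2L, -3L, -2L, -2L, -3L, -2L, -3L, -1L, 1L, -4L, -3L, -2L, 11L, 2L, -3L,
  -2L, -2L, -2L, -3L, -2L, -1L, -2L, -3L, 2L, -1L, -1L, -2L, -1L, 3L, -3L, -2L, -2L, 2L, 7L, -1L,
  0L, -3L, -3L, -3L, -1L, -2L, -2L, -3L, -3L, 3L, 1L, -2L, 1L, -1L, -2L, -2L, 0L, -3L, -1L, 4L
)

#' BLOSUM62 substitution matrix
#'
#' Returns the standard BLOSUM62 amino-acid substitution matrix over the 20
#' canonical residues, extended with an `X` row/column scoring 0 against
#' everything (unknown residues are alignment-neutral).
#'
#' @return A symmetric 21 x 21 integer matrix with residue dimnames.
#' @export
#' @examples
#' blosum62()["D", "D"] + blosum62()["R", "R"]
blosum62 <- function() {
  m <- matrix(.blosum62_values, 20, 20, byrow = TRUE,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m <- rbind(cbind(m, X = 0L), X = 0L)
  rownames(m)[21] <- "X"
  m
}

#' Scoring scheme for protein alignment
#'
#' Bundles a symmetric substitution matrix with affine gap penalties. A gap of
#' length L costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param matrix Symmetric substitution matrix with residue dimnames
#'   (default [blosum62()]).
#' @param gap_open Penalty for opening a gap; negative, `<= gap_extend`.
#' @param gap_extend Penalty for each further gapped position; negative.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = blosum62(), gap_open = -10, gap_extend = -1) {
  if (!isSymmetric(unname(as.matrix(matrix)))) {
    abort("substitution matrix must be symmetric")
  }
  if (!(gap_open <= gap_extend && gap_extend < 0)) {
    abort("gap penalties must satisfy gap_open <= gap_extend < 0")
  }
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", nrow(x$matrix), "-letter matrix, gap_open=",
      x$gap_open, ", gap_extend=", x$gap_extend, "\n", sep = "")
  invisible(x)
}
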