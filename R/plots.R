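# Plotting and broom-style summary methods.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_rect
#'   geom_col labs theme_minimal annotate
NULL

#' Plot a hydropathy profile
#'
#' Windowed Kyte-Doolittle hydropathy along the sequence, with the calling
#' threshold and (optionally) the called TM segments shaded.
#'
#' @param object A [hydropathy_profile()].
#' @param threshold Threshold line to draw (default 1.6).
#' @param segments Optional tibble of TM intervals to shade.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hydropathy_profile <- function(object, threshold = 1.6,
                                        segments = NULL, ...) {
  p <- ggplot(object, aes(x = .data$position, y = .data$value)) +
    geom_line(colour = "grey20") +
    geom_hline(yintercept = threshold, linetype = "dashed", colour = "firebrick") +
    labs(x = "residue position (0-based)", y = "mean hydropathy",
         title = "Kyte-Doolittle hydropathy profile") +
    theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0) {
    p <- p + geom_rect(data = segments,
                       aes(xmin = .data$start, xmax = .data$end,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "steelblue", alpha = 0.15)
  }
  p
}

#' Plot per-column conservation of an alignment
#'
#' Majority-residue frequency per gap-free column, with conserved blocks
#' highlighted.
#'
#' @param aln Alignment tibble.
#' @param min_identity,min_len Passed to [conserved_blocks()].
#' @return A ggplot.
#' @export
plot_conservation <- function(aln, min_identity = 0.9, min_len = 6) {
  m <- alignment_matrix(aln)
  freq <- apply(m, 2, function(col) {
    if (any(col == "-")) return(NA_real_)
    max(table(col)) / length(col)
  })
  df <- tibble(column = seq_along(freq) - 1L, identity = freq)
  blocks <- conserved_blocks(aln, min_identity, min_len)
  p <- ggplot(df, aes(x = .data$column, y = .data$identity)) +
    geom_col(width = 1, fill = "grey60", na.rm = TRUE) +
    labs(x = "alignment column (0-based)", y = "majority residue frequency",
         title = "Column conservation") +
    theme_minimal()
  if (nrow(blocks) > 0) {
    p <- p + geom_rect(data = blocks,
                       aes(xmin = .data$start, xmax = .data$end,
                           ymin = 0, ymax = 1),
                       inherit.aes = FALSE, fill = "darkorange", alpha = 0.25)
  }
  p
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an alignment into long form
#'
#' @param x Alignment tibble (class `aa_alignment`).
#' @param ... Ignored.
#' @return Long tibble: `id`, `column` (0-based), `residue`.
#' @exportS3Method generics::tidy
tidy.aa_alignment <- function(x, ...) {
  tidyr::unnest(tibble(id = x$id,
                       column = list(seq_len(alignment_ncol(x)) - 1L),
                       residue = strsplit(x$aligned, "")),
                c("column", "residue"))
}

#' One-row alignment summary
#'
#' @param x Alignment tibble.
#' @param ... Ignored.
#' @return Tibble with `n_sequences`, `n_columns`, `prop_gap`,
#'   `mean_identity` (mean majority-residue frequency over gap-free columns).
#' @exportS3Method generics::glance
glance.aa_alignment <- function(x, ...) {
  m <- alignment_matrix(x)
  gapfree <- apply(m, 2, function(col) all(col != "-"))
  ident <- if (any(gapfree)) {
    mean(apply(m[, gapfree, drop = FALSE], 2, function(col) max(table(col)) / length(col)))
  } else NA_real_
  tibble(n_sequences = nrow(m), n_columns = ncol(m),
         prop_gap = mean(m == "-"), mean_identity = ident)
}
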