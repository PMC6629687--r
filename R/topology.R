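# Seven-transmembrane topology detection by Kyte-Doolittle hydropathy.
#
# A sliding-window hydropathy profile stands in for HMM-based topology
# prediction: maximal runs of windowed mean hydropathy above a threshold are
# called as transmembrane (TM) segments, and a sequence passes the family
# screen when exactly seven are found. Orientation is fixed by the receptor
# family: extracellular N-terminus, so the loops after TMI, TMIII and TMV are
# intracellular. All intervals are 0-based, half-open.

# Kyte-Doolittle hydropathy index; X scores 0.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

REGION_LABELS <- c("N-terminal",
                   "TMI", "IC Loop 1", "TMII", "EC Loop 1", "TMIII",
                   "IC Loop 2", "TMIV", "EC Loop 2", "TMV", "IC Loop 3",
                   "TMVI", "EC Loop 3", "TMVII", "C-terminal")

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Windowed mean hydropathy per residue. Windows are truncated at the sequence
#' ends so the profile has exactly one value per residue; `X` contributes a
#' hydropathy of 0.
#'
#' @param residues A residue string (or a one-row sequence tibble).
#' @param window Odd window length `>= 5` (default 19, the classic setting for
#'   transmembrane helices).
#' @return A tibble of class `hydropathy_profile` with columns `position`
#'   (0-based) and `value`.
#' @export
hydropathy_profile <- function(residues, window = 19) {
  residues <- as_residue_string(residues)
  if (window < 5 || window %% 2 != 1) abort("window must be odd and >= 5")
  n <- nchar(residues)
  if (n < window) abort("sequence shorter than hydropathy window")
  h <- unname(KD_HYDROPATHY[strsplit(residues, "")[[1]]])
  half <- (window - 1) / 2
  cs <- cumsum(c(0, h))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  # window means of the tabulated scale are exact multiples of 0.1/window;
  # rounding removes accumulation-order noise so threshold ties are stable
  vals <- round((cs[hi + 1] - cs[lo]) / (hi - lo + 1), 9)
  structure(tibble(position = seq_len(n) - 1L, value = vals),
            window = as.integer(window),
            class = c("hydropathy_profile", class(tibble())))
}

as_residue_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("residues" %in% names(x), nrow(x) == 1)
    x <- x$residues
  }
  as.character(x)
}

#' Call transmembrane segments from a hydropathy profile
#'
#' Maximal runs of positions with windowed hydropathy at or above `threshold`
#' are called; runs separated by at most `merge_gap` positions are merged, and
#' merged runs shorter than `min_len` are discarded.
#'
#' @param profile A [hydropathy_profile()].
#' @param threshold Minimum windowed hydropathy (default 1.6).
#' @param min_len Minimum segment length in residues (default 15).
#' @param merge_gap Maximum sub-threshold gap bridged between runs (default 3).
#' @return Tibble with columns `start`, `end` (0-based, half-open), ascending.
#' @export
find_tm_segments <- function(profile, threshold = 1.6, min_len = 15, merge_gap = 3) {
  above <- profile$value >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0) return(tibble(start = integer(), end = integer()))
  merged <- runs[1, , drop = FALSE]
  for (k in seq_len(nrow(runs) - 1) + 1) {
    if (runs[k, 1] - merged[nrow(merged), 2] - 1 <= merge_gap) {
      merged[nrow(merged), 2] <- runs[k, 2]
    } else {
      merged <- rbind(merged, runs[k, ])
    }
  }
  keep <- (merged[, 2] - merged[, 1] + 1) >= min_len
  merged <- merged[keep, , drop = FALSE]
  tibble(start = as.integer(merged[, 1] - 1L), end = as.integer(merged[, 2]))
}

#' Assign structural regions from seven TM segments
#'
#' Given exactly seven ascending, non-overlapping TM intervals, derives the
#' full region map of a GPCR with an extracellular N-terminus: the loops
#' alternate intracellular (after TMI, TMIII, TMV) and extracellular (after
#' TMII, TMIV, TMVI), giving three loops on each side.
#'
#' @param segments Tibble with columns `start`, `end`: the 7 TM intervals.
#' @param seq_len Sequence length.
#' @return An object of class `gpcr_topology`: list with `tm` (the segments),
#'   `regions` (tibble `start`, `end`, `region`) and `seq_len`.
#' @export
assign_regions <- function(segments, seq_len) {
  if (nrow(segments) != 7) {
    abort(sprintf("expected exactly 7 TM segments, got %d", nrow(segments)))
  }
  s <- segments[order(segments$start), ]
  if (any(s$start >= s$end) || any(utils::head(s$end, -1) > utils::tail(s$start, -1))) {
    abort("TM segments must be non-empty, ascending and non-overlapping")
  }
  if (s$start[1] < 0 || s$end[7] > seq_len) abort("TM segments outside sequence")
  bounds <- c(0L, as.integer(rbind(s$start, s$end)), as.integer(seq_len))
  regions <- tibble(start = bounds[-length(bounds)], end = bounds[-1],
                    region = REGION_LABELS)
  structure(list(tm = s, regions = regions, seq_len = as.integer(seq_len)),
            class = "gpcr_topology")
}

#' @export
print.gpcr_topology <- function(x, ...) {
  cat("<gpcr_topology> 7 TM segments over", x$seq_len, "residues\n")
  print(x$regions, n = 15)
  invisible(x)
}

#' Region label at residue positions
#'
#' @param topology A `gpcr_topology`.
#' @param position Integer vector of 0-based residue positions.
#' @return Character vector of region labels.
#' @export
region_at <- function(topology, position) {
  idx <- findInterval(position, topology$regions$start)
  bad <- position < 0 | position >= topology$seq_len
  out <- topology$regions$region[idx]
  out[bad] <- NA_character_
  out
}

#' Screen one sequence for the seven-TM architecture
#'
#' @param residues Residue string (or one-row sequence tibble).
#' @param window,threshold,min_len,merge_gap Detector parameters, see
#'   [hydropathy_profile()] and [find_tm_segments()].
#' @return List with elements `pass` (logical), `segments` (tibble) and
#'   `topology` (`gpcr_topology` or `NULL` when the screen fails).
#' @export
screen_seven_tm <- function(residues, window = 19, threshold = 1.6,
                            min_len = 15, merge_gap = 3) {
  residues <- as_residue_string(residues)
  prof <- hydropathy_profile(residues, window)
  seg <- find_tm_segments(prof, threshold, min_len, merge_gap)
  pass <- nrow(seg) == 7
  list(pass = pass, segments = seg,
       topology = if (pass) assign_regions(seg, nchar(residues)) else NULL)
}

#' Screen a whole sequence set
#'
#' Runs [screen_seven_tm()] on every sequence and returns a tidy report.
#'
#' @param seqs Sequence tibble.
#' @inheritParams screen_seven_tm
#' @return Tibble with columns `id`, `pass`, `n_segments` and `segments`
#'   (list-column of interval tibbles); attribute `topologies` holds a named
#'   list of `gpcr_topology` objects for the passing sequences.
#' @export
screen_dataset <- function(seqs, window = 19, threshold = 1.6,
                           min_len = 15, merge_gap = 3) {
  seqs <- validate_sequences(seqs)
  res <- purrr::map(seqs$residues, screen_seven_tm, window = window,
                    threshold = threshold, min_len = min_len, merge_gap = merge_gap)
  out <- tibble(id = seqs$id,
                pass = purrr::map_lgl(res, "pass"),
                n_segments = purrr::map_int(res, ~ nrow(.x$segments)),
                segments = purrr::map(res, "segments"))
  topo <- purrr::map(res, "topology")
  names(topo) <- seqs$id
  attr(out, "topologies") <- topo[out$pass]
  out
}

#' Write a TSV screen report
#'
#' One row per sequence: id, pass flag and the seven segment intervals
#' (`tmK_start`, `tmK_end`), NA where the screen failed.
#'
#' @param screen Result of [screen_dataset()].
#' @param path Output path.
#' @export
write_screen_report <- function(screen, path) {
  seg_cols <- purrr::map(screen$segments, function(s) {
    v <- rep(NA_integer_, 14)
    if (nrow(s) == 7) v <- as.integer(rbind(s$start, s$end))
    setNames(as.list(v), paste0("tm", rep(1:7, each = 2), c("_start", "_end")))
  })
  wide <- dplyr::bind_cols(screen[, c("id", "pass", "n_segments")],
                           dplyr::bind_rows(seg_cols))
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
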