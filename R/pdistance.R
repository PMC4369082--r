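#' Uncorrected p-distance between two nucleotide sequences
#'
#' Globally aligns the two sequences (Needleman-Wunsch, match +1, mismatch
#' -1, gap -2 by default) and returns the proportion of differing aligned
#' columns: (mismatched columns + gapped columns) / aligned columns. Gap-gap
#' columns cannot occur in a pairwise alignment; columns containing `N` count
#' as differing. Identity is `1 - p_distance`.
#'
#' @param seq_a,seq_b non-empty nucleotide strings.
#' @param match,mismatch,gap alignment scores.
#' @return p-distance in `[0, 1]`.
#' @export
p_distance <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("p_distance of an empty sequence")
  cnt <- nw_pdistance_counts(normalize_dna(seq_a), normalize_dna(seq_b),
                             match = match, mismatch = mismatch, gap = gap,
                             band = abs(nchar(seq_a) - nchar(seq_b)) + 16L)
  unname((cnt[["mismatch"]] + cnt[["gaps"]]) / cnt[["aligned"]])
}

#' Pairwise divergence table for the elements of one repeat
#'
#' Selects the elements of `repeat_id` on one replicon whose genomic span
#' exceeds `min_fraction` of the reference repeat length, extracts their
#' strand-normalised sequences, and returns every unordered pair with its
#' uncorrected p-distance and midpoint separation (min-arc on circular
#' replicons).
#'
#' @param replicon an [annotated_replicon()] carrying sequence and elements.
#' @param repeat_id repeat name to collect.
#' @param min_fraction minimum `fraction_full` for a copy to be aligned
#'   (default 0.90, the threshold used for divergence analysis).
#' @return a `data.frame` with columns `element_a`, `element_b`,
#'   `separation_bp`, `p_distance`, `identity`.
#' @export
element_pairs <- function(replicon, repeat_id, min_fraction = 0.90) {
  seqchr <- replicon_sequence(replicon)
  e <- replicon$elements
  e <- e[!is.na(e$repeat_id) & e$repeat_id == repeat_id &
           e$fraction_full > min_fraction, , drop = FALSE]
  n <- nrow(e)
  empty <- data.frame(element_a = integer(), element_b = integer(),
                      separation_bp = numeric(), p_distance = numeric(),
                      identity = numeric())
  if (n < 2) return(empty)
  seqs <- vapply(seq_len(n), function(i) {
    s <- substr(seqchr, e$start[i] + 1L, e$end[i])
    if (e$strand[i] == "-") s <- revcomp_chr(s)
    s
  }, character(1))
  mids <- interval_midpoint(e$start, e$end)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pd <- vapply(seq_len(nrow(idx)), function(r) {
    p_distance(seqs[idx[r, 1]], seqs[idx[r, 2]])
  }, numeric(1))
  sep <- midpoint_separation(mids[idx[, 1]], mids[idx[, 2]],
                             replicon$length_bp, replicon$topology)
  data.frame(element_a = idx[, 1], element_b = idx[, 2],
             separation_bp = sep, p_distance = pd, identity = 1 - pd)
}
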