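## Local-alignment engine shared by search_hits and decompose_footprint:
## exact k-mer seeding (Biostrings::matchPDict) + Smith-Waterman extension
## (Biostrings::pairwiseAlignment), with Karlin-Altschul E-values.

#' Alignment scoring scheme
#'
#' BLASTN-like defaults: match +1, mismatch -2, gap open -5, gap extend -2.
#' The ungapped Karlin-Altschul lambda is solved from
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` under uniform base composition;
#' `K` is a fixed prefactor of the expectation `E = K * m * n * exp(-lambda * S)`.
#'
#' @param match,mismatch per-column scores.
#' @param gap_open,gap_extend gap penalties (negative).
#' @param K Karlin-Altschul prefactor.
#' @param seed_len exact-match word size used for seeding.
#' @return a list of class `scoring_scheme` with a precomputed `lambda`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = -5,
                           gap_extend = -2, K = 0.1, seed_len = 12) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0)
  f <- function(lam) 0.25 * exp(lam * match) + 0.75 * exp(lam * mismatch) - 1
  lambda <- stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, K = K, lambda = lambda,
                 seed_len = as.integer(seed_len)),
            class = "scoring_scheme")
}

## substitution matrix over A,C,G,T,N (N scores as mismatch against all)
scheme_submat <- function(scheme) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scheme$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scheme$match
  m["N", ] <- scheme$mismatch; m[, "N"] <- scheme$mismatch
  m
}

#' Expectation value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` for query length `m` against a search
#' space of `n` bp.
#'
#' @param score alignment score in the scheme's units.
#' @param query_len,subject_len lengths in bp.
#' @param scheme a [scoring_scheme()].
#' @return expectation value (>= 0).
#' @export
karlin_altschul_evalue <- function(score, query_len, subject_len,
                                   scheme = scoring_scheme()) {
  scheme$K * as.numeric(query_len) * as.numeric(subject_len) *
    exp(-scheme$lambda * score)
}

## minimal score that attains E < evalue_max in the given search space
min_score_for_evalue <- function(evalue_max, query_len, subject_len, scheme) {
  ceiling(log(scheme$K * as.numeric(query_len) * as.numeric(subject_len) /
                evalue_max) / scheme$lambda)
}

## best local alignment of pattern vs a character subject; returns NULL or
## list(score, p_start, p_end, s_start, s_end) with 0-based half-open coords
## relative to the subject string
best_local_alignment <- function(pattern, subject, scheme) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = scheme_submat(scheme),
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) return(NULL)
  list(score = sc,
       p_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
       p_end = Biostrings::end(Biostrings::pattern(pa)),
       s_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       s_end = Biostrings::end(Biostrings::subject(pa)))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
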