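#' @useDynLib ishop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom IRanges IRanges reduce countOverlaps start end width
#' @importFrom stats lm pbinom rbinom rexp runif rnorm coef setNames
#' @importFrom utils write.table read.table
"_PACKAGE"

## Coordinates are 0-based half-open everywhere inside the package;
## 1-based inclusive only at the GenBank boundary.

#' Construct a gene feature table
#'
#' Builds the standard feature `data.frame` used in [annotated_replicon()].
#' All coordinates are 0-based half-open.
#'
#' @param locus_id character vector of locus identifiers.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param is_pseudo logical; feature is annotated as a pseudogene.
#' @param is_is_like logical; the feature is itself of insertion-sequence
#'   character (an IS transposase gene or a degraded IS copy annotated as a
#'   gene). Used by the `native_only` enrichment variant.
#' @param product free-text product description.
#' @return a `data.frame` with one row per feature.
#' @export
gene_features <- function(locus_id = character(), start = integer(),
                          end = integer(), strand = "+",
                          is_pseudo = FALSE, is_is_like = FALSE,
                          product = "") {
  n <- length(locus_id)
  df <- data.frame(
    locus_id = as.character(locus_id),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    is_pseudo = rep_len(as.logical(is_pseudo), n),
    is_is_like = rep_len(as.logical(is_is_like), n),
    product = rep_len(as.character(product), n),
    stringsAsFactors = FALSE
  )
  df
}

#' Construct a repeat element table
#'
#' One row per genomic occurrence of a repeat. `fraction_full` is the genomic
#' span length divided by the reference repeat length; an element is called
#' full-length when `fraction_full >= 0.95`.
#'
#' @param repeat_id attributed repeat name (`NA` for unassigned leftovers).
#' @param start,end 0-based half-open genomic interval.
#' @param strand `"+"` or `"-"`.
#' @param fraction_full numeric in `[0, ~1.05]`.
#' @param score attribution alignment score.
#' @return a `data.frame` with one row per element.
#' @export
repeat_elements <- function(repeat_id = character(), start = integer(),
                            end = integer(), strand = "+",
                            fraction_full = numeric(), score = NA_real_) {
  n <- length(repeat_id)
  data.frame(
    repeat_id = as.character(repeat_id),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    fraction_full = rep_len(as.numeric(fraction_full), n),
    score = rep_len(as.numeric(score), n),
    is_full_length = rep_len(as.numeric(fraction_full), n) >= 0.95,
    stringsAsFactors = FALSE
  )
}

#' Annotated replicon
#'
#' Container for one replicon: sequence (optional), gene/pseudogene features
#' and attributed repeat elements, with circular or linear topology.
#'
#' @param id replicon identifier.
#' @param sequence nucleotide string over `A,C,G,T,N`, or `NULL` when only
#'   annotation is available. Ambiguity codes other than `N` are normalised
#'   to `N`.
#' @param length_bp replicon length; defaults to `nchar(sequence)`.
#' @param topology `"circular"` or `"linear"`.
#' @param features a [gene_features()] table.
#' @param elements a [repeat_elements()] table.
#' @return an object of class `AnnotatedReplicon`.
#' @export
annotated_replicon <- function(id, sequence = NULL, length_bp = NULL,
                               topology = c("circular", "linear"),
                               features = gene_features(),
                               elements = repeat_elements()) {
  topology <- match.arg(topology)
  if (!is.null(sequence)) {
    sequence <- normalize_dna(sequence)
    if (is.null(length_bp)) length_bp <- nchar(sequence)
    if (nchar(sequence) != length_bp)
      stop("sequence length (", nchar(sequence), ") != length_bp (", length_bp, ")")
  }
  if (is.null(length_bp)) stop("length_bp required when sequence is absent")
  x <- structure(
    list(id = as.character(id), length_bp = as.integer(length_bp),
         topology = topology, sequence = sequence,
         features = features, elements = elements),
    class = "AnnotatedReplicon"
  )
  validate_replicon(x)
  x
}

#' @export
print.AnnotatedReplicon <- function(x, ...) {
  cat(sprintf("AnnotatedReplicon %s: %d bp, %s, %d features (%d pseudo), %d elements\n",
              x$id, x$length_bp, x$topology, nrow(x$features),
              sum(x$features$is_pseudo), nrow(x$elements)))
  invisible(x)
}

validate_replicon <- function(x) {
  stopifnot(x$length_bp >= 1)
  for (tab in list(x$features, x$elements)) {
    if (nrow(tab) == 0) next
    if (any(tab$start >= tab$end))
      stop("feature with start >= end in replicon ", x$id)
    if (any(tab$start < 0))
      stop("negative coordinate in replicon ", x$id)
    ## origin-spanning features on circular replicons are stored unwrapped,
    ## so end may exceed length_bp by at most the wrapped span
    lim <- if (x$topology == "circular") 2L * x$length_bp else x$length_bp
    if (any(tab$end > lim))
      stop("feature beyond replicon end in replicon ", x$id)
  }
  invisible(TRUE)
}

#' @rdname annotated_replicon
#' @param x object to test.
#' @export
is_replicon <- function(x) inherits(x, "AnnotatedReplicon")

normalize_dna <- function(s) {
  s <- toupper(s)
  gsub("[^ACGTN]", "N", s)
}

replicon_sequence <- function(replicon) {
  if (is.null(replicon$sequence))
    stop("replicon ", replicon$id, " carries no sequence")
  replicon$sequence
}

#' Genomic interval
#'
#' Plain 0-based half-open interval on a named replicon.
#'
#' @param replicon_id replicon identifier.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @return an object of class `GenomicIntervalIS`.
#' @export
genomic_interval <- function(replicon_id, start, end) {
  if (start < 0 || start >= end) stop("require 0 <= start < end")
  structure(list(replicon_id = as.character(replicon_id),
                 start = as.numeric(start), end = as.numeric(end)),
            class = "GenomicIntervalIS")
}

interval_midpoint <- function(start, end) (start + end) / 2

#' Midpoint separation of two intervals
#'
#' Distance between interval midpoints. On circular replicons the minimum of
#' the two arcs is returned; the separation is symmetric and zero when the
#' midpoints coincide. Cross-replicon pairs are refused.
#'
#' @param a,b [genomic_interval()] objects on the same replicon.
#' @param replicon the [annotated_replicon()] they live on (supplies length
#'   and topology).
#' @return separation in bp.
#' @export
separation <- function(a, b, replicon) {
  if (a$replicon_id != b$replicon_id)
    stop("cross-replicon separation is undefined (", a$replicon_id,
         " vs ", b$replicon_id, ")")
  midpoint_separation(interval_midpoint(a$start, a$end),
                      interval_midpoint(b$start, b$end),
                      replicon$length_bp, replicon$topology)
}

## vectorised workhorse used by the spatial statistics
midpoint_separation <- function(m1, m2, length_bp, topology) {
  d <- abs(m1 - m2)
  if (topology == "circular") d <- pmin(d, length_bp - d)
  d
}

## IRanges view of a 0-based half-open table (for unions/overlaps)
as_iranges0 <- function(tab) {
  IRanges::IRanges(start = tab$start + 1L, end = tab$end)
}

## total bp covered by a set of (possibly overlapping) intervals
union_bp <- function(tab) {
  if (nrow(tab) == 0) return(0L)
  sum(IRanges::width(IRanges::reduce(as_iranges0(tab))))
}
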