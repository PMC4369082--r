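## shared fixture builders; all sequence fixtures are generated in code

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc <- function(s) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(s)))

## overwrite `insert` into `background` starting at 1-based position `pos`
overwrite_at <- function(background, pos, insert) {
  paste0(substr(background, 1, pos - 1), insert,
         substr(background, pos + nchar(insert), nchar(background)))
}

## replicon with planted element midpoints (for the positional statistics;
## no sequence needed)
replicon_with_elements <- function(mids, length_bp = 1e6,
                                   topology = "linear", repeat_id = "ISx",
                                   fraction_full = 1, width = 1000) {
  start <- pmax(0, round(mids - width / 2))
  annotated_replicon("toy", length_bp = length_bp, topology = topology,
                     elements = repeat_elements(
                       rep(repeat_id, length(mids)), start, start + width,
                       "+", fraction_full))
}

## mutate a fraction of positions of a sequence (substitutions only)
mutate_seq <- function(s, n_subs) {
  if (n_subs == 0) return(s)
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), n_subs)
  v[idx] <- vapply(v[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(v, collapse = "")
}

## minimal GenBank record text
toy_genbank_text <- function(id = "toy", len = 5000, circular = TRUE,
                             feature_lines = character(), sequence = NULL) {
  topo <- if (circular) "circular" else "linear  "
  out <- c(sprintf("LOCUS       %s             %d bp    DNA     %s BCT 01-JAN-2026",
                   id, len, topo),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", len),
           feature_lines)
  if (!is.null(sequence)) {
    out <- c(out, "ORIGIN")
    s <- tolower(sequence)
    for (off in seq(1, nchar(s), by = 60))
      out <- c(out, sprintf("%9d %s", off, substr(s, off, off + 59)))
  }
  c(out, "//")
}

## independent global-alignment oracle via Biostrings (same scoring as
## p_distance); returns the optimal score
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  m <- matrix(mismatch, 5, 5,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  diag(m) <- match
  m["N", ] <- mismatch; m[, "N"] <- mismatch
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = m,
    gapOpening = 0, gapExtension = gap)
  Biostrings::score(pa)
}
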