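#' Repeat sequence table
#'
#' One row per named reference repeat (nucleotide consensus).
#'
#' @param name repeat name (unique within a library).
#' @param sequence consensus nucleotide string.
#' @param source `"reference_catalogue"` or `"de_novo"`.
#' @param repeat_class one of the repeat classes (see [classify_repeat()]),
#'   or `"unclassified"`.
#' @param genome genome of origin (de novo repeats), `NA` for catalogue
#'   entries.
#' @param n_copies copies observed at discovery time (de novo).
#' @return a `data.frame` with columns `name`, `sequence`, `length_bp`,
#'   `source`, `repeat_class`, `genome`, `n_copies`.
#' @export
repeat_sequences <- function(name = character(), sequence = character(),
                             source = "de_novo",
                             repeat_class = "unclassified",
                             genome = NA_character_, n_copies = NA_integer_) {
  n <- length(name)
  data.frame(name = as.character(name), sequence = as.character(sequence),
             length_bp = nchar(as.character(sequence)),
             source = rep_len(as.character(source), n),
             repeat_class = rep_len(as.character(repeat_class), n),
             genome = rep_len(as.character(genome), n),
             n_copies = rep_len(as.integer(n_copies), n),
             stringsAsFactors = FALSE)
}

#' Repeat library
#'
#' A deduplicated collection of named repeats with a provenance log of
#' merge/removal decisions.
#'
#' @param repeats a [repeat_sequences()] table.
#' @param provenance character vector of log lines.
#' @return an object of class `RepeatLibrary`.
#' @export
repeat_library <- function(repeats = repeat_sequences(),
                           provenance = character()) {
  if (anyDuplicated(repeats$name[!is.na(repeats$name)]))
    stop("duplicate repeat names in library: ",
         paste(unique(repeats$name[duplicated(repeats$name)]), collapse = ", "))
  structure(list(repeats = repeats, provenance = provenance),
            class = "RepeatLibrary")
}

#' @export
print.RepeatLibrary <- function(x, ...) {
  cat(sprintf("RepeatLibrary: %d repeats (%d catalogue, %d de novo)\n",
              nrow(x$repeats), sum(x$repeats$source == "reference_catalogue"),
              sum(x$repeats$source == "de_novo")))
  invisible(x)
}

#' De novo discovery of long repeat families
#'
#' Seed-and-extend consensus finder: exact seed words of length `seed_len`
#' occurring at least `min_copies` times are extended bidirectionally, one
#' column at a time, for as long as at least `1 - max_divergence` of the
#' copies agree with the column majority; the family consensus is the
#' column-majority sequence. Families whose consensus is shorter than
#' `min_repeat_len` are discarded, and families subsumed by a longer family
#' (already-covered positions) are never re-reported. Forward-strand copies
#' drive discovery.
#'
#' @param replicons list of [annotated_replicon()] carrying sequence.
#' @param min_repeat_len minimum consensus length (default 500, the
#'   conventional lower bound for IS-sized repeats).
#' @param min_copies minimum family size (default 2).
#' @param seed_len exact seed word length.
#' @param max_divergence per-column fraction of copies allowed to disagree
#'   with the majority during extension.
#' @return a [repeat_sequences()] table of unnamed de novo repeats (named
#'   `tmp_<genome>_<k>` until [name_repeats()] is applied).
#' @export
find_denovo_repeats <- function(replicons, min_repeat_len = 500,
                                min_copies = 2, seed_len = 16,
                                max_divergence = 0.1) {
  if (min_repeat_len < seed_len)
    stop("min_repeat_len must be >= seed_len")
  if (is_replicon(replicons)) replicons <- list(replicons)
  out <- list()
  for (rep_obj in replicons) {
    fams <- denovo_one(replicon_sequence(rep_obj), min_repeat_len,
                       min_copies, seed_len, max_divergence)
    if (length(fams) == 0) next
    out[[length(out) + 1L]] <- repeat_sequences(
      name = sprintf("tmp_%s_%d", rep_obj$id, seq_along(fams)),
      sequence = vapply(fams, `[[`, character(1), "consensus"),
      source = "de_novo", genome = rep_obj$id,
      n_copies = vapply(fams, `[[`, integer(1), "n_copies"))
  }
  if (length(out) == 0) return(repeat_sequences())
  do.call(rbind, out)
}

denovo_one <- function(seqchr, min_repeat_len, min_copies, seed_len,
                       max_divergence) {
  n <- nchar(seqchr)
  if (n < 2 * seed_len) return(list())
  starts <- seq_len(n - seed_len + 1L)
  kmers <- substring(seqchr, starts, starts + seed_len - 1L)
  ord <- order(kmers, method = "radix")
  r <- rle(kmers[ord])
  multi <- which(r$lengths >= min_copies & !grepl("N", r$values, fixed = TRUE))
  if (length(multi) == 0) return(list())
  ends_run <- cumsum(r$lengths)
  seed_pos <- lapply(multi, function(i) {
    sort(ord[(ends_run[i] - r$lengths[i] + 1L):ends_run[i]])
  })
  o <- order(-r$lengths[multi])
  seed_pos <- seed_pos[o]

  covered <- logical(n)
  chars <- strsplit(seqchr, "", fixed = TRUE)[[1]]
  fams <- list()

  col_ok <- function(pos, keep) {
    ## pos: candidate column position per copy; returns majority base and
    ## agreement among in-bounds copies
    inb <- keep & pos >= 1 & pos <= n
    if (sum(inb) < min_copies) return(NULL)
    b <- chars[pos[inb]]
    tb <- sort(table(b), decreasing = TRUE)
    list(base = names(tb)[1], agree = tb[[1]] / sum(inb), inb = inb)
  }

  for (sp in seed_pos) {
    sp <- sp[!covered[sp]]
    if (length(sp) < min_copies) next
    keep <- rep(TRUE, length(sp))
    ## extend right from seed end, left from seed start
    left <- 0L; right <- seed_len - 1L
    cons_left <- character(0); cons_right <- character(0)
    repeat {
      cc <- col_ok(sp + right + 1L, keep)
      if (is.null(cc) || cc$agree < 1 - max_divergence) break
      right <- right + 1L
      keep <- keep & cc$inb
      cons_right <- c(cons_right, cc$base)
      if (right - left > 25000L) break
    }
    repeat {
      cc <- col_ok(sp + left - 1L, keep)
      if (is.null(cc) || cc$agree < 1 - max_divergence) break
      left <- left - 1L
      keep <- keep & cc$inb
      cons_left <- c(cons_left, cc$base)
      if (right - left > 25000L) break
    }
    width <- right - left + 1L
    if (width < min_repeat_len) next
    sp <- sp[keep]
    if (length(sp) < min_copies) next
    ## families subsumed by an already-reported (longer) family are dropped:
    ## a shifted re-discovery has most of its columns inside the mask
    cov <- mean(covered[unlist(lapply(sp, function(p)
      max(1L, p + left):min(n, p + right)))])
    if (cov > 0.5) next
    seed_part <- substr(seqchr, sp[1], sp[1] + seed_len - 1L)
    ## consensus for the seed columns themselves is the (identical) seed word
    consensus <- paste0(paste(rev(cons_left), collapse = ""), seed_part,
                        paste(cons_right, collapse = ""))
    for (p in sp) {
      covered[max(1L, p + left):min(n, p + right)] <- TRUE
    }
    fams[[length(fams) + 1L]] <- list(consensus = consensus,
                                      n_copies = length(sp))
  }
  fams
}

#' Remove repeats matching non-mobile gene annotations
#'
#' Drops de novo repeats whose supplied product annotation matches a keyword
#' list of non-mobile repeated genes (rRNA operons, tRNAs, photosynthesis
#' gene families and the like). The annotation table stands in for manual
#' curation; no live database is queried.
#'
#' @param repeats a [repeat_sequences()] table.
#' @param exclusion_annotations `data.frame` with columns `name` (repeat
#'   name) and `product`.
#' @param keywords regexes of non-mobile products.
#' @return the filtered table, with removals logged in
#'   `attr(, "removed_log")`.
#' @export
filter_known_gene_repeats <- function(repeats, exclusion_annotations,
                                      keywords = c("rRNA", "tRNA",
                                                   "photosystem",
                                                   "phycobilisome")) {
  if (is.null(exclusion_annotations) || nrow(exclusion_annotations) == 0) {
    attr(repeats, "removed_log") <- character()
    return(repeats)
  }
  unknown <- setdiff(exclusion_annotations$name, repeats$name)
  if (length(unknown))
    warning("annotation for unknown repeat id(s) ignored: ",
            paste(unknown, collapse = ", "))
  pat <- paste(keywords, collapse = "|")
  bad <- exclusion_annotations$name[
    grepl(pat, exclusion_annotations$product, ignore.case = TRUE)]
  drop <- repeats$name %in% bad
  log <- sprintf("removed %s (non-mobile annotation)", repeats$name[drop])
  out <- repeats[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_log") <- log
  out
}

## identity and coverage of the best local alignment of two repeats,
## measured over the shorter sequence
repeat_similarity <- function(seq_a, seq_b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "local",
    substitutionMatrix = scheme_submat(scoring_scheme(match = 1, mismatch = -2)),
    gapOpening = 5, gapExtension = 2)
  aw <- Biostrings::nchar(pa)
  if (aw == 0) return(c(identity = 0, coverage = 0))
  ident <- Biostrings::nmatch(pa) / aw
  cov <- aw / min(nchar(seq_a), nchar(seq_b))
  c(identity = ident, coverage = min(cov, 1))
}

#' Merge de novo repeats with a reference IS catalogue
#'
#' A de novo repeat aligning to a catalogue repeat at `>= dedup_identity`
#' identity over `>= dedup_coverage` of the shorter sequence is a redundancy:
#' it is dropped and the catalogue entry (and its name) survives. De novo
#' repeats are also deduplicated against each other by the same rule, the
#' longer member surviving. Repeats below the similarity threshold are kept
#' as previously unannotated repeats.
#'
#' @param denovo,catalogue [repeat_sequences()] tables; catalogue names must
#'   be unique and conventionally begin with `IS`.
#' @param dedup_identity nucleotide identity threshold (default 0.95).
#' @param dedup_coverage minimum alignment coverage of the shorter sequence
#'   (default 0.8).
#' @return a [repeat_library()] whose provenance logs every merge.
#' @export
assemble_library <- function(denovo, catalogue,
                             dedup_identity = 0.95, dedup_coverage = 0.8) {
  if (anyDuplicated(catalogue$name))
    stop("duplicate names in catalogue")
  log <- character()
  redundant <- function(a_seq, b_seq) {
    s <- repeat_similarity(a_seq, b_seq)
    s[["identity"]] >= dedup_identity && s[["coverage"]] >= dedup_coverage
  }
  keep <- rep(TRUE, nrow(denovo))
  for (i in seq_len(nrow(denovo))) {
    for (j in seq_len(nrow(catalogue))) {
      if (redundant(denovo$sequence[i], catalogue$sequence[j])) {
        keep[i] <- FALSE
        log <- c(log, sprintf("dropped de novo %s: redundant with catalogue %s",
                              denovo$name[i], catalogue$name[j]))
        break
      }
    }
  }
  denovo <- denovo[keep, , drop = FALSE]
  ## de novo vs de novo, longer survives
  if (nrow(denovo) > 1) {
    ord <- order(-denovo$length_bp)
    denovo <- denovo[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(denovo))
    for (i in seq_len(nrow(denovo) - 1)) {
      if (!keep[i]) next
      for (j in (i + 1):nrow(denovo)) {
        if (keep[j] && redundant(denovo$sequence[j], denovo$sequence[i])) {
          keep[j] <- FALSE
          log <- c(log, sprintf("merged de novo %s into %s",
                                denovo$name[j], denovo$name[i]))
        }
      }
    }
    denovo <- denovo[keep, , drop = FALSE]
  }
  reps <- rbind(catalogue, denovo)
  rownames(reps) <- NULL
  repeat_library(reps, provenance = log)
}

#' Name de novo repeats by organism and discovery order
#'
#' De novo repeats become `<Abbrev>_R_<k>` with `k` assigned in discovery
#' order within each genome of origin; catalogue names pass through
#' unchanged.
#'
#' @param library a [repeat_library()].
#' @param organism_abbrevs named character vector, genome id -> abbreviation.
#' @return the renamed library.
#' @export
name_repeats <- function(library, organism_abbrevs) {
  reps <- library$repeats
  dn <- which(reps$source == "de_novo")
  if (length(dn)) {
    genomes <- reps$genome[dn]
    missing <- setdiff(unique(genomes), names(organism_abbrevs))
    if (length(missing))
      stop("no organism abbreviation for genome(s): ",
           paste(missing, collapse = ", "))
    for (g in unique(genomes)) {
      idx <- dn[genomes == g]
      reps$name[idx] <- sprintf("%s_R_%d", organism_abbrevs[[g]],
                                seq_along(idx))
    }
  }
  repeat_library(reps, provenance = library$provenance)
}

#' Write / read a repeat library as FASTA
#'
#' One record per repeat; the header carries the name and, as key=value
#' pairs, the source and class.
#'
#' @param library a [repeat_library()].
#' @param path FASTA path.
#' @return `path` (write) or a `RepeatLibrary` (read).
#' @export
write_library_fasta <- function(library, path) {
  reps <- library$repeats
  ss <- Biostrings::DNAStringSet(reps$sequence)
  names(ss) <- sprintf("%s source=%s class=%s", reps$name, reps$source,
                       reps$repeat_class)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_library_fasta
#' @export
read_library_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  name <- sub("\\s.*$", "", hdr)
  get_kv <- function(key, default) {
    m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))
    vapply(m, function(x) if (length(x)) x[2] else default, character(1))
  }
  repeat_library(repeat_sequences(
    name = name, sequence = as.character(ss),
    source = get_kv("source", "reference_catalogue"),
    repeat_class = get_kv("class", "unclassified")))
}
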