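## Footprint mapping: thresholded local-alignment search of every library
## repeat against a replicon, merging of overlapping hits into footprints,
## and greedy iterative decomposition of each footprint into attributed
## repeat elements.

#' Search one repeat against a replicon
#'
#' Seeded local-alignment search on both strands. Exact `seed_len`-words of
#' the repeat are located in the replicon (Biostrings::matchPDict), seed hits
#' are clustered by diagonal into candidate windows, and each window is
#' aligned by Smith-Waterman. A window may contain several copies: after the
#' best alignment is recorded the flanking sub-windows are re-aligned until
#' no alignment reaches the score threshold. Hits are kept when their
#' Karlin-Altschul expectation `E = K*m*n*exp(-lambda*S)` is below
#' `evalue_max` (`m` = repeat length, `n` = replicon length).
#'
#' @param rep_seq repeat nucleotide sequence (character).
#' @param rep_name repeat name recorded in the hits.
#' @param replicon an [annotated_replicon()] carrying sequence.
#' @param evalue_max expectation threshold (default 1e-6, the conventional
#'   cutoff for IS footprint collection).
#' @param scheme a [scoring_scheme()].
#' @return `data.frame` of hits: `repeat_id`, `start`, `end` (0-based
#'   half-open genomic), `strand`, `score`, `evalue`, `qstart`, `qend`
#'   (0-based half-open on the repeat).
#' @export
search_hits <- function(rep_seq, rep_name, replicon, evalue_max = 1e-6,
                        scheme = scoring_scheme()) {
  L <- nchar(rep_seq)
  if (L < scheme$seed_len)
    stop("repeat ", rep_name, " is shorter than the seed length")
  seqchr <- replicon_sequence(replicon)
  glen <- replicon$length_bp
  smin <- min_score_for_evalue(evalue_max, L, glen, scheme)
  subj <- Biostrings::DNAString(seqchr)

  one_strand <- function(pattern, strand) {
    wins <- seed_windows(pattern, subj, scheme$seed_len, glen)
    hits <- list()
    for (w in wins) {
      hits <- c(hits, align_window(pattern, seqchr, w[1], w[2], smin, scheme))
    }
    if (length(hits) == 0) return(NULL)
    df <- do.call(rbind, lapply(hits, as.data.frame))
    if (strand == "-") {
      q <- df
      df$qstart <- L - q$qend
      df$qend <- L - q$qstart
    }
    df$strand <- strand
    df
  }

  fwd <- one_strand(rep_seq, "+")
  rev <- one_strand(revcomp_chr(rep_seq), "-")
  out <- rbind(fwd, rev)
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(repeat_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), evalue = numeric(),
                      qstart = integer(), qend = integer(),
                      stringsAsFactors = FALSE))
  }
  out$repeat_id <- rep_name
  out$evalue <- karlin_altschul_evalue(out$score, L, glen, scheme)
  out <- out[out$evalue < evalue_max, , drop = FALSE]
  out <- out[order(out$start, out$end), c("repeat_id", "start", "end",
                                          "strand", "score", "evalue",
                                          "qstart", "qend")]
  rownames(out) <- NULL
  out
}

## candidate genomic windows from exact seed words, clustered by diagonal
seed_windows <- function(pattern, subj, k, glen) {
  L <- nchar(pattern)
  qpos <- seq_len(L - k + 1L)
  words <- substring(pattern, qpos, qpos + k - 1L)
  ok <- !grepl("N", words, fixed = TRUE)
  if (!any(ok)) return(list())
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(words[ok]))
  mi <- Biostrings::matchPDict(pd, subj)
  si <- Biostrings::startIndex(mi)
  nhit <- lengths(si)
  if (sum(nhit) == 0) return(list())
  spos <- unlist(si[nhit > 0], use.names = FALSE)
  qp <- rep(qpos[ok][nhit > 0], nhit[nhit > 0])
  diag <- spos - qp
  o <- order(diag, spos)
  spos <- spos[o]; qp <- qp[o]; diag <- diag[o]
  brk <- c(0L, which(diff(diag) > max(30, 0.15 * L) |
                       diff(spos) > max(400, L)), length(diag))
  wins <- list()
  for (i in seq_len(length(brk) - 1L)) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    ## an alignment at the collection score floor spans > seed_len + 1 bp
    ## and so contains at least two overlapping seed words; isolated chance
    ## seed matches cannot yield a reportable hit
    if (length(idx) < 2L) next
    pad_l <- min(qp[idx]) - 1L + 40L
    pad_r <- L - (max(qp[idx]) + k - 1L) + 40L
    ws <- max(0L, min(spos[idx]) - 1L - pad_l)
    we <- min(glen, max(spos[idx]) + k - 1L + pad_r)
    wins[[length(wins) + 1L]] <- c(ws, we)
  }
  ## merge overlapping windows
  wins <- wins[order(vapply(wins, `[`, numeric(1), 1))]
  merged <- list()
  for (w in wins) {
    nlast <- length(merged)
    if (nlast && w[1] <= merged[[nlast]][2]) {
      merged[[nlast]][2] <- max(merged[[nlast]][2], w[2])
    } else merged[[nlast + 1L]] <- w
  }
  merged
}

## best local alignments within [ws, we) (0-based), recursing into flanks
align_window <- function(pattern, seqchr, ws, we, smin, scheme) {
  out <- list()
  stack <- list(c(ws, we))
  while (length(stack)) {
    w <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    if (w[2] - w[1] < scheme$seed_len) next
    sub <- substr(seqchr, w[1] + 1L, w[2])
    al <- best_local_alignment(pattern, sub, scheme)
    if (is.null(al) || al$score < smin) next
    out[[length(out) + 1L]] <- list(
      start = w[1] + al$s_start, end = w[1] + al$s_end,
      score = al$score, qstart = al$p_start, qend = al$p_end)
    stack <- c(stack, list(c(w[1], w[1] + al$s_start)),
               list(c(w[1] + al$s_end, w[2])))
  }
  out
}

#' Merge overlapping hits into footprints
#'
#' Hits (possibly from different repeats) whose genomic intervals overlap or
#' lie within `merge_gap` bp of each other are grouped; the footprint
#' interval is the union span of its hits. Output is sorted by start.
#'
#' @param hits a hit table from [search_hits()] (rows on one replicon).
#' @param merge_gap maximum gap between grouped hits (default 0).
#' @return list of footprints, each `list(start, end, hits)`.
#' @export
merge_footprints <- function(hits, merge_gap = 0) {
  if (is.null(hits) || nrow(hits) == 0) return(list())
  o <- order(hits$start, hits$end)
  hits <- hits[o, , drop = FALSE]
  groups <- integer(nrow(hits))
  g <- 1L; cur_end <- hits$end[1]; groups[1] <- 1L
  if (nrow(hits) > 1) for (i in 2:nrow(hits)) {
    if (hits$start[i] <= cur_end + merge_gap) {
      cur_end <- max(cur_end, hits$end[i])
    } else {
      g <- g + 1L
      cur_end <- hits$end[i]
    }
    groups[i] <- g
  }
  lapply(split(seq_len(nrow(hits)), groups), function(idx) {
    h <- hits[idx, , drop = FALSE]
    structure(list(start = min(h$start), end = max(h$end), hits = h),
              class = "Footprint")
  })
}

#' Decompose a footprint into attributed repeat elements
#'
#' Greedy iteration mirroring the identification procedure: every library
#' repeat is aligned against the unassigned footprint sequence; the
#' highest-scoring repeat's aligned span becomes one element; the remaining
#' segments are re-queried until nothing reaches `min_score`. Ties are
#' broken by longer aligned span, then lexicographic repeat name, making the
#' decomposition deterministic. Segments shorter than `min_leftover` are not
#' re-queried; all unattributed bp are reported as unassigned rows
#' (`repeat_id = NA`), so assigned spans plus leftovers tile the footprint
#' exactly.
#'
#' @param footprint a footprint from [merge_footprints()], or
#'   `list(start, end)`.
#' @param library a [repeat_library()].
#' @param replicon the [annotated_replicon()] the footprint lies on.
#' @param min_leftover smallest leftover segment re-queried (default 50 bp).
#' @param min_score minimum attribution alignment score.
#' @param scheme a [scoring_scheme()].
#' @param candidates optional repeat names to consider. When the footprint
#'   carries its hit table and `min_score` is at least the hit-collection
#'   score floor, restricting candidates to the hit repeats cannot change
#'   the result (a repeat without a collected hit cannot reach `min_score`
#'   on the footprint); [scan_replicon()] exploits this.
#' @return a [repeat_elements()] table sorted by start.
#' @export
decompose_footprint <- function(footprint, library, replicon,
                                min_leftover = 50, min_score = 30,
                                scheme = scoring_scheme(),
                                candidates = NULL) {
  seqchr <- replicon_sequence(replicon)
  reps <- library$repeats
  strands_of <- function(name) c("+", "-")
  if (!is.null(candidates)) {
    if (is.data.frame(candidates)) {
      reps <- reps[reps$name %in% unique(candidates$repeat_id), , drop = FALSE]
      strands_of <- function(name)
        unique(candidates$strand[candidates$repeat_id == name])
    } else {
      reps <- reps[reps$name %in% candidates, , drop = FALSE]
    }
  }
  if (nrow(reps) == 0) stop("library has no repeats")
  rep_rc <- vapply(reps$sequence, revcomp_chr, character(1), USE.NAMES = FALSE)

  rows <- list()
  unassigned <- list()
  stack <- list(c(footprint$start, footprint$end))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    wid <- seg[2] - seg[1]
    if (wid <= 0) next
    if (wid < min_leftover) {
      unassigned[[length(unassigned) + 1L]] <- seg
      next
    }
    sub <- substr(seqchr, seg[1] + 1L, seg[2])
    best <- NULL
    for (i in seq_len(nrow(reps))) {
      for (strand in strands_of(reps$name[i])) {
        pat <- if (strand == "+") reps$sequence[i] else rep_rc[i]
        al <- best_local_alignment(pat, sub, scheme)
        if (is.null(al) || al$score < min_score) next
        span <- al$s_end - al$s_start
        if (is.null(best) || al$score > best$score ||
            (al$score == best$score &&
               (span > best$span ||
                  (span == best$span && reps$name[i] < best$name)))) {
          best <- list(score = al$score, span = span, name = reps$name[i],
                       strand = strand, al = al, ref_len = reps$length_bp[i])
        }
      }
    }
    if (is.null(best)) {
      unassigned[[length(unassigned) + 1L]] <- seg
      next
    }
    gs <- seg[1] + best$al$s_start
    ge <- seg[1] + best$al$s_end
    rows[[length(rows) + 1L]] <- data.frame(
      repeat_id = best$name, start = gs, end = ge, strand = best$strand,
      fraction_full = (ge - gs) / best$ref_len, score = best$score,
      stringsAsFactors = FALSE)
    stack <- c(stack, list(c(seg[1], gs)), list(c(ge, seg[2])))
  }

  assigned <- if (length(rows)) do.call(rbind, rows) else NULL
  out <- repeat_elements()
  if (!is.null(assigned)) {
    out <- repeat_elements(assigned$repeat_id, assigned$start, assigned$end,
                           assigned$strand, assigned$fraction_full,
                           assigned$score)
  }
  if (length(unassigned)) {
    ua <- do.call(rbind, unassigned)
    out <- rbind(out, repeat_elements(
      rep(NA_character_, nrow(ua)), ua[, 1], ua[, 2], "+", NA_real_, NA_real_))
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a replicon against a repeat library
#'
#' Runs [search_hits()] for every library repeat, merges hits into
#' footprints, decomposes each footprint, and returns the replicon with its
#' `elements` table filled in. Footprints are attached as
#' `attr(, "footprints")`.
#'
#' @param replicon an [annotated_replicon()] carrying sequence.
#' @param library a [repeat_library()].
#' @param evalue_max expectation threshold for hit collection.
#' @param merge_gap footprint merging gap.
#' @param min_leftover,min_score decomposition controls
#'   (see [decompose_footprint()]).
#' @param scheme a [scoring_scheme()].
#' @return the replicon with attributed elements.
#' @export
scan_replicon <- function(replicon, library, evalue_max = 1e-6,
                          merge_gap = 0, min_leftover = 50, min_score = 30,
                          scheme = scoring_scheme()) {
  reps <- library$repeats
  if (nrow(reps) == 0) stop("library has no repeats")
  hits <- do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
    search_hits(reps$sequence[i], reps$name[i], replicon,
                evalue_max = evalue_max, scheme = scheme)
  }))
  fps <- merge_footprints(hits, merge_gap = merge_gap)
  elements <- do.call(rbind, lapply(fps, function(fp) {
    decompose_footprint(fp, library = library, replicon = replicon,
                        min_leftover = min_leftover, min_score = min_score,
                        scheme = scheme,
                        candidates = fp$hits[, c("repeat_id", "strand")])
  }))
  if (is.null(elements)) elements <- repeat_elements()
  rownames(elements) <- NULL
  replicon$elements <- elements
  attr(replicon, "footprints") <- fps
  replicon
}

#' Fraction of full length
#'
#' Genomic span length relative to the reference repeat length. Bands used
#' in reporting: full-length `>= 0.95`, severe fragment `< 0.15`, half
#' `< 0.50`, partial otherwise.
#'
#' @param element_len,reference_len lengths in bp; `reference_len >= 1`.
#' @return numeric fraction.
#' @export
fraction_of_full <- function(element_len, reference_len) {
  if (any(reference_len < 1)) stop("reference_len must be >= 1")
  element_len / reference_len
}

#' @rdname fraction_of_full
#' @param fraction numeric vector of fractions.
#' @export
fraction_band <- function(fraction) {
  cut(fraction, breaks = c(-Inf, 0.15, 0.50, 0.95, Inf), right = FALSE,
      labels = c("severe_fragment", "half", "partial", "full_length"))
}

#' Fragment-size histogram
#'
#' Distribution of `fraction_full` over bins of `bin_width`; the final bin
#' absorbs fractions above 1. Frequencies sum to 1.
#'
#' @param elements a [repeat_elements()] table (unassigned rows ignored).
#' @param bin_width bin width on the fraction axis.
#' @return list with `breaks`, `counts`, `freq`, `n`; `n = 0` flags an empty
#'   distribution.
#' @export
fragment_histogram <- function(elements, bin_width = 0.05) {
  fr <- elements$fraction_full[!is.na(elements$fraction_full)]
  breaks <- seq(0, 1, by = bin_width)
  if (length(fr) == 0) {
    return(list(breaks = breaks, counts = integer(length(breaks) - 1),
                freq = numeric(length(breaks) - 1), n = 0L, empty = TRUE))
  }
  fr <- pmin(fr, 1 - 1e-12)  # final bin absorbs > 1
  counts <- tabulate(findInterval(fr, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1)
  list(breaks = breaks, counts = counts, freq = counts / sum(counts),
       n = length(fr), empty = FALSE)
}

#' Genome occupancy summary
#'
#' Per-genome accounting of repeat content: hit counts, union bp covered by
#' elements (overlaps counted once), percent of genome occupied, hits per
#' Mbp, and the genome size with IS elements (and additionally pseudogene
#' bp outside elements) removed.
#'
#' @param replicons list of [annotated_replicon()] with attributed elements.
#' @param is_repeats names of repeats regarded as insertion sequences;
#'   default all attributed repeats.
#' @return list of class `OccupancySummary`.
#' @export
occupancy_summary <- function(replicons, is_repeats = NULL) {
  if (is_replicon(replicons)) replicons <- list(replicons)
  el <- do.call(rbind, lapply(replicons, function(r) {
    e <- r$elements
    if (nrow(e)) e$replicon_id <- r$id
    e
  }))
  total_len <- sum(vapply(replicons, function(r) as.numeric(r$length_bp),
                          numeric(1)))
  attributed <- el[!is.na(el$repeat_id), , drop = FALSE]
  if (is.null(is_repeats))
    is_repeats <- unique(attributed$repeat_id)
  is_el <- attributed[attributed$repeat_id %in% is_repeats, , drop = FALSE]

  per_repl_bp <- function(filter_fun) {
    sum(vapply(replicons, function(r) {
      e <- r$elements[filter_fun(r$elements), , drop = FALSE]
      as.numeric(union_bp(e))
    }, numeric(1)))
  }
  repeat_bp <- per_repl_bp(function(e) !is.na(e$repeat_id))
  is_bp <- per_repl_bp(function(e) !is.na(e$repeat_id) &
                         e$repeat_id %in% is_repeats)
  ## pseudogene bp not already inside elements
  pseudo_extra <- sum(vapply(replicons, function(r) {
    p <- r$features[r$features$is_pseudo, , drop = FALSE]
    if (nrow(p) == 0) return(0)
    pr <- IRanges::reduce(as_iranges0(p))
    er <- IRanges::reduce(as_iranges0(
      r$elements[!is.na(r$elements$repeat_id), , drop = FALSE]))
    both <- IRanges::reduce(c(pr, er))
    overlap <- sum(IRanges::width(pr)) + sum(IRanges::width(er)) -
      sum(IRanges::width(both))
    as.numeric(sum(IRanges::width(pr)) - overlap)
  }, numeric(1)))

  structure(list(
    total_repeat_hits = nrow(attributed),
    total_is_hits = nrow(is_el),
    repeat_bp = repeat_bp,
    percent_occupied = repeat_bp / total_len,
    repeats_per_mbp = nrow(attributed) / (total_len / 1e6),
    genome_bp = total_len,
    genome_minus_is_bp = total_len - is_bp,
    genome_minus_is_and_pseudo_bp = total_len - is_bp - pseudo_extra),
    class = "OccupancySummary")
}

#' @export
print.OccupancySummary <- function(x, ...) {
  cat(sprintf(paste0(
    "OccupancySummary: %d repeat hits (%d IS), %.0f bp occupied ",
    "(%.1f%%), %.1f repeats/Mbp\n"),
    x$total_repeat_hits, x$total_is_hits, x$repeat_bp,
    100 * x$percent_occupied, x$repeats_per_mbp))
  invisible(x)
}
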