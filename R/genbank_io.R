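## GenBank flat-file reader/writer. Coordinates are converted between the
## 1-based inclusive GenBank convention and the package's 0-based half-open
## convention at this boundary only.

#' Read a GenBank flat file
#'
#' Parses one or more records from a GenBank flat file into
#' [annotated_replicon()] objects. Gene-like features (`gene`, `CDS`, `rRNA`,
#' `tRNA`, `misc_feature`, ...) become rows of the feature table; pseudogene
#' status is taken from the `/pseudo` qualifier; `repeat_region` features
#' (as written by [write_genbank()]) become repeat elements. A feature whose
#' location is a `join()` across the origin of a circular replicon is stored
#' as a single feature with an unwrapped end coordinate, preserving its total
#' length. Records without an `ORIGIN` sequence load with `sequence = NULL`;
#' any sequence-requiring operation later refuses such replicons.
#'
#' @param path file path.
#' @return list of `AnnotatedReplicon`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_start <- grep("^LOCUS ", lines)
  if (length(rec_start) == 0) stop("no LOCUS line found in ", path)
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  lapply(seq_along(rec_start), function(i) {
    parse_genbank_record(lines[rec_start[i]:rec_end[i]])
  })
}

parse_genbank_record <- function(lines) {
  locus <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  id <- locus[2]
  len <- suppressWarnings(as.integer(locus[3]))
  if (is.na(len)) stop("malformed LOCUS line for record ", id)
  topology <- if (any(grepl("circular", lines[1]))) "circular" else "linear"

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  terminators <- grep("^(ORIGIN|CONTIG|//)", lines)

  feats <- gene_features()
  elems <- repeat_elements()
  if (length(fstart) == 1) {
    fend <- min(terminators[terminators > fstart] - 1L, length(lines))
    ftab <- parse_feature_block(lines[(fstart + 1):fend], id, len, topology)
    feats <- ftab$features
    elems <- ftab$elements
  }

  sequence <- NULL
  if (length(ostart) == 1) {
    send <- grep("^//", lines)
    send <- if (length(send)) min(send[send > ostart]) - 1L else length(lines)
    if (send > ostart) {
      seq_lines <- gsub("[^A-Za-z]", "", lines[(ostart + 1):send])
      sequence <- paste(seq_lines, collapse = "")
      if (nchar(sequence) == 0) sequence <- NULL
    }
  }
  if (!is.null(sequence) && nchar(sequence) != len)
    stop("record ", id, ": ORIGIN length ", nchar(sequence),
         " does not match LOCUS length ", len)

  annotated_replicon(id = id, sequence = sequence, length_bp = len,
                     topology = topology, features = feats, elements = elems)
}

## split the FEATURES block into (key, location+qualifier lines) chunks
parse_feature_block <- function(lines, rec_id, len, topology) {
  keep <- nchar(trimws(lines)) > 0
  lines <- lines[keep]
  is_key <- grepl("^ {2,8}[A-Za-z0-9_'-]+ {2,}", lines) &
    !grepl("^ {10,}", lines)
  if (!any(is_key)) {
    return(list(features = gene_features(), elements = repeat_elements()))
  }
  idx <- which(is_key)
  ends <- c(idx[-1] - 1L, length(lines))

  feat_rows <- list(); elem_rows <- list()
  auto <- 0L
  for (k in seq_along(idx)) {
    chunk <- lines[idx[k]:ends[k]]
    m <- regmatches(chunk[1], regexec("^ +([A-Za-z0-9_'-]+) +(.*)$", chunk[1]))[[1]]
    key <- m[2]
    if (key == "source") next
    ## location may continue over lines until the first qualifier
    qual_at <- grep("^ +/", chunk)
    loc_end <- if (length(qual_at)) min(qual_at) - 1L else length(chunk)
    loc <- paste0(m[3], paste(trimws(chunk[seq_len(loc_end)][-1]), collapse = ""))
    loc <- gsub("[[:space:]]", "", loc)
    pos <- parse_gb_location(loc, len, topology, rec_id)
    quals <- parse_qualifiers(chunk[qual_at], chunk, qual_at)

    if (key == "repeat_region") {
      elem_rows[[length(elem_rows) + 1L]] <- data.frame(
        repeat_id = quals[["rpt_family"]] %||% NA_character_,
        start = pos$start, end = pos$end, strand = pos$strand,
        fraction_full = as.numeric(quals[["fraction_full"]] %||% NA),
        score = as.numeric(quals[["align_score"]] %||% NA),
        stringsAsFactors = FALSE)
    } else {
      auto <- auto + 1L
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        locus_id = quals[["locus_tag"]] %||% sprintf("%s_f%03d", rec_id, auto),
        start = pos$start, end = pos$end, strand = pos$strand,
        is_pseudo = "pseudo" %in% names(quals),
        is_is_like = identical(quals[["is_like"]], "true") ||
          grepl("transposase|insertion sequence|\\bIS[0-9]", quals[["product"]] %||% "",
                ignore.case = TRUE),
        product = quals[["product"]] %||% "",
        stringsAsFactors = FALSE)
    }
  }
  feats <- if (length(feat_rows)) do.call(rbind, feat_rows) else gene_features()
  ## gene + CDS pairs share a locus_tag; keep the first occurrence but let a
  ## pseudo/product qualifier on either of the pair win
  if (nrow(feats) > 1 && anyDuplicated(feats$locus_id)) {
    feats <- do.call(rbind, lapply(split(feats, feats$locus_id), function(g) {
      r <- g[1, , drop = FALSE]
      r$is_pseudo <- any(g$is_pseudo)
      r$is_is_like <- any(g$is_is_like)
      r$product <- g$product[which(nzchar(g$product))[1]] %||% ""
      if (is.na(r$product)) r$product <- ""
      r
    }))
    feats <- feats[order(feats$start), , drop = FALSE]
    rownames(feats) <- NULL
  }
  elems <- if (length(elem_rows)) {
    e <- do.call(rbind, elem_rows)
    repeat_elements(e$repeat_id, e$start, e$end, e$strand, e$fraction_full, e$score)
  } else repeat_elements()
  list(features = feats, elements = elems)
}

parse_qualifiers <- function(qlines, chunk, qual_at) {
  ## stitch continuation lines (no leading /) onto their qualifier
  quals <- list()
  if (length(qual_at) == 0) return(quals)
  full <- character(0)
  for (i in seq_along(qual_at)) {
    from <- qual_at[i]
    to <- if (i < length(qual_at)) qual_at[i + 1] - 1L else length(chunk)
    full <- c(full, paste(trimws(chunk[from:to]), collapse = " "))
  }
  for (q in full) {
    m <- regmatches(q, regexec('^/([A-Za-z_]+)(="?([^"]*)"?)?$', q))[[1]]
    if (length(m) == 0) next
    quals[[m[2]]] <- if (nchar(m[4])) m[4] else m[2]
  }
  quals
}

## "123..456", "complement(...)", "join(a..b,c..d)", partials (<, >)
parse_gb_location <- function(loc, len, topology, rec_id) {
  strand <- "+"
  raw <- loc
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  join <- grepl("^join\\(", loc)
  if (join) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  rng <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    m <- regmatches(p, regexec("^([0-9]+)\\.\\.([0-9]+)$", p))[[1]]
    if (length(m) == 0) {
      if (grepl("^[0-9]+$", p)) return(c(as.integer(p), as.integer(p)))
      stop("cannot parse location '", raw, "' in record ", rec_id)
    }
    c(as.integer(m[2]), as.integer(m[3]))
  })
  s1 <- rng[[1]][1]; e_last <- rng[[length(rng)]][2]
  if (join && length(rng) == 2 && topology == "circular" &&
      rng[[1]][2] == len && rng[[2]][1] == 1) {
    ## origin-spanning: unwrap past the origin, total length preserved
    return(list(start = s1 - 1L, end = len + e_last, strand = strand))
  }
  lo <- min(vapply(rng, `[`, integer(1), 1))
  hi <- max(vapply(rng, `[`, integer(1), 2))
  list(start = lo - 1L, end = hi, strand = strand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a replicon as a GenBank flat file
#'
#' Emits gene features (with `/pseudo`, `/locus_tag`, `/product` qualifiers)
#' and each repeat element as a `repeat_region` feature carrying the repeat
#' name (`/rpt_family`), class, fraction-of-full-length and attribution score.
#' `read_genbank(write_genbank(x))` preserves intervals and qualifiers.
#'
#' @param replicon an [annotated_replicon()].
#' @param path output file path.
#' @param element_class optional named character vector mapping repeat names
#'   to classes, recorded in a `/note`.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(replicon, path, element_class = NULL) {
  x <- replicon
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  topo <- if (x$topology == "circular") "circular" else "linear  "
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s BCT 01-JAN-2026",
                     x$id, x$length_bp, topo), con)
  writeLines(sprintf("DEFINITION  %s annotated by ishop.", x$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", x$length_bp), con)

  fmt_loc <- function(start, end, strand) {
    if (end > x$length_bp && x$topology == "circular") {
      loc <- sprintf("join(%d..%d,1..%d)", start + 1L, x$length_bp,
                     end - x$length_bp)
    } else {
      loc <- sprintf("%d..%d", start + 1L, end)
    }
    if (strand == "-") loc <- sprintf("complement(%s)", loc)
    loc
  }
  qline <- function(s) writeLines(strwrap(s, width = 79, initial = strrep(" ", 21),
                                          prefix = strrep(" ", 21), exdent = 0)[1], con)

  f <- x$features
  if (nrow(f)) for (i in seq_len(nrow(f))) {
    writeLines(sprintf("     gene            %s",
                       fmt_loc(f$start[i], f$end[i], f$strand[i])), con)
    qline(sprintf('/locus_tag="%s"', f$locus_id[i]))
    if (nzchar(f$product[i])) qline(sprintf('/product="%s"', f$product[i]))
    if (f$is_pseudo[i]) qline("/pseudo")
    if (f$is_is_like[i]) qline('/is_like="true"')
  }
  e <- x$elements
  if (nrow(e)) for (i in seq_len(nrow(e))) {
    writeLines(sprintf("     repeat_region   %s",
                       fmt_loc(e$start[i], e$end[i], e$strand[i])), con)
    if (!is.na(e$repeat_id[i])) qline(sprintf('/rpt_family="%s"', e$repeat_id[i]))
    if (!is.na(e$fraction_full[i]))
      qline(sprintf('/fraction_full="%s"', format(e$fraction_full[i], digits = 6)))
    if (!is.na(e$score[i]))
      qline(sprintf('/align_score="%s"', format(e$score[i], digits = 8)))
    cls <- if (!is.null(element_class) && !is.na(e$repeat_id[i]))
      element_class[[e$repeat_id[i]]] else NULL
    if (!is.null(cls)) qline(sprintf('/note="class=%s"', cls))
  }

  if (!is.null(x$sequence)) {
    writeLines("ORIGIN", con)
    s <- tolower(x$sequence)
    n <- nchar(s)
    for (off in seq(1, n, by = 60)) {
      block <- substr(s, off, min(off + 59, n))
      tens <- sapply(seq(1, nchar(block), by = 10), function(j)
        substr(block, j, min(j + 9, nchar(block))))
      writeLines(sprintf("%9d %s", off, paste(tens, collapse = " ")), con)
    }
  }
  writeLines("//", con)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning bare
#' [annotated_replicon()] objects (no features).
#'
#' @param path FASTA file.
#' @param topology applied to every record.
#' @return list of `AnnotatedReplicon`.
#' @export
read_genome_fasta <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  lapply(seq_along(ss), function(i) {
    annotated_replicon(id = ids[i], sequence = as.character(ss[[i]]),
                       topology = topology)
  })
}
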