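## Repeat classification from supplied protein-similarity evidence.
## Live protein-database searches are replaced by an evidence-table
## contract: each row records a protein hit for one repeat with a category
## hint (transposase, phage, replication_related, dna_interacting, none).

REPEAT_CLASSES <- c("isfinder_is", "putative_is", "phage", "putative_mge",
                    "highly_repeated", "dna_interacting", "unclassified")

#' Protein evidence table
#'
#' @param repeat_id repeat name the evidence belongs to.
#' @param hit_description free-text description of the protein hit.
#' @param evalue expectation value of the hit (>= 0).
#' @param category_hint one of `transposase`, `phage`,
#'   `replication_related`, `dna_interacting`, `none`.
#' @return a `data.frame`.
#' @export
protein_evidence <- function(repeat_id = character(),
                             hit_description = character(),
                             evalue = numeric(), category_hint = "none") {
  n <- length(repeat_id)
  hint <- rep_len(as.character(category_hint), n)
  bad <- setdiff(unique(hint), c("transposase", "phage",
                                 "replication_related", "dna_interacting",
                                 "none"))
  if (length(bad)) stop("unknown category_hint: ", paste(bad, collapse = ", "))
  if (any(evalue < 0)) stop("evalue must be >= 0")
  data.frame(repeat_id = as.character(repeat_id),
             hit_description = rep_len(as.character(hit_description), n),
             evalue = rep_len(as.numeric(evalue), n),
             category_hint = hint, stringsAsFactors = FALSE)
}

#' Read a protein-evidence TSV
#'
#' Columns: `repeat_id`, `hit_description`, `evalue`, `category_hint`.
#'
#' @param path TSV path.
#' @return a [protein_evidence()] table.
#' @export
read_evidence_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  protein_evidence(df$repeat_id, df$hit_description, df$evalue,
                   df$category_hint)
}

#' Classify one repeat
#'
#' Precedence: (1) catalogue repeats are `isfinder_is`; (2) transposase
#' evidence below `evalue_is` makes a `putative_is`; (3) phage evidence
#' makes `phage`; (4) replication-related evidence (endonucleases,
#' RNA-directed DNA polymerases, helicases) makes `putative_mge` and
#' DNA-interacting evidence makes `dna_interacting`; (5) repeats without
#' informative evidence but with at least `high_copy_min` copies in a single
#' genome are `highly_repeated`; anything else is `unclassified`.
#' Conflicting evidence rows resolve to the highest-precedence class.
#'
#' @param repeat_row one row of a [repeat_sequences()] table.
#' @param evidence a [protein_evidence()] table (any repeats; filtered by
#'   name).
#' @param max_copies_in_any_genome copy number of this repeat in its
#'   richest genome.
#' @param evalue_is expectation threshold for evidence (default 1e-5).
#' @param high_copy_min copy threshold for `highly_repeated`; the
#'   "more than five copies" rule read strictly as >= 6.
#' @return a class string.
#' @export
classify_repeat <- function(repeat_row, evidence, max_copies_in_any_genome,
                            evalue_is = 1e-5, high_copy_min = 6) {
  if (repeat_row$source == "reference_catalogue") return("isfinder_is")
  ev <- evidence[evidence$repeat_id == repeat_row$name &
                   evidence$evalue < evalue_is, , drop = FALSE]
  hints <- ev$category_hint
  if ("transposase" %in% hints) return("putative_is")
  if ("phage" %in% hints) return("phage")
  if ("replication_related" %in% hints) return("putative_mge")
  if ("dna_interacting" %in% hints) return("dna_interacting")
  if (max_copies_in_any_genome >= high_copy_min) return("highly_repeated")
  "unclassified"
}

#' Classify every repeat in a library
#'
#' Copy numbers are taken from the attributed elements of the supplied
#' replicons (maximum per-genome count per repeat).
#'
#' @param library a [repeat_library()].
#' @param evidence a [protein_evidence()] table.
#' @param replicons list of scanned [annotated_replicon()].
#' @param evalue_is,high_copy_min see [classify_repeat()].
#' @return the library with `repeat_class` filled in.
#' @export
classify_library <- function(library, evidence, replicons,
                             evalue_is = 1e-5, high_copy_min = 6) {
  if (is_replicon(replicons)) replicons <- list(replicons)
  counts <- lapply(replicons, function(r) {
    e <- r$elements
    table(e$repeat_id[!is.na(e$repeat_id)])
  })
  max_copies <- function(name) {
    v <- vapply(counts, function(tb) {
      if (name %in% names(tb)) as.integer(tb[[name]]) else 0L
    }, integer(1))
    if (length(v)) max(v) else 0L
  }
  reps <- library$repeats
  reps$repeat_class <- vapply(seq_len(nrow(reps)), function(i) {
    classify_repeat(reps[i, ], evidence, max_copies(reps$name[i]),
                    evalue_is = evalue_is, high_copy_min = high_copy_min)
  }, character(1))
  repeat_library(reps, provenance = library$provenance)
}

#' Class census
#'
#' Per-class counts of distinct repeat sequences and of element copies.
#' Marginals conserve totals: the `n_sequences` column sums to the library
#' size and `n_copies` to the attributed element count.
#'
#' @param library a classified [repeat_library()].
#' @param elements a [repeat_elements()] table (or rbind of several).
#' @return `data.frame` with one row per class.
#' @export
class_census <- function(library, elements) {
  reps <- library$repeats
  el <- elements[!is.na(elements$repeat_id), , drop = FALSE]
  cls_of <- setNames(reps$repeat_class, reps$name)
  el_cls <- cls_of[el$repeat_id]
  data.frame(
    class = REPEAT_CLASSES,
    n_sequences = vapply(REPEAT_CLASSES, function(k)
      sum(reps$repeat_class == k), integer(1)),
    n_copies = vapply(REPEAT_CLASSES, function(k)
      sum(el_cls == k, na.rm = TRUE), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Names of IS-class repeats in a library
#'
#' @param library a classified [repeat_library()].
#' @return character vector of repeat names whose class is `isfinder_is` or
#'   `putative_is`.
#' @export
is_class_repeats <- function(library) {
  reps <- library$repeats
  reps$name[reps$repeat_class %in% c("isfinder_is", "putative_is")]
}
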