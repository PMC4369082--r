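## Pipeline orchestration: configuration, the end-to-end run, and report
## tables. All thresholds default to the conventional values used
## throughout the package and live in one place so sensitivity analyses are
## config-only.

#' Pipeline configuration
#'
#' @param genomes paths to genome files (GenBank `.gb/.gbk` or FASTA), or a
#'   list of [annotated_replicon()] objects.
#' @param catalogue path to a reference IS catalogue FASTA, or a
#'   [repeat_library()] (names conventionally begin `IS`).
#' @param evidence path to a protein-evidence TSV, or a
#'   [protein_evidence()] table, or `NULL`.
#' @param out_dir output directory.
#' @param denovo run de novo repeat discovery and merge into the library.
#' @param organism_abbrevs named vector genome id -> abbreviation for
#'   [name_repeats()].
#' @param min_repeat_len,evalue_hit,evalue_is,cluster_min_fraction,pdist_min_fraction,full_length,enrichment_distances_bp,omit_gap
#'   analysis thresholds (defaults: 500 bp, 1e-6, 1e-5, 0.70, 0.90, 0.95,
#'   5/10/50/100/200/500 kbp, 1000 bp).
#' @param min_score,min_leftover decomposition controls.
#' @param seed integer seed recorded in the run log and used for any
#'   stochastic step.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(genomes, catalogue, evidence = NULL,
                            out_dir = "ishop_out", denovo = FALSE,
                            organism_abbrevs = NULL,
                            min_repeat_len = 500, evalue_hit = 1e-6,
                            evalue_is = 1e-5, cluster_min_fraction = 0.70,
                            pdist_min_fraction = 0.90, full_length = 0.95,
                            enrichment_distances_bp = c(5, 10, 50, 100, 200,
                                                        500) * 1000,
                            omit_gap = 1000, min_score = 30,
                            min_leftover = 50, seed = 1L) {
  stopifnot(evalue_hit > 0, evalue_is > 0,
            cluster_min_fraction > 0, cluster_min_fraction < 1,
            pdist_min_fraction > 0, pdist_min_fraction < 1)
  structure(as.list(environment()), class = "PipelineConfig")
}

load_genomes <- function(genomes) {
  if (is.list(genomes) && all(vapply(genomes, is_replicon, logical(1))))
    return(genomes)
  out <- list()
  for (path in genomes) {
    if (!file.exists(path)) stop("genome file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    rs <- if (ext %in% c("gb", "gbk", "genbank")) read_genbank(path)
          else read_genome_fasta(path)
    out <- c(out, rs)
  }
  out
}

load_catalogue <- function(catalogue) {
  if (inherits(catalogue, "RepeatLibrary")) return(catalogue)
  if (!file.exists(catalogue)) stop("catalogue file not found: ", catalogue)
  read_library_fasta(catalogue)
}

#' Run the full annotation and statistics pipeline
#'
#' build-library -> scan -> classify -> stats -> report, writing to
#' `config$out_dir`: the merged library FASTA, one annotated GenBank per
#' replicon, and TSV tables (`occupancy.tsv`, `clusters.tsv`, `pairs.tsv`,
#' `fits.tsv`, `enrichment.tsv`, `report.tsv`) plus `run_log.txt` recording
#' the package version, seed and threshold set, and `data_dictionary.tsv`
#' documenting every column. Deterministic under a fixed config and seed.
#' Partial outputs are removed if a step fails.
#'
#' @param config a [pipeline_config()].
#' @return the output directory, invisibly; results are also returned in
#'   `attr(, "results")`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  genomes <- load_genomes(cfg$genomes)
  library <- load_catalogue(cfg$catalogue)
  if (nrow(library$repeats) == 0 && !cfg$denovo)
    stop("library has no repeats")
  evidence <- if (is.null(cfg$evidence)) protein_evidence()
    else if (is.data.frame(cfg$evidence)) cfg$evidence
    else read_evidence_tsv(cfg$evidence)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(cfg$out_dir, recursive = TRUE))

  ## build-library
  if (cfg$denovo) {
    dn <- find_denovo_repeats(genomes, min_repeat_len = cfg$min_repeat_len)
    library <- assemble_library(dn, library$repeats)
    if (!is.null(cfg$organism_abbrevs))
      library <- name_repeats(library, cfg$organism_abbrevs)
  }
  if (nrow(library$repeats) == 0) stop("library has no repeats")

  ## scan + classify
  scheme <- scoring_scheme()
  scanned <- lapply(genomes, scan_replicon, library = library,
                    evalue_max = cfg$evalue_hit, min_score = cfg$min_score,
                    min_leftover = cfg$min_leftover, scheme = scheme)
  library <- classify_library(library, evidence, scanned,
                              evalue_is = cfg$evalue_is)
  isr <- is_class_repeats(library)

  ## stats
  occ <- lapply(scanned, occupancy_summary, is_repeats = isr)
  clusters <- do.call(rbind, lapply(scanned, function(r) {
    ids <- unique(r$elements$repeat_id)
    ids <- ids[!is.na(ids)]
    ct <- do.call(rbind, lapply(ids, function(id)
      scan_clusters(r, id, min_fraction = cfg$cluster_min_fraction)))
    if (!is.null(ct) && nrow(ct)) ct$replicon_id <- r$id
    ct
  }))
  pairs <- do.call(rbind, lapply(scanned, function(r) {
    ids <- unique(r$elements$repeat_id)
    ids <- ids[!is.na(ids)]
    do.call(rbind, lapply(ids, function(id) {
      pt <- element_pairs(r, id, min_fraction = cfg$pdist_min_fraction)
      if (nrow(pt)) {
        pt$repeat_id <- id
        pt$replicon_id <- r$id
      }
      pt
    }))
  }))
  fits <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    fits <- do.call(rbind, lapply(split(pairs, pairs$repeat_id), function(pt) {
      if (nrow(pt) < 3 || stats::var(pt$separation_bp) == 0) return(NULL)
      f <- hopping_regression(pt, repeat_id = pt$repeat_id[1])
      data.frame(repeat_id = f$repeat_id, n_pairs = f$n_pairs,
                 slope_per_mbp = f$slope_per_mbp, intercept = f$intercept,
                 p_value = f$p_value, stringsAsFactors = FALSE)
    }))
    if (nrow(pairs) >= 3 && stats::var(pairs$separation_bp) > 0) {
      f <- pooled_hopping_regression(pairs)
      fits <- rbind(fits, data.frame(
        repeat_id = "pooled", n_pairs = f$n_pairs,
        slope_per_mbp = f$slope_per_mbp, intercept = f$intercept,
        p_value = f$p_value, stringsAsFactors = FALSE))
    }
  }
  enrichment <- do.call(rbind, lapply(
    c("all", "native_only", "omit_within_1kb"), function(v) {
      pf <- pseudogene_enrichment(scanned,
                                  distances_bp = cfg$enrichment_distances_bp,
                                  variant = v, is_repeats = isr,
                                  omit_gap = cfg$omit_gap)
      pf$variant <- v
      as.data.frame(pf)
    }))

  report <- genome_report(scanned, occ)

  ## write outputs
  tsv <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    utils::write.table(df, file.path(cfg$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_library_fasta(library, file.path(cfg$out_dir, "library.fasta"))
  cls <- setNames(library$repeats$repeat_class, library$repeats$name)
  for (r in scanned)
    write_genbank(r, file.path(cfg$out_dir, paste0(r$id, ".gbk")),
                  element_class = cls)
  tsv(report, "occupancy.tsv")
  tsv(clusters, "clusters.tsv")
  tsv(pairs, "pairs.tsv")
  tsv(fits, "fits.tsv")
  tsv(enrichment, "enrichment.tsv")
  tsv(data_dictionary(), "data_dictionary.tsv")
  writeLines(c(
    sprintf("ishop %s", as.character(utils::packageVersion("ishop"))),
    sprintf("seed\t%d", cfg$seed),
    sprintf("evalue_hit\t%g", cfg$evalue_hit),
    sprintf("evalue_is\t%g", cfg$evalue_is),
    sprintf("min_repeat_len\t%d", cfg$min_repeat_len),
    sprintf("cluster_min_fraction\t%g", cfg$cluster_min_fraction),
    sprintf("pdist_min_fraction\t%g", cfg$pdist_min_fraction),
    sprintf("full_length\t%g", cfg$full_length),
    sprintf("omit_gap\t%g", cfg$omit_gap),
    sprintf("enrichment_distances_bp\t%s",
            paste(cfg$enrichment_distances_bp, collapse = ","))),
    file.path(cfg$out_dir, "run_log.txt"))

  ok <- TRUE
  out <- cfg$out_dir
  attr(out, "results") <- list(genomes = scanned, library = library,
                               occupancy = occ, clusters = clusters,
                               pairs = pairs, fits = fits,
                               enrichment = enrichment, report = report)
  invisible(out)
}

#' Per-genome summary report
#'
#' One row per replicon: repeat hits, IS hits, hits per Mbp, pseudogenes per
#' Mbp, percent occupied and genome-minus-IS size.
#'
#' @param scanned list of scanned [annotated_replicon()].
#' @param occ matching list of [occupancy_summary()] results (computed when
#'   missing).
#' @return `data.frame`, rows in input order.
#' @export
genome_report <- function(scanned, occ = NULL) {
  if (is_replicon(scanned)) scanned <- list(scanned)
  if (is.null(occ)) occ <- lapply(scanned, occupancy_summary)
  do.call(rbind, lapply(seq_along(scanned), function(i) {
    r <- scanned[[i]]; o <- occ[[i]]
    mbp <- r$length_bp / 1e6
    data.frame(
      replicon_id = r$id, length_bp = r$length_bp,
      total_repeat_hits = o$total_repeat_hits,
      total_is_hits = o$total_is_hits,
      repeats_per_mbp = round(o$repeats_per_mbp, 2),
      pseudogenes = sum(r$features$is_pseudo),
      pseudogenes_per_mbp = round(sum(r$features$is_pseudo) / mbp, 2),
      percent_occupied = round(100 * o$percent_occupied, 2),
      genome_minus_is_bp = o$genome_minus_is_bp,
      stringsAsFactors = FALSE)
  }))
}

data_dictionary <- function() {
  data.frame(
    table = c("occupancy", "occupancy", "occupancy", "occupancy",
              "occupancy", "occupancy", "occupancy", "occupancy",
              "occupancy",
              "clusters", "clusters", "clusters", "clusters", "clusters",
              "clusters",
              "pairs", "pairs", "pairs", "pairs",
              "fits", "fits", "fits", "fits", "fits",
              "enrichment", "enrichment", "enrichment", "enrichment",
              "enrichment", "enrichment", "enrichment"),
    column = c("replicon_id", "length_bp", "total_repeat_hits",
               "total_is_hits", "repeats_per_mbp", "pseudogenes",
               "pseudogenes_per_mbp", "percent_occupied",
               "genome_minus_is_bp",
               "repeat_id", "k_in_run", "n_qualifying", "window_bp",
               "success_p", "probability",
               "element_a/element_b", "separation_bp", "p_distance",
               "identity",
               "repeat_id", "n_pairs", "slope_per_mbp", "intercept",
               "p_value",
               "distance_bp", "mean_pseudo_near_is", "mean_pseudo_near_gene",
               "enrichment_ratio", "wilcoxon_p", "defined", "variant"),
    description = c(
      "replicon identifier", "replicon length (bp)",
      "attributed repeat elements", "elements of IS-class repeats",
      "repeat elements per Mbp", "annotated pseudogenes",
      "pseudogenes per Mbp", "percent of genome covered by elements",
      "genome size with IS elements removed (bp)",
      "repeat name", "elements in the positional run",
      "qualifying elements on replicon (fraction > threshold)",
      "midpoint span of the run (bp)", "window / replicon size",
      "binomial probability of the run arising by chance",
      "row indices of the element pair", "midpoint separation (bp)",
      "uncorrected p-distance (proportion of differing aligned sites)",
      "1 - p_distance",
      "repeat name ('pooled' for the pooled fit)", "pairs in the fit",
      "change in p-distance (percentage units) per Mbp separation",
      "fit intercept (percentage units)", "two-sided p-value on the slope",
      "distance threshold (bp)", "mean pseudogene count near IS elements",
      "mean pseudogene count near non-IS genes",
      "mean_pseudo_near_is / mean_pseudo_near_gene",
      "two-sided Wilcoxon rank-sum p-value",
      "FALSE when the denominator mean is zero",
      "counting variant (all / native_only / omit_within_1kb)"),
    stringsAsFactors = FALSE)
}
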