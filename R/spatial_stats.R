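## The three spatial statistics: binomial cluster probability, local-hopping
## regression of divergence on separation, and pseudogene-proximity
## enrichment with rank-sum testing.

#' Binomial probability of a chance cluster
#'
#' Probability that at least `x_in_window` of `n_total` uniformly placed
#' elements fall inside a window of `window_bp` on a replicon of
#' `replicon_bp`. One element anchors the window with probability 1, so the
#' remaining `n_total - 1` elements are Bernoulli trials with success
#' probability `window_bp / replicon_bp`:
#' `P(Binomial(n_total - 1, p) >= x_in_window - 1)`.
#'
#' @param x_in_window elements observed in the window (`1 <= x <= n_total`).
#' @param n_total qualifying elements on the replicon.
#' @param window_bp,replicon_bp window and replicon sizes,
#'   `window_bp <= replicon_bp`.
#' @return probability in `[0, 1]`.
#' @export
cluster_probability <- function(x_in_window, n_total, window_bp,
                                replicon_bp) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (x_in_window < 1 || x_in_window > n_total)
    stop("require 1 <= x_in_window <= n_total")
  if (window_bp > replicon_bp) stop("window_bp must be <= replicon_bp")
  if (x_in_window == 1) return(1)
  p <- window_bp / replicon_bp
  if (p == 0) return(0)
  stats::pbinom(x_in_window - 2, size = n_total - 1, prob = p,
                lower.tail = FALSE)
}

#' Scan one repeat's elements for positional clusters
#'
#' Elements of one repeat on one replicon with `fraction_full >
#' min_fraction` are ordered by midpoint and split into runs wherever the
#' gap between consecutive qualifying elements exceeds the mean spacing
#' (`replicon_bp / n_qualifying`). Each run of `k >= 2` elements yields one
#' cluster test whose window is the midpoint span of the run. Because the
#' window is delimited by an observed element, that element is discounted
#' alongside the anchor: the reported probability is
#' `cluster_probability(x = k - 1, n_total = n_qualifying, window,
#' replicon)`, i.e. the chance that the `k - 2` interior elements co-locate
#' by chance. The minimum probability over runs is the repeat's headline
#' (`attr(, "headline")`). Circular replicons are linearised at the origin
#' for run detection.
#'
#' @param replicon an [annotated_replicon()] with attributed elements.
#' @param repeat_id repeat to scan.
#' @param min_fraction qualifying length fraction (default 0.70).
#' @return `data.frame` of cluster tests (possibly empty): `repeat_id`,
#'   `k_in_run`, `n_qualifying`, `window_bp`, `success_p`, `probability`.
#' @export
scan_clusters <- function(replicon, repeat_id, min_fraction = 0.70) {
  e <- replicon$elements
  e <- e[!is.na(e$repeat_id) & e$repeat_id == repeat_id &
           e$fraction_full > min_fraction, , drop = FALSE]
  empty <- data.frame(repeat_id = character(), k_in_run = integer(),
                      n_qualifying = integer(), window_bp = numeric(),
                      success_p = numeric(), probability = numeric())
  nq <- nrow(e)
  if (nq < 2) {
    attr(empty, "headline") <- NA_real_
    return(empty)
  }
  mids <- sort(interval_midpoint(e$start, e$end))
  gap_max <- replicon$length_bp / nq
  run_id <- cumsum(c(1, diff(mids) > gap_max))
  rows <- lapply(split(mids, run_id), function(m) {
    k <- length(m)
    if (k < 2) return(NULL)
    win <- max(m) - min(m)
    data.frame(repeat_id = repeat_id, k_in_run = k, n_qualifying = nq,
               window_bp = win, success_p = win / replicon$length_bp,
               probability = cluster_probability(k - 1, nq, win,
                                                 replicon$length_bp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    attr(empty, "headline") <- NA_real_
    return(empty)
  }
  rownames(out) <- NULL
  attr(out, "headline") <- min(out$probability)
  out
}

#' Linear model of divergence on genomic separation
#'
#' Ordinary least squares of the uncorrected p-distance (percentage units)
#' on midpoint separation (Mbp), as fitted with `lm`. A positive slope —
#' divergence growing with separation, identity falling — is the signature
#' of local hopping. The two-sided p-value tests the slope against zero.
#'
#' @param pairs a pair table from [element_pairs()] (columns
#'   `separation_bp`, `p_distance`), or an rbind of several for the pooled
#'   fit.
#' @param repeat_id label recorded in the fit.
#' @return list of class `HoppingFit`: `repeat_id`, `n_pairs`,
#'   `slope_per_mbp`, `intercept`, `p_value`, plus the identity-scale slope
#'   `identity_slope_per_mbp = -slope_per_mbp`.
#' @export
hopping_regression <- function(pairs, repeat_id = NA_character_) {
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 pairs for a fit (got ", n, ")")
  x <- pairs$separation_bp / 1e6
  y <- pairs$p_distance * 100
  if (stats::var(x) == 0)
    stop("zero variance in separations: fit refused")
  if (stats::var(y) == 0) {
    fit <- list(repeat_id = repeat_id, n_pairs = n, slope_per_mbp = 0,
                intercept = y[1], p_value = 1,
                identity_slope_per_mbp = 0)
    class(fit) <- "HoppingFit"
    return(fit)
  }
  m <- stats::lm(y ~ x)
  ## a noiseless planted line is a legitimate input; silence the
  ## perfect-fit warning from summary.lm
  sm <- suppressWarnings(summary(m))$coefficients
  fit <- list(repeat_id = repeat_id, n_pairs = n,
              slope_per_mbp = unname(sm["x", "Estimate"]),
              intercept = unname(sm["(Intercept)", "Estimate"]),
              p_value = unname(sm["x", "Pr(>|t|)"]),
              identity_slope_per_mbp = -unname(sm["x", "Estimate"]))
  class(fit) <- "HoppingFit"
  fit
}

#' @export
print.HoppingFit <- function(x, ...) {
  cat(sprintf(
    "HoppingFit %s: n = %d pairs, slope = %+.3f %%-units/Mbp (p = %.3g)\n",
    x$repeat_id, x$n_pairs, x$slope_per_mbp, x$p_value))
  invisible(x)
}

#' @rdname hopping_regression
#' @param pair_tables list of pair tables to pool into a single fit.
#' @export
pooled_hopping_regression <- function(pair_tables,
                                      repeat_id = "pooled") {
  if (is.data.frame(pair_tables)) pair_tables <- list(pair_tables)
  hopping_regression(do.call(rbind, pair_tables), repeat_id = repeat_id)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when `n_a + n_b <= exact_max` and the pooled sample has
#' no ties; otherwise the normal approximation with continuity and tie
#' correction. Standard parameters, double-sided.
#'
#' @param a,b non-empty numeric count vectors.
#' @param exact_max largest pooled size for the exact path (default 12).
#' @return list with `statistic` (Mann-Whitney U of `a`), `p_value`,
#'   `exact`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12) {
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = "two.sided", exact = use_exact, correct = TRUE))
  p <- wt$p.value
  ## at the exact centre of the null distribution the two-sided p is 1;
  ## the continuity correction must not push it below
  if (abs(unname(wt$statistic) - length(a) * length(b) / 2) < 1e-9) p <- 1
  list(statistic = unname(wt$statistic), p_value = p, exact = use_exact)
}

## closest-edge pseudogene counts within d of each focal interval.
## Intervals are IRanges (1-based closed); on circular replicons the
## pseudogene set is replicated at +/- L to emulate wrap-around, and counts
## are capped at the number of available pseudogenes.
.count_within <- function(focal, pseudo, d, length_bp, circular) {
  if (length(pseudo) == 0 || length(focal) == 0)
    return(rep(0L, length(focal)))
  subj <- pseudo
  if (circular) {
    subj <- c(pseudo, IRanges::shift(pseudo, length_bp),
              IRanges::shift(pseudo, -length_bp))
  }
  cnt <- IRanges::countOverlaps(focal, subj, maxgap = d)
  pmin(cnt, length(pseudo))
}

#' Pseudogene enrichment near IS elements
#'
#' For every focal IS element and every focal regular gene (non-pseudogene,
#' non-IS-like — the ratio's denominator is pseudogenes near regular
#' genes), counts the
#' pseudogenes whose closest-edge gap to the focal feature is at most `d`,
#' for each distance in `distances_bp`; the focal feature itself is never
#' counted and counts are pooled across replicons. The enrichment ratio is
#' the mean count near IS elements over the mean count near genes, compared
#' by a two-sided Wilcoxon rank-sum test. Variant `native_only` excludes
#' IS-like pseudogenes from the counted set; `omit_within_1kb` drops
#' pseudogenes closer than `omit_gap` to the focal feature (such pseudogenes
#' may be unrecognised fragments of the IS element itself).
#'
#' @param replicons list of [annotated_replicon()] with gene features and
#'   attributed elements.
#' @param distances_bp distance thresholds (default 5, 10, 50, 100, 200 and
#'   500 kbp).
#' @param variant `"all"`, `"native_only"` or `"omit_within_1kb"`.
#' @param is_repeats repeat names regarded as IS (default: all attributed).
#' @param omit_gap gap for the `omit_within_1kb` variant (default 1000 bp).
#' @return `data.frame` of class `EnrichmentProfile` with one row per
#'   distance: `distance_bp`, `mean_pseudo_near_is`,
#'   `mean_pseudo_near_gene`, `enrichment_ratio`, `wilcoxon_p`, `defined`;
#'   attributes `variant`, `computable`, `n_is`, `n_genes`,
#'   `n_pseudogenes`.
#' @export
pseudogene_enrichment <- function(replicons,
                                  distances_bp = c(5, 10, 50, 100, 200,
                                                   500) * 1000,
                                  variant = c("all", "native_only",
                                              "omit_within_1kb"),
                                  is_repeats = NULL, omit_gap = 1000) {
  variant <- match.arg(variant)
  if (is_replicon(replicons)) replicons <- list(replicons)

  per_repl <- lapply(replicons, function(r) {
    f <- r$features
    e <- r$elements[!is.na(r$elements$repeat_id), , drop = FALSE]
    if (!is.null(is_repeats)) e <- e[e$repeat_id %in% is_repeats, , drop = FALSE]
    genes <- f[!f$is_is_like & !f$is_pseudo, , drop = FALSE]
    pseudo <- f[f$is_pseudo, , drop = FALSE]
    if (variant == "native_only")
      pseudo <- pseudo[!pseudo$is_is_like, , drop = FALSE]
    list(r = r, is_el = e, genes = genes, pseudo = pseudo)
  })
  n_is <- sum(vapply(per_repl, function(p) nrow(p$is_el), integer(1)))
  n_genes <- sum(vapply(per_repl, function(p) nrow(p$genes), integer(1)))
  n_pseudo <- sum(vapply(per_repl, function(p) nrow(p$pseudo), integer(1)))

  mk <- function(rows) {
    out <- rows
    class(out) <- c("EnrichmentProfile", class(out))
    attr(out, "variant") <- variant
    attr(out, "computable") <- n_is > 0 && n_genes > 0
    attr(out, "n_is") <- n_is
    attr(out, "n_genes") <- n_genes
    attr(out, "n_pseudogenes") <- n_pseudo
    out
  }
  if (n_is == 0 || n_genes == 0) {
    return(mk(data.frame(distance_bp = distances_bp,
                         mean_pseudo_near_is = NA_real_,
                         mean_pseudo_near_gene = NA_real_,
                         enrichment_ratio = NA_real_,
                         wilcoxon_p = NA_real_, defined = FALSE)))
  }

  counts_at <- function(d) {
    is_counts <- integer(0); gene_counts <- integer(0)
    for (p in per_repl) {
      circ <- p$r$topology == "circular"
      L <- p$r$length_bp
      pr <- as_iranges0(p$pseudo)
      if (nrow(p$is_el)) {
        fi <- as_iranges0(p$is_el)
        base <- .count_within(fi, pr, d, L, circ)
        if (variant == "omit_within_1kb" && nrow(p$pseudo))
          base <- base - .count_within(fi, pr, omit_gap - 1L, L, circ)
        is_counts <- c(is_counts, base)
      }
      if (nrow(p$genes)) {
        fg <- as_iranges0(p$genes)
        base <- .count_within(fg, pr, d, L, circ)
        if (variant == "omit_within_1kb" && nrow(p$pseudo))
          base <- base - .count_within(fg, pr, omit_gap - 1L, L, circ)
        gene_counts <- c(gene_counts, base)
      }
    }
    list(is_counts = pmax(is_counts, 0L), gene_counts = pmax(gene_counts, 0L))
  }

  rows <- lapply(distances_bp, function(d) {
    cc <- counts_at(d)
    mi <- mean(cc$is_counts); mg <- mean(cc$gene_counts)
    defined <- mg > 0
    wp <- if (length(cc$is_counts) && length(cc$gene_counts) &&
              (stats::var(c(cc$is_counts, cc$gene_counts)) > 0))
      wilcoxon_rank_sum(cc$is_counts, cc$gene_counts)$p_value else 1
    data.frame(distance_bp = d, mean_pseudo_near_is = mi,
               mean_pseudo_near_gene = mg,
               enrichment_ratio = if (defined) mi / mg else NA_real_,
               wilcoxon_p = wp, defined = defined)
  })
  mk(do.call(rbind, rows))
}

#' Enrichment heat-map table across genomes
#'
#' One row per genome and distance with the enrichment ratio and a
#' significance flag (`wilcoxon_p < alpha`). Genomes with fewer than
#' `min_significant` significant distances, or with no annotated
#' pseudogenes, are omitted.
#'
#' @param profiles named list of [pseudogene_enrichment()] profiles, one per
#'   genome.
#' @param alpha significance level (default 0.05).
#' @param min_significant minimum significant distances to retain a genome.
#' @return `data.frame` with columns `genome`, `distance_bp`, `ratio`,
#'   `significant`.
#' @export
enrichment_heatmap_table <- function(profiles, alpha = 0.05,
                                     min_significant = 2) {
  stopifnot(length(profiles) >= 1)
  if (is.null(names(profiles)))
    names(profiles) <- sprintf("genome_%d", seq_along(profiles))
  rows <- lapply(names(profiles), function(g) {
    pf <- profiles[[g]]
    if (!isTRUE(attr(pf, "computable"))) return(NULL)
    if ((attr(pf, "n_pseudogenes") %||% 0) == 0) return(NULL)
    sig <- !is.na(pf$wilcoxon_p) & pf$wilcoxon_p < alpha
    if (sum(sig) < min_significant) return(NULL)
    data.frame(genome = g, distance_bp = pf$distance_bp,
               ratio = pf$enrichment_ratio, significant = sig,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(genome = character(), distance_bp = numeric(),
                      ratio = numeric(), significant = logical())
  rownames(out) <- NULL
  out
}
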