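#' Simulation configuration
#'
#' Parameters of the forward transposition simulator. The defaults describe a
#' bacterial replicon of moderate size carrying a few IS species that prefer
#' short-range ("local") hops: a 1 Mb circular replicon, 400 evenly spaced
#' genes of ~900 bp, 3 IS species of 1 kb seeded at 2 copies each, 60
#' transposition events that are copy-and-paste with probability 0.6 and
#' local with probability 0.75 (exponential hop kernel, mean 50 kb), ~5
#' substitutions per kb applied to each moved or created copy, a 0.3
#' probability that an insertion landing inside a gene pseudogenizes it, and
#' a background pseudogene rate of 5% independent of ISs.
#'
#' @param seed integer RNG seed.
#' @param replicon_bp replicon length before any insertion.
#' @param topology `"circular"` or `"linear"`.
#' @param n_genes number of evenly spaced genes.
#' @param gene_len_bp gene length (bp).
#' @param n_is_species number of distinct IS species.
#' @param is_len_bp reference length of every species.
#' @param initial_copies seeded copies per species.
#' @param n_transpositions number of transposition events.
#' @param p_copy_paste probability an event is copy-and-paste (source copy
#'   remains) rather than cut-and-paste.
#' @param p_local probability a hop is local; otherwise the destination is
#'   uniform on the replicon.
#' @param local_scale_bp mean of the exponential hop-distance kernel.
#' @param sub_rate substitutions per bp applied to the moved/created copy at
#'   each transposition event.
#' @param p_pseudogenize probability that an insertion strictly inside a gene
#'   marks that gene as a pseudogene.
#' @param p_truncate per-copy probability of one truncation event after the
#'   transposition history.
#' @param truncate_frac_range range of the fraction clipped from one end.
#' @param background_pseudo_rate fraction of genes pseudogenized
#'   independently of ISs.
#' @return a list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L, replicon_bp = 1e6,
                              topology = c("circular", "linear"),
                              n_genes = 400, gene_len_bp = 900,
                              n_is_species = 3, is_len_bp = 1000,
                              initial_copies = 2, n_transpositions = 60,
                              p_copy_paste = 0.6, p_local = 0.75,
                              local_scale_bp = 5e4, sub_rate = 0.005,
                              p_pseudogenize = 0.3, p_truncate = 0.15,
                              truncate_frac_range = c(0.2, 0.8),
                              background_pseudo_rate = 0.05) {
  topology <- match.arg(topology)
  cfg <- list(seed = as.integer(seed), replicon_bp = as.integer(replicon_bp),
              topology = topology, n_genes = as.integer(n_genes),
              gene_len_bp = as.integer(gene_len_bp),
              n_is_species = as.integer(n_is_species),
              is_len_bp = as.integer(is_len_bp),
              initial_copies = as.integer(initial_copies),
              n_transpositions = as.integer(n_transpositions),
              p_copy_paste = p_copy_paste, p_local = p_local,
              local_scale_bp = local_scale_bp, sub_rate = sub_rate,
              p_pseudogenize = p_pseudogenize, p_truncate = p_truncate,
              truncate_frac_range = truncate_frac_range,
              background_pseudo_rate = background_pseudo_rate)
  probs <- c(cfg$p_copy_paste, cfg$p_local, cfg$sub_rate, cfg$p_pseudogenize,
             cfg$p_truncate, cfg$background_pseudo_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$local_scale_bp >= cfg$replicon_bp)
    stop("local_scale_bp must be smaller than replicon_bp")
  structure(cfg, class = "SimulationConfig")
}

## ---- event application (shared by simulate() and replay_truth_log()) ----
## The working sequence is held as a raw vector: insertions, deletions and
## substitutions are then plain byte operations instead of string copies.

## deletion coordinate map: positions inside [s, e) collapse onto s
.map_deletion <- function(x, s, e) {
  ifelse(x <= s, x, ifelse(x >= e, x - (e - s), s))
}

.delete_span <- function(state, s, e) {
  state$seq <- raw_delete(state$seq, s, e)
  for (nm in c("features", "elements")) {
    tab <- state[[nm]]
    if (nrow(tab)) {
      tab$start <- .map_deletion(tab$start, s, e)
      tab$end <- .map_deletion(tab$end, s, e)
      state[[nm]] <- tab[tab$end - tab$start > 0, , drop = FALSE]
    }
  }
  state
}

.insert_at <- function(state, dest, frag) {
  if (is.character(frag)) frag <- charToRaw(frag)
  L <- length(frag)
  state$seq <- raw_insert(state$seq, dest, frag)
  for (nm in c("features", "elements")) {
    tab <- state[[nm]]
    if (nrow(tab)) {
      whole <- dest <= tab$start
      absorb <- !whole & dest < tab$end     # insertion inside the feature
      tab$start[whole] <- tab$start[whole] + L
      tab$end[whole | absorb] <- tab$end[whole | absorb] + L
      state[[nm]] <- tab
    }
  }
  state
}

apply_event <- function(state, ev) {
  switch(ev$type,
    cut_paste = {
      keep <- state$elements$element_id != ev$element_id
      state$elements <- state$elements[keep, , drop = FALSE]
      state <- .delete_span(state, ev$src[1], ev$src[2])
      state <- .insert_at(state, ev$dest, ev$seg)
      state$elements <- rbind(state$elements, data.frame(
        element_id = ev$element_id, repeat_id = ev$repeat_id,
        start = ev$dest, end = ev$dest + nchar(ev$seg), strand = ev$strand,
        stringsAsFactors = FALSE))
      state
    },
    copy_paste = {
      state <- .insert_at(state, ev$dest, ev$seg)
      state$elements <- rbind(state$elements, data.frame(
        element_id = ev$element_id, repeat_id = ev$repeat_id,
        start = ev$dest, end = ev$dest + nchar(ev$seg), strand = ev$strand,
        stringsAsFactors = FALSE))
      state
    },
    substitution_batch = {
      if (length(ev$positions)) {
        state$seq[ev$positions + 1L] <-
          charToRaw(paste(ev$bases, collapse = ""))
      }
      state
    },
    truncation = {
      state <- .delete_span(state, ev$region[1], ev$region[2])
      state
    },
    pseudogenization = {
      hit <- state$features$locus_id == ev$locus_id
      state$features$is_pseudo[hit] <- TRUE
      state
    },
    stop("unknown event type: ", ev$type))
}

## ---- the simulator ----

#' Simulate an IS-bearing replicon with known transposition history
#'
#' Builds a random background with evenly spaced genes, seeds the IS species
#' at random non-overlapping positions, then applies `n_transpositions`
#' transposition events. Each event picks a random extant copy; with
#' probability `p_local` the destination is the source midpoint plus a signed
#' exponential displacement (mean `local_scale_bp`), otherwise uniform; with
#' probability `p_copy_paste` the source remains (copy-and-paste). The moved
#' or created copy receives `Binomial(len, sub_rate)` substitutions; an
#' insertion strictly inside a gene pseudogenizes it with probability
#' `p_pseudogenize`. After the history, each copy is truncated with
#' probability `p_truncate` by a uniform fraction in `truncate_frac_range`
#' clipped from one end. Destinations falling strictly inside an existing
#' element are re-drawn (at most 100 attempts, then the event is skipped and
#' logged). Fully deterministic under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a list with components `replicon` (an [annotated_replicon()] whose
#'   elements are the planted truth), `library` (a `RepeatLibrary` of the
#'   species consensus sequences), and `truth` (a `TruthLog`; see
#'   [replay_truth_log()]).
#' @export
simulate_replicon <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  L0 <- cfg$replicon_bp

  ## background + evenly spaced genes (sequence held as a raw vector)
  seq0 <- as.raw(sample(c(65L, 67L, 71L, 84L), L0, replace = TRUE))
  features <- gene_features()
  if (cfg$n_genes > 0) {
    slot <- floor(L0 / cfg$n_genes)
    glen <- min(cfg$gene_len_bp, slot - 20L)
    if (glen < 30) stop("genes do not fit: decrease n_genes or gene_len_bp")
    gstart <- (seq_len(cfg$n_genes) - 1L) * slot + 10L
    features <- gene_features(
      locus_id = sprintf("g%05d", seq_len(cfg$n_genes)),
      start = gstart, end = gstart + glen,
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      is_pseudo = runif(cfg$n_genes) < cfg$background_pseudo_rate,
      is_is_like = FALSE, product = "simulated protein")
  }

  ## IS species (random consensus sequences)
  species <- sprintf("ISsim%d", seq_len(cfg$n_is_species))
  species_seq <- setNames(
    vapply(seq_len(cfg$n_is_species), function(i) random_dna(cfg$is_len_bp),
           character(1)), species)

  state <- list(seq = seq0, features = features,
                elements = data.frame(element_id = integer(),
                                      repeat_id = character(),
                                      start = integer(), end = integer(),
                                      strand = character(),
                                      stringsAsFactors = FALSE))
  next_id <- 1L

  dest_free <- function(state, dest) {
    e <- state$elements
    nrow(e) == 0 || !any(dest > e$start & dest < e$end)
  }

  ## initial placement: uniform, outside existing elements and genes
  for (sp in species) {
    for (k in seq_len(cfg$initial_copies)) {
      ok <- FALSE
      for (att in 1:100) {
        dest <- floor(runif(1, 0, length(state$seq) + 1))
        f <- state$features
        in_gene <- nrow(f) > 0 && any(dest > f$start & dest < f$end)
        if (dest_free(state, dest) && !in_gene) { ok <- TRUE; break }
      }
      if (!ok) next
      strand <- sample(c("+", "-"), 1)
      frag <- if (strand == "+") species_seq[[sp]] else
        revcomp_chr(species_seq[[sp]])
      state <- .insert_at(state, dest, frag)
      state$elements <- rbind(state$elements, data.frame(
        element_id = next_id, repeat_id = sp, start = dest,
        end = dest + nchar(frag), strand = strand, stringsAsFactors = FALSE))
      next_id <- next_id + 1L
    }
  }
  rownames(state$elements) <- NULL

  init <- state  # the initial genome; replay starts here
  events <- list()
  push <- function(ev) { events[[length(events) + 1L]] <<- ev }

  for (t in seq_len(cfg$n_transpositions)) {
    if (nrow(state$elements) == 0) break
    src_i <- sample(nrow(state$elements), 1)
    src <- state$elements[src_i, ]
    src_len <- src$end - src$start
    is_copy <- runif(1) < cfg$p_copy_paste
    glen <- length(state$seq)

    dest <- NA; displacement <- NA; local <- NA
    found <- FALSE
    for (att in 1:100) {
      local <- runif(1) < cfg$p_local
      if (local) {
        displacement <- rexp(1, 1 / cfg$local_scale_bp) * sample(c(-1, 1), 1)
        dest <- round(interval_midpoint(src$start, src$end) + displacement)
        if (cfg$topology == "circular") {
          dest <- ((dest %% glen) + glen) %% glen
        } else if (dest < 0 || dest > glen) next
      } else {
        displacement <- NA
        dest <- floor(runif(1, 0, glen + 1))
      }
      if (dest_free(state, dest)) { found <- TRUE; break }
    }
    if (!found) {
      push(list(type = "skipped", t = t, element_id = src$element_id))
      next
    }

    seg <- rawToChar(state$seq[(src$start + 1L):src$end])
    flip <- runif(1) < 0.5
    strand <- src$strand
    if (flip) {
      seg <- revcomp_chr(seg)
      strand <- if (strand == "+") "-" else "+"
    }

    if (!is_copy) {
      ## excision shifts the destination left when it lies past the source
      dest_adj <- if (dest >= src$end) dest - src_len else dest
      ev <- list(type = "cut_paste", t = t, element_id = src$element_id,
                 repeat_id = src$repeat_id,
                 src = c(src$start, src$end), dest = dest_adj, seg = seg,
                 strand = strand, displacement = displacement, local = local)
    } else {
      ev <- list(type = "copy_paste", t = t, element_id = next_id,
                 repeat_id = src$repeat_id, source_element = src$element_id,
                 dest = dest, seg = seg, strand = strand,
                 displacement = displacement, local = local)
      next_id <- next_id + 1L
    }

    ## gene containing the insertion point, before the state changes
    f <- state$features
    pre_dest <- dest
    host_gene <- if (nrow(f)) which(pre_dest > f$start & pre_dest < f$end) else integer()

    ## per-event substitutions, drawn now and applied to the copy before it
    ## is spliced in; the logged events (unmutated copy + substitution
    ## batch) replay to the same bytes
    Lseg <- nchar(ev$seg)
    nsub <- rbinom(1, Lseg, cfg$sub_rate)
    sev <- NULL
    ev_apply <- ev
    if (nsub > 0) {
      offs <- sort(sample.int(Lseg, nsub))
      old <- substring(ev$seg, offs, offs)
      bases <- vapply(old, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
        USE.NAMES = FALSE)
      sev <- list(type = "substitution_batch", t = t,
                  element_id = ev$element_id,
                  positions = ev$dest + offs - 1L, bases = bases)
      sr <- charToRaw(ev$seg)
      sr[offs] <- charToRaw(paste(bases, collapse = ""))
      ev_apply$seg <- rawToChar(sr)
    }
    push(ev)
    state <- apply_event(state, ev_apply)
    if (!is.null(sev)) push(sev)

    if (length(host_gene)) {
      gid <- f$locus_id[host_gene[1]]
      already <- f$is_pseudo[host_gene[1]]
      if (!already && runif(1) < cfg$p_pseudogenize) {
        pev <- list(type = "pseudogenization", t = t, locus_id = gid,
                    element_id = ev$element_id, dest = pre_dest)
        push(pev)
        state <- apply_event(state, pev)
      }
    }
  }

  ## truncation pass
  if (cfg$p_truncate > 0 && nrow(state$elements) > 0) {
    for (eid in state$elements$element_id) {
      if (runif(1) >= cfg$p_truncate) next
      row <- which(state$elements$element_id == eid)
      el <- state$elements[row, ]
      w <- el$end - el$start
      frac <- runif(1, cfg$truncate_frac_range[1], cfg$truncate_frac_range[2])
      cut <- min(round(frac * w), w - 20L)
      if (cut < 1) next
      from_left <- runif(1) < 0.5
      region <- if (from_left) c(el$start, el$start + cut)
                else c(el$end - cut, el$end)
      tev <- list(type = "truncation", element_id = eid, region = region,
                  from = if (from_left) "left" else "right")
      push(tev)
      state <- apply_event(state, tev)
    }
  }

  ## assemble outputs
  sp_len <- setNames(rep(cfg$is_len_bp, length(species)), species)
  el <- state$elements
  elements <- repeat_elements(
    repeat_id = el$repeat_id, start = el$start, end = el$end,
    strand = el$strand,
    fraction_full = (el$end - el$start) / sp_len[el$repeat_id])
  elements$element_id <- el$element_id
  replicon <- annotated_replicon(
    id = sprintf("sim_seed%d", cfg$seed), sequence = rawToChar(state$seq),
    topology = cfg$topology, features = state$features, elements = elements)

  lib <- repeat_library(repeat_sequences(
    name = species, sequence = unname(species_seq),
    source = "reference_catalogue", repeat_class = "isfinder_is"))

  truth <- structure(list(
    events = events,
    init = init,
    final_elements = elements,
    final_pseudo = state$features[state$features$is_pseudo, , drop = FALSE],
    config = cfg), class = "TruthLog")

  list(replicon = replicon, library = lib, truth = truth)
}

#' Uniform-placement replicon for statistical calibration
#'
#' Builds an annotation-only replicon in which IS element positions are
#' uniform, pseudogene labels are independent Bernoulli draws over the
#' genes, and all annotations are pairwise disjoint (the convention of real
#' feature tables, where a gene interrupted by an IS is annotated as split
#' rather than containing it). This is the null world of the spatial
#' statistics — no transposition dynamics, no IS-pseudogene dependence of
#' any kind — used to measure their type-I error. Contrast
#' [simulate_replicon()], whose insertion dynamics place elements inside
#' genes and thereby couple element and pseudogene geometry even when
#' `p_pseudogenize = 0`.
#'
#' Genes and elements are both placed by random sequential adsorption
#' (uniform draws, redrawn while overlapping anything already placed), so
#' the two focal sets see the same point-process geometry around them — a
#' regular gene lattice would quantise gene-to-gene distances and by itself
#' bias the enrichment ratio. Uses the current RNG state (seed with
#' [set.seed()]).
#'
#' @param n_elements IS elements to place.
#' @param replicon_bp,topology replicon geometry.
#' @param n_genes,gene_len_bp gene lattice.
#' @param pseudo_rate per-gene pseudogene probability.
#' @param element_len element width in bp.
#' @param repeat_id repeat name given to every element.
#' @return an [annotated_replicon()] without sequence.
#' @export
random_placement_replicon <- function(n_elements = 100, replicon_bp = 1e6,
                                      topology = "linear", n_genes = 400,
                                      gene_len_bp = 900, pseudo_rate = 0.05,
                                      element_len = 1000,
                                      repeat_id = "ISnull") {
  if (n_genes * gene_len_bp + n_elements * element_len > 0.6 * replicon_bp)
    stop("requested features exceed 60% packing; placement would jam")
  taken_s <- numeric(0); taken_e <- numeric(0)
  place <- function(n, width) {
    out <- numeric(0)
    for (k in seq_len(n)) {
      for (att in 1:500) {
        s <- floor(runif(1, 0, replicon_bp - width))
        if (!any(s < taken_e & s + width > taken_s)) break
        s <- NA
      }
      if (is.na(s)) next
      out <- c(out, s)
      taken_s <<- c(taken_s, s); taken_e <<- c(taken_e, s + width)
    }
    out
  }
  gs <- place(n_genes, gene_len_bp)
  es <- place(n_elements, element_len)
  feats <- gene_features()
  if (length(gs)) {
    feats <- gene_features(
      locus_id = sprintf("g%05d", seq_along(gs)),
      start = gs, end = gs + gene_len_bp,
      strand = "+", is_pseudo = runif(length(gs)) < pseudo_rate)
  }
  annotated_replicon(
    "placement_null", length_bp = replicon_bp, topology = topology,
    features = feats,
    elements = repeat_elements(rep(repeat_id, length(es)), es,
                               es + element_len, "+", 1))
}

#' Replay a simulation event log
#'
#' Re-applies every logged event to the stored initial genome. The replayed
#' sequence is byte-for-byte identical to the simulated replicon's sequence;
#' this is the integrity guarantee of the `TruthLog`.
#'
#' @param truth a `TruthLog` from [simulate_replicon()].
#' @return the replayed state: list with `seq`, `features`, `elements`.
#' @export
replay_truth_log <- function(truth) {
  stopifnot(inherits(truth, "TruthLog"))
  state <- truth$init
  for (ev in truth$events) {
    if (ev$type == "skipped") next
    state <- apply_event(state, ev)
  }
  state$seq <- rawToChar(state$seq)
  state
}

#' Compare called elements against planted truth
#'
#' A call matches a planted element when the repeat ids agree and the
#' reciprocal interval overlap is at least `min_reciprocal`. Recall is
#' computed over planted elements with `fraction_full >= min_truth_fraction`;
#' precision over all calls against the full planted set (a call that
#' recovers a short planted fragment is not a false positive).
#'
#' @param called a [repeat_elements()] table.
#' @param truth a `TruthLog` or a truth element table.
#' @param min_reciprocal reciprocal-overlap threshold (default 0.8).
#' @param min_truth_fraction restrict the recall denominator to planted
#'   copies at least this fraction of full length.
#' @param slack_bp boundary slack used for the `within_slack` summary.
#' @return list with `recall`, `precision`, `mean_boundary_error`,
#'   `within_slack`, `n_called`, `n_truth`.
#' @export
truth_compare <- function(called, truth, min_reciprocal = 0.8,
                          min_truth_fraction = 0, slack_bp = 20) {
  tt <- if (inherits(truth, "TruthLog")) truth$final_elements else truth
  called <- called[!is.na(called$repeat_id), , drop = FALSE]
  nC <- nrow(called); nT <- nrow(tt)
  matched_c <- logical(nC); matched_t <- logical(nT)
  berr <- numeric(0)
  if (nC && nT) {
    cand <- expand.grid(ci = seq_len(nC), ti = seq_len(nT))
    cand <- cand[called$repeat_id[cand$ci] == tt$repeat_id[cand$ti], , drop = FALSE]
    if (nrow(cand)) {
      ov <- pmin(called$end[cand$ci], tt$end[cand$ti]) -
        pmax(called$start[cand$ci], tt$start[cand$ti])
      wc <- called$end[cand$ci] - called$start[cand$ci]
      wt <- tt$end[cand$ti] - tt$start[cand$ti]
      rec <- pmin(ov / wc, ov / wt)
      cand <- cand[rec >= min_reciprocal, , drop = FALSE]
      rec <- rec[rec >= min_reciprocal]
      o <- order(-rec)
      for (k in o) {
        ci <- cand$ci[k]; ti <- cand$ti[k]
        if (matched_c[ci] || matched_t[ti]) next
        matched_c[ci] <- TRUE; matched_t[ti] <- TRUE
        berr <- c(berr, abs(called$start[ci] - tt$start[ti]),
                  abs(called$end[ci] - tt$end[ti]))
      }
    }
  }
  keep_t <- tt$fraction_full >= min_truth_fraction
  list(recall = if (any(keep_t)) mean(matched_t[keep_t]) else NA_real_,
       precision = if (nC) mean(matched_c) else NA_real_,
       mean_boundary_error = if (length(berr)) mean(berr) else 0,
       within_slack = if (length(berr)) mean(berr <= slack_bp) else 1,
       n_called = nC, n_truth = sum(keep_t))
}
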