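make_planted_replicon <- function(glen, plants) {
  ## plants: list of list(seq, pos) with 1-based positions
  g <- rand_dna(glen)
  for (p in plants) g <- overwrite_at(g, p$pos, p$seq)
  annotated_replicon("pl", sequence = g, topology = "linear")
}

test_that("an exact planted copy yields one near-complete significant hit", {
  set.seed(31)
  is_seq <- rand_dna(800)
  r <- make_planted_replicon(50000, list(list(seq = is_seq, pos = 20001)))
  h <- search_hits(is_seq, "ISx", r)
  expect_equal(nrow(h), 1)
  expect_lt(h$evalue, 1e-6)
  expect_gte((h$qend - h$qstart) / 800, 0.99)
  expect_equal(h$strand, "+")
  expect_lte(abs(h$start - 20000), 5)
})

test_that("a reverse-complemented copy is found on the minus strand", {
  set.seed(32)
  is_seq <- rand_dna(800)
  r <- make_planted_replicon(30000, list(list(seq = rc(is_seq), pos = 12001)))
  h <- search_hits(is_seq, "ISx", r)
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "-")
  expect_lte(abs(h$start - 12000), 5)
  expect_gte((h$qend - h$qstart) / 800, 0.99)
})

test_that("no false hits arise on repeat-free backgrounds", {
  for (trial in 1:20) {
    set.seed(300 + trial)
    r <- annotated_replicon("bg", sequence = rand_dna(50000),
                            topology = "linear")
    h <- search_hits(rand_dna(1000), "ISnone", r)
    expect_equal(nrow(h), 0, info = paste("trial", trial))
  }
})

test_that("a diverged truncated copy is still located", {
  set.seed(33)
  is_seq <- rand_dna(1000)
  frag <- mutate_seq(substr(is_seq, 201, 800), 12)  # 600 bp at 2% divergence
  r <- make_planted_replicon(40000, list(list(seq = frag, pos = 15001)))
  h <- search_hits(is_seq, "ISx", r)
  expect_equal(nrow(h), 1)
  expect_lt(abs(h$start - 15000), 25)
  expect_lt(abs(h$end - 15600), 25)
})

test_that("repeats shorter than the seed are refused", {
  r <- annotated_replicon("bg", sequence = rand_dna(1000),
                          topology = "linear")
  expect_error(search_hits("ACGT", "tiny", r), "seed")
})

test_that("footprint merging groups by interval overlap", {
  mk <- function(s, e) data.frame(repeat_id = "x", start = s, end = e,
                                  strand = "+", score = 100, evalue = 0,
                                  qstart = 0, qend = e - s)
  ## disjoint hits stay apart
  fps <- merge_footprints(rbind(mk(100, 900), mk(11000, 11900)))
  expect_length(fps, 2)
  ## overlapping hits fuse into the union span
  fps <- merge_footprints(rbind(mk(100, 900), mk(800, 1600)))
  expect_length(fps, 1)
  expect_equal(c(fps[[1]]$start, fps[[1]]$end), c(100, 1600))
  ## a chain of three mutually overlapping hits from different repeats
  h <- rbind(mk(100, 900), mk(700, 1500), mk(1300, 2100))
  h$repeat_id <- c("a", "b", "c")
  fps <- merge_footprints(h)
  expect_length(fps, 1)
  expect_equal(nrow(fps[[1]]$hits), 3)
  ## empty in, empty out
  expect_length(merge_footprints(mk(1, 2)[0, ]), 0)
})

test_that("decomposition resolves an element inserted into another", {
  set.seed(34)
  A <- rand_dna(1000)   # the inserted element
  B <- rand_dna(1100)   # the interrupted host element
  foot <- paste0(substr(B, 1, 500), A, substr(B, 501, 1100))
  g <- paste0(rand_dna(3000), foot, rand_dna(3000))
  r <- annotated_replicon("nest", sequence = g, topology = "linear")
  lib <- repeat_library(repeat_sequences(c("ISa", "ISb"), c(A, B)))
  el <- decompose_footprint(list(start = 3000, end = 3000 + nchar(foot)),
                            lib, r)
  el <- el[!is.na(el$repeat_id), ]
  expect_equal(nrow(el), 3)
  expect_equal(el$repeat_id, c("ISb", "ISa", "ISb"))
  expect_gte(el$fraction_full[2], 0.95)
  expect_equal(el$fraction_full[1], 500 / 1100, tolerance = 0.03)
  expect_equal(el$fraction_full[3], 600 / 1100, tolerance = 0.03)
  ## the assigned spans and leftovers tile the footprint exactly
  full <- decompose_footprint(list(start = 3000, end = 3000 + nchar(foot)),
                              lib, r)
  covered <- sum(full$end - full$start)
  expect_equal(covered, nchar(foot))
})

test_that("a footprint matching one repeat yields a single full element", {
  set.seed(35)
  A <- rand_dna(900)
  g <- paste0(rand_dna(2000), A, rand_dna(2000))
  r <- annotated_replicon("one", sequence = g, topology = "linear")
  lib <- repeat_library(repeat_sequences(c("ISa", "ISz"),
                                         c(A, rand_dna(700))))
  el <- decompose_footprint(list(start = 2000, end = 2900), lib, r)
  el <- el[!is.na(el$repeat_id), ]
  expect_equal(nrow(el), 1)
  expect_equal(el$repeat_id, "ISa")
  expect_gte(el$fraction_full, 0.95)
})

test_that("a tandem pair decomposes into two full-length elements", {
  set.seed(36)
  A <- rand_dna(800)
  g <- paste0(rand_dna(1500), A, A, rand_dna(1500))
  r <- annotated_replicon("tan", sequence = g, topology = "linear")
  lib <- repeat_library(repeat_sequences("ISa", A))
  el <- decompose_footprint(list(start = 1500, end = 1500 + 1600), lib, r)
  el <- el[!is.na(el$repeat_id), ]
  expect_equal(nrow(el), 2)
  expect_true(all(el$fraction_full >= 0.95))
  expect_true(all(el$repeat_id == "ISa"))
})

test_that("greedy decomposition recovers arbitrary planted tilings", {
  ## planted-truth oracle over random 2-3 segment constructions
  for (trial in 1:10) {
    set.seed(400 + trial)
    libseqs <- replicate(3, rand_dna(sample(600:1000, 1)))
    names(libseqs) <- c("ISa", "ISb", "ISc")
    lib <- repeat_library(repeat_sequences(names(libseqs), libseqs))
    k <- sample(2:3, 1)
    picks <- sample(names(libseqs), k, replace = FALSE)
    segs <- lapply(picks, function(nm) libseqs[[nm]])
    foot <- paste(unlist(segs), collapse = "")
    g <- paste0(rand_dna(1000), foot, rand_dna(1000))
    r <- annotated_replicon("tile", sequence = g, topology = "linear")
    el <- decompose_footprint(list(start = 1000, end = 1000 + nchar(foot)),
                              lib, r)
    el <- el[!is.na(el$repeat_id), ]
    expect_equal(el$repeat_id[order(el$start)], picks,
                 info = paste("trial", trial))
    expect_true(all(el$fraction_full >= 0.9))
  }
})

test_that("fraction_of_full and its bands follow the reporting convention", {
  expect_equal(fraction_of_full(800, 800), 1)
  expect_equal(fraction_of_full(100, 800), 0.125)
  expect_equal(fraction_of_full(790, 800), 0.9875)
  expect_error(fraction_of_full(10, 0), "reference_len")
  expect_equal(as.character(fraction_band(c(0.125, 0.3, 0.7, 0.99))),
               c("severe_fragment", "half", "partial", "full_length"))
})

test_that("fragment histograms normalise and flag empty input", {
  els <- repeat_elements(rep("x", 4), c(0, 10, 20, 30), c(5, 15, 25, 35),
                         "+", fraction_full = c(1, 1, 1, 1))
  h <- fragment_histogram(els)
  expect_equal(sum(h$freq), 1, tolerance = 1e-9)
  expect_equal(h$freq[length(h$freq)], 1)

  els2 <- repeat_elements(rep("x", 4), c(0, 10, 20, 30), c(5, 15, 25, 35),
                          "+", fraction_full = c(0.10, 0.10, 0.90, 1.0))
  h2 <- fragment_histogram(els2)
  expect_equal(h2$freq[3], 0.5)  # the [0.10, 0.15) bin
  expect_equal(sum(h2$freq), 1, tolerance = 1e-9)
  ## fractions above 1 fall into the final bin
  els3 <- repeat_elements("x", 0, 10, "+", fraction_full = 1.04)
  h3 <- fragment_histogram(els3)
  expect_equal(h3$freq[length(h3$freq)], 1)

  h0 <- fragment_histogram(repeat_elements())
  expect_true(h0$empty)
  expect_equal(h0$n, 0L)
})

test_that("occupancy accounting unions overlaps and scales per Mbp", {
  els <- repeat_elements(c("ISa", "ISa"), c(0, 500), c(1000, 1500), "+", 1)
  r <- annotated_replicon("occ", length_bp = 1e6, topology = "linear",
                          elements = els)
  s <- occupancy_summary(r)
  expect_equal(s$repeat_bp, 1500)  # overlap counted once
  expect_equal(s$total_repeat_hits, 2)
  expect_equal(s$repeats_per_mbp, 2)

  els2 <- repeat_elements("ISa", 0, 143000, "+", 1)
  r2 <- annotated_replicon("occ2", length_bp = 1e6, topology = "linear",
                           elements = els2)
  expect_equal(occupancy_summary(r2)$percent_occupied, 0.143)

  r3 <- annotated_replicon("occ3", length_bp = 1e6, topology = "linear")
  s3 <- occupancy_summary(r3)
  expect_equal(s3$total_repeat_hits, 0)
  expect_equal(s3$percent_occupied, 0)

  ## invariant to element order; never exceeds 1
  els_r <- els[rev(seq_len(nrow(els))), ]
  r4 <- annotated_replicon("occ4", length_bp = 1e6, topology = "linear",
                           elements = els_r)
  expect_equal(occupancy_summary(r4)$repeat_bp, s$repeat_bp)
  expect_lte(s$percent_occupied, 1)

  ## genome-minus-IS-and-pseudo removes only pseudogene bp outside elements
  feats <- gene_features(c("p1", "p2"), c(2000, 500), c(3000, 1200),
                         is_pseudo = TRUE)
  r5 <- annotated_replicon("occ5", length_bp = 1e6, topology = "linear",
                           features = feats, elements = els)
  s5 <- occupancy_summary(r5)
  expect_equal(s5$genome_minus_is_bp, 1e6 - 1500)
  ## pseudo bp: [2000,3000) entirely outside; [500,1200) inside elements
  expect_equal(s5$genome_minus_is_and_pseudo_bp, 1e6 - 1500 - 1000)
})
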