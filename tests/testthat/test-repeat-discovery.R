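test_that("a planted three-copy family is recovered near its true length", {
  set.seed(21)
  fam <- rand_dna(800)
  bg <- rand_dna(10000)
  g <- bg
  for (pos in c(1001, 4001, 7501)) g <- overwrite_at(g, pos, fam)
  ## planted-truth oracle: the exact segment occurs three times
  expect_equal(length(gregexpr(fam, g, fixed = TRUE)[[1]]), 3)
  r <- annotated_replicon("gen", sequence = g, topology = "linear")
  found <- find_denovo_repeats(r)
  expect_equal(nrow(found), 1)
  expect_lt(abs(found$length_bp - 800) / 800, 0.05)
  expect_equal(found$n_copies, 3L)
})

test_that("families below the length floor are filtered out", {
  set.seed(22)
  fam <- rand_dna(400)
  g <- rand_dna(12000)
  for (pos in c(501, 3001, 5501, 8001, 10501)) g <- overwrite_at(g, pos, fam)
  r <- annotated_replicon("gen", sequence = g, topology = "linear")
  found <- find_denovo_repeats(r, min_repeat_len = 500)
  expect_equal(nrow(found), 0)
  ## but discoverable when the floor is lowered
  found2 <- find_denovo_repeats(r, min_repeat_len = 300)
  expect_equal(nrow(found2), 1)
})

test_that("a repeat-free genome yields an empty result and parameters are checked", {
  set.seed(23)
  r <- annotated_replicon("gen", sequence = rand_dna(5000),
                          topology = "linear")
  expect_equal(nrow(find_denovo_repeats(r)), 0)
  expect_error(find_denovo_repeats(r, min_repeat_len = 10, seed_len = 16),
               "seed_len")
})

test_that("planted families of >= 3 copies are always recovered", {
  ## recall over seeded trials: one family of 600-1000 bp, 3-4 exact
  ## copies, background up to 100 kb
  for (trial in 1:20) {
    set.seed(100 + trial)
    flen <- sample(600:1000, 1)
    fam <- rand_dna(flen)
    glen <- sample(4:10, 1) * 10000
    ncop <- sample(3:4, 1)
    g <- rand_dna(glen)
    gap <- floor(glen / ncop)
    for (k in seq_len(ncop))
      g <- overwrite_at(g, (k - 1) * gap + 501, fam)
    r <- annotated_replicon("gen", sequence = g, topology = "linear")
    found <- find_denovo_repeats(r)
    expect_equal(nrow(found), 1, info = paste("trial", trial))
    expect_lt(abs(found$length_bp[1] - flen) / flen, 0.05)
  }
})

test_that("discovery is deterministic for a fixed genome", {
  set.seed(25)
  fam <- rand_dna(700)
  g <- rand_dna(20000)
  for (pos in c(2001, 9001, 15001)) g <- overwrite_at(g, pos, fam)
  r <- annotated_replicon("gen", sequence = g, topology = "linear")
  expect_identical(find_denovo_repeats(r), find_denovo_repeats(r))
})

test_that("non-mobile annotated repeats are removed by keyword", {
  reps <- repeat_sequences(name = c("r1", "r2", "r3"),
                           sequence = c("ACGT", "CCCC", "GGGG"))
  ann <- data.frame(name = c("r1", "r2"),
                    product = c("16S rRNA", "transposase"))
  expect_warning(
    out <- filter_known_gene_repeats(
      reps, rbind(ann, data.frame(name = "zz", product = "x"))),
    "unknown")
  expect_equal(out$name, c("r2", "r3"))
  expect_match(attr(out, "removed_log"), "r1")
  ## empty annotation table is the identity
  same <- filter_known_gene_repeats(reps, data.frame(name = character(),
                                                     product = character()))
  expect_equal(same$name, reps$name)
})

test_that("library assembly drops redundancies with catalogue precedence", {
  set.seed(26)
  cat_seq <- rand_dna(900)
  catalogue <- repeat_sequences("IS892", cat_seq,
                                source = "reference_catalogue")
  exact <- repeat_sequences("tmp_g_1", cat_seq, genome = "g")
  lib <- assemble_library(exact, catalogue)
  expect_equal(lib$repeats$name, "IS892")
  expect_match(lib$provenance, "redundant")

  ## ~90% identity: below the 95% threshold, both are retained
  diverged <- repeat_sequences("tmp_g_2", mutate_seq(cat_seq, 90),
                               genome = "g")
  lib2 <- assemble_library(diverged, catalogue)
  expect_setequal(lib2$repeats$name, c("IS892", "tmp_g_2"))

  ## identical de novo repeats from two genomes collapse to one
  twins <- rbind(repeat_sequences("tmp_a_1", cat_seq, genome = "a"),
                 repeat_sequences("tmp_b_1", cat_seq, genome = "b"))
  lib3 <- assemble_library(twins, repeat_sequences())
  expect_equal(nrow(lib3$repeats), 1)
  expect_match(lib3$provenance, "merged")

  expect_error(assemble_library(exact, rbind(catalogue, catalogue)),
               "duplicate")
})

test_that("no assembled library violates the dedup invariant", {
  set.seed(27)
  for (trial in 1:5) {
    base <- rand_dna(600)
    pool <- rbind(
      repeat_sequences(sprintf("tmp_g_%d", 1:2),
                       c(base, mutate_seq(base, 10)), genome = "g"),
      repeat_sequences("tmp_g_3", rand_dna(700), genome = "g"))
    lib <- assemble_library(pool, repeat_sequences())
    reps <- lib$repeats
    if (nrow(reps) > 1) {
      for (i in 1:(nrow(reps) - 1)) for (j in (i + 1):nrow(reps)) {
        s <- ishop:::repeat_similarity(reps$sequence[i], reps$sequence[j])
        expect_false(s[["identity"]] >= 0.95 && s[["coverage"]] >= 0.8)
      }
    }
  }
})

test_that("de novo repeats are named by organism and discovery order", {
  reps <- rbind(
    repeat_sequences("IS892", rand_dna(600), source = "reference_catalogue"),
    repeat_sequences(sprintf("tmp_synecho_%d", 1:3),
                     c(rand_dna(600), rand_dna(650), rand_dna(700)),
                     genome = "synecho"))
  lib <- repeat_library(reps)
  named <- name_repeats(lib, c(synecho = "Syn"))
  expect_equal(named$repeats$name,
               c("IS892", "Syn_R_1", "Syn_R_2", "Syn_R_3"))
  expect_error(name_repeats(lib, c(other = "Oth")), "synecho")
  empty <- name_repeats(repeat_library(), c(synecho = "Syn"))
  expect_equal(nrow(empty$repeats), 0)
})

test_that("library FASTA round-trips names, sources and classes", {
  lib <- repeat_library(repeat_sequences(
    c("IS1", "Abc_R_1"), c(rand_dna(60), rand_dna(80)),
    source = c("reference_catalogue", "de_novo"),
    repeat_class = c("isfinder_is", "putative_is")))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_library_fasta(lib, f)
  lib2 <- read_library_fasta(f)
  expect_equal(lib2$repeats$name, lib$repeats$name)
  expect_equal(lib2$repeats$sequence, lib$repeats$sequence)
  expect_equal(lib2$repeats$source, lib$repeats$source)
  expect_equal(lib2$repeats$repeat_class, lib$repeats$repeat_class)
})
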