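test_that("cluster probability reduces to the anchored binomial tail", {
  ## n_total = 1: the single element anchors the window
  expect_equal(cluster_probability(1, 1, 5000, 1e6), 1)
  ## window equal to the replicon: certain
  expect_equal(cluster_probability(3, 3, 1e6, 1e6), 1)
  ## x = 3 of n = 3 in a tenth of the replicon: P(Bin(2, 0.1) >= 2)
  expect_equal(cluster_probability(3, 3, 1e5, 1e6), 0.01)
  expect_error(cluster_probability(1, 0, 10, 100), "n_total")
  expect_error(cluster_probability(4, 3, 10, 100))
  ## zero-width window cannot hold more than the anchor
  expect_equal(cluster_probability(3, 5, 0, 100), 0)
})

test_that("cluster probability equals an explicit binomial summation", {
  ## independent oracle: direct sum of the probability mass, no pbinom
  tail_sum <- function(x, n, p) {
    if (x == 1) return(1)
    k <- (x - 1):(n - 1)
    sum(choose(n - 1, k) * p^k * (1 - p)^(n - 1 - k))
  }
  for (n in 1:6) for (x in 1:n) for (p in c(0.001, 0.01, 0.1, 0.5, 0.9)) {
    expect_equal(cluster_probability(x, n, p * 1e6, 1e6),
                 tail_sum(x, n, p), tolerance = 1e-12,
                 info = sprintf("n=%d x=%d p=%g", n, x, p))
  }
})

test_that("tight clusters are flagged with very small probabilities", {
  ## five full-length copies packed into 1% of the replicon
  r <- replicon_with_elements(c(5e5, 5e5 + 2000, 5e5 + 4000, 5e5 + 6000,
                                5e5 + 8000), length_bp = 1e6)
  ct <- scan_clusters(r, "ISx")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$k_in_run, 5)
  expect_lte(attr(ct, "headline"), 1e-5)
})

test_that("cluster scanning respects the qualifying-length filter", {
  mids <- c(1e5, 1.02e5, 1.04e5, 5e5, 9e5)
  r <- replicon_with_elements(mids, fraction_full = c(1, 1, 0.5, 1, 1))
  ## the 0.5-fraction copy neither anchors nor counts
  ct <- scan_clusters(r, "ISx", min_fraction = 0.70)
  expect_equal(unique(ct$n_qualifying), 4L)
  expect_equal(max(ct$k_in_run), 2L)
  ## fewer than two qualifying elements: empty result
  r2 <- replicon_with_elements(c(1e5, 2e5), fraction_full = c(1, 0.2))
  expect_equal(nrow(scan_clusters(r2, "ISx")), 0)
})

test_that("a flat divergence profile fits slope zero with p one", {
  pairs <- data.frame(separation_bp = c(1e5, 2e5, 3e5, 4e5),
                      p_distance = rep(0.02, 4))
  f <- hopping_regression(pairs, "flat")
  expect_equal(f$slope_per_mbp, 0)
  expect_equal(f$p_value, 1)
})

test_that("a noiseless planted line is recovered exactly", {
  ## p (percentage units) = 0.5 * separation(Mbp) + 1
  sep <- seq(2e5, 3e6, length.out = 12)
  pairs <- data.frame(separation_bp = sep,
                      p_distance = (0.5 * sep / 1e6 + 1) / 100)
  f <- hopping_regression(pairs, "line")
  expect_equal(f$slope_per_mbp, 0.5, tolerance = 1e-9)
  expect_equal(f$intercept, 1, tolerance = 1e-9)
  expect_equal(f$identity_slope_per_mbp, -0.5, tolerance = 1e-9)
  expect_lt(f$p_value, 1e-6)
})

test_that("regression preconditions are enforced", {
  two <- data.frame(separation_bp = c(1, 2), p_distance = c(0, 0.1))
  expect_error(hopping_regression(two), "3 pairs")
  same <- data.frame(separation_bp = rep(5e5, 4),
                     p_distance = c(0.1, 0.2, 0.3, 0.4))
  expect_error(hopping_regression(same), "zero variance")
})

test_that("pooling is consistent with the single-repeat fit", {
  set.seed(51)
  sep <- runif(30, 1e4, 2e6)
  pairs <- data.frame(separation_bp = sep,
                      p_distance = 0.01 + 0.002 * sep / 1e6 +
                        rnorm(30, 0, 1e-4))
  f1 <- hopping_regression(pairs)
  fp <- pooled_hopping_regression(pairs)
  expect_equal(fp$slope_per_mbp, f1$slope_per_mbp)
  expect_equal(fp$p_value, f1$p_value)
  ## two repeats lying on the same planted line pool to the common slope
  line <- function(sep) (0.3 * sep / 1e6 + 2) / 100
  s1 <- seq(1e5, 1e6, length.out = 8); s2 <- seq(2e5, 3e6, length.out = 9)
  fpool <- pooled_hopping_regression(list(
    data.frame(separation_bp = s1, p_distance = line(s1)),
    data.frame(separation_bp = s2, p_distance = line(s2))))
  expect_equal(fpool$slope_per_mbp, 0.3, tolerance = 1e-9)
  expect_equal(fpool$n_pairs, 17)
})

test_that("wilcoxon wrapper matches its contract on the canonical cases", {
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  sep <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(sep$exact)
  expect_equal(sep$p_value, 0.1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  ## power sanity: strongly shifted large samples
  set.seed(52)
  big <- wilcoxon_rank_sum(rnorm(200), rnorm(200) + 1)
  expect_false(big$exact)
  expect_lt(big$p_value, 1e-6)
})

test_that("a hand-countable arrangement gives enrichment ratio two", {
  ## three IS elements with two pseudogenes within 5 kbp each; three
  ## regular genes with one pseudogene each; everything else far apart
  L <- 4e6
  is_start <- c(2e5, 1e6, 1.8e6)
  gene_start <- c(2.6e6, 3.2e6, 3.8e6)
  feats <- rbind(
    gene_features(sprintf("ps%da", 1:3), is_start - 3000, is_start - 2500,
                  is_pseudo = TRUE),
    gene_features(sprintf("ps%db", 1:3), is_start + 3000, is_start + 3500,
                  is_pseudo = TRUE),
    gene_features(sprintf("g%d", 1:3), gene_start, gene_start + 900),
    gene_features(sprintf("ps%dc", 1:3), gene_start + 3000,
                  gene_start + 3500, is_pseudo = TRUE))
  els <- repeat_elements(rep("ISx", 3), is_start, is_start + 1000, "+", 1)
  r <- annotated_replicon("toy", length_bp = L, topology = "linear",
                          features = feats, elements = els)
  pf <- pseudogene_enrichment(r, distances_bp = 5000)
  expect_equal(pf$mean_pseudo_near_is, 2)
  expect_equal(pf$mean_pseudo_near_gene, 1)
  expect_equal(pf$enrichment_ratio, 2)
})

test_that("enrichment handles degenerate inputs by flagging", {
  ## no pseudogenes at all: ratio undefined, not zero-divided
  feats <- gene_features(c("g1", "g2"), c(100, 5000), c(400, 5400))
  els <- repeat_elements("ISx", 2000, 2500, "+", 1)
  r <- annotated_replicon("d1", length_bp = 1e5, topology = "linear",
                          features = feats, elements = els)
  pf <- pseudogene_enrichment(r, distances_bp = 5000)
  expect_false(pf$defined)
  expect_true(is.na(pf$enrichment_ratio))
  ## no IS elements: profile not computable
  r2 <- annotated_replicon("d2", length_bp = 1e5, topology = "linear",
                           features = feats)
  pf2 <- pseudogene_enrichment(r2, distances_bp = 5000)
  expect_false(attr(pf2, "computable"))
})

test_that("enrichment variants drop IS-like and adjacent pseudogenes", {
  L <- 1e6
  feats <- rbind(
    gene_features("ps_islike", 1e5 + 2000, 1e5 + 2400, is_pseudo = TRUE,
                  is_is_like = TRUE),
    gene_features("ps_native", 1e5 + 4000, 1e5 + 4400, is_pseudo = TRUE),
    gene_features("ps_close", 1e5 + 1100, 1e5 + 1300, is_pseudo = TRUE),
    gene_features("g1", 6e5, 6e5 + 900))
  els <- repeat_elements("ISx", 1e5, 1e5 + 1000, "+", 1)
  r <- annotated_replicon("v", length_bp = L, topology = "linear",
                          features = feats, elements = els)
  all_v <- pseudogene_enrichment(r, distances_bp = 5000, variant = "all")
  nat <- pseudogene_enrichment(r, distances_bp = 5000,
                               variant = "native_only")
  om <- pseudogene_enrichment(r, distances_bp = 5000,
                              variant = "omit_within_1kb")
  expect_equal(all_v$mean_pseudo_near_is, 3)
  expect_equal(nat$mean_pseudo_near_is, 2)   # IS-like pseudogene excluded
  expect_equal(om$mean_pseudo_near_is, 2)    # the 100 bp-gap one omitted
})

test_that("the heat-map table applies the omission rules", {
  mk_profile <- function(ps, n_pseudo) {
    pf <- data.frame(distance_bp = c(5000, 1e4, 5e4),
                     mean_pseudo_near_is = 1, mean_pseudo_near_gene = 1,
                     enrichment_ratio = 1.5, wilcoxon_p = ps,
                     defined = TRUE)
    class(pf) <- c("EnrichmentProfile", class(pf))
    attr(pf, "computable") <- TRUE
    attr(pf, "n_pseudogenes") <- n_pseudo
    pf
  }
  tabs <- enrichment_heatmap_table(list(
    all_sig = mk_profile(c(0.01, 0.01, 0.01), 10),
    one_sig = mk_profile(c(0.01, 0.5, 0.5), 10),
    no_pseudo = mk_profile(c(0.01, 0.01, 0.01), 0)))
  expect_setequal(unique(tabs$genome), "all_sig")
  expect_equal(nrow(tabs), 3)
})
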