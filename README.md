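# ishop — insertion-sequence annotation and local-hopping statistics

`ishop` annotates insertion-sequence (IS) content in bacterial genomes and
tests two spatial signatures of IS-driven genome erosion. It is written
for microbial genomicists studying mobile-element accumulation —
particularly in host-restricted symbionts, where IS elements and
pseudogenes pile up as the genome decays — and for anyone who needs a
reproducible, fully scriptable version of the classic IS survey workflow:
repeat library → genome scan → footprint decomposition → classification →
spatial statistics.

## What it computes

**Annotation.** A repeat library is built from de novo discovery (a
seed-and-extend consensus finder for repeats ≥ 500 bp) merged with a
reference IS catalogue; redundancies at ≥ 95% identity over ≥ 80% of the
shorter sequence collapse onto the catalogue name. Each library repeat is
searched against each genome by a seeded Smith–Waterman with
Karlin–Altschul significance, `E = K·m·n·e^{−λS}`, collecting hits at
`E < 10⁻⁶`. Overlapping hits form *footprints*, which are decomposed
greedily: the best-scoring repeat's aligned span becomes one IS element,
and the remaining segments are re-queried until nothing clears the score
floor. Elements carry a `fraction_full` (span / reference length;
full-length means ≥ 0.95). Repeats are classified from a protein-evidence
table into ISfinder IS / putative IS / phage / putative MGE / highly
repeated / DNA-interacting / unclassified.

**Statistics.** Three tests of spatial organisation:

* *Cluster probability* — for `n` copies of one IS, the chance that at
  least `x` fall in a window `w` of a replicon of length `L` by chance:
  `P(Binomial(n−1, w/L) ≥ x−1)` (one copy anchors the window).
* *Local hopping* — pairwise uncorrected p-distance between near-full
  copies regressed on genomic separation: `p [%] = β·d [Mbp] + α` by OLS,
  with a two-sided test on β. β > 0 (divergence growing with distance) is
  the local-hopping signature.
* *Pseudogene proximity* — mean pseudogene count within 5–500 kbp of IS
  elements over the same near regular genes, with a two-sided Wilcoxon
  rank-sum test per distance.

**Simulation.** `simulate_replicon()` generates replicons with known
transposition histories — copy/cut-and-paste events, an exponential
local-hop kernel, per-event substitutions, insertional pseudogenization,
truncation — and a replayable event log (`replay_truth_log()` reproduces
the final genome byte-for-byte). `truth_compare()` scores called elements
against the planted truth.

## Worked example

Simulate a half-megabase replicon with three IS species and 40
transposition events, scan it against its own species library, and run
the statistics:

```r
library(ishop)

cfg <- simulation_config(seed = 42, replicon_bp = 5e5, n_genes = 200,
                         n_is_species = 3, n_transpositions = 40,
                         sub_rate = 0.01, p_truncate = 0.2,
                         background_pseudo_rate = 0.05)
sim <- simulate_replicon(cfg)
scanned <- scan_replicon(sim$replicon, sim$library)
occupancy_summary(scanned)
#> OccupancySummary: 26 repeat hits (26 IS), 24345 bp occupied (4.6%), 49.6 repeats/Mbp

truth_compare(scanned$elements, sim$truth)[c("recall", "precision")]
#> recall 1.00, precision 1.00  (mean boundary error 0.02 bp)

hopping_regression(element_pairs(scanned, "ISsim1"), "ISsim1")
#> HoppingFit ISsim1: n = 45 pairs, slope = +3.079 %-units/Mbp (p = 0.17)

pseudogene_enrichment(scanned, distances_bp = c(5000, 50000))
#>   distance_bp mean_pseudo_near_is mean_pseudo_near_gene enrichment_ratio wilcoxon_p
#> 1        5000               0.423                 0.263            1.606      0.077
#> 2       50000               2.808                 2.704            1.038      0.616
```

Reading the output: the scanner recovered all 26 planted elements with
sub-basepair boundary accuracy and no false calls; 4.6% of this small
genome is IS-derived. The hopping slope is positive (+3.1 percentage
units of p-distance per Mbp of separation) but not significant at only 45
pairs — single-repeat fits need more copies, which is why the pooled fit
and the replicated recovery studies exist. Pseudogenes are ~1.6× enriched
within 5 kbp of IS elements (the default history pseudogenizes 30% of
interrupted genes), an enrichment that fades by 50 kbp, as expected when
the excess is insertional scarring rather than large-scale clustering.

`run_pipeline(pipeline_config(...))` chains everything — annotated
GenBank per replicon, library FASTA, and TSV tables for occupancy,
clusters, divergence pairs, regression fits and enrichment — and is also
exposed as a command line, `inst/scripts/ishop.R <simulate|run>`.

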