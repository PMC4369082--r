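---
title: "Annotating insertion sequences and testing their spatial organisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating insertion sequences and testing their spatial organisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ishop)
```

## The problem

Insertion sequences (ISs) are short (~0.8–1.3 kb) prokaryotic mobile
elements encoding a transposase that excises and reinserts them. In
host-restricted symbionts they accumulate, interrupt genes, and are thought
to drive reductive genome evolution: a genome rich in IS elements and
pseudogenes is a snapshot of ongoing erosion. Two spatial signatures make
that story testable from a single annotated genome:

* **local hopping** — if an IS tends to transpose short distances, nearby
  copies are separated by fewer transposition events and should be more
  similar in sequence, so pairwise divergence should *increase* with
  genomic separation;
* **pseudogene proximity** — if pseudogenes are scars of past insertions by
  elements that have since hopped away, pseudogenes should be enriched in
  the neighbourhood of present-day IS elements.

`ishop` provides the full chain needed to measure both: repeat-library
construction, footprint scanning and decomposition into attributed IS
elements, repeat classification, the spatial statistics, and a forward
simulator of transposition histories that supplies planted truth for every
step.

## Annotation pipeline

**Library construction.** De novo repeat families are found by a
seed-and-extend consensus finder (`find_denovo_repeats()`): exact seed
words (default 16 bp) occurring at least `min_copies = 2` times are
extended column by column while at least `1 - max_divergence` (default
90%) of the copies agree with the column majority; the consensus is the
column majority and families shorter than `min_repeat_len = 500` bp — the
conventional floor for IS-sized repeats — are discarded. Families whose
columns are mostly inside an already-reported family are subsumed and
dropped; this also suppresses one-off re-discoveries of a family shifted
by a chance flanking match. De novo families are merged with a reference
IS catalogue by `assemble_library()`: a de novo repeat aligning to a
catalogue entry at ≥ 95% identity over ≥ 80% of the shorter sequence is
redundant and the catalogue entry (and name) survives. The 95% figure is
the conventional boundary between a known and a previously unannotated
IS; the 80% coverage requirement is this package's choice, preventing two
repeats that merely share a domain from collapsing. De novo survivors are
named `<Abbrev>_R_<k>` in discovery order per genome.

**Footprint scanning.** `search_hits()` is a seeded Smith–Waterman
search: exact 12-mers of the repeat are located on both strands
(`Biostrings::matchPDict`), clustered by alignment diagonal into candidate
windows, and each window is aligned (`Biostrings::pairwiseAlignment`,
match +1, mismatch −2, gap open −5, gap extend −2). Significance uses the
Karlin–Altschul form `E = K·m·n·exp(−λS)` with λ solved from the scoring
scheme under uniform base composition and `K = 0.1`; hits with
`E < 1e-6` are collected. Two implementation notes: a window is re-queried
on the flanks of each accepted alignment so tandem copies in one window
are all found; and seed clusters containing a single word are skipped,
because any alignment reaching the collection score floor (≈ 26 with
these parameters) must contain at least two overlapping exact 12-mers —
this prunes the large number of chance background seed matches without
changing the result.

**Footprints and decomposition.** Overlapping hits from any repeats are
merged into *footprints* (`merge_footprints()`). Each footprint is then
explained by greedy iteration (`decompose_footprint()`): every candidate
repeat is aligned to the unassigned footprint sequence, the
highest-scoring repeat's aligned span becomes one element, and the
remaining segments are re-queried until nothing reaches `min_score = 30`.
Segments shorter than `min_leftover = 50` bp are not re-queried, and all
unattributed base pairs are reported as unassigned rows, so the assigned
elements plus leftovers tile the footprint exactly. Ties are broken by
longer aligned span, then lexicographic repeat name, which makes the
decomposition deterministic. An element's `fraction_full` is its genomic
span over the reference length (alignment columns are not used; the two
differ only through indels, and span length is the observable that
fragment-size distributions are built from); `≥ 0.95` counts as
full-length, `< 0.50` as half, `< 0.15` as a severe fragment.

**Classification.** Protein-level identification is consumed as a
precomputed evidence table (repeat, hit description, E-value, category
hint) rather than produced by a live database search. `classify_repeat()`
applies a fixed precedence: catalogue membership → transposase evidence at
`E < 1e-5` → phage evidence → replication-related (→ `putative_mge`) or
DNA-interacting evidence → high copy number (≥ 6 copies in one genome,
reading "more than five" strictly) → unclassified. The original
classification of ambiguous repeats involved case-by-case judgement; the
precedence order is this package's explicit, reproducible stand-in, and
conflicting evidence rows simply resolve to the highest precedence.

## The three spatial statistics

**Binomial cluster probability.** For a repeat with `n` qualifying copies
(span > 70% of full length) on a replicon, the chance that at least `x`
of them co-locate in a window of `w` bp is modelled by anchoring one
element (an element is certain to be somewhere) and treating the other
`n − 1` as Bernoulli trials with success probability `w / L`:
`cluster_probability(x, n, w, L) = P(Binomial(n−1, w/L) ≥ x−1)`.

`scan_clusters()` must also *choose* the windows, and this is where a
subtlety lives. Sorting the qualifying copies by midpoint, runs are split
where the gap between consecutive copies exceeds the mean spacing
`L / n`, and each run of `k ≥ 2` yields one test whose window is the
run's midpoint span. Because that window is delimited by an observed
element, using `x = k` would be anti-conservative: the span of `n`
uniform points is Beta-distributed, and the naive plug-in rejects a true
uniform null far above its nominal level (analytically ~15–25% at
α = 0.05). The window-defining element is therefore discounted along with
the anchor — the reported probability is
`cluster_probability(k − 1, n, w, L)`, the chance that the `k − 2`
*interior* elements co-locate by chance. The calibration study (500
uniform placements of five elements) measures the resulting rejection
rate below its nominal 5%; a five-element cluster packed into 1% of the
replicon still scores ~4 × 10⁻⁶. Runs are detected on linearised coordinates; a cluster
spanning a circular replicon's origin is split in two, which can only
make the reported probability conservative.

**Divergence vs separation.** For each repeat, copies with span > 90% of
full length are compared pairwise: the uncorrected p-distance is the
proportion of differing aligned columns (mismatches plus gapped columns
over aligned columns) of a global alignment (match +1, mismatch −1, gap
−2), and separation is midpoint-to-midpoint, min-arc on circular
replicons (the anchor convention is unstated in the field; midpoints make
the distance a metric and are insensitive to truncation side).
`hopping_regression()` fits `p_distance [%] ~ separation [Mbp]` by
ordinary least squares and reports the two-sided slope test. A positive
slope — divergence growing with distance — is the local-hopping
signature. Because percent identity and p-distance are complementary, the
same trend can be quoted with either sign; fits carry both
`slope_per_mbp` and `identity_slope_per_mbp = -slope_per_mbp` so no sign
convention is forced on the reader. `pooled_hopping_regression()` applies
the identical contract to pairs pooled over repeats; pairs never cross
replicons.

**Pseudogene proximity.** For each focal IS element and each focal
regular gene (non-pseudogene, non-IS-like — the ratio's denominator is
pseudogenes near *regular* genes), `pseudogene_enrichment()` counts
pseudogenes whose closest-edge gap is at most `d`, for `d` in 5, 10, 50,
100, 200, 500 kbp, pooled across replicons. The enrichment ratio is the
mean count near IS elements over the mean count near genes; the two count
vectors are compared by a two-sided Wilcoxon rank-sum test (exact when
the pooled sample is ≤ 12 without ties, else normal approximation with
continuity and tie correction; the two-sided p at the exact centre of the
null distribution is 1 by definition). Variant `native_only` excludes
IS-like pseudogenes from the counted set; `omit_within_1kb` drops
pseudogenes closer than 1 kb to the focal feature, which may be
unrecognised fragments of the IS element itself. No multiple-testing
correction is applied across distances or genomes by default, matching
the convention of reporting per-distance significance flags;
`enrichment_heatmap_table()` omits genomes with fewer than two
significant distances or no annotated pseudogenes.

## The forward simulator

`simulate_replicon()` generates the ground truth every statistic is
validated against. A replicon is a uniform-random A/C/G/T background with
evenly spaced genes; IS species are random sequences seeded at random
positions. Each transposition event picks a random extant copy, draws a
destination — with probability `p_local` the source midpoint plus a
signed exponential displacement of mean `local_scale_bp`, otherwise
uniform — and moves (cut-and-paste) or duplicates (copy-and-paste) the
copy, with a random strand flip. The moved/created copy receives
`Binomial(length, sub_rate)` substitutions: mutation is per *event*, not
per unit time, which directly instantiates the idea that copies separated
by more transposition events have diverged more. An insertion landing
strictly inside a gene pseudogenizes it with probability
`p_pseudogenize`. After the history, each copy is truncated with
probability `p_truncate` by a uniform fraction clipped from one end.
Destinations falling inside an existing element are re-drawn (≤ 100
attempts, then the event is skipped and logged).

The defaults describe a moderately IS-rich bacterial replicon: 1 Mb
circular, 400 genes of 900 bp, 3 species of 1 kb at 2 copies each, 60
events, `p_copy_paste = 0.6`, `p_local = 0.75` with a 50 kb kernel,
`sub_rate = 0.005`/bp/event, `p_pseudogenize = 0.3`, `p_truncate = 0.15`,
5% background pseudogenes. The kernel scale and per-event mutation count
are calibration choices — the phenomenon they emulate is qualitative in
the literature — and both are config knobs that the recovery studies
sweep.

Every event is logged, and `replay_truth_log()` re-applies the log to the
stored initial genome; the replayed sequence is byte-identical to the
simulated one. The same event-application code runs the simulation
itself, so the log is correct by construction, and the replay test guards
the bookkeeping (coordinate shifts of every feature and element under
insertion, excision and truncation).

What the simulator deliberately does *not* model: GC-content skew,
target-site duplications (2–20 bp, below the boundary accuracy that
matters here), selection, recombination-mediated deletion between repeat
copies, and horizontal transfer. Passing recovery tests therefore shows
the statistics detect the encoded mechanisms under neutral placement —
not that real genomes are free of the confounders these processes
create.

## Calibration and power: how the validation studies were designed

These design points were settled by analysis and pilot simulation before
the studies were frozen; they are reported because two of them uncovered
genuinely instructive geometry.

* **Cluster-scan null.** 500 uniform placements of 5 full-length copies
  on a 1 Mb linear replicon. The discounted-element convention above is
  what makes this test valid; the naive convention cannot be rescued by
  any run definition we examined.
* **Hopping recovery.** 50 histories per regime of 40 copies of one 1 kb
  species on a 5 Mb replicon (single-lineage copy-and-paste, 39 events,
  `sub_rate = 0.005`): exponential 50 kb kernel vs uniform transposition.
  The local regime must yield a positive, significant slope in ≥ 80% of
  replicates; the uniform regime in ≤ 10%.
* **Enrichment recovery.** 50 histories at 150 events per Mb — an IS-rich
  regime comparable to the most heavily colonised symbiont genomes
  (~170 IS hits/Mbp) — with `p_pseudogenize = 0.9`, uniform placement
  (`p_local = 0`) so element positions are exchangeable, and 5%
  background pseudogenes so the insertional signal is identifiable at the
  ratio ≥ 1.3 level. Sparser histories proved underpowered in pilot
  runs: the study would then measure sampling noise, not correctness.
* **Enrichment null.** The obvious null — the same simulator with
  `p_pseudogenize = 0` — is *not* a null: insertions land inside
  background pseudogenes and genes host elements, so IS and pseudogene
  geometry are coupled and the ratio genuinely inflates to ~1.2–1.3. The
  rank-sum test is right to reject it. A second trap: placing genes on a
  regular lattice quantises gene-to-gene distances (third neighbours are
  never within 5 kb) while elements sample all phases, biasing the ratio
  to ~1.2 again. The calibration null is therefore
  `random_placement_replicon()`: genes *and* elements placed by random
  sequential adsorption (disjoint annotations, as in real feature
  tables), pseudogene labels independent Bernoulli draws at rate 0.2.
  The 20% rate — an eroded-genome regime — keeps per-window counts high
  enough for a stable ratio; at sparse pseudogene counts the rank-sum
  normal approximation is itself noticeably anti-conservative. The
  acceptance study measures this null's rejection rate and mean ratio
  directly.
* **End-to-end recovery.** One 5 Mb genome, 20 species, 120 events,
  `sub_rate = 0.02`, truncation on: recall and precision ≥ 95% against
  planted elements of ≥ 50% length, with recall restricted to that subset
  and precision measured against the full planted set (recovering a
  shorter planted fragment is not a false positive), and byte-identical
  pipeline reruns under a fixed seed.

Problem sizes throughout (replicon lengths, copy numbers, replicate
counts) are the package's validation design; they keep each study's
statistical resolution comfortably finer than the thresholds it checks.

## Numerical choices

* **Global alignment.** `p_distance()` uses a banded Needleman–Wunsch
  (Rcpp) whose band doubles until the optimal score is stable, so results
  equal the full-matrix optimum for any input while the common case —
  near-full-length copies of one repeat — costs O(n·w). The score path is
  verified in the test suite against `Biostrings::pairwiseAlignment` as an
  independent oracle.
* **E-values.** λ is solved by `uniroot` from
  `¼e^{λ·match} + ¾e^{λ·mismatch} = 1`; `K = 0.1` is a fixed prefactor.
  The search-space product uses repeat length × replicon length per
  strand. The calibration test requires zero false hits at `E < 1e-6` on
  repeat-free backgrounds across 20 seeded trials.
* **Coordinates.** 0-based half-open everywhere internally; 1-based
  inclusive only in GenBank files. A feature joined across a circular
  origin is stored unwrapped (end beyond the replicon length) so its
  length is preserved and `start < end` holds.
* **Ambiguity.** Non-ACGTN characters are normalised to `N` on read; `N`
  scores as a mismatch against everything, including itself.
* **Determinism.** All tie-breaks are explicit (span, then name); the
  simulator and pipeline are reproducible from their seeds; reruns are
  byte-identical.

## Known limitations

Cluster windows on circular replicons do not wrap the origin (clusters
spanning it are split; conservative). De novo discovery is driven by
forward-strand copies; a family present only as reverse-complement pairs
is found at the scanning stage once any orientation is in the library,
but not discovered de novo. The decomposition is greedy — exhaustive
best-attribution is exponential — with the planted-tiling tests showing
greedy and truth agree on footprints of up to three nested or tandem
segments. The enrichment statistics treat pooled counts as exchangeable
across focal features; under strong spatial clustering of IS elements the
rank-sum p-values are anti-conservative, which is why the calibration
null uses exchangeable placement and why per-genome significance flags
should be read as descriptive, not confirmatory, in heavily clustered
genomes.
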