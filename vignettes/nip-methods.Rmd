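---
title: "Comparing metabolic organization with networks of interacting pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing metabolic organization with networks of interacting pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nipevo)
```

## The model

A *network of interacting pathways* (NIP) represents one taxon's metabolism
at the level of functional modules rather than individual reactions. Given
the taxon's pathway annotations — each pathway a set of metabolites — the
NIP is the undirected graph whose vertices are the pathways, with an edge
between two pathways whenever they share at least one metabolite, weighted
by the number of shared metabolites. The weight is read as the intensity of
potential metabolic cross-talk between the two modules: pathways exchanging
many compounds are functionally closer than pathways touching through a
single intermediate. Pathways sharing no metabolite with any other pathway
remain as isolated vertices, because the vertex count itself — the breadth
of the taxon's metabolic repertoire — is one of the quantities compared
across taxa.

Directionality (whether a metabolite is consumed or produced on either
side) is deliberately collapsed: the NIP is a symmetric co-occurrence
structure, and the descriptor suite below is defined on undirected graphs.

### Annotation hygiene

Two preprocessing steps precede network construction.

*Currency exclusion.* Ubiquitous currency metabolites (ATP, NAD, and the
like) are retained — they carry real cross-talk signal at the pathway level
— with the single exception of water, which is chemically uninformative.
`read_annotations()` therefore takes an exclusion list defaulting to the
water identifier; pathways emptied by the exclusion are dropped.

*Consistency filtering.* Pathway counts scale with the logarithm of genome
size (ORF count) across taxa. A taxon far below that trend is most likely
under-annotated rather than genuinely metabolically poor, and would
contaminate group comparisons with annotation artifacts.
`filter_consistent_taxa()` fits `n_pathways ~ log(orf_count)` by ordinary
least squares and removes the taxa in the lowest tail of the residuals
(default: the lowest 5%, i.e. `floor(0.05 * n)` taxa, ties broken by taxon
id so the cut is deterministic). The natural logarithm is used; the base
only rescales the slope and leaves residual ranks and r² unchanged.

*Strain merging.* When several strains of one species are annotated
separately, `merge_strains()` unions their pathway sets and the metabolite
sets of shared pathways, and takes the maximum ORF count: a merged taxon is
credited with the metabolic capability of each of its strains. The
alternative — keeping the best-annotated representative strain — discards
strain-specific pathways and was rejected for that reason. Group labels
must agree within a merge group; conflicts are errors, not silent choices.

## The 52 descriptors

Each NIP is summarized by 52 numbers (`descriptor_registry()`): 25 basic
descriptors in four families and 27 information-theoretic derivatives.

The basic families:

* **Degree/adjacency (9)** — vertex/edge counts, total adjacency, mean
  degree, degree range, connectedness (density `2E/(V(V-1))`), and the
  weighted analogues total weight, mean strength, strength range.
* **Distance (6)** — radius, diameter, total and mean shortest-path
  distance, the range of per-vertex distance sums, and the mean *weighted*
  distance, where an edge of weight `w` has length `1/w`. The reciprocal
  convention encodes the modelling choice above: heavy cross-talk shortens
  effective metabolic distance.
* **Centrality (6)** — mean degree centrality, mean harmonic closeness,
  and mean vertex/edge betweenness in unweighted and weighted variants.
* **Cliques/clustering (4)** — mean (Barrat-weighted and unweighted)
  clustering coefficients, the number of maximal cliques, and the largest
  clique size. Cliques — fully inter-connected pathway subsets — capture
  local blocks of tight metabolic integration.

The derivatives are Shannon-type indices on equivalence distributions: an
integer-valued graph quantity partitions its carriers into classes of equal
value with sizes `n_1..n_k`, `N = sum n_i`, and

* average information `AI = -sum (n_i/N) log2(n_i/N)`,
* total information `TI = N log2 N - sum n_i log2 n_i`,
* normalized information `NI = AI / log2 N` (0 when `N = 1`).

Nine distributions are profiled — vertex degrees, vertex strengths, edge
weights, vertex distance sums, vertex eccentricities, finite pairwise
distances, maximal-clique sizes, per-vertex clique membership counts, and
per-vertex triangle counts — giving 27 derived descriptors. Only
integer-valued quantities are used: exact-value classes need no binning, so
the indices carry no arbitrary bandwidth parameter. Two NIPs with the same
mean degree but different degree heterogeneity separate on `AI`/`TI`
(higher = more diverse organization), which is precisely the kind of
"complexity" contrast the suite is meant to expose.

### Numerical conventions

* **Disconnected graphs.** Distances average over reachable pairs only;
  eccentricities are within-component; closeness is harmonic
  (`C(v) = mean of 1/d(v,u)`, with `1/Inf = 0`), which is well defined
  without any connectivity assumption. A pathway absent from a component
  contributes no phantom infinite distance.
* **Betweenness normalization.** Vertex betweenness is divided by
  `(n-1)(n-2)/2`, the number of unordered pairs excluding the vertex (so a
  star center scores exactly 1). Edge betweenness is divided by `n(n-1)/2`:
  every vertex pair, including an edge's own endpoints, can route through
  an edge.
* **Degenerate inputs.** An empty graph yields an all-`NaN` vector with a
  warning; quantities undefined on a particular graph (edge-weight
  information of an edgeless graph, average distance with no reachable
  pair) are `NaN` rather than a fabricated 0. Degree-<2 vertices have
  clustering 0.
* **Determinism.** Vertex order is lexicographic in all serializations;
  clique output is sorted; repeated runs are byte-identical.

The entire suite is verified against an independently written naive
implementation (Floyd–Warshall distances, dynamic-programming path counts,
exhaustive path enumeration, `2^n` subset clique enumeration) to `1e-9` on
random weighted graphs. Those test graphs draw weights from `{1, 2, 4, 8}`
so reciprocal edge lengths are exact dyadic doubles: ties between
equal-length weighted shortest paths are then detected identically by both
implementations instead of depending on `1/3 + 1/3`-style floating resolution.
Real NIP weights are arbitrary positive integers; the restriction applies
only to the oracle comparison.

## Group discrimination

`training_table()` joins the descriptor table with one labeled contrast;
`evaluate_models()` runs stratified k-fold cross-validation (default 10)
over a roster of standard classifiers — logistic/multinomial regression, a
single-hidden-layer perceptron, a recursive-partitioning tree, a
best-single-threshold OneR baseline, 1-nearest-neighbour, random forest,
and an RBF SVM — reporting pooled cross-validated accuracy and Cohen's
kappa together with resubstitution scores, ranked by CV accuracy. Kappa is
the headline number: with unbalanced groups (e.g. 525 vs 61 taxa) raw
accuracy flatters the majority-class guesser, while kappa corrects for
chance agreement.

Feature standardization is fit on the training folds only and applied to
the held-out fold, so no scaling information leaks across the split. Fold
assignment is deterministic given the seed, and the same fold assignment is
reused across all models and all feature subsets, making comparisons
paired.

`select_features()` answers "how few descriptors suffice?" by greedy
forward selection on CV kappa, stopping once the subset is within a
tolerance (default 0.01 kappa) of the full 52-descriptor performance or
when no candidate improves it. Ties are broken by registry order, so the
selection is reproducible. When the full-set kappa is itself near chance
the subset is meaningless; the result is then flagged `degenerate` rather
than suppressed.

## Pathway-level shifts

Beyond whole-network summaries, `compare_pathways()` asks which pathways
drive a group difference, using six per-pathway scores: frequency (the
fraction of a group's taxa possessing the pathway), degree and strength
(connectivity), and harmonic closeness plus unweighted/weighted betweenness
(centrality). Frequency shifts are tested with Fisher's exact test on
presence/absence counts; the other scores with two-sided Mann–Whitney U
tests on per-taxon values restricted to taxa that possess the pathway — a
pathway's centrality *given that it is present* is a different question
from whether it is present, and the latter is already the frequency test.
Pathways possessed by fewer than two taxa in either group skip the rank
tests (a one-point sample has no rank information); this is logged.

The amplitude of a shift is the difference of group medians (for frequency,
the difference of frequencies): medians are robust to the occasional
outlier taxon and consistent with the median-based category aggregation.
All (pathway × score) p-values of one contrast form a single
Benjamini–Hochberg family. Category summaries then report, per functional
category and score, the median amplitude, median FDR, and a direction
(increase/decrease/none by the sign of the median amplitude).

Descriptor-level group tests (`compare_descriptors()`) use Mann–Whitney
for two groups or Kruskal–Wallis for three or more, Bonferroni-corrected
over the 52 descriptors — a deliberately stricter correction, since these
52 tests are the study's primary claims, while the pathway screen is
exploratory and FDR control suffices there.

## The synthetic benchmark

Real pathway databases cannot ship with a package, and a fixed snapshot
would in any case leave planted ground truth unknown. The generator
(`generate_universe()`, `generate_taxa()`) therefore emulates the
*structure* of curated pathway annotations:

* ~150 pathways over a pool of ~2000 metabolites;
* overlap driven by two hub tiers — a handful of global currency-like
  metabolites (each joining any pathway with probability 0.18) and
  per-category hub metabolites (probability 0.5 within their category),
  plus ~10 private metabolites per pathway. A full-retention NIP then sits
  in the regime of real pathway networks: density ≈ 0.3, mean inter-pathway
  distance ≈ 1.7, diameter 3–4, mean clustering ≈ 0.6, right-skewed degrees
  — and a maximal-clique count in the low thousands rather than the
  combinatorial explosion a uniformly random graph of equal density
  produces;
* taxa as independent pathway retentions, with per-group baseline retention,
  optional per-category bias, and an `effect_size` dial that interpolates
  every group difference toward the pooled average (`effect_size = 0` gives
  exchangeable groups for null calibration);
* ORF counts generated from the inverse of the pathways-vs-log(ORF)
  relation with lognormal noise, so the consistency filter's regression
  holds by construction, and `make_inconsistent()` can plant known
  under-annotated taxa for filter-recovery tests.

The default planted scenario (`default_scenario()`) contrasts 50
annotation-rich taxa (retention 0.90) with 50 reduced taxa (retention 0.50,
lipid and glycan pathways additionally halved) — a genome-reduction-like
contrast. What the generator does *not* emulate: phylogenetic correlation
between taxa (taxa are independent draws), reaction stoichiometry, enzyme
assignments, or annotation noise that is correlated across pathways.
Passing the planted-recovery tests therefore shows the pipeline detects
effects of the planted kind at realistic network scales; it does not certify
performance on real, phylogenetically structured data.

## Problem sizes and seeds

All randomness flows through explicit integer seeds; identical seeds and
inputs give byte-identical output files (full-precision TSV serialization,
deterministic fold assignment, deterministic tie-breaks). The test-suite
problem sizes — 50 random oracle graphs up to 30 vertices, exhaustive
betweenness enumeration up to 8 vertices, `2^n` clique enumeration up to 10
vertices, 500-replicate null calibration of the corrected tests, the
100-taxon planted and null scenarios, and a 20-seed filter-recovery panel —
were chosen as the smallest scales at which each property is genuinely
informative: oracle equivalence is scale-free once weighted-tie handling is
exercised, and the planted scenario's power is already near 1 at 50 taxa
per group.

## Known limitations

* The descriptor registry is this package's normative definition of the
  52-descriptor suite; other descriptor collections in the comparative
  metabolism literature (e.g. closeness-centralization indices defined on
  reaction-level networks) are intentionally out of scope.
* Maximal-clique enumeration is output-sensitive; adversarial dense graphs
  can still be exponential. The generator avoids that regime by
  construction, but user-supplied NIPs with tens of thousands of cliques
  will dominate runtime.
* With ~50 taxa per group, best-of-roster model selection inflates the
  null distribution of the reported CV kappa (winner's curse); the null
  scenario keeps it within ±0.15, but users comparing very small groups
  should interpret a modest kappa from many models cautiously; contrasts
  as lopsided as 4 vs 15 taxa are below the range where the kappa estimate
  is stable.
* Mann–Whitney p-values switch from the exact distribution to a
  tie-corrected normal approximation when samples are large or tied;
  exactness is only guaranteed in the small-sample no-tie regime the tests
  cover.
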