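---
title: "MorbiMap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MorbiMap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MorbiMap)
```

MorbiMap characterizes shared and disease-specific multimorbidity
architecture from a typed biomedical knowledge graph. This vignette is the
package's own account of the statistical machinery: what each stage
computes, which knobs matter, what the synthetic generator does and does
not emulate, and where genuinely open design choices were resolved.

## 1. HeteSim relevance on typed metapaths

The graph model is a directed heterogeneous graph: nodes carry a semantic
type (`DSYN`, `PHSU`, `AAPP`, `TARGET`, ...), edges carry a predicate. A
*metapath* is a typed path schema; relevance between a source concept and
a target disease along a metapath is HeteSim: the cosine similarity of the
source's forward reachability probability distribution and the target's
backward reachability distribution at the path midpoint.

Numerical conventions, all deliberate:

* **Transition probabilities** are uniform over a node's out-edges
  (in-edges for the backward walk) within each typed relation step — the
  standard row-normalized-adjacency construction, requiring no edge
  weights.
* **Odd edge-length paths** split the middle edge: each edge instance of
  the middle relation acts as an artificial midpoint node, preserving the
  symmetric meeting-in-the-middle semantics. The implementation computes
  midpoint distributions by sparse products of per-step transition
  matrices; the test suite verifies it against an independent brute-force
  path-instance enumeration oracle to 1e-9 on a corpus of small random
  typed graphs, and verifies exact symmetry under simultaneous edge and
  path reversal.
* **Dangling nodes** (zero out-degree on the path) contribute a zero
  distribution and score 0; they are not an error, because sparse
  synthetic graphs produce them routinely.
* **Path-length convention.** "Metapath length 3" is read as at most 3
  edges, equivalently at most 2 intermediate nodes; both readings coincide
  and `max_length` is configurable because counting conventions differ
  across the literature.
* **Aggregation** across metapaths is the unweighted arithmetic mean.
  Weighting by instance count is a conceivable alternative; equal
  weighting is the default because nothing in the source framework's
  description indicates otherwise, and the choice is isolated in
  `aggregateScores()`.

## 2. Score normalization

Raw mean-aggregated scores are standardized (`(x - mean)/sd`, sample sd)
and converted to percentiles by mid-rank/n, ties sharing their average
rank. Mid-rank/n is deterministic, monotone in the raw score, and maps an
untied top score to exactly 1.0. Two degenerate-input rules keep the
pipeline total: constant score vectors standardize to all zeros (not NaN),
and a constant vector's percentiles are the full-tie mid-rank value.

Downstream stages default to the **percentile** channel, since the
harmonic-mean threshold presumes unit-interval scores; the standardized
channel is exposed for diagnostics but rejected where unit-interval bounds
are required. This default is a package choice — either normalization is
defensible — and is switchable via `scores$channel`.

## 3. The 13-category ontology

DSYN nodes map to a closed, canonically ordered 13-category mechanistic
ontology (`dsynCategories()`): Metabolic; Immune/Inflammatory/Infectious;
Cardiovascular; Other/Neuro-Psych; Sensory (EET); Gastrointestinal;
Endocrine; Hematological; Dermatological; Liver; Kidney;
Musculoskeletal/Orthopedic; Environmental Toxins. Provisional
"Neurological" and "Psychiatric" assignments are merged into
Other/Neuro-Psych (`mergeNeuroPsych()`, idempotent), because such labels
are dominated by disease-defining and disease-adjacent features rather
than independent comorbidity. The mapping itself is an *input artifact*
(curated upstream); the package validates it — closed alphabet, one
category per node, alias resolution, conflicting duplicates rejected with
every conflict named — but never infers it. Unmapped nodes are dropped
with a count by default (the analyses concern mapped high-importance
nodes); `error` and `bucket` policies are available.

The pharmacologic channel reuses the same machinery with an open class
alphabet (`phsuClasses()`: anti-inflammatory, antioxidant,
neuromodulatory, cardiometabolic, antimicrobial, toxin-related, other),
open because mechanistic drug classes are not a closed vocabulary.

## 4. Intersections, baseline, enrichment

A node in both disease tables joins the pair's intersection when the
harmonic mean of its two normalized scores meets the threshold, default
0.5 **inclusive**. Membership is monotone non-increasing in the threshold.
Composition is reported as counts, percentages normalized to 100%, and
enrichment Z-scores against a global baseline: the category distribution
of the pooled high-importance nodes of all three diseases.

Three choices here were genuinely open and are resolved as follows:

* **"High-importance"** is the top fraction `q = 0.10` of each disease's
  percentile-ranked table (deterministic head after ordering by raw score
  with id tie-break). No principled cutoff presents itself; 10% is a
  conventional screening fraction and `q` is configurable.
* **Baseline pooling** counts each node once (`union`) even when shared,
  avoiding double-weighting of exactly the nodes intersections are made
  of; `concat` (once per disease) is provided as a switch.
* **The enrichment formula** is the one-sample proportion Z under a
  binomial null. "Z-score enrichment" admits several nulls; the binomial
  form is the standard choice, and a seeded permutation null
  (`zEnrichmentPermutation()`, default 10,000 draws) is provided for
  sensitivity — the suite checks the two agree in sign away from zero.
  Degenerate baseline cells (`p0` of 0 or 1) yield 0 when the observed
  count is consistent and a signed-infinity sentinel with a warning when
  it is not.

## 5. Hierarchies, similarity, landscape, Borda

Per-entity category scores are aggregated by **sum** of normalized scores
(default), which reflects both node count and strength; `mean` and
`count` modes are provided since aggregation mode is a free choice, and
outputs record the mode. Ranks 1..13 are forced to a strict permutation,
ties broken by canonical category order; correlations nonetheless use
tie-aware forms (`stats::cor`, Spearman and Kendall tau-b) for robustness.
Zero-variance inputs flag the correlation `NA` with a warning rather than
erroring.

The landscape is the entity-by-category rank matrix plus the
rank-preserving transform `15 - rank`; each row is a permutation of
{2..14} summing to 104, and no averaging across entities ever occurs —
ordinal data stay ordinal. The Borda summary orders categories by summed
disease ranks with ties broken by lower median rank, then lower minimum
rank. These two rules cannot be total (three-way ties with identical
median and minimum exist), so a final canonical-order fallback exists,
is flagged in the tie trace, and warns — determinism is required, silent
arbitrariness is not. The shipped reference rank matrix
(`referenceDiseaseRanks()`) exercises the median rule on its
Gastrointestinal/Endocrine tie and is reproduced exactly by
`bordaAggregate()`.

## 6. The synthetic generator

`generateDiseaseTables()` emulates the statistical structure the analysis
assumes, not the biology of any real graph:

* **Sharing rule.** Each of a disease's `n` node slots is, with
  probability `overlap_fraction`, drawn without replacement from a common
  core pool of `n` ids; otherwise a disease-specific node is minted.
  Expected pairwise Jaccard overlap is approximately
  `p^2 / (2 - p^2)` — a closed form the tests check empirically.
* **Categories.** Core-pool nodes draw categories from a base-uniform
  profile whose planted categories (default Metabolic and
  Immune/Inflammatory/Infectious) are multiplied by `shared_core_boost`;
  disease-specific nodes draw from per-disease weight profiles. The
  default profiles are `14 - rank` over the shipped reference disease
  rank columns, which plants the pairwise similarity ordering
  AD–FTD > AD–ALS > ALS–FTD.
* **Scores.** Beta-distributed (unit interval, concentration 8) with mean
  0.45, shifted up by 0.10 for planted categories; a shared node's
  per-disease score mixes a shared latent factor (weight 0.6) with
  independent noise, so shared relevance is correlated but imperfect —
  the regime in which harmonic-mean intersections carry information.
* **Planting is the pair (frequency boost, score shift).** The
  no-planting control is `shared_core_boost = 1` *and* `score_shift = 0`;
  under it, top-3 recovery of the planted categories sits at the chance
  level obtained by permuting category labels. The defaults
  (`n_nodes = 2000`, `overlap_fraction = 0.3`, `shared_core_boost = 5`)
  are the standard study conditions used by the recovery suite and the
  acceptance script.

What the generator does **not** emulate: literature bias and reporting
heterogeneity, realistic UMLS vocabularies or node names, hub structure
of real semantic graphs, or temporal ordering of comorbidity. Passing
recovery tests therefore show that the pipeline detects the structure it
is designed to detect at realistic sizes — not that any real-data finding
is reproduced.

`plantedRecoverySuite()` runs the full analysis per replicate and reports
(i) how often every planted category ranks in the top 3 of every pairwise
intersection percentage profile and (ii) how often the planted similarity
ordering is recovered by Spearman correlation of the disease hierarchies.
At the standard conditions both rates exceed 0.95 over 100 replicates.

## 7. Pipeline determinism and problem sizes

`runPipeline()` executes simulate → normalize → categorize → intersect →
enrich → hierarchy → similarity → landscape → borda → report. A single
run seed is expanded into per-stage substreams by a fixed derivation
(`seed * 131 + stage index`, mod 2^31), so stochastic stages are
reproducible in isolation. The report bundle (delimited tables + JSON
summary + MD5 manifest) contains no timestamps and is byte-identical
across repeat runs with the same config and seed.

Unit tests run the generator at 200–1000 nodes per disease and the
recovery property at 500; the acceptance-grade checks use the standard
conditions (2000 nodes, 100 replicates) and a 100-graph HeteSim oracle
corpus — sizes chosen so the full suite completes in well under a minute
while estimates remain stable.

## 8. Known limitations

* HeteSim here is exact; no randomized or approximate variant is
  provided, so very large graphs are out of scope by design.
* Rank correlations at 13 categories are descriptive; no p-values are
  attached, deliberately, since asymptotic approximations at n = 13 are
  fragile.
* The binomial enrichment null ignores the finite-pool dependence between
  categories (percentages must sum to 100); the permutation null is the
  appropriate sensitivity check.
* The ontology imposes single-category membership; genuinely pleiotropic
  concepts are forced into one bin by the upstream mapping.
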