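---
title: "Methods: synergy-enriched knowledge graphs, embeddings, and repurposing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergy-enriched knowledge graphs, embeddings, and repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures the package implements, the
assumptions behind them, the tunable parameters that matter, and the design
choices made where the design was genuinely open. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The pipeline at a glance

1. **Harmonise** combination-screen records to one ZIP score per (drug pair,
   cell line); **label** pairs synergism / antagonism / additive; keep pairs
   whose per-cell-line labels are unanimous and non-additive.
2. **Enrich** the knowledge graph with reciprocal `has_synergism_with` /
   `has_antagonism_with` edges.
3. **Split** triples per relation stratum (train / validation / test), with
   every relation type guaranteed present in training.
4. **Embed** the graph with one of five models; **rank** relation types
   between drug pairs; **evaluate** by rank-k true-prediction percentage and
   macro one-vs-rest ROC-AUC.
5. **Classify** pairs with classical learners under nested cross-validation,
   on handcrafted (topology + physicochemical + fingerprint) or embedding
   features.
6. **Predict** all unknown drug pairs in both orientations, keep mutual
   rank-1 combination calls, and segregate synergism from antagonism.
7. **Prune** the graph to its causal-only form (relation whitelist, isolated
   nodes, hub nodes) while keeping a disease-retained copy.
8. **Nominate** repurposing candidates: safe synergistic partners of anchor
   drugs with a shared pathway to the disease.

## Synergy harmonisation and labelling

ZIP scores from combination screens are replicate-averaged within a
(pair, cell line) key before labelling, and labels are then compared across
cell lines: label the mean, never mean the labels, within a cell line;
across cell lines demand unanimity. A pair synergistic in one cell line and
antagonistic in another carries no transferable class signal and is dropped;
all-additive pairs are dropped too, because additive edges are both rare in
screens and uninformative for class prediction, and adding them would mainly
add class imbalance.

The class thresholds default to ±10 ZIP units (`t_syn = 10`,
`t_ant = -10`), inclusive, with the dead band read as additive. Screen
databases do not publish a canonical cut-off; ±10 is wide enough that
measurement noise of a few ZIP units rarely crosses class boundaries, and
the thresholds are ordinary arguments wherever they are used.

## Embedding models and training

All five models are trained with mini-batch Adam (defaults: learning rate
0.01, betas 0.9/0.999, batch 256) under SLCWA. Loss conventions follow the
model families: margin ranking (margin 1.0 by default) for the
distance-based TransE / TransR / RotatE, softplus for the bilinear
ComplEx / HolE. HolE's logistic nonlinearity lives inside the loss; the raw
bilinear score is used for ranking, which changes nothing (the logistic is
monotone) and keeps the numerics clean. Complex parameters are stored as
paired real matrices; RotatE relations are stored as phase angles so the
unit-modulus constraint holds exactly rather than by projection; TransE
entity vectors are renormalised to unit length after every step. Circular
correlation is computed via FFT, with the O(d²) double-loop definition kept
in the test suite as the oracle.

**Negative sampling.** Each positive yields `negatives` (default 4)
corruptions. A fraction `relation_corruption` (default 1/3) of corruptions
replaces the relation with a uniform draw from the vocabulary; the remainder
replace head or tail (fair coin) with a uniform entity. The relation share
exists because the downstream task is ranking relation types between a fixed
entity pair: corrupting only entities never penalises a wrong relation on a
true pair, and models trained that way score all relations similarly for a
given pair — they learn link plausibility but not relation discrimination.
Under plain SLCWA a corruption may coincide with an observed triple;
`filter_negatives = TRUE` resamples those collisions.

**What is deliberately absent:** no hyperparameter search pipeline, no early
stopping, no GPU path. Epoch count, dimension (default 64) and seeds are
explicit configuration, which keeps every training run exactly
reproducible: identical config and seed give identical parameters.

## Evaluation

The rank-k true-prediction percentage is 100 · n_true(k) / n_pairs, with the
denominator the number of evaluated pairs — each pair contributes exactly
one prediction at each rank, so summing n_true over all ranks returns the
number of pairs. Ranks beyond 3 are computed on request but reported
separately, since in practice nearly all true predictions concentrate in the
top ranks. Binary ROC-AUC is the Mann–Whitney concordance probability with
midranks (ties count one half), which handles tied scores exactly; the
multiclass version binarises the truth one-vs-rest per relation type, uses
that type's score column, and macro-averages (unweighted mean over types).
Types never observed in the truth are excluded from the mean with a warning.

## Pair features and nested cross-validation

Pair feature vectors are order-invariant by construction: the two drugs are
put in lexicographic order before any per-drug block is laid out. Topology
features (degree, local clustering, PageRank with damping 0.85, shortest
path, cosine similarity) treat the KG as an undirected simple graph. Cosine
similarity is computed between the drugs' adjacency indicator vectors — the
only vector representation available before any embedding exists.
Disconnected pairs get a shortest-path sentinel of the largest finite
distance plus one, keeping the feature finite and monotone. Morgan-style
fingerprints enter as the pair's Tanimoto coefficient plus the elementwise
OR and AND of the two bit vectors, which preserves symmetry at bounded
dimensionality (raw concatenation would not be order-invariant). Missing
physicochemical values are mean-imputed with the imputation mask recorded.

The nested scheme: stratified 90/10 hold-out (exact floor arithmetic with
largest-remainder allocation per class, so a 20,840-pair training portion
splits into exactly 18,756 + 2,084 at 90/10); ten inner 90/10 loops each
pick the best grid point by validation AUC; ten instances refit on the full
training portion with the per-loop winners are each scored on the hold-out.
Grids are small fixed defaults per learner (`default_grids()`); publishing
large grids without a search budget would be false precision.

## Pair prediction and the mutual filter

Every unordered drug pair is scored in both orientations and only the rank-1
relation of each orientation is kept. A pair survives the mutual filter only
when both orientations agree on the same combination relation; disagreement
("nonmutual" calls) or agreement on a non-combination relation drops the
pair with a reason code — the latter is a "no combination call", not forced
into either class. A laxer agreement-in-top-3 reading was considered and
rejected as the default: the rank-1 extraction is the sharper, more
auditable rule. Scores are model-native and not comparable across models;
within a model, segregated sets order by the pair's weaker orientation
score.

## Causal-only pruning

The causal whitelist defaults to `increases`, `decreases`,
`causes_no_change` ("no effect"), and is configuration, not constant —
curation vocabularies differ. The pipeline order is fixed: whitelist filter,
isolated-node sweep, hub removal, isolated-node sweep again. Hub removal
defaults to node-type selection (`Pathology`), because disease nodes are the
dominant super-hubs of a pharmacome; a degree threshold is available as an
additional rule. The disease-retained companion copy is produced in the same
run and differs from the causal-only graph exactly by the hub-removal step,
so pathway tracing and embedding always share provenance.

## Repurposing

Candidates are the predicted synergistic partners of anchor drugs, ranked by
synergy score. The safety filter is an explicit user-supplied exclusion
list: "cytotoxic or severe side effects" is an editorial judgement, not a
computable predicate, and an auditable list keeps it honest — excluded
drugs stay in the report with their rank and a failed flag. Pathway evidence
enumerates simple paths (≤ `max_len` edges, default 4 — mechanism chains of
drug → protein → protein → disease length) from each drug to the disease,
traversing causal edges direction-agnostically while recording each step's
relation; a candidate is `pathway_supported` when one of its paths shares at
least one interior node with an anchor path. Requiring a shared node rather
than an identical path matches how mechanisms converge on common effectors.
A disease absent from the graph is reported as `no_disease_node`, distinct
from present-but-unreachable (`no_connecting_pathways`); the two situations
have different remedies (wrong graph vs missing curation). Path sharing is
assessed against the anchor drug's paths by default; sharing with any
disease path is available by composing the pieces directly.

## The synthetic generator: what it emulates, and what not

`generate_planted_kg()` samples ground-truth embeddings and keeps the
`triple_budget` top-scoring candidate triples, so every emitted triple
outscores every non-emitted one under the generator model — the property
that makes "recovery" well defined. Entities are drawn around cluster
centroids (about two clusters per relation) and each relation connects one
ordered centroid pair: the translation between centroids for TransE, the
elementwise phase difference for RotatE, the centroids' circular correlation
for HolE. This plants the community structure real biomedical KGs have
(relations connect entity neighbourhoods — drug classes to target families
— rather than arbitrary point pairs), and it is what makes held-out
relation recovery achievable for every model family rather than only for
the generator's own: with i.i.d. entity embeddings the planted regularity
is essentially private to the generating model.

The synergy generator draws a latent class per pair (additive with
probability `additive_rate`, otherwise synergism/antagonism equiprobably)
and emits per-cell-line ZIP = class mean ± noise, with class means ±15 and
noise sd 2 by default: a 2.5 σ margin against the ±10 thresholds, so
per-cell-line mislabelling is ≈ Φ(−2.5) ≈ 0.6% and filter behaviour is
predictable in closed form. A controlled fraction of pairs gets sign-flipped
cell lines to plant exactly the cross-cell-line inconsistency the filter
must remove.

What the generator does **not** emulate: dose–response surfaces (ZIP values
are drawn, not computed from inhibition matrices), pharmacological
plausibility of descriptors, scale-free degree distributions, and the
incompleteness patterns of curated KGs. Passing tests therefore demonstrate
correctness of the machinery and recoverability under controlled conditions
— not performance on a real pharmacome.

## Problem sizes and numerical choices

The reference conditions used throughout the tests and the acceptance
script: planted KG with 500 sampled entities, 8 relation types, 5,000
triples, embedding dimension 64, 80 epochs; synergy tables of 500 pairs over
3 cell lines; classifier benchmarks on 300 pairs with 10 features. These
sizes make every property checkable in minutes on one CPU while keeping all
estimated quantities far from their decision boundaries.

Numerical details worth knowing: distance scores add 1e−12 inside square
roots so gradients at exact coincidence stay finite; relation-ranking ties
break by vocabulary order, making rankings fully deterministic; stratified
splits use floor-plus-largest-remainder allocation; the empty-union Tanimoto
is defined as 0 with a warning; a relation stratum with a single triple is
forced into the training split so the relation vocabulary is always covered.

## Known limitations

Pure-R training is practical to a few hundred thousand triples per run, not
to full pharmacome scale with hyperparameter search. Scores are not
calibrated probabilities, and cross-model score comparison is meaningless.
Cell-line-specific synergy modelling, dose reasoning, and literature
validation of nominated candidates are out of scope: the report's verdicts
are structural (synergy + safety + pathway), and candidates still require
experimental follow-up.
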