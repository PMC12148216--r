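# kgsynergy

Drug-synergy enrichment, knowledge-graph embedding, and repurposing
nomination on biomedical knowledge graphs (pharmacomes), in R.

## What it does, and for whom

High-throughput combination screens (DrugcombDB-style exports) measure how
two drugs interact on a cell line, summarised by a synergy score such as the
zero-interaction-potency (ZIP) score: positive means synergism, negative
antagonism, near zero an additive (non-interacting) combination. A
pharmacome — a knowledge graph (KG) of drugs, proteins, genes and
pathologies connected by typed directed relations — can be *enriched* with
these combination effects as `has_synergism_with` / `has_antagonism_with`
edges, after which link prediction over the enriched graph proposes new
synergistic partners, and shared drug–disease pathways in the causal part of
the graph turn those partners into drug-repurposing candidates. The package
is aimed at computational drug-discovery groups who want this whole chain —
screen harmonisation, KG embedding, pair classification, causal pruning,
candidate nomination — reproducible from four plain-text inputs
(`kg.tsv`, `KG_labels.tsv`, `Drugs.csv`, `Drug_combinations.csv`).

## The models at the core

Five knowledge-graph embedding models are implemented from scratch and
trained under the stochastic local closed-world assumption (SLCWA: negatives
are random corruptions of observed triples), with higher score = more
plausible triple (h, r, t):

| model   | score                                             |
|---------|---------------------------------------------------|
| TransE  | −‖h + r − t‖₂                                     |
| TransR  | −‖M_r h + r − M_r t‖₂²                            |
| RotatE  | −‖h ∘ r − t‖, complex h, t, unit-modulus r        |
| ComplEx | Re(Σᵢ hᵢ rᵢ t̄ᵢ), complex embeddings              |
| HolE    | r · (h ⋆ t), ⋆ = circular correlation (via FFT)   |

For a fixed drug pair the model ranks all relation types by score
(`rank_relations()`); evaluation reports the percentage of true predictions
at rank k, 100 · n_true(k) / n_pairs, and the macro one-vs-rest multiclass
ROC-AUC (mean of per-relation-type binary AUCs). Classical pair
classification runs five learners (logistic regression, elastic net,
gradient boosting, random forest, SVM) under nested cross-validation:
a stratified 90/10 hold-out, ten inner 90/10 grid-search loops, and ten
refit instances scored on the hold-out by ROC-AUC.

## Worked example

Everything below is generated — no downloads. The synthetic generator plants
a KG from ground-truth embeddings and a combination screen with known latent
classes, so recovery is checkable.

```r
library(kgsynergy)

spec <- synthetic_spec(seed = 0)          # 500 entities, 8 relations, 5000 triples
planted <- generate_planted_kg(spec)
planted$kg
#> Knowledge graph: 313 entities (5 types), 5000 triples (5000 unique), 8 relation types
# (500 sampled entities; the 313 taking part in a top-scoring triple register)

drugs <- planted$kg$entities[planted$kg$entity_type == "Drug"]
screen <- generate_synergy_table(spec, drugs)
labels <- consistency_filter(screen)      # unanimous non-additive pairs
table(labels$label)
#>
#> antagonism  synergism
#>        183        190

enriched <- enrich_kg(planted$kg, labels)
sp  <- split_triples(enriched, test_frac = 0.2, val_frac = 0.2, seed = 0)
fit <- kge(knowledge_graph(rbind(sp$train, sp$validation)),
           model = "HolE", dim = 64, epochs = 80, seed = 0)
fit
#> HolE knowledge-graph embedding (d = 64): 313 entities, 10 relations
#> trained 80 epochs (softplus loss), final mean loss 0.16489

rank_relations(fit, drugs[1], drugs[2])[1:3, ]
#>             relation     score rank
#> 1 has_synergism_with  1.094465    1
#> 2             rel_02 -3.878728    2
#> 3             rel_06 -4.674104    3
```

The ranking covers every relation type once; rank-1 agreement between the
forward and reverse orientation of a pair is what `mutual_filter()` demands
before a pair enters the predicted synergism/antagonism sets, and
`nominate_candidates()` turns the synergism set plus anchor drugs, a safety
exclusion list and a disease node into a verdict per candidate
(`pathway_supported` / `synergy_only` / `excluded`).

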