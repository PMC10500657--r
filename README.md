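# chemkgqa

Embedding-based question answering over chemistry knowledge graphs.

Chemistry knowledge graphs (species, computed properties, reaction
mechanisms) are awkward to query directly: their ontologies are deep, their
relations are heavily 1-to-N, and much of their content is numeric rather
than relational. `chemkgqa` implements an information-retrieval QA stack for
such graphs built on knowledge-graph embeddings:

* **Five embedding methods** — TransE, TransR, ComplEx, and their
  joint-numerical extensions TransEA and **TransRA** (TransR plus a linear
  attribute head). A triple *(h, r, t)* is scored by a translation distance
  ‖**h** + **r** − **t**‖ (TransE), by the same distance after a learned
  per-relation projection **M**ᵣ (TransR), or by the bilinear similarity
  Re⟨**h**, **r**, conj(**t**)⟩ (ComplEx). The joint methods additionally
  fit every numeric attribute triple *(e, l, v)* with a linear head
  **e**·**l** + b ≈ v, combining the two objectives as
  (1 − α)·L_relation + α·L_attribute.
* **Implicit multihop relation derivation** — in deep ontologies a species'
  property can sit 3 hops away; composite relations (`r1|r2|r3`) are
  enumerated over simple paths and materialized as extra training triples,
  turning multihop questions into 1-hop questions.
* **A per-ontology QA workflow** — fuzzy entity linking over labels,
  formulas and aliases; template-based relation prediction; n-hop candidate
  extraction; hypothetical-triple scoring; two-round numerical filtering
  (round 1 on predicted values **e**·**l** + b with a slack, round 2 exact
  on stored values).
* **Cross-ontology score alignment** — answers from independently trained
  embedding spaces are put on one scale by a learned per-ontology affine
  adjustment `w_o · s + u_o · x(q)` driven by question–ontology affiliation,
  with plain max-normalization as the ablation baseline.
* **Evaluation harness** — mean reciprocal rank (MRR = mean 1/rankᵢ) and
  hits@k under raw and filtered link-prediction protocols, and gold-head
  vs fuzzy-linked QA protocols.
* **A synthetic generator** — knowledge graphs with planted translation
  geometry, 1-to-N fan-out, noisy linear attributes, deep calculation
  chains, label tables and scripted question sets, so the whole stack is
  testable without any external dataset.

## Worked example

```r
library(chemkgqa)

cfg     <- synthetic_config(seed = 42L)        # 200 entities, 8 relations,
planted <- generate_planted_kg(cfg)            # 3 numeric attributes
kg      <- planted$kgs[[1]]
kg
#> <knowledge_graph 'onto1': 200 entities, 8 relations, 1254 triples, 420 attribute triples>

space <- train_embeddings(training_kg(planted), "TransRA",
                          training_config(seed = 43L))
evaluate_link_prediction(training_kg(planted),
                         planted$truth[[1]]$test_triples,
                         space, protocol = "filtered")
#> <eval_report protocol=filtered-link-prediction Q=242 mrr=0.8163 hits@1=0.7314 hits@5=0.9256 hits@10=0.9793>

attribute_error_metrics(space, kg)$mean_absolute_error
#> [1] 0.0168
```

The filtered report says: over 242 held-out triples, ranking every entity
as a candidate tail (with other known-true tails removed), the true tail
lands at reciprocal rank 0.82 on average and inside the top 10 in 98% of
cases. The attribute head recovers the planted numeric values to a mean
absolute error of 0.017 — about one third of the generator's observation
noise (σ = 0.05).

Answering a generated question end to end:

```r
q <- Filter(function(x) x$type == "single-hop",
            generate_questions(planted, cfg)[[1]]$questions)[[1]]
q$question
#> [1] "tell me the katodu of dazima"
spec <- question_spec(head_entity = q$head, relation = q$relation,
                      hops = 3, top_k = 3)
answer(spec, kg, space)[, c("entity", "score", "norm_score")]
#>        entity    score norm_score
#> 1 onto1:E0080 3.916232  0.2034078
#> 2 onto1:E0081 3.995559  0.2001778
#> 3 onto1:E0170 4.150483  0.1941566
q$gold
#> [1] "onto1:E0080" "onto1:E0081" "onto1:E0170" "onto1:E0171" "onto1:E0172"
```

All three returned answers are valid tails of the queried 1-to-N relation
(`score` is the TransRA distance of the hypothetical triple; `norm_score`
is its higher-is-better transform `1/(1+d)` used for merging).

A command-line wrapper over the same functions is installed at
`inst/cli/kgqa.R` (commands `generate`, `train`, `derive`, `evaluate`,
`answer`, `filter`, `align-train`, `align-rerank`).

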