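---
title: "Methods: hybrid knowledge-graph-embedding QA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid knowledge-graph-embedding QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Chemistry knowledge graphs mix three features that strain standard
query-by-template retrieval: deep ontology structure (a computed property
can sit three or more relations away from its species), heavily 1-to-N
relations (one species connected to many reactions or calculations), and a
large numeric component (molecular weights, energies, spectra) that a
purely relational representation ignores. `chemkgqa` implements an
information-retrieval QA engine for such graphs: entities and relations are
embedded in a vector space, a question is reduced to a head entity plus a
relation embedding, and candidate answers extracted from the head's graph
neighborhood are ranked by the plausibility of the hypothetical triple
*(h, r, a′)*.

# Embedding methods

For a triple $(h, r, t)$ with embeddings $\hat h, \hat r, \hat t \in
\mathbb{R}^d$:

* **TransE** scores by the translation distance
  $f(h,r,t) = \lVert \hat h + \hat r - \hat t\rVert$ (L1 or L2); it is 0
  exactly when $\hat t = \hat h + \hat r$.
* **TransR** first projects entities into a relation-specific space through
  a learned $d\times d$ matrix $M_r$ and scores
  $\lVert M_r \hat h + \hat r - M_r \hat t\rVert^2$. The projection gives
  each relation its own geometry, which helps 1-to-N relations where many
  tails must be simultaneously close to one translated head.
* **ComplEx** embeds in $\mathbb{C}^d$ and scores by
  $\mathrm{Re}\langle \hat h, \hat r, \overline{\hat t}\rangle$, a
  similarity (higher is better) that can represent asymmetric relations.
* **TransEA / TransRA** add numeric attribute triples $(e, l, v)$ through a
  linear head: the attribute $l$ gets a vector $\hat l$ and bias $b_l$, and
  the model is penalized by $(\hat e \cdot \hat l + b_l - v)^2$ (squared by
  default; absolute available). The relation loss $L_r$ and attribute loss
  $L_a$ are combined as the convex sum $(1-\alpha) L_r + \alpha L_a$. The
  literature states only that the two losses are summed with an adjustable
  factor; the convex form is chosen here because it makes $\alpha$
  interpretable as a pure trade-off and makes $\alpha = 0$ reduce the
  joint methods exactly to their bases (a property the test suite asserts
  on identical seeded training traces).

All methods are trained with margin ranking over corrupted triples: for
each positive, one side (head or tail, uniformly) is replaced by a random
entity and the hinge $\max(0, \gamma + f_{pos} - f_{neg})$ is minimized by
plain stochastic gradient descent. ComplEx similarities are negated into
distances so one ranking convention serves everywhere; a logistic loss is
available for ComplEx as an option, but margin ranking is the default so
that the five methods differ only in their score functions.

## Training parameters

| parameter | default | meaning |
|---|---|---|
| `dim` | 16 | embedding dimension; small because the target graphs here are a few hundred entities |
| `margin` γ | 1 | hinge margin on (squared) distances |
| `alpha` α | 0.3 | attribute weight, joint methods only |
| `learning_rate` | 0.01 | SGD step |
| `epochs` | 500 | passes over the relation triples |
| `batch_size` | 128 | triples per update |
| `negatives` | 1 | corruptions per positive |
| `norm_order` | 2 | L2; `squared` defaults off for TransE/TransEA and on for TransR/TransRA, matching each method's customary inner form; both are exposed since the sources print them inconsistently |
| `norm_constraint` | on (off for ComplEx) | project entity rows to the unit ball after each batch |
| `filtered_negatives` | on | corruptions avoid known true triples (best effort inside batches) |

Initialization is uniform in $[-6/\sqrt d, 6/\sqrt d]$ per coordinate with
entities projected to the unit ball; TransR projections start at the
identity (zero would kill all gradients). Initialization draws happen in a
fixed order (entities, relations, projections, attributes) and the RNG is
re-seeded before the epoch loop, so methods with different parameter sets
still consume identical training randomness — this is what makes the
α = 0 reduction identities hold bitwise.

The per-epoch mean combined loss is recorded. Because SGD batch noise makes
tiny relative fluctuations unavoidable near convergence, the monotonicity
check used in the tests reads "non-increasing over any 5-epoch window" with
a tolerance of 5% *of the trace's scale* (its maximum), not 5% of the
current value.

# Multihop relation derivation

Composite relations are enumerated over **simple** entity paths (no
repeated entities) of length 2..`max_hops`, keeping those realized by at
least `min_support` distinct paths, and one triple (start, composite
label, end) is materialized per realizing path. Labels join the step
relations with the reserved separator `|` (rejected in input IRIs at parse
time); traversing against edge direction is supported and marked with a
`^` prefix but is off by default, since the calculation-chain structures
this targets point forward. Only instance-level support is counted; a
schema-level filter would be a natural extension hook. Deriving on an
already-augmented graph adds nothing: composite relations are excluded
from the path alphabet, making augmentation idempotent.

# QA workflow

1. **Entity linking.** The fuzzy baseline ranks entities by normalized edit
   similarity ($1 - \mathrm{dist}/\max(\mathrm{lengths})$) between the
   mention and any of the entity's label strings — primary label plus
   pipe-separated aliases, which may include formulas. No-match below the
   threshold (default 0.6) is an explicit empty result, not an error.
2. **Relation prediction.** The default predictor matches the question
   against per-relation templates by token overlap and returns the matched
   relation's embedding row exactly; it defines the contract a learned
   predictor would plug into. Numerical qualifiers ("larger", "smaller",
   "close to"; a bare "at 100 K" counts as close) are parsed with regular
   expressions; units are compared as literal text, with no unit
   conversion.
3. **Candidate extraction** takes all entities within `hops` (default 3)
   of the head. Traversal is undirected by default because answers in deep
   ontologies can sit on inverse paths; the scored hypothetical triple
   still treats the candidate as tail, and a forward-only policy is a flag
   away.
4. **Scoring and ranking.** Distances are mapped to $1/(1+d)$ so one
   higher-is-better scale serves ranking and cross-engine merging (and
   keeps the max-normalization baseline meaningful on distance engines).
   Ties break deterministically by entity id. In QA evaluation the rank of
   a question is the best *position* of an acceptable gold answer in this
   deterministic list — the operational quantity a user of the top-k list
   experiences — while link-prediction evaluation uses tie-adjusted ranks
   (average policy by default, so a constant-score model cannot look
   perfect).

## Two-round numerical filtering

Round 1 keeps entities whose *predicted* value $\hat v = \hat e \cdot \hat
l + b$ satisfies the operator with slack δ; round 2 keeps survivors whose
*stored* value satisfies it exactly, reporting separately the survivors
with no stored value. δ defaults to two sample standard deviations of the
prediction residual for that attribute, recomputed per attribute — no
slack rule is given in the sources, and this choice targets high round-1
recall while still pruning most candidates. The closeness tolerance τ
defaults to 5% of the filter value. Setting δ = ∞ disables round 1, which
makes the pipeline equal a brute-force filter over stored values; the test
suite uses this as its oracle.

# Score alignment

Engines trained independently produce incomparable score scales. The
alignment model applies $s' = w_o \, s_{norm} + u_o \cdot x(q)$, where
$s_{norm}$ is the max-normalized score, $x(q)$ a bag-of-words indicator of
the question, and $(w_o, u_o)$ are learned per ontology by pairwise margin
ranking (margin 0.1, SGD, 200 epochs) of gold answers above all others.
This is the smallest model family faithful to "predict a score bias from
the question–ontology affiliation and the domain": a positive per-ontology
scale (kept ≥ 10⁻⁶, so within-ontology order is never changed — only the
cross-ontology interleaving) plus a question-dependent bias. Whether the
original formulation rescales as well as biases is unstated; both are
included here and either can be frozen. Affiliation probabilities
themselves come from an independent per-label Bernoulli naive-Bayes
classifier; an empty question falls back to each label's base rate.

The ablation baseline divides each engine's scores by its maximum and
merges. Note its failure mode, which the constructed benchmark in the
tests exercises: max-normalization pins every engine's top answer at 1.0,
so cross-engine ties at the top are broken blindly, while the aligned
model resolves them from the question's vocabulary.

# The synthetic generator

The generator plants exactly the structure the methods assume, so that
recovery is an identifiable target rather than a hope:

* entities carry latent vectors on the integer lattice spanned by the
  general relations' latent translations (norm 0.5 before a global
  rescale into the unit ball, which preserves translation structure);
  every pair one lattice step apart is materialized as a triple, giving a
  dense, geometrically consistent graph in which relation paths commute;
* 1-to-N fan-out comes from multiple entities per lattice cell, drawn
  truncated-geometric (p = 0.5, cap 5) — near-duplicate points that stress
  pure translation exactly the way species→reaction hubs do;
* numeric attributes are noisy linear readouts $v = e^* \cdot l^* + b^* +
  \mathcal N(0, \sigma)$, default σ = 0.05 against values of order 1;
* deep chains place a leaf value `chain_depth` (default 3) hops from its
  species, reserving dedicated hop relations;
* labels are unique pseudo-words with abbreviation and formula-style
  aliases; questions are generated from held-out template phrasings
  (training and testing phrasings are disjoint), with optional
  single-character mention misspellings for entity-linking experiments.

Default study conditions: 200 entities, 8 relations, 3 attributes,
σ = 0.05, 12 chains, a 20% test split constrained so every entity and
relation stays covered in training. At these sizes the full test suite
runs in about a minute and the acceptance script in under two on one CPU.

What the generator does **not** emulate: textual diversity of real
questions (templates are rigid, so entity-linking and relation-prediction
results here are upper bounds), schema heterogeneity across ontologies,
reaction semantics, agent invocation, and the scale of real chemistry KGs
(tens of thousands of entities). Passing tests demonstrate correctness of
the machinery and recoverability of planted structure — not performance on
any real ontology, whose headline numbers depend on data this package
deliberately does not ship.

# Degenerate inputs and numerical conventions

* Serialization is canonical: rows sort lexicographically by IRI strings,
  so `write(parse(write(kg)))` is byte-stable regardless of id assignment
  (ids themselves are first-seen, 1-based).
* A bare literal in a relation position is a parse error, never a silent
  attribute; non-finite attribute values are rejected.
* Unsquared L2 gradients guard the norm with a 10⁻¹² floor; hinge-inactive
  pairs contribute nothing.
* `negative_sample` is strict (errors with an exhaustion condition when a
  filtered corruption is impossible); inside training batches filtering is
  best-effort with 10 resampling rounds, since a rare false negative only
  perturbs one SGD step.
* Empty candidate sets yield empty answer lists, not errors; unresolved
  heads, relations and operators are distinct typed signals.
* All stochastic components take explicit integer seeds and derived seeds
  stay below 2³¹.

# Known limitations

ComplEx under margin ranking converges to noticeably weaker desk-scale
link-prediction metrics than the translation family on lattice-structured
graphs (visible in the acceptance output); the logistic option narrows the
gap but is not the default, to keep the methods comparable. The
"complex-with-attributes" coupling is not implemented: the sources flag
joint numerical embedding as markedly less effective for ComplEx, and no
coupling form is specified. The template-based relation predictor is a
baseline contract, not a contribution; a learned predictor can replace it
behind the same interface.
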