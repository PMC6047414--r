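---
title: "Extracting mutation-affected protein interactions with memory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting mutation-affected protein interactions with memory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppimnet)
```

## The task and the model

`ppimnet` addresses document-level extraction of protein–protein
interactions affected by mutations (PPIm).  The unit of annotation is an
unordered Entrez Gene ID pair within one abstract; the unit of
classification is a *candidate instance* — one co-occurring mention pair
with a masked context window.  Because labels exist only at the document
level, every mention-pair occurrence of a gold pair is labeled positive and
every other candidate negative (distant labeling).  This is the central
assumption of the training regime, and it is knowingly noisy: a gold pair's
mention may co-occur in a sentence that says nothing about the interaction,
yet the instance is still labeled positive.

The classifier is a pair of memory networks sharing attention parameters.
The context-word embeddings form an external memory `m` (one `d`-vector per
token); each network attends over that memory with one entity embedding as
its query.  One computational layer (hop) performs:

1. **Position impact.**  Memory column `i` is scaled by
   `per(p_i) = (1 − p_i/n) − (k/d)(1 − 2 p_i/n)`, where `p_i` is the token
   distance to the network's entity mention, `n` the context length, `k`
   the layer number, `d` the embedding dimension.  Tokens closer to the
   entity contribute more; the `k/d` term lets later layers flatten the
   profile slightly.  We take `k` as the 1-based layer index, a scalar per
   token per layer.  (In the memory-network lineage this index is sometimes
   a *dimension* index producing a vector profile; the scalar reading
   matches the formula as used here, and the discrepancy is documented
   rather than resolved.)
2. **Attention.**  `g_i = tanh(Wa [m_i; e] + ba)`, `α = softmax(g)`,
   `v_att = Σ α_i m_i`.  `Wa` is `1 × 2d` and `ba` a scalar.
3. **Query update.**  `e′ = Wt e ⊕ v_att` with `⊕` the dimension-wise sum
   (or max in the `MNM-Max` variant).

After `K` hops the two queries are concatenated, the pair's knowledge-base
relation embedding is appended, and a 2-way softmax yields
`P(interaction | instance)`.  Training minimizes the mean cross-entropy
with Adam; prediction takes the argmax, and a document-level pair is
positive iff at least one of its instances is.

Prior knowledge enters in two places.  Entity embeddings come from TransE,
trained on interaction-database triples by minibatch descent on the margin
ranking loss `max(0, γ + ‖h + r − t‖ − ‖h′ + r − t′‖)` with filtered
corruption sampling (head or tail replaced uniformly, redrawn while the
corruption is a known true triple, capped at 100 tries) and per-update
renormalization of entity vectors to the unit sphere.  Relation embeddings
of a pair are the mean of the TransE relation vectors of all triples
linking the pair in either direction, and the zero vector for pairs absent
from the KB — so "the KB knows this pair" is itself a learnable signal.

## Named variants

Configuration tuples reproduce the standard ablations: `AE` (entity
embeddings are averaged mention-word vectors, no relation embedding), `TE`
(TransE entities, no relation embedding), `AE-TR` (averaged-word entities
plus relation embedding), `MNM-DA` (each network has its own attention
parameters), `MNM-Max` (dimension-wise max pooling), `MNM-Single` (one
memory network whose attention input concatenates both queries to each
memory column; each query is updated separately with the shared `Wt`, and
the classifier input remains `[e′₁; e′₂; e_rel]` for comparability).

## Parameters that matter

| parameter | default | notes |
|---|---|---|
| `K` (hops) | 4 | the published sweet spot; the packaged experiments use 2, which suffices at synthetic scale |
| `d` (dimension) | 100 | words, entities and relations share it; experiments here use 32 |
| TransE margin γ | 1.0 | conventional; loss scale only matters relative to it |
| TransE lr / epochs / batch | 0.01 / 500 / 512 | plain SGD on the ranking loss; desk-scale KBs converge in ≤ 200 epochs |
| Adam lr / batch | 0.001 / 100 | the published optimizer settings |
| epochs (classifier) | 30 | no early stopping; tune by cross-validation if needed |
| sentence-support N | 2 | a pair needs `> N` supporting sentences (strict) |
| distance rules | < 3 sentences, 3 < tokens < 50 | both bounds strict, applied to collapsed mention-head positions |

Entity and relation vectors are frozen inputs by default
(`finetune_kb_vectors = FALSE`) to keep the knowledge ablations clean; word
embeddings are always trained, with out-of-vocabulary tokens mapped to a
trained `<unk>` vector.

## Numerical and procedural choices

* **Sign of the ranking loss.**  We optimize
  `γ + d(pos) − d(neg)` inside the hinge — the form that actually pulls
  `h + r` toward `t` — and treat the opposite ordering sometimes seen in
  print as a typo.
* **Sentence segmentation / tokenization** are rule-based and
  dependency-free: sentences split on `[.?!]` + whitespace + capital/digit;
  tokens split on whitespace with edge punctuation detached and internal
  `.,'-%` joins kept (`3.5` stays one token and masks to `NUMBER` via
  `^[0-9][0-9.,%]*$`); all tokens are lowercased.  Multi-token mentions
  collapse to a single stream token at the mention head, so token distances
  are measured before mention removal (removal first would make the
  3 < dist < 50 rule self-referential).
* **Context distances** anchor to the removed mention slots with a floor of
  1, and flanks at document edges are taken as-is (no padding).
* **Ties.**  An exact 0.5/0.5 posterior predicts the negative class
  (conservative, matching the task's low positive prior); in max pooling,
  ties between `Wt e` and `v_att` route the (sub)gradient to `Wt e`.
* **Clamps.**  Probabilities are clamped at 1e-12 before logs; softmax is
  computed with max subtraction; TransE distances floor at 1e-12 when
  normalizing gradients.
* **Determinism.**  Every stochastic stage (generator, initialization,
  shuffling, corruption) is seeded; identical seeds give bitwise-identical
  loss traces and predictions on one platform.
* **Zero-denominator scoring conventions**: precision/recall/F1 are 0 when
  their denominators are 0.

## What the synthetic generator emulates

The generator builds abstracts as sentence sequences.  Each gene pair of a
document gets one co-mention layout — mentions 5–14 tokens apart, sometimes
split across adjacent sentences — followed by two buffer sentences so that
distinct layouts never jointly satisfy the sentence-distance rule.  Gold
pairs (probability 0.5 per co-mentioned pair) receive an interaction
trigger word (`phosphorylation`, `mutant`, `binds`, `kinase`, `interact`,
`complex` — vocabulary chosen to echo the words that attention analyses of
real systems find most indicative) in the between-span with probability
0.9; non-gold pairs with probability 0.05.  Filler text is Zipf-distributed
over a synthetic vocabulary; gene surfaces are `GENE<k>` with gene ID `<k>`
so normalization is exact by construction.  The KB gives each gold pair a
triple with probability 0.9 under a 5-relation vocabulary, plus 0.5 decoy
triples per gold pair over non-gold pairs; it emulates a curated database
whose coverage predates any train/test split, so one KB serves both
corpora.  Word vectors are random unit vectors.

What passing tests on these corpora demonstrate: the pipeline is internally
consistent (candidate rules, masking, aggregation, scoring all match
independent oracles), gradients are correct, the classifier can find and
attend to lexical interaction signal, and KB consistency translates into
measurable performance gains over the knowledge-free ablation.  What they
do **not** show: performance on real PubMed prose (no synonymy, anaphora,
entity-recognition noise, or train/test distribution shift), and absolute
scores are not comparable to published figures on the real benchmark,
which depend on an external entity recognizer and million-triple KBs.

## Problem sizes used by the packaged experiments

The test suite and `scripts/acceptance.R` run the end-to-end experiment on
200 training and 100 held-out documents with `K = 2`, `d = 32`, 100 TransE
epochs and 100 classifier epochs; the knowledge-ablation comparison uses
five seeds at 120/60 documents and 60 epochs; TransE sanity checks use a
20-entity, 3-relation, 60-triple KB over five seeds.  These sizes were
chosen so the whole suite runs in minutes on one CPU while leaving the
signal-recovery margins comfortable.  Held-out micro-F1 of the full model
at these conditions is typically 0.85–0.92: the residual errors are
dominated by the 10% of gold instances generated without a trigger and the
5% of negatives with a spurious one, i.e. by the generator's designed label
noise, not by pipeline defects.

## Known limitations

* Entity recognition and normalization are out of scope; annotations are
  inputs, and real-world recall is bounded by the upstream recognizer.
* The generator lays out each gene pair exactly once per document, so the
  sentence-support rule (which needs more than two co-mention sentences)
  never fires on synthetic corpora: its micro-F1 there is 0 and merging
  leaves the model's predictions unchanged.  The rule itself is validated
  on dedicated hand-built and randomized fixtures.
* The rule-based sentence splitter is adequate for the generator and for
  typical abstract prose but will mis-split on unusual abbreviation
  patterns; a mention straddling a detected boundary is assigned to the
  sentence containing its start.
* Training is plain R; it is comfortable at thousands of instances and
  `d ≤ 100` but not designed for the full-scale benchmark with
  million-triple KBs.
* `pair_relation_vector` ignores relation multiplicity beyond averaging,
  and direction information in the KB is deliberately discarded because
  evaluation identity is an unordered pair.
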