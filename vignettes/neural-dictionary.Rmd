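---
title: "A neural dictionary for ontology concept recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neural dictionary for ontology concept recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodict)
```

## The problem

Biomedical ontologies such as the Human Phenotype Ontology (HPO) or
SNOMED-CT provide, for each concept, a canonical name, a handful of
synonyms, and is_a (taxonomic) relations. Dictionary-based annotators match
text against those surface forms and therefore miss valid synonyms the
curators never listed ("renal cancer" for *Renal neoplasm*). Supervised
named-entity models need annotated corpora covering every class, which do
not exist for vocabularies with 10^4-10^5 concepts.

`neurodict` implements a middle road: a *neural dictionary* trained only on
the ontology itself (every name and synonym is a training example for its
concept), which generalizes to unseen synonyms through pretrained word
vectors, and which uses the taxonomy as an implicit prior on the geometry of
the concept embeddings.

## The model

**Encoder.** A phrase is a sequence of word vectors `x^(1) ... x^(T)`
(dimension `word_dim`). A width-one convolution projects each vector, an
element-wise max aggregates over tokens, and a dense head maps the pooled
vector into the concept space:

    v = max_t ELU(W x^(t) + b)
    e = l2norm(ReLU(U v))

Because the filters span one word and max pooling is commutative, the
encoding is *exactly* invariant to word order (a property test asserts
this). That discards syntax by design: for short noun phrases the reduction
in parameters outweighs the loss, and it is what lets a model trained on
"decreased retinal pigmentation" accept "retinal pigmentation, decreased".

**Concept embeddings.** The model does not learn the scoring matrix `H`
directly. It learns a raw matrix `H_raw` with one row per concept and
composes

    H = A %*% H_raw

where `A` is the taxonomy's *ancestry matrix*: row *i* is the unit vector on
*i* plus the mean of its parents' rows, evaluated in topological order.
Equivalently, a concept's final embedding is its parents' (averaged) final
embedding plus its own raw offset — parents place a concept globally, the
concept learns only its local displacement, and a gradient step on one
concept moves its whole subtree. `A[i, j]` is nonzero only when *j* is an
ancestor of *i* (reflexively); a root's row is its own unit vector; in a
tree the row of a depth-*d* node sums to exactly *d + 1*. Two consequences
of the recursive definition are worth stating because they are easy to get
wrong:

* with multiple inheritance the parents are *averaged* (a diamond
  root -> {a, b} -> c gives row(c) coefficients `{c: 1, a: 0.5, b: 0.5,
  root: 1}`), and
* coefficients reaching a shared ancestor along several paths *accumulate*
  (they are not clipped at 1) — the fixed point of the recursion, not a
  set union.

Setting `use_hierarchy = FALSE` replaces `A` by the identity, reducing the
model to a flat softmax classifier; a finite-difference test verifies that
in that configuration the gradient of the loss with respect to `H_raw` is
exactly the flat linear-softmax gradient.

**Scoring.** `softmax(H e + bias)` over all concepts. The bias is
per-concept (the standard softmax-classifier reading of "plus a bias
term"). When `use_negatives = TRUE` the matrix carries one extra learnable
row for a dummy NONE class with no taxonomy parents; it participates in the
same softmax and absorbs phrases that match no concept.

## Training

Positives are all distinct (surface form, concept) pairs from the ontology.
Negatives are random 1-10-token n-grams from an out-of-domain corpus,
labelled NONE; by default as many negatives as positives are drawn once
before training (`negative_ratio = 1`; resampling per epoch is possible but
not the default). The loss is cross-entropy, minimized by Adam (learning
rate 0.002, beta1 0.9, beta2 0.999, eps 1e-8) with batch size 256 for 100
epochs at full scale — no early stopping, weight decay or dropout. Examples
are reshuffled every epoch; the final short minibatch is kept. Word vectors
are frozen inputs, not parameters. Given a fixed seed the whole procedure is
bitwise reproducible, and ensembles are built by training under several
seeds and averaging predicted probabilities at inference.

Numerical guards: ELU uses alpha = 1; the l2 normalization divides by
`max(norm, 1e-12)`, so an all-negative ReLU output maps to the zero vector
(reachable early in training) instead of NaN; softmax is computed with the
max-subtraction trick; a non-finite loss aborts with the epoch number.

## Annotating documents

Text is lowercased, split into sentences on `.?!;` + whitespace, and
tokenized as maximal alphanumeric runs with character offsets preserved.
Every within-sentence n-gram of 1-7 tokens is scored; candidates below the
score threshold are dropped; overlaps are then resolved pairwise to a fixed
point in a deterministic order: same concept -> keep the smaller span,
different concepts -> keep the longer span (favouring "conotruncal heart
defect" over "heart defect"), equal lengths -> higher score, then smaller
concept id. The 1-7 scan window and the 1-10 negative lengths are both kept
configurable since they are two different constants of the method.

The threshold is picked on a validation split by exhaustive grid search on
micro F1 (ties go to the *largest* threshold, favouring precision). Default
grid: 0.05 steps over [0.50, 0.95], which brackets the published per-variant
operating points (0.85 full; 0.80 without hierarchy; 0.80 without negatives;
0.75 with neither), available via `variant_config()`.

One property that intuition suggests but that is **false** in general:
the final annotation set is *not* monotone in the threshold. The filter
stage is monotone (a higher threshold only removes candidates), but overlap
resolution is not monotone in its input — removing a low-scoring long span
can let spans it previously suppressed through. The tests therefore assert
monotonicity of the filter and that annotations are always drawn from the
surviving candidates, not end-to-end set inclusion.

## Evaluation

Document-level metrics compare the reported concept set `R_d` against the
gold set `L_d`: micro (pooled counts) and macro (per-document ratios
averaged) precision/recall/F1, with the convention that an empty `R_d`
contributes macro precision 1.0 and an empty `L_d` macro recall 1.0 (the
same convention is mirrored for empty pooled denominators so every metric is
total). Extended metrics replace each set by its ancestor closure before
micro-style pooling and add the pooled Jaccard index
`sum |E(R_d) ∩ E(L_d)| / sum |E(R_d) ∪ E(L_d)|`; the pooling is micro
across documents, an interpretive choice (the alternative per-document
macro-extended variants are easy to derive from `document_eval` records but
are not computed by default). Isolated-phrase ranking is scored as recall at
k (R@1, R@5) with ties in the ranking broken lexicographically by concept
id.

## The synthetic workspace

All tests run offline on generated data (`fixture_spec()`,
`make_fixture_workspace()`). The generator reproduces the *structural*
properties the model exploits:

* a rooted taxonomy whose concept names are compositional — a child's name
  is its own modifier word followed by its parent's name;
* each content word is a "synonym group" of interchangeable surface forms;
  fixture word vectors place group members near a shared centroid
  (within-group cosine >= 0.8), emulating pretrained embeddings of
  synonymous words;
* ontology synonyms substitute alternative training forms slot-by-slot,
  while *held-out paraphrases* use forms reserved for evaluation — solvable
  only through word-vector proximity, never by memorization;
* documents embed mentions inside filler sentences from a disjoint
  vocabulary, with the gold concept set recorded per document; the negative
  corpus is drawn from a further disjoint vocabulary.

Default sizes are desk-scale by intent: 30 concepts, 3 synonyms per concept,
word vectors of dimension 25, concept/filter dimensions 64, 50-100 epochs at
batch 32, 3-seed ensembles, 10 documents. On that study the held-out R@1
(averaged over three seeds) is around 0.85-0.9 and R@5 is 1.0, and the
recognition pipeline reaches micro F1 around 0.8-0.9 with extended F1 higher
still — the acceptance script recomputes all of these from scratch at run
time rather than quoting them.

What the generator does *not* emulate — and what passing tests therefore do
not show — includes: real lexical morphology (fastText subword effects),
clinical register, negation and uncertainty ("no heart defect" is
annotated), abbreviations, cross-sentence mentions, and the sheer class
count of a real ontology. The published full-scale benchmark numbers are
not reproducible from this package without the external corpora.

A note on calibration discovered while building the worked-sentence test:
with a negative corpus whose vocabulary is fully disjoint from the
ontology's, sub-spans of a trained surface ("conotruncal heart" inside
"conotruncal heart defect") score almost as high as the full surface, and
the same-concept rule then prefers the smaller span. Negatives drawn from a
corpus that — like any encyclopedia — also contains ontology words in
non-mention contexts teach the NONE class to absorb such fragments, after
which the full surface wins cleanly. The hand-built English test world uses
such a corpus (verified never to contain a real surface form); the generator
keeps its vocabularies disjoint, which is the cleaner default for unit
tests.

## Limitations

* Bag-of-words encoding cannot distinguish phrases that differ only in word
  order.
* Zero-vector OOV handling (the default) collapses all unknown words to one
  point; the deterministic hash-random policy is available for ablations,
  and true subword inference is out of scope.
* Overlap resolution is greedy pairwise, deterministic but not globally
  optimal; only its pairwise behavior is specified.
* Annotation is span-local: no negation handling, no document context
  beyond the n-gram.
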