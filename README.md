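# neurodict

Ontology concept recognition in free text with a neural dictionary.

Clinical and biomedical vocabularies (the Human Phenotype Ontology,
SNOMED-CT, ...) give every concept a name, some synonyms and is_a relations
— but never every way a clinician actually writes a concept. Rule-based
annotators cannot match unseen synonyms, and supervised taggers need
annotated corpora covering tens of thousands of classes. `neurodict` trains
a ranking model **on the ontology alone**: every name/synonym is a training
example for its concept, pretrained word vectors supply the lexical
generalization, and the taxonomy supplies a structural prior on the concept
embeddings. The package is aimed at text-mining methodologists who want a
trainable, fully deterministic concept recognizer plus the evaluation suite
that goes with it.

## The model

A phrase with word vectors `x^(1..T)` is encoded by a width-one convolution,
max-over-time pooling and a dense head:

    v = max_t ELU(W x^(t) + b)
    e = l2norm(ReLU(U v))

Concepts are scored by `softmax(H e + bias)`. `H` is not learned directly:
the model learns raw per-concept offsets `H_raw` and composes

    H = A %*% H_raw

through the sparse **ancestry matrix** `A`, in which row *i* is the unit
vector on concept *i* plus the mean of its parents' rows (so `A[i, j] != 0`
only when *j* is an ancestor of *i*, and a diamond gives coefficients
`{1, 0.5, 0.5, 1}`). Each concept therefore learns only its displacement
from its parents. A dummy NONE class, trained on random n-grams from an
unrelated corpus, absorbs phrases matching no concept. Documents are
annotated by scoring all 1-7-token sentence n-grams, thresholding the
softmax score, and resolving overlaps (same concept: keep the smaller span;
different concepts: keep the longer, more specific span).

Training: cross-entropy with Adam (learning rate 0.002, batch 256, 100
epochs at full scale), per-epoch reshuffling, frozen word vectors,
seed-exact reproducibility, and probability-averaged ensembles across
seeds. The two ablation switches (`use_hierarchy`, `use_negatives`) and
their published operating thresholds are exposed via `variant_config()`.

## Worked example

Everything below runs on a generated workspace: a 30-concept taxonomy with
compositional names, 3 word-substitution synonyms per concept, matched
word vectors (synonym groups near shared centroids), documents with planted
mentions, and a held-out paraphrase set whose surface forms never occur in
training.

```r
library(neurodict)

spec <- fixture_spec(n_concepts = 30, word_dim = 25, seed = 0)
ws   <- make_fixture_workspace(spec)

pos  <- build_training_set(ws$ontology)
neg  <- sample_negatives(ws$negative_corpus, length(pos), seed = 0)
cfg  <- model_config(word_dim = 25, concept_dim = 64, conv_filters = 64, seed = 0)
plan <- train_plan(epochs = 100, batch_size = 32, ensemble_size = 3, seeds = 0:2)
ens  <- train_ensemble(cfg, plan, ws$ontology, ws$word_vectors, pos, neg)

recall_at_k(ens, ws$heldout, 1)   # 1.0  -- unseen paraphrases, top-1
recall_at_k(ens, ws$heldout, 5)   # 1.0

th <- select_threshold(ens, ws$corpus$documents[1:5], ws$corpus$gold[1:5],
                       grid = seq(0.3, 0.95, 0.05))
th                                # 0.4

annotate_text(ens, ws$corpus$documents[[6]], threshold = th, doc_id = "doc006")
#>   doc_id start end                                    text concept score
#> 1 doc006    46  61                         lex004a lex001a TC:0004 0.417
#> 2 doc006    90 129 lex022a lex017a lex008b lex006c lex001c TC:0022 0.709
#> 3 doc006   158 189         lex024b lex012c lex004c lex001c TC:0024 0.734
ws$corpus$gold[["doc006"]]
#> [1] "TC:0004" "TC:0022" "TC:0024"
```

The three annotations are exactly the three planted mentions: the model
recovered each concept from a synonym or name variant, rejected all filler
spans via the NONE class and the threshold, and the overlap resolver reduced
each mention region to a single span. Evaluating documents 6-10 against
their gold sets:

```r
docs <- lapply(names(ws$corpus$documents)[6:10], function(id) {
  a <- annotate_text(ens, ws$corpus$documents[[id]], threshold = th, doc_id = id)
  document_eval(id, a$concept, ws$corpus$gold[[id]])
})
eval_report(docs, ws$ontology)
#> evaluation over 5 documents
#>   micro    P 0.8571  R 0.8000  F1 0.8276
#>   macro    P 0.8333  R 0.8000  F1 0.8163
#>   extended P 0.9730  R 0.9730  F1 0.9730  Jaccard 0.9474
```

The extended metrics credit ancestor-level agreement: most residual errors
confuse a concept with a taxonomic neighbour, so F1 rises from 0.83 to 0.97
when each set is closed under ancestors.

Real data enter through the same interfaces: `parse_obo()` for the
ontology, `load_word_vectors()` for word2vec-format text vectors,
`cmd_annotate()`/`cmd_evaluate()` (or the `inst/cli/neurodict.R` script) for
documents and gold files, and `build_closed_subset()` to carve an
ancestor-closed training subset out of a large terminology.

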