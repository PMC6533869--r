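#' Fixture specification
#'
#' Parameters of the synthetic workspace generator. Everything produced from
#' a spec is a pure function of the spec (including `seed`); regeneration is
#' bitwise identical.
#'
#' The generated world mimics the structure the model exploits in real
#' ontologies: concept names are compositional (a child's name is its own
#' modifier word followed by its parent's name, like "conotruncal" +
#' "heart defect"), each content word is one of several interchangeable
#' surface forms ("synonym group") whose fixture word vectors lie close
#' together, synonyms substitute alternative forms word-by-word, and
#' held-out paraphrases use forms never seen in training — so a model can
#' only solve them through word-vector proximity, not memorization.
#'
#' @param n_concepts number of concepts (>= 1).
#' @param branching maximum children per node in the taxonomy tree.
#' @param synonyms_per_concept synonyms to attach per concept (where the
#'   form combinatorics allow).
#' @param n_forms surface forms per synonym group.
#' @param train_forms how many of the forms may appear in names/synonyms;
#'   the remaining `n_forms - train_forms` are reserved for held-out
#'   paraphrases.
#' @param multi_parent_rate probability that a non-root concept receives a
#'   second parent (creating a DAG rather than a tree).
#' @param vocab_size size of the filler and of the negative vocabularies.
#' @param word_dim fixture word-vector dimensionality.
#' @param n_docs documents in the annotated corpus.
#' @param mentions_per_doc concept mentions embedded per document.
#' @param seed integer seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_concepts = 30L, branching = 3L,
                         synonyms_per_concept = 3L, n_forms = 5L,
                         train_forms = 3L, multi_parent_rate = 0,
                         vocab_size = 50L, word_dim = 25L, n_docs = 10L,
                         mentions_per_doc = 3L, seed = 0L) {
  stopifnot(n_concepts >= 1L, branching >= 1L, synonyms_per_concept >= 0L,
            n_forms >= 1L, train_forms >= 1L, train_forms <= n_forms,
            vocab_size >= 1L, word_dim >= 1L, n_docs >= 0L,
            mentions_per_doc >= 0L)
  structure(list(n_concepts = as.integer(n_concepts),
                 branching = as.integer(branching),
                 synonyms_per_concept = as.integer(synonyms_per_concept),
                 n_forms = as.integer(n_forms),
                 train_forms = as.integer(train_forms),
                 multi_parent_rate = multi_parent_rate,
                 vocab_size = as.integer(vocab_size),
                 word_dim = as.integer(word_dim),
                 n_docs = as.integer(n_docs),
                 mentions_per_doc = as.integer(mentions_per_doc),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

lexeme_forms <- function(i, n_forms) {
  sprintf("lex%03d%s", i, letters[seq_len(n_forms)])
}

#' Generate a toy ontology with compositional synonyms
#'
#' Builds a rooted taxonomy (tree, plus optional extra multi-parent edges)
#' of `spec$n_concepts` concepts. Concept `i` owns synonym group `i` of
#' `spec$n_forms` interchangeable word forms. The canonical name of a
#' concept is form 1 of its own group followed by its (first) parent's name
#' tokens; synonyms replace each word slot with a random form among the
#' first `spec$train_forms` forms of the slot's group.
#'
#' The synonym-group structure is attached as `attr(ont, "lexicon")` and is
#' shared with [fixture_word_vectors()] and [make_heldout_phrases()].
#'
#' @param spec a [fixture_spec()].
#' @return An [ontology()] with a `lexicon` attribute (`groups`: list of
#'   form vectors; `slots`: list concept id -> group indices of its name
#'   slots; `train_forms`).
#' @export
make_toy_ontology <- function(spec) {
  n <- spec$n_concepts
  ids <- sprintf("TC:%04d", seq_len(n))
  groups <- lapply(seq_len(n), lexeme_forms, n_forms = spec$n_forms)
  withr_seed(spec$seed, {
    parents <- vector("list", n)
    slots <- vector("list", n) # group indices: own modifier first, then parent's
    child_count <- integer(n)
    slots[[1L]] <- 1L
    for (i in seq_len(n)[-1L]) {
      eligible <- which(child_count[seq_len(i - 1L)] < spec$branching)
      if (length(eligible) == 0L) {
        stop("branching limit too small to place concept ", i)
      }
      p <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      child_count[p] <- child_count[p] + 1L
      parents[[i]] <- ids[p]
      slots[[i]] <- c(i, slots[[p]])
      if (spec$multi_parent_rate > 0 && i > 2L &&
          stats::runif(1) < spec$multi_parent_rate) {
        extra <- setdiff(seq_len(i - 1L), p)
        if (length(extra) > 0L) {
          q <- if (length(extra) == 1L) extra else sample(extra, 1L)
          parents[[i]] <- c(parents[[i]], ids[q])
        }
      }
    }
    surface <- function(slot_idx, form_choice) {
      paste(vapply(seq_along(slot_idx),
                   function(k) groups[[slot_idx[k]]][form_choice[k]],
                   character(1)),
            collapse = " ")
    }
    nms <- character(n)
    syns <- vector("list", n)
    for (i in seq_len(n)) {
      k <- length(slots[[i]])
      nms[i] <- surface(slots[[i]], rep(1L, k))
      have <- character()
      tries <- 0L
      while (length(have) < spec$synonyms_per_concept && tries < 100L) {
        tries <- tries + 1L
        cand <- surface(slots[[i]],
                        sample.int(spec$train_forms, k, replace = TRUE))
        if (cand != nms[i] && !cand %in% have) have <- c(have, cand)
      }
      syns[[i]] <- have
    }
    ont <- ontology(stats::setNames(nms, ids),
                    parents = stats::setNames(parents, ids),
                    synonyms = stats::setNames(syns, ids))
    attr(ont, "lexicon") <- list(groups = groups,
                                 slots = stats::setNames(slots, ids),
                                 train_forms = spec$train_forms)
    ont
  })
}

filler_vocab <- function(spec) sprintf("fill%04d", seq_len(spec$vocab_size))

#' Fixture word vectors matched to a toy ontology
#'
#' Builds a deterministic word-vector table covering the ontology's synonym
#' groups (group members near a shared centroid, emulating pretrained
#' vectors mapping synonyms close together), the filler vocabulary used in
#' generated documents, and any extra tokens (e.g. a negative corpus
#' vocabulary) as independent random unit vectors.
#'
#' @param ont a toy ontology from [make_toy_ontology()].
#' @param spec the [fixture_spec()] used to build `ont`.
#' @param extra_vocab additional tokens to cover.
#' @return A `word_vector_table`.
#' @export
fixture_word_vectors <- function(ont, spec, extra_vocab = character()) {
  lex <- attr(ont, "lexicon")
  if (is.null(lex)) stop("ontology has no lexicon attribute; use make_toy_ontology()")
  vocab <- c(unlist(lex$groups, use.names = FALSE), filler_vocab(spec),
             extra_vocab)
  make_fixture_vectors(vocab, dim = spec$word_dim, seed = spec$seed + 1L,
                       groups = lex$groups)
}

#' Generate an annotated document corpus
#'
#' Each document consists of filler sentences (from a vocabulary disjoint
#' from the ontology's) with `spec$mentions_per_doc` concept mentions
#' embedded, one per sentence, surrounded by filler words. A mention's
#' surface form is the concept's name or one of its synonyms (source
#' `"train"`), or a held-out paraphrase (source `"heldout"`). The gold
#' record of a document is the set of concepts mentioned in it.
#'
#' @param ont a toy ontology from [make_toy_ontology()].
#' @param spec the [fixture_spec()] used to build `ont`.
#' @param source where mention surfaces come from: `"train"` or `"heldout"`.
#' @param seed_offset added to `spec$seed` so several corpora (e.g. a
#'   validation and a test split) can be drawn from one spec.
#' @return A list with `documents` (named character vector, doc_id -> text)
#'   and `gold` (named list, doc_id -> character vector of concept ids).
#' @export
make_annotated_corpus <- function(ont, spec, source = c("train", "heldout"),
                                  seed_offset = 2L) {
  source <- match.arg(source)
  lex <- attr(ont, "lexicon")
  if (is.null(lex)) stop("ontology has no lexicon attribute; use make_toy_ontology()")
  fills <- filler_vocab(spec)
  n <- length(ont$ids)
  withr_seed(spec$seed + seed_offset, {
    docs <- character(spec$n_docs)
    gold <- vector("list", spec$n_docs)
    doc_ids <- sprintf("doc%03d", seq_len(spec$n_docs))
    for (d in seq_len(spec$n_docs)) {
      k <- min(spec$mentions_per_doc, n)
      cids <- if (k > 0L) ont$ids[sample.int(n, k)] else character()
      sentences <- character()
      for (cid in cids) {
        surf <- if (source == "train") {
          forms <- c(ont$names[[cid]], ont$synonyms[[cid]])
          forms[sample.int(length(forms), 1L)]
        } else {
          paste(heldout_tokens(lex, cid), collapse = " ")
        }
        pre <- fills[sample.int(length(fills), 2L)]
        post <- fills[sample.int(length(fills), 1L)]
        sentences <- c(sentences, paste(c(pre, surf, post), collapse = " "))
      }
      # plain filler sentences on either side
      pad <- function() paste(fills[sample.int(length(fills), 3L)], collapse = " ")
      docs[d] <- paste0(paste(c(pad(), sentences, pad()), collapse = ". "), ".")
      gold[[d]] <- sort(unique(cids))
    }
    list(documents = stats::setNames(docs, doc_ids),
         gold = stats::setNames(gold, doc_ids))
  })
}

# one random held-out paraphrase (token vector) for a concept
heldout_tokens <- function(lex, cid) {
  slot_idx <- lex$slots[[cid]]
  vapply(slot_idx, function(g) {
    forms <- lex$groups[[g]]
    held <- forms[seq.int(lex$train_forms + 1L, length(forms))]
    held[sample.int(length(held), 1L)]
  }, character(1))
}

#' Generate held-out paraphrases for synonym-classification tests
#'
#' For each concept, draws paraphrases in which every word slot uses a
#' surface form reserved for evaluation (never present in any training name
#' or synonym). Duplicate paraphrases within a concept are dropped.
#'
#' @param ont a toy ontology from [make_toy_ontology()].
#' @param per_concept paraphrases to draw per concept.
#' @param seed integer seed.
#' @return A list of records with `tokens` and `label`, usable directly
#'   with [recall_at_k()].
#' @export
make_heldout_phrases <- function(ont, per_concept = 2L, seed = 0L) {
  lex <- attr(ont, "lexicon")
  if (is.null(lex)) stop("ontology has no lexicon attribute; use make_toy_ontology()")
  if (lex$train_forms >= length(lex$groups[[1L]])) {
    stop("fixture spec reserved no held-out forms (train_forms == n_forms)")
  }
  withr_seed(seed, {
    out <- list()
    for (cid in ont$ids) {
      seen <- character()
      tries <- 0L
      while (length(seen) < per_concept && tries < 50L) {
        tries <- tries + 1L
        toks <- heldout_tokens(lex, cid)
        key <- paste(toks, collapse = " ")
        if (!key %in% seen) {
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- list(tokens = toks, label = cid)
        }
      }
    }
    out
  })
}

#' Generate a negative-example corpus
#'
#' A token stream drawn from a vocabulary disjoint from both the ontology
#' synonym groups and the document filler words, standing in for the
#' out-of-domain text (e.g. an encyclopedia dump) from which NONE-labelled
#' negatives are sampled.
#'
#' @param spec a [fixture_spec()].
#' @return A character vector of at least `10 * spec$vocab_size` tokens.
#' @export
make_negative_corpus <- function(spec) {
  vocab <- sprintf("neg%04d", seq_len(spec$vocab_size))
  withr_seed(spec$seed + 3L, {
    vocab[sample.int(spec$vocab_size, 10L * spec$vocab_size, replace = TRUE)]
  })
}

#' Generate a complete synthetic workspace
#'
#' Convenience wrapper bundling everything the pipeline needs: the toy
#' ontology, matched word vectors (covering ontology, filler and negative
#' vocabulary), a training-surface annotated corpus, a held-out paraphrase
#' set and a negative corpus.
#'
#' @param spec a [fixture_spec()].
#' @param heldout_per_concept paraphrases per concept.
#' @return A list with `ontology`, `word_vectors`, `corpus`, `heldout`,
#'   `negative_corpus` and `spec`.
#' @export
make_fixture_workspace <- function(spec = fixture_spec(),
                                   heldout_per_concept = 2L) {
  ont <- make_toy_ontology(spec)
  negs <- make_negative_corpus(spec)
  wv <- fixture_word_vectors(ont, spec, extra_vocab = unique(negs))
  corpus <- make_annotated_corpus(ont, spec, source = "train")
  heldout <- make_heldout_phrases(ont, per_concept = heldout_per_concept,
                                  seed = spec$seed + 4L)
  list(ontology = ont, word_vectors = wv, corpus = corpus,
       heldout = heldout, negative_corpus = negs, spec = spec)
}
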