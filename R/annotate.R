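#' Tokenize a phrase
#'
#' The package-wide token convention: lowercase, then maximal runs of
#' letters and digits (all punctuation discarded). Used for ontology
#' surface forms, query phrases and documents alike, so training and
#' inference see identical token streams.
#'
#' @param s a character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_phrase <- function(s) {
  s <- tolower(s)
  m <- gregexpr("[a-z0-9]+", s)[[1L]]
  if (m[1L] == -1L) return(character())
  regmatches(s, list(m))[[1L]]
}

#' Tokenize a document
#'
#' Lowercases the text, splits sentences on `.`, `?`, `!` or `;` followed by
#' whitespace (or end of text), and extracts tokens as maximal runs of
#' letters and digits; punctuation is discarded. Character offsets are
#' 0-based half-open positions into the original string.
#'
#' @param text a character scalar.
#' @param doc_id document identifier carried through to annotations.
#' @return An object of class `tokenized_document`: a list with `doc_id`,
#'   `tokens`, `sentence` (sentence index per token), `start`/`end`
#'   (character offsets per token) and `n_sentences`.
#' @export
tokenize_document <- function(text, doc_id = "doc") {
  stopifnot(is.character(text), length(text) == 1L)
  lower <- tolower(text)
  tm <- gregexpr("[a-z0-9]+", lower)[[1L]]
  if (tm[1L] == -1L) {
    return(structure(list(doc_id = doc_id, tokens = character(),
                          sentence = integer(), start = integer(),
                          end = integer(), n_sentences = 0L),
                     class = "tokenized_document"))
  }
  tok_start <- as.integer(tm)
  tok_len <- attr(tm, "match.length")
  tokens <- regmatches(lower, list(tm))[[1L]]
  bm <- gregexpr("[.?!;](?=\\s|$)", text, perl = TRUE)[[1L]]
  bounds <- if (bm[1L] == -1L) integer() else as.integer(bm)
  sentence <- vapply(tok_start, function(s) 1L + sum(bounds < s), integer(1))
  sentence <- as.integer(factor(sentence)) # renumber densely
  structure(list(doc_id = doc_id, tokens = tokens, sentence = sentence,
                 start = tok_start - 1L, end = tok_start - 1L + tok_len,
                 n_sentences = if (length(sentence)) max(sentence) else 0L),
            class = "tokenized_document")
}

#' Enumerate candidate n-gram spans
#'
#' Lists every contiguous within-sentence token span of `min_len` to
#' `max_len` tokens, each exactly once. Spans never cross sentence
#' boundaries. The default 1..7 window is the scan range used for concept
#' recognition in running text.
#'
#' @param doc a `tokenized_document`.
#' @param min_len,max_len span length bounds in tokens.
#' @return A data frame with columns `sentence`, `first`, `last` (global
#'   token indices, inclusive).
#' @export
extract_ngrams <- function(doc, min_len = 1L, max_len = 7L) {
  stopifnot(min_len >= 1L, min_len <= max_len)
  out <- list()
  for (s in seq_len(doc$n_sentences)) {
    idx <- which(doc$sentence == s)
    nt <- length(idx)
    for (len in min_len:min(max_len, nt)) {
      firsts <- idx[seq_len(nt - len + 1L)]
      out[[length(out) + 1L]] <- data.frame(sentence = s, first = firsts,
                                            last = firsts + len - 1L)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(sentence = integer(), first = integer(), last = integer()))
  }
  do.call(rbind, out)
}

as_model_list <- function(model_or_ensemble) {
  if (inherits(model_or_ensemble, "neural_dictionary")) {
    list(model_or_ensemble)
  } else {
    stopifnot(length(model_or_ensemble) > 0L,
              all(vapply(model_or_ensemble, inherits, logical(1),
                         "neural_dictionary")))
    model_or_ensemble
  }
}

# Ensemble-averaged probability matrix over a list of phrases.
ensemble_prob_matrix <- function(models, phrase_list) {
  mats <- lapply(models, score_phrases_matrix, phrase_list = phrase_list)
  Reduce(`+`, mats) / length(mats)
}

#' Score candidate spans with the (ensemble) model
#'
#' Every span is matched to its best non-NONE concept with the
#' ensemble-averaged softmax probability as score. Spans whose overall best
#' row is the NONE class still report their best concept here — the
#' threshold filter is what removes them downstream.
#'
#' @param model_or_ensemble a `neural_dictionary` or list of them.
#' @param doc a `tokenized_document`.
#' @param spans a span data frame from [extract_ngrams()].
#' @return A data frame of candidates: `sentence`, `first`, `last`,
#'   `concept`, `score`.
#' @export
score_spans <- function(model_or_ensemble, doc, spans) {
  models <- as_model_list(model_or_ensemble)
  if (nrow(spans) == 0L) {
    return(data.frame(sentence = integer(), first = integer(),
                      last = integer(), concept = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  phrases <- lapply(seq_len(nrow(spans)),
                    function(i) doc$tokens[spans$first[i]:spans$last[i]])
  P <- ensemble_prob_matrix(models, phrases)
  ids <- colnames(P)
  keep <- ids != NONE_LABEL
  Pc <- P[, keep, drop = FALSE]
  cids <- ids[keep]
  ord <- order(cids, method = "radix") # lexicographic tie-break via first max
  Pc <- Pc[, ord, drop = FALSE]
  cids <- cids[ord]
  best <- max.col(Pc, ties.method = "first")
  data.frame(sentence = spans$sentence, first = spans$first,
             last = spans$last, concept = cids[best],
             score = Pc[cbind(seq_len(nrow(Pc)), best)],
             stringsAsFactors = FALSE)
}

#' Filter candidates by score threshold
#'
#' Keeps exactly the candidates whose softmax score is at least the
#' threshold. The published defaults per ablation variant are available
#' through [variant_config()] (0.85 for the full model; 0.8 without the
#' hierarchy; 0.8 without negatives; 0.75 with neither).
#'
#' @param candidates candidate data frame from [score_spans()].
#' @param threshold a value in `[0, 1]`.
#' @return The surviving rows of `candidates`.
#' @export
filter_by_threshold <- function(candidates, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("`threshold` must be a single value in [0, 1]")
  }
  candidates[candidates$score >= threshold, , drop = FALSE]
}

spans_overlap <- function(c1, c2) {
  c1$sentence == c2$sentence && c1$first <= c2$last && c2$first <= c1$last
}

# Given two overlapping candidates (rows i, j of df), return the index to DROP.
overlap_loser <- function(df, i, j) {
  len_i <- df$last[i] - df$first[i]
  len_j <- df$last[j] - df$first[j]
  if (df$concept[i] == df$concept[j]) {
    # same concept: retain the smaller n-gram
    if (len_i != len_j) return(if (len_i > len_j) i else j)
  } else if (len_i != len_j) {
    # different concepts: choose the longer n-gram
    return(if (len_i < len_j) i else j)
  }
  # equal lengths: drop the lower score, then the larger concept id
  if (df$score[i] != df$score[j]) return(if (df$score[i] < df$score[j]) i else j)
  if (df$concept[i] != df$concept[j]) {
    return(if (df$concept[i] > df$concept[j]) i else j)
  }
  j
}

#' Resolve overlapping candidate spans
#'
#' Applies the pairwise consistency rules to a fixed point: when two
#' surviving spans overlap and match the same concept, the smaller n-gram is
#' retained; when they match different concepts, the longer n-gram is
#' retained (favouring the more specific concept, as in "conotruncal heart
#' defect" over "heart defect"); equal-length conflicts are settled by
#' higher score, then lexicographically smaller concept id. Candidates are
#' processed in a deterministic order (sentence, start, end, concept), so
#' the result does not depend on input order.
#'
#' @param candidates candidate data frame (one document).
#' @return The pairwise non-overlapping surviving candidates.
#' @export
resolve_overlaps <- function(candidates) {
  df <- candidates[order(candidates$sentence, candidates$first,
                         candidates$last, candidates$concept,
                         method = "radix"), , drop = FALSE]
  repeat {
    n <- nrow(df)
    dropped <- FALSE
    for (i in seq_len(max(n - 1L, 0L))) {
      for (j in (i + 1L):n) {
        if (i >= j || j > n) break
        if (df$sentence[j] != df$sentence[i] || df$first[j] > df$last[i]) break
        loser <- overlap_loser(df, i, j)
        df <- df[-loser, , drop = FALSE]
        dropped <- TRUE
        break
      }
      if (dropped) break
    }
    if (!dropped) break
  }
  rownames(df) <- NULL
  df
}

#' Annotate free text with ontology concepts
#'
#' Full recognition pipeline: tokenize, enumerate all 1..`max_len`-token
#' within-sentence n-grams, score each against the (ensemble) model, drop
#' candidates below the score threshold, and resolve overlaps. Character
#' spans are 0-based half-open offsets into the original text.
#'
#' @param model_or_ensemble a `neural_dictionary` or list of them.
#' @param text character scalar to annotate.
#' @param threshold minimum softmax score (see [filter_by_threshold()]).
#' @param doc_id document id for the output rows.
#' @param min_len,max_len n-gram scan range in tokens.
#' @return A data frame of annotations: `doc_id`, `start`, `end`, `text`,
#'   `concept`, `score`, sorted by start offset; pairwise non-overlapping.
#' @export
annotate_text <- function(model_or_ensemble, text, threshold = 0.85,
                          doc_id = "doc", min_len = 1L, max_len = 7L) {
  doc <- tokenize_document(text, doc_id)
  empty <- data.frame(doc_id = character(), start = integer(),
                      end = integer(), text = character(),
                      concept = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(doc$tokens) == 0L) return(empty)
  spans <- extract_ngrams(doc, min_len, max_len)
  cand <- score_spans(model_or_ensemble, doc, spans)
  cand <- filter_by_threshold(cand, threshold)
  if (nrow(cand) == 0L) return(empty)
  kept <- resolve_overlaps(cand)
  out <- data.frame(
    doc_id = doc_id,
    start = doc$start[kept$first],
    end = doc$end[kept$last],
    concept = kept$concept,
    score = kept$score,
    stringsAsFactors = FALSE
  )
  out$text <- substr(rep(text, nrow(out)), out$start + 1L, out$end)
  out <- out[order(out$start, out$end, method = "radix"),
             c("doc_id", "start", "end", "text", "concept", "score")]
  rownames(out) <- NULL
  out
}

#' Write / read annotation tables
#'
#' Tab-separated with columns `doc_id`, `start`, `end`, `matched_text`,
#' `concept_id`, `score`.
#'
#' @param annotations annotation data frame from [annotate_text()].
#' @param path file path.
#' @return `path` invisibly (write); a data frame (read).
#' @export
write_annotations <- function(annotations, path) {
  df <- annotations
  names(df) <- c("doc_id", "start", "end", "matched_text", "concept_id", "score")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "",
                    colClasses = c("character", "integer", "integer",
                                   "character", "character", "numeric"))
}
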