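#' Per-document evaluation record
#'
#' Pairs the set of concepts reported by the annotator for a document with
#' the gold label set for that document.
#'
#' @param doc_id document id.
#' @param reported character vector of reported concept ids (R_d).
#' @param labels character vector of gold concept ids (L_d).
#' @return A list of class `document_eval`.
#' @export
document_eval <- function(doc_id, reported, labels) {
  structure(list(doc_id = doc_id,
                 reported = unique(as.character(reported)),
                 labels = unique(as.character(labels))),
            class = "document_eval")
}

f1_of <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

# denominator-zero convention: a ratio with an empty denominator is 1.0
# (stated for the macro metrics; mirrored for the micro metrics so every
# metric is total)
safe_ratio <- function(num, den) if (den == 0) 1 else num / den

#' Micro precision / recall / F1
#'
#' Counts are pooled over all documents: precision is
#' `sum |R_d intersect L_d| / sum |R_d|`, recall is
#' `sum |R_d intersect L_d| / sum |L_d|`; an empty pooled denominator makes
#' that component 1.0.
#'
#' @param docs non-empty list of [document_eval()] records.
#' @return A named list `(precision, recall, f1)`.
#' @export
micro_metrics <- function(docs) {
  stopifnot(length(docs) > 0L)
  hits <- sum(vapply(docs, function(d) length(intersect(d$reported, d$labels)),
                     numeric(1)))
  p <- safe_ratio(hits, sum(vapply(docs, function(d) length(d$reported), numeric(1))))
  r <- safe_ratio(hits, sum(vapply(docs, function(d) length(d$labels), numeric(1))))
  list(precision = p, recall = r, f1 = f1_of(p, r))
}

#' Macro precision / recall / F1
#'
#' Per-document precision `|R_d intersect L_d| / |R_d|` and recall
#' `|R_d intersect L_d| / |L_d|` are averaged across documents. A document
#' with an empty reported set contributes precision 1.0, and one with an
#' empty label set contributes recall 1.0.
#'
#' @inheritParams micro_metrics
#' @return A named list `(precision, recall, f1)`.
#' @export
macro_metrics <- function(docs) {
  stopifnot(length(docs) > 0L)
  ps <- vapply(docs, function(d) {
    safe_ratio(length(intersect(d$reported, d$labels)), length(d$reported))
  }, numeric(1))
  rs <- vapply(docs, function(d) {
    safe_ratio(length(intersect(d$reported, d$labels)), length(d$labels))
  }, numeric(1))
  p <- mean(ps); r <- mean(rs)
  list(precision = p, recall = r, f1 = f1_of(p, r))
}

#' Ancestor-extended metrics and Jaccard index
#'
#' Both the reported and the label set of each document are extended to
#' include all their ancestor concepts; micro-pooled precision, recall and
#' F1 are then computed over the extended sets, along with the pooled
#' Jaccard index `sum |E(R_d) intersect E(L_d)| / sum |E(R_d) union E(L_d)|`.
#' This credits a prediction that lands near the gold concept in the
#' taxonomy even when the exact id differs.
#'
#' @inheritParams micro_metrics
#' @param ont the evaluation [ontology()]; every id in `docs` must resolve.
#' @return A named list `(precision, recall, f1, jaccard)`.
#' @export
extended_metrics <- function(docs, ont) {
  stopifnot(length(docs) > 0L)
  ext <- function(s) {
    if (length(s) == 0L) return(character())
    unique(unlist(lapply(s, function(id) ancestors(ont, id)), use.names = FALSE))
  }
  hits <- 0; nr <- 0; nl <- 0; nu <- 0
  for (d in docs) {
    er <- ext(d$reported); el <- ext(d$labels)
    hits <- hits + length(intersect(er, el))
    nr <- nr + length(er)
    nl <- nl + length(el)
    nu <- nu + length(union(er, el))
  }
  p <- safe_ratio(hits, nr)
  r <- safe_ratio(hits, nl)
  list(precision = p, recall = r, f1 = f1_of(p, r),
       jaccard = safe_ratio(hits, nu))
}

#' Full evaluation report
#'
#' Computes the complete metric suite — micro, macro and ancestor-extended
#' precision/recall/F1 plus the Jaccard index — for a document collection.
#'
#' @inheritParams extended_metrics
#' @return A list of class `eval_report` with elements `micro`, `macro`,
#'   `extended`.
#' @export
eval_report <- function(docs, ont) {
  structure(list(micro = micro_metrics(docs),
                 macro = macro_metrics(docs),
                 extended = extended_metrics(docs, ont),
                 n_docs = length(docs)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) sprintf("%.4f", v)
  cat("evaluation over", x$n_docs, "documents\n")
  cat("  micro    P", fmt(x$micro$precision), " R", fmt(x$micro$recall),
      " F1", fmt(x$micro$f1), "\n")
  cat("  macro    P", fmt(x$macro$precision), " R", fmt(x$macro$recall),
      " F1", fmt(x$macro$f1), "\n")
  cat("  extended P", fmt(x$extended$precision), " R", fmt(x$extended$recall),
      " F1", fmt(x$extended$f1), " Jaccard", fmt(x$extended$jaccard), "\n")
  invisible(x)
}

#' Recall at k for isolated phrases
#'
#' The synonym-classification protocol: each phrase is scored against all
#' concepts and counts as recalled if its gold concept appears among the
#' top k ranked (non-NONE) concepts of the ensemble-averaged distribution.
#'
#' @param model_or_ensemble a `neural_dictionary` or list of them.
#' @param phrases non-empty list of records, each with `tokens` (character
#'   vector) and `label` (gold concept id).
#' @param k rank cutoff (>= 1).
#' @return The fraction of phrases recalled, in `[0, 1]`.
#' @export
recall_at_k <- function(model_or_ensemble, phrases, k = 1L) {
  stopifnot(length(phrases) > 0L, k >= 1L)
  models <- as_model_list(model_or_ensemble)
  ids <- models[[1L]]$ids
  golds <- vapply(phrases, function(p) p$label, character(1))
  bad <- setdiff(golds, ids)
  if (length(bad) > 0L) stop("unknown gold id(s): ", paste(unique(bad), collapse = ", "))
  P <- ensemble_prob_matrix(models, lapply(phrases, function(p) p$tokens))
  hits <- vapply(seq_along(phrases), function(i) {
    d <- structure(P[i, ], class = "score_distribution")
    golds[i] %in% top_k(d, k)$concept
  }, logical(1))
  mean(hits)
}

#' Select the annotation threshold on a validation set
#'
#' Annotates each validation document at every candidate threshold and
#' returns the grid value maximizing the micro F1 against the gold sets.
#' Span scoring is done once per document; only the filter and overlap
#' resolution are re-run per grid point. Ties are broken towards the
#' largest threshold (favouring precision).
#'
#' @param model_or_ensemble a `neural_dictionary` or list of them.
#' @param texts named character vector (or list), doc_id -> document text.
#' @param gold named list, doc_id -> character vector of gold concept ids.
#' @param grid numeric vector of candidate thresholds in `[0, 1]`; defaults
#'   to 0.05 steps over `[0.5, 0.95]`, which brackets the published
#'   per-variant thresholds.
#' @param min_len,max_len n-gram scan range.
#' @return The selected threshold (an element of `grid`).
#' @export
select_threshold <- function(model_or_ensemble, texts, gold,
                             grid = seq(0.5, 0.95, by = 0.05),
                             min_len = 1L, max_len = 7L) {
  stopifnot(length(grid) > 0L, all(grid >= 0 & grid <= 1))
  doc_ids <- names(texts)
  stopifnot(!is.null(doc_ids), all(doc_ids %in% names(gold)))
  cands <- lapply(doc_ids, function(id) {
    doc <- tokenize_document(texts[[id]], id)
    score_spans(model_or_ensemble, doc, extract_ngrams(doc, min_len, max_len))
  })
  f1s <- vapply(grid, function(th) {
    docs <- lapply(seq_along(doc_ids), function(i) {
      kept <- resolve_overlaps(filter_by_threshold(cands[[i]], th))
      document_eval(doc_ids[i], kept$concept, gold[[doc_ids[i]]])
    })
    micro_metrics(docs)$f1
  }, numeric(1))
  best <- max(f1s)
  max(grid[f1s == best]) # largest threshold among ties
}

#' Read a gold-annotation file
#'
#' Tab-separated with two columns: document id and a comma-separated list of
#' concept ids (which may be empty).
#'
#' @param path file path.
#' @return A named list, doc_id -> character vector of concept ids.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("cannot read gold file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    ids <- if (length(parts) < 2L || !nzchar(trimws(parts[2L]))) {
      character()
    } else {
      trimws(strsplit(parts[2L], ",", fixed = TRUE)[[1L]])
    }
    out[[trimws(parts[1L])]] <- ids
  }
  out
}

#' Write a gold-annotation file
#'
#' @param gold named list, doc_id -> character vector of concept ids.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  lines <- vapply(names(gold), function(id) {
    paste0(id, "\t", paste(gold[[id]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
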