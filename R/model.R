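#' Model configuration
#'
#' Collects the architecture hyperparameters of the neural dictionary. The
#' defaults are the full-scale values used for real ontologies (word vectors
#' of dimension 100, convolution with 1024 filters of width one word, dense
#' projection and concept embeddings of dimension 1024). Tests and fixtures
#' use much smaller dimensions.
#'
#' @param word_dim dimensionality of the input word vectors.
#' @param concept_dim dimensionality of the concept embeddings (also the
#'   output size of the dense layer).
#' @param conv_filters number of width-one convolution filters.
#' @param use_hierarchy if `TRUE`, final concept embeddings are composed
#'   through the taxonomy's ancestry matrix; if `FALSE` the ancestry matrix
#'   is effectively the identity and the model is a flat softmax classifier.
#' @param use_negatives if `TRUE`, the model carries an extra learnable
#'   "NONE" row trained on negative examples, so that phrases matching no
#'   concept can be absorbed by the dummy class.
#' @param seed integer seed for parameter initialization.
#' @return A list of class `model_config`.
#' @export
model_config <- function(word_dim = 100L, concept_dim = 1024L,
                         conv_filters = 1024L, use_hierarchy = TRUE,
                         use_negatives = TRUE, seed = 0L) {
  stopifnot(word_dim >= 1L, concept_dim >= 1L, conv_filters >= 1L)
  structure(list(word_dim = as.integer(word_dim),
                 concept_dim = as.integer(concept_dim),
                 conv_filters = as.integer(conv_filters),
                 use_hierarchy = isTRUE(use_hierarchy),
                 use_negatives = isTRUE(use_negatives),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Ablation variants of the neural dictionary
#'
#' The model has two switchable components — the taxonomy prior (ancestry
#' matrix) and the negative-sampled NONE class — giving four ablation
#' variants. Each variant has a published default score threshold for the
#' document annotator.
#'
#' @param variant one of `"full"` (hierarchy + negatives, threshold 0.85),
#'   `"flat"` (no hierarchy, negatives, 0.8), `"nonone"` (hierarchy, no
#'   negatives, 0.8), `"flat-nonone"` (neither, 0.75).
#' @return A list with `use_hierarchy`, `use_negatives` and `threshold`.
#' @export
variant_config <- function(variant = c("full", "flat", "nonone", "flat-nonone")) {
  variant <- match.arg(variant)
  switch(variant,
    "full" = list(use_hierarchy = TRUE, use_negatives = TRUE, threshold = 0.85),
    "flat" = list(use_hierarchy = FALSE, use_negatives = TRUE, threshold = 0.80),
    "nonone" = list(use_hierarchy = TRUE, use_negatives = FALSE, threshold = 0.80),
    "flat-nonone" = list(use_hierarchy = FALSE, use_negatives = FALSE,
                         threshold = 0.75))
}

# label used for the dummy class absorbing non-concept phrases
NONE_LABEL <- "NONE"

elu <- function(x, alpha = 1) {
  neg <- x <= 0
  x[neg] <- alpha * (exp(x[neg]) - 1)
  x
}

elu_grad <- function(x, alpha = 1) {
  g <- matrix(1, nrow = nrow(x), ncol = ncol(x))
  neg <- x <= 0
  g[neg] <- alpha * exp(x[neg])
  g
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

NORM_EPS <- 1e-12

#' Encode a phrase into the concept-embedding space
#'
#' Implements the phrase encoder: each word vector `x` is projected by the
#' width-one convolution `ELU(W x + b)`; the projected vectors are
#' aggregated with element-wise max-over-time pooling into `v`; a dense
#' layer with ReLU and l2 normalization maps `v` to the final embedding
#' `e = l2norm(ReLU(U v))`. Because the filters have width one and max
#' pooling is commutative, the encoding is invariant to token order.
#'
#' @param params a list with `W` (`conv_filters x word_dim`), `b`
#'   (`conv_filters`), `U` (`concept_dim x conv_filters`) — e.g. a trained
#'   `neural_dictionary` object.
#' @param token_vectors numeric matrix with one row per token and `word_dim`
#'   columns (a single vector is accepted for a one-word phrase).
#' @return A list with `pooled` (the max-pooled vector `v`) and `embedding`
#'   (the unit-norm vector `e`; all-zero if the ReLU output is all zero).
#' @export
encode_phrase <- function(params, token_vectors) {
  if (is.null(dim(token_vectors))) token_vectors <- matrix(token_vectors, nrow = 1L)
  if (nrow(token_vectors) == 0L) stop("phrase must contain at least one token")
  if (ncol(token_vectors) != ncol(params$W)) {
    stop("word-vector dimension ", ncol(token_vectors),
         " does not match encoder word_dim ", ncol(params$W))
  }
  z <- elu(token_vectors %*% t(params$W) +
             matrix(params$b, nrow(token_vectors), length(params$b), byrow = TRUE))
  v <- apply(z, 2L, max)
  r <- relu(as.numeric(params$U %*% v))
  n <- sqrt(sum(r^2))
  e <- if (n > NORM_EPS) r / n else r
  list(pooled = v, embedding = e)
}

# Batched forward pass of the encoder.
# X: (total tokens) x word_dim matrix; ex: integer vector assigning each row
# of X to an example (1..B, contiguous). Returns everything score/backprop
# need. Used by scoring and by the trainer.
encoder_forward <- function(W, b, U, X, ex) {
  B <- max(ex)
  Zpre <- X %*% t(W) + matrix(b, nrow(X), length(b), byrow = TRUE)
  Z <- elu(Zpre)
  F <- ncol(Z)
  V <- matrix(0, B, F)
  amax <- matrix(0L, B, F) # row index in X of the pooled maximum, per filter
  starts <- c(1L, which(diff(ex) != 0L) + 1L)
  ends <- c(starts[-1L] - 1L, length(ex))
  for (i in seq_len(B)) {
    rows <- starts[i]:ends[i]
    if (length(rows) == 1L) {
      V[i, ] <- Z[rows, ]
      amax[i, ] <- rows
    } else {
      sub <- Z[rows, , drop = FALSE]
      am <- max.col(t(sub), ties.method = "first")
      amax[i, ] <- rows[am]
      V[i, ] <- sub[cbind(am, seq_len(F))]
    }
  }
  Umat <- V %*% t(U)
  R <- relu(Umat)
  norms <- sqrt(rowSums(R^2))
  E <- R / pmax(norms, NORM_EPS)
  E[norms <= NORM_EPS, ] <- 0
  list(Zpre = Zpre, V = V, amax = amax, Umat = Umat, E = E, norms = norms)
}

#' Compose final concept embeddings through the ancestry matrix
#'
#' When the hierarchy is used, the final embedding matrix is `H = A %*% raw`,
#' so each concept's final embedding is the (parent-averaged) sum of its own
#' raw embedding and those of all its ancestors. When the hierarchy is
#' ignored the raw matrix is returned unchanged (the ancestry matrix is
#' treated as the identity). A trailing NONE row, if present, has no
#' taxonomy parents and always passes through unchanged.
#'
#' @param raw numeric matrix of raw embeddings; `n` concept rows (in the
#'   ancestry matrix's id order), optionally followed by one NONE row.
#' @param ancestry an `ancestry_matrix` from [build_ancestry_matrix()].
#' @param use_hierarchy logical flag.
#' @param has_none if `TRUE` the last row of `raw` is the NONE row.
#' @return A numeric matrix of the same shape as `raw`.
#' @export
compose_final_embeddings <- function(raw, ancestry, use_hierarchy = TRUE,
                                     has_none = FALSE) {
  if (!use_hierarchy) return(raw)
  n <- length(ancestry$ids)
  expected <- n + as.integer(has_none)
  if (nrow(raw) != expected) {
    stop("raw embedding matrix has ", nrow(raw), " rows; expected ", expected)
  }
  if (has_none) {
    rbind(as.matrix(ancestry$A %*% raw[seq_len(n), , drop = FALSE]),
          raw[n + 1L, , drop = FALSE])
  } else {
    as.matrix(ancestry$A %*% raw)
  }
}

# (Re)build the cached final embedding matrix H of a model.
refresh_embeddings <- function(model) {
  model$H <- compose_final_embeddings(model$H_raw, model$ancestry,
                                      use_hierarchy = model$config$use_hierarchy,
                                      has_none = model$config$use_negatives)
  model
}

#' Initialize an untrained neural dictionary
#'
#' Allocates and seeds all learnable parameters: the encoder weights `W`,
#' `b`, `U`, the raw concept embedding matrix (one row per concept plus a
#' NONE row when negatives are used) and the per-row bias. Weight matrices
#' use Glorot-uniform initialization; raw embeddings start as small
#' Gaussians; biases start at zero.
#'
#' @param config a [model_config()].
#' @param ontology an [ontology()] object.
#' @param word_vectors a `word_vector_table` whose `dim` equals
#'   `config$word_dim`.
#' @return An object of class `neural_dictionary`.
#' @export
init_model <- function(config, ontology, word_vectors) {
  if (word_vectors$dim != config$word_dim) {
    stop("word-vector table dim ", word_vectors$dim,
         " does not match config word_dim ", config$word_dim)
  }
  ancestry <- build_ancestry_matrix(ontology)
  n <- length(ancestry$ids)
  k <- n + as.integer(config$use_negatives)
  model <- withr_seed(config$seed, {
    glorot <- function(nr, nc) {
      s <- sqrt(6 / (nr + nc))
      matrix(stats::runif(nr * nc, -s, s), nr, nc)
    }
    list(
      config = config,
      ids = ancestry$ids,
      ancestry = ancestry,
      names = ontology$names[ancestry$ids],
      W = glorot(config$conv_filters, config$word_dim),
      b = numeric(config$conv_filters),
      U = glorot(config$concept_dim, config$conv_filters),
      H_raw = matrix(stats::rnorm(k * config$concept_dim, sd = 0.1),
                     k, config$concept_dim),
      bias = numeric(k),
      word_vectors = word_vectors
    )
  })
  class(model) <- "neural_dictionary"
  refresh_embeddings(model)
}

#' @export
print.neural_dictionary <- function(x, ...) {
  cat("neural_dictionary:", length(x$ids), "concepts",
      if (x$config$use_negatives) "+ NONE" else "",
      "| hierarchy:", x$config$use_hierarchy,
      "| dims (word/conv/concept):",
      paste(x$config$word_dim, x$config$conv_filters, x$config$concept_dim,
            sep = "/"), "\n")
  invisible(x)
}

row_labels <- function(model) {
  if (model$config$use_negatives) c(model$ids, NONE_LABEL) else model$ids
}

#' Score a phrase against all concepts
#'
#' Encodes the phrase and returns the softmax distribution over all
#' concepts (plus the NONE class when the model carries one):
#' `softmax(H e + bias)`.
#'
#' @param model a `neural_dictionary`.
#' @param tokens character vector of phrase tokens (non-empty), or a numeric
#'   matrix of precomputed token vectors.
#' @return A named numeric vector of probabilities summing to 1, of class
#'   `score_distribution`.
#' @export
score_concepts <- function(model, tokens) {
  if (is.character(tokens)) {
    if (length(tokens) == 0L) stop("phrase must contain at least one token")
    tokens <- wv_lookup(model$word_vectors, tokens)
  }
  enc <- encode_phrase(model, tokens)
  logits <- as.numeric(model$H %*% enc$embedding) + model$bias
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  structure(stats::setNames(p, row_labels(model)), class = "score_distribution")
}

# Score many phrases at once; returns a B x rows probability matrix.
score_phrases_matrix <- function(model, phrase_list) {
  mats <- lapply(phrase_list, function(tok) {
    if (is.character(tok)) wv_lookup(model$word_vectors, tok) else tok
  })
  X <- do.call(rbind, mats)
  ex <- rep.int(seq_along(mats), vapply(mats, nrow, integer(1)))
  fw <- encoder_forward(model$W, model$b, model$U, X, ex)
  logits <- fw$E %*% t(model$H) +
    matrix(model$bias, nrow(fw$E), length(model$bias), byrow = TRUE)
  p <- softmax_rows(logits)
  colnames(p) <- row_labels(model)
  p
}

#' Top-k concepts of a score distribution
#'
#' Returns the k highest-scoring concepts (the NONE class is never
#' reported), in descending score order; ties are broken by lexicographic
#' concept id so rankings are reproducible.
#'
#' @param dist a `score_distribution` (named probability vector).
#' @param k number of concepts to return (capped at the number of concepts).
#' @return A data frame with columns `concept`, `score`.
#' @export
top_k <- function(dist, k = 1L) {
  stopifnot(k >= 1L)
  ids <- names(dist)
  keep <- ids != NONE_LABEL
  ids <- ids[keep]
  sc <- as.numeric(dist[keep])
  ord <- order(-sc, ids, method = "radix")
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(concept = ids[ord], score = sc[ord], stringsAsFactors = FALSE)
}

#' Average the predictions of an ensemble
#'
#' Combines several score distributions over the same concept set by
#' arithmetic averaging of the probabilities, which is how seed-varied
#' model ensembles are used at inference time.
#'
#' @param dists a non-empty list of `score_distribution` vectors with
#'   identical names.
#' @return A `score_distribution` (still sums to 1).
#' @export
ensemble_scores <- function(dists) {
  if (length(dists) == 0L) stop("need at least one distribution")
  nm <- names(dists[[1L]])
  for (d in dists) {
    if (!identical(names(d), nm)) stop("distributions cover different concept sets")
  }
  avg <- Reduce(`+`, lapply(dists, as.numeric)) / length(dists)
  structure(stats::setNames(avg, nm), class = "score_distribution")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the configuration, the
#' encoder parameters, the raw concept embeddings and biases, the concept-id
#' index, the ancestry matrix and the word-vector table. Saving and
#' re-loading round-trips the model bitwise.
#'
#' @param model a `neural_dictionary`.
#' @param path file path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "neural_dictionary"))
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "neural_dictionary")) stop("not a neural_dictionary checkpoint")
  model
}
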