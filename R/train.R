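#' Training plan
#'
#' Optimization hyperparameters. The defaults are the published recipe:
#' Adam with learning rate 0.002, batch size 256, 100 epochs, and a
#' 10-model ensemble over seeds 0..9. `negative_ratio` controls how many
#' NONE-labelled negatives are sampled per positive example (the negatives
#' are drawn once before training).
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size (the last, incomplete batch of an epoch
#'   is kept).
#' @param epochs number of passes over the training data.
#' @param negative_ratio negatives sampled per positive (>= 0).
#' @param ensemble_size number of seed-varied models in the ensemble.
#' @param seeds integer vector of length `ensemble_size`.
#' @return A list of class `train_plan`.
#' @export
train_plan <- function(learning_rate = 0.002, batch_size = 256L,
                       epochs = 100L, negative_ratio = 1.0,
                       ensemble_size = 10L,
                       seeds = seq_len(ensemble_size) - 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, negative_ratio >= 0,
            learning_rate > 0)
  if (length(seeds) != ensemble_size) {
    stop("`seeds` must have length `ensemble_size`")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 negative_ratio = negative_ratio,
                 ensemble_size = as.integer(ensemble_size),
                 seeds = as.integer(seeds)),
            class = "train_plan")
}

#' Build the positive training set from an ontology
#'
#' One training example per distinct (surface form, concept) pair, where the
#' surface forms of a concept are its canonical name and all its synonyms
#' (duplicated strings under one concept count once). Strings are tokenized
#' with the package-wide tokenizer.
#'
#' @param ont an [ontology()] object.
#' @return A list of examples, each a list with `tokens` (character vector)
#'   and `label` (concept id).
#' @export
build_training_set <- function(ont) {
  out <- list()
  for (id in ont$ids) {
    strings <- unique(c(ont$names[[id]], ont$synonyms[[id]]))
    for (s in strings) {
      toks <- tokenize_phrase(s)
      if (length(toks) == 0L) next
      out[[length(out) + 1L]] <- list(tokens = toks, label = id)
    }
  }
  out
}

#' Sample negative examples from an unrelated corpus
#'
#' Draws random n-grams from a token stream of out-of-domain text (the role
#' Wikipedia plays at full scale) and labels them with the dummy NONE
#' concept. N-gram lengths are uniform on 1..10, matching the assumption
#' that ontology surface forms are at most 10 tokens long; start positions
#' are uniform over the valid range.
#'
#' @param corpus_tokens character vector of at least 10 tokens.
#' @param count number of negatives to draw (>= 0).
#' @param seed integer seed; the draw is a pure function of
#'   `(corpus_tokens, count, seed)`.
#' @param max_len maximum n-gram length (default 10).
#' @return A list of examples (`tokens`, `label = "NONE"`).
#' @export
sample_negatives <- function(corpus_tokens, count, seed = 0L, max_len = 10L) {
  if (length(corpus_tokens) < 10L) {
    stop("negative corpus must contain at least 10 tokens")
  }
  stopifnot(count >= 0L)
  if (count == 0L) return(list())
  n <- length(corpus_tokens)
  withr_seed(seed, {
    lens <- sample.int(max_len, count, replace = TRUE)
    starts <- vapply(lens, function(l) sample.int(n - l + 1L, 1L), integer(1))
    lapply(seq_len(count), function(i) {
      list(tokens = corpus_tokens[starts[i]:(starts[i] + lens[i] - 1L)],
           label = NONE_LABEL)
    })
  })
}

# Cross-entropy loss and gradients for one minibatch.
# X: tokens x word_dim; ex: contiguous example index per row of X;
# y: integer target row (concept index, or the NONE row) per example.
batch_gradients <- function(W, b, U, H_raw, bias, ancestry, use_hierarchy,
                            has_none, X, ex, y) {
  H <- compose_final_embeddings(H_raw, ancestry, use_hierarchy, has_none)
  fw <- encoder_forward(W, b, U, X, ex)
  B <- nrow(fw$E)
  logits <- fw$E %*% t(H) + matrix(bias, B, length(bias), byrow = TRUE)
  P <- softmax_rows(logits)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y)], 1e-300)))

  G <- P
  G[cbind(seq_len(B), y)] <- G[cbind(seq_len(B), y)] - 1
  G <- G / B
  gbias <- colSums(G)
  gH <- t(G) %*% fw$E
  if (use_hierarchy) {
    n <- length(ancestry$ids)
    gH_raw <- gH
    gH_raw[seq_len(n), ] <- as.matrix(Matrix::t(ancestry$A) %*%
                                        gH[seq_len(n), , drop = FALSE])
  } else {
    gH_raw <- gH
  }
  dE <- G %*% H
  denom <- pmax(fw$norms, NORM_EPS)
  dR <- (dE - fw$E * rowSums(dE * fw$E)) / denom
  dR[fw$norms <= NORM_EPS, ] <- 0
  dUmat <- dR * (fw$Umat > 0)
  gU <- t(dUmat) %*% fw$V
  dV <- dUmat %*% U
  dPool <- matrix(0, nrow(X), nrow(W))
  nr <- nrow(X)
  for (i in seq_len(B)) {
    idx <- (seq_len(ncol(dPool)) - 1L) * nr + fw$amax[i, ]
    dPool[idx] <- dPool[idx] + dV[i, ]
  }
  dZ <- dPool * elu_grad(fw$Zpre)
  gW <- t(dZ) %*% X
  gb <- colSums(dZ)
  list(loss = loss, gW = gW, gb = gb, gU = gU, gH_raw = gH_raw, gbias = gbias)
}

adam_state <- function(param) list(m = param * 0, v = param * 0)

adam_step <- function(param, grad, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train a neural dictionary
#'
#' Minimizes the cross-entropy between the softmax output and the example
#' labels with Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8). Examples are
#' reshuffled across minibatches at the beginning of every epoch; word
#' vectors are frozen inputs; the learnable parameters are the encoder
#' weights `W`, `b`, `U`, the raw concept embeddings and the per-row bias.
#' Training is a pure function of `(config, plan, data)`: the same seed
#' yields a bitwise-identical model.
#'
#' @param config a [model_config()]; `config$seed` drives initialization and
#'   shuffling.
#' @param plan a [train_plan()].
#' @param ontology an [ontology()] object (supplies the concept index and
#'   the ancestry matrix).
#' @param word_vectors a `word_vector_table`.
#' @param positives list of positive examples, e.g. from
#'   [build_training_set()]; defaults to building them from `ontology`.
#' @param negatives list of NONE-labelled examples, e.g. from
#'   [sample_negatives()]. Required non-empty when `config$use_negatives`;
#'   ignored (with a warning) otherwise.
#' @return A trained `neural_dictionary` with a `training_log` data frame
#'   (`epoch`, `loss`) attached.
#' @export
train_model <- function(config, plan, ontology, word_vectors,
                        positives = build_training_set(ontology),
                        negatives = list()) {
  if (length(positives) == 0L) stop("no positive training examples")
  if (config$use_negatives && length(negatives) == 0L) {
    stop("config$use_negatives is TRUE but no negative examples were supplied")
  }
  if (!config$use_negatives && length(negatives) > 0L) {
    warning("model has no NONE class; ignoring supplied negatives")
    negatives <- list()
  }
  model <- init_model(config, ontology, word_vectors)
  examples <- c(positives, negatives)
  n_rows <- length(model$ids) + as.integer(config$use_negatives)
  label_idx <- stats::setNames(seq_along(model$ids), model$ids)
  y_all <- vapply(examples, function(e) {
    if (identical(e$label, NONE_LABEL)) {
      if (!config$use_negatives) stop("NONE-labelled example but use_negatives is FALSE")
      n_rows
    } else {
      i <- label_idx[[e$label]]
      if (is.null(i)) stop("unknown label in training data: ", e$label)
      i
    }
  }, integer(1))
  mats <- lapply(examples, function(e) wv_lookup(word_vectors, e$tokens))
  ntok <- vapply(mats, nrow, integer(1))
  if (any(ntok == 0L)) stop("empty token sequence in training data")

  st <- list(W = adam_state(model$W), b = adam_state(model$b),
             U = adam_state(model$U), H_raw = adam_state(model$H_raw),
             bias = adam_state(model$bias))
  lr <- plan$learning_rate
  log_loss <- numeric(plan$epochs)
  t_step <- 0L
  N <- length(examples)
  withr_seed(config$seed + 1L, {
    for (epoch in seq_len(plan$epochs)) {
      ord <- sample.int(N)
      batch_starts <- seq(1L, N, by = plan$batch_size)
      ep_loss <- 0
      for (bs in batch_starts) {
        sel <- ord[bs:min(bs + plan$batch_size - 1L, N)]
        X <- do.call(rbind, mats[sel])
        ex <- rep.int(seq_along(sel), ntok[sel])
        gr <- batch_gradients(model$W, model$b, model$U, model$H_raw,
                              model$bias, model$ancestry,
                              config$use_hierarchy, config$use_negatives,
                              X, ex, y_all[sel])
        if (!is.finite(gr$loss)) {
          stop("training loss diverged (non-finite) at epoch ", epoch)
        }
        t_step <- t_step + 1L
        for (p in c("W", "b", "U", "H_raw", "bias")) {
          upd <- adam_step(model[[p]], gr[[paste0("g", p)]], st[[p]], lr, t_step)
          model[[p]] <- upd$param
          st[[p]] <- upd$state
        }
        ep_loss <- ep_loss + gr$loss * length(sel)
      }
      log_loss[epoch] <- ep_loss / N
    }
  })
  model <- refresh_embeddings(model)
  model$training_log <- data.frame(epoch = seq_len(plan$epochs),
                                   loss = log_loss)
  model
}

#' Train a seed-varied ensemble
#'
#' Trains `plan$ensemble_size` models that differ only in the seed driving
#' parameter initialization and epoch reshuffling. At inference time their
#' probability distributions are averaged with [ensemble_scores()].
#'
#' @inheritParams train_model
#' @return A list of `neural_dictionary` models, one per seed.
#' @export
train_ensemble <- function(config, plan, ontology, word_vectors,
                           positives = build_training_set(ontology),
                           negatives = list()) {
  if (anyDuplicated(plan$seeds) > 0L) {
    warning("duplicate seeds in ensemble plan; the duplicated models will be identical")
  }
  lapply(plan$seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    train_model(cfg, plan, ontology, word_vectors,
                positives = positives, negatives = negatives)
  })
}

#' Read a key = value configuration file
#'
#' Parses the flat `key = value` files used by the command-line interface
#' to override [model_config()] and [train_plan()] fields. Values are
#' coerced to numeric or logical where possible; `seeds` may be a
#' comma-separated list.
#'
#' @param path file path.
#' @return A named list.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) stop("malformed config line: ", ln)
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) {
      num
    } else if (all(toupper(vals) %in% c("TRUE", "FALSE"))) {
      as.logical(toupper(vals))
    } else {
      vals
    }
  }
  out
}
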