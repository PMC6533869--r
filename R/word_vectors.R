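#' Load word vectors from word2vec text format
#'
#' The expected format is the plain-text word2vec convention: a header line
#' `"V D"` (vocabulary size and dimensionality) followed by V lines, each a
#' token and D real numbers separated by whitespace. This is the format
#' emitted by fastText and word2vec for pretrained embeddings.
#'
#' @param path path to the vector file.
#' @param oov_policy how [wv_lookup()] resolves out-of-vocabulary tokens:
#'   `"zero"` (default) returns the zero vector, `"hash-random"` returns a
#'   unit-norm vector derived deterministically from a hash of the token.
#' @return An object of class `word_vector_table`.
#' @export
load_word_vectors <- function(path, oov_policy = c("zero", "hash-random")) {
  oov_policy <- match.arg(oov_policy)
  if (!file.exists(path)) stop("cannot read word-vector file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 1L) stop("empty word-vector file: ", path)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("malformed header at line 1: expected 'V D'")
  }
  v <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
  if (length(lines) - 1L < v) stop("header declares ", v, " rows but file has ",
                                   length(lines) - 1L)
  tokens <- character(v)
  mat <- matrix(0, nrow = v, ncol = d)
  for (i in seq_len(v)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(parts) != d + 1L) {
      stop("malformed row at line ", i + 1L, ": expected 1 token + ", d,
           " values, got ", length(parts), " fields")
    }
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals)) stop("non-numeric field at line ", i + 1L)
    tokens[i] <- parts[1L]
    mat[i, ] <- vals
  }
  dup <- duplicated(tokens)
  if (any(dup)) {
    warning("duplicate token(s) in word-vector file; keeping first occurrence: ",
            paste(unique(tokens[dup]), collapse = ", "))
    mat <- mat[!dup, , drop = FALSE]
    tokens <- tokens[!dup]
  }
  rownames(mat) <- tokens
  word_vector_table(mat, oov_policy = oov_policy)
}

word_vector_table <- function(mat, oov_policy = "zero") {
  structure(list(dim = ncol(mat), vectors = mat, oov_policy = oov_policy),
            class = "word_vector_table")
}

#' @export
print.word_vector_table <- function(x, ...) {
  cat("word_vector_table:", nrow(x$vectors), "tokens, dim", x$dim,
      "- OOV policy:", x$oov_policy, "\n")
  invisible(x)
}

#' Resolve tokens to word vectors
#'
#' Lookup is total: every token string yields a vector of the table's
#' dimensionality. In-vocabulary tokens return their stored row; unknown
#' tokens are resolved by the table's OOV policy (`"zero"` or
#' `"hash-random"`), and the same token always yields the same vector.
#'
#' @param table a `word_vector_table`.
#' @param tokens character vector of tokens.
#' @return A `length(tokens) x dim` numeric matrix, one row per token.
#' @export
wv_lookup <- function(table, tokens) {
  out <- matrix(0, nrow = length(tokens), ncol = table$dim)
  hit <- tokens %in% rownames(table$vectors)
  if (any(hit)) out[hit, ] <- table$vectors[tokens[hit], , drop = FALSE]
  if (any(!hit) && table$oov_policy == "hash-random") {
    for (i in which(!hit)) out[i, ] <- hash_unit_vector(tokens[i], table$dim)
  }
  rownames(out) <- tokens
  out
}

# Deterministic token -> unit vector, independent of R's RNG state.
# Polynomial rolling hash seeds a Lehmer-style LCG; Box-Muller gives
# normals which are then l2-normalized.
hash_unit_vector <- function(token, dim) {
  m <- 2147483647 # 2^31 - 1
  h <- 17
  for (b in utf8ToInt(token)) h <- (h * 131 + b) %% m
  if (h == 0) h <- 1
  nu <- 2L * ((dim + 1L) %/% 2L)
  u <- numeric(nu)
  for (i in seq_len(nu)) {
    h <- (h * 48271) %% m
    u[i] <- h / m
  }
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  half <- nu %/% 2L
  r <- sqrt(-2 * log(u[seq_len(half)]))
  th <- 2 * pi * u[half + seq_len(half)]
  z <- c(r * cos(th), r * sin(th))[seq_len(dim)]
  z / sqrt(sum(z^2))
}

#' Generate deterministic fixture word vectors
#'
#' Produces a reproducible word-vector table for testing: one unit-norm
#' vector per token, a pure function of `(vocab, dim, seed)`. Tokens can be
#' organised into synonym groups; members of a group are drawn near a shared
#' centroid so that their pairwise cosine similarity is high (>= 0.8),
#' emulating the property of pretrained embeddings that semantically similar
#' words map to close vectors — which is what lets the phrase encoder
#' generalize to unseen synonyms.
#'
#' @param vocab character vector of tokens (non-empty).
#' @param dim embedding dimensionality (>= 1).
#' @param seed integer seed.
#' @param groups optional list of character vectors; each element is a
#'   synonym group whose members are placed near a common centroid. Tokens
#'   must belong to at most one group.
#' @param oov_policy passed through to the table.
#' @return A `word_vector_table`.
#' @export
make_fixture_vectors <- function(vocab, dim, seed = 0L, groups = list(),
                                 oov_policy = "zero") {
  if (length(vocab) == 0L) stop("`vocab` must be non-empty")
  if (dim < 1L) stop("`dim` must be >= 1")
  vocab <- unique(vocab)
  mat <- matrix(0, nrow = length(vocab), ncol = dim,
                dimnames = list(vocab, NULL))
  withr_seed(seed, {
    group_of <- stats::setNames(rep(NA_integer_, length(vocab)), vocab)
    centroids <- lapply(groups, function(g) unit(stats::rnorm(dim)))
    for (gi in seq_along(groups)) {
      for (tok in groups[[gi]]) {
        if (!is.na(group_of[[tok]])) stop("token in two synonym groups: ", tok)
        group_of[tok] <- gi
      }
    }
    for (i in seq_along(vocab)) {
      gi <- group_of[[vocab[i]]]
      if (is.na(gi)) {
        mat[i, ] <- unit(stats::rnorm(dim))
      } else {
        # centroid + small orthogonal jitter: within-group cosine stays high
        mat[i, ] <- unit(centroids[[gi]] + 0.25 * unit(stats::rnorm(dim)))
      }
    }
  })
  word_vector_table(mat, oov_policy = oov_policy)
}

unit <- function(x) {
  n <- sqrt(sum(x^2))
  if (n < 1e-12) x else x / n
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}

#' Write a word-vector table in word2vec text format
#'
#' @param table a `word_vector_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_word_vectors <- function(table, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(table$vectors), table$dim), con)
  for (i in seq_len(nrow(table$vectors))) {
    writeLines(paste(rownames(table$vectors)[i],
                     paste(format(table$vectors[i, ], digits = 17,
                                  scientific = TRUE, trim = TRUE),
                           collapse = " ")), con)
  }
  invisible(path)
}
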