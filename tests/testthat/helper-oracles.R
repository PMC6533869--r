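# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most direct route available (brute-force set arithmetic,
# memoized recursion, straight-line formula evaluation) so they share no code
# with the implementation paths they check.

# --- random DAG generation (independent of the fixtures module) -------------

rand_dag <- function(n, seed, max_parents = 3L) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  if (n > 1L) {
    for (i in 2:n) {
      k <- sample.int(min(max_parents, i - 1L), 1L)
      parents[[ids[i]]] <- ids[sample.int(i - 1L, k)]
    }
  }
  ontology(stats::setNames(paste("node", ids), ids), parents = parents)
}

# --- ancestry oracles --------------------------------------------------------

# memoized depth-first evaluation of the recursive row definition
oracle_ancestry_dense <- function(ont) {
  ids <- ont$ids
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  memo <- vector("list", n)
  row_of <- function(id) {
    i <- idx[[id]]
    if (!is.null(memo[[i]])) return(memo[[i]])
    r <- numeric(n)
    r[i] <- 1
    ps <- ont$parents[[id]]
    if (length(ps) > 0L) {
      acc <- numeric(n)
      for (p in ps) acc <- acc + row_of(p)
      r <- r + acc / length(ps)
    }
    memo[[i]] <<- r
    r
  }
  out <- t(vapply(ids, row_of, numeric(n)))
  dimnames(out) <- list(ids, ids)
  out
}

oracle_ancestors_bfs <- function(ont, id) {
  seen <- character()
  queue <- id
  while (length(queue) > 0L) {
    x <- queue[1L]; queue <- queue[-1L]
    if (x %in% seen) next
    seen <- c(seen, x)
    queue <- c(queue, ont$parents[[x]])
  }
  sort(seen)
}

# --- metric oracles (plain set arithmetic, no shared helpers) ----------------

oracle_micro <- function(docs) {
  hit <- 0; nr <- 0; nl <- 0
  for (d in docs) {
    hit <- hit + length(intersect(d$reported, d$labels))
    nr <- nr + length(d$reported); nl <- nl + length(d$labels)
  }
  p <- if (nr == 0) 1 else hit / nr
  r <- if (nl == 0) 1 else hit / nl
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(p, r, f)
}

oracle_macro <- function(docs) {
  p <- mean(sapply(docs, function(d) {
    if (length(d$reported) == 0) 1 else length(intersect(d$reported, d$labels)) / length(d$reported)
  }))
  r <- mean(sapply(docs, function(d) {
    if (length(d$labels) == 0) 1 else length(intersect(d$reported, d$labels)) / length(d$labels)
  }))
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(p, r, f)
}

oracle_extended <- function(docs, ont) {
  closure <- function(s) {
    out <- character()
    for (c0 in s) out <- union(out, oracle_ancestors_bfs(ont, c0))
    out
  }
  hit <- 0; nr <- 0; nl <- 0; nu <- 0
  for (d in docs) {
    er <- closure(d$reported); el <- closure(d$labels)
    hit <- hit + length(intersect(er, el))
    nr <- nr + length(er); nl <- nl + length(el)
    nu <- nu + length(union(er, el))
  }
  p <- if (nr == 0) 1 else hit / nr
  r <- if (nl == 0) 1 else hit / nl
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  j <- if (nu == 0) 1 else hit / nu
  c(p, r, f, j)
}

random_doc_collection <- function(seed, max_docs = 10L, ont = NULL) {
  set.seed(seed)
  pool <- if (is.null(ont)) sprintf("c%02d", 1:8) else ont$ids
  n <- sample.int(max_docs, 1L)
  lapply(seq_len(n), function(i) {
    document_eval(paste0("d", i),
                  sample(pool, sample.int(length(pool), 1L) - 1L),
                  sample(pool, sample.int(length(pool), 1L) - 1L))
  })
}

# --- shared trained fixtures (built once per test run) -----------------------

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .test_cache)) {
    assign(name, builder(), envir = .test_cache)
  }
  get(name, envir = .test_cache)
}

# A small ontology of organ defects with compositional English names, an
# intermediate "modifier defect" layer (multi-parent DAG, as in real
# phenotype ontologies), word-level synonym substitutions, and a negative
# corpus that also contains isolated ontology words in jumbled order (as an
# encyclopedia corpus would), which is what teaches the NONE class to absorb
# partial spans.
heart_world <- function() {
  organs <- c(heart = "cardiac", lung = "pulmonary",
              kidney = "renal", liver = "hepatic")
  mods <- list(heart = c("conotruncal", "septal"), lung = c("apical", "basal"),
               kidney = c("cortical", "medullary"), liver = c("lobar", "portal"))
  nms <- c("HD:0001" = "defect")
  par <- list()
  syn <- list("HD:0001" = c("anomaly", "malformation"))
  k <- 1L
  modid <- character()
  for (org in names(organs)) {
    for (mod in mods[[org]]) {
      k <- k + 1L
      id <- sprintf("HD:%04d", k)
      modid[mod] <- id
      nms[id] <- paste(mod, "defect")
      par[[id]] <- "HD:0001"
      syn[[id]] <- c(paste(mod, "anomaly"), paste(mod, "malformation"))
    }
  }
  organ_id <- character()
  for (org in names(organs)) {
    k <- k + 1L
    oid <- sprintf("HD:%04d", k)
    organ_id[org] <- oid
    nms[oid] <- paste(org, "defect")
    par[[oid]] <- "HD:0001"
    syn[[oid]] <- c(paste(organs[[org]], "defect"), paste(org, "anomaly"),
                    paste(organs[[org]], "malformation"))
    for (mod in mods[[org]]) {
      k <- k + 1L
      mid <- sprintf("HD:%04d", k)
      nms[mid] <- paste(mod, org, "defect")
      par[[mid]] <- c(oid, modid[[mod]])
      syn[[mid]] <- c(paste(mod, organs[[org]], "defect"),
                      paste(mod, org, "anomaly"),
                      paste(mod, organs[[org]], "anomaly"))
    }
  }
  ont <- ontology(nms, parents = par, synonyms = syn)
  ctx <- c("the", "patient", "was", "diagnosed", "with", "showed",
           "presented", "and")
  ontwords <- unique(unlist(strsplit(c(nms, unlist(syn)), " ")))
  wv <- make_fixture_vectors(
    c(ontwords, ctx, sprintf("unrel%02d", 1:20)), dim = 20, seed = 1,
    groups = list(c("defect", "anomaly", "malformation"),
                  c("heart", "cardiac"), c("lung", "pulmonary"),
                  c("kidney", "renal"), c("liver", "hepatic")))
  pos <- build_training_set(ont)
  surfaces <- unique(c(ont$names, unlist(ont$synonyms)))
  negcorp <- neurodict:::withr_seed(99, {
    base <- sample(c(sprintf("unrel%02d", 1:20), ctx), 800, replace = TRUE)
    slots <- seq(2L, 790L, by = 7L)
    base[slots] <- sample(ontwords, length(slots), replace = TRUE)
    base
  })
  bigr <- paste(negcorp[-length(negcorp)], negcorp[-1L])
  trigr <- paste(negcorp[1:(length(negcorp) - 2L)], negcorp[2:(length(negcorp) - 1L)],
                 negcorp[3:length(negcorp)])
  stopifnot(!any(bigr %in% surfaces), !any(trigr %in% surfaces))
  neg <- sample_negatives(negcorp, 2L * length(pos), seed = 0)
  cfg <- model_config(word_dim = 20, concept_dim = 32, conv_filters = 32,
                      seed = 0)
  plan <- train_plan(learning_rate = 0.01, epochs = 150, batch_size = 16,
                     ensemble_size = 3, seeds = 0:2)
  ens <- train_ensemble(cfg, plan, ont, wv, pos, neg)
  list(ontology = ont, word_vectors = wv, ensemble = ens, config = cfg,
       plan = plan, positives = pos, negatives = neg,
       heart_defect = organ_id[["heart"]],
       conotruncal = names(nms)[nms == "conotruncal heart defect"])
}

get_heart_world <- function() cached("heart_world", heart_world)

# A tiny trained memorizer over a 10-concept generator fixture; enough to
# top-rank its own training surfaces.
tiny_world <- function() {
  spec <- fixture_spec(n_concepts = 10L, word_dim = 16L, n_docs = 4L,
                       mentions_per_doc = 2L, seed = 3L)
  ws <- make_fixture_workspace(spec)
  pos <- build_training_set(ws$ontology)
  neg <- sample_negatives(ws$negative_corpus, length(pos), seed = 0)
  cfg <- model_config(word_dim = 16, concept_dim = 32, conv_filters = 32,
                      seed = 0)
  plan <- train_plan(learning_rate = 0.01, epochs = 60, batch_size = 16,
                     ensemble_size = 1, seeds = 0)
  model <- train_model(cfg, plan, ws$ontology, ws$word_vectors, pos, neg)
  c(ws, list(model = model, positives = pos, negatives = neg,
             config = cfg, plan = plan))
}

get_tiny_world <- function() cached("tiny_world", tiny_world)

# random untrained model over a random-name ontology, for contract tests
random_model <- function(seed, n_concepts = 6L, word_dim = 7L,
                         use_hierarchy = TRUE, use_negatives = TRUE) {
  ont <- rand_dag(n_concepts, seed)
  vocab <- sprintf("tok%02d", 1:15)
  wv <- make_fixture_vectors(vocab, dim = word_dim, seed = seed)
  cfg <- model_config(word_dim = word_dim, concept_dim = 9L,
                      conv_filters = 8L, use_hierarchy = use_hierarchy,
                      use_negatives = use_negatives, seed = seed)
  list(model = init_model(cfg, ont, wv), vocab = vocab, ontology = ont)
}
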