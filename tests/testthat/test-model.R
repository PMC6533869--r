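rand_params <- function(seed, F = 6L, wd = 4L, cd = 5L) {
  set.seed(seed)
  list(W = matrix(rnorm(F * wd), F, wd), b = rnorm(F),
       U = matrix(rnorm(cd * F), cd, F))
}

elu_ref <- function(x) ifelse(x > 0, x, exp(x) - 1)

test_that("encoding a single token is ELU(W x + b) passed through the head", {
  p <- rand_params(1)
  x <- rnorm(4)
  enc <- encode_phrase(p, x)
  expect_equal(enc$pooled, as.numeric(elu_ref(p$W %*% x + p$b)))
  # duplicated token changes nothing: max pooling is idempotent
  enc2 <- encode_phrase(p, rbind(x, x))
  expect_identical(enc$embedding, enc2$embedding)
})

test_that("encoding matches a straight-line recomputation of the formula", {
  p <- rand_params(2)
  set.seed(22)
  X <- matrix(rnorm(12), 3, 4)
  enc <- encode_phrase(p, X)
  proj <- sapply(seq_len(3), function(t) elu_ref(p$W %*% X[t, ] + p$b))
  v <- apply(proj, 1, max)
  r <- pmax(as.numeric(p$U %*% v), 0)
  e <- r / sqrt(sum(r^2))
  expect_equal(enc$pooled, v, tolerance = 1e-12)
  expect_equal(enc$embedding, e, tolerance = 1e-12)
  expect_equal(sqrt(sum(enc$embedding^2)), 1, tolerance = 1e-9)
})

test_that("encoding is exactly invariant to token order", {
  p <- rand_params(3)
  set.seed(33)
  X <- matrix(rnorm(20), 5, 4)
  for (s in 1:10) {
    perm <- sample(5)
    expect_identical(encode_phrase(p, X)$embedding,
                     encode_phrase(p, X[perm, , drop = FALSE])$embedding)
  }
})

test_that("encoder rejects empty phrases and wrong dimensions", {
  p <- rand_params(4)
  expect_error(encode_phrase(p, matrix(0, 0, 4)), "at least one token")
  expect_error(encode_phrase(p, matrix(0, 2, 3)), "dimension")
})

test_that("hierarchy off returns raw embeddings unchanged, bitwise", {
  dia <- ontology(c(r = "r", a = "a", b = "b", c = "c"),
                  parents = list(a = "r", b = "r", c = c("a", "b")))
  am <- build_ancestry_matrix(dia)
  set.seed(5)
  raw <- matrix(rnorm(4 * 3), 4, 3)
  expect_identical(compose_final_embeddings(raw, am, use_hierarchy = FALSE), raw)
})

test_that("hierarchical composition unrolls the parent-sum recursion", {
  chain <- ontology(c(r = "r", c1 = "c1", c2 = "c2"),
                    parents = list(c1 = "r", c2 = "c1"))
  am <- build_ancestry_matrix(chain)
  set.seed(6)
  raw <- matrix(rnorm(9), 3, 3)
  rownames(raw) <- am$ids
  H <- compose_final_embeddings(raw, am, use_hierarchy = TRUE)
  expect_equal(H["c2", ], raw["c2", ] + raw["c1", ] + raw["r", ],
               tolerance = 1e-12)

  dia <- ontology(c(r = "r", a = "a", b = "b", c = "c"),
                  parents = list(a = "r", b = "r", c = c("a", "b")))
  amd <- build_ancestry_matrix(dia)
  rawd <- matrix(rnorm(12), 4, 3, dimnames = list(amd$ids, NULL))
  Hd <- compose_final_embeddings(rawd, amd, use_hierarchy = TRUE)
  expect_equal(Hd["c", ],
               rawd["c", ] + 0.5 * rawd["a", ] + 0.5 * rawd["b", ] + rawd["r", ],
               tolerance = 1e-12)
  # a NONE row passes through identity-composed
  rawn <- rbind(rawd, none = rnorm(3))
  Hn <- compose_final_embeddings(rawn, amd, use_hierarchy = TRUE, has_none = TRUE)
  expect_identical(Hn[5, ], rawn[5, ])
  expect_equal(Hn[1:4, ], Hd, tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("composition on random DAGs equals the recursive definition", {
  for (s in 1:15) {
    ont <- rand_dag(sample(5:50, 1), s + 100)
    am <- build_ancestry_matrix(ont)
    n <- length(am$ids)
    raw <- matrix(rnorm(n * 4), n, 4)
    H <- compose_final_embeddings(raw, am, use_hierarchy = TRUE)
    expect_lt(max(abs(H - oracle_ancestry_dense(ont)[am$ids, am$ids] %*% raw)),
              1e-8)
  }
})

test_that("score distributions are probabilities and symmetric cases split evenly", {
  rm <- random_model(1)
  d <- score_concepts(rm$model, c("tok01", "tok05"))
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_true(all(d >= 0))

  # two concepts with identical final embeddings and biases score 0.5 each
  flat <- random_model(2, n_concepts = 2L, use_hierarchy = FALSE,
                       use_negatives = FALSE)
  m <- flat$model
  m$H_raw[2, ] <- m$H_raw[1, ]
  m$bias[] <- 0
  m <- neurodict:::refresh_embeddings(m)
  d2 <- score_concepts(m, "tok01")
  expect_equal(unname(as.numeric(d2)), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("scores equal a straight-line softmax(H e + bias) evaluation", {
  rm <- random_model(7)
  m <- rm$model
  toks <- c("tok03", "tok09", "tok12")
  e <- encode_phrase(m, wv_lookup(m$word_vectors, toks))$embedding
  z <- as.numeric(m$H %*% e) + m$bias
  ref <- exp(z - max(z)) / sum(exp(z - max(z)))
  expect_equal(unname(as.numeric(score_concepts(m, toks))), ref,
               tolerance = 1e-12)
})

test_that("top_k ranks by score with lexicographic tie-breaking, never NONE", {
  d <- structure(c(a = 0.25, c = 0.25, b = 0.25, NONE = 0.25),
                 class = "score_distribution")
  expect_equal(top_k(d, 1)$concept, "a")
  expect_equal(top_k(d, 10)$concept, c("a", "b", "c"))
  d2 <- structure(c(a = 0.7, b = 0.2, c = 0.1), class = "score_distribution")
  expect_equal(top_k(d2, 2)$concept, c("a", "b"))
  expect_equal(top_k(d2, 2)$score, c(0.7, 0.2))
})

test_that("ensemble averaging is the entrywise mean and stays normalized", {
  one <- structure(c(a = 0.3, b = 0.7), class = "score_distribution")
  expect_equal(as.numeric(ensemble_scores(list(one))), c(0.3, 0.7))
  two <- ensemble_scores(list(structure(c(a = 1, b = 0), class = "score_distribution"),
                              structure(c(a = 0, b = 1), class = "score_distribution")))
  expect_equal(unname(as.numeric(two)), c(0.5, 0.5))

  set.seed(42)
  ds <- lapply(1:10, function(i) {
    x <- runif(4)
    structure(stats::setNames(x / sum(x), c("a", "b", "c", "d")),
              class = "score_distribution")
  })
  avg <- ensemble_scores(ds)
  ref <- colMeans(do.call(rbind, lapply(ds, as.numeric)))
  expect_equal(unname(as.numeric(avg)), unname(ref), tolerance = 1e-12)
  expect_equal(sum(avg), 1, tolerance = 1e-9)
  bad <- structure(c(a = 0.5, z = 0.5), class = "score_distribution")
  expect_error(ensemble_scores(list(one, bad)), "different concept sets")
})

test_that("softmax output is a distribution across many random phrases/models", {
  for (s in 1:10) {
    rm <- random_model(s + 200, use_hierarchy = s %% 2 == 0,
                       use_negatives = s %% 3 == 0)
    set.seed(s)
    for (j in 1:10) {
      toks <- sample(rm$vocab, sample(1:7, 1), replace = TRUE)
      d <- score_concepts(rm$model, toks)
      expect_equal(sum(d), 1, tolerance = 1e-9)
      expect_true(all(d >= 0))
    }
  }
})

test_that("analytic gradients match finite differences on a 5-concept toy", {
  ont <- rand_dag(5, 9)
  wv <- make_fixture_vectors(sprintf("tok%02d", 1:8), dim = 4, seed = 9)
  cfg <- model_config(word_dim = 4, concept_dim = 5, conv_filters = 4,
                      use_hierarchy = FALSE, use_negatives = FALSE, seed = 9)
  m <- init_model(cfg, ont, wv)
  phrases <- list(c("tok01", "tok02"), "tok03", c("tok04", "tok05", "tok06"))
  mats <- lapply(phrases, wv_lookup, table = m$word_vectors)
  X <- do.call(rbind, mats)
  ex <- rep.int(seq_along(mats), sapply(mats, nrow))
  y <- c(1L, 3L, 5L)
  gr <- neurodict:::batch_gradients(m$W, m$b, m$U, m$H_raw, m$bias,
                                    m$ancestry, FALSE, FALSE, X, ex, y)
  loss_at <- function(W = m$W, b = m$b, U = m$U, H = m$H_raw, bias = m$bias) {
    neurodict:::batch_gradients(W, b, U, H, bias, m$ancestry, FALSE, FALSE,
                                X, ex, y)$loss
  }
  h <- 1e-5
  num_grad <- function(param, setter) {
    g <- param
    for (i in seq_along(param)) {
      up <- param; up[i] <- up[i] + h
      dn <- param; dn[i] <- dn[i] - h
      g[i] <- (setter(up) - setter(dn)) / (2 * h)
    }
    g
  }
  gH_num <- num_grad(m$H_raw, function(p) loss_at(H = p))
  expect_lt(max(abs(gH_num - gr$gH_raw)), 1e-4)
  gb_num <- num_grad(m$bias, function(p) loss_at(bias = p))
  expect_lt(max(abs(gb_num - gr$gbias)), 1e-4)
  gU_num <- num_grad(m$U, function(p) loss_at(U = p))
  expect_lt(max(abs(gU_num - gr$gU)), 1e-4)
  gW_num <- num_grad(m$W, function(p) loss_at(W = p))
  expect_lt(max(abs(gW_num - gr$gW)), 1e-4)

  # without hierarchy or NONE the concept-embedding gradient is that of a
  # flat linear softmax on the encoded phrase: sum_i (p_i - y_i) outer e_i
  flat_grad <- matrix(0, 5, 5)
  for (i in seq_along(phrases)) {
    e <- encode_phrase(m, mats[[i]])$embedding
    z <- as.numeric(m$H_raw %*% e) + m$bias
    p <- exp(z - max(z)); p <- p / sum(p)
    p[y[i]] <- p[y[i]] - 1
    flat_grad <- flat_grad + outer(p, e) / length(phrases)
  }
  expect_lt(max(abs(flat_grad - gr$gH_raw)), 1e-10)
})

test_that("checkpoints round-trip bitwise", {
  rm <- random_model(11)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(rm$model, path)
  back <- load_checkpoint(path)
  expect_identical(back, rm$model)
  expect_error(load_checkpoint(file.path(tempdir(), "nope.rds")), "not found")
})
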