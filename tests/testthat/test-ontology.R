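obo_file <- function(text) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

test_that("parse_obo reads terms, synonyms, is_a, alt_id and skips obsoletes", {
  path <- obo_file(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: X:1",
    "name: alpha",
    "alt_id: X:9",
    "",
    "[Term]",
    "id: X:2",
    "name: beta",
    'synonym: "beta prime" EXACT []',
    'synonym: "second beta" BROAD [src]',
    "is_a: X:1 ! alpha",
    "",
    "[Term]",
    "id: X:3",
    "name: gone",
    "is_obsolete: true",
    "",
    "[Typedef]",
    "id: part_of"
  ))
  ont <- parse_obo(path)
  expect_setequal(ont$ids, c("X:1", "X:2"))
  expect_equal(unname(ont$names["X:2"]), "beta")
  expect_setequal(ont$synonyms[["X:2"]], c("beta prime", "second beta"))
  expect_equal(ont$parents[["X:2"]], "X:1")
  expect_equal(unname(ont$alt_ids["X:9"]), "X:1")
  expect_equal(ont$roots, "X:1")
})

test_that("single-term file yields a one-concept ontology rooted at it", {
  ont <- parse_obo(obo_file(c("[Term]", "id: A:1", "name: only")))
  expect_equal(ont$ids, "A:1")
  expect_equal(ont$roots, "A:1")
  expect_equal(ont$topo_order, "A:1")
})

test_that("topological order puts every parent before its children", {
  path <- obo_file(c(
    "[Term]", "id: Z", "name: z", "is_a: Y", "",
    "[Term]", "id: Y", "name: y", "is_a: X", "",
    "[Term]", "id: X", "name: x"
  ))
  ont <- parse_obo(path)
  expect_equal(ont$topo_order, c("X", "Y", "Z"))
  for (s in 1:20) {
    ont <- rand_dag(25, s)
    pos <- stats::setNames(seq_along(ont$topo_order), ont$topo_order)
    for (id in ont$ids) {
      for (p in ont$parents[[id]]) expect_lt(pos[[p]], pos[[id]])
    }
  }
})

test_that("structural errors are reported: cycles and dangling is_a", {
  cyc <- obo_file(c(
    "[Term]", "id: Z", "name: z", "is_a: Y", "",
    "[Term]", "id: Y", "name: y", "is_a: Z"
  ))
  expect_error(parse_obo(cyc), "cycle")
  dang <- obo_file(c("[Term]", "id: Z", "name: z", "is_a: NOPE"))
  expect_error(parse_obo(dang), "dangling")
  expect_error(parse_obo(file.path(tempdir(), "does-not-exist.obo")), "read")
})

test_that("ancestors returns the reflexive-transitive parent closure", {
  chain <- ontology(c(X = "x", Y = "y", Z = "z"),
                    parents = list(Y = "X", Z = "Y"))
  expect_setequal(ancestors(chain, "Z"), c("Z", "Y", "X"))
  expect_equal(ancestors(chain, "X"), "X")
  dia <- ontology(c(r = "r", a = "a", b = "b", c = "c"),
                  parents = list(a = "r", b = "r", c = c("a", "b")))
  expect_setequal(ancestors(dia, "c"), oracle_ancestors_bfs(dia, "c"))
  expect_setequal(ancestors(dia, "c"), c("c", "a", "b", "r"))
  expect_error(ancestors(chain, "nope"), "unknown")
})

test_that("ancestors of a node contains the ancestors of each parent", {
  for (s in 1:10) {
    ont <- rand_dag(20, s)
    for (id in ont$ids) {
      anc <- ancestors(ont, id)
      for (p in ont$parents[[id]]) {
        expect_true(all(ancestors(ont, p) %in% anc))
      }
    }
  }
})

test_that("ancestry matrix: base cases match hand-unrolled recursion", {
  single <- ontology(c(A = "a"))
  expect_equal(as.matrix(build_ancestry_matrix(single)$A),
               matrix(1, 1, 1, dimnames = list("A", "A")))
  chain <- ontology(c(r = "r", c1 = "c1", c2 = "c2"),
                    parents = list(c1 = "r", c2 = "c1"))
  A <- as.matrix(build_ancestry_matrix(chain)$A)
  expect_equal(unname(A["c2", c("c2", "c1", "r")]), c(1, 1, 1))
  dia <- ontology(c(r = "r", a = "a", b = "b", c = "c"),
                  parents = list(a = "r", b = "r", c = c("a", "b")))
  Ad <- as.matrix(build_ancestry_matrix(dia)$A)
  expect_equal(unname(Ad["c", c("c", "a", "b", "r")]), c(1, 0.5, 0.5, 1))
  # roots have a single nonzero entry; diagonal is 1
  expect_equal(unname(Ad["r", ]), c(1, 0, 0, 0))
  expect_equal(unname(diag(Ad)), rep(1, 4))
})

test_that("ancestry matrix equals the memoized recursive oracle on random DAGs", {
  for (s in 1:30) {
    ont <- rand_dag(sample(5:40, 1), s)
    A <- as.matrix(build_ancestry_matrix(ont)$A)
    expect_lt(max(abs(A - oracle_ancestry_dense(ont))), 1e-10)
  }
})

test_that("in a tree, the row sum of a node at depth d is exactly d + 1", {
  # chain of depth 5 plus a branch
  ids <- c("r", paste0("n", 1:5), "m1")
  par <- list(n1 = "r", n2 = "n1", n3 = "n2", n4 = "n3", n5 = "n4", m1 = "n2")
  ont <- ontology(stats::setNames(ids, ids), parents = par)
  A <- build_ancestry_matrix(ont)$A
  rs <- Matrix::rowSums(A)
  expect_identical(unname(rs[c("r", "n3", "n5", "m1")]), c(1, 4, 6, 4))
})

test_that("nonzero pattern of A is confined to ancestors", {
  for (s in 1:10) {
    ont <- rand_dag(15, s)
    A <- as.matrix(build_ancestry_matrix(ont)$A)
    for (id in ont$ids) {
      nz <- colnames(A)[A[id, ] != 0]
      expect_setequal(nz, ancestors(ont, id))
    }
  }
})

test_that("build_closed_subset matches the per-seed closure-union oracle", {
  chain <- ontology(c(r = "r", c1 = "c1", c2 = "c2"),
                    parents = list(c1 = "r", c2 = "c1"))
  res <- build_closed_subset(chain, "c2")
  expect_equal(res$counts, list(seeds = 1L, added_ancestors = 2L, total = 3L))
  expect_setequal(res$ontology$ids, c("r", "c1", "c2"))

  full <- build_closed_subset(chain, c("r", "c1", "c2"))
  expect_equal(full$counts$added_ancestors, 0L)
  expect_equal(full$counts$total, 3L)

  ont <- rand_dag(30, 7)
  set.seed(7)
  seeds <- sample(ont$ids, 10)
  res <- build_closed_subset(ont, seeds)
  want <- character()
  for (s in seeds) want <- union(want, oracle_ancestors_bfs(ont, s))
  expect_setequal(res$ontology$ids, want)
  expect_equal(res$counts$total, length(want))
  expect_equal(res$counts$total, res$counts$seeds + res$counts$added_ancestors)
  expect_error(build_closed_subset(ont, "missing"), "unknown")
})

test_that("closing a closed subset is idempotent and counts stay consistent", {
  for (s in 1:10) {
    ont <- rand_dag(25, s)
    set.seed(s)
    seeds <- sample(ont$ids, 5)
    res <- build_closed_subset(ont, seeds)
    expect_equal(res$counts$total, res$counts$seeds + res$counts$added_ancestors)
    again <- build_closed_subset(res$ontology, res$ontology$ids)
    expect_equal(again$counts$added_ancestors, 0L)
    expect_setequal(again$ontology$ids, res$ontology$ids)
  }
})

test_that("subset ontologies round-trip through OBO", {
  ont <- rand_dag(20, 11)
  set.seed(11)
  res <- build_closed_subset(ont, sample(ont$ids, 6))
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(res$ontology, path)
  back <- parse_obo(path)
  expect_setequal(back$ids, res$ontology$ids)
  expect_equal(back$parents[back$ids], res$ontology$parents[back$ids])
  expect_equal(back$names[back$ids], res$ontology$names[back$ids])
})
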