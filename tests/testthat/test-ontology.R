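test_that("parse_obo reads terms, synonyms and is_a edges", {
  g <- parse_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: A:1", "name: parent",
    'synonym: "kid" EXACT []',
    "",
    "[Term]", "id: A:2", "name: child thing",
    'synonym: "offspring" RELATED [PMID:1]',
    "is_a: A:1 ! parent",
    "",
    "[Term]", "id: A:3", "name: gone", "is_obsolete: true",
    "",
    "[Typedef]", "id: part_of", "name: part of"))
  expect_setequal(names(g$concepts), c("A:1", "A:2"))
  expect_equal(g$roots, "A:1")
  expect_equal(g$concepts[["A:2"]]$parents, "A:1")
  expect_equal(g$concepts[["A:1"]]$synonyms, "kid")
  expect_equal(g$concepts[["A:2"]]$synonyms, "offspring")
})

test_that("parse_obo rejects duplicates, dangling is_a and cycles", {
  expect_error(parse_obo(c("[Term]", "id: A:1", "name: x",
                           "[Term]", "id: A:1", "name: y")),
               "duplicate")
  expect_error(parse_obo(c("[Term]", "id: A:1", "name: x", "is_a: A:9")),
               "undefined")
  expect_error(parse_obo(c("[Term]", "id: A:1", "name: x", "is_a: A:2",
                           "[Term]", "id: A:2", "name: y", "is_a: A:1")),
               "cycle")
})

test_that("OBO round-trips through write_obo and parse_obo", {
  g <- make_toy_ontology(fixture_spec(seed = 3L))
  g2 <- parse_obo(write_obo(g))
  expect_setequal(names(g2$concepts), names(g$concepts))
  for (id in names(g$concepts)) {
    expect_equal(g2$concepts[[id]]$name, g$concepts[[id]]$name)
    expect_equal(sort(g2$concepts[[id]]$synonyms),
                 sort(g$concepts[[id]]$synonyms))
    expect_equal(sort(g2$concepts[[id]]$parents),
                 sort(g$concepts[[id]]$parents))
  }
})

test_that("dictionary_as_graph hangs all entries under one virtual root", {
  entries <- data.frame(id = c("M:1", "M:2", "M:3"),
                        term = c("headache", "nausea", "rash"),
                        synonyms = c("cephalalgia", "", "eruption|exanthema"))
  g <- dictionary_as_graph(entries)
  expect_length(g$concepts, 4L)
  expect_length(g$roots, 1L)
  expect_equal(g$concepts[["M:3"]]$synonyms, c("eruption", "exanthema"))
  expect_true(all(vapply(entries$id, function(i)
    identical(g$concepts[[i]]$parents, g$roots), logical(1))))

  empty <- dictionary_as_graph(data.frame(id = character(0),
                                          term = character(0)))
  expect_length(empty$concepts, 1L)
  expect_error(dictionary_as_graph(data.frame(id = "ROOT:0000000",
                                              term = "clash")),
               "reserved root id")
})

test_that("ancestor weights decay as s^distance, keeping the best path", {
  g <- chain_graph()
  w <- ancestor_weights(g, "A:3", s = 0.65)
  expect_equal(w, c("A:1" = 0.4225, "A:2" = 0.65, "A:3" = 1))
  expect_equal(ancestor_weights(g, "A:1", s = 0.3), c("A:1" = 1))

  diamond <- parse_obo(c(
    "[Term]", "id: D:1", "name: top",
    "[Term]", "id: D:2", "name: left", "is_a: D:1",
    "[Term]", "id: D:3", "name: right", "is_a: D:1",
    "[Term]", "id: D:4", "name: bottom", "is_a: D:2", "is_a: D:3"))
  w <- ancestor_weights(diamond, "D:4", s = 0.5)
  expect_equal(w[["D:1"]], 0.25)  # two equal-length paths, max kept
  expect_error(ancestor_weights(g, "nope"), "unknown")
})

test_that("ancestor weights agree with path enumeration on random DAGs", {
  set.seed(42)
  for (trial in 1:60) {
    g <- random_dag(sample(5:30, 1L))
    id <- sample(names(g$concepts), 1L)
    s <- runif(1, 0.3, 1)
    expect_equal(ancestor_weights(g, id, s), oracle_ancestor_weights(g, id, s))
  }
})

test_that("Wang similarity matches its hand-computed values", {
  two <- parse_obo(c("[Term]", "id: B:1", "name: parent",
                     "[Term]", "id: B:2", "name: child", "is_a: B:1"))
  expect_equal(wang_similarity(two, "B:2", "B:1"), 1.65 / 2.65,
               tolerance = 1e-12)
  expect_equal(wang_similarity(two, "B:1", "B:1"), 1)

  tree <- parse_obo(c("[Term]", "id: C:1", "name: top",
                      "[Term]", "id: C:2", "name: l1", "is_a: C:1",
                      "[Term]", "id: C:3", "name: l2", "is_a: C:1"))
  expect_equal(wang_similarity(tree, "C:2", "C:3"), 1.3 / 3.3,
               tolerance = 1e-12)
})

test_that("Wang similarity is symmetric, maximal at identity, and matches the oracle on random DAGs", {
  set.seed(7)
  for (trial in 1:40) {
    g <- random_dag(sample(5:30, 1L))
    ids <- sample(names(g$concepts), 2L)
    s <- runif(1, 0.3, 0.99)
    ab <- wang_similarity(g, ids[1], ids[2], s)
    expect_equal(ab, wang_similarity(g, ids[2], ids[1], s))
    expect_equal(ab, oracle_wang(g, ids[1], ids[2], s))
    expect_equal(wang_similarity(g, ids[1], ids[1], s), 1)
    expect_lte(ab, 1)
    expect_gte(ab, 0)  # 0 exactly when the two ancestor sets are disjoint
  }
})

test_that("on a chain, similarity to an ancestor decreases with distance", {
  lines <- c("[Term]", "id: L:1", "name: level 1")
  for (i in 2:6) {
    lines <- c(lines, "[Term]", paste0("id: L:", i),
               paste0("name: level ", i), paste0("is_a: L:", i - 1L))
  }
  g <- parse_obo(lines)
  sims <- vapply(1:5, function(d) {
    wang_similarity(g, "L:6", paste0("L:", 6 - d))
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
})
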