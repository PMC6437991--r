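test_that("term index has one entry per usable surface with cached heads", {
  toy <- rerank_toy()
  # 5 concepts, names only, all in vocabulary
  expect_length(toy$index$entries, 5L)
  expect_equal(toy$index$dropped, 0L)
  mc <- Filter(function(e) e$surface == "medical center", toy$index$entries)[[1]]
  expect_equal(mc$head$token, "center")

  # a concept whose only surface is OOV is dropped and counted
  g <- parse_obo(c("[Term]", "id: Z:1", "name: x",
                   "[Term]", "id: Z:2", "name: qqunknown", "is_a: Z:1"))
  idx <- build_term_index(g, xy_store())
  expect_length(idx$entries, 1L)
  expect_equal(idx$dropped, 1L)

  g_oov <- parse_obo(c("[Term]", "id: Z:1", "name: qqunknown"))
  expect_error(build_term_index(g_oov, xy_store()), "empty")
})

test_that("semantic ranking returns the top-k concepts of a full sort", {
  set.seed(123)
  for (trial in 1:200) {
    n_concepts <- sample(3:12, 1L)
    dim <- sample(3:6, 1L)
    entries <- list()
    for (ci in seq_len(n_concepts)) {
      for (t in seq_len(sample(1:4, 1L))) {
        v <- rnorm(dim)
        entries[[length(entries) + 1L]] <- list(
          concept_id = sprintf("C:%03d", ci),
          surface = sprintf("s%d_%d", ci, t),
          tokens = "tok", vector = v, head = NULL, head_vector = NULL)
      }
    }
    if (length(entries) > 50L) entries <- entries[1:50]
    mat <- t(vapply(entries, `[[`, numeric(dim), "vector"))
    index <- structure(list(
      entries = entries,
      matrix = mat / sqrt(rowSums(mat^2)),
      concept_ids = vapply(entries, `[[`, character(1), "concept_id"),
      dropped = 0L, stopwords = character(0)), class = "term_index")
    mv <- structure(list(vector = rnorm(dim), contributing = 1L,
                         oov_tokens = character(0)), class = "phrase_vector")
    k <- sample(1:6, 1L)
    got <- rank_candidates(mv, index, k = k)
    # oracle: exhaustive cosine per entry, max per concept, full sort
    sims <- vapply(entries, function(e)
      cosine_similarity(mv$vector, e$vector), numeric(1))
    per_concept <- tapply(sims, index$concept_ids, max)
    ord <- order(-per_concept, names(per_concept))
    want <- names(per_concept)[ord][seq_len(min(k, length(per_concept)))]
    expect_equal(got$concept_id, want)
    expect_true(all(diff(got$score) <= 1e-12))
    expect_false(anyDuplicated(got$concept_id) > 0L)
  }
})

test_that("k larger than the number of concepts returns everything ordered", {
  toy <- rerank_toy()
  mv <- compose_vector(c("medical", "center"), toy$store)
  got <- rank_candidates(mv, toy$index, k = 100L)
  expect_equal(nrow(got), 5L)
  expect_equal(got$concept_id[1], "OBT:001423")
  expect_equal(got$score[1], 1, tolerance = 1e-12)
})

test_that("re-ranking applies the convex head-weighted score", {
  toy <- rerank_toy()
  mv <- compose_vector(preprocess_phrase(toy$mention)$tokens, toy$store)
  sem <- rank_candidates(mv, toy$index, k = 5L)
  head <- find_head(toy$parse)

  # w = 0 leaves scores and order untouched
  rr0 <- rerank_candidates(sem, head, toy$index, toy$store, w = 0)
  expect_equal(rr0$score, sem$score)
  expect_equal(rr0$concept_id, sem$concept_id)

  # direct arithmetic: S_RR = w * cos(heads) + (1 - w) * S_S
  rr <- rerank_candidates(sem, head, toy$index, toy$store, w = 0.25)
  for (cid in sem$concept_id) {
    e <- toy$index$entries[[sem$entry[match(cid, sem$concept_id)]]]
    s_head <- cosine_similarity(lookup_vector(toy$store, "children"),
                                e$head_vector)
    s_sem <- sem$score[match(cid, sem$concept_id)]
    expect_equal(rr$score[match(cid, rr$concept_id)],
                 0.25 * s_head + 0.75 * s_sem, tolerance = 1e-12)
    # convexity: the re-ranked score lies between its two ingredients
    expect_gte(rr$score[match(cid, rr$concept_id)],
               min(s_head, s_sem) - 1e-12)
    expect_lte(rr$score[match(cid, rr$concept_id)],
               max(s_head, s_sem) + 1e-12)
  }

  # with w = 1 the order is the head-similarity order
  rr1 <- rerank_candidates(sem, head, toy$index, toy$store, w = 1)
  s_heads <- vapply(sem$entry, function(i) cosine_similarity(
    lookup_vector(toy$store, "children"),
    toy$index$entries[[i]]$head_vector), numeric(1))
  expect_equal(rr1$concept_id,
               sem$concept_id[order(-s_heads, sem$concept_id)])
})

test_that("an OOV head leaves the semantic score in place", {
  store <- toy_store(rbind(alpha = c(1, 0), beta = c(0.6, 0.8),
                           gamma = c(0, 1)))
  g <- parse_obo(c("[Term]", "id: X:1", "name: alpha",
                   "[Term]", "id: X:2", "name: beta qqoovhead",
                   "is_a: X:1"))
  idx <- build_term_index(g, store)
  mv <- compose_vector("alpha", store)
  sem <- rank_candidates(mv, idx, k = 2L)
  rr <- rerank_candidates(sem, find_head(flat_parse("gamma")), idx, store,
                          w = 0.25)
  i_oov <- match("X:2", rr$concept_id)  # head "qqoovhead" has no vector
  expect_equal(rr$score[i_oov], sem$score[match("X:2", sem$concept_id)])
})

test_that("the day-care mention is re-ranked from a center concept to child", {
  toy <- rerank_toy()
  res <- link_mention(toy$mention, toy$graph, toy$store, toy$index,
                      linker_config(k = 5L, w = 0.25), parse = toy$parse)
  sem <- res$trace$semantic
  expect_equal(sem$concept_id[1], "OBT:001423")       # center-like on top
  i_child <- match("OBT:002146", sem$concept_id)
  expect_gt(i_child, 1L)                              # child buried below
  expect_equal(res$trace$reranked$concept_id[1], "OBT:002146")
  expect_equal(res$concept_id, "OBT:002146")          # child wins after
  expect_equal(res$trace$head$token, "children")
})

test_that("a mention equal to a concept name links to it with score 1", {
  toy <- rerank_toy()
  res <- link_mention("clinic", toy$graph, toy$store, toy$index,
                      linker_config(use_rerank = FALSE))
  expect_equal(res$concept_id, "OBT:001801")
  expect_equal(res$score, 1, tolerance = 1e-12)
})

test_that("all-OOV mentions follow the configured fallback", {
  toy <- rerank_toy()
  res <- link_mention("zzqx gibberish", toy$graph, toy$store, toy$index,
                      linker_config(fallback = "root"))
  expect_equal(res$concept_id, "OBT:000001")
  expect_equal(res$fallback, "root")

  # exact_then_root catches a raw surface whose tokens have no vectors,
  # even though that surface is itself dropped from the term index
  g <- parse_obo(c("[Term]", "id: X:1", "name: alpha",
                   "[Term]", "id: X:2", "name: qqrare term", "is_a: X:1"))
  store <- toy_store(rbind(alpha = c(1, 0), beta = c(0, 1)))
  idx <- build_term_index(g, store)
  expect_equal(idx$dropped, 1L)
  res <- link_mention("QQrare term", g, store, idx,
                      linker_config(fallback = "exact_then_root"))
  expect_equal(res$concept_id, "X:2")
  expect_equal(res$fallback, "exact")

  res <- link_mention("zzqx", g, store, idx,
                      linker_config(fallback = "abstain"))
  expect_true(is.na(res$concept_id))
  expect_equal(res$fallback, "abstain")
})

test_that("PPP stripping changes the composed mention before ranking", {
  toy <- rerank_toy()
  ppp <- parse_bracketed(paste0(
    "(NP (NP (NN clinic)) (PP (IN of) (NP (DT the) (NN center))))"))
  with_strip <- link_mention("clinic of the center", toy$graph, toy$store,
                             toy$index, linker_config(use_rerank = FALSE),
                             parse = ppp)
  expect_equal(with_strip$concept_id, "OBT:001801")
  expect_equal(with_strip$score, 1, tolerance = 1e-12)
  expect_true(isTRUE(with_strip$trace$ppp_stripped))
  no_strip <- link_mention("clinic of the center", toy$graph, toy$store,
                           toy$index,
                           linker_config(use_rerank = FALSE,
                                         use_ppp_strip = FALSE),
                           parse = ppp)
  expect_lt(no_strip$score, 1)
})

test_that("WMD ranking orders candidates by ascending transport cost", {
  toy <- rerank_toy()
  tokens <- preprocess_phrase("medical center")$tokens
  mv <- compose_vector(tokens, toy$store)
  got <- rank_candidates(mv, toy$index, k = 5L, metric = "wmd",
                         mention_tokens = tokens, store = toy$store)
  expect_equal(got$concept_id[1], "OBT:001423")
  expect_equal(got$score[1], 0, tolerance = 1e-9)  # identical tokens
  dists <- vapply(toy$index$entries[got$entry], function(e)
    word_movers_distance(tokens, e$tokens, toy$store), numeric(1))
  expect_equal(got$score, -dists, tolerance = 1e-9)
})
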