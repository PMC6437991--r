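# Independent brute-force oracles and small in-code fixtures shared by the
# tests. The oracles deliberately avoid the package's own code paths.

# --- ontology oracles -------------------------------------------------------

# all is_a paths from id to every ancestor, by exhaustive enumeration
enumerate_paths <- function(graph, id) {
  out <- list()
  walk <- function(node, len) {
    out[[node]] <<- c(out[[node]], len)
    for (p in graph$concepts[[node]]$parents) walk(p, len + 1L)
  }
  walk(id, 0L)
  out
}

# ancestor weights as max over enumerated paths of s^length
oracle_ancestor_weights <- function(graph, id, s) {
  paths <- enumerate_paths(graph, id)
  w <- vapply(paths, function(lens) max(s^lens), numeric(1))
  w[order(names(w))]
}

oracle_wang <- function(graph, c1, c2, s) {
  w1 <- oracle_ancestor_weights(graph, c1, s)
  w2 <- oracle_ancestor_weights(graph, c2, s)
  shared <- intersect(names(w1), names(w2))
  (sum(w1[shared]) + sum(w2[shared])) / (sum(w1) + sum(w2))
}

# random DAG: node i may take parents among nodes < i, so it is acyclic and
# node 1 is always a root
random_dag <- function(n, max_parents = 2L) {
  concepts <- list(list(id = "N001", name = "node 1",
                        synonyms = character(0), parents = character(0)))
  for (i in 2:n) {
    np <- sample(0:min(max_parents, i - 1L), 1L)
    parents <- if (np > 0L) sprintf("N%03d", sample(i - 1L, np)) else character(0)
    concepts[[i]] <- list(id = sprintf("N%03d", i),
                          name = paste("node", i),
                          synonyms = character(0), parents = parents)
  }
  ontolink:::new_ontology_graph(concepts)
}

# --- transport oracle -------------------------------------------------------

# exact min-cost transport by enumerating all integer plans on the scaled
# problem (marginals k/m, l/n become integers after scaling by m*n)
oracle_transport <- function(mass_a, mass_b, cost) {
  # smallest integer scaling of both marginals; an optimal vertex of the
  # transportation polytope is integral at that scaling
  scale <- NULL
  for (L in 1:24) {
    if (all(abs(mass_a * L - round(mass_a * L)) < 1e-9) &&
        all(abs(mass_b * L - round(mass_b * L)) < 1e-9)) { scale <- L; break }
  }
  stopifnot(!is.null(scale))
  ra <- as.integer(round(mass_a * scale))
  rb <- as.integer(round(mass_b * scale))
  m <- length(ra); n <- length(rb)
  best <- Inf
  recurse <- function(i, rows_left, cols_left, acc) {
    if (acc >= best) return(invisible(NULL))
    if (i > m) {
      if (all(cols_left == 0L)) best <<- acc
      return(invisible(NULL))
    }
    # enumerate ways to split rows_left[i] units over the n columns
    split_row <- function(j, left, cols, acc2) {
      if (acc2 >= best) return(invisible(NULL))
      if (j == n) {
        if (left <= cols[n]) {
          cols[n] <- cols[n] - left
          recurse(i + 1L, rows_left, cols, acc2 + left * cost[i, n])
        }
        return(invisible(NULL))
      }
      for (x in 0:min(left, cols[j])) {
        cols2 <- cols; cols2[j] <- cols2[j] - x
        split_row(j + 1L, left - x, cols2, acc2 + x * cost[i, j])
      }
    }
    split_row(1L, rows_left[i], cols_left, acc)
  }
  recurse(1L, ra, rb, 0)
  best / scale
}

oracle_wmd <- function(tokens_a, tokens_b, store) {
  dist_of <- function(tokens) {
    known <- tokens[tokens %in% rownames(store$vectors)]
    tab <- table(known)
    list(vecs = store$vectors[names(tab), , drop = FALSE],
         mass = as.numeric(tab) / length(known))
  }
  da <- dist_of(tokens_a); db <- dist_of(tokens_b)
  cost <- outer(seq_along(da$mass), seq_along(db$mass),
                Vectorize(function(i, j) sqrt(sum((da$vecs[i, ] - db$vecs[j, ])^2))))
  oracle_transport(da$mass, db$mass, cost)
}

# --- shared in-code fixtures ------------------------------------------------

# tiny store on explicit vectors
toy_store <- function(vectors) ontolink:::new_embedding_store(vectors)

# the dim-2 store used throughout the embedding examples
xy_store <- function() toy_store(rbind(x = c(1, 0), y = c(0, 1)))

# small hand-built ontology: root with two children, one grandchild
chain_graph <- function() {
  parse_obo(c(
    "[Term]", "id: A:1", "name: root habitat",
    "[Term]", "id: A:2", "name: middle", "is_a: A:1",
    "[Term]", "id: A:3", "name: leaf", "is_a: A:2"))
}

# clinic/child toy reproducing the re-ranking worked example qualitatively:
# the mention "children attending a day-care center" must rank a
# center-like concept first semantically and the child concept first after
# head-word re-ranking
rerank_toy <- function() {
  vecs <- rbind(
    center    = c(1, 0, 0),
    medical   = c(1, 0, 0),
    clinic    = c(1, 0, 0.2),
    research  = c(0.9, 0, 0.3),
    study     = c(0.8, 0, 0.4),
    child     = c(0.3, 0.95, 0),
    children  = c(0, 1, 0),
    attending = c(0.8, 0.2, 0),
    day       = c(0.8, 0.2, 0),
    care      = c(0.8, 0.2, 0),
    habitat   = c(0, 0, 1))
  store <- toy_store(vecs)
  graph <- parse_obo(c(
    "[Term]", "id: OBT:000001", "name: habitat",
    "[Term]", "id: OBT:000259", "name: research and study center",
    "is_a: OBT:000001",
    "[Term]", "id: OBT:001423", "name: medical center", "is_a: OBT:000001",
    "[Term]", "id: OBT:001801", "name: clinic", "is_a: OBT:000001",
    "[Term]", "id: OBT:002146", "name: child", "is_a: OBT:000001"))
  list(graph = graph, store = store,
       index = build_term_index(graph, store),
       mention = "children attending a day-care center",
       parse = parse_bracketed(paste0(
         "(NP (NP (NNS children)) (VP (VBG attending)",
         " (NP (DT a) (JJ day-care) (NN center))))")))
}

# rank-1 accuracy of predictions against a gold table with list column
rank1_accuracy <- function(predictions, gold) {
  gkey <- paste(gold$doc_id, gold$mention_id)
  pkey <- paste(predictions$doc_id, predictions$mention_id)
  hits <- vapply(seq_len(nrow(predictions)), function(i) {
    predictions$concept_id[i] %in% gold$concept_ids[[match(pkey[i], gkey)]]
  }, logical(1))
  mean(hits)
}

# full fixture pipeline at a given noise level, returning rank-1 accuracy
fixture_accuracy <- function(noise_sd, seed = 11L, n_mentions = 200L) {
  spec <- fixture_spec(seed = seed, noise_sd = noise_sd,
                       n_mentions = n_mentions)
  graph <- make_toy_ontology(spec)
  store <- make_toy_embeddings(graph, spec)
  corpus <- make_toy_corpus(graph, store, spec)
  index <- build_term_index(graph, store)
  preds <- link_corpus(corpus$mentions, graph, store, index,
                       linker_config(), corpus$parses)
  rank1_accuracy(preds, corpus$gold)
}
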