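# The linker: term index over the ontology vocabulary, semantic candidate
# ranking, and head-word weighted re-ranking of the top k candidates.

#' Linker configuration
#'
#' @param k number of semantic candidates kept for re-ranking (default 5).
#' @param w weight of the head-word similarity in the re-ranking score,
#'   in \[0, 1\] (default 0.25); the final score is
#'   `w * sim(heads) + (1 - w) * sim(phrases)`.
#' @param metric semantic similarity metric: `"cosine"` or `"wmd"` (word
#'   mover's distance; candidates are ranked by ascending distance).
#' @param use_rerank apply the syntactic re-ranking stage.
#' @param use_ppp_strip strip possessive prepositional phrases ("X of Y")
#'   from mentions before embedding.
#' @param fallback what to do for mentions with no usable token:
#'   `"exact_then_root"` (case-insensitive exact surface match, else the
#'   ontology root), `"root"`, or `"abstain"`.
#' @return A `linker_config` list.
#' @export
linker_config <- function(k = 5L, w = 0.25,
                          metric = c("cosine", "wmd"),
                          use_rerank = TRUE, use_ppp_strip = TRUE,
                          fallback = c("exact_then_root", "root", "abstain")) {
  stopifnot(k >= 1L, w >= 0, w <= 1)
  structure(list(k = as.integer(k), w = w, metric = match.arg(metric),
                 use_rerank = use_rerank, use_ppp_strip = use_ppp_strip,
                 fallback = match.arg(fallback)),
            class = "linker_config")
}

#' Build the term index over an ontology's names and synonyms
#'
#' One index entry per (concept, surface) pair, where the surfaces are the
#' concept name and each synonym. Each entry carries the preprocessed
#' tokens, the averaged phrase vector, the head word of the surface (from a
#' supplied parse, else a flat parse whose head is the last token) and the
#' head's vector when in vocabulary. Surfaces that preprocess to zero
#' tokens or are entirely out of vocabulary are dropped and counted.
#'
#' @param graph an `ontology_graph`.
#' @param store an `embedding_store`.
#' @param parses optional named list of `parse_node`, keyed by surface
#'   string, for concept-name parses from an external parser.
#' @param stopwords stop-word list used in preprocessing.
#' @return Object of class `term_index`: list with `entries` (list of
#'   per-surface records), `matrix` (row-normalized entry vectors),
#'   `concept_ids` per row, `dropped` (count of unusable surfaces) and
#'   `stopwords`.
#' @export
build_term_index <- function(graph, store, parses = NULL,
                             stopwords = default_stopwords()) {
  entries <- list()
  dropped <- 0L
  for (cp in graph$concepts) {
    for (surface in c(cp$name, cp$synonyms)) {
      tp <- tryCatch(preprocess_phrase(surface, stopwords),
                     ontolink_empty_phrase = function(e) NULL)
      if (is.null(tp)) { dropped <- dropped + 1L; next }
      pv <- tryCatch(compose_vector(tp$tokens, store),
                     ontolink_all_oov = function(e) NULL)
      if (is.null(pv)) { dropped <- dropped + 1L; next }
      tree <- if (!is.null(parses) && !is.null(parses[[surface]])) {
        parses[[surface]]
      } else {
        flat_parse(tp$tokens)
      }
      head <- find_head(tree)
      hv <- lookup_vector(store, tolower(head$token))
      entries[[length(entries) + 1L]] <- list(
        concept_id = cp$id, surface = surface, tokens = tp$tokens,
        vector = pv$vector, head = head, head_vector = hv)
    }
  }
  if (length(entries) == 0L) {
    stop("term index is empty: no ontology surface has an in-vocabulary token")
  }
  mat <- t(vapply(entries, `[[`, numeric(store$dim), "vector"))
  norms <- sqrt(rowSums(mat^2))
  structure(list(entries = entries,
                 matrix = mat / pmax(norms, .Machine$double.eps),
                 concept_ids = vapply(entries, `[[`, character(1), "concept_id"),
                 dropped = dropped,
                 stopwords = stopwords),
            class = "term_index")
}

#' @export
print.term_index <- function(x, ...) {
  cat("<term_index> ", length(x$entries), " term entries over ",
      length(unique(x$concept_ids)), " concepts (", x$dropped,
      " surfaces dropped)\n", sep = "")
  invisible(x)
}

#' Rank candidate concepts for a mention by semantic similarity
#'
#' Scores every term entry against the mention (cosine of the averaged
#' phrase vectors, or negated word mover's distance), aggregates to
#' concepts by taking each concept's best-scoring surface, and returns the
#' top `k` distinct concepts. Ties are broken by the lexicographically
#' smaller concept id so rankings are deterministic.
#'
#' @param mention_vec a `phrase_vector` for the mention.
#' @param index a `term_index`.
#' @param k number of candidates to return.
#' @param metric `"cosine"` or `"wmd"`.
#' @param mention_tokens mention tokens; required for `metric = "wmd"`.
#' @param store the `embedding_store`; required for `metric = "wmd"`.
#' @return A `candidate_list`: data.frame with columns `concept_id`,
#'   `surface`, `score`, carrying attribute `stage = "semantic"`.
#' @export
rank_candidates <- function(mention_vec, index, k = 5L,
                            metric = c("cosine", "wmd"),
                            mention_tokens = NULL, store = NULL) {
  metric <- match.arg(metric)
  stopifnot(k >= 1L, length(index$entries) >= 1L)
  if (metric == "cosine") {
    v <- mention_vec$vector
    v <- v / sqrt(sum(v^2))
    scores <- as.vector(index$matrix %*% v)
  } else {
    stopifnot(!is.null(mention_tokens), !is.null(store))
    scores <- -vapply(index$entries, function(e) {
      word_movers_distance(mention_tokens, e$tokens, store)
    }, numeric(1))
  }
  surfaces <- vapply(index$entries, `[[`, character(1), "surface")
  # best surface per concept, then top-k concepts
  ord <- order(-scores, index$concept_ids, surfaces)
  first <- ord[!duplicated(index$concept_ids[ord])]
  top <- first[seq_len(min(k, length(first)))]
  out <- data.frame(concept_id = index$concept_ids[top],
                    surface = surfaces[top],
                    score = scores[top],
                    entry = top,
                    stringsAsFactors = FALSE)
  attr(out, "stage") <- "semantic"
  out
}

#' Re-rank candidates by head-word weighted similarity
#'
#' Rescores each candidate `c` of mention `m` as
#' `S_RR(m, c) = w * S(m_head, c_head) + (1 - w) * S(m, c)`,
#' where `S(m_head, c_head)` is the cosine similarity of the head-word
#' vectors and `S(m, c)` the candidate's semantic-stage score. When the
#' mention head or a candidate's head is out of vocabulary, that
#' candidate's score is left at `S(m, c)`.
#'
#' @param candidates a semantic-stage `candidate_list`.
#' @param mention_head a `head_result` for the mention.
#' @param index the `term_index` the candidates came from.
#' @param store the `embedding_store`.
#' @param w head weight in \[0, 1\].
#' @return A `candidate_list` with `stage = "reranked"`, re-sorted (ties by
#'   concept id).
#' @export
rerank_candidates <- function(candidates, mention_head, index, store,
                              w = 0.25) {
  stopifnot(identical(attr(candidates, "stage"), "semantic"),
            w >= 0, w <= 1)
  mh_vec <- lookup_vector(store, tolower(mention_head$token))
  new_scores <- candidates$score
  if (!is.null(mh_vec)) {
    for (i in seq_len(nrow(candidates))) {
      e <- index$entries[[candidates$entry[i]]]
      if (is.null(e$head_vector)) next
      s_head <- cosine_similarity(mh_vec, e$head_vector)
      new_scores[i] <- w * s_head + (1 - w) * candidates$score[i]
    }
  }
  out <- candidates
  out$score <- new_scores
  out <- out[order(-out$score, out$concept_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage") <- "reranked"
  out
}

#' Link a single mention to an ontology concept
#'
#' Full pipeline: preprocess the mention, optionally strip a possessive
#' prepositional phrase using its parse, average the token vectors, rank
#' all concepts semantically, keep the top `k`, find the mention head and
#' re-rank, and return the rank-1 concept. Mentions with no usable token
#' (empty after preprocessing, or fully out of vocabulary) are resolved by
#' the configured fallback.
#'
#' @param text the mention string.
#' @param graph the `ontology_graph`.
#' @param store the `embedding_store`.
#' @param index the `term_index` built from `graph` and `store`.
#' @param config a `linker_config`.
#' @param parse optional `parse_node` for the mention; when absent a flat
#'   parse of the preprocessed tokens is used.
#' @return List with `concept_id` (NA when abstaining), `score`, `fallback`
#'   (`"none"`, `"exact"`, `"root"` or `"abstain"`) and `trace` (tokens,
#'   head, semantic and re-ranked candidate lists).
#' @export
link_mention <- function(text, graph, store, index,
                         config = linker_config(), parse = NULL) {
  trace <- list()
  tokens <- tryCatch({
    tp <- preprocess_phrase(text, index$stopwords)
    tp$tokens
  }, ontolink_empty_phrase = function(e) NULL)
  tree <- if (!is.null(parse)) parse else if (!is.null(tokens)) {
    flat_parse(tokens)
  } else {
    NULL
  }
  if (!is.null(tokens) && config$use_ppp_strip && !is.null(parse)) {
    kept_raw <- strip_possessive_pp(parse)
    if (length(kept_raw) < length(parse_leaves(parse))) {
      stripped <- tryCatch(
        preprocess_phrase(paste(kept_raw, collapse = " "), index$stopwords),
        ontolink_empty_phrase = function(e) NULL)
      if (!is.null(stripped)) {
        tokens <- stripped$tokens
        tree <- flat_parse(tokens)  # head comes from the kept NP
        trace$ppp_stripped <- TRUE
      }
    }
  }
  mention_vec <- if (is.null(tokens)) NULL else {
    tryCatch(compose_vector(tokens, store),
             ontolink_all_oov = function(e) NULL)
  }
  if (is.null(mention_vec)) {
    return(.fallback_link(text, graph, index, config, trace))
  }
  trace$tokens <- tokens
  trace$oov_tokens <- mention_vec$oov_tokens
  sem <- rank_candidates(mention_vec, index, k = config$k,
                         metric = config$metric,
                         mention_tokens = tokens, store = store)
  trace$semantic <- sem
  final <- sem
  if (config$use_rerank) {
    head <- find_head(tree)
    trace$head <- head
    final <- rerank_candidates(sem, head, index, store, w = config$w)
    trace$reranked <- final
  }
  list(concept_id = final$concept_id[1], score = final$score[1],
       fallback = "none", trace = trace)
}

.fallback_link <- function(text, graph, index, config, trace) {
  trace$all_oov <- TRUE
  if (config$fallback == "exact_then_root") {
    # match against every ontology surface, not only the indexed ones: an
    # all-OOV mention's exact match is usually itself OOV and unindexed
    target <- tolower(trimws(text))
    hits <- character(0)
    for (cp in graph$concepts) {
      if (target %in% tolower(c(cp$name, cp$synonyms))) hits <- c(hits, cp$id)
    }
    if (length(hits)) {
      trace$fallback <- "exact"
      return(list(concept_id = sort(hits)[1], score = NA_real_,
                  fallback = "exact", trace = trace))
    }
  }
  if (config$fallback == "abstain") {
    trace$fallback <- "abstain"
    return(list(concept_id = NA_character_, score = NA_real_,
                fallback = "abstain", trace = trace))
  }
  trace$fallback <- "root"
  list(concept_id = sort(graph$roots)[1], score = NA_real_,
       fallback = "root", trace = trace)
}

#' Link every mention of a corpus
#'
#' Applies [link_mention()] to each row of a mentions data.frame, using the
#' parse table when a parse is available for a mention.
#'
#' @param mentions mentions data.frame ([read_a1()] / [read_mentions_tsv()]).
#' @param graph,store,index,config as in [link_mention()].
#' @param parses optional named list of `parse_node` keyed by
#'   `"doc_id:mention_id"` or by bare mention id (as from
#'   [read_parse_table()]).
#' @return Predictions data.frame: `doc_id`, `mention_id`, `text`,
#'   `concept_id`, `score`, `fallback`; abstained mentions are omitted.
#' @export
link_corpus <- function(mentions, graph, store, index,
                        config = linker_config(), parses = NULL) {
  rows <- lapply(seq_len(nrow(mentions)), function(i) {
    parse <- if (!is.null(parses)) {
      p <- parses[[paste(mentions$doc_id[i], mentions$mention_id[i],
                         sep = ":")]]
      if (is.null(p)) p <- parses[[mentions$mention_id[i]]]
      if (is.character(p)) p <- parse_bracketed(p)
      p
    } else NULL
    res <- link_mention(mentions$text[i], graph, store, index, config, parse)
    if (is.na(res$concept_id)) return(NULL)
    data.frame(doc_id = mentions$doc_id[i],
               mention_id = mentions$mention_id[i],
               text = mentions$text[i],
               concept_id = res$concept_id,
               score = ifelse(is.na(res$score), 0, res$score),
               fallback = res$fallback,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(doc_id = character(0),
                                      mention_id = character(0),
                                      text = character(0),
                                      concept_id = character(0),
                                      score = numeric(0),
                                      fallback = character(0),
                                      stringsAsFactors = FALSE)
  out
}
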