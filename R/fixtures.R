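# Deterministic synthetic fixtures: a toy habitat-style ontology, clustered
# toy embeddings and a mention corpus with parses, so the full pipeline can
# be exercised and written to the real external formats without downloads.

#' Fixture specification
#'
#' @param seed integer seed; all fixture randomness derives from it.
#' @param n_levels depth of the complete concept tree below the root.
#' @param branching children per node.
#' @param dim embedding dimension (>= 2).
#' @param noise_sd standard deviation of the per-token Gaussian noise added
#'   to the concept base vectors.
#' @param n_mentions number of corpus mentions.
#' @param paraphrase_rate fraction of mentions rendered as an unseen
#'   paraphrase of the concept (an alias token tied to the concept's base
#'   vector that appears in no ontology surface) instead of an exact
#'   name/synonym string; these are the mentions whose linking can degrade
#'   with noise.
#' @param oov_rate fraction of mentions replaced by out-of-vocabulary
#'   gibberish, exercising the fallback path.
#' @param ppp_rate fraction of (non-gibberish) mentions wrapped in an
#'   "X of the patients" possessive construction, exercising PPP stripping.
#' @param n_docs number of documents the mentions are spread over.
#' @param n_distractors extra vocabulary tokens unrelated to any concept.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_levels = 2L, branching = 3L,
                         dim = 20L, noise_sd = 0, n_mentions = 200L,
                         paraphrase_rate = 0.5, oov_rate = 0,
                         ppp_rate = 0.2, n_docs = 5L, n_distractors = 30L) {
  stopifnot(dim >= 2L, noise_sd >= 0,
            paraphrase_rate >= 0, paraphrase_rate <= 1,
            oov_rate >= 0, oov_rate <= 1, ppp_rate >= 0, ppp_rate <= 1)
  structure(list(seed = as.integer(seed), n_levels = as.integer(n_levels),
                 branching = as.integer(branching), dim = as.integer(dim),
                 noise_sd = noise_sd, n_mentions = as.integer(n_mentions),
                 paraphrase_rate = paraphrase_rate, oov_rate = oov_rate,
                 ppp_rate = ppp_rate, n_docs = as.integer(n_docs),
                 n_distractors = as.integer(n_distractors)),
            class = "fixture_spec")
}

# run expr under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# unique lowercase letter tag for concept i: "qa", "qb", ..., "qaa", ...
.int2tag <- function(i) {
  s <- ""
  repeat {
    s <- paste0(letters[(i - 1L) %% 26L + 1L], s)
    i <- (i - 1L) %/% 26L
    if (i == 0L) break
  }
  paste0("q", s)
}

#' Generate a toy ontology
#'
#' A complete is_a tree of depth `n_levels` with `branching` children per
#' node. Every concept carries a unique distinctive token in its name
#' (`concept-<tag>`) and in its one or two synonyms (`<tag> site`,
#' `typical <tag>`), so surfaces of different concepts never collide.
#'
#' @param spec a `fixture_spec`.
#' @return An `ontology_graph`.
#' @export
make_toy_ontology <- function(spec) {
  concepts <- list()
  counter <- 0L
  add <- function(level, parent_id) {
    counter <<- counter + 1L
    tag <- .int2tag(counter)
    id <- sprintf("TOY:%06d", counter)
    syns <- paste(tag, "site")
    if (counter %% 2L == 0L) syns <- c(syns, paste("typical", tag))
    concepts[[length(concepts) + 1L]] <<- list(
      id = id, name = paste0("concept-", tag), synonyms = syns,
      parents = if (is.null(parent_id)) character(0) else parent_id)
    if (level < spec$n_levels) {
      for (b in seq_len(spec$branching)) add(level + 1L, id)
    }
    id
  }
  add(0L, NULL)
  new_ontology_graph(concepts)
}

# tokens of all surfaces of a concept, with the package's preprocessing
.concept_tokens <- function(cp, stopwords) {
  unique(unlist(lapply(c(cp$name, cp$synonyms), function(s) {
    tryCatch(preprocess_phrase(s, stopwords)$tokens,
             ontolink_empty_phrase = function(e) character(0))
  })))
}

.alias_token <- function(id) paste0(sub("TOY:0*", "alias", id), "x")

#' Generate toy embeddings clustered around concept base vectors
#'
#' Each concept draws a unit-norm base vector. Every token occurring in a
#' concept's name or synonyms gets the average of the bases of the concepts
#' it occurs in, plus per-token Gaussian noise of sd `noise_sd`. Each
#' concept additionally gets an unseen alias token (used for paraphrase
#' mentions) drawn from the same base, and distractor tokens get
#' independent random unit vectors.
#'
#' @param graph the toy `ontology_graph`.
#' @param spec a `fixture_spec`.
#' @param stopwords stop words used to tokenize the surfaces.
#' @return An `embedding_store`.
#' @export
make_toy_embeddings <- function(graph, spec,
                                stopwords = default_stopwords()) {
  .with_seed(spec$seed, {
    ids <- names(graph$concepts)
    bases <- matrix(stats::rnorm(length(ids) * spec$dim), ncol = spec$dim)
    bases <- bases / sqrt(rowSums(bases^2))
    rownames(bases) <- ids
    tok2cps <- list()
    for (cp in graph$concepts) {
      for (tok in .concept_tokens(cp, stopwords)) {
        tok2cps[[tok]] <- c(tok2cps[[tok]], cp$id)
      }
    }
    toks <- sort(names(tok2cps))
    vecs <- t(vapply(toks, function(tok) {
      v <- colMeans(bases[tok2cps[[tok]], , drop = FALSE])
      v + stats::rnorm(spec$dim, 0, spec$noise_sd)
    }, numeric(spec$dim)))
    alias <- t(vapply(ids, function(id) {
      bases[id, ] + stats::rnorm(spec$dim, 0, spec$noise_sd)
    }, numeric(spec$dim)))
    rownames(alias) <- vapply(ids, .alias_token, character(1))
    extra_toks <- c("patients", paste0("filler", seq_len(spec$n_distractors)))
    extra <- matrix(stats::rnorm(length(extra_toks) * spec$dim),
                    ncol = spec$dim)
    extra <- extra / sqrt(rowSums(extra^2))
    rownames(extra) <- extra_toks
    new_embedding_store(rbind(vecs, alias, extra))
  })
}

#' Generate a toy mention corpus with gold normalizations and parses
#'
#' Each mention is sampled from a concept: rendered as the exact name or a
#' synonym, or (with `paraphrase_rate`) as an unseen alias phrase tied to
#' the concept's base vector. A fraction `ppp_rate` is wrapped as
#' `"<surface> of the patients"` with a matching NP-PP(of)-NP parse to
#' exercise possessive-PP stripping, and a fraction `oov_rate` is replaced
#' by out-of-vocabulary gibberish to exercise the fallback. Flat NP parses
#' are emitted for all other mentions. Mentions are spread over `n_docs`
#' documents with consistent standoff character offsets.
#'
#' @param graph the toy `ontology_graph`.
#' @param store the matching `embedding_store` (unused for sampling but
#'   kept so corpus and embeddings stay in lockstep in signatures).
#' @param spec a `fixture_spec`.
#' @return List with `mentions` (data.frame), `gold` (data.frame),
#'   `parses` (named list of bracketed strings keyed by
#'   `doc_id:mention_id`-unique mention ids) and `doc_texts`.
#' @export
make_toy_corpus <- function(graph, store, spec) {
  .with_seed(spec$seed + 1L, {
    ids <- names(graph$concepts)
    pick <- sample(ids, spec$n_mentions, replace = TRUE)
    doc_of <- sprintf("doc%02d", rep_len(seq_len(spec$n_docs),
                                         spec$n_mentions))
    u_kind <- stats::runif(spec$n_mentions)
    u_oov <- stats::runif(spec$n_mentions)
    u_ppp <- stats::runif(spec$n_mentions)
    u_surface <- stats::runif(spec$n_mentions)
    texts <- character(spec$n_mentions)
    parses <- character(spec$n_mentions)
    for (i in seq_len(spec$n_mentions)) {
      cp <- graph$concepts[[pick[i]]]
      if (u_oov[i] < spec$oov_rate) {
        texts[i] <- sprintf("zzgibber%d zzunseen%d", i, i)
        parses[i] <- serialize_parse(
          flat_parse(strsplit(texts[i], " ")[[1]]))
        next
      }
      surface <- if (u_kind[i] < spec$paraphrase_rate) {
        paste(.alias_token(cp$id), "site")
      } else {
        surfaces <- c(cp$name, cp$synonyms)
        surfaces[ceiling(u_surface[i] * length(surfaces))]
      }
      toks <- preprocess_phrase(surface)$tokens
      if (u_ppp[i] < spec$ppp_rate) {
        texts[i] <- paste(surface, "of the patients")
        inner <- paste(vapply(toks, function(t) sprintf("(NN %s)", t),
                              character(1)), collapse = " ")
        parses[i] <- sprintf(
          "(NP (NP %s) (PP (IN of) (NP (DT the) (NNS patients))))", inner)
      } else {
        texts[i] <- surface
        parses[i] <- serialize_parse(flat_parse(toks))
      }
    }
    # per-doc standoff ids and character offsets in a synthetic doc text
    mention_id <- character(spec$n_mentions)
    spans <- vector("list", spec$n_mentions)
    doc_texts <- stats::setNames(
      rep("", spec$n_docs), sprintf("doc%02d", seq_len(spec$n_docs)))
    counters <- stats::setNames(integer(spec$n_docs), names(doc_texts))
    for (i in seq_len(spec$n_mentions)) {
      d <- doc_of[i]
      counters[d] <- counters[d] + 1L
      mention_id[i] <- paste0("T", counters[d])
      start <- nchar(doc_texts[d])
      spans[[i]] <- matrix(c(start, start + nchar(texts[i])), 1L, 2L,
                           dimnames = list(NULL, c("start", "end")))
      doc_texts[d] <- paste0(doc_texts[d], texts[i], " . ")
    }
    key <- paste(doc_of, mention_id, sep = ":")
    mentions <- data.frame(doc_id = doc_of, mention_id = mention_id,
                           entity_type = "Habitat", spans = I(spans),
                           text = texts, stringsAsFactors = FALSE)
    gold <- data.frame(doc_id = doc_of, mention_id = mention_id,
                       concept_ids = I(as.list(pick)),
                       stringsAsFactors = FALSE)
    list(mentions = mentions, gold = gold,
         parses = stats::setNames(as.list(parses), key),
         doc_texts = doc_texts)
  })
}

#' Write a full fixture set to disk in the real external formats
#'
#' Emits the ontology as OBO, the embeddings in word2vec text format, the
#' corpus as per-document .a1/.a2 standoff plus .txt source text, a parse
#' table, and generic mentions/gold TSVs.
#'
#' @param dir output directory (created if needed).
#' @param spec a `fixture_spec`.
#' @return Invisibly, a list with the in-memory fixture objects and `dir`.
#' @export
write_fixture_dir <- function(dir, spec = fixture_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  graph <- make_toy_ontology(spec)
  store <- make_toy_embeddings(graph, spec)
  corpus <- make_toy_corpus(graph, store, spec)
  writeLines(write_obo(graph), file.path(dir, "ontology.obo"))
  write_word_vectors(store, file.path(dir, "vectors.txt"))
  for (d in unique(corpus$mentions$doc_id)) {
    m <- corpus$mentions[corpus$mentions$doc_id == d, , drop = FALSE]
    g <- corpus$gold[corpus$gold$doc_id == d, , drop = FALSE]
    writeLines(format_a1(m), file.path(dir, paste0(d, ".a1")))
    writeLines(format_a2(g), file.path(dir, paste0(d, ".a2")))
    writeLines(corpus$doc_texts[[d]], file.path(dir, paste0(d, ".txt")))
  }
  write_parse_table(corpus$parses, file.path(dir, "parses.tsv"))
  con <- file(file.path(dir, "mentions.tsv"), "w", encoding = "UTF-8")
  writeLines(paste(corpus$mentions$doc_id, corpus$mentions$mention_id,
                   corpus$mentions$text, sep = "\t"), con)
  close(con)
  con <- file(file.path(dir, "gold.tsv"), "w", encoding = "UTF-8")
  for (i in seq_len(nrow(corpus$gold))) {
    writeLines(paste(corpus$gold$doc_id[i], corpus$gold$mention_id[i],
                     corpus$mentions$text[i], corpus$gold$concept_ids[[i]],
                     sep = "\t"), con)
  }
  close(con)
  invisible(list(dir = dir, spec = spec, graph = graph, store = store,
                 corpus = corpus))
}
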