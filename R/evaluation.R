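# Evaluation: ontology-aware precision via Wang similarity, exact-match
# micro/macro precision/recall/F, and the two reference baselines.

#' Ontology-aware precision of normalization predictions
#'
#' For each predicted mention, the similarity to the gold annotation is the
#' Wang similarity between the predicted and the reference concept (the
#' maximum over referents when a mention has several gold concepts), and
#' \deqn{Precision = \sum S_p / N} with `N` the number of predicted
#' mentions. Exact predictions contribute 1; predictions in the right
#' region of the ontology still earn partial credit.
#'
#' @param predictions predictions data.frame (`doc_id`, `mention_id`,
#'   `concept_id`).
#' @param gold normalization data.frame (`doc_id`, `mention_id`,
#'   `concept_ids` list column).
#' @param graph the `ontology_graph`.
#' @param s Wang decay parameter (default 0.65, the Bacteria Biotope
#'   evaluation setting).
#' @return Precision in (0, 1].
#' @export
bb_precision <- function(predictions, gold, graph, s = 0.65) {
  if (nrow(predictions) == 0L) stop("no predictions to evaluate")
  gkey <- paste(gold$doc_id, gold$mention_id)
  pkey <- paste(predictions$doc_id, predictions$mention_id)
  miss <- setdiff(pkey, gkey)
  if (length(miss)) {
    stop("prediction(s) for mention(s) absent from gold: ",
         paste(utils::head(miss, 3L), collapse = ", "))
  }
  sims <- vapply(seq_len(nrow(predictions)), function(i) {
    refs <- gold$concept_ids[[match(pkey[i], gkey)]]
    max(vapply(refs, function(r) {
      wang_similarity(graph, predictions$concept_id[i], r, s)
    }, numeric(1)))
  }, numeric(1))
  sum(sims) / nrow(predictions)
}

#' Per-document exact-match counts
#'
#' Compares predictions with gold by exact concept-id matching: a
#' prediction is a true positive when its concept is among the mention's
#' gold concepts; remaining predictions are false positives; gold records
#' with no correct prediction are false negatives. Documents appearing only
#' in the gold (no predictions) are kept with tp = fp = 0.
#'
#' @param predictions,gold as in [bb_precision()].
#' @return data.frame with columns `doc_id`, `tp`, `fp`, `fn`.
#' @export
exact_counts <- function(predictions, gold) {
  docs <- sort(unique(c(predictions$doc_id, gold$doc_id)))
  out <- lapply(docs, function(d) {
    p <- predictions[predictions$doc_id == d, , drop = FALSE]
    g <- gold[gold$doc_id == d, , drop = FALSE]
    correct <- logical(nrow(p))
    hit <- logical(nrow(g))
    for (i in seq_len(nrow(p))) {
      j <- match(p$mention_id[i], g$mention_id)
      if (!is.na(j) && p$concept_id[i] %in% g$concept_ids[[j]]) {
        correct[i] <- TRUE
        hit[j] <- TRUE
      }
    }
    data.frame(doc_id = d, tp = sum(correct), fp = sum(!correct),
               fn = sum(!hit), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Harmonic mean of a precision and a recall
#'
#' The aggregation used for both micro and macro F: `2PR / (P + R)`,
#' defined as 0 when both inputs are 0.
#'
#' @param p,r precision and recall in \[0, 1\].
#' @return F-score in \[0, 1\].
#' @export
f_score <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Micro-averaged precision, recall and F-score
#'
#' Pools true/false positives and false negatives over all documents:
#' `P = sum(tp) / sum(tp + fp)`, `R = sum(tp) / sum(tp + fn)`,
#' `F = 2PR / (P + R)`.
#'
#' @param counts data.frame from [exact_counts()].
#' @return Named list with `precision`, `recall`, `fscore`.
#' @export
micro_scores <- function(counts) {
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  if (tp + fp == 0 || tp + fn == 0) {
    warning("no predictions or no gold records; scores set to 0")
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(precision = p, recall = r, fscore = f_score(p, r))
}

#' Macro-averaged precision, recall and F-score
#'
#' Averages per-document precision and recall over documents (a document
#' with a zero denominator contributes 0 and stays in the average); the
#' F-score is the harmonic mean of the macro precision and macro recall.
#'
#' @param counts data.frame from [exact_counts()].
#' @return Named list with `precision`, `recall`, `fscore`.
#' @export
macro_scores <- function(counts) {
  if (nrow(counts) == 0L) {
    warning("no documents; scores set to 0")
    return(list(precision = 0, recall = 0, fscore = 0))
  }
  pd <- ifelse(counts$tp + counts$fp == 0, 0,
               counts$tp / (counts$tp + counts$fp))
  rd <- ifelse(counts$tp + counts$fn == 0, 0,
               counts$tp / (counts$tp + counts$fn))
  p <- mean(pd); r <- mean(rd)
  list(precision = p, recall = r, fscore = f_score(p, r))
}

#' Exact-match-or-root baseline
#'
#' Assigns each mention the concept whose name or synonym equals the
#' mention text case-insensitively (ties broken by the smaller concept id);
#' mentions with no exact match go to the ontology root.
#'
#' @param mentions mentions data.frame.
#' @param graph the `ontology_graph`.
#' @return Predictions data.frame.
#' @export
baseline_exact_or_root <- function(mentions, graph) {
  surf <- list()
  for (cp in graph$concepts) {
    for (sfc in tolower(c(cp$name, cp$synonyms))) {
      surf[[sfc]] <- c(surf[[sfc]], cp$id)
    }
  }
  root <- sort(graph$roots)[1]
  data.frame(
    doc_id = mentions$doc_id,
    mention_id = mentions$mention_id,
    text = mentions$text,
    concept_id = vapply(tolower(trimws(mentions$text)), function(t) {
      ids <- surf[[t]]
      if (is.null(ids)) root else sort(ids)[1]
    }, character(1), USE.NAMES = FALSE),
    score = NA_real_,
    fallback = "baseline",
    stringsAsFactors = FALSE
  )
}

#' All-to-root baseline
#'
#' Assigns every mention to the ontology root concept.
#'
#' @param mentions mentions data.frame.
#' @param graph the `ontology_graph`.
#' @return Predictions data.frame.
#' @export
baseline_all_root <- function(mentions, graph) {
  data.frame(
    doc_id = mentions$doc_id,
    mention_id = mentions$mention_id,
    text = mentions$text,
    concept_id = sort(graph$roots)[1],
    score = NA_real_,
    fallback = "baseline",
    stringsAsFactors = FALSE
  )
}
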