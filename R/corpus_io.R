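# Corpus IO: BioNLP-ST standoff (.a1 entity spans, .a2 normalizations)
# and generic mention/gold/prediction TSV formats.
#
# Mentions are data.frames with columns doc_id, mention_id, entity_type,
# spans (list column of 2-column start/end matrices, 0-based half-open)
# and text. Normalization records are data.frames with doc_id, mention_id
# and concept_ids (list column, >= 1 id per record).

.empty_mentions <- function() {
  data.frame(doc_id = character(0), mention_id = character(0),
             entity_type = character(0), spans = I(list()),
             text = character(0), stringsAsFactors = FALSE)
}

#' Read a BioNLP-ST .a1 entity file
#'
#' Each line is `Tn<TAB>TYPE start end[;start end...]<TAB>text`.
#' Discontinuous annotations keep their fragments as separate rows of the
#' span matrix; offsets are 0-based half-open; the mention text is taken
#' verbatim from the third column.
#'
#' @param path file path (or a character vector of lines via `lines =`).
#' @param doc_id document identifier stored with each mention; defaults to
#'   the file base name without extension.
#' @param lines optional character vector of lines instead of a file.
#' @return Mentions data.frame (see file header).
#' @export
read_a1 <- function(path, doc_id = NULL, lines = NULL) {
  if (is.null(lines)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (is.null(doc_id)) doc_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (is.null(doc_id)) doc_id <- "doc"
  lines <- lines[nzchar(lines)]
  ids <- character(0); types <- character(0)
  spans <- list(); texts <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop(".a1 line ", i, " has fewer than 3 columns")
    if (!grepl("^T[0-9]+$", parts[1])) next  # non-entity standoff lines
    mid <- parts[1]
    if (mid %in% ids) stop(".a1 line ", i, ": duplicate mention id ", mid)
    ann <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    frag <- strsplit(paste(ann[-1], collapse = " "), ";", fixed = TRUE)[[1]]
    sp <- t(vapply(frag, function(f) {
      se <- strsplit(trimws(f), " ", fixed = TRUE)[[1]]
      v <- suppressWarnings(as.integer(se))
      if (length(v) != 2L || anyNA(v) || v[1] < 0L || v[2] < v[1]) {
        stop(".a1 line ", i, ": malformed offsets '", f, "'")
      }
      v
    }, integer(2)))
    dimnames(sp) <- list(NULL, c("start", "end"))
    if (nrow(sp) > 1L) {
      if (is.unsorted(sp[, "start"], strictly = TRUE) ||
          any(sp[-1L, "start"] < sp[-nrow(sp), "end"])) {
        stop(".a1 line ", i, ": overlapping or unsorted fragments")
      }
    }
    ids <- c(ids, mid); types <- c(types, ann[1])
    spans <- c(spans, list(sp)); texts <- c(texts, parts[3])
  }
  data.frame(doc_id = rep(doc_id, length(ids)), mention_id = ids,
             entity_type = types, spans = I(spans), text = texts,
             stringsAsFactors = FALSE)
}

#' Write mentions of one document to .a1 lines
#' @param mentions mentions data.frame (single doc).
#' @return Character vector of .a1 lines.
#' @export
format_a1 <- function(mentions) {
  vapply(seq_len(nrow(mentions)), function(i) {
    sp <- mentions$spans[[i]]
    frag <- paste(apply(sp, 1L, paste, collapse = " "), collapse = ";")
    paste(mentions$mention_id[i],
          paste(mentions$entity_type[i], frag),
          mentions$text[i], sep = "\t")
  }, character(1))
}

#' Read a BioNLP-ST .a2 normalization file
#'
#' Each line is `Nn<TAB>OntoBiotope Annotation:Tm Referent:CONCEPT`.
#' Multiple referents for one mention are merged into a single record with
#' several concept ids.
#'
#' @param path file path (or `lines =`).
#' @param doc_id document id; defaults to the file base name.
#' @param lines optional character vector of lines.
#' @return Normalization data.frame: `doc_id`, `mention_id`, `concept_ids`
#'   (list column).
#' @export
read_a2 <- function(path, doc_id = NULL, lines = NULL) {
  if (is.null(lines)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (is.null(doc_id)) doc_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (is.null(doc_id)) doc_id <- "doc"
  lines <- lines[nzchar(lines)]
  refs <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !grepl("^N[0-9]+$", parts[1])) next
    m_ann <- regmatches(parts[2], regexec("Annotation:(\\S+)", parts[2]))[[1]]
    m_ref <- regmatches(parts[2], regexec("Referent:(\\S+)", parts[2]))[[1]]
    if (length(m_ann) < 2L || length(m_ref) < 2L) {
      stop(".a2 line ", i, " lacks Annotation:/Referent: fields")
    }
    mid <- m_ann[2]
    refs[[mid]] <- c(refs[[mid]], m_ref[2])
  }
  data.frame(doc_id = rep(doc_id, length(refs)),
             mention_id = names(refs),
             concept_ids = I(unname(refs)),
             stringsAsFactors = FALSE)
}

#' Write normalization records of one document to .a2 lines
#' @param records normalization data.frame (single doc).
#' @param type annotation type written on each line.
#' @return Character vector of .a2 lines.
#' @export
format_a2 <- function(records, type = "OntoBiotope") {
  out <- character(0)
  n <- 0L
  for (i in seq_len(nrow(records))) {
    for (cid in records$concept_ids[[i]]) {
      n <- n + 1L
      out <- c(out, sprintf("N%d\t%s Annotation:%s Referent:%s",
                            n, type, records$mention_id[i], cid))
    }
  }
  out
}

#' Read a generic mentions TSV
#'
#' Format: `doc_id<TAB>mention_id<TAB>text`, UTF-8, no header. Character
#' offsets are unavailable in this format and left empty.
#'
#' @param path file path.
#' @return Mentions data.frame.
#' @export
read_mentions_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_mentions())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) < 3L)) {
    stop("mentions TSV requires 3 columns: doc_id, mention_id, text")
  }
  data.frame(
    doc_id = vapply(parts, `[[`, character(1), 1L),
    mention_id = vapply(parts, `[[`, character(1), 2L),
    entity_type = NA_character_,
    spans = I(rep(list(matrix(integer(0), 0, 2,
                              dimnames = list(NULL, c("start", "end")))),
                  length(parts))),
    text = vapply(parts, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
}

#' Read a generic gold-normalization TSV
#'
#' Format: `doc_id<TAB>mention_id<TAB>text<TAB>concept_id`. Multiple lines
#' for one mention merge into one record with several concept ids.
#'
#' @param path file path.
#' @return Normalization data.frame.
#' @export
read_gold_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) < 4L)) {
    stop("gold TSV requires 4 columns: doc_id, mention_id, text, concept_id")
  }
  key <- paste(vapply(parts, `[[`, character(1), 1L),
               vapply(parts, `[[`, character(1), 2L), sep = "\r")
  cids <- split(vapply(parts, `[[`, character(1), 4L), key)
  keys <- strsplit(names(cids), "\r", fixed = TRUE)
  out <- data.frame(
    doc_id = vapply(keys, `[[`, character(1), 1L),
    mention_id = vapply(keys, `[[`, character(1), 2L),
    concept_ids = I(unname(lapply(cids, unique))),
    stringsAsFactors = FALSE
  )
  out[order(out$doc_id, out$mention_id), , drop = FALSE]
}

#' Write predictions to TSV
#'
#' Format: `doc_id<TAB>mention_id<TAB>mention_text<TAB>concept_id<TAB>score
#' <TAB>fallback_flag`.
#'
#' @param predictions predictions data.frame as returned by [link_corpus()].
#' @param path output file path.
#' @export
write_predictions_tsv <- function(predictions, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%s\t%s\t%s\t%s\t%.6f\t%s",
                     predictions$doc_id, predictions$mention_id,
                     predictions$text, predictions$concept_id,
                     predictions$score, predictions$fallback),
             con)
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions_tsv()]
#' @param path file path.
#' @return Predictions data.frame.
#' @export
read_predictions_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) < 6L)) {
    stop("predictions TSV requires 6 columns")
  }
  data.frame(
    doc_id = vapply(parts, `[[`, character(1), 1L),
    mention_id = vapply(parts, `[[`, character(1), 2L),
    text = vapply(parts, `[[`, character(1), 3L),
    concept_id = vapply(parts, `[[`, character(1), 4L),
    score = as.numeric(vapply(parts, `[[`, character(1), 5L)),
    fallback = vapply(parts, `[[`, character(1), 6L),
    stringsAsFactors = FALSE
  )
}
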