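# Ontology graphs: OBO parsing, flat dictionaries, ancestor weights and
# Wang semantic similarity over the is_a hierarchy.

#' Construct an ontology graph from a list of concepts
#'
#' Low-level constructor shared by [parse_obo()] and [dictionary_as_graph()].
#' Validates referential integrity and acyclicity of the `is_a` relation.
#'
#' @param concepts named list; each element a list with fields `id`, `name`,
#'   `synonyms` (character vector) and `parents` (character vector of ids).
#' @return An object of class `ontology_graph`: a list with `concepts`
#'   (named list as above) and `roots` (ids with no parents).
#' @keywords internal
new_ontology_graph <- function(concepts) {
  ids <- vapply(concepts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate concept id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(concepts) <- ids
  for (cp in concepts) {
    bad <- setdiff(cp$parents, ids)
    if (length(bad)) {
      stop("concept ", cp$id, " has is_a reference to undefined id(s): ",
           paste(bad, collapse = ", "))
    }
  }
  cyc <- .find_cycle(concepts)
  if (!is.null(cyc)) {
    stop("is_a relation contains a cycle involving concept ", cyc)
  }
  roots <- ids[vapply(concepts, function(cp) length(cp$parents) == 0L, logical(1))]
  if (length(roots) == 0L && length(ids) > 0L) {
    stop("ontology has no root concept")
  }
  structure(list(concepts = concepts, roots = unname(roots)),
            class = "ontology_graph")
}

# Returns one member of a cycle in the is_a relation, or NULL if acyclic.
.find_cycle <- function(concepts) {
  state <- new.env(parent = emptyenv())  # ids: 1 = visiting, 2 = done
  hit <- NULL
  visit <- function(id) {
    st <- get0(id, envir = state, ifnotfound = 0L)
    if (st == 1L) { hit <<- id; return(TRUE) }
    if (st == 2L) return(FALSE)
    assign(id, 1L, envir = state)
    for (p in concepts[[id]]$parents) {
      if (visit(p)) return(TRUE)
    }
    assign(id, 2L, envir = state)
    FALSE
  }
  for (id in names(concepts)) {
    if (visit(id)) return(hit)
  }
  NULL
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", length(x$concepts), " concepts, ",
      length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

#' Parse an OBO 1.2 flat file into an ontology graph
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `synonym` and `is_a` lines.
#' Synonym strings are taken from the quoted part of the synonym line
#' irrespective of the scope tag (EXACT, RELATED, ...). Terms flagged
#' `is_obsolete: true` are skipped. Other stanza types (`[Typedef]`, ...) and
#' other relationship types are ignored; only `is_a` edges enter the graph.
#'
#' @param x path to an OBO file, or a character vector of its lines.
#' @return An `ontology_graph`.
#' @examples
#' lines <- c("[Term]", "id: A:1", "name: root",
#'            "[Term]", "id: A:2", "name: leaf", "is_a: A:1 ! root")
#' g <- parse_obo(lines)
#' g$roots  # "A:1"
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, encoding = "UTF-8", warn = FALSE)
  } else {
    as.character(x)
  }
  lines <- sub("\\s+$", "", lines)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  concepts <- list()
  if (length(starts)) {
    ends <- c(starts[-1] - 1L, length(lines))
    for (i in seq_along(starts)) {
      if (lines[starts[i]] != "[Term]") next
      body <- lines[seq(starts[i] + 1L, length.out = max(0L, ends[i] - starts[i]))]
      cp <- .parse_term_stanza(body)
      if (is.null(cp)) next  # obsolete
      concepts[[length(concepts) + 1L]] <- cp
    }
  }
  new_ontology_graph(concepts)
}

.parse_term_stanza <- function(body) {
  val <- function(key) {
    m <- grep(paste0("^", key, ":"), body, value = TRUE)
    trimws(sub(paste0("^", key, ":\\s*"), "", m))
  }
  if (length(val("is_obsolete")) && tolower(val("is_obsolete")[1]) == "true") {
    return(NULL)
  }
  id <- val("id")
  if (length(id) != 1L || !nzchar(id)) stop("[Term] stanza without a single id")
  name <- val("name")
  if (length(name) != 1L || !nzchar(name)) {
    stop("[Term] ", id, " without a single name")
  }
  syn_lines <- val("synonym")
  synonyms <- character(0)
  for (s in syn_lines) {
    m <- regmatches(s, regexec('^"((?:[^"\\\\]|\\\\.)*)"', s))[[1]]
    if (length(m) < 2L) stop("[Term] ", id, " has malformed synonym line: ", s)
    synonyms <- c(synonyms, gsub('\\\\(.)', "\\1", m[2]))
  }
  # strip trailing "! comment" from is_a targets
  parents <- vapply(val("is_a"), function(s) trimws(sub("\\s*!.*$", "", s)),
                    character(1), USE.NAMES = FALSE)
  list(id = id, name = name, synonyms = synonyms, parents = parents)
}

#' Serialize an ontology graph to OBO format lines
#'
#' Inverse of [parse_obo()] for the fields this package models
#' (id, name, synonyms, is_a). Synonyms are written with scope EXACT.
#'
#' @param graph an `ontology_graph`.
#' @return Character vector of OBO lines.
#' @export
write_obo <- function(graph) {
  out <- c("format-version: 1.2", "")
  for (cp in graph$concepts) {
    out <- c(out, "[Term]", paste0("id: ", cp$id), paste0("name: ", cp$name))
    for (s in cp$synonyms) {
      out <- c(out, sprintf('synonym: "%s" EXACT []', gsub('"', '\\\\"', s)))
    }
    for (p in cp$parents) {
      out <- c(out, paste0("is_a: ", p, " ! ", graph$concepts[[p]]$name))
    }
    out <- c(out, "")
  }
  out
}

#' Build an ontology graph from a flat dictionary
#'
#' Flat terminologies (MedDRA-style id/term/synonym tables) are mapped onto
#' the same graph structure as OBO ontologies: one virtual root is added and
#' every entry becomes a direct child of it, so ranking, fallbacks and
#' Wang-similarity scoring work unchanged.
#'
#' @param entries data.frame with columns `id`, `term` and optionally
#'   `synonyms` (either a list column of character vectors or a
#'   pipe-separated string column).
#' @param root_id,root_name identity of the virtual root concept.
#' @return An `ontology_graph`.
#' @export
dictionary_as_graph <- function(entries, root_id = "ROOT:0000000",
                                root_name = "dictionary root") {
  stopifnot(is.data.frame(entries), all(c("id", "term") %in% names(entries)))
  if (any(entries$id == root_id)) {
    stop("dictionary entry uses the reserved root id ", root_id)
  }
  syn <- if ("synonyms" %in% names(entries)) entries$synonyms else
    rep(list(character(0)), nrow(entries))
  if (is.character(syn)) {
    syn <- lapply(syn, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
    })
  }
  concepts <- c(
    list(list(id = root_id, name = root_name, synonyms = character(0),
              parents = character(0))),
    lapply(seq_len(nrow(entries)), function(i) {
      list(id = entries$id[i], name = entries$term[i],
           synonyms = syn[[i]], parents = root_id)
    })
  )
  new_ontology_graph(concepts)
}

#' Read a flat dictionary TSV
#'
#' Format: `id<TAB>preferred_term[<TAB>synonym1|synonym2|...]`, UTF-8,
#' no header.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `term`, `synonyms` (list column),
#'   suitable for [dictionary_as_graph()].
#' @export
read_dictionary_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(parts, length, integer(1))
  if (any(ncol < 2L)) {
    stop("dictionary TSV line ", which(ncol < 2L)[1], " has fewer than 2 columns")
  }
  data.frame(
    id = vapply(parts, `[[`, character(1), 1L),
    term = vapply(parts, `[[`, character(1), 2L),
    synonyms = I(lapply(parts, function(p) {
      if (length(p) >= 3L && nzchar(p[3])) strsplit(p[3], "|", fixed = TRUE)[[1]]
      else character(0)
    })),
    stringsAsFactors = FALSE
  )
}

#' Decay-weighted ancestor contributions of a concept
#'
#' Assigns every ancestor `a` of `id` (including `id` itself) an S-value
#' `s^d`, where `d` is the is_a path length from `id` to `a`; over multiple
#' paths the maximum (i.e. the shortest-path weight) is kept. The concept
#' itself always has weight 1.
#'
#' @param graph an `ontology_graph`.
#' @param id concept id present in `graph`.
#' @param s per-edge decay factor in (0, 1].
#' @return Named numeric vector of weights over the ancestor closure.
#' @export
ancestor_weights <- function(graph, id, s = 0.65) {
  if (!id %in% names(graph$concepts)) stop("unknown concept id: ", id)
  stopifnot(s > 0, s <= 1)
  w <- new.env(parent = emptyenv())
  # relax upward; revisiting only on improvement terminates on any DAG
  visit <- function(node, val) {
    cur <- get0(node, envir = w, ifnotfound = -Inf)
    if (val <= cur) return(invisible(NULL))
    assign(node, val, envir = w)
    for (p in graph$concepts[[node]]$parents) visit(p, val * s)
  }
  visit(id, 1)
  out <- unlist(as.list(w))
  out[order(names(out))]
}

#' Wang semantic similarity between two ontology concepts
#'
#' Compares the decay-weighted ancestor sets of the two concepts:
#' \deqn{W(c_1, c_2) = \frac{\sum_{a \in T_1 \cap T_2} (S_1(a) + S_2(a))}
#'                          {\sum_{a \in T_1} S_1(a) + \sum_{a \in T_2} S_2(a)}}
#' where \eqn{T_i} is the ancestor closure of \eqn{c_i} and \eqn{S_i(a)} the
#' [ancestor_weights()] S-value \eqn{s^d}. The score is symmetric, equals 1
#' iff the two concepts coincide, and decreases as the shared ancestry
#' becomes more remote. `s = 0.65` matches the setting used by the Bacteria
#' Biotope normalization evaluation.
#'
#' @param graph an `ontology_graph`.
#' @param c1,c2 concept ids.
#' @param s per-edge decay in (0, 1].
#' @return Similarity score in (0, 1].
#' @export
wang_similarity <- function(graph, c1, c2, s = 0.65) {
  w1 <- ancestor_weights(graph, c1, s)
  w2 <- ancestor_weights(graph, c2, s)
  shared <- intersect(names(w1), names(w2))
  (sum(w1[shared]) + sum(w2[shared])) / (sum(w1) + sum(w2))
}
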