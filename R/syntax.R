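# Constituency parses: Penn-Treebank bracketed notation, head-word
# extraction (top-level rightmost noun) and possessive-PP stripping.

NOUN_TAGS <- c("NN", "NNS", "NNP", "NNPS")

#' Construct a parse node
#' @param label phrase or POS tag.
#' @param children list of `parse_node` (internal nodes).
#' @param token leaf token (leaves only).
#' @return Object of class `parse_node`.
#' @export
parse_node <- function(label, children = list(), token = NULL) {
  stopifnot(nzchar(label))
  if (!is.null(token)) stopifnot(length(children) == 0L, nzchar(token))
  structure(list(label = label, children = children, token = token),
            class = "parse_node")
}

is_leaf <- function(node) !is.null(node$token)

#' Parse a Penn Treebank bracketed string into a tree
#'
#' Whitespace-insensitive. A wrapper node with an empty label, as emitted by
#' parsers that print `( (NP ...) )` or `(ROOT (NP ...))`, is stripped when
#' it has a single child.
#'
#' @param s bracketed parse string, e.g. `"(NP (JJ medical) (NN center))"`.
#' @return A `parse_node`.
#' @export
parse_bracketed <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  read_node <- function() {
    if (!identical(peek(), "(")) stop("malformed parse: expected '(' in ", s)
    advance()
    label <- if (!is.na(peek()) && !peek() %in% c("(", ")")) advance() else ""
    kids <- list()
    leaf_tok <- NULL
    repeat {
      p <- peek()
      if (is.na(p)) stop("unbalanced parentheses in parse: ", s)
      if (p == ")") { advance(); break }
      if (p == "(") {
        kids[[length(kids) + 1L]] <- read_node()
      } else {
        leaf_tok <- advance()
      }
    }
    if (!is.null(leaf_tok)) {
      if (length(kids) > 0L) stop("node mixes token and children in: ", s)
      if (!nzchar(label)) stop("leaf without POS label in: ", s)
      return(parse_node(label, token = leaf_tok))
    }
    if (length(kids) == 0L) stop("empty node in parse: ", s)
    if (!nzchar(label) || toupper(label) == "ROOT") {
      if (length(kids) == 1L) return(kids[[1]])
      label <- if (nzchar(label)) label else "ROOT"
    }
    parse_node(label, children = kids)
  }
  node <- read_node()
  if (pos <= length(toks)) stop("trailing content after parse: ", s)
  node
}

#' Serialize a parse tree to bracketed notation
#' @param tree a `parse_node`.
#' @return A single bracketed string.
#' @export
serialize_parse <- function(tree) {
  if (is_leaf(tree)) return(paste0("(", tree$label, " ", tree$token, ")"))
  paste0("(", tree$label, " ",
         paste(vapply(tree$children, serialize_parse, character(1)),
               collapse = " "), ")")
}

#' All leaf tokens of a parse tree, left to right
#' @param tree a `parse_node`.
#' @return Character vector of tokens.
#' @export
parse_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$token)
  unlist(lapply(tree$children, parse_leaves))
}

#' Build a degenerate flat parse for a token list
#'
#' Used when no real parse is available: an NP whose tokens are all tagged
#' NN, so [find_head()] returns the last token.
#' @param tokens non-empty character vector.
#' @return A `parse_node`.
#' @export
flat_parse <- function(tokens) {
  stopifnot(length(tokens) >= 1L)
  parse_node("NP", children = lapply(tokens, function(t) parse_node("NN", token = t)))
}

# descend through single-child wrappers until an NP (or a non-unary node)
.outermost_np <- function(tree) {
  node <- tree
  repeat {
    if (is_leaf(node)) return(NULL)
    if (node$label == "NP") return(node)
    if (length(node$children) == 1L) { node <- node$children[[1]]; next }
    return(NULL)
  }
}

.last_leaf <- function(tree) {
  lv <- parse_leaves(tree)
  lv[length(lv)]
}

#' Find the head word of a mention or concept-name parse
#'
#' The head is the top-level rightmost noun: starting from the outermost
#' noun phrase, its immediate children are scanned right to left and the
#' first noun-tagged (NN/NNS/NNP/NNPS) leaf is returned. If none is found,
#' the search recurses into the rightmost NP child; a tree with no suitable
#' noun falls back to the last leaf token. For
#' `"(NP (NP (NNS children)) (VP ... (NP ... (NN center))))"` the head is
#' therefore `"children"`, not `"center"`.
#'
#' @param tree a `parse_node`.
#' @return Object of class `head_result`: list with `token` and `source`
#'   (`"parse"` or `"fallback_last_token"`).
#' @export
find_head <- function(tree) {
  np <- .outermost_np(tree)
  if (is.null(np)) {
    return(structure(list(token = .last_leaf(tree),
                          source = "fallback_last_token"),
                     class = "head_result"))
  }
  node <- np
  repeat {
    kids <- node$children
    for (i in rev(seq_along(kids))) {
      k <- kids[[i]]
      if (is_leaf(k) && k$label %in% NOUN_TAGS) {
        return(structure(list(token = k$token, source = "parse"),
                         class = "head_result"))
      }
    }
    np_kids <- which(vapply(kids, function(k) !is_leaf(k) && k$label == "NP",
                            logical(1)))
    if (length(np_kids) == 0L) {
      return(structure(list(token = .last_leaf(node),
                            source = "fallback_last_token"),
                       class = "head_result"))
    }
    node <- kids[[max(np_kids)]]
  }
}

.is_punct_node <- function(node) {
  grepl("^[[:punct:]]+$", node$label)
}

#' Strip a possessive prepositional phrase from a mention parse
#'
#' Mentions of the form "NP of NP" (e.g. "throats of two healthy children")
#' carry their information in the first noun phrase only. When the
#' outermost NP decomposes as `NP [NP, PP(IN "of", NP)]` (punctuation
#' ignored), the leaves of the left NP are returned; any other shape is
#' returned unchanged.
#'
#' @param tree a `parse_node`.
#' @return Character vector of kept tokens (never empty).
#' @export
strip_possessive_pp <- function(tree) {
  np <- .outermost_np(tree)
  if (is.null(np)) return(parse_leaves(tree))
  kids <- Filter(function(k) !.is_punct_node(k), np$children)
  if (length(kids) != 2L) return(parse_leaves(tree))
  left <- kids[[1]]; right <- kids[[2]]
  ok <- !is_leaf(left) && left$label == "NP" &&
    !is_leaf(right) && right$label == "PP" &&
    length(right$children) >= 1L &&
    is_leaf(right$children[[1]]) &&
    right$children[[1]]$label == "IN" &&
    tolower(right$children[[1]]$token) == "of"
  if (!ok) return(parse_leaves(tree))
  parse_leaves(left)
}

#' Read a parse table file
#'
#' Format: `mention_id<TAB>bracketed_parse`, UTF-8, no header. Used to
#' inject parses produced by an external constituency parser.
#'
#' @param path file path.
#' @return Named list of `parse_node`, keyed by mention id.
#' @export
read_parse_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("parse table line ", i, " must have 2 columns")
    out[[parts[1]]] <- parse_bracketed(parts[2])
  }
  out
}

#' Write a parse table file
#' @param parses named list of `parse_node` or bracketed strings.
#' @param path output file path.
#' @export
write_parse_table <- function(parses, path) {
  ser <- vapply(parses, function(p) {
    if (inherits(p, "parse_node")) serialize_parse(p) else as.character(p)
  }, character(1))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(parses), ser, sep = "\t"), con)
  invisible(path)
}
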