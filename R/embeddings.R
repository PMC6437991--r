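# Word vectors: word2vec file IO, mention/term preprocessing, phrase-vector
# composition by averaging, cosine similarity and word mover's distance.

#' Construct an embedding store
#'
#' @param vectors numeric matrix, one row per token, rownames = tokens.
#' @return Object of class `embedding_store` with fields `dim` and `vectors`.
#' @keywords internal
new_embedding_store <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)),
            all(nzchar(rownames(vectors))))
  structure(list(dim = ncol(vectors), vectors = vectors),
            class = "embedding_store")
}

#' @export
print.embedding_store <- function(x, ...) {
  cat("<embedding_store> ", nrow(x$vectors), " tokens, dim ", x$dim, "\n",
      sep = "")
  invisible(x)
}

#' Look up one token's vector, or NULL if out of vocabulary
#' @param store an `embedding_store`.
#' @param token a single token.
#' @export
lookup_vector <- function(store, token) {
  i <- match(token, rownames(store$vectors))
  if (is.na(i)) NULL else store$vectors[i, ]
}

#' Load word vectors in word2vec text or binary format
#'
#' Text format: first line `<vocab_size> <dim>`, then one
#' `<token> <v1> ... <vdim>` line per token. Binary format: the same header
#' line, then for each token the token bytes terminated by a space followed
#' by `dim` little-endian float32 values (gensim/word2vec `save_word2vec_format`
#' binary layout). If a token occurs more than once, the last vector wins.
#'
#' @param path file path.
#' @param format `"text"` or `"binary"`.
#' @return An `embedding_store`.
#' @export
load_word_vectors <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "text") .load_w2v_text(path) else .load_w2v_binary(path)
}

.load_w2v_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty word-vector file: ", path)
  hdr <- scan(text = lines[1], what = numeric(), quiet = TRUE)
  if (length(hdr) != 2L) stop("malformed word2vec header line: ", lines[1])
  dim <- as.integer(hdr[2])
  if (length(lines) == 1L) stop("word-vector file has a header but no vectors")
  toks <- character(length(lines) - 1L)
  mat <- matrix(0, nrow = length(lines) - 1L, ncol = dim)
  for (i in seq_along(toks)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) != dim + 1L) {
      stop("word-vector line ", i + 1L, " has ", length(parts) - 1L,
           " values, expected ", dim)
    }
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) stop("word-vector line ", i + 1L, " has non-numeric values")
    toks[i] <- parts[1]
    mat[i, ] <- vals
  }
  keep <- !duplicated(toks, fromLast = TRUE)  # last occurrence wins
  mat <- mat[keep, , drop = FALSE]
  rownames(mat) <- toks[keep]
  new_embedding_store(mat)
}

.load_w2v_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- ""
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("empty word-vector file: ", path)
    if (ch == "\n") break
    hdr <- paste0(hdr, ch)
  }
  nums <- scan(text = hdr, what = numeric(), quiet = TRUE)
  if (length(nums) != 2L) stop("malformed word2vec binary header: ", hdr)
  n <- as.integer(nums[1]); dim <- as.integer(nums[2])
  if (n < 1L) stop("word-vector file declares zero vocabulary")
  toks <- character(n)
  mat <- matrix(0, nrow = n, ncol = dim)
  for (i in seq_len(n)) {
    tok <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) stop("truncated word2vec binary file at entry ", i)
      if (b == charToRaw(" ")) break
      if (b == charToRaw("\n")) next  # leading newline between records
      tok <- c(tok, b)
    }
    toks[i] <- rawToChar(tok)
    v <- readBin(con, "numeric", n = dim, size = 4L, endian = "little")
    if (length(v) != dim) stop("truncated vector for token ", toks[i])
    mat[i, ] <- v
  }
  keep <- !duplicated(toks, fromLast = TRUE)
  mat <- mat[keep, , drop = FALSE]
  rownames(mat) <- toks[keep]
  new_embedding_store(mat)
}

#' Write an embedding store in word2vec text format
#' @param store an `embedding_store`.
#' @param path output file path.
#' @export
write_word_vectors <- function(store, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(store$vectors), store$dim), con)
  for (i in seq_len(nrow(store$vectors))) {
    writeLines(paste(rownames(store$vectors)[i],
                     paste(format(store$vectors[i, ], scientific = FALSE,
                                  trim = TRUE, digits = 12),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' Default English stop-word list
#'
#' The classic 127-token English list packaged under `inst/extdata`;
#' replaceable via the `stopwords` arguments throughout the package.
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "ontolink")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Read a stop-word list file (one token per line, UTF-8)
#' @param path file path.
#' @export
read_stopwords <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x[nzchar(trimws(x))]
}

.cond <- function(class, msg, ...) {
  structure(class = c(class, "ontolink_error", "error", "condition"),
            list(message = msg, ...))
}

#' Preprocess a mention or concept-term string into tokens
#'
#' Pipeline order: lowercase, strip non-ASCII characters, split on any
#' non-alphanumeric character (so hyphens and punctuation vanish), drop
#' empty tokens, drop stop words. "a day-care center" therefore yields
#' tokens `day`, `care`, `center`.
#'
#' @param text a single non-empty string.
#' @param stopwords character vector of stop words (already lowercase).
#' @return Object of class `tokenized_phrase`: list with `source`, `tokens`,
#'   `removed_stopwords` and `removed_nonascii` (count of stripped
#'   characters).
#' @section Errors: if no token survives, a condition of class
#'   `ontolink_empty_phrase` is signalled so the caller can fall back.
#' @export
preprocess_phrase <- function(text, stopwords = default_stopwords()) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  low <- tolower(text)
  ascii <- gsub("[^\x01-\x7F]", "", low, useBytes = TRUE)
  Encoding(ascii) <- "UTF-8"
  n_stripped <- nchar(low, type = "chars") - nchar(ascii, type = "chars")
  toks <- strsplit(ascii, "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  is_stop <- toks %in% stopwords
  kept <- toks[!is_stop]
  if (length(kept) == 0L) {
    stop(.cond("ontolink_empty_phrase",
               paste0("no tokens left after preprocessing: '", text, "'")))
  }
  structure(list(source = text, tokens = kept,
                 removed_stopwords = toks[is_stop],
                 removed_nonascii = n_stripped),
            class = "tokenized_phrase")
}

#' Compose a phrase vector by averaging token vectors
#'
#' Sums the vectors of the in-vocabulary tokens and divides by their count;
#' out-of-vocabulary tokens are skipped and reported, so a phrase with any
#' known word still gets a vector.
#'
#' @param tokens non-empty character vector of tokens.
#' @param store an `embedding_store`.
#' @return Object of class `phrase_vector`: list with `vector` (length
#'   `store$dim`), `contributing` (number of tokens averaged) and
#'   `oov_tokens`.
#' @section Errors: if every token is out of vocabulary, a condition of
#'   class `ontolink_all_oov` is signalled.
#' @export
compose_vector <- function(tokens, store) {
  stopifnot(length(tokens) >= 1L)
  idx <- match(tokens, rownames(store$vectors))
  oov <- tokens[is.na(idx)]
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    stop(.cond("ontolink_all_oov",
               paste0("all tokens out of vocabulary: ",
                      paste(tokens, collapse = " "))))
  }
  v <- colSums(store$vectors[idx, , drop = FALSE]) / length(idx)
  structure(list(vector = unname(v), contributing = length(idx),
                 oov_tokens = oov),
            class = "phrase_vector")
}

#' Cosine similarity of two vectors
#' @param a,b numeric vectors of equal length with non-zero norm.
#' @return Similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

#' Word mover's distance between two token lists
#'
#' Minimum cumulative distance the embedded words of one phrase must travel
#' to reach the other's: the exact optimal-transport cost between the
#' count-normalized distributions of the in-vocabulary token vectors, with
#' Euclidean ground distance. Phrases here are a handful of tokens, so the
#' transportation linear program is solved exactly (simplex).
#'
#' @param tokens_a,tokens_b character vectors (duplicates carry extra mass).
#' @param store an `embedding_store`.
#' @return Non-negative distance; 0 iff the normalized distributions agree.
#' @section Errors: `ontolink_all_oov` if either side has no in-vocabulary
#'   token.
#' @export
word_movers_distance <- function(tokens_a, tokens_b, store) {
  da <- .token_distribution(tokens_a, store)
  db <- .token_distribution(tokens_b, store)
  cost <- matrix(0, nrow(da$vecs), nrow(db$vecs))
  for (i in seq_len(nrow(da$vecs))) {
    d <- sweep(db$vecs, 2L, da$vecs[i, ])
    cost[i, ] <- sqrt(rowSums(d^2))
  }
  solve_transport(da$mass, db$mass, cost)
}

.token_distribution <- function(tokens, store) {
  stopifnot(length(tokens) >= 1L)
  known <- tokens[tokens %in% rownames(store$vectors)]
  if (length(known) == 0L) {
    stop(.cond("ontolink_all_oov",
               paste0("all tokens out of vocabulary: ",
                      paste(tokens, collapse = " "))))
  }
  tab <- table(known)
  vecs <- store$vectors[names(tab), , drop = FALSE]
  list(vecs = vecs, mass = as.numeric(tab) / length(known))
}

#' Solve a small transportation problem exactly
#'
#' Minimizes `sum(P * cost)` over plans `P >= 0` with row sums `mass_a` and
#' column sums `mass_b` (both summing to 1), via the simplex method. One of
#' the marginal constraints is redundant and dropped.
#'
#' @param mass_a,mass_b non-negative marginals, each summing to 1.
#' @param cost cost matrix, `length(mass_a)` x `length(mass_b)`.
#' @return The optimal transport cost.
#' @export
solve_transport <- function(mass_a, mass_b, cost) {
  m <- length(mass_a); n <- length(mass_b)
  stopifnot(nrow(cost) == m, ncol(cost) == n,
            abs(sum(mass_a) - 1) < 1e-9, abs(sum(mass_b) - 1) < 1e-9)
  if (m == 1L) return(sum(mass_b * cost[1, ]))
  if (n == 1L) return(sum(mass_a * cost[, 1]))
  # variables x_ij in row-major order
  A <- matrix(0, m + n - 1L, m * n)
  b <- numeric(m + n - 1L)
  for (i in seq_len(m)) {
    A[i, (i - 1L) * n + seq_len(n)] <- 1
    b[i] <- mass_a[i]
  }
  for (j in seq_len(n - 1L)) {          # last column constraint is redundant
    A[m + j, (seq_len(m) - 1L) * n + j] <- 1
    b[m + j] <- mass_b[j]
  }
  res <- boot::simplex(a = as.vector(t(cost)), A3 = A, b3 = b, maxi = FALSE)
  if (res$solved != 1) stop("transportation LP did not solve")
  unname(res$value)
}
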