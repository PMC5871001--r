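QSM_MAGIC <- charToRaw("QSM1")
QSM_VERSION <- 1L

#' Save an embedding model in the QSM1 binary format
#'
#' Layout (little-endian): magic bytes `"QSM1"`, uint32 format version,
#' uint32 |V|, uint32 dim, then |V| records of (uint16 UTF-8 byte length,
#' term bytes, dim x float32 vector) — a binary associative list of
#' word-to-vector pairs. Vectors are stored at single precision; loading a
#' file written from single-precision values is bit-exact, and one
#' save/load pass quantizes doubles to that precision.
#'
#' The optional phrase inventory is appended as a uint32 count plus
#' length-prefixed phrase keys, so [query_vector()] can re-apply the
#' corpus's phrase merging after a round trip.
#'
#' @param model An `embedding_model` (only `vectors`, `dim`, `phrases` are
#'   persisted; inner-node vectors are training-time state).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  vecs <- model$vectors
  if (is.null(vecs) || ncol(vecs) == 0L) {
    stop("save_model: refusing to save a model with an empty vocabulary")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(QSM_MAGIC, con)
  writeBin(c(QSM_VERSION, ncol(vecs), nrow(vecs)), con, size = 4L,
           endian = "little")
  terms <- colnames(vecs)
  for (i in seq_len(ncol(vecs))) {
    b <- charToRaw(enc2utf8(terms[i]))
    if (length(b) > 65535L) stop("save_model: term longer than 65535 bytes")
    writeBin(length(b), con, size = 2L, endian = "little")
    writeBin(b, con)
    writeBin(as.numeric(vecs[, i]), con, size = 4L, endian = "little")
  }
  ph <- model$phrases
  if (is.null(ph)) ph <- character(0)
  writeBin(length(ph), con, size = 4L, endian = "little")
  for (p in ph) {
    b <- charToRaw(enc2utf8(p))
    writeBin(length(b), con, size = 2L, endian = "little")
    writeBin(b, con)
  }
  invisible(path)
}

read_exact <- function(con, what, n, size, path) {
  offset <- seek(con)
  out <- readBin(con, what, n = n, size = size, endian = "little",
                 signed = if (size <= 2L) FALSE else TRUE)
  if (length(out) != n) {
    stop("load_model: truncated file '", path, "' at byte offset ", offset,
         " (wanted ", n, " x ", size, "-byte ", what, ", got ", length(out),
         ")")
  }
  out
}

#' Load a QSM1 model file
#'
#' @param path File written by [save_model()].
#' @return An `embedding_model` with `vectors`, `dim`, and `phrases`
#'   (inner-node vectors and the Huffman tree are not persisted).
#' @export
load_model <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L || !identical(magic, QSM_MAGIC)) {
    stop("load_model: '", path, "' is not a QSM1 model (bad magic at byte offset 0)")
  }
  hdr <- read_exact(con, "integer", 3L, 4L, path)
  version <- hdr[1L]; nv <- hdr[2L]; dim <- hdr[3L]
  if (version != QSM_VERSION) {
    stop("load_model: unsupported format version ", version,
         " (header at byte offset 4)")
  }
  if (nv < 1L || dim < 1L) {
    stop("load_model: invalid header (|V| = ", nv, ", dim = ", dim,
         ") at byte offset 8")
  }
  vecs <- matrix(0, nrow = dim, ncol = nv)
  terms <- character(nv)
  for (i in seq_len(nv)) {
    len <- read_exact(con, "integer", 1L, 2L, path)
    terms[i] <- rawToChar(read_exact(con, "raw", len, 1L, path))
    vecs[, i] <- read_exact(con, "numeric", dim, 4L, path)
  }
  Encoding(terms) <- "UTF-8"
  if (anyDuplicated(terms)) {
    stop("load_model: duplicate terms in '", path,
         "' (payload disagrees with declared vocabulary)")
  }
  nph <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  phrases <- character(0)
  if (length(nph) == 1L && nph > 0L) {
    phrases <- character(nph)
    for (i in seq_len(nph)) {
      len <- read_exact(con, "integer", 1L, 2L, path)
      phrases[i] <- rawToChar(read_exact(con, "raw", len, 1L, path))
    }
    Encoding(phrases) <- "UTF-8"
  }
  colnames(vecs) <- terms
  structure(list(vectors = vecs, inner = NULL, dim = dim,
                 vocab = NULL, tree = NULL, phrases = phrases,
                 loss = numeric(0), architecture = "loaded"),
            class = "embedding_model")
}

normalize_query_tokens <- function(model, query) {
  toks <- tokenize(query)
  if (length(toks) == 0L) {
    stop("query_vector: query is empty after tokenization")
  }
  merged <- if (length(model$phrases)) {
    merge_phrases(toks, model$phrases)
  } else {
    toks
  }
  list(tokens = toks, merged = merged,
       joined = paste(toks, collapse = "_"))
}

#' Vector representation of a (possibly multi-word) query
#'
#' The query is tokenized and the model's phrase inventory applied. If the
#' underscore-joined form of the whole query is itself a vocabulary entry
#' its vector is returned; otherwise the mean of the in-vocabulary token
#' vectors.
#'
#' @param model An `embedding_model`.
#' @param query Query string.
#' @return Numeric vector of length `model$dim`.
#' @export
query_vector <- function(model, query) {
  q <- normalize_query_tokens(model, query)
  vocab_terms <- colnames(model$vectors)
  if (q$joined %in% vocab_terms) {
    return(model$vectors[, q$joined])
  }
  known <- q$merged[q$merged %in% vocab_terms]
  if (length(known) == 0L) {
    stop("query_vector: no query token is in the vocabulary: ", query)
  }
  rowMeans(model$vectors[, known, drop = FALSE])
}

#' Top-k alternative queries by cosine similarity
#'
#' Scores every vocabulary word against the query vector by cosine
#' similarity (an exact full scan) and returns the `k` best, excluding the
#' query's own tokens and its underscore-joined phrase form. Ties are
#' broken lexicographically; zero-norm vectors are never candidates
#' (cosine is undefined for them).
#'
#' @param model An `embedding_model`.
#' @param query Query string.
#' @param k Number of suggestions (default 5).
#' @return A `suggestion_list`: data frame with columns `term` and `score`
#'   (cosine similarity, non-increasing).
#' @export
top_k <- function(model, query, k = 5L) {
  stopifnot(k >= 1L)
  qv <- query_vector(model, query)
  q <- normalize_query_tokens(model, query)
  exclude <- unique(c(q$tokens, q$merged, q$joined))
  vecs <- model$vectors
  norms <- sqrt(colSums(vecs^2))
  qn <- sqrt(sum(qv^2))
  if (qn == 0) stop("top_k: query vector has zero norm")
  ok <- norms > 0 & !(colnames(vecs) %in% exclude)
  if (!any(ok)) {
    return(empty_suggestion_list())
  }
  sims <- as.numeric(crossprod(vecs[, ok, drop = FALSE], qv)) /
    (norms[ok] * qn)
  terms <- colnames(vecs)[ok]
  o <- order(-sims, terms)
  o <- o[seq_len(min(k, length(o)))]
  out <- data.frame(term = terms[o], score = sims[o],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("suggestion_list", "data.frame")
  out
}

empty_suggestion_list <- function() {
  out <- data.frame(term = character(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("suggestion_list", "data.frame")
  out
}

#' Cosine similarity between two vectors
#' @param a,b Numeric vectors of equal length with positive norm.
#' @return Cosine similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine_similarity: zero-norm vector")
  sum(a * b) / (na * nb)
}
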