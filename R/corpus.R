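#' Tokenize text for corpus building
#'
#' Splits text into lowercased word tokens, dropping punctuation, while
#' keeping database identifiers (accession-style letter/digit compounds such
#' as `at1g01010` or `q9s7u2-1`) as single tokens even when they contain
#' internal punctuation. Identifier preservation is what distinguishes this
#' tokenizer from a plain character-class segmenter: biological corpora are
#' dense in accessions whose parts are meaningless in isolation.
#'
#' @param text Character vector; each element is tokenized independently.
#' @param id_pattern Perl regular expression matched before the generic
#'   word rule; matches are emitted as single unsplit tokens. The default
#'   matches letters immediately followed by digits, optionally interleaved,
#'   with optional `-`/`.`/`:`-joined alphanumeric suffixes.
#' @return For a single string, a character vector of tokens; for a longer
#'   input, a list of such vectors.
#' @examples
#' tokenize("Salt stress, tolerance.")
#' tokenize("AT1G01010 expression")
#' @export
tokenize <- function(text, id_pattern = default_id_pattern()) {
  stopifnot(is.character(text))
  # Alternation order matters: the identifier rule is tried first at each
  # position, so identifiers win over the generic alphanumeric-run rule.
  rx <- paste0("(?:", id_pattern, ")|[\\p{L}\\p{N}]+")
  out <- lapply(text, function(x) {
    if (is.na(x) || !nzchar(x)) return(character(0))
    m <- gregexpr(rx, x, perl = TRUE)
    tolower(unlist(regmatches(x, m), use.names = FALSE))
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Default database-identifier pattern
#'
#' Letters immediately followed by digits, optionally interleaved, plus
#' optional punctuated alphanumeric suffixes (`AT1G01010.1`, `Q9S7U2-2`).
#' @return A Perl-compatible regular expression string.
#' @export
default_id_pattern <- function() {
  "[\\p{L}]+[\\p{N}][\\p{L}\\p{N}]*(?:[-.:][\\p{L}\\p{N}]+)+|[\\p{L}]+[\\p{N}][\\p{L}\\p{N}]*"
}

#' Count unigrams and adjacent bigrams in a tokenized corpus
#'
#' Bigrams are counted between strictly adjacent tokens within a document;
#' no pairs are formed across document boundaries.
#'
#' @param docs A list of character vectors (tokenized documents), or a
#'   character vector of raw documents which is passed through [tokenize()].
#' @param id_pattern Identifier pattern forwarded to [tokenize()] when `docs`
#'   is raw text.
#' @return A `corpus_stats` object: list with `unigrams` (named integer
#'   vector), `bigrams` (named integer vector, names are
#'   `"<term_i> <term_j>"`), and `total_tokens`.
#' @export
count_ngrams <- function(docs, id_pattern = default_id_pattern()) {
  if (is.character(docs)) docs <- lapply(docs, tokenize, id_pattern = id_pattern)
  stopifnot(is.list(docs))
  toks <- unlist(docs, use.names = FALSE)
  if (length(toks) == 0L) {
    return(structure(list(unigrams = integer(0), bigrams = integer(0),
                          total_tokens = 0L), class = "corpus_stats"))
  }
  uni <- table(toks)
  unigrams <- as.integer(uni)
  names(unigrams) <- names(uni)
  pair_keys <- unlist(lapply(docs, function(tk) {
    n <- length(tk)
    if (n < 2L) return(character(0))
    paste(tk[-n], tk[-1L])
  }), use.names = FALSE)
  if (length(pair_keys) == 0L) {
    bigrams <- integer(0)
  } else {
    bi <- table(pair_keys)
    bigrams <- as.integer(bi)
    names(bigrams) <- names(bi)
  }
  structure(list(unigrams = unigrams, bigrams = bigrams,
                 total_tokens = length(toks)),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("Corpus statistics:", x$total_tokens, "tokens,",
      length(x$unigrams), "distinct terms,",
      length(x$bigrams), "distinct adjacent bigrams\n")
  invisible(x)
}

#' Discounted collocation score for a word pair
#'
#' `score = (count_ij - delta) / (count_i * count_j)`. The discount `delta`
#' prevents phrases made of very infrequent words from being formed: a pair
#' must co-occur more than `delta` times before its score is positive.
#'
#' @param count_ij Co-occurrence count of the ordered pair.
#' @param count_i,count_j Marginal counts of the two words; must be positive.
#' @param delta Non-negative discount (default 5).
#' @return The score (double), vectorized over its arguments.
#' @export
phrase_score <- function(count_ij, count_i, count_j, delta = 5) {
  if (any(delta < 0)) stop("delta must be non-negative")
  if (any(count_i <= 0) || any(count_j <= 0)) {
    stop("phrase_score: word counts must be positive (zero denominator)")
  }
  (count_ij - delta) / (count_i * count_j)
}

#' Extract collocation phrases from corpus counts
#'
#' Returns exactly the adjacent word pairs whose discounted collocation
#' score exceeds `score_threshold`.
#'
#' @param stats A `corpus_stats` object from [count_ngrams()].
#' @param delta Discount coefficient (default 5).
#' @param score_threshold Minimum score, exclusive (default 9e-8).
#' @return A data frame with columns `term_i`, `term_j`, `count_ij`, `score`,
#'   ordered by decreasing score then lexicographically; class
#'   `phrase_table`.
#' @export
extract_phrases <- function(stats, delta = 5, score_threshold = 9e-8) {
  stopifnot(inherits(stats, "corpus_stats"))
  if (length(stats$bigrams) == 0L) {
    return(empty_phrase_table())
  }
  parts <- strsplit(names(stats$bigrams), " ", fixed = TRUE)
  term_i <- vapply(parts, `[`, character(1), 1L)
  term_j <- vapply(parts, `[`, character(1), 2L)
  score <- phrase_score(as.numeric(stats$bigrams),
                        as.numeric(stats$unigrams[term_i]),
                        as.numeric(stats$unigrams[term_j]),
                        delta = delta)
  keep <- score > score_threshold
  out <- data.frame(term_i = term_i[keep], term_j = term_j[keep],
                    count_ij = as.integer(stats$bigrams[keep]),
                    score = score[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$term_i, out$term_j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phrase_table", "data.frame")
  out
}

empty_phrase_table <- function() {
  out <- data.frame(term_i = character(0), term_j = character(0),
                    count_ij = integer(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("phrase_table", "data.frame")
  out
}

phrase_keys <- function(phrases) {
  if (inherits(phrases, "data.frame")) {
    paste(phrases$term_i, phrases$term_j)
  } else if (is.list(phrases)) {
    vapply(phrases, function(p) paste(p[1L], p[2L]), character(1))
  } else {
    as.character(phrases)  # already "a b" keys
  }
}

#' Merge known phrases into single tokens
#'
#' Greedy left-to-right single pass: whenever two adjacent tokens form a
#' known phrase the pair is replaced by one joined token (underscore
#' delimiter) and scanning resumes after it, so replacements never overlap.
#' Ties between overlapping candidates are resolved by leftmost start.
#'
#' @param tokens Character vector of tokens.
#' @param phrases A `phrase_table`, a list of 2-element character vectors,
#'   or a character vector of `"term_i term_j"` keys.
#' @param sep Join delimiter (default `"_"`).
#' @return Character vector with matched pairs joined.
#' @export
merge_phrases <- function(tokens, phrases, sep = "_") {
  keys <- phrase_keys(phrases)
  n <- length(tokens)
  if (n < 2L || length(keys) == 0L) return(tokens)
  lookup <- new.env(parent = emptyenv(), size = length(keys))
  for (k in keys) assign(k, TRUE, envir = lookup)
  out <- character(n)
  m <- 0L
  i <- 1L
  while (i <= n) {
    if (i < n && exists(paste(tokens[i], tokens[i + 1L]), envir = lookup,
                        inherits = FALSE)) {
      m <- m + 1L
      out[m] <- paste(tokens[i], tokens[i + 1L], sep = sep)
      i <- i + 2L
    } else {
      m <- m + 1L
      out[m] <- tokens[i]
      i <- i + 1L
    }
  }
  out[seq_len(m)]
}

#' Overlap between mined phrases and ontology term labels
#'
#' Counts mined phrases whose space-joined form exactly matches an ontology
#' term label or synonym (case-insensitive). Used to calibrate the phrase
#' score threshold: the threshold/discount pair maximizing ontology overlap
#' yields the most terminology-like phrase inventory.
#'
#' @param phrases As in [merge_phrases()].
#' @param term_labels Character vector of ontology labels and synonyms, or an
#'   `ontology_graph` (labels and synonyms are pooled).
#' @return List with `count` (matching phrases) and `fraction` (of all
#'   phrases; 0 when there are no phrases).
#' @export
ontology_overlap <- function(phrases, term_labels) {
  if (inherits(term_labels, "ontology_graph")) {
    term_labels <- ontology_label_pool(term_labels)
  }
  keys <- phrase_keys(phrases)
  if (length(keys) == 0L) return(list(count = 0L, fraction = 0))
  hits <- tolower(keys) %in% tolower(term_labels)
  list(count = sum(hits), fraction = mean(hits))
}

#' Read a corpus as one document per line (or one .txt file per document)
#'
#' @param path A text file (one document per line) or a directory of `.txt`
#'   files (one document per file, sorted by file name).
#' @return Character vector of raw documents.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    vapply(files, function(f)
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = " "),
      character(1), USE.NAMES = FALSE)
  } else {
    readLines(path, encoding = "UTF-8", warn = FALSE)
  }
}

#' Write a phrase table as TSV
#' @param phrases A `phrase_table`.
#' @param path Output file.
#' @export
write_phrase_table <- function(phrases, path) {
  utils::write.table(phrases, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rewrite a corpus with phrases merged into single tokens
#'
#' Tokenizes each document, merges phrases, and returns (or writes) the
#' corpus in one-document-per-line form. `passes > 1` repeats phrase mining
#' on the rewritten corpus, which can join a merged bigram with a third word.
#'
#' @param docs Character vector of raw documents.
#' @param phrases A `phrase_table` (or `NULL` to mine them here).
#' @param delta,score_threshold Mining parameters used when `phrases` is
#'   `NULL` or `passes > 1`.
#' @param passes Number of mining/merging passes (default 1: bigrams only).
#' @param id_pattern Forwarded to [tokenize()].
#' @return List with `docs` (list of merged token vectors) and `phrases`
#'   (the final `phrase_table`).
#' @export
rewrite_corpus <- function(docs, phrases = NULL, delta = 5,
                           score_threshold = 9e-8, passes = 1L,
                           id_pattern = default_id_pattern()) {
  stopifnot(passes >= 1L)
  tok <- lapply(docs, tokenize, id_pattern = id_pattern)
  for (p in seq_len(passes)) {
    ph <- if (p == 1L && !is.null(phrases)) phrases else {
      extract_phrases(count_ngrams(tok), delta = delta,
                      score_threshold = score_threshold)
    }
    if (nrow(ph) == 0L) break
    tok <- lapply(tok, merge_phrases, phrases = ph)
    acc <- if (p == 1L || !exists("acc", inherits = FALSE)) ph else rbind(acc, ph)
  }
  list(docs = tok,
       phrases = if (exists("acc", inherits = FALSE)) acc
                 else empty_phrase_table())
}
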