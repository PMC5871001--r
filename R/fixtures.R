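#' Specification for a planted-synonym corpus
#'
#' Describes a corpus in which disjoint groups of interchangeable words
#' (synonym groups) are embedded in group-specific contexts: every
#' document is about one group and contains exactly one occurrence of one
#' group word, at a random position, surrounded by words drawn from the
#' group's dedicated context vocabulary plus shared background noise.
#' Interchangeable words therefore never co-occur with each other but
#' share their context distribution exactly — the distributional
#' hypothesis as a clean, recoverable planted structure. (If group words
#' were simply sprinkled through the documents, group words and context
#' words would have identical context distributions and nearest-neighbour
#' recovery would be impossible by construction.)
#'
#' @param n_groups Number of synonym groups (default 10).
#' @param group_size Interchangeable words per group (default 3).
#' @param n_docs Documents (default 2000).
#' @param doc_length Tokens per document (default 12).
#' @param context_vocab_per_group Context words dedicated to each group
#'   (default 20).
#' @param n_background Shared background words (default 50).
#' @param p_background Probability a non-target slot holds background
#'   noise rather than a group-context word (default 0.1).
#' @param context_overlap Fraction of context slots drawn from a pool
#'   common to all groups instead of the group's own vocabulary
#'   (default 0, i.e. fully disjoint contexts; raise it to probe graceful
#'   degradation of recovery).
#' @return A `synonym_spec` list, with `groups` (list of word vectors).
#' @export
synonym_spec <- function(n_groups = 10L, group_size = 3L, n_docs = 2000L,
                         doc_length = 12L, context_vocab_per_group = 20L,
                         n_background = 50L, p_background = 0.1,
                         context_overlap = 0) {
  stopifnot(n_groups >= 1L, group_size >= 1L, n_docs >= 1L,
            doc_length >= 2L, p_background >= 0, p_background <= 1,
            context_overlap >= 0, context_overlap <= 1)
  groups <- lapply(seq_len(n_groups), function(g)
    sprintf("syn%02d%s", g, letters[seq_len(group_size)]))
  structure(list(groups = groups, n_docs = n_docs, doc_length = doc_length,
                 context_vocab_per_group = context_vocab_per_group,
                 n_background = n_background, p_background = p_background,
                 context_overlap = context_overlap),
            class = "synonym_spec")
}

#' Generate a corpus with planted synonym groups
#'
#' Pure function of `spec` and `seed`: identical arguments give an
#' identical corpus.
#'
#' @param spec A [synonym_spec()].
#' @param seed Integer seed.
#' @return List of token vectors (one per document).
#' @export
generate_synonym_corpus <- function(spec = synonym_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synonym_spec"))
  set.seed(as.integer(seed))
  n_groups <- length(spec$groups)
  ctx <- lapply(seq_len(n_groups), function(g)
    sprintf("ctx%02dw%02d", g, seq_len(spec$context_vocab_per_group)))
  shared_ctx <- sprintf("ctxsharedw%02d",
                        seq_len(max(spec$context_vocab_per_group, 1L)))
  background <- if (spec$n_background > 0L) {
    sprintf("bg%03d", seq_len(spec$n_background))
  } else {
    character(0)
  }
  nctx <- spec$doc_length - 1L
  lapply(seq_len(spec$n_docs), function(d) {
    g <- sample.int(n_groups, 1L)
    target <- sample(spec$groups[[g]], 1L)
    doc <- sample(ctx[[g]], nctx, replace = TRUE)
    if (spec$context_overlap > 0) {
      swap <- stats::runif(nctx) < spec$context_overlap
      if (any(swap)) doc[swap] <- sample(shared_ctx, sum(swap), replace = TRUE)
    }
    if (length(background) && spec$p_background > 0) {
      noise <- stats::runif(nctx) < spec$p_background
      if (any(noise)) doc[noise] <- sample(background, sum(noise),
                                           replace = TRUE)
    }
    append(doc, target, after = sample.int(spec$doc_length, 1L) - 1L)
  })
}

#' Same-group nearest-neighbour precision of a trained model
#'
#' For every planted group word present in the model, checks whether its
#' top-1 cosine neighbour among the other group words is from the same
#' group; returns the fraction for which it is.
#'
#' @param model An `embedding_model` trained on a synonym corpus.
#' @param spec The [synonym_spec()] used to generate that corpus.
#' @return Precision in \[0, 1\].
#' @export
synonym_recovery_precision <- function(model, spec) {
  words <- unlist(spec$groups, use.names = FALSE)
  group_of <- rep(seq_along(spec$groups), lengths(spec$groups))
  names(group_of) <- words
  present <- words[words %in% colnames(model$vectors)]
  hits <- vapply(present, function(w) {
    nb <- top_k(model, w, k = 1L)
    nrow(nb) == 1L && !is.na(group_of[nb$term]) &&
      group_of[[nb$term]] == group_of[[w]]
  }, logical(1))
  mean(hits)
}

#' Generate a corpus with planted collocation phrases
#'
#' Background tokens are sampled independently from a vocabulary large
#' enough that no background bigram recurs often enough to clear the
#' discount, while each planted bigram is inserted as an adjacent pair
#' `n_planted_occurrences` times — chosen so its score clears the
#' threshold with margin. Phrase mining on the output should therefore
#' return exactly the planted set.
#'
#' @param n_phrases Number of planted bigrams (default 10).
#' @param n_docs Documents (default 400).
#' @param doc_length Background tokens per document (default 10).
#' @param background_vocab Background vocabulary size (default 200).
#' @param n_planted_occurrences Adjacent insertions per planted bigram
#'   (default 30).
#' @param seed Integer seed.
#' @return List with `docs` (token vectors) and `planted` (data frame
#'   `term_i`, `term_j`).
#' @export
generate_phrase_corpus <- function(n_phrases = 10L, n_docs = 400L,
                                   doc_length = 10L,
                                   background_vocab = 200L,
                                   n_planted_occurrences = 30L,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  planted <- data.frame(
    term_i = sprintf("phrA%02d", seq_len(n_phrases)),
    term_j = sprintf("phrB%02d", seq_len(n_phrases)),
    stringsAsFactors = FALSE)
  bg <- sprintf("w%03d", seq_len(background_vocab))
  docs <- lapply(seq_len(n_docs), function(d)
    sample(bg, doc_length, replace = TRUE))
  # insert each planted pair as an adjacent pair at a random position of a
  # random document, n_planted_occurrences times
  for (i in seq_len(n_phrases)) {
    for (r in seq_len(n_planted_occurrences)) {
      d <- sample.int(n_docs, 1L)
      pos <- sample.int(length(docs[[d]]) + 1L, 1L) - 1L
      docs[[d]] <- append(docs[[d]],
                          c(planted$term_i[i], planted$term_j[i]),
                          after = pos)
    }
  }
  list(docs = docs, planted = planted)
}

#' Generate a toy ontology tree with depth-monotone term counts
#'
#' Builds a rooted tree (optionally a DAG via `extra_parent_prob`) of the
#' given depth and branching factor, together with a term-frequency table
#' in which the root's count equals the corpus total (`P(root) = 1`) and
#' counts decrease strictly with depth. Ancestor-monotone counts guarantee
#' Lin similarity in \[0, 1\] without clamping, and deeper common
#' ancestors give strictly larger similarities.
#'
#' Each term gets a space-delimited label (`"toy term d<depth> n<k>"`) and
#' one synonym (`"toy synonym d<depth> n<k>"`) so label/synonym matching
#' can be exercised.
#'
#' @param depth Tree depth; 1 means the root alone.
#' @param branching Children per internal node (default 2).
#' @param total Root corpus count (default 10000).
#' @param decay Count ratio between a child and its parent (default 0.3).
#' @param extra_parent_prob Probability a non-root term gains a second
#'   parent on the level above (default 0: plain tree).
#' @param seed Integer seed (used only when `extra_parent_prob > 0`).
#' @return List with `graph` (an `ontology_graph`) and `freq` (a
#'   `term_freq_table`).
#' @export
generate_toy_ontology <- function(depth, branching = 2L, total = 10000,
                                  decay = 0.3, extra_parent_prob = 0,
                                  seed = 1L) {
  stopifnot(depth >= 1L, branching >= 1L, decay > 0, decay < 1)
  set.seed(as.integer(seed))
  ids <- "TOY:0001"
  labels <- c("TOY:0001" = "toy term d1 n1")
  synonyms <- list("TOY:0001" = "toy synonym d1 n1")
  parents <- list("TOY:0001" = character(0))
  counts <- c("TOY:0001" = total)
  level <- "TOY:0001"
  n_id <- 1L
  for (d in seq_len(depth - 1L)) {
    next_level <- character(0)
    k <- 0L
    for (p in level) {
      for (b in seq_len(branching)) {
        n_id <- n_id + 1L
        k <- k + 1L
        id <- sprintf("TOY:%04d", n_id)
        ids <- c(ids, id)
        labels[id] <- sprintf("toy term d%d n%d", d + 1L, k)
        synonyms[[id]] <- sprintf("toy synonym d%d n%d", d + 1L, k)
        parents[[id]] <- p
        if (extra_parent_prob > 0 && length(level) > 1L &&
            stats::runif(1) < extra_parent_prob) {
          parents[[id]] <- unique(c(parents[[id]],
                                    sample(setdiff(level, p), 1L)))
        }
        # strictly below every ancestor; jitter keeps siblings distinct
        counts[id] <- max(1, round(counts[[p]] * decay) - (k - 1L))
        next_level <- c(next_level, id)
      }
    }
    level <- next_level
  }
  graph <- structure(list(ids = ids, labels = labels, synonyms = synonyms,
                          parents = parents),
                     class = "ontology_graph")
  assert_acyclic(graph)
  list(graph = graph, freq = term_freq_table(counts, total = total))
}

#' Write an ontology graph as an OBO file
#'
#' Minimal OBO 1.2 serialization (id, name, synonym, is_a), round-trippable
#' through [parse_obo()]; useful for the toy-ontology fixtures.
#'
#' @param graph An `ontology_graph`.
#' @param path Output file path.
#' @export
write_obo <- function(graph, path) {
  out <- c("format-version: 1.2", "")
  for (id in graph$ids) {
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", graph$labels[[id]]))
    for (s in graph$synonyms[[id]]) {
      out <- c(out, sprintf('synonym: "%s" EXACT []', s))
    }
    for (p in graph$parents[[id]]) {
      out <- c(out, sprintf("is_a: %s ! %s", p, graph$labels[[p]]))
    }
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Write a corpus as one document per line
#' @param docs List of token vectors or character vector of documents.
#' @param path Output file path.
#' @export
write_corpus <- function(docs, path) {
  lines <- if (is.list(docs)) {
    vapply(docs, paste, character(1), collapse = " ")
  } else {
    docs
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
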