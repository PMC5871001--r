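# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (no count_ngrams, no build_huffman,
# no top_k internals) so agreement is meaningful.

# n-gram counting by naive enumeration over token positions
bf_count_ngrams <- function(docs) {
  uni <- list(); bi <- list(); total <- 0L
  for (tk in docs) {
    total <- total + length(tk)
    for (w in tk) uni[[w]] <- (uni[[w]] %||% 0L) + 1L
    if (length(tk) >= 2L) {
      for (i in seq_len(length(tk) - 1L)) {
        k <- paste(tk[i], tk[i + 1L])
        bi[[k]] <- (bi[[k]] %||% 0L) + 1L
      }
    }
  }
  list(unigrams = unlist(uni), bigrams = unlist(bi), total = total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# phrase filter by explicit loop over every counted bigram
bf_extract_phrases <- function(docs, delta, threshold) {
  cnt <- bf_count_ngrams(docs)
  keys <- names(cnt$bigrams)
  if (is.null(keys)) return(character(0))
  keep <- vapply(keys, function(k) {
    p <- strsplit(k, " ", fixed = TRUE)[[1L]]
    s <- (cnt$bigrams[[k]] - delta) /
      (cnt$unigrams[[p[1L]]] * cnt$unigrams[[p[2L]]])
    s > threshold
  }, logical(1))
  sort(keys[keep])
}

# Minimal weighted code length by exhaustive search over all merge orders
# (every Huffman-like merge sequence; guaranteed to visit an optimal code).
bf_optimal_weighted_length <- function(freqs) {
  rec <- function(w, acc) {
    n <- length(w)
    if (n == 1L) return(acc)
    best <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        merged <- c(w[-c(i, j)], w[i] + w[j])
        # each merge adds one bit to every symbol inside the merged node,
        # contributing its weight once to the total length
        val <- rec(merged, acc + w[i] + w[j])
        if (val < best) best <- val
      }
    }
    best
  }
  rec(freqs, 0)
}

# cosine top-k by explicit per-word loop
bf_top_k <- function(model, query_vec, exclude, k) {
  terms <- colnames(model$vectors)
  scores <- numeric(0)
  keep <- character(0)
  for (w in terms) {
    if (w %in% exclude) next
    v <- model$vectors[, w]
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    keep <- c(keep, w)
    scores <- c(scores, sum(v * query_vec) / (nv * sqrt(sum(query_vec^2))))
  }
  o <- order(-scores, keep)
  data.frame(term = keep[o], score = scores[o],
             stringsAsFactors = FALSE)[seq_len(min(k, length(keep))), ]
}

# central-difference gradient of -log hs_probability wrt the context vector
bf_numeric_grad <- function(model, target, ctx, eps = 1e-5) {
  vapply(seq_along(ctx), function(i) {
    e <- numeric(length(ctx)); e[i] <- eps
    (-log(hs_probability(model, target, ctx + e)) +
       log(hs_probability(model, target, ctx - e))) / (2 * eps)
  }, numeric(1))
}

# random embedding model with given vocabulary size/dim (plus Huffman tree)
random_model <- function(nv, dim, seed = 1L, quantize = FALSE) {
  set.seed(seed)
  freqs <- stats::setNames(sample(1:100, nv, replace = TRUE),
                           sprintf("word%03d", seq_len(nv)))
  tree <- build_huffman(freqs)
  vecs <- matrix(stats::rnorm(dim * nv), dim, nv,
                 dimnames = list(NULL, names(freqs)))
  inner <- matrix(stats::rnorm(dim * max(nv - 1L, 1L)), dim)
  if (quantize) {
    vecs[] <- readBin(writeBin(as.numeric(vecs), raw(), size = 4L),
                      "numeric", n = length(vecs), size = 4L)
  }
  structure(list(vectors = vecs, inner = inner, dim = as.integer(dim),
                 vocab = NULL, tree = tree, phrases = character(0),
                 loss = numeric(0), architecture = "random"),
            class = "embedding_model")
}

# ancestors of a term by naive repeated path expansion (for DAG checks)
bf_subsumers <- function(graph, id) {
  res <- id
  frontier <- id
  while (length(frontier)) {
    nxt <- unique(unlist(graph$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, res)
    res <- c(res, nxt)
    frontier <- nxt
  }
  sort(res)
}

# Resnik by enumerating every root-to-term path pair on tree-shaped graphs
bf_resnik_tree <- function(t1, t2, graph, freq) {
  paths_to_root <- function(id) {
    ps <- graph$parents[[id]]
    if (length(ps) == 0L) return(list(id))
    out <- list()
    for (p in ps) {
      for (pp in paths_to_root(p)) out[[length(out) + 1L]] <- c(id, pp)
    }
    out
  }
  best <- -Inf
  for (p1 in paths_to_root(t1)) {
    for (p2 in paths_to_root(t2)) {
      for (s in intersect(p1, p2)) {
        ic <- -log(freq$counts[[s]] / freq$total)
        if (ic > best) best <- ic
      }
    }
  }
  best
}
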