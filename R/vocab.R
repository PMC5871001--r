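#' Build a frequency-filtered vocabulary
#'
#' Terms with corpus frequency below `min_count` are discarded. Indexing is
#' deterministic: descending frequency, ties broken lexicographically;
#' indices run 1..|V| without gaps.
#'
#' @param corpus A character vector of tokens or a list of token vectors.
#' @param min_count Minimum corpus frequency to keep a term (default 5, the
#'   conventional floor for this algorithm family).
#' @return A `vocabulary` object: data frame with columns `term`, `index`,
#'   `freq`, plus attribute `total_count` (sum of kept frequencies).
#' @export
build_vocabulary <- function(corpus, min_count = 5L) {
  stopifnot(min_count >= 1L)
  toks <- if (is.list(corpus)) unlist(corpus, use.names = FALSE) else corpus
  tab <- table(toks)
  freq <- as.integer(tab)
  term <- names(tab)
  keep <- freq >= min_count
  if (!any(keep)) {
    stop("build_vocabulary: no term reaches min_count = ", min_count)
  }
  term <- term[keep]
  freq <- freq[keep]
  o <- order(-freq, term)
  out <- data.frame(term = term[o], index = seq_along(term),
                    freq = freq[o], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total_count") <- sum(out$freq)
  class(out) <- c("vocabulary", "data.frame")
  out
}

#' Write a vocabulary as TSV (term, index, frequency)
#' @param vocab A `vocabulary`.
#' @param path Output file.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(vocab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build the Huffman coding tree over vocabulary frequencies
#'
#' Classic Huffman construction: repeatedly merge the two lightest nodes.
#' The resulting binary tree drives the hierarchical softmax output layer:
#' each word's probability is a product of logistic decisions along its
#' root-to-leaf path, so evaluation costs O(code length) = O(log2 |V|)
#' instead of O(|V|), and frequent words get the shortest paths.
#'
#' Tie-breaking is fully deterministic: among equal weights the earliest
#' inserted node is picked, and bit 0 goes to the lighter (then
#' earlier-inserted) child of each merge.
#'
#' @param vocab A `vocabulary`, or a named numeric vector of frequencies.
#' @return A `huffman_tree` object: list with `codes` (named list of 0/1
#'   integer vectors per term), `paths` (named list of inner-node indices,
#'   1-based, same length as the code), and `inner_node_count`. A one-word
#'   vocabulary yields the degenerate tree with an empty code and no inner
#'   nodes.
#' @export
build_huffman <- function(vocab) {
  if (inherits(vocab, "vocabulary")) {
    freq <- as.numeric(vocab$freq)
    terms <- vocab$term
  } else {
    freq <- as.numeric(vocab)
    terms <- names(vocab)
    if (length(freq) == 0L) stop("build_huffman: empty vocabulary")
    if (is.null(terms)) stop("build_huffman: frequencies must be named")
  }
  nv <- length(freq)
  if (nv == 0L) stop("build_huffman: empty vocabulary")
  if (nv == 1L) {
    codes <- list(integer(0)); paths <- list(integer(0))
    names(codes) <- names(paths) <- terms
    return(structure(list(codes = codes, paths = paths,
                          inner_node_count = 0L),
                     class = "huffman_tree"))
  }
  # Node arrays: leaves 1..nv, inner nodes appended as created.
  n_total <- 2L * nv - 1L
  weight <- c(freq, rep(NA_real_, nv - 1L))
  parent <- integer(n_total)
  bit <- integer(n_total)          # bit assigned on the edge to the parent
  alive <- c(rep(TRUE, nv), rep(FALSE, nv - 1L))
  order_in <- seq_len(n_total)     # insertion order; leaves first
  for (k in seq_len(nv - 1L)) {
    cand <- which(alive)
    # two minima by (weight, insertion order)
    o <- cand[order(weight[cand], order_in[cand])]
    lo <- o[1L]; hi <- o[2L]
    new <- nv + k
    weight[new] <- weight[lo] + weight[hi]
    parent[c(lo, hi)] <- new
    bit[lo] <- 0L; bit[hi] <- 1L
    alive[c(lo, hi)] <- FALSE
    alive[new] <- TRUE
  }
  root <- n_total
  codes <- vector("list", nv)
  paths <- vector("list", nv)
  for (i in seq_len(nv)) {
    b <- integer(0); p <- integer(0)
    node <- i
    while (node != root) {
      b <- c(bit[node], b)
      p <- c(parent[node] - nv, p)  # inner nodes numbered 1..nv-1
      node <- parent[node]
    }
    codes[[i]] <- b
    paths[[i]] <- p
  }
  names(codes) <- names(paths) <- terms
  structure(list(codes = codes, paths = paths,
                 inner_node_count = nv - 1L),
            class = "huffman_tree")
}

#' @export
print.huffman_tree <- function(x, ...) {
  lens <- lengths(x$codes)
  cat("Huffman tree:", length(x$codes), "leaves,", x$inner_node_count,
      "inner nodes, code lengths", min(lens), "-", max(lens), "\n")
  invisible(x)
}
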