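#' @useDynLib semsuggest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Hierarchical-softmax probability of a word given a context vector
#'
#' The vocabulary is arranged as a Huffman binary tree; the probability of a
#' word is the product, over the inner nodes on its root-to-leaf path, of a
#' logistic decision \eqn{\sigma(s_k \langle v_{n_k}, h\rangle)} with
#' \eqn{s_k = +1} when the code bit is 0 and \eqn{-1} when it is 1. Exactly
#' `length(code(target))` node terms are evaluated, so the cost is
#' O(log2 |V|) rather than O(|V|), and the probabilities over the whole
#' vocabulary sum to one by construction.
#'
#' @param model An `embedding_model` (see [train_embeddings()]); its
#'   `inner` matrix holds the inner-node vectors.
#' @param target Word whose conditional probability is evaluated.
#' @param context_vector Numeric vector of length `model$dim`.
#' @param tree Huffman tree; defaults to the model's own.
#' @return Probability in (0, 1); 1 for a one-word vocabulary (empty code).
#' @export
hs_probability <- function(model, target, context_vector, tree = model$tree) {
  code <- tree$codes[[target]]
  path <- tree$paths[[target]]
  if (is.null(code)) stop("hs_probability: unknown target word: ", target)
  stopifnot(length(context_vector) == model$dim)
  p <- 1
  for (k in seq_along(code)) {
    x <- sum(model$inner[, path[k]] * context_vector)
    s <- if (code[k] == 0L) 1 else -1
    p <- p * sigmoid(s * x)
  }
  p
}

#' One stochastic-gradient step on the hierarchical-softmax loss
#'
#' Minimizes the negative log of [hs_probability()] for one
#' (target, context) pair: the inner-node vectors on the target's path are
#' updated in place (in the returned model), and the gradient with respect
#' to the context vector is returned so that callers can propagate it to the
#' input word vectors. The inner-node gradient uses the pre-update vectors,
#' matching plain simultaneous SGD.
#'
#' @inheritParams hs_probability
#' @param lr Learning rate (non-negative; 0 leaves parameters unchanged).
#' @return List with `model` (inner vectors updated), `grad_context`
#'   (d loss / d context_vector), and `loss` (negative log probability at
#'   the pre-step parameters).
#' @export
hs_gradient_step <- function(model, target, context_vector, lr,
                             tree = model$tree) {
  if (lr < 0) stop("hs_gradient_step: lr must be non-negative")
  code <- tree$codes[[target]]
  path <- tree$paths[[target]]
  if (is.null(code)) stop("hs_gradient_step: unknown target word: ", target)
  grad <- numeric(model$dim)
  loss <- 0
  for (k in seq_along(code)) {
    v <- model$inner[, path[k]]
    f <- sigmoid(sum(v * context_vector))
    t_k <- if (code[k] == 0L) 1 else 0
    g <- f - t_k
    loss <- loss - log(if (t_k == 1) f else 1 - f)
    grad <- grad + g * v
    model$inner[, path[k]] <- v - lr * g * context_vector
  }
  list(model = model, grad_context = grad, loss = loss)
}

#' Enumerate the (input, target) training pairs for one document
#'
#' For skip-gram the center word is the input and each word within the
#' window is a target; for CBOW the (unordered) context set is the input
#' and the center word the target. Exposed so the window logic can be
#' inspected and tested independently of the optimizer.
#'
#' @param tokens Character vector (one document).
#' @param window Window half-width.
#' @param architecture `"skipgram"` or `"cbow"`.
#' @return For skip-gram, a data frame `input`, `target` (one row per
#'   prediction); for CBOW, a list with elements `context` (character
#'   vector) and `target`.
#' @export
training_pairs <- function(tokens, window, architecture = c("skipgram", "cbow")) {
  architecture <- match.arg(architecture)
  n <- length(tokens)
  if (architecture == "skipgram") {
    inp <- character(0); tgt <- character(0)
    for (t in seq_len(n)) {
      js <- setdiff(max(1L, t - window):min(n, t + window), t)
      inp <- c(inp, rep(tokens[t], length(js)))
      tgt <- c(tgt, tokens[js])
    }
    data.frame(input = inp, target = tgt, stringsAsFactors = FALSE)
  } else {
    lapply(seq_len(n), function(t) {
      js <- setdiff(max(1L, t - window):min(n, t + window), t)
      list(context = tokens[js], target = tokens[t])
    })
  }
}

#' Train word vectors with CBOW or skip-gram and hierarchical softmax
#'
#' Stochastic gradient descent over the corpus. CBOW predicts each center
#' word from the mean of the context word vectors inside the window;
#' skip-gram uses the center word's vector to predict each window word
#' separately. The learning rate decays linearly from `initial_lr` to
#' `min_lr` over all `epochs * n_tokens` center-word presentations. The
#' window is fixed (no per-position random shrinking), training is
#' single-threaded, and an identical seed, configuration, and corpus yields
#' an identical model.
#'
#' @param docs List of token vectors (e.g. `rewrite_corpus(...)$docs`), or a
#'   character vector of raw documents (tokenized with defaults).
#' @param vocab Optional `vocabulary`; built from `docs` with `min_count`
#'   when omitted. Corpus tokens outside the vocabulary are skipped.
#' @param architecture `"skipgram"` or `"cbow"`.
#' @param dim Word-vector dimensionality (default 200).
#' @param window Context half-width (default 5).
#' @param epochs Passes over the corpus (default 5).
#' @param initial_lr,min_lr Linear learning-rate schedule endpoints
#'   (defaults 0.025 and 1e-4).
#' @param seed Integer seed for the random word-vector initialization
#'   (uniform in \[-0.5/dim, 0.5/dim\]; inner-node vectors start at zero).
#' @param subsample Frequent-word subsampling threshold; 0 (default)
#'   disables it. When positive, each occurrence of word w is dropped with
#'   probability `max(0, 1 - sqrt(subsample / f_w))`, `f_w` its relative
#'   frequency, once before training.
#' @param min_count Vocabulary frequency floor when `vocab` is omitted.
#' @param phrases Optional phrase inventory stored on the model so queries
#'   get the same phrase merging the corpus did.
#' @param engine `"C"` (compiled inner loop, default) or `"R"` (reference
#'   implementation with identical arithmetic, for cross-checking).
#' @return An `embedding_model`: list with `vectors` (dim x |V| matrix,
#'   columns named by term), `inner` (dim x (|V|-1) inner-node matrix),
#'   `dim`, `vocab`, `tree`, `phrases`, and `loss` (mean negative log
#'   probability per epoch).
#' @export
train_embeddings <- function(docs, vocab = NULL,
                             architecture = c("skipgram", "cbow"),
                             dim = 200L, window = 5L, epochs = 5L,
                             initial_lr = 0.025, min_lr = 1e-4,
                             seed = 1L, subsample = 0,
                             min_count = 5L, phrases = NULL,
                             engine = c("C", "R")) {
  architecture <- match.arg(architecture)
  engine <- match.arg(engine)
  stopifnot(dim >= 1L, window >= 1L, epochs >= 1L, min_lr <= initial_lr)
  if (is.character(docs)) docs <- lapply(docs, tokenize)
  if (length(docs) == 0L || sum(lengths(docs)) == 0L) {
    stop("train_embeddings: empty corpus")
  }
  if (is.null(vocab)) vocab <- build_vocabulary(docs, min_count = min_count)
  tree <- build_huffman(vocab)
  nv <- nrow(vocab)

  # Map documents to vocabulary indices, skipping out-of-vocabulary tokens.
  idx <- stats::setNames(vocab$index, vocab$term)
  sent <- lapply(docs, function(tk) {
    v <- idx[tk]
    as.integer(v[!is.na(v)])
  })
  sent <- sent[lengths(sent) > 0L]
  if (length(sent) == 0L) stop("train_embeddings: corpus empty after vocabulary filter")

  set.seed(as.integer(seed))
  syn0 <- matrix(stats::runif(dim * nv, -0.5, 0.5) / dim, nrow = dim)
  syn1 <- matrix(0, nrow = dim, ncol = max(nv - 1L, 1L))

  if (subsample > 0) {
    freq_rel <- vocab$freq / attr(vocab, "total_count")
    p_drop <- pmax(0, 1 - sqrt(subsample / freq_rel))
    sent <- lapply(sent, function(s) s[stats::runif(length(s)) >= p_drop[s]])
    sent <- sent[lengths(sent) > 0L]
    if (length(sent) == 0L) stop("train_embeddings: corpus empty after subsampling")
  }

  code_len <- lengths(tree$codes)
  codes_flat <- unlist(tree$codes, use.names = FALSE)
  paths_flat <- unlist(tree$paths, use.names = FALSE)
  if (is.null(codes_flat)) codes_flat <- integer(0)
  if (is.null(paths_flat)) paths_flat <- integer(0)

  fit <- if (engine == "C") {
    train_loop_cpp(sent, syn0, syn1, as.integer(code_len),
                   as.integer(codes_flat), as.integer(paths_flat),
                   architecture == "cbow", as.integer(window),
                   as.integer(epochs), initial_lr, min_lr)
  } else {
    train_loop_r(sent, syn0, syn1, code_len, codes_flat, paths_flat,
                 cbow = architecture == "cbow", window = window,
                 epochs = epochs, initial_lr = initial_lr, min_lr = min_lr)
  }
  colnames(fit$syn0) <- vocab$term
  structure(list(vectors = fit$syn0, inner = fit$syn1, dim = as.integer(dim),
                 vocab = vocab, tree = tree,
                 phrases = if (is.null(phrases)) character(0)
                           else phrase_keys(phrases),
                 loss = as.numeric(fit$epoch_loss) /
                        pmax(as.numeric(fit$epoch_pairs), 1),
                 architecture = architecture),
            class = "embedding_model")
}

# Pure-R reference trainer; arithmetic mirrors the compiled loop
# operation-for-operation so the two engines can be compared directly.
train_loop_r <- function(sent, syn0, syn1, code_len, codes_flat, paths_flat,
                         cbow, window, epochs, initial_lr, min_lr) {
  dim <- nrow(syn0)
  code_off <- c(0L, cumsum(code_len))
  n_tokens <- sum(lengths(sent))
  total <- as.numeric(epochs) * n_tokens
  processed <- 0
  epoch_loss <- numeric(epochs)
  epoch_pairs <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    for (s in sent) {
      n <- length(s)
      for (t in seq_len(n)) {
        alpha <- initial_lr - (initial_lr - min_lr) * (processed / total)
        if (alpha < min_lr) alpha <- min_lr
        processed <- processed + 1
        lo <- max(1L, t - window); hi <- min(n, t + window)
        ctx <- setdiff(lo:hi, t)
        if (length(ctx) == 0L) next
        if (cbow) {
          h <- numeric(dim)
          for (j in ctx) h <- h + syn0[, s[j]]
          cn <- length(ctx)
          h <- h / cn
          w <- s[t]
          neu1e <- numeric(dim)
          for (k in seq_len(code_len[w])) {
            kk <- code_off[w] + k
            node <- paths_flat[kk]
            v <- syn1[, node]
            f <- 1 / (1 + exp(-sum(v * h)))
            tk <- if (codes_flat[kk] == 0L) 1 else 0
            g <- f - tk
            epoch_loss[ep] <- epoch_loss[ep] - log(if (tk == 1) f else 1 - f)
            neu1e <- neu1e + g * v
            syn1[, node] <- v - alpha * g * h
          }
          epoch_pairs[ep] <- epoch_pairs[ep] + 1
          gshare <- neu1e / cn
          for (j in ctx) syn0[, s[j]] <- syn0[, s[j]] - alpha * gshare
        } else {
          h <- syn0[, s[t]]
          neu1e <- numeric(dim)
          for (j in ctx) {
            w <- s[j]
            for (k in seq_len(code_len[w])) {
              kk <- code_off[w] + k
              node <- paths_flat[kk]
              v <- syn1[, node]
              f <- 1 / (1 + exp(-sum(v * h)))
              tk <- if (codes_flat[kk] == 0L) 1 else 0
              g <- f - tk
              epoch_loss[ep] <- epoch_loss[ep] - log(if (tk == 1) f else 1 - f)
              neu1e <- neu1e + g * v
              syn1[, node] <- v - alpha * g * h
            }
            epoch_pairs[ep] <- epoch_pairs[ep] + 1
          }
          syn0[, s[t]] <- h - alpha * neu1e
        }
      }
    }
  }
  list(syn0 = syn0, syn1 = syn1, epoch_loss = epoch_loss,
       epoch_pairs = epoch_pairs)
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("Embedding model (", x$architecture, "): ",
      ncol(x$vectors), " words x ", x$dim, " dimensions\n", sep = "")
  if (length(x$loss)) {
    cat("Mean -log P per epoch:", paste(signif(x$loss, 4), collapse = ", "),
        "\n")
  }
  invisible(x)
}
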