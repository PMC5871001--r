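#' Parse an OBO 1.2/1.4 ontology file
#'
#' Reads `[Term]` stanzas, capturing `id`, `name`, `synonym` (the quoted
#' text, any scope), and `is_a` edges. Obsolete terms are skipped. Only
#' `is_a` edges are kept; `part_of` and other relationships are ignored.
#' The edge set must form a DAG.
#'
#' @param path OBO file path, or a character vector of OBO lines.
#' @return An `ontology_graph`: list with `ids`, `labels` (named by id),
#'   `synonyms` (named list of character vectors), and `parents` (named
#'   list of parent ids).
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, encoding = "UTF-8", warn = FALSE)
  } else {
    path
  }
  lines <- sub("\\s*!.*$", "", lines)   # trailing comments
  stanza_starts <- grep("^\\[", lines)
  term_starts <- stanza_starts[lines[stanza_starts] == "[Term]"]
  ids <- character(0); labels <- character(0)
  synonyms <- list(); parents <- list()
  ends <- c(stanza_starts[-1L] - 1L, length(lines))
  for (si in seq_along(stanza_starts)) {
    if (!(stanza_starts[si] %in% term_starts)) next
    body <- lines[(stanza_starts[si] + 1L):ends[si]]
    get_vals <- function(tag) {
      v <- body[startsWith(body, paste0(tag, ":"))]
      trimws(sub(paste0("^", tag, ":"), "", v))
    }
    if (length(get_vals("is_obsolete")) &&
        any(get_vals("is_obsolete") == "true")) next
    id <- get_vals("id")
    if (length(id) != 1L || !nzchar(id)) {
      stop("parse_obo: [Term] stanza at line ", stanza_starts[si],
           " has no unique id")
    }
    name <- get_vals("name")
    syn_raw <- get_vals("synonym")
    syn <- sub('^"(.*)".*$', "\\1", syn_raw)
    isa <- sub("\\s.*$", "", get_vals("is_a"))
    ids <- c(ids, id)
    labels <- c(labels, if (length(name)) name[1L] else id)
    synonyms[[id]] <- syn[nzchar(syn)]
    parents[[id]] <- isa[nzchar(isa)]
  }
  if (length(ids) == 0L) stop("parse_obo: no [Term] stanzas found")
  names(labels) <- ids
  # drop dangling parent references (e.g. to obsolete terms)
  parents <- lapply(parents, function(p) p[p %in% ids])
  g <- structure(list(ids = ids, labels = labels, synonyms = synonyms,
                      parents = parents),
                 class = "ontology_graph")
  assert_acyclic(g)
  g
}

assert_acyclic <- function(graph) {
  # Kahn's algorithm over is_a edges (child -> parent)
  indeg <- stats::setNames(integer(length(graph$ids)), graph$ids)
  for (id in graph$ids) {
    for (p in graph$parents[[id]]) indeg[p] <- indeg[p] + 1L
  }
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    seen <- seen + 1L
    for (p in graph$parents[[v]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(graph$ids)) {
    stop("parse_obo: is_a edges contain a cycle")
  }
  invisible(TRUE)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("Ontology graph:", length(x$ids), "terms,",
      sum(lengths(x$parents)), "is_a edges\n")
  invisible(x)
}

ontology_label_pool <- function(graph) {
  c(unname(graph$labels), unlist(graph$synonyms, use.names = FALSE))
}

#' All subsumers of a term (the term itself plus is_a ancestors)
#' @param graph An `ontology_graph`.
#' @param id Term id.
#' @return Character vector of term ids.
#' @export
subsumers <- function(graph, id) {
  if (!(id %in% graph$ids)) stop("subsumers: unknown term: ", id)
  out <- character(0)
  stack <- id
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v %in% out) next
    out <- c(out, v)
    stack <- c(stack, graph$parents[[v]])
  }
  out
}

#' Term-frequency table for information content
#'
#' Holds flat corpus counts per ontology term; `P(T) = count(T) / total`.
#' Counts are not propagated up the is_a hierarchy by default (the flat
#' reading of "relative frequency in the text corpus"); use
#' `propagate_counts()` for classic cumulative Resnik counts.
#'
#' @param counts Named non-negative integer vector (names are term ids).
#' @param total Positive total token count; defaults to `sum(counts)`.
#' @return A `term_freq_table`: list with `counts` and `total`.
#' @export
term_freq_table <- function(counts, total = sum(counts)) {
  stopifnot(length(counts) > 0, !is.null(names(counts)),
            all(counts >= 0), total > 0, all(counts <= total))
  structure(list(counts = counts, total = total), class = "term_freq_table")
}

#' Read a term-frequency table from TSV (term, count)
#' @param path TSV file with two columns: term id (or label) and count.
#' @param total Total token count; defaults to the column sum.
#' @return A `term_freq_table`.
#' @export
read_freq_table <- function(path, total = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("term", "count"),
                          stringsAsFactors = FALSE, quote = "")
  counts <- stats::setNames(as.numeric(df$count), df$term)
  term_freq_table(counts, total = if (is.null(total)) sum(counts) else total)
}

#' Propagate term counts up the is_a hierarchy
#'
#' Classic cumulative counting: each term's count becomes the sum of its
#' own flat count and the flat counts of all its descendants, making
#' ancestors always at least as frequent as their descendants.
#'
#' @param freq A `term_freq_table` with flat counts.
#' @param graph The `ontology_graph`.
#' @return A `term_freq_table` with cumulative counts; its total is the
#'   largest cumulative root count, so the most general root has P = 1 (the
#'   usual normalization for cumulative information content).
#' @export
propagate_counts <- function(freq, graph) {
  cum <- stats::setNames(numeric(length(graph$ids)), graph$ids)
  for (id in graph$ids) {
    cnt <- if (id %in% names(freq$counts)) freq$counts[[id]] else 0
    if (cnt > 0) {
      anc <- subsumers(graph, id)
      cum[anc] <- cum[anc] + cnt
    }
  }
  term_freq_table(cum, total = max(cum))
}

ic_of <- function(id, freq) {
  cnt <- if (id %in% names(freq$counts)) freq$counts[[id]] else 0
  if (cnt <= 0) return(Inf)
  -log(cnt / freq$total)
}

resnik_detail <- function(t1, t2, graph, freq) {
  common <- intersect(subsumers(graph, t1), subsumers(graph, t2))
  if (length(common) == 0L) {
    stop("resnik: terms ", t1, " and ", t2, " have no common subsumer")
  }
  ics <- vapply(common, ic_of, numeric(1), freq = freq)
  best <- which.max(ics)
  if (!is.finite(ics[best])) {
    stop("resnik: maximizing subsumer '", common[best],
         "' has zero corpus count")
  }
  list(value = ics[[best]], subsumer = common[[best]])
}

#' Resnik information-content similarity of two ontology terms
#'
#' `max over common subsumers T_s of -ln(P(T_s))`, where the subsumer set
#' includes the terms themselves (every term subsumes itself) — which is
#' what makes a term maximally similar to its own synonyms. A rare shared
#' parent (low `P`) carries high information content, so two terms whose
#' only common ancestor is a ubiquitous root score 0.
#'
#' @param t1,t2 Term ids in `graph`.
#' @param graph An `ontology_graph`.
#' @param freq A `term_freq_table`.
#' @return Non-negative similarity (0 when the best subsumer has P = 1).
#' @export
resnik <- function(t1, t2, graph, freq) {
  resnik_detail(t1, t2, graph, freq)$value
}

#' Identify the information-content-maximizing common subsumer
#' @inheritParams resnik
#' @return The term id of the subsumer whose information content realizes
#'   the Resnik similarity.
#' @export
resnik_best_subsumer <- function(t1, t2, graph, freq) {
  resnik_detail(t1, t2, graph, freq)$subsumer
}

#' Lin similarity (0-1 scaled information-content similarity)
#'
#' `2 * Sim_Resnik(T1, T2) / (-ln(P(T1) * P(T2)))`, i.e. twice the
#' information content of the best common subsumer over the summed
#' information content of the two terms. Values are clamped to \[0, 1\]
#' (flat corpus counting can make a subsumer rarer than its descendants;
#' clamped rows are flagged by [evaluate_suggestions()]). `lin(t, t) = 1`
#' whenever `P(t) < 1`.
#'
#' @inheritParams resnik
#' @return Similarity in \[0, 1\].
#' @export
lin <- function(t1, t2, graph, freq) {
  lin_detail(t1, t2, graph, freq)$value
}

lin_detail <- function(t1, t2, graph, freq) {
  r <- resnik_detail(t1, t2, graph, freq)
  denom <- ic_of(t1, freq) + ic_of(t2, freq)
  if (!is.finite(denom)) {
    stop("lin: zero corpus count on ", t1, " or ", t2)
  }
  if (denom == 0) {
    stop("lin: both terms have P = 1; similarity undefined")
  }
  raw <- 2 * r$value / denom
  list(value = min(1, max(0, raw)), raw = raw, resnik = r$value,
       subsumer = r$subsumer, clamped = raw > 1)
}

#' Match a suggestion string to an ontology term
#'
#' Case-insensitive exact match of the suggestion (underscore phrase
#' delimiters mapped back to spaces) against term labels first, then
#' synonyms; the first graph in the supplied order wins.
#'
#' @param suggestion Suggestion string (may contain `_` as phrase joiner).
#' @param graphs One `ontology_graph` or an ordered list of them.
#' @return Named list with `id` and `graph` (index), or `NULL` when
#'   unmatched.
#' @export
match_to_ontology <- function(suggestion, graphs) {
  if (inherits(graphs, "ontology_graph")) graphs <- list(graphs)
  key <- tolower(gsub("_", " ", suggestion, fixed = TRUE))
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    hit <- which(tolower(g$labels) == key)
    if (length(hit)) return(list(id = g$ids[hit[1L]], graph = gi))
  }
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    for (id in g$ids) {
      if (key %in% tolower(g$synonyms[[id]])) {
        return(list(id = id, graph = gi))
      }
    }
  }
  NULL
}

#' Evaluate suggestion quality by ontology information-content similarity
#'
#' For each query: take the model's `top_n` suggestions, keep the ones that
#' match an ontology term, and compute Lin similarity between each matched
#' suggestion and the matched original query term. Queries that do not
#' match any ontology are reported as skipped.
#'
#' @param queries Character vector of query strings.
#' @param model An `embedding_model`.
#' @param graphs Ordered list of `ontology_graph`s (or a single graph).
#' @param freq A `term_freq_table` shared by all graphs.
#' @param top_n Suggestions inspected per query (default 10).
#' @return A `similarity_report`: list with `rows` (data frame: query,
#'   suggestion, query_term, suggestion_term, subsumer, sim_resnik,
#'   sim_lin, clamped), `skipped` (unmatched queries), and aggregates
#'   `mean_lin`, `frac_above_0.8`, `min_lin`.
#' @export
evaluate_suggestions <- function(queries, model, graphs, freq, top_n = 10L) {
  stopifnot(length(queries) > 0)
  if (inherits(graphs, "ontology_graph")) graphs <- list(graphs)
  rows <- list()
  skipped <- character(0)
  for (q in queries) {
    qm <- match_to_ontology(q, graphs)
    if (is.null(qm)) { skipped <- c(skipped, q); next }
    sugg <- tryCatch(top_k(model, q, k = top_n),
                     error = function(e) empty_suggestion_list())
    for (i in seq_len(nrow(sugg))) {
      sm <- match_to_ontology(sugg$term[i], graphs)
      if (is.null(sm) || sm$graph != qm$graph) next
      g <- graphs[[qm$graph]]
      ld <- tryCatch(lin_detail(qm$id, sm$id, g, freq),
                     error = function(e) NULL)
      if (is.null(ld)) next
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, suggestion = sugg$term[i],
        query_term = qm$id, suggestion_term = sm$id,
        subsumer = ld$subsumer, sim_resnik = ld$resnik,
        sim_lin = ld$value, clamped = ld$clamped,
        stringsAsFactors = FALSE)
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else data.frame(
    query = character(0), suggestion = character(0),
    query_term = character(0), suggestion_term = character(0),
    subsumer = character(0), sim_resnik = numeric(0),
    sim_lin = numeric(0), clamped = logical(0), stringsAsFactors = FALSE)
  structure(list(
    rows = rows, skipped = skipped,
    mean_lin = if (nrow(rows)) mean(rows$sim_lin) else NA_real_,
    frac_above_0.8 = if (nrow(rows)) mean(rows$sim_lin > 0.8) else NA_real_,
    min_lin = if (nrow(rows)) min(rows$sim_lin) else NA_real_),
    class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("Suggestion similarity report:", nrow(x$rows), "scored pairs;",
      length(x$skipped), "queries skipped (no ontology match)\n")
  if (nrow(x$rows)) {
    cat(sprintf("  mean Sim_Lin %.3f | fraction > 0.8: %.2f | min %.3f\n",
                x$mean_lin, x$frac_above_0.8, x$min_lin))
  }
  invisible(x)
}

#' Write a similarity report as TSV and/or JSON
#' @param report A `similarity_report`.
#' @param tsv,json Optional output paths.
#' @export
write_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(report$rows, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(rows = report$rows, skipped = report$skipped,
           mean_lin = report$mean_lin,
           frac_above_0.8 = report$frac_above_0.8,
           min_lin = report$min_lin),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
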