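toy_obo_lines <- function() {
  c("format-version: 1.2",
    "",
    "[Term]",
    "id: T:0001",
    "name: organism quality",
    "",
    "[Term]",
    "id: T:0002",
    "name: stress response",
    'synonym: "stress tolerance" EXACT []',
    "is_a: T:0001 ! organism quality",
    "",
    "[Term]",
    "id: T:0003",
    "name: salt stress",
    'synonym: "salinity stress" EXACT []',
    "is_a: T:0002 ! stress response",
    "",
    "[Term]",
    "id: T:0004",
    "name: drought stress",
    "is_a: T:0002 ! stress response",
    "",
    "[Term]",
    "id: T:0005",
    "name: old salt stress",
    "is_obsolete: true",
    "is_a: T:0002",
    "",
    "[Term]",
    "id: T:0006",
    "name: osmotic and salt stress",
    "is_a: T:0003 ! salt stress",
    "is_a: T:0004 ! drought stress",
    "")
}

test_that("OBO parsing captures terms, synonyms, is_a edges, and skips obsolete", {
  f <- tempfile(fileext = ".obo")
  writeLines(toy_obo_lines(), f)
  g <- parse_obo(f)
  expect_setequal(g$ids, c("T:0001", "T:0002", "T:0003", "T:0004", "T:0006"))
  expect_false("T:0005" %in% g$ids)   # obsolete dropped
  expect_identical(unname(g$labels["T:0003"]), "salt stress")
  expect_identical(g$synonyms[["T:0003"]], "salinity stress")
  expect_identical(g$parents[["T:0003"]], "T:0002")
  # multi-parent term: both ancestor paths found
  expect_setequal(subsumers(g, "T:0006"),
                  c("T:0006", "T:0003", "T:0004", "T:0002", "T:0001"))
  expect_identical(sort(subsumers(g, "T:0006")), bf_subsumers(g, "T:0006"))

  # three-term chain fixture has exactly two edges
  g3 <- parse_obo(c("[Term]", "id: A", "name: root", "",
                    "[Term]", "id: B", "name: mid", "is_a: A", "",
                    "[Term]", "id: C", "name: leaf", "is_a: B", ""))
  expect_identical(sum(lengths(g3$parents)), 2L)

  expect_error(parse_obo(c("[Term]", "name: no id", "")), "id")
  expect_error(parse_obo(c("[Term]", "id: X", "is_a: Y", "",
                           "[Term]", "id: Y", "is_a: X", "")), "cycle")
})

test_that("Resnik similarity is the information content of the best common subsumer", {
  f <- tempfile(fileext = ".obo")
  writeLines(toy_obo_lines(), f)
  g <- parse_obo(f)

  total <- 1000
  freq <- term_freq_table(c("T:0001" = 1000, "T:0002" = round(1000 * exp(-2)),
                            "T:0003" = 20, "T:0004" = 25, "T:0006" = 5),
                          total = total)
  # root with P = 1 as only common subsumer -> 0
  freq_root_only <- term_freq_table(c("T:0001" = 1000, "T:0002" = 1000,
                                      "T:0003" = 20, "T:0004" = 25,
                                      "T:0006" = 5), total = total)
  expect_equal(resnik("T:0003", "T:0004", freq = freq_root_only, graph = g),
               0)
  # common subsumer with P = e^-2 -> 2 (within rounding of the count)
  expect_equal(resnik("T:0003", "T:0004", freq = freq, graph = g),
               -log(round(1000 * exp(-2)) / 1000))
  # symmetry
  expect_equal(resnik("T:0003", "T:0004", g, freq),
               resnik("T:0004", "T:0003", g, freq))
  # a term subsumes itself: resnik(t, t) = IC(t)
  expect_equal(resnik("T:0003", "T:0003", g, freq), -log(20 / total))

  # rarer subsumer carries more information: counts mirroring a broad
  # taxonomic root versus a specific plant family under one shared total
  g2 <- parse_obo(c("[Term]", "id: ORG", "name: cellular organism", "",
                    "[Term]", "id: POA", "name: poaceae", "is_a: ORG", "",
                    "[Term]", "id: TRI", "name: triticum", "is_a: POA", "",
                    "[Term]", "id: ZEA", "name: zea", "is_a: POA", "",
                    "[Term]", "id: CHL", "name: chlamydomonas",
                    "is_a: ORG", ""))
  f2 <- term_freq_table(c(ORG = 1456281, POA = 8131, TRI = 900, ZEA = 800,
                          CHL = 700), total = 2e6)
  via_family <- resnik("TRI", "ZEA", g2, f2)    # best subsumer: poaceae
  via_root <- resnik("TRI", "CHL", g2, f2)      # only subsumer: organism
  expect_gt(via_family, via_root)
  expect_equal(via_family, -log(8131 / 2e6))
  expect_equal(via_root, -log(1456281 / 2e6))

  expect_error(resnik("T:0003", "nope", g, freq), "unknown")
})

test_that("Lin similarity is the 0-1 scaled form with the synonym identity", {
  g <- parse_obo(c("[Term]", "id: R", "name: root", "",
                   "[Term]", "id: S", "name: subsumer", "is_a: R", "",
                   "[Term]", "id: A", "name: term a", "is_a: S", "",
                   "[Term]", "id: B", "name: term b", "is_a: S", ""))
  # closed-form: P(A) = P(B) = e^-3, P(subsumer) = e^-2 -> 2*2/6
  n <- 1e6
  freq <- term_freq_table(c(R = n, S = round(n * exp(-2)),
                            A = round(n * exp(-3)), B = round(n * exp(-3))),
                          total = n)
  expect_equal(lin("A", "B", g, freq), 2 / 3, tolerance = 1e-4)
  # direct synonym case: lin(t, t) = 1 whenever P(t) < 1
  expect_equal(lin("A", "A", g, freq), 1.0)
  expect_equal(lin("S", "S", g, freq), 1.0)
  # common subsumer at P = 1 -> numerator 0
  freq2 <- term_freq_table(c(R = n, S = n, A = 10, B = 10), total = n)
  expect_equal(lin("A", "B", g, freq2), 0)
  # both terms at P = 1: undefined
  freq3 <- term_freq_table(c(R = n, S = n, A = n, B = n), total = n)
  expect_error(lin("A", "B", g, freq3), "P = 1")
  # symmetry
  expect_equal(lin("A", "B", g, freq), lin("B", "A", g, freq))
})

test_that("similarity properties hold on generated toy ontologies", {
  toy <- generate_toy_ontology(depth = 4, branching = 2, seed = 3)
  g <- toy$graph; freq <- toy$freq
  leaves <- setdiff(g$ids, unique(unlist(g$parents)))

  # symmetry and [0, 1] range on random pairs
  set.seed(17)
  for (rep in 1:15) {
    p <- sample(g$ids, 2)
    r12 <- resnik(p[1], p[2], g, freq)
    expect_equal(r12, resnik(p[2], p[1], g, freq))
    l12 <- lin(p[1], p[2], g, freq)
    expect_gte(l12, 0); expect_lte(l12, 1)
  }

  # tree-shaped fixture: ancestor-set Resnik equals path-enumeration oracle
  for (rep in 1:10) {
    p <- sample(g$ids, 2)
    expect_equal(resnik(p[1], p[2], g, freq),
                 bf_resnik_tree(p[1], p[2], g, freq))
  }

  # deeper common ancestor implies strictly larger Lin (brute force over
  # all leaf pairs, comparing sibling pairs against non-sibling pairs)
  sib <- lin(leaves[1], leaves[2], g, freq)       # share a depth-3 parent
  cousin <- lin(leaves[1], leaves[3], g, freq)    # share a depth-2 ancestor
  distant <- lin(leaves[1], leaves[5], g, freq)   # share only higher nodes
  expect_gt(sib, cousin)
  expect_gt(cousin, distant)

  # depth-1 ontology: root only, any self pair undefined (P(root) = 1)
  toy1 <- generate_toy_ontology(depth = 1)
  expect_identical(length(toy1$graph$ids), 1L)
  expect_error(lin(toy1$graph$ids, toy1$graph$ids, toy1$graph, toy1$freq),
               "P = 1")

  # replacing the maximizing subsumer by a rarer one never decreases lin:
  # halving the best subsumer's count increases both metrics
  p <- c(leaves[1], leaves[2])
  best <- resnik_best_subsumer(p[1], p[2], g, freq)
  freq_rarer <- freq
  freq_rarer$counts[best] <- max(1, floor(freq$counts[[best]] / 2))
  expect_gte(resnik(p[1], p[2], g, freq_rarer), resnik(p[1], p[2], g, freq))
  expect_gte(lin(p[1], p[2], g, freq_rarer), lin(p[1], p[2], g, freq))
})

test_that("ontology matching maps phrase delimiters and respects graph order", {
  g_to <- parse_obo(c("[Term]", "id: TO:1", "name: salt stress", ""))
  g_go <- parse_obo(c("[Term]", "id: GO:1", "name: response to salt",
                      'synonym: "salt stress" EXACT []', ""))
  hit <- match_to_ontology("salt_stress", list(g_to, g_go))
  expect_identical(hit$id, "TO:1")
  # precedence: earlier-configured graph wins on a shared label
  hit2 <- match_to_ontology("salt_stress", list(g_go, g_to))
  expect_identical(hit2$id, "TO:1")  # label match beats synonym match
  g_go2 <- parse_obo(c("[Term]", "id: GO:2", "name: salt stress", ""))
  hit3 <- match_to_ontology("salt stress", list(g_go2, g_to))
  expect_identical(hit3$id, "GO:2")
  expect_null(match_to_ontology("unmatched token", list(g_to, g_go)))
  # synonyms are matched when no label matches anywhere
  hit4 <- match_to_ontology("SALINITY STRESS",
                            parse_obo(toy_obo_lines()))
  expect_identical(hit4$id, "T:0003")
})

test_that("evaluation reports rows, aggregates, and skipped queries", {
  # model in which each group word's neighbours are its synonyms, and an
  # ontology in which those synonyms are recorded on the same term
  toy <- generate_toy_ontology(depth = 3, branching = 2, seed = 5)
  g <- toy$graph
  labels <- unname(g$labels)
  set.seed(23)
  vecs <- matrix(stats::rnorm(8 * length(labels)), 8)
  colnames(vecs) <- gsub(" ", "_", labels)
  model <- structure(list(vectors = vecs, dim = 8L,
                          phrases = labels, loss = numeric(0),
                          architecture = "random"),
                     class = "embedding_model")

  rep1 <- evaluate_suggestions(labels, model, g, toy$freq, top_n = 3)
  # aggregates recomputable from rows
  expect_equal(rep1$mean_lin, mean(rep1$rows$sim_lin))
  expect_equal(rep1$frac_above_0.8, mean(rep1$rows$sim_lin > 0.8))
  expect_equal(rep1$min_lin, min(rep1$rows$sim_lin))

  # all-synonym case: every suggestion resolves to the query's own term
  g_syn <- parse_obo(c("[Term]", "id: X:1", "name: alpha beta",
                       'synonym: "gamma delta" EXACT []', "",
                       "[Term]", "id: X:0", "name: rootish", ""))
  g_syn$parents[["X:1"]] <- "X:0"
  vec2 <- matrix(c(1, 0, 0.99, 0.141), 2)
  colnames(vec2) <- c("alpha_beta", "gamma_delta")
  msyn <- structure(list(vectors = vec2, dim = 2L, phrases = character(0),
                         loss = numeric(0), architecture = "random"),
                    class = "embedding_model")
  fr <- term_freq_table(c("X:1" = 5, "X:0" = 100), total = 100)
  rep2 <- evaluate_suggestions("alpha beta", msyn, g_syn, fr, top_n = 5)
  expect_identical(nrow(rep2$rows), 1L)
  expect_equal(rep2$mean_lin, 1.0)
  expect_equal(rep2$frac_above_0.8, 1.0)

  # no ontology matches: empty report, all queries skipped
  rep3 <- evaluate_suggestions(c("zzz", "qqq"), msyn, g_syn, fr)
  expect_identical(nrow(rep3$rows), 0L)
  expect_identical(rep3$skipped, c("zzz", "qqq"))

  # report writers produce parseable files
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_report(rep1, tsv = tsv, json = js)
  expect_identical(nrow(utils::read.delim(tsv)), nrow(rep1$rows))
  expect_equal(jsonlite::fromJSON(js)$mean_lin, rep1$mean_lin)
})

test_that("count propagation makes ancestors at least as frequent as descendants", {
  toy <- generate_toy_ontology(depth = 3, branching = 2, seed = 9)
  flat <- toy$freq
  cum <- propagate_counts(flat, toy$graph)
  for (id in toy$graph$ids) {
    for (p in toy$graph$parents[[id]]) {
      expect_gte(cum$counts[[p]], cum$counts[[id]])
    }
  }
  root <- toy$graph$ids[lengths(toy$graph$parents[toy$graph$ids]) == 0]
  expect_equal(unname(cum$counts[[root]]), sum(flat$counts))
  expect_equal(cum$total, unname(cum$counts[[root]]))  # P(root) = 1
})
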