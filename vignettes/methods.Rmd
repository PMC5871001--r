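---
title: "Methods: corpus-trained query suggestion and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corpus-trained query suggestion and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semsuggest)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices behind them, and what
the bundled synthetic-data generators can and cannot demonstrate.

## The suggestion model

The premise is distributional: words that occur in similar contexts tend
to carry similar meaning. `semsuggest` turns a search corpus into a
suggestion service in four stages.

**1. Tokenization.** Text is split into lowercased alphanumeric runs;
punctuation-only tokens are dropped. Database accessions
(letters immediately followed by digits, optionally interleaved, with
optional `-`/`.`/`:`-joined suffixes — `at1g01010`, `q9s7u2-2`) are
matched first and emitted unsplit, because their fragments are
meaningless search terms. Lowercasing everything is a deliberate choice:
query matching must be case-insensitive, and keeping case variants as
separate vocabulary entries would fragment their training signal. The
identifier pattern is configurable (`id_pattern`) since accession
grammars differ across databases.

**2. Phrase mining.** Multi-word terms ("salt stress", "heading date")
mean more than their parts, so frequent adjacent pairs are promoted to
single phrase tokens. The collocation score

$$\mathrm{score}(\omega_i,\omega_j)=
  \frac{\mathrm{count}(\omega_i\omega_j)-\delta}
       {\mathrm{count}(\omega_i)\,\mathrm{count}(\omega_j)}$$

uses a discount $\delta$ (default 5) that suppresses pairs of rare words:
a pair must co-occur more than $\delta$ times before it can score above
zero. The score threshold (default $9\times10^{-8}$) is the second
tunable; in practice one calibrates the $(\delta,\ \mathrm{threshold})$
pair by maximizing overlap between the mined phrase inventory and term
labels of domain ontologies (`ontology_overlap()`), on the reasoning that
a phrase inventory resembling curated terminology is the most useful one.
Bigrams are counted between strictly adjacent tokens within one document;
no pairs cross document boundaries. Merging is a greedy left-to-right
single pass with non-overlapping replacements and leftmost-start
tie-breaking; one pass (bigrams only) is the default, with
`passes > 1` available to grow trigrams out of already-joined tokens.

**3. Word-vector training.** Two log-linear architectures are provided:
CBOW, which predicts the center word from the mean of the context-word
vectors inside a symmetric window, and skip-gram, which uses the center
word's vector to predict each window word separately. Both use a
hierarchical-softmax output layer: the vocabulary is a Huffman binary
tree over word frequencies, the probability of a word is a product of
logistic decisions $\sigma(s_k\langle v_{n_k},h\rangle)$ along its
root-to-leaf path ($s_k=+1$ where the code bit is 0, $-1$ otherwise),
and evaluating or training one word costs $O(\log_2|V|)$ — the tree makes
the distribution sum to one by construction, which the tests verify by
direct summation.

**4. Suggestion.** Trained input vectors are ranked by cosine similarity
to the query vector — cosine is the standard similarity for this vector
family, and rankings are invariant under uniform rescaling of the
vectors. A multi-word query first tries its phrase token
(`heading_date`), falling back to the mean of its in-vocabulary token
vectors; the query's own tokens and joined form are excluded from the
candidates by exact string match only, since near-duplicates
("salinity stress" for "salt stress") are legitimate suggestions.
Zero-norm vectors are excluded from candidacy because cosine is
undefined for them. The search is an exact full scan; at the vocabulary
sizes this package targets there is no need for approximate indexing.

## Training parameters

| parameter | default | rationale |
|---|---|---|
| `dim` | 200 | vector dimensionality; the production-scale setting for corpus-trained suggestion models (tests use 8–50 to stay fast) |
| `window` | 5 | context half-width, the conventional default for this algorithm family; fixed, not randomly shrunk per position (see below) |
| `epochs` | 5 | passes over the corpus |
| `initial_lr` | 0.025 | conventional starting learning rate for hierarchical-softmax SGD |
| `min_lr` | 1e-4 | floor of the linear decay, reached at the last training token |
| `min_count` | 5 | vocabulary frequency floor; rarer words have too little signal to train |
| `subsample` | 0 (off) | optional frequent-word dropping, `p = 1-\sqrt{t/f}`; off because the corpus sizes targeted here rarely need it |

The learning rate decays linearly from `initial_lr` to `min_lr` over all
`epochs × n_tokens` center-word presentations. Dynamic window shrinking
(sampling an effective window in `[1, window]` per position, as some
implementations of this family do) is deliberately **not** used: a fixed
window keeps the training-pair enumeration transparent and exactly
testable (`training_pairs()`), at the cost of weighting distant context
words equally.

## Numerical and determinism choices

* **Initialization.** Word vectors start uniform in
  $[-0.5/\mathrm{dim},\ +0.5/\mathrm{dim}]$; inner-node vectors start at
  zero. Zero inner vectors make every path decision $\sigma(0)=0.5$ at
  step 0, so $P(w\mid c)=0.5^{|\mathrm{code}(w)|}$ exactly — a useful
  analytic anchor that the tests assert.
* **Huffman tie-breaking.** When merge candidates have equal weight the
  earliest-inserted node wins, and bit 0 goes to the lighter (then
  earlier) child. Any tie rule yields an optimal code; fixing one makes
  construction deterministic, which the bitwise-reproducibility contract
  of training requires.
* **CBOW context gradient.** The context vector is the *mean* of the
  window vectors, and the gradient passed back to each context word is
  the context gradient divided by the window size — the mathematically
  exact derivative of the mean (some reference implementations skip the
  division; with a shared learning rate this is only a rescaling, but the
  exact form is what the finite-difference tests check).
* **Two engines, one arithmetic.** The compiled loop accumulates dot
  products in extended precision, matching R's `sum()`, so the R
  reference engine and the C++ engine produce bit-identical models on
  the same inputs — the equivalence is asserted in the tests rather than
  assumed. Training is single-threaded; there is no lock-free concurrent
  mode, whose update races would break reproducibility.
* **Training loss.** The reported per-epoch loss is the mean negative
  log probability *online* (evaluated at the parameters current when
  each pair is visited). It drops steeply and then sits on a plateau
  where SGD with a still-finite learning rate oscillates by a fraction
  of a percent; the tests therefore assert a strict early decrease and
  monotone non-increase up to a 1% oscillation band, not strict
  monotonicity at the plateau.
* **Model format.** The `QSM1` file stores a binary associative list:
  magic bytes, version, $|V|$, dim, then per word a length-prefixed
  UTF-8 term and its float32 vector, plus the phrase inventory so
  queries get the same phrase merging the corpus did. Vectors are
  persisted at single precision — ample for cosine ranking at half the
  size; save→load is bit-exact for single-precision values and one
  save/load pass quantizes a double-precision model. Truncation and
  header corruption are reported with the byte offset. Inner-node
  vectors are training-time state and are not persisted.
* **Vocabulary indexing.** Descending frequency with lexicographic tie
  order, indices 1..$|V|$ gap-free (1-based, as is natural in R).

## Ontology-based evaluation

Suggestion quality is judged by how semantically close a suggestion is
to its query, measured in curated domain knowledge. Both strings are
matched (case-insensitively, exactly, labels before synonyms, first
ontology in the configured order winning) to terms of OBO ontologies;
then

$$\mathrm{Sim}_{\mathrm{Resnik}}(T_1,T_2)=\max_{T_s}\,(-\ln P(T_s)),
\qquad
\mathrm{Sim}_{\mathrm{Lin}}(T_1,T_2)=
 \frac{2\,\mathrm{Sim}_{\mathrm{Resnik}}(T_1,T_2)}
      {-\ln(P(T_1)P(T_2))}$$

where $T_s$ ranges over common subsumers via `is_a` edges and $P(T)$ is
the term's relative corpus frequency. A rare shared parent means the
two terms share a *specific* concept; a ubiquitous shared root
certifies almost nothing, and scores 0.

Three design choices deserve explanation:

* **A term subsumes itself.** The subsumer set includes $T_1$ and $T_2$
  themselves. This is what makes the direct-synonym case exact: a
  suggestion recorded as a synonym resolves to the same term node, the
  best subsumer is the term itself, and
  $\mathrm{Sim}_{\mathrm{Lin}} = 2\,\mathrm{IC}(t)/(2\,\mathrm{IC}(t)) = 1$
  whenever $P(t)<1$.
* **Flat counts by default.** $P(T)$ is read from a user-supplied table
  of flat string counts in the corpus, *not* propagated up the DAG.
  Flat counting is the natural reading of "relative frequency of the
  term in the text corpus", and it is what a corpus-side pipeline can
  compute without ontology-aware annotation. Its price: a subsumer can
  be rarer than its descendants, which can push the Lin ratio above 1.
  Values are clamped to $[0,1]$ and such rows flagged, preserving the
  0–1 scale contract. Classic cumulative counting (ancestors inherit
  descendant counts, root gets $P=1$) is available via
  `propagate_counts()`.
* **Only `is_a` is traversed.** Other relationship types (`part_of`,
  regulates) encode different semantics and are ignored; obsolete terms
  are dropped at parse time.

Degenerate cases are errors, not silent numbers: no common subsumer,
zero count on the maximizing subsumer, or both terms at $P=1$ (zero
information content) all raise with an explanatory message.

## The synthetic-data generators

The package is testable end-to-end without downloads because its study
conditions are generated:

* **Synonym corpus** (`generate_synonym_corpus()`): 10 groups of 3
  interchangeable words, 2,000 documents of 12 tokens, 20 dedicated
  context words per group, 50 shared background words with a 10% noise
  rate. Every document is about one group and contains exactly **one**
  group-word occurrence at a random position. This "one target per
  document" design is essential, not incidental: interchangeable words
  must share their context distribution while *never co-occurring with
  each other* — if group words were sprinkled independently through the
  documents, group words and context words would have identical context
  distributions and no embedding method could rank a synonym above a
  context word. With the planted design, skip-gram
  (dim 50, window 5, 5 epochs) recovers same-group top-1 neighbours at
  ≥ 0.9 precision averaged over seeds. A `context_overlap` parameter
  mixes a shared context pool into all groups to probe graceful
  degradation.
* **Phrase corpus** (`generate_phrase_corpus()`): 200 background words
  sampled independently over ~4,000 token slots keep every background
  bigram's expected count near 0.1, so the probability that any chance
  pair co-occurs more than the discount $\delta=5$ is negligible, while
  each of the 10 planted pairs is inserted adjacently 30 times — its
  score is at least $(30-5)/(\mathrm{count}_i\cdot\mathrm{count}_j)$,
  orders of magnitude above the $9\times10^{-8}$ threshold. Mining
  therefore returns exactly the planted set (precision and recall 1).
* **Toy ontologies** (`generate_toy_ontology()`): trees (optionally
  DAGs) whose root count equals the corpus total ($P(\mathrm{root})=1$)
  and whose counts decrease strictly with depth (child ≈ 0.3 × parent).
  Ancestor-monotone counts make the Lin clamp a no-op and give the
  clean ordering "deeper common ancestor ⇒ strictly larger similarity"
  that the property tests check by brute force.

**What passing these tests does and does not show.** The generators
emulate the *statistical skeleton* the methods assume: planted
distributional equivalence, collocations that clear the score threshold,
monotone information content. They do not emulate real abstracts — no
Zipfian vocabulary, no syntax, no polysemy, no cross-topic documents, no
ontology with realistic breadth or multiple inheritance patterns.
Passing the recovery tests shows the optimizer and scoring machinery are
correct, not that any particular real corpus will yield suggestions of a
given quality; that always depends on corpus size and domain coverage.

All generators are pure functions of their specification and seed.

## Problem sizes in the test suite

The suite favours exhaustively checkable sizes: Huffman optimality is
verified against a full search over merge orders for vocabularies up to
6 words (1,000 random draws); hierarchical-softmax normalization is
summed directly over vocabularies up to 100 words; gradient checks run
100 random instances against central differences; phrase-mining
equivalence uses 50 random corpora of 10,000 tokens; the planted-synonym
recovery experiment trains on the default 2,000-document corpus for five
seeds. The one full-scale default left untouched by tests is
`dim = 200`, which only scales the arithmetic already verified at
smaller dimensionality.

## Known limitations

* Exact full-scan suggestion is $O(|V|\cdot\mathrm{dim})$ per query —
  fine up to a few hundred thousand vocabulary entries, beyond which an
  approximate index (required to agree with the exact scan) would be
  the natural extension.
* Phrase mining is frequency-based and adjacent-only; discontinuous or
  reordered multi-word terms are not captured.
* The evaluation matches suggestions to ontology terms by exact string
  equality (after delimiter mapping); fuzzily matched or compositional
  suggestions are reported as unmatched rather than scored.
* Negative sampling, GPU training, and multi-threaded (non-reproducible)
  training are out of scope.
* The HTTP server is single-threaded and unauthenticated by design; put
  it behind a reverse proxy for anything beyond local use.
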