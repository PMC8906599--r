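---
title: "Mining statistical-methods sections: topics and boilerplate text"
author: "methodsminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining statistical-methods sections: topics and boilerplate text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methodsminer)
```

## The problem

Statistical-methods sections are short, formulaic pieces of text: a few
sentences naming the tests used, the software, the significance threshold and
how data are summarized. Because the same defaults are described over and
over, phrasing is frequently reused verbatim or near-verbatim across
unrelated studies — "boilerplate" text, with sentences such as *"A p-value <
0.05 was considered statistically significant"* recurring across thousands of
papers. Quantifying this reuse, and mapping the topics that methods sections
cluster into, gives a picture of how statistical practice is actually
communicated.

`methodsminer` implements that analysis as a reusable pipeline over corpora
of methods sections (one record per study):

1. **Normalization** — standardize notation and statistical terminology so
   that textual comparisons measure content, not typography.
2. **Topic modelling** — tf-idf weighting of a term-by-document matrix,
   factorized by non-negative matrix factorization (NMF).
3. **Boilerplate detection** — an asymmetric Jaccard *containment* score
   over word-token sets, at section and sentence level, with MinHash
   locality-sensitive hashing (LSH) to avoid the quadratic all-pairs scan.
4. **Synthetic corpora** — a generator that plants boilerplate at known
   containment levels with full ground truth, so every stage is testable
   without any external download.

## Normalization pipeline

`normalize_document()` applies, in order: sentence splitting, symbol
verbalization, formatting and reference removal, lower-casing, whitespace
tokenization, stop-word removal, and statistical-term standardization.

The order is deliberate. Sentence splitting runs **first**, on raw text,
because it needs the punctuation that later stages destroy; sentence-level
boilerplate scoring depends on it. Splits occur at `.`, `!` or `?` followed
by whitespace and an uppercase letter or digit, with a guard list
("e.g.", "i.e.", "vs.", "et al.", ...) suppressing false boundaries;
decimal numbers can never split because no whitespace follows the period.

Key choices, all configurable:

* **Symbol map** (`default_symbol_map()`): `%` → `percent`, `<` →
  `less-than`, `>` → `greater-than`, `±` → `plus-or-minus`, `=` →
  `equal-to`, `≤`/`≥` → spelled-out forms, plus Greek letters used in
  statistical notation (`α`, `β`, `χ`) and `×`. Values are ASCII tokens and
  never contain a mapped key, so the map is idempotent.
* **Decimal points and version numbers.** Punctuation is removed except
  intra-word hyphens and periods flanked by digits, so `chi-square`,
  `0.05` and `version 5.0` survive intact. This matters: the most common
  boilerplate sentences quote the `0.05` threshold, and destroying it would
  change every containment score against them.
* **Stop words** (`default_stoplist()`): a standard snowball-style English
  list (plus de-apostrophized contraction forms, since apostrophes are
  stripped before stop-word removal), **minus** a retain set
  (`between`, `against`, `before`, `after`, `within`, `above`, `below`,
  `over`, `under`, `per`, `not`, `no`). Dropping those prepositions and
  negations would change the meaning of methods descriptions
  ("compared *between* groups", "*not* normally distributed").
* **Term dictionary** (`default_term_dictionary()`): ~120 variant-to-
  canonical mappings that rewrite plural, unhyphenated and concatenated
  spellings of statistical terms to a singular hyphenated form
  (`chi squares`, `chisquare`, `chi-squared` → `chi-square`;
  `analysis of variance` → `anova`). Matching is longest-first over 1–3-gram
  windows and the constructor closes the map so canonical forms map to
  themselves, making the operation idempotent.

The stop list and dictionary are declared approximations: there is no
published reference list for this domain, so the shipped defaults are locked
by golden tests rather than claimed to be canonical, and both load from
plain-text data files that users can replace.

## Topic model

For $N$ documents over $M$ vocabulary terms, the content matrix
$P \in \mathbb{R}^{M \times N}$ holds tf-idf weights

$$P_{td} = \mathrm{tf}(t,d) \cdot \left( \ln\frac{1+N}{1+\mathrm{df}(t)} + 1 \right),$$

with raw counts for tf and the smoothed idf that never divides by zero;
each document column is then scaled to unit Euclidean norm. Terms with
document frequency below `min_df = 2` or above `max_df_fraction = 0.95`
of documents are dropped. The tf-idf variant matters to every downstream
number, which is why it is pinned down exactly here.

NMF approximates $P \approx W H^{\mathsf T}$ with non-negative
$W \in \mathbb{R}^{M\times g}$ (term loadings) and
$H \in \mathbb{R}^{N\times g}$ (document loadings) by minimizing the
Frobenius objective $\tfrac12\lVert P - WH^{\mathsf T}\rVert_F^2$.
`fit_nmf()` uses Lee–Seung multiplicative updates because they guarantee a
monotonically non-increasing objective — a property the package's tests
assert on every fixture (tolerance $10^{-12}$ per step) — and preserve
non-negativity by construction. Initialization is element-wise
$|N(0,1)|\cdot\sqrt{\bar P / g}$ from a fixed seed, so identical inputs and
seed give bit-identical factors. Iteration stops when the relative objective
decrease falls below `tol = 1e-4` (default `max_iter = 200`).

A document's topic is the argmax of its row of $H$ (the maximum coefficient
is its *coherence* score). Ties break to the lowest topic index and an
all-zero row is reported as topic 0 ("unassigned"), so assignment is total
and deterministic. Multiplying $P$ by any positive constant rescales the
factors but leaves the argmax — and hence all assignments — unchanged.
`g = 10` is the default topic count, matching common practice for
methods-section corpora; there is no automatic selection of `g`.

Multiplicative updates converge to stationary points, not certified global
optima. On exactly low-rank inputs they typically recover the factorization
to numerical precision (the validation suite checks rank-1 and rank-3
recovery to relative error below $10^{-6}$), but for general `g` the attained
objective can depend on the seed; the monotonicity, non-negativity and
determinism guarantees do not.

## Containment score and match semantics

For token sets $A$ and $B$,

$$J(A, B) = \frac{|A \cap B|}{|B|}$$

is the fraction of the *target* $B$'s distinct tokens found in $A$. Unlike
the symmetric Jaccard index, this containment score equals 1 whenever $B$ is
embedded in $A$, so a short boilerplate sentence hidden inside a longer one
still scores 1. A score of **0.9 or higher** defines boilerplate; at the
default threshold a 10-token target tolerates exactly one substituted word.

In an unsupervised all-pairs scan neither member of a pair is privileged,
so `pairwise_scan()` and `brute_force_scan()` compute both directions and
report the maximum with the achieving direction — conservative, in that an
embedding in either direction is found. Emitted records are exactly the
pairs at or above the threshold; *exact* matches are pairs with identical
token sets (containment 1 both ways). Raw-string identity is stricter than
token-set identity (word order and duplicates are erased by tokenization)
and can be checked separately against the raw corpus. Sentences shorter
than 3 tokens are excluded from scans: almost any pair of such fragments
matches, and they carry no methodological content.

## MinHash and LSH

Scanning all sentence pairs is quadratic; LSH prunes it. Each token set gets
a `k = 256`-component MinHash signature: component $i$ applies a seeded
full-avalanche 64-bit mix to each token's base hash and keeps the minimum.
Because each component behaves as an independent random function, the
probability that two signatures agree in a component equals the symmetric
Jaccard similarity of the two sets — the estimator is unbiased, which the
test suite verifies by simulation (an earlier affine multiply-shift variant
showed a measurable downward bias of ~0.005 and was replaced). All hashing
is fixed-constant integer arithmetic, reproducible across platforms for a
given seed.

Signatures are cut into `b = 64` bands of `r = 4` rows; sets sharing any
band bucket become candidates, which are then verified with the exact
containment score. The banding curve gives collision probability
$1-(1-s^r)^b$ at symmetric similarity $s$. The parameters were chosen for
the detection boundary rather than for minimal candidate counts: two
equal-size sentences at the containment threshold 0.9 have symmetric
Jaccard $9/11 \approx 0.82$, where `b = 64, r = 4` misses with probability
$\approx 3\times10^{-17}$, while a steeper curve (e.g. `b = 32, r = 8`)
would miss such a pair about 7 times in 10,000 — enough to break exact
agreement with the brute-force scan on realistic corpora. The cost is more
false candidates at low similarity, but candidates are cheap to verify
exactly. At section level, where set sizes differ widely and symmetric
Jaccard under-represents containment, an additional channel admits any two
sets sharing a token of corpus document frequency ≤ 5.

LSH can only prune candidates, never invent them, so LSH-path records are
always a subset of brute-force records; the package's acceptance suite
requires the two record sets to be *identical* on the planted validation
corpus at both levels.

## Targeted searches

`targeted_search()` mirrors published boilerplate tables: a gating n-gram
(by default the whole target) selects the "potential matches" — documents
containing it as a contiguous token subsequence — and every sentence of
those documents is scored against the target's token set, summarizing each
document's best score (median, quartiles, count at the threshold). The gate
and the scored target are separate arguments because published tables gate
on a short bold phrase (e.g. a software name) while scoring a full
sentence; passing `ngram = NULL` disables gating and scores every document,
which is the mode used for validation against planted ground truth (a
mutated copy need not contain any particular contiguous sub-phrase).

## The synthetic generator

`generate_corpus()` emulates the statistical structure the pipeline
consumes, not natural language:

* Each of `g = 5` topics (default) has a 300-token vocabulary, disjoint
  across topics unless `vocab_overlap_fraction > 0`; documents draw
  5–15 sentences of 8–18 tokens i.i.d. from their topic's vocabulary.
  These defaults give a median section length of roughly 130–150 words —
  the scale of real published methods sections, which are typically a
  one-to-two-hundred-word paragraph.
* Templates are planted as whole extra sentences with a configured
  probability. Templates ship in *post-normalization* token form (stop
  words already removed, symbols already verbalized, e.g.
  `p-value less-than 0.05 considered statistically significant`), so the
  planted ground truth refers to exactly the representation the scanner
  scores and survives the (idempotent) pipeline unchanged.
* Mutation substitutes `k` positions with novel tokens absent from the
  template and from every topic vocabulary, so the containment of a planted
  copy against its template is **exactly** $(n-k)/n$ for a template of $n$
  distinct tokens — substitution only, because insertions or deletions
  would destroy the closed form in the target direction. A 10-token
  template with `k = 1` sits exactly at the 0.9 threshold.
* A `placeholder_rate` fraction of documents is emitted as
  `"Not applicable"`, exercising the missing-section screen that registry
  corpora need.

Token sampling is i.i.d. within topic (no grammar, no burstiness, no
correlated topic mixtures) because tf-idf/NMF and set-based containment are
insensitive to word order — this is the minimal structure that exercises
them. Consequently, passing tests demonstrate the *algorithms* are correct
(exact scores, oracle-equivalent LSH, recoverable planted structure); they
do not demonstrate that real methods sections separate as cleanly, that real
boilerplate is as lexically distinct from its background, or that the
shipped stop list and dictionary match any particular journal's style.
Generated metadata covers only the fields the pipeline reads.

## Numerical and degenerate-input conventions

* Quartiles everywhere are type-7 (linear interpolation), the R default,
  so summary statistics are exactly reproducible.
* NMF denominators carry an additive $10^{-10}$ guard; traces are recorded
  after each full update sweep.
* `containment()` with an empty target is an error (the score is
  undefined), an empty query scores 0; empty token sets are rejected by
  `minhash()`.
* Ties: argmax topic assignment takes the lowest index; term rankings break
  ties lexicographically; scan records sort by query then target id, so
  every output is deterministic for a fixed seed.
* An empty vocabulary after document-frequency filtering, `g > min(M, N)`,
  non-finite or negative matrix entries, duplicate document ids and
  malformed records are all explicit errors naming the offending entity.

## Validation problem sizes

The packaged validation suite runs at sizes chosen to exercise every code
path while keeping the full suite fast: a 300-document corpus (5 disjoint
topics, all five containment levels 1.0/0.95/0.9/0.8/0.5 planted) for the
LSH-vs-brute-force equivalence and recall/precision checks; a 500-document
corpus for topic recovery (adjusted Rand index ≥ 0.9 against ground truth,
computed with the independent `mclust` implementation); 1,000 random pairs
against a set-arithmetic containment oracle; 100 seeded replicates of
256-component signatures for MinHash calibration (within 3 standard
errors); and two complete pipeline runs compared byte-for-byte.

## Limitations

* Containment is purely lexical; paraphrase and translation are invisible
  ("semantic" similarity is out of scope, as is any attribution of
  copying — this is not plagiarism detection).
* LSH recall guarantees are probabilistic and tuned for comparable set
  sizes; section-level scans of very unequal documents rely on the
  rare-token channel.
* The stop list and term dictionary are best-effort approximations of
  unpublished domain lists; scores depend on them, which is why they are
  shipped as replaceable data and locked by tests.
* NMF topic counts are user-chosen; no model-selection criterion is
  provided.
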