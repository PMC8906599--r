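test_that("symbols verbalize to plain-text tokens", {
  expect_equal(convert_symbols("p < 0.05"), "p less-than 0.05")
  expect_equal(convert_symbols("mean ± SEM"), "mean plus-or-minus SEM")
  expect_equal(convert_symbols("95%"), "95 percent")
  expect_equal(convert_symbols("p <= 0.01"), "p less-than-or-equal-to 0.01")
  expect_equal(convert_symbols("alpha = 0.05"), "alpha equal-to 0.05")
  # applying the map twice equals applying once
  x <- "p < 0.05 and 95% CI, ± 2"
  expect_equal(convert_symbols(convert_symbols(x)), convert_symbols(x))
})

test_that("formatting, references and punctuation are stripped conservatively", {
  expect_equal(strip_formatting("ANOVA [12] was used"), "ANOVA was used")
  expect_equal(strip_formatting("models [1, 2] and [3-5] fit"), "models and fit")
  expect_equal(strip_formatting("(version 5.0 for windows)"),
               "version 5.0 for windows")
  expect_equal(strip_formatting("chi-square"), "chi-square")
  expect_equal(strip_formatting("a p-value of 0.05"), "a p-value of 0.05")
  expect_equal(strip_formatting("line one\r\nline two"), "line one line two")
  expect_equal(strip_formatting("effect $\\beta$ was large"),
               "effect was large")
  # non-ASCII characters vanish, bracketed text is retained without brackets
  expect_equal(strip_formatting("déjà vu (approximately)"),
               "d j vu approximately")
})

test_that("sentences split on terminal punctuation with guards", {
  expect_equal(
    split_sentences("Data are mean ± SEM. P < 0.05 was significant."),
    c("Data are mean ± SEM.", "P < 0.05 was significant."))
  expect_length(split_sentences("a p-value of 0.05 was used"), 1)
  expect_length(split_sentences(""), 0)
  expect_length(split_sentences("We used e.g. ANOVA vs. Regression here."), 1)
  expect_length(split_sentences("Smith et al. Reported results."), 1)
  expect_length(split_sentences("First point. Second point. Third."), 3)
})

test_that("stop-word removal respects the retain list", {
  st <- stoplist(c("the", "was", "between"), retained = "between")
  expect_equal(remove_stopwords(c("the", "difference", "between", "groups"), st),
               c("difference", "between", "groups"))
  expect_equal(remove_stopwords(character(0), st), character(0))
  expect_equal(remove_stopwords(c("anova", "regression"), st),
               c("anova", "regression"))
  # shipped defaults keep the spec'd retained prepositions
  def <- default_stoplist()
  expect_length(intersect(def$stop_words, def$retained), 0)
  expect_true(all(c("between", "against", "per", "not") %in% def$retained))
  expect_false("between" %in% def$stop_words)
})

test_that("statistical terms standardize to singular hyphenated form", {
  d <- default_term_dictionary()
  expect_equal(standardize_terms(c("chi", "square"), d), "chi-square")
  expect_equal(standardize_terms("chisquares", d), "chi-square")
  expect_equal(standardize_terms(c("chi-squares"), d), "chi-square")
  expect_equal(standardize_terms(c("hosmer", "lemeshow"), d), "hosmer-lemeshow")
  expect_equal(standardize_terms(c("wilcoxon", "rank", "sum", "test"), d),
               c("wilcoxon-rank-sum", "test"))
  expect_equal(standardize_terms(c("intention", "to", "treat"), d),
               "intention-to-treat")
  expect_equal(standardize_terms(c("one", "way", "analysis", "of", "variance"), d),
               c("one-way", "anova"))
  # longest match wins
  expect_equal(standardize_terms(c("linear", "mixed", "models"), d),
               "linear-mixed-model")
  # stable under re-application, and canonical forms pass through
  out <- standardize_terms(c("chi", "squares", "p", "values", "anova"), d)
  expect_equal(standardize_terms(out, d), out)
})

test_that("the flagship significance sentence normalizes to the locked tokens", {
  doc <- normalize_document(
    "d1", "A p-value < 0.05 was considered statistically significant.")
  expect_equal(doc$tokens,
               c("p-value", "less-than", "0.05", "considered",
                 "statistically", "significant"))
  doc2 <- normalize_document("d2", "Data are presented as mean ± SEM.")
  expect_equal(doc2$tokens,
               c("data", "presented", "mean", "plus-or-minus", "sem"))
  doc3 <- normalize_document(
    "d3", "Statistical analysis was performed using GraphPad Prism (version 5.0 for Windows).")
  expect_equal(doc3$tokens,
               c("statistical", "analysis", "performed", "using", "graphpad",
                 "prism", "version", "5.0", "windows"))
})

test_that("normalization is idempotent, ASCII-only and order-preserving", {
  texts <- c(
    "A p-value < 0.05 was considered statistically significant.",
    "Continuous variables were expressed as mean ± standard deviation [3].",
    "One-way ANOVA with Tukey post hoc tests. Chi squares where appropriate!",
    "At a confidence level of 95% and a precision of 5%, 73 patients are needed.",
    "Déjà vu: α = 0.05, χ² tests (SPSS version 17.0)."
  )
  for (tx in texts) {
    doc <- normalize_document("x", tx)
    # idempotence at the token level
    again <- normalize_document("x", paste(doc$tokens, collapse = " "))
    expect_equal(again$tokens, doc$tokens)
    # tokens are lowercase ASCII and non-empty
    expect_true(all(nzchar(doc$tokens)))
    expect_false(any(grepl("[^ -~]", doc$tokens)))
    expect_equal(doc$tokens, tolower(doc$tokens))
    # no dictionary variant survives as a contiguous n-gram
    d <- default_term_dictionary()
    flat <- paste(doc$tokens, collapse = " ")
    variant_keys <- setdiff(d$keys, d$values)
    hits <- vapply(variant_keys, function(k) {
      grepl(paste0("(^| )", k, "( |$)"), flat, fixed = FALSE)
    }, logical(1))
    expect_false(any(hits))
  }
  # order preservation: surviving tokens appear in original order
  tx <- "The difference between groups was tested against the null."
  raw <- tolower(strsplit(strip_formatting(tx), " ")[[1]])
  doc <- normalize_document("x", tx)
  kept <- doc$tokens[doc$tokens %in% raw]
  expect_equal(kept, raw[raw %in% doc$tokens])
  # a document of only stop words yields no sentences
  expect_length(normalize_document("x", "It was. They were!")$sentences, 0)
})

test_that("normalized corpora round-trip through JSONL", {
  sim <- generate_corpus(generator_config(g = 2, docs_per_topic = 5, seed = 2))
  norm <- normalize_corpus(sim$corpus)
  path <- tempfile(fileext = ".jsonl")
  write_normalized(norm, path, header = "# test header")
  back <- read_normalized(path)
  expect_equal(back$id, norm$id)
  expect_equal(back$sentences, norm$sentences)
  expect_equal(back$tokens, norm$tokens)
})
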