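# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files these helpers write into tempdir().

# A tiny three-document corpus with known word counts.
tiny_corpus <- function() {
  corpus(
    id = c("d1", "d2", "d3"),
    text = c(
      "A p-value < 0.05 was considered statistically significant. Data are mean ± SEM.",
      "Statistical analysis was performed using GraphPad Prism software.",
      "Nil"
    ),
    source = "plos",
    heading = c("Statistical analysis", "Data analysis", "Statistics")
  )
}

write_tiny_jsonl <- function(path = tempfile(fileext = ".jsonl")) {
  writeLines(c(
    '{"id":"d1","source":"plos","heading":"Statistical analysis","text":"ANOVA was used."}',
    '{"id":"d2","source":"anzctr","text":"Descriptive statistics will be used.","sample_size":40}',
    '{"id":"d3","text":"Nil","n_funders":0}'
  ), path)
  path
}

write_tiny_xml <- function(path = tempfile(fileext = ".xml")) {
  writeLines(c(
    "<studies>",
    "  <study>",
    "    <id>ACTRN1</id>",
    "    <statistical_methods>ANOVA</statistical_methods>",
    "    <study_type>interventional</study_type>",
    "    <target_sample_size>120</target_sample_size>",
    "  </study>",
    "  <study>",
    "    <id>ACTRN2</id>",
    "    <study_type>observational</study_type>",
    "  </study>",
    "</studies>"
  ), path)
  path
}

# Templates with distinct synthetic tokens at the containment levels used
# throughout the validation corpora: (n - k) / n in {1, 0.95, 0.9, 0.8, 0.5}.
planted_templates <- function(prob = 0.25) {
  list(
    template("t100", sprintf("tpla%02d", 1:10), prob = prob, k = 0L),
    template("t095", sprintf("tplb%02d", 1:20), prob = prob, k = 1L),
    template("t090", sprintf("tplc%02d", 1:10), prob = prob, k = 1L),
    template("t080", sprintf("tpld%02d", 1:10), prob = prob, k = 2L),
    template("t050", sprintf("tple%02d", 1:10), prob = prob, k = 5L)
  )
}

# The 300-document validation corpus: 5 disjoint-vocabulary topics with all
# five containment levels planted.
planted_corpus_config <- function(seed = 20260923) {
  generator_config(
    g = 5L, vocab_size = 300L, vocab_overlap_fraction = 0,
    docs_per_topic = 60L,
    sentences_per_doc = c(5L, 15L), tokens_per_sentence = c(8L, 18L),
    templates = planted_templates(), placeholder_rate = 0, seed = seed
  )
}

# Independent set-arithmetic containment oracle used to check the package's
# intersection-kernel path.
containment_oracle <- function(A, B) {
  a <- unique(A)
  b <- unique(B)
  length(intersect(a, b)) / length(b)
}

expect_same_records <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}

# Corpus comparison on fields only (the provenance label records where a
# corpus came from and legitimately differs across a round-trip).
corpus_df <- function(x) {
  out <- as.data.frame(x)
  attr(out, "provenance") <- NULL
  out
}
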