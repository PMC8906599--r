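test_that("containment scores basic set arithmetic", {
  expect_equal(containment(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(containment(c("a", "b"), c("b", "c")), 0.5)
  # target embedded in a larger sentence scores 1
  B <- c("p-value", "less-than", "0.05")
  A <- c(B, "w1", "w2", "w3", "w4")
  expect_equal(containment(A, B), 1)
  expect_equal(containment(B, A), 3 / 7)
  # boundary of the boilerplate threshold
  expect_equal(containment(letters[1:9], letters[1:10]), 0.9)
  expect_error(containment(c("a"), character(0)), "empty")
  # duplicates do not count twice
  expect_equal(containment(c("a", "a", "b"), c("a", "b", "b")), 1)
})

test_that("containment agrees with a set-arithmetic oracle on random pairs", {
  set.seed(2024)
  pool <- sprintf("w%03d", 1:60)
  for (i in 1:200) {
    A <- sample(pool, sample(1:25, 1))
    B <- sample(pool, sample(1:25, 1))
    expect_identical(containment(A, B), containment_oracle(A, B))
  }
})

test_that("minhash signatures are deterministic and separate disjoint sets", {
  s1 <- minhash(letters[1:10], k = 64, seed = 5)
  s2 <- minhash(sample(letters[1:10]), k = 64, seed = 5)
  expect_identical(as.numeric(s1), as.numeric(s2))  # set semantics
  expect_false(identical(as.numeric(s1),
                         as.numeric(minhash(letters[1:10], k = 64, seed = 6))))
  other <- minhash(sprintf("z%02d", 1:10), k = 64, seed = 5)
  expect_lte(mean(as.numeric(s1) == as.numeric(other)), 2 / 64)
  expect_error(minhash(character(0)), "empty")
  expect_error(minhash(letters, k = 8), "k must")
})

test_that("minhash collision rate estimates symmetric Jaccard", {
  # |A| = |B| = 30, overlap 20, union 40: J = 0.5
  A <- sprintf("a%02d", 1:30)
  B <- c(A[1:20], sprintf("b%02d", 1:10))
  fracs <- vapply(1:30, function(seed) {
    mean(as.numeric(minhash(A, k = 256, seed = seed)) ==
           as.numeric(minhash(B, k = 256, seed = seed)))
  }, numeric(1))
  se <- sqrt(0.5 * 0.5 / (30 * 256))
  expect_lt(abs(mean(fracs) - 0.5), 3 * se)
})

test_that("scans find identical and near-identical units with exact semantics", {
  mk_norm <- function(ids, sent_lists) {
    out <- tibble::tibble(id = ids, sentences = sent_lists,
                          tokens = lapply(sent_lists, function(s) unlist(s)))
    class(out) <- c("mm_normalized", class(tibble::tibble()))
    out
  }
  sents <- list(
    list(c("p-value", "less-than", "0.05", "significant"), sprintf("x%d", 1:5)),
    list(c("p-value", "less-than", "0.05", "significant"), sprintf("y%d", 1:5)),
    list(sprintf("z%d", 1:6))
  )
  norm <- mk_norm(c("d1", "d2", "d3"), sents)

  sen <- brute_force_scan(token_sets(norm, "sentence"), "sentence", 0.9)
  expect_equal(nrow(sen), 1)
  expect_equal(sen$score, 1)
  expect_true(sen$is_exact)
  expect_equal(sen$query_id, "d1")
  expect_equal(sen$target_id, "d2")

  # two documents with identical sections at section level
  norm2 <- mk_norm(c("a", "b"), list(list(sprintf("s%d", 1:8)),
                                     list(sprintf("s%d", 1:8))))
  sec_bf <- brute_force_scan(token_sets(norm2, "section"), "section", 0.9)
  sec_lsh <- pairwise_scan(token_sets(norm2, "section"), "section", 0.9)
  expect_equal(nrow(sec_bf), 1)
  expect_true(sec_bf$is_exact)
  expect_same_records(sec_bf, sec_lsh)

  # 9-of-10 token overlap scores exactly 0.9: one boilerplate record
  norm3 <- mk_norm(c("q", "r"), list(list(sprintf("t%02d", 1:10)),
                                     list(c(sprintf("t%02d", 1:9), "novel"))))
  m <- brute_force_scan(token_sets(norm3, "sentence"), "sentence", 0.9)
  expect_equal(nrow(m), 1)
  expect_equal(m$score, 0.9)
  expect_false(m$is_exact)

  # disjoint vocabularies produce nothing
  norm4 <- mk_norm(c("u", "v"), list(list(sprintf("u%d", 1:6)),
                                     list(sprintf("v%d", 1:6))))
  expect_equal(nrow(brute_force_scan(token_sets(norm4, "sentence"),
                                     "sentence", 0.9)), 0)
  expect_equal(nrow(pairwise_scan(token_sets(norm4, "sentence"),
                                  "sentence", 0.9)), 0)
})

test_that("LSH candidates never invent matches and scans are deterministic", {
  for (seed in c(1, 2)) {
    sim <- generate_corpus(generator_config(
      g = 3, docs_per_topic = 15, vocab_size = 150,
      templates = planted_templates(prob = 0.3), seed = seed))
    norm <- normalize_corpus(sim$corpus)
    sets <- token_sets(norm, "sentence")
    bf <- brute_force_scan(sets, "sentence", threshold = 0.9)
    ps <- pairwise_scan(sets, "sentence", threshold = 0.9, seed = seed)
    # subset property via row keys
    key <- function(m) paste(m$query_id, m$query_index, m$target_id,
                             m$target_index)
    expect_true(all(key(ps) %in% key(bf)))
    # determinism: identical call, identical records in identical order
    ps2 <- pairwise_scan(sets, "sentence", threshold = 0.9, seed = seed)
    expect_same_records(ps, ps2)
  }
  expect_error(pairwise_scan(tibble::tibble(), k = 256, b = 10, r = 10),
               "b \\* r")
})

test_that("targeted search gates on the n-gram and summarizes best scores", {
  sent <- c("p-value", "less-than", "0.05", "significant")
  mk <- function(id, sents) {
    tibble::tibble(id = id, sentences = list(sents),
                   tokens = list(unlist(sents)))
  }
  norm <- dplyr::bind_rows(
    mk("d1", list(sent, sprintf("x%d", 1:4))),
    mk("d2", list(c(sent, "extra", "tokens"))),
    mk("d3", list(sent)),
    mk("d4", list(sprintf("y%d", 1:4)))
  )
  class(norm) <- c("mm_normalized", class(tibble::tibble()))
  res <- targeted_search(norm, sent, threshold = 0.9)
  expect_equal(res$potential_matches, 3)
  expect_equal(res$boilerplate_count, 3)
  expect_equal(res$median, 1)

  none <- targeted_search(norm, c("absent", "phrase"), threshold = 0.9)
  expect_equal(none$potential_matches, 0)
  expect_equal(none$boilerplate_count, 0)

  # gating n-gram shorter than the scored target: embedded sentences count
  res2 <- targeted_search(norm, target = sent, ngram = c("p-value", "less-than"))
  expect_equal(res2$potential_matches, 3)

  # ungated search scores every document
  res3 <- targeted_search(norm, target = sent, ngram = NULL)
  expect_equal(res3$potential_matches, 4)
})

test_that("mutated planted copies score exactly (n-k)/n in targeted search", {
  tpl <- list(template("t080", sprintf("tpld%02d", 1:10), prob = 1, k = 2L))
  sim <- generate_corpus(generator_config(
    g = 2, docs_per_topic = 20, templates = tpl, seed = 77))
  norm <- normalize_corpus(sim$corpus)
  res <- targeted_search(norm, sprintf("tpld%02d", 1:10), threshold = 0.9,
                         ngram = NULL)
  # every document carries one planted copy at containment 0.8 exactly
  best <- tapply(res$scores$score, res$scores$id, max)
  expect_true(all(best == 0.8))
  expect_equal(res$median, 0.8)
  expect_equal(res$boilerplate_count, 0)
})
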