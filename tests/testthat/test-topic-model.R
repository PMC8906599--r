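norm_from_tokens <- function(tokens_list) {
  out <- tibble::tibble(
    id = sprintf("d%d", seq_along(tokens_list)),
    sentences = lapply(tokens_list, list),
    tokens = tokens_list
  )
  class(out) <- c("mm_normalized", class(tibble::tibble()))
  out
}

test_that("tf-idf matches a hand computation on a toy corpus", {
  x <- norm_from_tokens(list(c("a", "a", "b"), c("a", "c"), c("b", "c", "c")))
  tf <- build_tfidf(x, min_df = 1, max_df_fraction = 1)
  # all three terms occur in 2 of 3 documents: idf = ln(4/3) + 1
  idf <- log(4 / 3) + 1
  raw <- matrix(c(2, 1, 0,
                  1, 0, 1,
                  0, 1, 2), nrow = 3,
                dimnames = list(NULL, c("a", "b", "c")))
  expected <- apply(raw, 1, function(cnt) {
    v <- cnt * idf
    v / sqrt(sum(v^2))
  })
  expect_equal(unname(as.matrix(tf$P)), unname(expected), tolerance = 1e-12)
  expect_equal(tf$vocabulary$term, c("a", "b", "c"))
  expect_equal(tf$vocabulary$doc_frequency, c(2L, 2L, 2L))
})

test_that("tf-idf edge behaviour: idf floor, unit columns, df filters", {
  # a term in every document hits the idf floor ln(1) + 1 = 1
  x <- norm_from_tokens(replicate(10, c("ubiq"), simplify = FALSE))
  tf <- build_tfidf(x, min_df = 1, max_df_fraction = 1)
  expect_equal(unname(as.matrix(tf$P)[1, ]), rep(1, 10))

  # single doc, single term: unit norm
  tf1 <- build_tfidf(norm_from_tokens(list(c("only", "only"))),
                     min_df = 1, max_df_fraction = 1)
  expect_equal(sum(as.matrix(tf1$P)^2), 1)

  # min_df drops singletons; over-ubiquitous terms drop via max_df_fraction
  x <- norm_from_tokens(list(c("common", "rare1"), c("common", "rare2"),
                             c("common", "kept"), c("kept", "x1")))
  tf2 <- build_tfidf(x, min_df = 2, max_df_fraction = 0.6)
  expect_equal(tf2$vocabulary$term, "kept")
  expect_error(build_tfidf(x, min_df = 10, max_df_fraction = 1), "empty")
})

test_that("NMF recovers exactly low-rank matrices and keeps a monotone objective", {
  set.seed(41)
  u <- abs(rnorm(30)) + 0.1
  v <- abs(rnorm(20)) + 0.1
  P1 <- outer(u, v)
  fit <- fit_nmf(P1, g = 1, seed = 3, max_iter = 2000, tol = 0)
  rel <- norm(P1 - fit$W %*% t(fit$H), "F") / norm(P1, "F")
  expect_lt(rel, 1e-6)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
  expect_true(min(fit$W) >= 0 && min(fit$H) >= 0)

  # larger g cannot fit worse than smaller g at convergence
  set.seed(42)
  P <- matrix(abs(rnorm(30 * 20)), 30, 20)
  f5 <- fit_nmf(P, g = 5, seed = 7, max_iter = 500, tol = 0)
  f3 <- fit_nmf(P, g = 3, seed = 7, max_iter = 500, tol = 0)
  expect_lte(min(f5$objective_trace), min(f3$objective_trace) + 1e-9)

  expect_error(fit_nmf(P, g = 25), "g must")
  expect_error(fit_nmf(matrix(c(1, NA, 2, 3), 2, 2), g = 1), "non-finite")
})

test_that("NMF is bit-deterministic for a fixed seed", {
  set.seed(11)
  P <- matrix(abs(rnorm(40 * 15)), 40, 15)
  a <- fit_nmf(P, g = 4, seed = 123, max_iter = 50, tol = 0)
  b <- fit_nmf(P, g = 4, seed = 123, max_iter = 50, tol = 0)
  expect_identical(a$W, b$W)
  expect_identical(a$H, b$H)
  expect_identical(a$objective_trace, b$objective_trace)
  c2 <- fit_nmf(P, g = 4, seed = 124, max_iter = 50, tol = 0)
  expect_false(identical(a$W, c2$W))
})

test_that("topic assignment takes the row-wise maximum with deterministic ties", {
  fit <- structure(list(
    W = matrix(0, 2, 3), g = 3L,
    H = rbind(c(0.1, 0.9, 0.0),
              c(0.5, 0.5, 0.1),
              c(0, 0, 0)),
    doc_ids = c("a", "b", "c")
  ), class = "mm_nmf")
  a <- assign_topics(fit)
  expect_equal(a$topic, c(2L, 1L, 0L))
  expect_equal(a$coherence, c(0.9, 0.5, 0))
})

test_that("scaling the content matrix leaves topic assignments unchanged", {
  set.seed(5)
  P <- matrix(abs(rnorm(25 * 12)), 25, 12)
  a <- assign_topics(fit_nmf(P, g = 3, seed = 9, max_iter = 80, tol = 0))
  b <- assign_topics(fit_nmf(2 * P, g = 3, seed = 9, max_iter = 80, tol = 0))
  expect_equal(a$topic, b$topic)
})

test_that("top terms rank by loading with lexicographic tie-break", {
  fit <- structure(list(
    W = matrix(c(0.5, 0.9, 0.5, 0.1), 4, 1,
               dimnames = list(NULL, NULL)),
    H = matrix(1, 1, 1), g = 1L,
    terms = c("zeta", "anova", "alpha", "beta"),
    doc_ids = "d"
  ), class = "mm_nmf")
  tt <- top_terms(fit, 1, k = 3)
  expect_equal(tt$term, c("anova", "alpha", "zeta"))
  # k larger than vocabulary returns everything
  expect_equal(nrow(top_terms(fit, 1, k = 100)), 4)
  expect_error(top_terms(fit, 2, k = 1), "topic")
})

test_that("planted disjoint-vocabulary topics are recovered", {
  skip_if_not_installed("mclust")
  sim <- generate_corpus(generator_config(
    g = 5, docs_per_topic = 30, vocab_overlap_fraction = 0,
    templates = list(), seed = 17))
  norm <- normalize_corpus(sim$corpus)
  tf <- build_tfidf(norm)
  fit <- fit_nmf(tf$P, g = 5, seed = 1)
  a <- assign_topics(fit)
  ari <- mclust::adjustedRandIndex(a$topic, sim$truth_documents$topic)
  expect_gte(ari, 0.9)
  # top terms of each fitted topic come from a single planted vocabulary
  prefixes <- vapply(seq_len(5), function(t) {
    tt <- top_terms(fit, t, k = 5)
    length(unique(substr(tt$term, 1, 2)))
  }, numeric(1))
  expect_true(sum(prefixes == 1) >= 4)
})
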