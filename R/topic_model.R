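# Topic modelling: tf-idf content matrix and non-negative matrix
# factorization by multiplicative updates under the Frobenius objective.

#' Build a tf-idf content matrix
#'
#' Builds the M-term x N-document content matrix P from a normalized corpus.
#' Entries are tf(t, d) * idf(t) with tf the raw count of term t in document
#' d and the smoothed idf = ln((1 + N) / (1 + df(t))) + 1; each document
#' column is then scaled to unit Euclidean norm. Terms with document
#' frequency below `min_df` or above `max_df_fraction * N` are dropped.
#'
#' @param x a `mm_normalized` tibble (or any tibble with `id` and `tokens`
#'   list-column).
#' @param min_df minimum document frequency (count).
#' @param max_df_fraction maximum document frequency as a fraction of N.
#' @return list with `vocabulary` (tibble: `term`, `doc_frequency`) and `P`
#'   (sparse `dgCMatrix`, rows = terms, columns = document ids).
#' @export
build_tfidf <- function(x, min_df = 2L, max_df_fraction = 0.95) {
  if (nrow(x) == 0L) stop_input("normalized corpus is empty")
  if (min_df < 1L) stop_input("min_df must be >= 1")
  if (max_df_fraction <= 0 || max_df_fraction > 1) {
    stop_input("max_df_fraction must be in (0, 1]")
  }
  n_docs <- nrow(x)
  doc_lens <- lengths(x$tokens)
  doc_index <- rep.int(seq_len(n_docs), doc_lens)
  all_tokens <- unlist(x$tokens, use.names = FALSE)
  if (length(all_tokens) == 0L) stop_input("no tokens in corpus")

  terms <- sort(unique(all_tokens), method = "radix")
  term_index <- match(all_tokens, terms)
  # document frequency: distinct documents containing each term
  pair_keys <- paste0(term_index, "\r", doc_index)
  dedup <- !duplicated(pair_keys)
  df_count <- tabulate(term_index[dedup], nbins = length(terms))

  keep <- df_count >= min_df & df_count <= max_df_fraction * n_docs
  if (!any(keep)) stop_input("vocabulary empty after document-frequency filtering")
  kept_terms <- terms[keep]
  kept_df <- df_count[keep]

  sel <- keep[term_index]
  ti <- match(all_tokens[sel], kept_terms)
  di <- doc_index[sel]
  counts <- Matrix::sparseMatrix(
    i = ti, j = di, x = 1,
    dims = c(length(kept_terms), n_docs),
    dimnames = list(kept_terms, x$id)
  )
  idf <- log((1 + n_docs) / (1 + kept_df)) + 1
  P <- Matrix::Diagonal(x = idf) %*% counts
  norms <- sqrt(Matrix::colSums(P^2))
  norms[norms == 0] <- 1
  P <- P %*% Matrix::Diagonal(x = 1 / norms)
  dimnames(P) <- list(kept_terms, x$id)
  list(
    vocabulary = tibble::tibble(term = kept_terms, doc_frequency = kept_df),
    P = methods::as(P, "CsparseMatrix")
  )
}

nmf_objective <- function(P, W, H, normP2) {
  WtW <- crossprod(W)
  HtH <- crossprod(H)
  cross <- sum(as.matrix(Matrix::crossprod(P, W)) * H)
  0.5 * (normP2 - 2 * cross + sum(WtW * HtH))
}

#' Fit non-negative matrix factorization
#'
#' Approximates the content matrix P (M x N) by W H' with non-negative
#' W (M x g term loadings) and H (N x g document loadings), minimizing the
#' Frobenius objective 0.5 * ||P - W H'||_F^2 by Lee-Seung multiplicative
#' updates from a seeded non-negative random initialization
#' (|N(0, 1)| scaled by sqrt(mean(P) / g)). The objective is recorded after
#' every iteration and is non-increasing; iteration stops when the relative
#' objective decrease falls below `tol` or `max_iter` is reached.
#'
#' @param P non-negative matrix (sparse `dgCMatrix` or base matrix), rows =
#'   terms, columns = documents.
#' @param g number of topics, `1 <= g <= min(M, N)`.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative objective-decrease tolerance for convergence.
#' @return list of class `mm_nmf` with `W`, `H`, `g`, `objective_trace`,
#'   `seed`, `n_iter`, `converged`.
#' @export
fit_nmf <- function(P, g = 10L, seed = 1L, max_iter = 200L, tol = 1e-4) {
  M <- nrow(P)
  N <- ncol(P)
  if (g < 1L || g > min(M, N)) {
    stop_input("g must satisfy 1 <= g <= min(M, N) = %d", min(M, N))
  }
  if (max_iter < 1L) stop_input("max_iter must be >= 1")
  if (inherits(P, "sparseMatrix")) {
    if (any(!is.finite(P@x))) stop_input("P contains non-finite entries")
    if (any(P@x < 0)) stop_input("P must be non-negative")
  } else {
    if (any(!is.finite(P))) stop_input("P contains non-finite entries")
    if (any(P < 0)) stop_input("P must be non-negative")
    P <- methods::as(methods::as(Matrix::Matrix(P, sparse = TRUE), "generalMatrix"),
                     "CsparseMatrix")
  }
  mean_p <- sum(P) / (as.double(M) * N)
  scale0 <- sqrt(mean_p / g)
  if (!is.finite(scale0) || scale0 <= 0) scale0 <- 1e-3
  init <- with_seed(seed, {
    list(W = matrix(abs(rnorm(M * g)) * scale0, M, g),
         H = matrix(abs(rnorm(N * g)) * scale0, N, g))
  })
  W <- init$W
  H <- init$H
  eps <- 1e-10
  normP2 <- sum(P@x^2)
  trace <- numeric(max_iter)
  converged <- FALSE
  n_iter <- 0L
  prev <- Inf
  for (it in seq_len(max_iter)) {
    # H <- H * (P'W) / (H W'W)
    PtW <- as.matrix(Matrix::crossprod(P, W))
    H <- H * PtW / (H %*% crossprod(W) + eps)
    # W <- W * (PH) / (W H'H)
    PH <- as.matrix(P %*% H)
    W <- W * PH / (W %*% crossprod(H) + eps)
    obj <- nmf_objective(P, W, H, normP2)
    trace[it] <- obj
    n_iter <- it
    if (is.finite(prev) && prev > 0 && (prev - obj) / prev < tol) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  structure(
    list(W = W, H = H, g = as.integer(g),
         objective_trace = trace[seq_len(n_iter)],
         seed = as.integer(seed), n_iter = n_iter, converged = converged,
         terms = rownames(P), doc_ids = colnames(P)),
    class = "mm_nmf"
  )
}

#' @export
print.mm_nmf <- function(x, ...) {
  cat(sprintf(
    "<mm_nmf> g = %d topics, %d x %d matrix, %d iteration(s), %s (objective %.6g)\n",
    x$g, nrow(x$W), nrow(x$H), x$n_iter,
    if (x$converged) "converged" else "max_iter reached",
    x$objective_trace[x$n_iter]))
  invisible(x)
}

#' Assign documents to topics
#'
#' Each document gets the topic with the maximum coefficient in its row of
#' H (the topic coherence score). Ties break to the lowest topic index; a
#' document whose H row is all zero is unassigned (topic 0, coherence 0).
#'
#' @param fit a `mm_nmf` result.
#' @return tibble with `id`, `topic` (integer, 0 = unassigned) and
#'   `coherence`.
#' @export
assign_topics <- function(fit) {
  H <- fit$H
  topic <- apply(H, 1L, which.max)
  coherence <- H[cbind(seq_len(nrow(H)), topic)]
  zero <- apply(H, 1L, function(r) all(r == 0))
  topic[zero] <- 0L
  coherence[zero] <- 0
  tibble::tibble(
    id = fit$doc_ids %||% as.character(seq_len(nrow(H))),
    topic = as.integer(topic),
    coherence = as.numeric(coherence)
  )
}

#' Top terms of a topic
#'
#' The k terms with the largest loadings in the topic's column of W,
#' descending; ties break lexicographically.
#'
#' @param fit a `mm_nmf` result.
#' @param topic topic index in `1..g`.
#' @param k number of terms (capped at M).
#' @return tibble with `term` and `weight`.
#' @export
top_terms <- function(fit, topic, k = 10L) {
  if (topic < 1L || topic > fit$g) stop_input("topic must be in 1..%d", fit$g)
  if (k < 1L) stop_input("k must be >= 1")
  w <- fit$W[, topic]
  terms <- fit$terms %||% as.character(seq_along(w))
  ord <- order(-w, terms, method = "radix")
  sel <- ord[seq_len(min(k, length(w)))]
  tibble::tibble(term = terms[sel], weight = as.numeric(w[sel]))
}
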