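# Boilerplate detection: asymmetric Jaccard containment over word-token
# sets, scored either exhaustively (the brute-force oracle) or via MinHash
# locality-sensitive hashing to prune the all-pairs comparison space.

#' Build token sets from a normalized corpus
#'
#' At `"section"` level each document yields one set (index 0) holding all
#' its distinct tokens; at `"sentence"` level each sentence yields one set
#' indexed by its ordinal (1-based).
#'
#' @param x a `mm_normalized` tibble.
#' @param level `"section"` or `"sentence"`.
#' @return tibble with `owner_id`, `unit`, `index`, `tokens` (list-column of
#'   unique token vectors) and `cardinality`.
#' @export
token_sets <- function(x, level = c("section", "sentence")) {
  level <- match.arg(level)
  if (level == "section") {
    toks <- lapply(x$tokens, function(t) sort(unique(t), method = "radix"))
    out <- tibble::tibble(
      owner_id = x$id, unit = "section", index = 0L,
      tokens = toks, cardinality = lengths(toks)
    )
  } else {
    n_sent <- lengths(x$sentences)
    toks <- lapply(unlist(x$sentences, recursive = FALSE),
                   function(t) sort(unique(t), method = "radix"))
    out <- tibble::tibble(
      owner_id = rep.int(x$id, n_sent),
      unit = "sentence",
      index = unlist(lapply(n_sent, seq_len), use.names = FALSE) %||% integer(0),
      tokens = toks %||% list(),
      cardinality = lengths(toks)
    )
  }
  out[out$cardinality > 0L, , drop = FALSE]
}

#' Asymmetric Jaccard containment score
#'
#' `containment(A, B) = |A intersect B| / |B|`: the fraction of the target
#' B's distinct tokens found in A. Equals 1 when B is embedded in A, which
#' is what makes the score detect short boilerplate sentences inside longer
#' ones.
#'
#' @param A,B character vectors of tokens (duplicates ignored).
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' containment(c("a", "b"), c("b", "c"))  # 0.5
containment <- function(A, B) {
  a <- unique(as.character(A))
  b <- unique(as.character(B))
  if (length(b) == 0L) stop_input("containment undefined: target set B is empty")
  if (length(a) == 0L) return(0)
  vocab <- sort(unique(c(a, b)), method = "radix")
  sa <- sort(match(a, vocab))
  sb <- sort(match(b, vocab))
  inter <- cpp_intersection_sizes(list(sa, sb),
                                  matrix(c(1L, 2L), nrow = 1L))
  inter / length(b)
}

#' MinHash signature of a token set
#'
#' k seeded hash permutations of 64-bit token hashes; component i is the
#' 32-bit slice of the minimum of permutation i over the set. Deterministic
#' given tokens, `k` and `seed`; the fraction of equal components between
#' two signatures estimates their symmetric Jaccard similarity.
#'
#' @param tokens non-empty character vector.
#' @param k number of hash permutations (>= 16).
#' @param seed integer seed.
#' @return numeric vector of length `k` of class `mm_minhash`.
#' @export
minhash <- function(tokens, k = 256L, seed = 1L) {
  tokens <- unique(as.character(tokens))
  if (length(tokens) == 0L) stop_input("minhash undefined for an empty token set")
  if (k < 16L) stop_input("k must be >= 16")
  sig <- cpp_minhash(list(seq_along(tokens)), tokens, as.integer(k),
                     as.integer(seed))
  structure(as.numeric(sig[, 1L]), k = as.integer(k),
            seed = as.integer(seed), class = "mm_minhash")
}

# Encode token sets against a shared vocabulary: sorted unique integer ids.
encode_sets <- function(token_list) {
  vocab <- sort(unique(unlist(token_list, use.names = FALSE)), method = "radix")
  sets <- lapply(token_list, function(t) sort(match(t, vocab)))
  list(vocab = vocab, sets = sets)
}

# Candidate pairs from banded minhash signatures plus (optionally) a
# rare-token channel: sets sharing a token whose corpus frequency is at most
# rare_df_max are also admitted. Returns a 2-column matrix of 1-based set
# indices with i < j.
lsh_candidates <- function(enc, k, b, r, seed, rare_df_max = 0L) {
  n <- length(enc$sets)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  sig <- cpp_minhash(enc$sets, enc$vocab, as.integer(k), as.integer(seed))
  keys <- cpp_band_keys(sig, as.integer(b), as.integer(r), as.integer(seed))
  pair_chunks <- list()
  pc <- 0L
  group_pairs <- function(groups) {
    groups <- groups[lengths(groups) > 1L]
    lapply(groups, function(g) {
      g <- sort.int(g)
      m <- length(g)
      cbind(rep(g[-m], times = (m - 1L):1L),
            unlist(lapply(2L:m, function(s) g[s:m]), use.names = FALSE))
    })
  }
  for (band in seq_len(nrow(keys))) {
    chunks <- group_pairs(split(seq_len(n), keys[band, ]))
    for (ch in chunks) {
      pc <- pc + 1L
      pair_chunks[[pc]] <- ch
    }
  }
  if (rare_df_max > 0L) {
    tok_df <- tabulate(unlist(enc$sets, use.names = FALSE),
                       nbins = length(enc$vocab))
    rare <- which(tok_df > 1L & tok_df <= rare_df_max)
    if (length(rare) > 0L) {
      owner <- rep.int(seq_len(n), lengths(enc$sets))
      tok <- unlist(enc$sets, use.names = FALSE)
      sel <- tok %in% rare
      chunks <- group_pairs(split(owner[sel], tok[sel]))
      for (ch in chunks) {
        pc <- pc + 1L
        pair_chunks[[pc]] <- ch
      }
    }
  }
  if (pc == 0L) return(matrix(integer(0), ncol = 2L))
  pairs <- do.call(rbind, pair_chunks)
  pairs[!duplicated(pairs[, 1L] * (n + 1) + pairs[, 2L]), , drop = FALSE]
}

# Shared record assembly: pair indices + intersection sizes -> MatchRecords.
empty_match_records <- function() {
  tibble::tibble(
    query_id = character(0), query_unit = character(0),
    query_index = integer(0), target_id = character(0),
    target_unit = character(0), target_index = integer(0),
    score = numeric(0), direction = character(0),
    is_boilerplate = logical(0), is_exact = logical(0)
  )
}

make_match_records <- function(sets, i, j, inter, threshold) {
  if (length(i) == 0L) return(empty_match_records())
  ci <- sets$cardinality[i]
  cj <- sets$cardinality[j]
  # query covers target when |Q n T| / |T| is the larger direction
  score_qt <- inter / cj
  score_tq <- inter / ci
  score <- pmax(score_qt, score_tq)
  keep <- score >= threshold
  if (!any(keep)) return(empty_match_records())
  i <- i[keep]; j <- j[keep]
  inter <- inter[keep]; ci <- ci[keep]; cj <- cj[keep]
  score_qt <- score_qt[keep]; score_tq <- score_tq[keep]; score <- score[keep]
  out <- tibble::tibble(
    query_id = sets$owner_id[i],
    query_unit = sets$unit[i],
    query_index = sets$index[i],
    target_id = sets$owner_id[j],
    target_unit = sets$unit[j],
    target_index = sets$index[j],
    score = score,
    direction = ifelse(score_qt >= score_tq,
                       "query_covers_target", "target_covers_query"),
    is_boilerplate = score >= threshold,
    is_exact = inter == ci & inter == cj
  )
  out[order(out$query_id, out$query_index, out$target_id, out$target_index,
            method = "radix"), , drop = FALSE]
}

scan_prepare <- function(sets, level, min_tokens) {
  if (!is.null(level)) sets <- sets[sets$unit == level, , drop = FALSE]
  sets <- sets[sets$cardinality >= min_tokens, , drop = FALSE]
  sets
}

#' Exhaustive all-pairs boilerplate scan (oracle)
#'
#' Compares every cross-document pair of token sets and emits one
#' MatchRecord per unordered pair whose containment score, taken as the
#' maximum over both directions, reaches the threshold. Exact matches are
#' pairs with identical token sets (containment 1 both ways).
#'
#' @param sets a token-set tibble from [token_sets()].
#' @param level optionally restrict to `"section"` or `"sentence"` sets.
#' @param threshold boilerplate threshold in `(0, 1]`.
#' @param min_tokens sets smaller than this are excluded (default 3;
#'   very short sentences match spuriously).
#' @return a MatchRecord tibble (see [pairwise_scan()]), sorted by query and
#'   target.
#' @export
brute_force_scan <- function(sets, level = NULL, threshold = 0.9,
                             min_tokens = 3L) {
  sets <- scan_prepare(sets, level, min_tokens)
  if (nrow(sets) < 2L) return(make_match_records(sets, integer(0), integer(0),
                                                 integer(0), threshold))
  enc <- encode_sets(sets$tokens)
  doc <- match(sets$owner_id, unique(sets$owner_id))
  hits <- cpp_all_pairs(enc$sets, doc, threshold)
  make_match_records(sets, hits$i, hits$j, hits$inter, threshold)
}

#' LSH-accelerated boilerplate scan
#'
#' Generates candidate pairs by banded MinHash locality-sensitive hashing
#' (sets sharing at least one band bucket), optionally augmented by a
#' rare-token channel (sets sharing any token with corpus frequency at most
#' `rare_df_max`; used at section level where set sizes differ widely), then
#' verifies each candidate with the exact containment score in both
#' directions. Record semantics are identical to [brute_force_scan()]: LSH
#' can only prune candidates, never invent matches, so the result is always
#' a subset of the brute-force records.
#'
#' @inheritParams brute_force_scan
#' @param k number of minhash permutations.
#' @param b,r bands and rows per band; `b * r` must equal `k`.
#' @param seed integer seed for the hash family.
#' @param rare_df_max admit candidates sharing a token with document
#'   frequency at most this value (0 disables the channel).
#' @return a MatchRecord tibble with columns `query_id`, `query_unit`,
#'   `query_index`, `target_id`, `target_unit`, `target_index`, `score`,
#'   `direction`, `is_boilerplate`, `is_exact`.
#' @export
pairwise_scan <- function(sets, level = NULL, threshold = 0.9, k = 256L,
                          b = 64L, r = 4L, seed = 1L, min_tokens = 3L,
                          rare_df_max = if (identical(level, "section")) 5L else 0L) {
  if (b * r != k) stop_input("LSH parameters must satisfy b * r = k")
  if (threshold <= 0 || threshold > 1) stop_input("threshold must be in (0, 1]")
  sets <- scan_prepare(sets, level, min_tokens)
  if (nrow(sets) < 2L) return(make_match_records(sets, integer(0), integer(0),
                                                 integer(0), threshold))
  enc <- encode_sets(sets$tokens)
  pairs <- lsh_candidates(enc, k, b, r, seed, rare_df_max = rare_df_max)
  if (nrow(pairs) > 0L) {
    cross_doc <- sets$owner_id[pairs[, 1L]] != sets$owner_id[pairs[, 2L]]
    pairs <- pairs[cross_doc, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) return(make_match_records(sets, integer(0), integer(0),
                                                   integer(0), threshold))
  inter <- cpp_intersection_sizes(enc$sets, pairs)
  make_match_records(sets, pairs[, 1L], pairs[, 2L], inter, threshold)
}

#' Targeted n-gram / sentence search
#'
#' Finds documents containing the gating n-gram as a contiguous token
#' subsequence (the "potential matches"), scores every sentence of those
#' documents against the target token set with the containment score, and
#' summarizes each document's best score. By default the gating n-gram is
#' the target itself; passing a shorter `ngram` reproduces the published
#' table layout where a bold sub-phrase gates the search while the full
#' sentence is scored, and `ngram = NULL` disables gating (every document
#' is scored and counts as a potential match).
#'
#' @param x a `mm_normalized` tibble.
#' @param target character vector of normalized tokens (run the query text
#'   through [normalize_document()] first if it is raw).
#' @param threshold boilerplate threshold.
#' @param ngram gating token sequence, `NULL` to score all documents.
#' @return list of class `mm_targeted` with `target`, `potential_matches`,
#'   `boilerplate_count`, `median`, `q1`, `q3` (quartiles of per-document
#'   best scores) and `scores`, a tibble of (`id`, `sentence_index`,
#'   `score`) for every sentence of every potential match.
#' @export
targeted_search <- function(x, target, threshold = 0.9, ngram = target) {
  target <- as.character(target)
  if (length(target) == 0L) stop_input("target must be non-empty")
  if (is.null(ngram) || length(ngram) == 0L) {
    hit <- rep(TRUE, nrow(x))
  } else {
    needle <- paste0(" ", paste(as.character(ngram), collapse = " "), " ")
    hay <- vapply(x$tokens,
                  function(t) paste0(" ", paste(t, collapse = " "), " "),
                  character(1))
    hit <- grepl(needle, hay, fixed = TRUE)
  }
  target_set <- unique(target)
  rows <- which(hit)
  scores <- if (length(rows) == 0L) {
    tibble::tibble(id = character(0), sentence_index = integer(0),
                   score = numeric(0))
  } else {
    do.call(rbind, lapply(rows, function(rix) {
      sents <- x$sentences[[rix]]
      tibble::tibble(
        id = x$id[rix],
        sentence_index = seq_along(sents),
        score = vapply(sents, function(s) {
          length(intersect(unique(s), target_set)) / length(target_set)
        }, numeric(1))
      )
    }))
  }
  best <- if (nrow(scores) > 0L) {
    tapply(scores$score, scores$id, max)
  } else numeric(0)
  q <- if (length(best) > 0L) {
    stats::quantile(as.numeric(best), c(0.25, 0.5, 0.75), type = 7,
                    names = FALSE)
  } else c(NA_real_, NA_real_, NA_real_)
  structure(
    list(
      target = paste(target, collapse = " "),
      potential_matches = sum(hit),
      boilerplate_count = sum(best >= threshold),
      median = q[2], q1 = q[1], q3 = q[3],
      threshold = threshold,
      scores = scores
    ),
    class = "mm_targeted"
  )
}

#' @export
print.mm_targeted <- function(x, ...) {
  cat(sprintf(
    "<targeted search> \"%s\"\n  potential matches: %d; boilerplate (score >= %.2f): %d\n  best-score median %.3g (IQR %.3g to %.3g)\n",
    x$target, x$potential_matches, x$threshold, x$boilerplate_count,
    x$median, x$q1, x$q3))
  invisible(x)
}
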