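# Text normalization: the cleaning pipeline applied to every methods section
# before topic modelling and boilerplate scoring. Order matters: sentences are
# split first (splitting needs the punctuation that later stages destroy),
# then symbols are verbalized, formatting stripped, text lowercased and
# tokenized, stop words removed and statistical terms standardized.

mm_extdata <- function(file) {
  path <- system.file("extdata", file, package = "methodsminer")
  if (!nzchar(path)) stop("missing package data file: ", file)
  path
}

read_token_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

read_tsv_map <- function(path) {
  lines <- read_token_file(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed mapping line(s) in ", path)
  stats::setNames(vapply(parts, `[[`, character(1), 2L),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Symbol-to-text map
#'
#' Mapping from symbols (single characters or short sequences such as `<=`)
#' to lowercase plain-text tokens, e.g. `%` to `percent` and `<` to
#' `less-than`. Values must be ASCII tokens and must not contain any mapped
#' key, so applying the map twice equals applying it once.
#'
#' @param map named character vector: `names` are symbols, values tokens.
#' @return A `mm_symbol_map` object.
#' @export
symbol_map <- function(map) {
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    stop_input("symbol map must have non-empty symbol names")
  }
  if (anyDuplicated(names(map))) stop_input("symbol map keys must be unique")
  if (any(grepl("[^ -~]", map))) {
    stop_input("symbol map values must be ASCII tokens")
  }
  for (key in names(map)) {
    if (any(grepl(key, map, fixed = TRUE))) {
      stop_input("symbol map value contains mapped key '%s'", key)
    }
  }
  # longest keys first so multi-character symbols win over their prefixes
  map <- map[order(-nchar(names(map)), names(map), method = "radix")]
  structure(list(map = map), class = "mm_symbol_map")
}

#' @rdname symbol_map
#' @export
default_symbol_map <- function() {
  symbol_map(read_tsv_map(mm_extdata("symbol_map.tsv")))
}

#' Stop-word list with a retain set
#'
#' Stop words are removed from tokenized text except those in the retain
#' set: prepositions like "between" and "against" that carry meaning in
#' statistical-methods descriptions are kept. The retain set is subtracted
#' at construction, so the two sets are disjoint.
#'
#' @param stop_words character vector of lowercase tokens.
#' @param retained lowercase tokens exempt from removal.
#' @return A `mm_stoplist` object.
#' @export
stoplist <- function(stop_words, retained = character(0)) {
  stop_words <- unique(tolower(stop_words))
  retained <- unique(tolower(retained))
  structure(list(stop_words = setdiff(stop_words, retained),
                 retained = retained),
            class = "mm_stoplist")
}

#' @rdname stoplist
#' @export
default_stoplist <- function() {
  stoplist(read_token_file(mm_extdata("stop_words.txt")),
           read_token_file(mm_extdata("retained_words.txt")))
}

#' Statistical-term dictionary
#'
#' Maps variant spellings of statistical terms (plural, unhyphenated and
#' combined forms like "chi squares" or "chisquare", 1-3 tokens long) to a
#' canonical singular hyphenated token ("chi-square"). The constructor closes
#' the mapping so every canonical form maps to itself, making
#' [standardize_terms()] idempotent.
#'
#' @param map named character vector: names are variant token sequences
#'   (words separated by single spaces), values canonical tokens.
#' @return A `mm_term_dictionary` object.
#' @export
term_dictionary <- function(map) {
  keys <- tolower(names(map))
  vals <- tolower(unname(map))
  # idempotent closure: canonical forms map to themselves
  extra <- setdiff(unique(vals), keys)
  keys <- c(keys, extra)
  vals <- c(vals, extra)
  # a key that is itself a canonical form must map to itself
  self_violation <- keys %in% unique(vals) & vals != keys
  if (any(self_violation)) {
    stop_input("canonical form(s) remapped elsewhere: %s",
               paste(keys[self_violation], collapse = ", "))
  }
  ngram <- lengths(strsplit(keys, " ", fixed = TRUE))
  if (any(ngram > 3L)) stop_input("dictionary variants are limited to 3 words")
  env <- new.env(parent = emptyenv(), size = length(keys) * 2L)
  for (i in seq_along(keys)) assign(keys[i], vals[i], envir = env)
  first <- new.env(parent = emptyenv())
  for (k in keys) {
    assign(strsplit(k, " ", fixed = TRUE)[[1]][1], TRUE, envir = first)
  }
  structure(list(map = env, first = first, max_n = max(ngram),
                 keys = keys, values = vals),
            class = "mm_term_dictionary")
}

#' @rdname term_dictionary
#' @export
default_term_dictionary <- function() {
  term_dictionary(read_tsv_map(mm_extdata("term_dictionary.tsv")))
}

#' Verbalize mathematical symbols
#'
#' Replaces each mapped symbol with its plain-text token padded by spaces,
#' then collapses runs of whitespace. `"p < 0.05"` becomes
#' `"p less-than 0.05"` and `"95%"` becomes `"95 percent"`.
#'
#' @param text character vector.
#' @param map a [symbol_map()]; defaults to the shipped map.
#' @return character vector.
#' @export
convert_symbols <- function(text, map = default_symbol_map()) {
  x <- text
  for (key in names(map$map)) {
    x <- gsub(key, paste0(" ", map$map[[key]], " "), x, fixed = TRUE)
  }
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Strip formatting, references and punctuation
#'
#' Removes bracketed citation markers (`[12]`, `[1, 2]`, `[3-5]`), inline
#' equation blocks delimited by `$`, carriage returns and other layout
#' whitespace, and all punctuation except intra-word hyphens and decimal
#' points flanked by digits (so `chi-square` and `0.05` survive). Remaining
#' brackets are dropped but their inner text kept; non-ASCII characters are
#' deleted and whitespace collapsed.
#'
#' @param text character vector.
#' @return character vector.
#' @export
strip_formatting <- function(text) {
  x <- gsub("[\x01\x02]", " ", text, useBytes = FALSE)
  x <- gsub("\\$\\$[^$]*\\$\\$", " ", x)
  x <- gsub("\\$[^$]*\\$", " ", x)
  # in-text reference markers: digits (with separators/ranges) in brackets
  x <- gsub("\\[[0-9]+([,;[:space:]–—-]+[0-9]+)*\\]", " ", x,
            perl = TRUE)
  x <- gsub("[\r\n\t]+", " ", x)
  x <- gsub("[][(){}]", "", x)
  x <- gsub("(?<=[0-9])\\.(?=[0-9])", "\x01", x, perl = TRUE)
  x <- gsub("(?<=[A-Za-z0-9])-(?=[A-Za-z0-9])", "\x02", x, perl = TRUE)
  x <- gsub("[[:punct:]]+", " ", x)
  x <- chartr("\x01\x02", ".-", x)
  x <- gsub("[^ -~]+", " ", x, perl = TRUE)
  gsub("[[:space:]]+", " ", trimws(x))
}

#' Remove stop words
#'
#' Drops tokens that are in the stop list and not in its retain set;
#' surviving tokens keep their original order.
#'
#' @param tokens lowercase character vector.
#' @param stops a [stoplist()].
#' @return character vector.
#' @export
remove_stopwords <- function(tokens, stops = default_stoplist()) {
  tokens[!tokens %in% stops$stop_words]
}

#' Standardize statistical terms
#'
#' Longest-match, left-to-right replacement of variant n-grams (n <= 3) by
#' their canonical singular hyphenated token: `"chi", "square"` becomes
#' `"chi-square"`. Output is stable under re-application.
#'
#' @param tokens lowercase character vector.
#' @param dict a [term_dictionary()].
#' @return character vector.
#' @export
standardize_terms <- function(tokens, dict = default_term_dictionary()) {
  n <- length(tokens)
  if (n == 0L) return(tokens)
  out <- vector("list", n)
  oi <- 0L
  i <- 1L
  max_n <- dict$max_n
  while (i <= n) {
    oi <- oi + 1L
    if (!exists(tokens[i], envir = dict$first, inherits = FALSE)) {
      out[[oi]] <- tokens[i]
      i <- i + 1L
      next
    }
    hit <- NULL
    hit_len <- 0L
    for (len in seq.int(min(max_n, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      if (exists(key, envir = dict$map, inherits = FALSE)) {
        hit <- get(key, envir = dict$map)
        hit_len <- len
        break
      }
    }
    if (is.null(hit)) {
      out[[oi]] <- tokens[i]
      i <- i + 1L
    } else {
      out[[oi]] <- hit
      i <- i + hit_len
    }
  }
  unlist(out[seq_len(oi)], use.names = FALSE)
}

SENTENCE_ABBREVIATIONS <- c("e.g", "i.e", "vs", "et al", "etc", "cf", "ca",
                            "approx", "fig", "figs")

#' Split raw text into sentences
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace and an uppercase letter or digit. Common abbreviations
#' ("e.g.", "i.e.", "vs.", "et al.", ...) suppress splits, and decimal
#' numbers never split because the rule requires whitespace after the
#' punctuation.
#'
#' @param text a single character string of raw (unstripped) text.
#' @return character vector of sentences; `character(0)` for blank input.
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1L)
  t <- gsub("[[:space:]]+", " ", trimws(text))
  if (!nzchar(t)) return(character(0))
  m <- gregexpr("[.!?]+ (?=[A-Z0-9])", t, perl = TRUE)[[1]]
  if (m[1] == -1L) return(t)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  ok <- vapply(starts, function(s) {
    pre <- tolower(substr(t, max(1L, s - 8L), s - 1L))
    !any(vapply(SENTENCE_ABBREVIATIONS, function(a) {
      grepl(paste0("(^|[^a-z])", gsub(".", "\\.", a, fixed = TRUE), "$"), pre)
    }, logical(1)))
  }, logical(1))
  cuts <- starts[ok] + lens[ok]   # position where the next sentence begins
  bounds <- c(1L, cuts)
  ends <- c(cuts - 1L, nchar(t))
  out <- substring(t, bounds, ends)
  out <- trimws(out)
  out[nzchar(out)]
}

normalize_text <- function(text, map, stops, dict) {
  sentences <- split_sentences(text)
  toks <- lapply(sentences, function(s) {
    s <- convert_symbols(s, map)
    s <- strip_formatting(s)
    s <- tolower(s)
    if (!nzchar(s)) return(character(0))
    tok <- strsplit(s, " ", fixed = TRUE)[[1]]
    tok <- tok[nzchar(tok)]
    tok <- remove_stopwords(tok, stops)
    standardize_terms(tok, dict)
  })
  toks[lengths(toks) > 0L]
}

#' Normalize one document
#'
#' Runs the full cleaning pipeline on a document's raw text: sentence
#' splitting, symbol verbalization, formatting/reference removal,
#' lowercasing, whitespace tokenization, stop-word removal and
#' statistical-term standardization. Sentences that end up empty are
#' dropped.
#'
#' @param id document identifier.
#' @param text raw section text.
#' @param map a [symbol_map()].
#' @param stops a [stoplist()].
#' @param dict a [term_dictionary()].
#' @return list with `id`, `sentences` (list of token vectors) and `tokens`
#'   (their concatenation).
#' @export
#' @examples
#' doc <- normalize_document(
#'   "d1", "A p-value < 0.05 was considered statistically significant.")
#' doc$tokens
normalize_document <- function(id, text, map = default_symbol_map(),
                               stops = default_stoplist(),
                               dict = default_term_dictionary()) {
  sentences <- normalize_text(text, map, stops, dict)
  list(id = id, sentences = sentences,
       tokens = unlist(sentences, use.names = FALSE) %||% character(0))
}

#' Normalize a corpus
#'
#' Applies [normalize_document()] to every document of a corpus.
#'
#' @param x a `mm_corpus`.
#' @inheritParams normalize_document
#' @return A `mm_normalized` tibble with columns `id`, `sentences`
#'   (list-column of token-vector lists) and `tokens` (list-column of
#'   flattened token vectors).
#' @export
normalize_corpus <- function(x, map = default_symbol_map(),
                             stops = default_stoplist(),
                             dict = default_term_dictionary()) {
  sent <- lapply(x$text, normalize_text, map = map, stops = stops, dict = dict)
  out <- tibble::tibble(
    id = x$id,
    sentences = sent,
    tokens = lapply(sent, function(s) {
      unlist(s, use.names = FALSE) %||% character(0)
    })
  )
  class(out) <- c("mm_normalized", class(tibble::tibble()))
  out
}

#' Write / read normalized documents as JSONL
#'
#' One JSON object per line with keys `id` and `sentences` (array of token
#' arrays). A leading `#` header line, when present, is ignored on read.
#'
#' @param x a `mm_normalized` tibble.
#' @param path file path.
#' @param header optional header comment line (written verbatim).
#' @return `path` (write) or a `mm_normalized` tibble (read).
#' @export
write_normalized <- function(x, path, header = NULL) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    as.character(jsonlite::toJSON(
      list(id = jsonlite::unbox(x$id[i]), sentences = x$sentences[[i]]),
      digits = NA
    ))
  }, character(1))
  if (!is.null(header)) lines <- c(header, lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_normalized
#' @export
read_normalized <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
             error = function(e) {
               stop_input("malformed normalized record at line %d of %s", i, path)
             })
  })
  out <- tibble::tibble(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    sentences = lapply(recs, function(r) {
      lapply(r$sentences, function(s) as.character(unlist(s)))
    })
  )
  out$tokens <- lapply(out$sentences, function(s) {
    unlist(s, use.names = FALSE) %||% character(0)
  })
  class(out) <- c("mm_normalized", class(tibble::tibble()))
  out
}
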