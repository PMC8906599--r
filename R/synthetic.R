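# Synthetic-corpus generator: corpora with known topic structure and planted
# boilerplate at controlled containment levels, with full ground truth, so
# the pipeline is testable without any external download.

#' Boilerplate template
#'
#' A template is a sequence of distinct normalized tokens planted as a whole
#' sentence into generated documents. Each planted copy has `k` of its `n`
#' distinct tokens substituted by novel tokens, so its containment score
#' against the template set is exactly `(n - k) / n`.
#'
#' @param id template identifier.
#' @param tokens character vector of distinct normalized tokens.
#' @param prob per-document planting probability.
#' @param k substitutions per planted copy (`0 <= k <= length(tokens)`).
#' @return list of class `mm_template`.
#' @export
template <- function(id, tokens, prob = 0.2, k = 0L) {
  tokens <- as.character(tokens)
  if (anyDuplicated(tokens)) stop_input("template tokens must be distinct")
  if (length(tokens) < 1L) stop_input("template must have at least one token")
  if (k < 0L || k > length(tokens)) {
    stop_input("k must satisfy 0 <= k <= %d", length(tokens))
  }
  if (prob < 0 || prob > 1) stop_input("prob must be in [0, 1]")
  structure(list(id = as.character(id), tokens = tokens,
                 prob = prob, k = as.integer(k)),
            class = "mm_template")
}

# Shipped boilerplate sentences, in post-normalization token form (the form
# the scanner scores), echoing the most common phrasings in published
# methods sections.
#' @rdname template
#' @export
default_templates <- function() {
  list(
    template("pvalue-significant",
             c("p-value", "less-than", "0.05", "considered", "statistically",
               "significant"), prob = 0.2, k = 0L),
    template("mean-sem",
             c("data", "presented", "mean", "plus-or-minus", "sem"),
             prob = 0.15, k = 0L),
    template("software-prism",
             c("statistical", "analysis", "performed", "using", "graphpad",
               "prism", "software"), prob = 0.1, k = 1L)
  )
}

#' Generator configuration
#'
#' Defines the study conditions the generator emulates: short methods
#' sections (the defaults give a median length of about 130 words, matching
#' published reports of methods-section length) with topic-specific
#' vocabularies, planted boilerplate templates and a fraction of
#' placeholder ("Not applicable") sections.
#'
#' @param g number of topics.
#' @param vocab_size tokens per topic vocabulary.
#' @param vocab_overlap_fraction fraction of each topic's vocabulary drawn
#'   from a pool shared by all topics, in `[0, 1)`.
#' @param docs_per_topic documents per topic.
#' @param sentences_per_doc integer range `c(min, max)`, uniform.
#' @param tokens_per_sentence integer range `c(min, max)`, uniform.
#' @param templates list of [template()] objects.
#' @param placeholder_rate fraction of documents emitted with placeholder
#'   text instead of content.
#' @param seed integer seed; together with the config it fully determines
#'   the output.
#' @return list of class `mm_generator_config`.
#' @export
generator_config <- function(g = 5L, vocab_size = 300L,
                             vocab_overlap_fraction = 0,
                             docs_per_topic = 60L,
                             sentences_per_doc = c(5L, 15L),
                             tokens_per_sentence = c(8L, 18L),
                             templates = default_templates(),
                             placeholder_rate = 0,
                             seed = 1L) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(g >= 1L, "g must be >= 1")
  chk(vocab_size >= 1L, "vocab_size must be >= 1")
  chk(vocab_overlap_fraction >= 0 && vocab_overlap_fraction < 1,
      "vocab_overlap_fraction must be in [0, 1)")
  chk(docs_per_topic >= 1L, "docs_per_topic must be >= 1")
  chk(length(sentences_per_doc) == 2L && all(sentences_per_doc >= 1L) &&
        sentences_per_doc[1] <= sentences_per_doc[2],
      "sentences_per_doc must be an increasing pair of lengths >= 1")
  chk(length(tokens_per_sentence) == 2L && all(tokens_per_sentence >= 1L) &&
        tokens_per_sentence[1] <= tokens_per_sentence[2],
      "tokens_per_sentence must be an increasing pair of lengths >= 1")
  chk(placeholder_rate >= 0 && placeholder_rate <= 1,
      "placeholder_rate must be in [0, 1]")
  chk(all(vapply(templates, inherits, logical(1), "mm_template")),
      "templates must be a list of template() objects")
  if (length(problems) > 0L) {
    stop_input("invalid generator config: %s", paste(problems, collapse = "; "))
  }
  structure(
    list(g = as.integer(g), vocab_size = as.integer(vocab_size),
         vocab_overlap_fraction = vocab_overlap_fraction,
         docs_per_topic = as.integer(docs_per_topic),
         sentences_per_doc = as.integer(sentences_per_doc),
         tokens_per_sentence = as.integer(tokens_per_sentence),
         templates = templates,
         placeholder_rate = placeholder_rate,
         seed = as.integer(seed)),
    class = "mm_generator_config"
  )
}

# Novel-token factory: tokens guaranteed absent from every topic vocabulary
# and every template ("zz" prefix; vocabulary tokens use topic prefixes).
novel_token_factory <- function() {
  counter <- 0L
  function(n = 1L) {
    out <- sprintf("zznovel%06d", counter + seq_len(n))
    counter <<- counter + n
    out
  }
}

#' Mutate a boilerplate template
#'
#' Replaces `k` distinct positions of the template with novel tokens absent
#' from the template (and, inside the generator, from all topic
#' vocabularies). The containment of the mutated sentence against the
#' template token set is exactly `(n - k) / n` for a template of `n`
#' distinct tokens.
#'
#' @param tokens template tokens (distinct).
#' @param k number of substitutions, `0 <= k <= length(tokens)`.
#' @param novel function returning `n` fresh novel tokens; defaults to an
#'   internal factory.
#' @return list with `sentence` (token vector) and `expected_containment`.
#' @export
mutate_template <- function(tokens, k, novel = novel_token_factory()) {
  n <- length(unique(tokens))
  if (k > n) stop_input("k (%d) exceeds number of distinct template tokens (%d)", k, n)
  sentence <- tokens
  if (k > 0L) {
    pos <- sample.int(length(tokens), k)
    sentence[pos] <- novel(k)
  }
  list(sentence = sentence, expected_containment = (n - k) / n)
}

render_sentence <- function(tokens) {
  s <- paste(tokens, collapse = " ")
  paste0(toupper(substr(s, 1L, 1L)), substr(s, 2L, nchar(s)))
}

#' Generate a synthetic corpus with ground truth
#'
#' Each document samples its tokens i.i.d. from its topic's vocabulary,
#' then each template is planted (after mutation) as an extra whole sentence
#' with its configured probability. A `placeholder_rate` fraction of
#' documents is emitted with the text "Not applicable" instead. The output
#' is fully determined by the config (including its seed).
#'
#' @param config a [generator_config()].
#' @return list with `corpus` (a `mm_corpus`), `truth_documents` (tibble:
#'   `id`, `topic`, `is_missing`) and `truth_sentences` (tibble: `id`,
#'   `sentence_index`, `is_planted`, `template_id`, `expected_containment`),
#'   where `sentence_index` refers to the document's sentence order.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "mm_generator_config"))
  with_seed(config$seed, {
    novel <- novel_token_factory()
    n_shared <- floor(config$vocab_overlap_fraction * config$vocab_size)
    shared <- if (n_shared > 0L) sprintf("shared%04d", seq_len(n_shared)) else character(0)
    vocabs <- lapply(seq_len(config$g), function(t) {
      own <- sprintf("t%dw%04d", t, seq_len(config$vocab_size - n_shared))
      c(shared, own)
    })
    n_docs <- config$g * config$docs_per_topic
    ids <- sprintf("syn%05d", seq_len(n_docs))
    topics <- rep(seq_len(config$g), each = config$docs_per_topic)
    is_missing <- runif(n_docs) < config$placeholder_rate

    texts <- character(n_docs)
    sent_truth <- vector("list", n_docs)
    for (d in seq_len(n_docs)) {
      if (is_missing[d]) {
        texts[d] <- "Not applicable"
        sent_truth[[d]] <- NULL
        next
      }
      vocab <- vocabs[[topics[d]]]
      n_sent <- sample(config$sentences_per_doc[1]:config$sentences_per_doc[2], 1L)
      sents <- lapply(seq_len(n_sent), function(s) {
        len <- sample(config$tokens_per_sentence[1]:config$tokens_per_sentence[2], 1L)
        sample(vocab, len, replace = TRUE)
      })
      planted <- data.frame(pos = integer(0), template_id = character(0),
                            expected = numeric(0), stringsAsFactors = FALSE)
      for (tp in config$templates) {
        if (runif(1) < tp$prob) {
          mut <- mutate_template(tp$tokens, tp$k, novel)
          pos <- sample.int(length(sents) + 1L, 1L)
          sents <- append(sents, list(mut$sentence), after = pos - 1L)
          # earlier planted positions at or past the insertion shift by one
          planted$pos[planted$pos >= pos] <- planted$pos[planted$pos >= pos] + 1L
          planted <- rbind(planted, data.frame(
            pos = pos, template_id = tp$id,
            expected = mut$expected_containment, stringsAsFactors = FALSE))
        }
      }
      texts[d] <- paste(vapply(sents, render_sentence, character(1)),
                        collapse = ". ")
      texts[d] <- paste0(texts[d], ".")
      truth <- tibble::tibble(
        id = ids[d],
        sentence_index = seq_along(sents),
        is_planted = FALSE,
        template_id = NA_character_,
        expected_containment = NA_real_
      )
      if (nrow(planted) > 0L) {
        truth$is_planted[planted$pos] <- TRUE
        truth$template_id[planted$pos] <- planted$template_id
        truth$expected_containment[planted$pos] <- planted$expected
      }
      sent_truth[[d]] <- truth
    }

    corp <- corpus(id = ids, text = texts, source = "synthetic",
                   provenance = sprintf("generator seed %d", config$seed))
    truth_docs <- tibble::tibble(
      id = ids,
      topic = ifelse(is_missing, NA_integer_, topics),
      is_missing = is_missing
    )
    truth_sents <- dplyr::bind_rows(sent_truth)
    list(corpus = corp, truth_documents = truth_docs,
         truth_sentences = truth_sents)
  })
}

#' Write a generated corpus and its ground truth to disk
#'
#' Corpus as JSONL (round-trips bit-exactly through [read_corpus()]),
#' document truth and sentence truth as TSV.
#'
#' @param sim result of [generate_corpus()].
#' @param dir writable output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    corpus = file.path(dir, "corpus.jsonl"),
    truth_documents = file.path(dir, "truth_documents.tsv"),
    truth_sentences = file.path(dir, "truth_sentences.tsv")
  )
  write_corpus(sim$corpus, paths[["corpus"]])
  readr::write_tsv(sim$truth_documents, paths[["truth_documents"]],
                   progress = FALSE)
  readr::write_tsv(sim$truth_sentences, paths[["truth_sentences"]],
                   progress = FALSE)
  invisible(paths)
}
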