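# Reporting pipeline: subcommand-style stages (simulate -> normalize ->
# topics -> scan -> search -> report) tied together by a plain-text run
# config, each writing TSV/JSONL artifacts with a reproducibility header.

#' Read a run configuration
#'
#' Plain-text `key = value` lines (a TOML-like subset): `#` starts a
#' comment, values may be quoted, comma-separated values become vectors and
#' numeric-looking values become numbers. Search targets use the `targets`
#' key with `;`-separated phrases.
#'
#' @param path config file path.
#' @param overrides named list merged over the file values (used by the
#'   command-line front-end for `--seed` / `--out`).
#' @return named list of class `mm_run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_input("config file not found: %s", path)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        stop_input("malformed config line (expected key = value): '%s'", ln)
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      val <- gsub('^"|"$', "", val)
      if (key == "targets") {
        val <- trimws(strsplit(val, ";", fixed = TRUE)[[1]])
      } else if (grepl(",", val, fixed = TRUE)) {
        parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
        nums <- suppressWarnings(as.numeric(parts))
        val <- if (!anyNA(nums)) nums else parts
      } else if (grepl("^-?[0-9.]+([eE][+-]?[0-9]+)?$", val)) {
        val <- as.numeric(val)
      } else if (val %in% c("true", "false")) {
        val <- val == "true"
      }
      vals[[key]] <- val
    }
  }
  for (nm in names(overrides)) {
    if (!is.null(overrides[[nm]])) vals[[nm]] <- overrides[[nm]]
  }
  defaults <- list(
    input = NULL, format = NULL, outdir = ".", seed = 1,
    g = 10, max_iter = 200, tol = 1e-4, min_df = 2, max_df_fraction = 0.95,
    threshold = 0.9, k = 256, bands = 64, rows = 4, min_tokens = 3,
    top_k = 10, targets = character(0),
    docs_per_topic = 60, vocab_size = 300, vocab_overlap_fraction = 0,
    sentences_per_doc = c(5, 15), tokens_per_sentence = c(8, 18),
    placeholder_rate = 0
  )
  for (nm in names(defaults)) {
    if (is.null(vals[[nm]])) vals[[nm]] <- defaults[[nm]]
  }
  structure(vals, class = "mm_run_config")
}

config_hash <- function(config) {
  # hash the analysis parameters, not file locations, so identical analyses
  # into different directories produce identical outputs
  keys <- setdiff(sort(names(config), method = "radix"), c("outdir", "input"))
  flat <- paste(vapply(keys, function(k) {
    paste0(k, "=", paste(format(config[[k]], digits = 15), collapse = ","))
  }, character(1)), collapse = ";")
  sprintf("%013.0f", cpp_fnv52(flat))
}

output_header <- function(config) {
  sprintf("# methodsminer %s seed=%d config=%s",
          as.character(utils::packageVersion("methodsminer")),
          as.integer(config$seed), config_hash(config))
}

write_report_tsv <- function(df, path, config) {
  writeLines(output_header(config), path, useBytes = TRUE)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

load_input_corpus <- function(config) {
  if (is.null(config$input)) stop_input("config key 'input' is required")
  if (identical(config$format, "xml") ||
      grepl("\\.xml$", config$input, ignore.case = TRUE)) {
    read_anzctr_xml(config$input)
  } else {
    read_corpus(config$input,
                format = config$format %||% c("jsonl", "csv"))
  }
}

outpath <- function(config, file) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$outdir, file)
}

#' Pipeline stage: generate a synthetic corpus
#'
#' Writes `corpus.jsonl`, `truth_documents.tsv` and `truth_sentences.tsv`
#' to the configured output directory.
#'
#' @param config a `mm_run_config`.
#' @return paths of the written files, invisibly.
#' @export
cmd_simulate <- function(config) {
  gc_cfg <- generator_config(
    g = if (is.null(config$g)) 5L else as.integer(config$g),
    vocab_size = as.integer(config$vocab_size),
    vocab_overlap_fraction = config$vocab_overlap_fraction,
    docs_per_topic = as.integer(config$docs_per_topic),
    sentences_per_doc = as.integer(config$sentences_per_doc),
    tokens_per_sentence = as.integer(config$tokens_per_sentence),
    placeholder_rate = config$placeholder_rate,
    seed = as.integer(config$seed)
  )
  sim <- generate_corpus(gc_cfg)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_fixture(sim, config$outdir)
  message(sprintf("simulate: wrote %d documents", nrow(sim$corpus)))
  invisible(paths)
}

#' Pipeline stage: normalize a corpus
#'
#' Reads the input corpus, screens out placeholder sections, normalizes the
#' rest and writes `normalized.jsonl`.
#'
#' @param config a `mm_run_config`.
#' @return path of the normalized file, invisibly.
#' @export
cmd_normalize <- function(config) {
  corp <- load_input_corpus(config)
  parts <- screen_missing(corp)
  norm <- normalize_corpus(parts$present)
  path <- outpath(config, "normalized.jsonl")
  write_normalized(norm, path, header = output_header(config))
  message(sprintf("normalize: %d document(s) in, %d placeholder/missing dropped, %d normalized",
                  nrow(corp), nrow(parts$missing), nrow(norm)))
  invisible(path)
}

topic_word_stats <- function(norm, assignments) {
  joined <- dplyr::left_join(assignments, norm, by = "id")
  joined$n_words <- lengths(joined$tokens)
  joined$n_sentences <- lengths(joined$sentences)
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$topic),
    n_docs = dplyr::n(),
    words_median = stats::median(.data$n_words),
    words_q1 = stats::quantile(.data$n_words, 0.25, type = 7, names = FALSE),
    words_q3 = stats::quantile(.data$n_words, 0.75, type = 7, names = FALSE),
    sentences_median = stats::median(.data$n_sentences),
    sentences_q1 = stats::quantile(.data$n_sentences, 0.25, type = 7, names = FALSE),
    sentences_q3 = stats::quantile(.data$n_sentences, 0.75, type = 7, names = FALSE),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$topic)
}

#' Pipeline stage: topic model
#'
#' Builds the tf-idf matrix, fits NMF, assigns topics and writes
#' `assignments.tsv`, `topic_summary.tsv` (document counts plus word/sentence
#' medians and IQRs per topic) and `top_terms.tsv`.
#'
#' @param config a `mm_run_config`.
#' @return paths of the written files, invisibly.
#' @export
cmd_topics <- function(config) {
  norm <- read_normalized(outpath(config, "normalized.jsonl"))
  g <- as.integer(config$g)
  if (nrow(norm) < g) {
    stop_input("cannot fit %d topics to %d document(s); reduce g", g, nrow(norm))
  }
  tf <- build_tfidf(norm, min_df = as.integer(config$min_df),
                    max_df_fraction = config$max_df_fraction)
  fit <- fit_nmf(tf$P, g = g, seed = as.integer(config$seed),
                 max_iter = as.integer(config$max_iter), tol = config$tol)
  assignments <- assign_topics(fit)
  tops <- dplyr::bind_rows(lapply(seq_len(g), function(t) {
    tt <- top_terms(fit, t, k = as.integer(config$top_k))
    tt$topic <- t
    tt$rank <- seq_len(nrow(tt))
    tt[, c("topic", "rank", "term", "weight")]
  }))
  paths <- c(
    assignments = outpath(config, "assignments.tsv"),
    topic_summary = outpath(config, "topic_summary.tsv"),
    top_terms = outpath(config, "top_terms.tsv")
  )
  write_report_tsv(assignments, paths[["assignments"]], config)
  write_report_tsv(topic_word_stats(norm, assignments),
                   paths[["topic_summary"]], config)
  write_report_tsv(tops, paths[["top_terms"]], config)
  message(sprintf("topics: fit g=%d on %d documents (%d terms), %s",
                  g, nrow(norm), nrow(tf$P),
                  if (fit$converged) "converged" else "max_iter reached"))
  invisible(paths)
}

scan_rollup <- function(matches_section, matches_sentence, assignments) {
  ids_close <- function(m) unique(c(m$query_id, m$target_id))
  ids_exact <- function(m) unique(c(m$query_id[m$is_exact], m$target_id[m$is_exact]))
  per_topic <- function(ids_vec) {
    vapply(split(assignments$id, assignments$topic), function(ids) {
      sum(ids %in% ids_vec)
    }, numeric(1))
  }
  topics <- sort(unique(assignments$topic))
  tibble::tibble(
    topic = topics,
    n_docs = as.integer(table(factor(assignments$topic, levels = topics))),
    section_close = per_topic(ids_close(matches_section)),
    section_exact = per_topic(ids_exact(matches_section)),
    sentence_close = per_topic(ids_close(matches_sentence)),
    sentence_exact = per_topic(ids_exact(matches_sentence))
  )
}

#' Pipeline stage: all-pairs boilerplate scan
#'
#' Runs the LSH-accelerated scan at section and sentence level and writes
#' `matches_section.tsv`, `matches_sentence.tsv` and `scan_rollup.tsv`
#' (per-topic counts of studies with close / exact matches, using
#' `assignments.tsv` when a topic stage has run, otherwise a single
#' all-documents row).
#'
#' @param config a `mm_run_config`.
#' @return paths of the written files, invisibly.
#' @export
cmd_scan <- function(config) {
  norm <- read_normalized(outpath(config, "normalized.jsonl"))
  run_level <- function(level) {
    pairwise_scan(token_sets(norm, level), level = level,
                  threshold = config$threshold, k = as.integer(config$k),
                  b = as.integer(config$bands), r = as.integer(config$rows),
                  seed = as.integer(config$seed),
                  min_tokens = as.integer(config$min_tokens))
  }
  m_section <- run_level("section")
  m_sentence <- run_level("sentence")
  apath <- outpath(config, "assignments.tsv")
  assignments <- if (file.exists(apath)) {
    readr::read_tsv(apath, comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  } else {
    tibble::tibble(id = norm$id, topic = 1L)
  }
  paths <- c(
    matches_section = outpath(config, "matches_section.tsv"),
    matches_sentence = outpath(config, "matches_sentence.tsv"),
    rollup = outpath(config, "scan_rollup.tsv")
  )
  write_report_tsv(m_section, paths[["matches_section"]], config)
  write_report_tsv(m_sentence, paths[["matches_sentence"]], config)
  write_report_tsv(scan_rollup(m_section, m_sentence, assignments),
                   paths[["rollup"]], config)
  message(sprintf("scan: %d section match(es), %d sentence match(es)",
                  nrow(m_section), nrow(m_sentence)))
  invisible(paths)
}

#' Pipeline stage: targeted n-gram searches
#'
#' Runs [targeted_search()] for every configured target phrase (raw text;
#' each is normalized with the default pipeline first) and writes
#' `search_report.tsv` with one row per target: potential matches, best-score
#' median and quartiles, and boilerplate count.
#'
#' @param config a `mm_run_config`.
#' @return path of the report, invisibly (`NULL` with a warning when no
#'   targets are configured).
#' @export
cmd_search <- function(config) {
  targets <- config$targets
  if (length(targets) == 0L) {
    warning("no targets configured; search stage is a no-op")
    return(invisible(NULL))
  }
  norm <- read_normalized(outpath(config, "normalized.jsonl"))
  rows <- lapply(targets, function(tg) {
    toks <- normalize_document("query", tg)$tokens
    res <- targeted_search(norm, toks, threshold = config$threshold)
    tibble::tibble(
      target = res$target,
      potential_matches = res$potential_matches,
      median = res$median, q1 = res$q1, q3 = res$q3,
      boilerplate_count = res$boilerplate_count
    )
  })
  path <- outpath(config, "search_report.tsv")
  write_report_tsv(dplyr::bind_rows(rows), path, config)
  message(sprintf("search: %d target(s)", length(targets)))
  invisible(path)
}

#' Pipeline stage: corpus summary report
#'
#' Word-count statistics and the missing-section split of the raw input
#' corpus, written as `corpus_report.tsv`.
#'
#' @param config a `mm_run_config`.
#' @return path of the report, invisibly.
#' @export
cmd_report <- function(config) {
  corp <- load_input_corpus(config)
  parts <- screen_missing(corp)
  stats_row <- if (nrow(parts$present) > 0L) {
    s <- word_count_stats(parts$present)
    tibble::tibble(
      n_documents = nrow(corp),
      n_present = nrow(parts$present),
      n_missing = nrow(parts$missing),
      words_median = s$median, words_q1 = s$q1, words_q3 = s$q3,
      frac_short = s$frac_short, frac_long = s$frac_long
    )
  } else {
    tibble::tibble(n_documents = nrow(corp), n_present = 0L,
                   n_missing = nrow(parts$missing),
                   words_median = NA_real_, words_q1 = NA_real_,
                   words_q3 = NA_real_, frac_short = NA_real_,
                   frac_long = NA_real_)
  }
  path <- outpath(config, "corpus_report.tsv")
  write_report_tsv(stats_row, path, config)
  message(sprintf("report: %d document(s), %d with a present section",
                  nrow(corp), nrow(parts$present)))
  invisible(path)
}

#' Run the full pipeline
#'
#' simulate (optional) -> normalize -> topics -> scan -> search (if targets
#' are configured) -> report, all into `config$outdir`.
#'
#' @param config a `mm_run_config`.
#' @param simulate generate the input corpus first (sets `input` to the
#'   simulated `corpus.jsonl`).
#' @return the config, invisibly.
#' @export
run_pipeline <- function(config, simulate = FALSE) {
  if (simulate) {
    cmd_simulate(config)
    config$input <- outpath(config, "corpus.jsonl")
    config$format <- "jsonl"
  }
  cmd_normalize(config)
  cmd_topics(config)
  cmd_scan(config)
  if (length(config$targets) > 0L) cmd_search(config)
  cmd_report(config)
  invisible(config)
}
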