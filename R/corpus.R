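#' Construct a methods-section corpus
#'
#' A corpus is a tibble with one row per study and a stable row order.
#' Required columns are `id` and `text`; `source` is one of `"plos"`,
#' `"anzctr"` or `"synthetic"` (defaulting to `"synthetic"` when a record
#' omits it). Optional metadata: `heading`, `date` (ISO string),
#' `study_type` (`"interventional"`, `"observational"` or `"unknown"`),
#' `sample_size` (positive), `n_funders` (non-negative).
#'
#' @param id character vector of unique, non-empty study identifiers
#'   (DOIs or registry numbers).
#' @param text character vector of raw section text.
#' @param source,heading,date,study_type,sample_size,n_funders optional
#'   metadata vectors, recycled if length 1.
#' @param provenance free-text label describing where the corpus came from.
#' @return A `mm_corpus` tibble.
#' @export
#' @examples
#' corpus(id = c("d1", "d2"), text = c("ANOVA was used.", "Nil"))
corpus <- function(id, text, source = "synthetic", heading = "",
                   date = NA_character_, study_type = "unknown",
                   sample_size = NA_real_, n_funders = NA_real_,
                   provenance = "in-memory") {
  n <- length(id)
  out <- tibble::tibble(
    id = as.character(id),
    source = rep_len(as.character(source), n),
    heading = rep_len(as.character(heading), n),
    text = as.character(text),
    date = rep_len(as.character(date), n),
    study_type = rep_len(as.character(study_type), n),
    sample_size = rep_len(as.numeric(sample_size), n),
    n_funders = rep_len(as.numeric(n_funders), n)
  )
  validate_corpus(out)
  attr(out, "provenance") <- provenance
  class(out) <- c("mm_corpus", class(tibble::tibble()))
  out
}

validate_corpus <- function(x) {
  if (any(!nzchar(x$id) | is.na(x$id))) {
    stop_input("corpus ids must be non-empty")
  }
  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0L) {
    stop_input("duplicate document id(s): %s",
               paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(x$source), c("plos", "anzctr", "synthetic"))
  if (length(bad) > 0L) {
    stop_input("unknown source value(s): %s", paste(bad, collapse = ", "))
  }
  st <- setdiff(unique(x$study_type),
                c("interventional", "observational", "unknown", NA_character_))
  if (length(st) > 0L) {
    stop_input("unknown study_type value(s): %s", paste(st, collapse = ", "))
  }
  if (any(!is.na(x$sample_size) & x$sample_size <= 0)) {
    stop_input("sample_size must be positive where present")
  }
  if (any(!is.na(x$n_funders) & x$n_funders < 0)) {
    stop_input("n_funders must be non-negative where present")
  }
  invisible(x)
}

#' @export
print.mm_corpus <- function(x, ...) {
  cat(sprintf("<mm_corpus> %d document(s); provenance: %s\n",
              nrow(x), attr(x, "provenance") %||% "unknown"))
  NextMethod()
}

corpus_from_fields <- function(fields, provenance) {
  corpus(
    id = fields$id, text = fields$text,
    source = fields$source, heading = fields$heading, date = fields$date,
    study_type = fields$study_type, sample_size = fields$sample_size,
    n_funders = fields$n_funders, provenance = provenance
  )
}

#' Read a corpus from JSONL or CSV
#'
#' JSONL files hold one JSON object per line with keys `id`, `source`,
#' `heading`, `text`, `date`, `study_type`, `sample_size`, `n_funders`
#' (metadata keys optional, unknown keys ignored). CSV files use the same
#' columns with a mandatory header row. Records must at minimum carry `id`
#' and `text`; ids must be unique.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension when
#'   missing.
#' @return A `mm_corpus` tibble.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  if (length(format) > 1L) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  format <- match.arg(format, c("jsonl", "csv"))
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (format == "jsonl") read_corpus_jsonl(path) else read_corpus_csv(path)
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(corpus(id = character(0), text = character(0),
                  provenance = paste0("jsonl:", path)))
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$id) || is.null(rec$text)) {
      stop_input("malformed JSONL record at line %d of %s", i, path)
    }
    recs[[i]] <- rec
  }
  fields <- list(
    id = vapply(recs, function(r) scalar_chr(r$id), character(1)),
    text = vapply(recs, function(r) scalar_chr(r$text), character(1)),
    source = vapply(recs, function(r) r$source %||% "synthetic", character(1)),
    heading = vapply(recs, function(r) scalar_chr(r$heading) %||% "", character(1)),
    date = vapply(recs, function(r) scalar_chr(r$date), character(1)),
    study_type = vapply(recs, function(r) r$study_type %||% "unknown", character(1)),
    sample_size = vapply(recs, function(r) scalar_num(r$sample_size), numeric(1)),
    n_funders = vapply(recs, function(r) scalar_num(r$n_funders), numeric(1))
  )
  fields$heading[is.na(fields$heading)] <- ""
  corpus_from_fields(fields, paste0("jsonl:", path))
}

read_corpus_csv <- function(path) {
  df <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) stop_input("malformed CSV in %s: %s", path, conditionMessage(e))
  )
  if (!all(c("id", "text") %in% names(df))) {
    stop_input("CSV %s must have header columns 'id' and 'text'", path)
  }
  get_col <- function(nm, default) {
    if (nm %in% names(df)) {
      v <- df[[nm]]
      v[is.na(v)] <- default
      v
    } else rep(default, nrow(df))
  }
  fields <- list(
    id = df$id,
    text = ifelse(is.na(df$text), "", df$text),
    source = get_col("source", "synthetic"),
    heading = get_col("heading", ""),
    date = if ("date" %in% names(df)) df$date else rep(NA_character_, nrow(df)),
    study_type = get_col("study_type", "unknown"),
    sample_size = suppressWarnings(as.numeric(get_col("sample_size", NA_character_))),
    n_funders = suppressWarnings(as.numeric(get_col("n_funders", NA_character_)))
  )
  corpus_from_fields(fields, paste0("csv:", path))
}

#' Write a corpus to JSONL
#'
#' One JSON object per line; metadata fields that are `NA` are omitted so the
#' file round-trips bit-exactly through [read_corpus()].
#'
#' @param x a `mm_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    rec <- list(id = x$id[i], source = x$source[i], heading = x$heading[i],
                text = x$text[i])
    if (!is.na(x$date[i])) rec$date <- x$date[i]
    if (!is.na(x$study_type[i]) && x$study_type[i] != "unknown") {
      rec$study_type <- x$study_type[i]
    }
    if (!is.na(x$sample_size[i])) rec$sample_size <- x$sample_size[i]
    if (!is.na(x$n_funders[i])) rec$n_funders <- x$n_funders[i]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a minimal registry-style XML corpus
#'
#' Reads records shaped like
#' `<studies><study><id>...</id><statistical_methods>...</statistical_methods>
#' <study_type>...</study_type>...</study></studies>`, the minimal slice of a
#' clinical-trials-registry export that this pipeline consumes. A study whose
#' `statistical_methods` element is absent yields a document with empty text.
#'
#' @param path XML file path.
#' @return A `mm_corpus` with `source = "anzctr"`.
#' @export
read_anzctr_xml <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_input("not well-formed XML: %s", path))
  studies <- xml2::xml_find_all(doc, ".//study")
  get_el <- function(node, el) {
    hit <- xml2::xml_find_first(node, el)
    if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
  }
  id <- vapply(studies, get_el, character(1), el = "id")
  txt <- vapply(studies, get_el, character(1), el = "statistical_methods")
  txt[is.na(txt)] <- ""
  st <- vapply(studies, get_el, character(1), el = "study_type")
  st <- ifelse(is.na(st) | !st %in% c("interventional", "observational"),
               "unknown", st)
  date <- vapply(studies, get_el, character(1), el = "date")
  ss <- suppressWarnings(as.numeric(vapply(studies, get_el, character(1),
                                           el = "target_sample_size")))
  nf <- suppressWarnings(as.numeric(vapply(studies, get_el, character(1),
                                           el = "n_funders")))
  corpus(id = id, text = txt, source = "anzctr", study_type = st,
         date = date, sample_size = ss, n_funders = nf,
         provenance = paste0("xml:", path))
}

# Headings that mark a statistical-methods section. Matching is partial:
# case-insensitive substring containment after trimming.
SECTION_HEADING_TERMS <- c(
  "statistical analysis", "statistical analyses", "statistical method",
  "statistical methods", "statistics", "data analysis", "data analyses"
)

#' Does a section heading denote a statistical-methods section?
#'
#' Case-insensitive partial match of the heading against the frequently used
#' terms "statistical analysis/analyses", "statistical method(s)",
#' "statistics" and "data analysis/analyses".
#'
#' @param heading character vector of headings.
#' @param terms heading terms to match against (lowercase).
#' @return logical vector.
#' @export
#' @examples
#' match_section_heading(c("Statistical analysis", "Microarray analysis"))
match_section_heading <- function(heading, terms = SECTION_HEADING_TERMS) {
  h <- tolower(trimws(heading))
  vapply(h, function(x) {
    nzchar(x) && any(vapply(terms, grepl, logical(1), x = x, fixed = TRUE))
  }, logical(1), USE.NAMES = FALSE)
}

#' Split a corpus into present and missing sections
#'
#' A section counts as missing when its text, lower-cased and trimmed, equals
#' one of the placeholder strings registries accept in lieu of a description
#' ("Not applicable", "Nil", "None", ...), or is empty.
#'
#' @param x a `mm_corpus`.
#' @param placeholders lowercase placeholder strings.
#' @return list with `mm_corpus` elements `present` and `missing`
#'   (a partition of `x`).
#' @export
screen_missing <- function(x,
                           placeholders = c("not applicable", "nil", "none",
                                            "n/a", "")) {
  if (length(placeholders) == 0L) stop_input("placeholders must be non-empty")
  is_missing <- tolower(trimws(x$text)) %in% tolower(placeholders)
  split_part <- function(keep) {
    out <- x[keep, , drop = FALSE]
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- class(x)
    out
  }
  list(present = split_part(!is_missing), missing = split_part(is_missing))
}

count_words <- function(text) {
  t <- trimws(text)
  ifelse(nzchar(t), lengths(strsplit(t, "\\s+")), 0L)
}

#' Word-count summary of a corpus
#'
#' Whitespace-delimited word counts of the raw text, summarized by median and
#' inter-quartile range (type-7 quantiles) plus the fractions of short
#' (`<= lower`) and long (`>= upper`) sections.
#'
#' @param x a `mm_corpus` (non-empty).
#' @param lower,upper word-count cutoffs for the short/long fractions.
#' @return list with `n`, `median`, `q1`, `q3`, `frac_short`, `frac_long`
#'   and the per-document `counts`.
#' @export
word_count_stats <- function(x, lower = 50, upper = 500) {
  if (nrow(x) == 0L) stop_input("corpus is empty")
  counts <- count_words(x$text)
  q <- stats::quantile(counts, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(
    n = length(counts),
    median = q[2], q1 = q[1], q3 = q[3],
    frac_short = mean(counts <= lower),
    frac_long = mean(counts >= upper),
    counts = counts
  )
}
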